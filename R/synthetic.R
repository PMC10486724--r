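#' Parameters of a synthetic AFM scene
#'
#' Defines everything needed to render a seeded synthetic neutrophil
#' topography with known ground truth: the scan geometry, a spherical-cap or
#' spread cell body with optional nuclear-lobe bumps, band-limited spongiform
#' membrane roughness in the two analysis bands, a halo of shed cell
#' fragments with a unimodal or bimodal size mixture, NET granule chains, and
#' substrate noise. Defaults describe a 5 x 5 um membrane patch of a resting
#' cell surface (512 points, first-order roughness of period 1000 nm and
#' amplitude 40 nm, second-order 150 nm / 2.3 nm, 1 nm substrate noise).
#'
#' @param grid_points Scan points per line (>= 64); AFM scans here use 512 or
#'   1024.
#' @param field_size_nm Physical side length of the square field (nm); 5000
#'   for membrane patches, 30000-100000 for whole-cell scenes.
#' @param cell_height_nm Maximum cell height (nm); 0 renders no cell body.
#' @param cell_diameter_nm Basal cell diameter (nm).
#' @param n_lobes Number of nuclear-lobe bumps, 0-4.
#' @param lobe_height_nm Height of each lobe bump (nm).
#' @param band1_period_nm,band1_amplitude_nm First-order (600-1200 nm window)
#'   roughness period and amplitude; amplitude 0 disables the band.
#' @param band2_period_nm,band2_amplitude_nm Second-order (50-300 nm window)
#'   roughness period and amplitude.
#' @param n_fragments Number of halo fragments to scatter.
#' @param fragment_size_mixture List of mixture components, each
#'   `list(weight, mean_nm, sd_nm)`; weights must sum to 1.
#' @param fragment_height_mean_nm Mean fragment bump height (nm).
#' @param granule_size_mean_nm,granule_size_sd_nm NET granule size
#'   distribution (nm).
#' @param n_granule_chains Number of granule chains in the NET mesh; 0
#'   disables the mesh.
#' @param substrate_noise_sd_nm Gaussian substrate noise SD (nm).
#' @param seed Integer seed; one named RNG sub-stream is derived per
#'   component, so scenes are bit-reproducible.
#' @param spread_exponent Super-Gaussian exponent of the cell cap; larger
#'   values flatten the top (spread cells), smaller keep it domed.
#' @param lobe_sd_nm Gaussian width of a lobe bump (nm).
#'
#' @return An object of class `scene_params` (a validated named list).
#' @export
scene_params <- function(grid_points = 512L,
                         field_size_nm = 5000,
                         cell_height_nm = 0,
                         cell_diameter_nm = 9800,
                         n_lobes = 0L,
                         lobe_height_nm = 200,
                         band1_period_nm = 1000,
                         band1_amplitude_nm = 40,
                         band2_period_nm = 150,
                         band2_amplitude_nm = 2.3,
                         n_fragments = 0L,
                         fragment_size_mixture = list(list(weight = 1, mean_nm = 330, sd_nm = 150)),
                         fragment_height_mean_nm = 16,
                         granule_size_mean_nm = 50,
                         granule_size_sd_nm = 20,
                         n_granule_chains = 0L,
                         substrate_noise_sd_nm = 1,
                         seed = 1L,
                         spread_exponent = 3,
                         lobe_sd_nm = 700) {
  p <- list(grid_points = as.integer(grid_points), field_size_nm = field_size_nm,
            cell_height_nm = cell_height_nm, cell_diameter_nm = cell_diameter_nm,
            n_lobes = as.integer(n_lobes), lobe_height_nm = lobe_height_nm,
            band1_period_nm = band1_period_nm, band1_amplitude_nm = band1_amplitude_nm,
            band2_period_nm = band2_period_nm, band2_amplitude_nm = band2_amplitude_nm,
            n_fragments = as.integer(n_fragments),
            fragment_size_mixture = fragment_size_mixture,
            fragment_height_mean_nm = fragment_height_mean_nm,
            granule_size_mean_nm = granule_size_mean_nm,
            granule_size_sd_nm = granule_size_sd_nm,
            n_granule_chains = as.integer(n_granule_chains),
            substrate_noise_sd_nm = substrate_noise_sd_nm,
            seed = as.integer(seed),
            spread_exponent = spread_exponent, lobe_sd_nm = lobe_sd_nm)
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (p$grid_points < 64) {
    afm_abort("grid_points must be >= 64.", "afmtopo_invalid_parameter")
  }
  lens <- c(p$field_size_nm, p$cell_diameter_nm, p$band1_period_nm,
            p$band2_period_nm, p$granule_size_mean_nm, p$lobe_sd_nm)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    afm_abort("All lengths must be positive.", "afmtopo_invalid_parameter")
  }
  if (p$cell_height_nm < 0 || p$substrate_noise_sd_nm < 0 ||
      p$band1_amplitude_nm < 0 || p$band2_amplitude_nm < 0) {
    afm_abort("Heights, amplitudes and noise SD must be non-negative.",
              "afmtopo_invalid_parameter")
  }
  if (p$n_lobes < 0 || p$n_lobes > 4) {
    afm_abort("n_lobes must be between 0 and 4.", "afmtopo_invalid_parameter")
  }
  w <- vapply(p$fragment_size_mixture, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) {
    afm_abort("Fragment mixture weights must sum to 1.",
              "afmtopo_invalid_parameter")
  }
  if (p$band1_amplitude_nm > 0 &&
      (p$band1_period_nm < 600 || p$band1_period_nm > 1200)) {
    afm_abort("band1_period_nm must lie in the first-order window [600, 1200] nm.",
              "afmtopo_invalid_parameter")
  }
  if (p$band2_amplitude_nm > 0 &&
      (p$band2_period_nm < 50 || p$band2_period_nm > 300)) {
    afm_abort("band2_period_nm must lie in the second-order window [50, 300] nm.",
              "afmtopo_invalid_parameter")
  }
  invisible(p)
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("<scene_params> %d px over %g nm (%.3g nm/px), seed %d\n",
              x$grid_points, x$field_size_nm,
              x$field_size_nm / x$grid_points, x$seed))
  cat(sprintf("  cell: h %g nm, d %g nm, %d lobes | bands: %g/%g nm, %g/%g nm\n",
              x$cell_height_nm, x$cell_diameter_nm, x$n_lobes,
              x$band1_period_nm, x$band1_amplitude_nm,
              x$band2_period_nm, x$band2_amplitude_nm))
  cat(sprintf("  fragments: %d | granule chains: %d | noise %g nm\n",
              x$n_fragments, x$n_granule_chains, x$substrate_noise_sd_nm))
  invisible(x)
}

# ---- component generators ----

#' Band-limited spongiform roughness field
#'
#' Seeded white noise is shaped in the 2-D frequency domain: modes whose
#' dominant wavevector component lies within 20% of `1/period_nm` (with a
#' Gaussian envelope of width 8% of the center frequency, applied around both
#' lattice axes so the texture has no preferred direction) are retained, and
#' the field is rescaled so that the peak of the row-averaged 1-D profile
#' spectrum equals `amplitude_nm^2`. Shaping the dominant *component* rather
#' than the radial magnitude keeps the 1-D profile spectra - the quantity the
#' analysis pipeline measures - peaked at `1/period_nm` instead of smearing
#' them toward lower frequencies, so the generated patch reads back its own
#' period and amplitude. This emulates the quasi-periodic "spongiform"
#' membrane roughness at a controlled amplitude and period.
#'
#' @param grid_points Points per side.
#' @param field_size_nm Physical side length (nm).
#' @param period_nm Center spatial period of the roughness (nm); must be
#'   Nyquist-representable (`2 * pixel < period < field/2`).
#' @param amplitude_nm Target roughness amplitude (nm); 0 returns a flat field.
#' @param seed Integer RNG seed; the field is deterministic given the seed.
#' @return A zero-mean [heightmap()].
#' @export
make_roughness_field <- function(grid_points, field_size_nm, period_nm,
                                 amplitude_nm, seed) {
  n <- as.integer(grid_points)
  px <- field_size_nm / n
  if (amplitude_nm == 0) {
    return(heightmap(matrix(0, n, n), px))
  }
  if (period_nm <= 2 * px || period_nm >= field_size_nm / 2) {
    afm_abort(sprintf(
      "period %g nm not representable on this grid (need %g < period < %g nm).",
      period_nm, 2 * px, field_size_nm / 2), "afmtopo_invalid_parameter")
  }
  nu0 <- 1 / period_nm
  kf <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * px)
  fx <- matrix(abs(kf), n, n, byrow = TRUE)
  fy <- matrix(abs(kf), n, n, byrow = FALSE)
  env <- function(f) exp(-(f - nu0)^2 / (2 * (0.08 * nu0)^2))
  wx <- env(fx) * (abs(fx - nu0) <= 0.2 * nu0) * (fy <= 1.2 * nu0)
  wy <- env(fy) * (abs(fy - nu0) <= 0.2 * nu0) * (fx <= 1.2 * nu0)
  w <- pmax(wx, wy)
  if (!any(w > 0)) {
    afm_abort("No representable frequencies in the roughness band.",
              "afmtopo_invalid_parameter")
  }
  g <- with_local_seed(seed, {
    noise <- matrix(stats::rnorm(n * n), n, n)
    co <- stats::fft(noise) * w
    Re(stats::fft(co, inverse = TRUE)) / (n * n)
  })
  g <- g - mean(g)
  # calibrate: in-band peak of the row-averaged profile spectrum == amplitude^2
  smat <- apply(g, 1, function(r) profile_spectrum(r, px)$S_nm2)
  sbar <- rowMeans(smat)
  nus <- seq_along(sbar) / (n * px)
  in_band <- nus >= 0.8 * nu0 & nus <= 1.2 * nu0
  peak <- max(sbar[in_band])
  g <- g * (amplitude_nm / sqrt(peak))
  heightmap(g, px)
}

# Super-Gaussian cap, height H, basal diameter D. The edge height at
# r = D/2 sits just below the 20 nm segmentation floor, so the thresholded
# footprint diameter matches the nominal diameter to well under a pixel.
cell_cap <- function(r, H, D, p) {
  edge <- min(18, H / 10)
  H * exp(-log(H / max(edge, 1e-6)) * pmin((2 * r / D)^(2 * p), 50))
}

lobe_ring_radius <- function(D) 0.22 * D

#' Synthetic cell body
#'
#' Renders a smooth super-Gaussian cap of the requested maximum height and
#' basal diameter, with `n_lobes` Gaussian bumps emulating nuclear lobes
#' placed inside the cap (a single lobe sits at the apex; several sit on a
#' ring, with a shallow central depression so each lobe is a distinct summit).
#' The field is rescaled so its maximum equals `cell_height_nm` exactly.
#'
#' @param params A [scene_params()].
#' @return A [heightmap()] of the noise-free cell body.
#' @export
make_cell_body <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$grid_points
  px <- params$field_size_nm / n
  H <- params$cell_height_nm
  D <- params$cell_diameter_nm
  if (H == 0) return(heightmap(matrix(0, n, n), px))
  if (D > 0.9 * params$field_size_nm) {
    afm_abort("Cell does not fit in the field with a 10% margin.",
              "afmtopo_invalid_parameter")
  }
  ctr <- params$field_size_nm / 2
  g <- coord_grids(n, n, px)
  r <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  body <- cell_cap(r, H, D, params$spread_exponent)
  k <- params$n_lobes
  if (k >= 1) {
    L <- params$lobe_height_nm
    sig <- params$lobe_sd_nm
    if (k == 1) {
      pos <- matrix(c(ctr, ctr), 1)
    } else {
      rho <- lobe_ring_radius(D)
      ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 7
      pos <- cbind(ctr + rho * cos(ang), ctr + rho * sin(ang))
      # carve the cap apex so the ring lobes are the only summits
      body <- body - 0.35 * L * exp(-r^2 / (2 * (0.8 * rho)^2))
    }
    for (i in seq_len(nrow(pos))) {
      d2 <- (g$x - pos[i, 1])^2 + (g$y - pos[i, 2])^2
      body <- body + L * exp(-d2 / (2 * sig^2))
    }
  }
  body[body < 0] <- 0
  body <- body * (H / max(body))
  heightmap(body, px)
}

# Draw (size, height) pairs for fragments. Sizes come from the mixture
# truncated to positive values; heights are normal with SD 25% of the mean,
# floored just above the 10 nm detection floor. Pairs whose above-floor
# paraboloid cross-section would cover fewer than ~8 pixels are redrawn (up
# to 50 times) so that, at fragment-section resolution, every planted
# fragment is recoverable by the detector; at coarse whole-cell resolution
# the cap disengages the rule and fragments are planted as scenery.
draw_fragments <- function(n, mixture, height_mean_nm, px_nm, floor_nm = 10) {
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  size <- numeric(n); height <- numeric(n)
  for (i in seq_len(n)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      ci <- sample.int(length(mixture), 1, prob = w)
      m <- mixture[[ci]]
      s <- stats::rnorm(1, m$mean_nm, m$sd_nm)
      h <- max(floor_nm + 4, stats::rnorm(1, height_mean_nm, 0.25 * height_mean_nm))
      if (s > 0) {
        area_px <- pi * (s / 2 * sqrt(1 - floor_nm / h))^2 / px_nm^2
        if (area_px >= 8 || tries >= 50L) break
      }
    }
    size[i] <- s; height[i] <- h
  }
  list(size = size, height = height)
}

#' Scatter halo fragments around a cell
#'
#' Plants `n_fragments` paraboloid bumps with equivalent diameters drawn from
#' the configured size mixture (truncated to positive values) and heights
#' normal around `fragment_height_mean_nm`. Fragments are placed by rejection
#' sampling so that they overlap neither each other nor the exclusion
#' footprint, and size-height pairs below the detector's resolution at the
#' scene's pixel size are redrawn, so every planted fragment is recoverable
#' at fragment-section resolution. The returned truth list matches the
#' rendered bumps one-to-one.
#'
#' @param params A [scene_params()].
#' @param exclusion_footprint Optional logical matrix (cell footprint) that
#'   fragments must avoid.
#' @param seed RNG seed (defaults to the scene's fragment sub-stream).
#' @return A list: `map` (a [heightmap()] of the fragment field) and
#'   `fragments` (tibble `center_x_nm`, `center_y_nm`, `diameter_nm`,
#'   `height_nm`).
#' @export
scatter_fragments <- function(params, exclusion_footprint = NULL,
                              seed = component_seed(params$seed, "fragments")) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$grid_points
  px <- params$field_size_nm / n
  nfrag <- params$n_fragments
  field <- matrix(0, n, n)
  truth <- tibble::tibble(center_x_nm = numeric(0), center_y_nm = numeric(0),
                          diameter_nm = numeric(0), height_nm = numeric(0))
  if (nfrag == 0) {
    return(list(map = heightmap(field, px), fragments = truth))
  }
  res <- with_local_seed(seed, {
    drawn <- draw_fragments(nfrag, params$fragment_size_mixture,
                            params$fragment_height_mean_nm, px)
    sizes <- drawn$size
    heights <- drawn$height
    centers <- matrix(NA_real_, nfrag, 2)
    placed <- 0L
    attempts <- 0L
    g <- coord_grids(n, n, px)
    while (placed < nfrag && attempts < 10 * nfrag) {
      attempts <- attempts + 1L
      i <- placed + 1L
      rad <- sizes[i] / 2
      cx <- stats::runif(1, rad + px, params$field_size_nm - rad - px)
      cy <- stats::runif(1, rad + px, params$field_size_nm - rad - px)
      ok <- TRUE
      if (placed > 0) {
        dd <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                   (centers[seq_len(placed), 2] - cy)^2)
        ok <- all(dd > (sizes[seq_len(placed)] / 2 + rad + 3 * px))
      }
      if (ok && !is.null(exclusion_footprint)) {
        near <- (g$x - cx)^2 + (g$y - cy)^2 <= (rad + 2 * px)^2
        ok <- !any(exclusion_footprint & near)
      }
      if (ok) {
        centers[i, ] <- c(cx, cy)
        placed <- i
      }
    }
    list(sizes = sizes, heights = heights, centers = centers, placed = placed)
  })
  if (res$placed < nfrag) {
    afm_abort(sprintf("Could only place %d of %d fragments in %d attempts.",
                      res$placed, nfrag, 10 * nfrag),
              "afmtopo_placement_error", placed = res$placed)
  }
  for (i in seq_len(nfrag)) {
    field <- add_bump(field, px, res$centers[i, 1], res$centers[i, 2],
                      radius_nm = res$sizes[i] / 2, height_nm = res$heights[i],
                      shape = "paraboloid")
  }
  truth <- tibble::tibble(center_x_nm = res$centers[, 1],
                          center_y_nm = res$centers[, 2],
                          diameter_nm = res$sizes, height_nm = res$heights)
  list(map = heightmap(field, px), fragments = truth)
}

#' Synthetic NET granule mesh
#'
#' Renders chains of small bumps along random-walk paths: granules within a
#' chain overlap in sequence (beads on a filament) while different chains are
#' laid down independently. Granule sizes are drawn from the configured normal
#' distribution; granules must be resolvable (mean size > 2 pixels, so mesh
#' scenes are generated at <= 3 nm/pixel for 30-50 nm granules).
#'
#' @param params A [scene_params()].
#' @param seed RNG seed (defaults to the scene's mesh sub-stream).
#' @param granules_per_chain Number of granules in each chain.
#' @return A list: `map` (a [heightmap()]) and `granules` (tibble
#'   `center_x_nm`, `center_y_nm`, `size_nm`, `height_nm`, `chain`).
#' @export
make_net_mesh <- function(params, seed = component_seed(params$seed, "mesh"),
                          granules_per_chain = 20L) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$grid_points
  px <- params$field_size_nm / n
  field <- matrix(0, n, n)
  truth <- tibble::tibble(center_x_nm = numeric(0), center_y_nm = numeric(0),
                          size_nm = numeric(0), height_nm = numeric(0),
                          chain = integer(0))
  if (params$n_granule_chains == 0) {
    return(list(map = heightmap(field, px), granules = truth))
  }
  if (params$granule_size_mean_nm <= 2 * px) {
    afm_abort(sprintf(
      "Granules of mean size %g nm are below the resolvable size at %g nm/pixel.",
      params$granule_size_mean_nm, px), "afmtopo_invalid_parameter")
  }
  fs <- params$field_size_nm
  out <- with_local_seed(seed, {
    rows <- list()
    for (ch in seq_len(params$n_granule_chains)) {
      x <- stats::runif(1, 0.1 * fs, 0.9 * fs)
      y <- stats::runif(1, 0.1 * fs, 0.9 * fs)
      ang <- stats::runif(1, 0, 2 * pi)
      for (gi in seq_len(granules_per_chain)) {
        size <- max(2.5 * px, stats::rnorm(1, params$granule_size_mean_nm,
                                           params$granule_size_sd_nm))
        rows[[length(rows) + 1L]] <- c(x, y, size, 0.5 * size, ch)
        ang <- ang + stats::rnorm(1, 0, 0.45)
        x <- x + 0.75 * size * cos(ang)
        y <- y + 0.75 * size * sin(ang)
        if (x < 0.05 * fs || x > 0.95 * fs) { ang <- pi - ang; x <- pmin(pmax(x, 0.05 * fs), 0.95 * fs) }
        if (y < 0.05 * fs || y > 0.95 * fs) { ang <- -ang; y <- pmin(pmax(y, 0.05 * fs), 0.95 * fs) }
      }
    }
    do.call(rbind, rows)
  })
  for (i in seq_len(nrow(out))) {
    # beads overlap in sequence; take the envelope
    field <- add_bump(field, px, out[i, 1], out[i, 2],
                      radius_nm = out[i, 3], height_nm = out[i, 4],
                      shape = "gaussian", combine = "max")
  }
  truth <- tibble::tibble(center_x_nm = out[, 1], center_y_nm = out[, 2],
                          size_nm = out[, 3], height_nm = out[, 4],
                          chain = as.integer(out[, 5]))
  list(map = heightmap(field, px), granules = truth)
}

# Render a single bump into `field`, touching only a local pixel window.
# Gaussian bumps use sd = radius/4 and a 1.25*radius support window.
add_bump <- function(field, px, cx, cy, radius_nm, height_nm,
                     shape = c("paraboloid", "gaussian"),
                     combine = c("add", "max")) {
  shape <- match.arg(shape)
  combine <- match.arg(combine)
  n <- nrow(field)
  w_nm <- if (shape == "paraboloid") radius_nm else 1.25 * radius_nm
  j0 <- max(1L, floor((cx - w_nm) / px) + 1L)
  j1 <- min(n, ceiling((cx + w_nm) / px) + 1L)
  i0 <- max(1L, floor((cy - w_nm) / px) + 1L)
  i1 <- min(n, ceiling((cy + w_nm) / px) + 1L)
  if (j1 < j0 || i1 < i0) return(field)
  xs <- (seq.int(j0, j1) - 1) * px
  ys <- (seq.int(i0, i1) - 1) * px
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  bump <- if (shape == "paraboloid") {
    pmax(height_nm * (1 - d2 / radius_nm^2), 0)
  } else {
    height_nm * exp(-d2 / (2 * (radius_nm / 4)^2))
  }
  blk <- field[i0:i1, j0:j1]
  field[i0:i1, j0:j1] <- if (combine == "add") blk + bump else pmax(blk, bump)
  field
}

# Rule table shared by the scene truth and the classifier target.
type_from_params <- function(params) {
  if (params$n_granule_chains > 0 || params$cell_height_nm < 150) return("4")
  if (params$cell_height_nm >= 900) {
    if (params$cell_diameter_nm <= 12000) return("1") else return("other")
  }
  if (params$n_lobes >= 2) return("2")
  "3"
}

#' Compose a full synthetic AFM scene
#'
#' Sums substrate noise, the cell body, band-limited membrane roughness
#' (confined to the cell footprint and tapered with the cap profile), halo
#' fragments outside the footprint, and optionally a NET granule mesh. The
#' returned ground truth records every planted quantity plus the cell-type
#' label assigned from the parameters by the same rule table the classifier
#' targets; identical parameters (including seed) give bit-identical scenes.
#'
#' @param params A [scene_params()].
#' @return A list of class `afm_scene`: `map` ([heightmap()]), `truth`
#'   (class `ground_truth`), and `components` (named list of the component
#'   height matrices; the scene is their pixel-wise sum).
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$grid_points
  px <- params$field_size_nm / n
  comps <- list()

  comps$noise <- if (params$substrate_noise_sd_nm > 0) {
    with_local_seed(component_seed(params$seed, "noise"),
                    matrix(stats::rnorm(n * n, 0, params$substrate_noise_sd_nm), n, n))
  } else matrix(0, n, n)

  body <- make_cell_body(params)
  comps$cell <- body$heights

  weight <- if (params$cell_height_nm > 0) {
    comps$cell / max(comps$cell)
  } else matrix(1, n, n)
  rough <- matrix(0, n, n)
  if (params$band1_amplitude_nm > 0) {
    rough <- rough + make_roughness_field(n, params$field_size_nm,
                                          params$band1_period_nm,
                                          params$band1_amplitude_nm,
                                          component_seed(params$seed, "band1"))$heights
  }
  if (params$band2_amplitude_nm > 0) {
    rough <- rough + make_roughness_field(n, params$field_size_nm,
                                          params$band2_period_nm,
                                          params$band2_amplitude_nm,
                                          component_seed(params$seed, "band2"))$heights
  }
  comps$roughness <- rough * weight
  if (params$cell_height_nm > 0) {
    # the advertised cell height is that of the rough membrane surface:
    # rescale body + membrane roughness jointly so the scene apex matches
    cellpart <- comps$cell + comps$roughness
    sc <- params$cell_height_nm / max(cellpart)
    comps$cell <- comps$cell * sc
    comps$roughness <- comps$roughness * sc
  }

  footprint <- if (params$cell_height_nm > 0) {
    ctr <- params$field_size_nm / 2
    g <- coord_grids(n, n, px)
    sqrt((g$x - ctr)^2 + (g$y - ctr)^2) <= params$cell_diameter_nm / 2
  } else matrix(FALSE, n, n)

  frag <- scatter_fragments(params, exclusion_footprint = footprint)
  comps$fragments <- frag$map$heights

  mesh <- make_net_mesh(params)
  comps$mesh <- mesh$map$heights

  total <- Reduce(`+`, comps)
  map <- heightmap(total, px,
                   metadata = list(generator = "afmtopo-synthetic",
                                   seed = params$seed))
  truth <- structure(list(
    true_cell_height_nm = params$cell_height_nm,
    true_diameter_nm = params$cell_diameter_nm,
    true_n_lobes = params$n_lobes,
    true_type = type_from_params(params),
    band_periods_nm = c(band1 = params$band1_period_nm,
                        band2 = params$band2_period_nm),
    band_amplitudes_nm = c(band1 = params$band1_amplitude_nm,
                           band2 = params$band2_amplitude_nm),
    fragments = frag$fragments,
    granules = mesh$granules,
    mesh_present = params$n_granule_chains > 0,
    seed = params$seed
  ), class = "ground_truth")
  structure(list(map = map, truth = truth, components = comps),
            class = "afm_scene")
}

#' Preset scene parameters for the four activation stages
#'
#' Presets are calibrated to the measured morphometrics and roughness of each
#' activation stage: `"control"` (type 1: tall spherical cell, 1.2 um high,
#' 9.8 um across, first-order roughness amplitude 40 nm giving S about
#' 1600 nm^2), `"spread"` (type 2: 0.638 um high, 1.7x wider, 3 nuclear
#' lobes, roughness amplitude 21 nm, a 26-fragment halo of mean size 330 nm),
#' `"flat"` (type 3: 0.3 um, lost nuclear segmentation, roughness amplitude
#' 4 nm, a denser 40-fragment halo), `"netosis"` (type 4: no intact body, a
#' dense halo with the bimodal 250/810 nm fragment size mixture),
#' `"patch_control"` (5 x 5 um membrane patch only, both roughness bands),
#' `"granule_mesh"` (1.5 x 1.5 um NET mesh patch at 2.9 nm/pixel with
#' 50 +/- 20 nm granules), and `"fragment_section"` (a 6 x 6 um halo section
#' at 11.7 nm/pixel with the 30-min fragment statistics: 26 fragments of size
#' 330 +/- 150 nm and height 16 +/- 4 nm).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [scene_params()].
#' @return A [scene_params()].
#' @export
scene_preset <- function(name = c("control", "spread", "flat", "netosis",
                                  "patch_control", "granule_mesh",
                                  "fragment_section"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(grid_points = 256L, field_size_nm = 30000,
                   cell_height_nm = 1200, cell_diameter_nm = 9800,
                   n_lobes = 0L, band1_period_nm = 1000, band1_amplitude_nm = 40,
                   band2_amplitude_nm = 0, n_fragments = 0L),
    spread = list(grid_points = 256L, field_size_nm = 30000,
                  cell_height_nm = 638, cell_diameter_nm = 16700,
                  n_lobes = 3L, lobe_height_nm = 200, spread_exponent = 4,
                  band1_period_nm = 1000, band1_amplitude_nm = 21,
                  band2_amplitude_nm = 0, n_fragments = 26L,
                  fragment_height_mean_nm = 16),
    flat = list(grid_points = 256L, field_size_nm = 30000,
                cell_height_nm = 300, cell_diameter_nm = 16700,
                n_lobes = 1L, spread_exponent = 4,
                band1_period_nm = 600, band1_amplitude_nm = 4,
                band2_amplitude_nm = 0, n_fragments = 40L,
                fragment_height_mean_nm = 40),
    netosis = list(grid_points = 256L, field_size_nm = 30000,
                   cell_height_nm = 0, band1_amplitude_nm = 0,
                   band2_amplitude_nm = 0, n_fragments = 110L,
                   fragment_size_mixture = list(
                     list(weight = 0.5, mean_nm = 250, sd_nm = 60),
                     list(weight = 0.5, mean_nm = 810, sd_nm = 120)),
                   fragment_height_mean_nm = 61),
    patch_control = list(grid_points = 512L, field_size_nm = 5000,
                         band1_period_nm = 1000, band1_amplitude_nm = 40,
                         band2_period_nm = 150, band2_amplitude_nm = 2.3),
    granule_mesh = list(grid_points = 512L, field_size_nm = 1500,
                        band1_amplitude_nm = 0, band2_amplitude_nm = 0,
                        substrate_noise_sd_nm = 0.3,
                        granule_size_mean_nm = 50, granule_size_sd_nm = 20,
                        n_granule_chains = 6L),
    fragment_section = list(grid_points = 512L, field_size_nm = 6000,
                            band1_amplitude_nm = 0, band2_amplitude_nm = 0,
                            n_fragments = 26L,
                            fragment_height_mean_nm = 16)
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(scene_params, args)
}

# ---- serialisation ----

#' Write/read scene parameters as a YAML config
#'
#' @param params A [scene_params()].
#' @param path File path.
#' @return `read_scene_params()` returns a [scene_params()];
#'   `write_scene_params()` returns `path` invisibly.
#' @export
write_scene_params <- function(params, path) {
  stopifnot(inherits(params, "scene_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_scene_params
#' @export
read_scene_params <- function(path) {
  p <- yaml::read_yaml(path)
  p$fragment_size_mixture <- lapply(p$fragment_size_mixture, as.list)
  do.call(scene_params, p)
}

#' Write/read scene ground truth as JSON
#'
#' @param truth A `ground_truth` object from [make_scene()].
#' @param path File path.
#' @return `read_ground_truth()` returns a `ground_truth`;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$band_periods_nm <- as.list(x$band_periods_nm)      # keep names in JSON
  x$band_amplitudes_nm <- as.list(x$band_amplitudes_nm)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fragments <- tibble::as_tibble(x$fragments)
  x$granules <- tibble::as_tibble(x$granules)
  x$band_periods_nm <- unlist(x$band_periods_nm)
  x$band_amplitudes_nm <- unlist(x$band_amplitudes_nm)
  structure(x, class = "ground_truth")
}
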