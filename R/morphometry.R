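#' Estimate the substrate background of a height map
#'
#' Robust two-pass estimator. The candidate substrate is seeded from the
#' lowest-quartile heights, whose median and MAD give a crude level and noise
#' scale; the substrate set is then re-selected as all pixels below that crude
#' level plus six noise SDs, and the final level and noise SD are the median
#' and scaled MAD of this set. The second pass removes the downward bias a
#' pure lowest-quartile median would have on a cell-free map, while cell
#' pixels (tens to hundreds of nm above substrate) stay excluded. Assumes at
#' least ~25% of pixels are substrate.
#'
#' @param map A [heightmap()].
#' @return A one-row tibble of class `background_model`: `level_nm`,
#'   `noise_sd_nm`.
#' @export
estimate_background <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  h <- as.vector(map$heights)
  q1 <- stats::quantile(h, 0.25, names = FALSE)
  seed_set <- h[h <= q1]
  crude_level <- stats::median(seed_set)
  crude_sd <- stats::mad(seed_set)
  subs <- h[h <= crude_level + 6 * crude_sd]
  out <- tibble::tibble(level_nm = stats::median(subs),
                        noise_sd_nm = stats::mad(subs))
  class(out) <- c("background_model", class(out))
  out
}

segmentation_threshold <- function(bg, floor_nm = 20) {
  bg$level_nm + max(3 * bg$noise_sd_nm, floor_nm)
}

#' Segment the main cell from a height map
#'
#' Thresholds the map at `level + max(3 * noise_sd, 20 nm)` (the 20 nm floor
#' prevents noise-driven masks on clean substrates), keeps the largest
#' connected component and fills its holes. Secondary above-threshold
#' components (other cells, large debris) are reported via attributes.
#'
#' @param map A [heightmap()].
#' @param bg A `background_model` from [estimate_background()].
#' @return A logical matrix mask with attributes `threshold_nm`,
#'   `n_secondary` (number of other components) and `particle_cover`
#'   (fraction of above-threshold pixels outside the selected mask).
#' @export
segment_cell <- function(map, bg) {
  stopifnot(inherits(map, "heightmap"), inherits(bg, "background_model"))
  thr <- segmentation_threshold(bg)
  bin <- map$heights > thr
  if (!any(bin)) {
    afm_abort("No pixel above the segmentation threshold: empty scene.",
              "afmtopo_empty_scene")
  }
  lab <- EBImage::bwlabel(bin * 1)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  mask <- lab == main
  mask <- EBImage::fillHull(mask * 1) > 0
  attr(mask, "threshold_nm") <- thr
  attr(mask, "n_secondary") <- length(sizes) - 1L
  attr(mask, "particle_cover") <- sum(bin & !mask) / sum(bin)
  mask
}

#' Maximum cell height above background
#'
#' @param map A [heightmap()].
#' @param mask Logical mask from [segment_cell()].
#' @param bg A `background_model`.
#' @return `h_max` in nm: maximum in-mask height minus the background level.
#' @export
cell_height <- function(map, mask, bg) {
  if (!any(mask)) afm_abort("Empty mask.", "afmtopo_invalid_input")
  max(map$heights[mask]) - bg$level_nm
}

#' Equivalent-circle cell diameter
#'
#' Area-based: `2 * sqrt(area / pi)` with area = pixel count x pixel size^2.
#' Rotation-stable, unlike a single profile width.
#'
#' @param mask Logical mask from [segment_cell()].
#' @param pixel_size_nm Lateral pixel size in nm.
#' @return Diameter in um.
#' @export
cell_diameter <- function(mask, pixel_size_nm) {
  npx <- sum(mask)
  if (npx == 0) afm_abort("Empty mask.", "afmtopo_invalid_input")
  2 * sqrt(npx * pixel_size_nm^2 / pi) / 1000
}

#' Width of the cell profile through its apex
#'
#' Secondary, figure-style size measure: the in-mask extent of the grid row
#' passing through the cell's highest point, in um.
#'
#' @inheritParams cell_height
#' @return Width in um.
#' @export
cell_profile_width <- function(map, mask, bg) {
  if (!any(mask)) afm_abort("Empty mask.", "afmtopo_invalid_input")
  hm <- map$heights
  hm[!mask] <- -Inf
  apex <- which(hm == max(hm), arr.ind = TRUE)[1, ]
  sum(mask[apex[1], ]) * map$pixel_size_nm / 1000
}

# Gaussian smoothing with physical FWHM (nm); reflective padding via EBImage.
smooth_heights <- function(heights, pixel_size_nm, fwhm_nm) {
  sigma_px <- fwhm_nm / 2.355 / pixel_size_nm
  if (sigma_px < 0.3) return(heights)
  as.matrix(EBImage::gblur(heights, sigma = sigma_px))
}

# Topographic prominence of every in-mask local summit, by descending
# flood with union-find: when the component of a lower summit first touches
# the component of a higher one at height z, the lower summit's prominence
# is its height minus z. The global summit gets its height above the in-mask
# minimum.
peak_prominences <- function(z, mask) {
  nr <- nrow(z); nc <- ncol(z)
  idx <- which(mask)
  ord <- idx[order(z[idx], decreasing = TRUE)]
  parent <- integer(nr * nc)      # 0 = inactive
  comp_peak <- integer(nr * nc)   # root -> index of its summit
  prom <- numeric(0); peak_at <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (p in ord) {
    r <- (p - 1L) %% nr + 1L
    cc <- (p - 1L) %/% nr + 1L
    nbr <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
        q <- (c2 - 1L) * nr + rr
        if (parent[q] != 0L) nbr <- c(nbr, q)
      }
    }
    parent[p] <- p
    roots <- unique(vapply(nbr, find, integer(1)))
    if (length(roots) == 0) {
      comp_peak[p] <- p  # new summit
    } else {
      heights_r <- z[comp_peak[roots]]
      keep <- roots[which.max(heights_r)]
      for (rt in roots) {
        if (rt != keep) {
          # the lower summit dies here: prominence = summit - saddle
          prom <- c(prom, z[comp_peak[rt]] - z[p])
          peak_at <- c(peak_at, comp_peak[rt])
          parent[rt] <- keep
        }
      }
      parent[p] <- keep
    }
  }
  root <- find(ord[1])
  prom <- c(prom, z[comp_peak[root]] - min(z[idx]))
  peak_at <- c(peak_at, comp_peak[root])
  tibble::tibble(index = peak_at, height = z[peak_at], prominence = prom)
}

#' Count nuclear-lobe summits of a segmented cell
#'
#' AFM sees the nucleus only through the apex topography: segmented nuclear
#' lobes appear as distinct summits of the cell surface. The masked map is
#' smoothed with a Gaussian kernel of physical FWHM `smooth_fwhm_nm` and
#' regional maxima whose topographic prominence exceeds
#' `max(5 * noise_sd, 10% of h_max)` are counted. The default width of
#' 1200 nm sits at the top of the first-order roughness window: spongiform
#' membrane roughness (periods <= 1200 nm) is suppressed by orders of
#' magnitude, while nuclear lobes - micrometres wide and several
#' micrometres apart - lose little prominence and are never merged.
#'
#' @inheritParams cell_height
#' @param smooth_fwhm_nm Physical smoothing kernel width (nm).
#' @return Integer number of lobes (>= 1 for any non-empty mask).
#' @export
count_lobes <- function(map, mask, bg, smooth_fwhm_nm = 1200) {
  if (!any(mask)) afm_abort("Empty mask.", "afmtopo_invalid_input")
  sm <- smooth_heights(map$heights, map$pixel_size_nm, smooth_fwhm_nm)
  hmax <- max(map$heights[mask]) - bg$level_nm
  floor_nm <- max(5 * bg$noise_sd_nm, 0.1 * hmax)
  pk <- peak_prominences(sm, mask)
  sum(pk$prominence > floor_nm)
}

#' Classify a cell into the four activation types
#'
#' Rule-based typing of the activation/NETosis stages, applied in order:
#' type 4 (disrupted, NET release) if the mask is fragmented
#' (solidity < 0.5), a NET mesh is flagged, or the object is flat
#' (`h_max < 150 nm`) amid extensive off-mask particle cover; type 1
#' (spherical) if `h_max >= 900 nm` and diameter <= 12 um; type 2 (spread,
#' segmented nucleus) if lower with >= 2 lobes; type 3 (spread, lost
#' segmentation) if lower with <= 1 lobe; `"other"` otherwise. Thresholds sit
#' between the reported stage morphometrics (1.2 um control vs 0.64 um
#' spread heights; 9.8 um control vs 16.7 um spread diameters).
#'
#' @param features A one-row data frame with `h_max_nm`, `diameter_um`,
#'   `n_lobes`, `solidity` (e.g. from [measure_cell()]).
#' @param mesh_present Logical flag: NET mesh detected/known in the scene.
#' @param particle_cover Fraction of above-threshold pixels outside the cell
#'   mask; high cover plus a flat object signals cell disintegration.
#' @return A type label: `"1"`, `"2"`, `"3"`, `"4"` or `"other"`.
#' @export
classify_type <- function(features, mesh_present = FALSE, particle_cover = 0) {
  stopifnot(all(c("h_max_nm", "diameter_um", "n_lobes", "solidity")
                %in% names(features)))
  f <- as.list(features[1, ])
  if (isTRUE(mesh_present) || f$solidity < 0.5 ||
      (f$h_max_nm < 150 && particle_cover > 0.3)) {
    return("4")
  }
  if (f$h_max_nm >= 900) {
    return(if (f$diameter_um <= 12) "1" else "other")
  }
  if (f$n_lobes >= 2) "2" else "3"
}

mask_solidity <- function(mask, pixel_size_nm) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(1)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hx <- pts[hull, 2]; hy <- pts[hull, 1]
  n <- length(hull)
  hull_area <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
  if (hull_area <= 0) return(1)
  min(1, nrow(pts) / hull_area)
}

#' Full morphometric measurement of the main cell in a scene
#'
#' Convenience pipeline: background estimation, segmentation, height,
#' diameter, lobe count, solidity, and type classification.
#'
#' @param map A [heightmap()].
#' @param mesh_present Optional known/detected NET mesh flag forwarded to
#'   [classify_type()].
#' @return A one-row tibble: `h_max_nm`, `diameter_um`, `area_um2`,
#'   `n_lobes`, `solidity`, `profile_width_um`, `particle_cover`,
#'   `type_label`.
#' @export
measure_cell <- function(map, mesh_present = FALSE) {
  bg <- estimate_background(map)
  mask <- segment_cell(map, bg)
  px <- map$pixel_size_nm
  out <- tibble::tibble(
    h_max_nm = cell_height(map, mask, bg),
    diameter_um = cell_diameter(mask, px),
    area_um2 = sum(mask) * px^2 / 1e6,
    n_lobes = count_lobes(map, mask, bg),
    solidity = mask_solidity(mask, px),
    profile_width_um = cell_profile_width(map, mask, bg),
    particle_cover = attr(mask, "particle_cover")
  )
  out$type_label <- classify_type(out, mesh_present = mesh_present,
                                  particle_cover = out$particle_cover)
  out
}

#' Distribution of cell types in a sample
#'
#' @param labels Character/factor vector of type labels (`"1"`..`"4"`,
#'   `"other"`), one per cell.
#' @param time_min Optional activation time for the sample (minutes).
#' @param activator Optional activator label (e.g. `"A23187"`, `"PMA"`).
#' @return A tibble with one row per observed type: `type_label`, `n`,
#'   `fraction_pct` (summing to 100), plus the time/activator columns when
#'   given.
#' @export
type_distribution <- function(labels, time_min = NA_real_,
                              activator = NA_character_) {
  if (length(labels) == 0) {
    afm_abort("Need at least one label.", "afmtopo_invalid_input")
  }
  tab <- table(as.character(labels))
  tibble::tibble(
    activator = activator, time_min = time_min,
    type_label = names(tab), n = as.integer(tab),
    fraction_pct = 100 * as.integer(tab) / length(labels)
  )
}
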