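#' Detect cell fragments or NET granules in a height map
#'
#' Connected-component particle detection: the map is despeckled with a 3 x 3
#' median filter (so single-pixel noise excursions at the threshold contour
#' neither split a particle nor seed false ones), pixels above
#' `level + max(3 * noise_sd, floor)` and outside the exclusion mask are
#' labelled, and components smaller than `min_area_px` pixels are discarded.
#' The height floor is 10 nm for the `fragment` scale class (sub-micron halo
#' debris) and 2 nm for `granule` (30-50 nm NET beads imaged at <= 3
#' nm/pixel); the two classes share one code path. Touching particles merge
#' into one component (no watershed splitting).
#'
#' Because the component is the *above-threshold* cross-section, the raw
#' equivalent diameter understates the particle's basal size; for a
#' paraboloid cap of peak height `h` cut at height `c` the basal diameter is
#' the measured one divided by `sqrt(1 - c/h)`. This threshold-cut-corrected
#' estimate is reported as `est_basal_diameter_nm`.
#'
#' @param map A [heightmap()], cropped to the analysis region (e.g. a
#'   6 x 5 um fragment section).
#' @param bg A `background_model` from [estimate_background()].
#' @param exclusion_mask Optional logical matrix covering the main cell body.
#' @param scale_class `"fragment"` or `"granule"`.
#' @param min_area_px Minimum component area in pixels.
#' @param region_id Optional label for the source region.
#' @return A `particle_set`: tibble with one row per particle
#'   (`centroid_x_nm`, `centroid_y_nm`, `equivalent_diameter_nm`,
#'   `est_basal_diameter_nm`, `max_height_nm`, `area_nm2`), with attributes
#'   `scale_class`, `region_id` and `threshold_nm`.
#' @export
detect_particles <- function(map, bg, exclusion_mask = NULL,
                             scale_class = c("fragment", "granule"),
                             min_area_px = 4L, region_id = NA_character_) {
  stopifnot(inherits(map, "heightmap"))
  if (!inherits(bg, "background_model")) {
    afm_abort("A background model is required.", "afmtopo_invalid_input")
  }
  scale_class <- match.arg(scale_class)
  floor_nm <- switch(scale_class, fragment = 10, granule = 2)
  thr <- bg$level_nm + max(3 * bg$noise_sd_nm, floor_nm)
  bin <- despeckle(map$heights) > thr
  if (!is.null(exclusion_mask)) bin <- bin & !exclusion_mask
  # 1-px closing re-attaches rim slivers that noise detaches from low
  # particles; planted/real inter-particle gaps are several pixels wide
  bin <- EBImage::closing(bin * 1, EBImage::makeBrush(3, "box")) > 0
  if (!is.null(exclusion_mask)) bin <- bin & !exclusion_mask
  px <- map$pixel_size_nm
  empty <- tibble::tibble(centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
                          equivalent_diameter_nm = numeric(0),
                          max_height_nm = numeric(0), area_nm2 = numeric(0))
  if (!any(bin)) {
    return(new_particle_set(empty, scale_class, region_id, thr))
  }
  lab <- EBImage::bwlabel(bin * 1)
  ids <- lab[lab > 0]
  areas <- tabulate(ids)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) {
    return(new_particle_set(empty, scale_class, region_id, thr))
  }
  pos <- which(lab > 0)
  lv <- lab[pos]
  rows <- (pos - 1L) %% nrow(lab) + 1L
  cols <- (pos - 1L) %/% nrow(lab) + 1L
  sel <- lv %in% keep
  lv <- lv[sel]; rows <- rows[sel]; cols <- cols[sel]; pos <- pos[sel]
  cx <- tapply(map$origin[1] + (cols - 1) * px, lv, mean)
  cy <- tapply(map$origin[2] + (rows - 1) * px, lv, mean)
  hmax <- tapply(map$heights[pos], lv, max) - bg$level_nm
  area_nm2 <- areas[keep] * px^2
  eq_d <- 2 * sqrt(area_nm2 / pi)
  cut <- (thr - bg$level_nm) / as.numeric(hmax)
  out <- tibble::tibble(
    centroid_x_nm = as.numeric(cx),
    centroid_y_nm = as.numeric(cy),
    equivalent_diameter_nm = eq_d,
    est_basal_diameter_nm = eq_d / sqrt(pmax(1 - cut, 0.05)),
    max_height_nm = as.numeric(hmax),
    area_nm2 = area_nm2
  )
  new_particle_set(out, scale_class, region_id, thr)
}

# 3x3 median despeckle; EBImage's filter works on a normalised range
despeckle <- function(heights) {
  rng <- range(heights)
  if (rng[2] <= rng[1]) return(heights)
  norm <- (heights - rng[1]) / (rng[2] - rng[1])
  as.matrix(EBImage::medianFilter(norm, size = 1)) * (rng[2] - rng[1]) + rng[1]
}

new_particle_set <- function(tbl, scale_class, region_id, thr) {
  attr(tbl, "scale_class") <- scale_class
  attr(tbl, "region_id") <- region_id
  attr(tbl, "threshold_nm") <- thr
  class(tbl) <- c("particle_set", class(tbl))
  tbl
}

#' Summary statistics of a particle set
#'
#' @param set A `particle_set` from [detect_particles()], or any data frame
#'   with `equivalent_diameter_nm` and `max_height_nm` columns.
#' @return A one-row tibble: `n`, `mean_diameter_nm`, `sd_diameter_nm`,
#'   `mean_height_nm`, `sd_height_nm` (SDs are 0 for a single particle).
#' @export
particle_stats <- function(set) {
  if (nrow(set) == 0) afm_abort("Empty particle set.", "afmtopo_invalid_input")
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  tibble::tibble(
    n = nrow(set),
    mean_diameter_nm = mean(set$equivalent_diameter_nm),
    sd_diameter_nm = sd0(set$equivalent_diameter_nm),
    mean_height_nm = mean(set$max_height_nm),
    sd_height_nm = sd0(set$max_height_nm)
  )
}

#' Relative-frequency size histogram
#'
#' Left-closed bins `[0, w), [w, 2w), ...`; frequencies sum to 1.
#'
#' @param set A `particle_set`, or a numeric vector of sizes (nm).
#' @param bin_width_nm Bin width in nm (> 0).
#' @return A tibble: `bin_left_nm`, `bin_right_nm`, `count`, `frequency`.
#' @export
size_histogram <- function(set, bin_width_nm) {
  sizes <- if (is.numeric(set)) set else set$equivalent_diameter_nm
  if (length(sizes) == 0) afm_abort("Empty particle set.", "afmtopo_invalid_input")
  if (!is.numeric(bin_width_nm) || bin_width_nm <= 0) {
    afm_abort("Bin width must be positive.", "afmtopo_invalid_parameter")
  }
  bin <- floor(sizes / bin_width_nm)
  tab <- table(bin)
  lefts <- as.numeric(names(tab)) * bin_width_nm
  tibble::tibble(
    bin_left_nm = lefts, bin_right_nm = lefts + bin_width_nm,
    count = as.integer(tab),
    frequency = as.integer(tab) / length(sizes)
  )
}

#' Unimodal vs bimodal decision for a size distribution
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances,
#' deterministic model-based hierarchical initialisation) and declares two
#' modes when the two-component BIC improves on the one-component BIC by
#' more than `delta_bic`. Captures the reported transition of the fragment
#' size distribution from normal to bimodal during activation. The decision
#' is invariant to rescaling the sizes (nm vs um), since a change of units
#' shifts both models' log-likelihoods equally.
#'
#' @param sizes Numeric vector of particle sizes (>= 8 values).
#' @param delta_bic BIC improvement required to accept two modes.
#' @return A list of class `modality_result`: `n_modes` (1 or 2),
#'   `mode_positions_nm` (component means, ascending), `weights`,
#'   `score_diff` (two-component BIC minus one-component BIC).
#' @export
modality_test <- function(sizes, delta_bic = 2) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 8) {
    afm_abort("Need at least 8 sizes for a modality decision.",
              "afmtopo_insufficient_data")
  }
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller's frame
  fit1 <- mclust::Mclust(sizes, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- mclust::Mclust(sizes, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit2)) {
    score_diff <- -Inf
  } else {
    score_diff <- as.numeric(fit2$bic) - as.numeric(fit1$bic)
  }
  if (is.finite(score_diff) && score_diff > delta_bic) {
    ord <- order(fit2$parameters$mean)
    res <- list(n_modes = 2L,
                mode_positions_nm = as.numeric(fit2$parameters$mean[ord]),
                weights = as.numeric(fit2$parameters$pro[ord]),
                score_diff = score_diff)
  } else {
    res <- list(n_modes = 1L,
                mode_positions_nm = as.numeric(fit1$parameters$mean),
                weights = 1,
                score_diff = if (is.finite(score_diff)) score_diff else NA_real_)
  }
  structure(res, class = "modality_result")
}

#' @export
print.modality_result <- function(x, ...) {
  cat(sprintf("<modality_result> %d mode(s) at %s nm (BIC diff %.2f)\n",
              x$n_modes, paste(round(x$mode_positions_nm, 1), collapse = ", "),
              x$score_diff))
  invisible(x)
}
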