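#' Spectral windows for membrane roughness orders
#'
#' Roughness of the neutrophil membrane is analysed in two period bands chosen
#' to match its characteristic "spongiform" structure: first order 600-1200 nm
#' (large sponge-like formations) and second order 50-300 nm (small ones).
#'
#' @param label Window label, conventionally `"order_I"` or `"order_II"`.
#' @param period_min_nm,period_max_nm Period band limits in nm.
#' @return An object of class `spectral_window`.
#' @export
#' @examples
#' spectral_window("order_I")
spectral_window <- function(label = c("order_I", "order_II"),
                            period_min_nm = NULL, period_max_nm = NULL) {
  if (is.null(period_min_nm) || is.null(period_max_nm)) {
    label <- match.arg(label)
    p <- switch(label, order_I = c(600, 1200), order_II = c(50, 300))
    period_min_nm <- period_min_nm %||% p[1]
    period_max_nm <- period_max_nm %||% p[2]
  } else {
    label <- label[1]
  }
  if (!(period_min_nm > 0 && period_min_nm < period_max_nm)) {
    afm_abort("Need 0 < period_min_nm < period_max_nm.",
              "afmtopo_invalid_parameter")
  }
  structure(list(label = label, period_min_nm = period_min_nm,
                 period_max_nm = period_max_nm),
            class = "spectral_window")
}

#' Remove the best-fit line or plane
#'
#' Least-squares detrending: a line for 1-D profiles, a plane for 2-D maps.
#' The result has zero mean and zero linear trend, which makes the roughness
#' spectrum insensitive to overall tilt of the scan.
#'
#' @param x A numeric vector, a profile tibble from [extract_profile()], a
#'   numeric matrix, or a [heightmap()].
#' @return Same kind of object as the input, detrended.
#' @export
detrend <- function(x) {
  if (inherits(x, "heightmap")) {
    out <- x
    out$heights <- detrend_matrix(x$heights)
    return(out)
  }
  if (is.data.frame(x) && "height_nm" %in% names(x)) {
    out <- x
    out$height_nm <- detrend_vector(x$height_nm)
    return(out)
  }
  if (is.matrix(x)) return(detrend_matrix(x))
  if (is.numeric(x)) return(detrend_vector(x))
  afm_abort("Cannot detrend this object.", "afmtopo_invalid_parameter")
}

detrend_vector <- function(h) {
  n <- length(h)
  if (n < 3) afm_abort("Need at least 3 samples to detrend.",
                       "afmtopo_numeric_error")
  t <- seq_len(n) - (n + 1) / 2
  h - mean(h) - sum(t * h) / sum(t * t) * t
}

detrend_matrix <- function(z) {
  if (nrow(z) < 3 || ncol(z) < 3) {
    afm_abort("Need at least 3 samples per dimension to detrend.",
              "afmtopo_numeric_error")
  }
  # centered row/column coordinates are orthogonal, so the plane fit separates
  r <- seq_len(nrow(z)) - (nrow(z) + 1) / 2
  c_ <- seq_len(ncol(z)) - (ncol(z) + 1) / 2
  b_r <- sum(r * rowSums(z)) / (sum(r * r) * ncol(z))
  b_c <- sum(c_ * colSums(z)) / (sum(c_ * c_) * nrow(z))
  z - mean(z) - outer(r, rep(1, ncol(z))) * b_r - outer(rep(1, nrow(z)), c_) * b_c
}

#' One-sided spatial spectrum of a height profile
#'
#' Computes the spectral intensity S (nm^2) versus spatial frequency
#' nu (1/nm) of a uniformly sampled profile. The normalisation is one-sided
#' amplitude-squared: a pure cosine of amplitude A at an on-grid frequency
#' yields S = A^2 at that frequency, i.e. S is the square of the roughness
#' amplitude at each spatial period. The profile is detrended internally; the
#' zero-frequency and (for even N) Nyquist terms are excluded.
#'
#' @param profile A numeric height vector (nm) or a profile tibble from
#'   [extract_profile()].
#' @param pixel_size_nm Sampling step in nm; taken from the profile attribute
#'   when a tibble is given.
#' @return A `spatial_spectrum`: tibble with columns `nu_per_nm` (ascending,
#'   `k/(N * pixel_size)`), `S_nm2`, plus attributes `n_points` and
#'   `pixel_size_nm`.
#' @export
profile_spectrum <- function(profile, pixel_size_nm = NULL) {
  if (is.data.frame(profile)) {
    pixel_size_nm <- pixel_size_nm %||% attr(profile, "pixel_size_nm")
    profile <- profile$height_nm
  }
  if (is.null(pixel_size_nm)) {
    afm_abort("`pixel_size_nm` is required.", "afmtopo_invalid_parameter")
  }
  n <- length(profile)
  if (n < 8) afm_abort("Profile too short for a spectrum (need N >= 8).",
                       "afmtopo_invalid_input")
  h <- detrend_vector(profile)
  co <- stats::fft(h)
  kmax <- ceiling(n / 2) - 1L  # excludes DC; excludes Nyquist for even N
  k <- seq_len(kmax)
  s <- (2 / n)^2 * Mod(co[k + 1])^2
  new_spatial_spectrum(k / (n * pixel_size_nm), s, n, pixel_size_nm)
}

new_spatial_spectrum <- function(nu, s, n_points, pixel_size_nm) {
  out <- tibble::tibble(nu_per_nm = nu, S_nm2 = s)
  attr(out, "n_points") <- n_points
  attr(out, "pixel_size_nm") <- pixel_size_nm
  class(out) <- c("spatial_spectrum", class(out))
  out
}

#' Spatial period from spatial frequency
#'
#' @param nu_per_nm Spatial frequency in 1/nm; must be positive.
#' @return The spatial period L = 1/nu in nm.
#' @export
#' @examples
#' period_from_frequency(0.002) # 500 nm
period_from_frequency <- function(nu_per_nm) {
  if (any(!is.finite(nu_per_nm)) || any(nu_per_nm <= 0)) {
    afm_abort("Spatial frequency must be positive.", "afmtopo_domain_error")
  }
  1 / nu_per_nm
}

#' Peak intensity within a spectral window
#'
#' Extracts the core roughness readout for one order: `S_max` (maximum
#' spectral intensity over the window, nm^2), the frequency `nu_max` at which
#' it occurs, and the corresponding spatial period `L_max = 1/nu_max` (nm),
#' the characteristic distance between roughness maxima. Window edges are
#' inclusive in frequency; ties are broken toward the lowest frequency
#' (largest period).
#'
#' @param spectrum A `spatial_spectrum` from [profile_spectrum()].
#' @param window A [spectral_window()] or a label understood by it.
#' @return A one-row tibble: `window`, `S_max_nm2`, `nu_max_per_nm`,
#'   `L_max_nm`.
#' @export
spectral_summary <- function(spectrum, window = "order_I") {
  if (is.character(window)) window <- spectral_window(window)
  stopifnot(inherits(window, "spectral_window"))
  lo <- 1 / window$period_max_nm
  hi <- 1 / window$period_min_nm
  eps <- 1e-12
  in_win <- spectrum$nu_per_nm >= lo - eps & spectrum$nu_per_nm <= hi + eps
  if (!any(in_win)) {
    afm_abort(sprintf("No spectral points inside window %s (%g-%g nm).",
                      window$label, window$period_min_nm, window$period_max_nm),
              "afmtopo_window_error")
  }
  nu <- spectrum$nu_per_nm[in_win]
  s <- spectrum$S_nm2[in_win]
  imax <- which(s == max(s))
  i <- imax[which.min(nu[imax])]
  tibble::tibble(window = window$label, S_max_nm2 = s[i],
                 nu_max_per_nm = nu[i], L_max_nm = 1 / nu[i])
}

# 2-D fft frequency grid magnitudes (1/nm)
fft_radial_freq <- function(nr, nc, pixel_size_nm) {
  fr <- function(n) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    k / n
  }
  fy <- fr(nr) / pixel_size_nm
  fx <- fr(nc) / pixel_size_nm
  sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
}

#' Band-pass order surface of a height map
#'
#' Reconstructs the first- or second-order roughness surface: the map is plane
#' detrended, Fourier transformed in 2-D, coefficients whose radial (isotropic)
#' spatial frequency lies inside the window's band `[1/period_max, 1/period_min]`
#' (inclusive) are retained, and the result is transformed back. The output is
#' real and zero-mean; its variance equals the in-band spectral power.
#'
#' @param map A [heightmap()].
#' @param window A [spectral_window()] or label.
#' @return A [heightmap()] holding the band-limited surface.
#' @export
bandpass_surface <- function(map, window = "order_I") {
  stopifnot(inherits(map, "heightmap"))
  if (is.character(window)) window <- spectral_window(window)
  z <- detrend_matrix(map$heights)
  nr <- nrow(z); nc <- ncol(z)
  rad <- fft_radial_freq(nr, nc, map$pixel_size_nm)
  nyq <- 1 / (2 * map$pixel_size_nm)
  if (1 / window$period_max_nm > nyq) {
    afm_abort("Spectral window lies entirely above the Nyquist frequency.",
              "afmtopo_window_error")
  }
  eps <- 1e-12
  keep <- rad >= 1 / window$period_max_nm - eps & rad <= 1 / window$period_min_nm + eps
  co <- stats::fft(z)
  co[!keep] <- 0
  out <- map
  g <- Re(stats::fft(co, inverse = TRUE)) / (nr * nc)
  out$heights <- g - mean(g)
  out$metadata$band <- window$label
  out
}

#' Membrane-patch roughness spectrum of a segmented cell
#'
#' Cuts a square membrane patch (default 5 x 5 um, the standard nanosurface
#' scan size) centered on the cell apex, computes the spatial spectrum of
#' every patch row and averages them, then summarises both spectral windows.
#' Row-averaging stabilises `S_max` compared to a single cross-section; pass
#' `rows = "apex"` for the figure-style single-profile spectrum.
#'
#' @param map A [heightmap()].
#' @param cell_mask Optional logical matrix marking the cell; when given, the
#'   patch is centered on the highest pixel inside the mask and must fit
#'   inside the map. `NULL` analyses the map center (e.g. for standalone
#'   membrane patches).
#' @param patch_size_nm Physical patch side length, default 5000.
#' @param rows `"all"` (average all patch rows) or `"apex"` (single row
#'   through the apex).
#' @return A list with `spectrum` (the averaged `spatial_spectrum`),
#'   `summary` (two-row tibble, one per window), and `patch` (the cropped
#'   [heightmap()]).
#' @export
cell_patch_spectrum <- function(map, cell_mask = NULL, patch_size_nm = 5000,
                                rows = c("all", "apex")) {
  rows <- match.arg(rows)
  stopifnot(inherits(map, "heightmap"))
  px <- map$pixel_size_nm
  npatch <- floor(patch_size_nm / px)
  if (npatch < 8) {
    afm_abort("Patch too small for spectral analysis.", "afmtopo_geometry_error")
  }
  if (npatch > min(dim(map$heights))) {
    afm_abort("Cell/map too small for the requested patch.",
              "afmtopo_geometry_error")
  }
  if (is.null(cell_mask)) {
    ci <- (dim(map$heights) + 1) / 2
  } else {
    stopifnot(is.logical(cell_mask), all(dim(cell_mask) == dim(map$heights)))
    if (!any(cell_mask)) afm_abort("Empty cell mask.", "afmtopo_geometry_error")
    hmask <- map$heights
    hmask[!cell_mask] <- -Inf
    ci <- which(hmask == max(hmask), arr.ind = TRUE)[1, ]
  }
  i0 <- round(ci[1] - npatch / 2); j0 <- round(ci[2] - npatch / 2)
  i0 <- min(max(1, i0), nrow(map$heights) - npatch + 1)
  j0 <- min(max(1, j0), ncol(map$heights) - npatch + 1)
  patch <- heightmap(map$heights[i0:(i0 + npatch - 1), j0:(j0 + npatch - 1)],
                     px, origin = map$origin + c(j0 - 1, i0 - 1) * px)
  if (rows == "apex") {
    spec <- profile_spectrum(patch$heights[round(npatch / 2), ], px)
  } else {
    mats <- apply(patch$heights, 1, function(r) profile_spectrum(r, px)$S_nm2)
    first <- profile_spectrum(patch$heights[1, ], px)
    spec <- new_spatial_spectrum(first$nu_per_nm, rowMeans(mats), npatch, px)
  }
  summ <- dplyr::bind_rows(spectral_summary(spec, "order_I"),
                           spectral_summary(spec, "order_II"))
  list(spectrum = spec, summary = summ, patch = patch)
}
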