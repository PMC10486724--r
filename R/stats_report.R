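#' Correlation and regression of spectral intensity on cell height
#'
#' During activation the membrane flattens and its roughness spectrum
#' collapses together, so the peak spectral intensity `S_max` (nm^2) tracks
#' the maximum cell height `h_max` (nm). This fits the ordinary
#' least-squares regression of `S_max` on `h_max` (slope `b` in nm, fixing
#' the direction of the reported regression coefficients) together with the
#' Pearson correlation `r`, pooling all time points of one activator arm and
#' order.
#'
#' @param pairs A data frame with columns `h_max_nm` and `S_max_nm2` (one row
#'   per cell/time observation).
#' @param order_label,activator Optional labels stored with the result.
#' @return An object of class `afm_regression` with elements `r`, `b_nm`,
#'   `b_se_nm`, `intercept_nm2`, `n`, `order_label`, `activator` and the
#'   underlying `lm` fit. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
correlate_height_spectrum <- function(pairs, order_label = NA_character_,
                                      activator = NA_character_) {
  stopifnot(all(c("h_max_nm", "S_max_nm2") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3) afm_abort("Need at least 3 pairs.", "afmtopo_invalid_input")
  if (stats::var(pairs$h_max_nm) == 0) {
    afm_abort("Degenerate input: h_max has zero variance.",
              "afmtopo_degenerate_input")
  }
  fit <- stats::lm(S_max_nm2 ~ h_max_nm, data = pairs)
  co <- suppressWarnings(stats::coef(summary(fit)))  # exact fits are fine
  structure(list(
    r = stats::cor(pairs$h_max_nm, pairs$S_max_nm2),
    b_nm = unname(co["h_max_nm", "Estimate"]),
    b_se_nm = unname(co["h_max_nm", "Std. Error"]),
    intercept_nm2 = unname(co["(Intercept)", "Estimate"]),
    n = n, order_label = order_label, activator = activator,
    fit = fit
  ), class = "afm_regression")
}

#' @export
print.afm_regression <- function(x, ...) {
  cat(sprintf("<afm_regression> n = %d: r = %.3f, b = %.4g +/- %.2g nm\n",
              x$n, x$r, x$b_nm, x$b_se_nm))
  invisible(x)
}

#' Tidy an S_max-on-h_max regression
#'
#' @param x An `afm_regression` from [correlate_height_spectrum()].
#' @param ... Unused.
#' @return A one-row tibble: `activator`, `order_label`, `r`, `b_nm`,
#'   `b_se_nm`, `intercept_nm2`, `n`.
#' @method tidy afm_regression
#' @export
tidy.afm_regression <- function(x, ...) {
  tibble::tibble(activator = x$activator, order_label = x$order_label,
                 r = x$r, b_nm = x$b_nm, b_se_nm = x$b_se_nm,
                 intercept_nm2 = x$intercept_nm2, n = x$n)
}

#' @rdname tidy.afm_regression
#' @method glance afm_regression
#' @export
glance.afm_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(r = x$r, r_squared = s$r.squared, sigma = s$sigma, n = x$n)
}

#' Ratio of two regression coefficients
#'
#' Reported to a fixed number of decimals (two by default, the convention
#' used for the activator-arm slope ratios such as 0.86/1.12 = 0.77).
#'
#' @param b_num_nm,b_den_nm Numerator and denominator coefficients.
#' @param decimals Decimals to round the quotient to.
#' @return The rounded ratio.
#' @export
#' @examples
#' coefficient_ratio(0.86, 1.12) # 0.77
coefficient_ratio <- function(b_num_nm, b_den_nm, decimals = 2) {
  if (b_den_nm == 0) afm_abort("Zero denominator.", "afmtopo_domain_error")
  round(b_num_nm / b_den_nm, decimals)
}

#' Fold-change of a spectral intensity relative to control
#'
#' `control / value`, reported to two significant figures (the convention
#' behind statements like "1800 to 10 nm^2: a factor of 180").
#'
#' @param value_control,value_t Control and activated values; both > 0.
#' @return The fold-change, 2 significant figures.
#' @export
#' @examples
#' fold_change(1800, 10) # 180
fold_change <- function(value_control, value_t) {
  if (value_control <= 0 || value_t <= 0) {
    afm_abort("Fold-change needs positive values.", "afmtopo_domain_error")
  }
  signif(value_control / value_t, 2)
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-sided Mann-Whitney comparison
#'
#' Rank-sum test between two samples: the exact null distribution of U is
#' used when the smaller sample has at most 8 observations and there are no
#' ties; otherwise the normal approximation with tie correction (and
#' continuity correction) is used. Significance stars follow the
#' conventional thresholds (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param sample_a,sample_b Numeric samples, each with at least 3 values.
#' @return A one-row tibble: `statistic` (U for sample_a), `p_value`,
#'   `stars`, `method`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    afm_abort("Each sample needs at least 3 values.", "afmtopo_invalid_input")
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- min(length(sample_a), length(sample_b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 stars = p_stars(wt$p.value),
                 method = if (exact) "exact" else "normal approximation")
}

#' Assemble the time-course report bundle
#'
#' Collects the pipeline's readouts into the standard table families: cell
#' type distribution per time point, height/diameter summary statistics,
#' per-window spectral summaries, fragment counts and sizes, granule
#' statistics, and the pooled height-spectrum correlation/regression block
#' per activator arm and order. Missing inputs produce an explicit gap note
#' instead of a table.
#'
#' @param cells Tibble of per-cell morphometrics with columns `activator`,
#'   `time_min`, `h_max_nm`, `diameter_um`, `n_lobes`, `type_label`.
#' @param spectra Optional tibble of per-cell spectral summaries:
#'   `activator`, `time_min`, `window`, `S_max_nm2`, `L_max_nm`, and
#'   `h_max_nm` for the regression block.
#' @param fragments Optional tibble of per-section fragment statistics:
#'   `activator`, `time_min`, plus the [particle_stats()] columns.
#' @param granules Optional tibble of granule statistics per arm.
#' @return A list of class `afm_report`: tibbles `types`, `morphometrics`,
#'   `spectra_summary`, `fragments`, `granules`, `regression`, and a
#'   character vector `notes`.
#' @export
build_report <- function(cells, spectra = NULL, fragments = NULL,
                         granules = NULL) {
  need <- c("activator", "time_min", "h_max_nm", "diameter_um", "type_label")
  if (!all(need %in% names(cells))) {
    afm_abort(paste0("`cells` lacks columns: ",
                     paste(setdiff(need, names(cells)), collapse = ", ")),
              "afmtopo_schema_error")
  }
  notes <- character(0)

  types <- cells |>
    dplyr::group_by(.data$activator, .data$time_min) |>
    dplyr::group_modify(~ type_distribution(.x$type_label)[-(1:2)]) |>
    dplyr::ungroup()

  morpho <- cells |>
    dplyr::group_by(.data$activator, .data$time_min) |>
    dplyr::summarise(
      n = dplyr::n(),
      h_max_mean_nm = mean(.data$h_max_nm), h_max_sd_nm = stats::sd(.data$h_max_nm),
      diameter_mean_um = mean(.data$diameter_um),
      diameter_sd_um = stats::sd(.data$diameter_um),
      .groups = "drop")

  if (!is.null(spectra)) {
    if (!all(c("window", "S_max_nm2") %in% names(spectra))) {
      afm_abort("`spectra` lacks window/S_max_nm2 columns.",
                "afmtopo_schema_error")
    }
    spec_tab <- spectra |>
      dplyr::group_by(.data$activator, .data$time_min, .data$window) |>
      dplyr::summarise(n = dplyr::n(),
                       S_max_mean_nm2 = mean(.data$S_max_nm2),
                       S_max_sd_nm2 = stats::sd(.data$S_max_nm2),
                       L_max_mean_nm = mean(.data$L_max_nm),
                       .groups = "drop")
    regression <- spectra |>
      dplyr::filter(!is.na(.data$h_max_nm)) |>
      dplyr::group_by(.data$activator, .data$window) |>
      dplyr::group_modify(function(d, g) {
        if (nrow(d) >= 3 && stats::var(d$h_max_nm) > 0) {
          tidy.afm_regression(correlate_height_spectrum(d))[-(1:2)]
        } else tibble::tibble()
      }) |>
      dplyr::ungroup()
  } else {
    spec_tab <- NULL; regression <- NULL
    notes <- c(notes, "spectra input missing: spectral and regression tables omitted")
  }

  if (is.null(fragments)) {
    notes <- c(notes, "fragment input missing: fragment tables omitted")
  }
  if (is.null(granules)) {
    notes <- c(notes, "granule input missing: granule tables omitted")
  }
  structure(list(types = types, morphometrics = morpho,
                 spectra_summary = spec_tab, fragments = fragments,
                 granules = granules, regression = regression, notes = notes),
            class = "afm_report")
}

#' Write a report bundle to a directory
#'
#' Writes `types.csv`, `morphometrics.csv`, `spectra_summary.csv`,
#' `fragments.csv`, `granules.csv`, `regression.json` and a `run.log`
#' listing what was written and any gap notes. Content is deterministic for
#' identical inputs (the log carries no timestamps).
#'
#' @param report An `afm_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "afm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  for (nm in c("types", "morphometrics", "spectra_summary", "fragments",
               "granules")) {
    tab <- report[[nm]]
    if (!is.null(tab)) {
      utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
      log <- c(log, paste0("wrote ", nm, ".csv (", nrow(tab), " rows)"))
    }
  }
  if (!is.null(report$regression)) {
    jsonlite::write_json(report$regression, file.path(dir, "regression.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    log <- c(log, "wrote regression.json")
  }
  log <- c(log, paste0("note: ", report$notes))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}
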