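# Internal helpers shared across modules.

#' @importFrom rlang abort
afm_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "afmtopo_error"), ...)
}

# Run `expr` under a fixed RNG state, restoring the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a deterministic sub-seed (< 2^31) for a named component stream, so a
# single scene seed yields one independent, reproducible stream per component.
component_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((abs(seed) * 48271 + h * 9973) %% 2147483629) + 1L
}

# Physical coordinate grids (nm) for a rows x cols heightmap.
coord_grids <- function(nrow, ncol, pixel_size_nm, origin = c(0, 0)) {
  x <- origin[1] + (seq_len(ncol) - 1) * pixel_size_nm
  y <- origin[2] + (seq_len(nrow) - 1) * pixel_size_nm
  list(
    x = matrix(x, nrow = nrow, ncol = ncol, byrow = TRUE),
    y = matrix(y, nrow = nrow, ncol = ncol, byrow = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
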