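# Independent oracles used to freeze expected values; these deliberately do
# not call the package's own spectral/statistics code paths.

# Brute-force one-sided amplitude-squared spectrum by direct summation,
# after removing the least-squares line.
dft_oracle <- function(h, pixel_size_nm) {
  n <- length(h)
  t <- seq_len(n) - (n + 1) / 2
  h <- h - mean(h) - sum(t * h) / sum(t * t) * t
  kmax <- ceiling(n / 2) - 1
  ks <- seq_len(kmax)
  s <- vapply(ks, function(k) {
    re <- sum(h * cos(2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(h * sin(2 * pi * k * (seq_len(n) - 1) / n))
    (2 / n)^2 * (re^2 + im^2)
  }, numeric(1))
  list(nu = ks / (n * pixel_size_nm), S = s)
}

# Exhaustive strict 8-neighbour local-maximum scan (interior pixels only).
# `tol` guards against floating-point micro-plateaus on analytically flat
# surfaces (e.g. the top of a high-exponent super-Gaussian cap).
local_maxima_scan <- function(z, min_height = -Inf, tol = 1e-9) {
  nr <- nrow(z); nc <- ncol(z)
  hits <- 0L
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- z[i, j]
    if (v <= min_height) next
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v > max(nb[-5]) + tol) hits <- hits + 1L
  }
  hits
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations to group A.
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(m)])
  u_obs <- r_obs - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  r_all <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  u_all <- r_all - m * (m + 1) / 2
  mu <- m * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small flat map with Gaussian noise.
noise_map <- function(n = 64, sd = 1, px = 10, seed = 1) {
  set.seed(seed)
  heightmap(matrix(rnorm(n * n, 0, sd), n, n), pixel_size_nm = px)
}
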