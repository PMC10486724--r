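test_that("detrend removes lines and planes and is idempotent", {
  n <- 100
  x <- seq_len(n)
  ramp <- 3 + 0.25 * x
  expect_equal(detrend(ramp), rep(0, n), tolerance = 1e-10)
  cosine <- 5 * cos(2 * pi * 4 * (x - (n + 1) / 2) / n)  # even about center
  rec <- detrend(cosine + ramp)
  expect_equal(rec, cosine, tolerance = 1e-9 * max(abs(cosine)))
  expect_equal(detrend(rec), rec, tolerance = 1e-9)
  # 2-D plane
  z <- outer(seq_len(20), seq_len(30), function(i, j) 2 + 0.1 * i - 0.3 * j)
  expect_equal(detrend(z), matrix(0, 20, 30), tolerance = 1e-10)
  expect_error(detrend(c(1, 2)), class = "afmtopo_numeric_error")
  expect_error(detrend("a"), class = "afmtopo_invalid_parameter")
})

test_that("profile_spectrum follows the amplitude-squared convention", {
  n <- 512
  px <- 5000 / n
  x <- (seq_len(n) - 1) * px
  # amplitude 40 nm, period 1000 nm -> S = 1600 nm^2 at nu = 0.001
  # (phase centered on the grid so the cosine is orthogonal to the trend line)
  prof <- 40 * cos(2 * pi * (x - (n - 1) * px / 2) / 1000)
  sp <- profile_spectrum(prof, px)
  i <- which.max(sp$S_nm2)
  expect_equal(sp$nu_per_nm[i], 0.001, tolerance = 1e-12)
  expect_equal(sp$S_nm2[i], 1600, tolerance = 1600 * 1e-6)
  expect_lt(sort(sp$S_nm2, decreasing = TRUE)[2], 1600 * 1e-9)
  # zero profile -> all-zero spectrum
  expect_true(all(profile_spectrum(rep(0, 64), 10)$S_nm2 == 0))
  expect_error(profile_spectrum(rep(1, 5), 10), class = "afmtopo_invalid_input")
})

test_that("two on-grid cosines match the brute-force DFT oracle", {
  n <- 128
  px <- 10
  tc <- (seq_len(n) - 1) - (n - 1) / 2
  prof <- 12 * cos(2 * pi * 8 * tc / n) + 5 * cos(2 * pi * 21 * tc / n + pi)
  sp <- profile_spectrum(prof, px)
  orc <- dft_oracle(prof, px)
  expect_equal(sp$nu_per_nm, orc$nu, tolerance = 1e-12)
  expect_equal(sp$S_nm2, orc$S, tolerance = 1e-9)
  expect_equal(sp$S_nm2[8], 144, tolerance = 1e-6 * 144)
  expect_equal(sp$S_nm2[21], 25, tolerance = 1e-6 * 25)
})

test_that("Parseval, scale equivariance and shift invariance hold", {
  set.seed(7)
  px <- 10
  for (n in c(127, 128)) {
    # odd N: arbitrary signal (all spectral mass is in the reported bins);
    # even N: trend-free even cosines (no power leaks into the Nyquist bin)
    if (n %% 2 == 1) {
      prof <- cumsum(rnorm(n))
    } else {
      tc <- (seq_len(n) - 1) - (n - 1) / 2
      prof <- rowSums(sapply(2:20, function(k)
        rnorm(1, 0, 3) * cos(2 * pi * k * tc / n + sample(c(0, pi), 1))))
    }
    sp <- profile_spectrum(prof, px)
    v <- mean((detrend(prof) - mean(detrend(prof)))^2)
    expect_equal(sum(sp$S_nm2) / 2, v, tolerance = 1e-9 * v)
    # scale: heights x3 => S x9, L_max unchanged
    sp3 <- profile_spectrum(3 * prof, px)
    expect_equal(sp3$S_nm2, 9 * sp$S_nm2, tolerance = 1e-9)
    expect_identical(which.max(sp3$S_nm2), which.max(sp$S_nm2))
    # shift: constant + linear ramp leave the spectrum unchanged
    spr <- profile_spectrum(prof + 40 + 0.8 * seq_len(n), px)
    expect_equal(spr$S_nm2, sp$S_nm2, tolerance = 1e-9 * max(sp$S_nm2))
  }
})

test_that("spectral_summary picks the in-window peak with low-frequency ties", {
  sp <- structure(
    tibble::tibble(nu_per_nm = c(0.0005, 0.001, 0.0015, 0.004, 0.009),
                   S_nm2 = c(9000, 1600, 1600, 5.3, 2)),
    class = c("spatial_spectrum", "tbl_df", "tbl", "data.frame"))
  s1 <- spectral_summary(sp, "order_I")
  expect_equal(s1$S_max_nm2, 1600)
  expect_equal(s1$nu_max_per_nm, 0.001)  # tie broken to lowest frequency
  expect_equal(s1$L_max_nm, 1000)
  s2 <- spectral_summary(sp, "order_II")
  expect_equal(s2$S_max_nm2, 5.3)
  expect_equal(s2$L_max_nm, 250)
  narrow <- spectral_window("custom", 10, 20)
  expect_error(spectral_summary(sp, narrow), class = "afmtopo_window_error")
})

test_that("period_from_frequency is the reciprocal with domain checks", {
  expect_equal(period_from_frequency(0.001), 1000)
  expect_equal(period_from_frequency(0.002), 500)
  expect_equal(period_from_frequency(0.008), 125)
  expect_equal(period_from_frequency(0.5), 2)
  expect_error(period_from_frequency(0), class = "afmtopo_domain_error")
  expect_error(period_from_frequency(-1), class = "afmtopo_domain_error")
})

test_that("bandpass_surface keeps in-band structure and rejects out-of-band", {
  n <- 128
  px <- 6400 / n  # 8 on-grid cycles of the 800 nm period
  coord <- (seq_len(n) - 1) * px
  ctr <- (n - 1) * px / 2
  z <- outer(coord, coord, function(y, x) 25 * cos(2 * pi * (x - ctr) / 800))
  hm <- heightmap(z, px)
  inb <- bandpass_surface(hm, "order_I")
  expect_equal(inb$heights, z - mean(z), tolerance = 1e-6)
  out <- bandpass_surface(hm, "order_II")
  expect_lt(max(abs(out$heights)), 25 * 1e-9)
  # Parseval partition on white noise
  set.seed(3)
  wn <- heightmap(matrix(rnorm(n * n), n, n), px)
  v1 <- stats::var(as.vector(bandpass_surface(wn, "order_I")$heights))
  v2 <- stats::var(as.vector(bandpass_surface(wn, "order_II")$heights))
  vd <- stats::var(as.vector(detrend(wn)$heights))
  expect_lt(v1 + v2, vd)
  # band variance equals in-band 2-D spectral power
  zd <- detrend(wn$heights)
  co <- fft(zd) / (n * n)
  rad <- afmtopo:::fft_radial_freq(n, n, px)
  pw <- sum(Mod(co[rad >= 1 / 1200 - 1e-12 & rad <= 1 / 600 + 1e-12])^2)
  expect_equal(mean(bandpass_surface(wn, "order_I")$heights^2), pw,
               tolerance = 1e-6 * pw)
  expect_error(bandpass_surface(hm, spectral_window("x", 2, 10)),
               class = "afmtopo_window_error")
})

test_that("cell_patch_spectrum recovers planted roughness and scales", {
  sc <- make_scene(scene_params(seed = 31))
  ps <- cell_patch_spectrum(sc$map)
  s1 <- ps$summary[ps$summary$window == "order_I", ]
  expect_lt(abs(s1$S_max_nm2 - 1600) / 1600, 0.15)
  expect_lte(abs(1 / s1$L_max_nm - 0.001), 1 / 5000 + 1e-12)  # one bin
  # doubling all heights quadruples S_max in both windows
  dbl <- sc$map; dbl$heights <- 2 * dbl$heights
  ps2 <- cell_patch_spectrum(dbl)
  expect_equal(ps2$summary$S_max_nm2, 4 * ps$summary$S_max_nm2,
               tolerance = 1e-9)
  expect_equal(ps2$summary$L_max_nm, ps$summary$L_max_nm)
  # roughness-free dome: second-order intensity at the noise floor
  dome <- make_scene(scene_preset("control", band1_amplitude_nm = 0))
  psd <- cell_patch_spectrum(dome$map,
                             cell_mask = segment_cell(dome$map,
                                                      estimate_background(dome$map)))
  expect_lt(psd$summary$S_max_nm2[psd$summary$window == "order_II"], 5)
  # patch must fit
  tiny <- heightmap(matrix(rnorm(64), 8, 8), 10)
  expect_error(cell_patch_spectrum(tiny), class = "afmtopo_geometry_error")
})
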