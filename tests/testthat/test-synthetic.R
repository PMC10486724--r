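test_that("scene_params enforces its invariants", {
  expect_s3_class(scene_params(), "scene_params")
  expect_error(scene_params(grid_points = 32), class = "afmtopo_invalid_parameter")
  expect_error(scene_params(field_size_nm = -1), class = "afmtopo_invalid_parameter")
  expect_error(scene_params(n_lobes = 5), class = "afmtopo_invalid_parameter")
  expect_error(scene_params(fragment_size_mixture = list(
    list(weight = 0.6, mean_nm = 300, sd_nm = 50))),
    class = "afmtopo_invalid_parameter")
  # band periods must lie inside their windows when the band is enabled
  expect_error(scene_params(band1_period_nm = 500, band1_amplitude_nm = 10),
               class = "afmtopo_invalid_parameter")
  expect_error(scene_params(band2_period_nm = 400, band2_amplitude_nm = 1),
               class = "afmtopo_invalid_parameter")
  expect_s3_class(scene_params(band1_period_nm = 500, band1_amplitude_nm = 0),
                  "scene_params")
})

test_that("roughness fields are calibrated, band-limited and deterministic", {
  expect_true(all(make_roughness_field(64, 5000, 1000, 0, 1)$heights == 0))
  a <- make_roughness_field(256, 5000, 1000, 40, seed = 9)
  b <- make_roughness_field(256, 5000, 1000, 40, seed = 9)
  expect_identical(a$heights, b$heights)
  expect_equal(mean(a$heights), 0, tolerance = 1e-9)
  # profile spectrum peaks within one frequency bin of 1/period (DFT oracle)
  nus <- dft_oracle(a$heights[1, ], a$pixel_size_nm)$nu
  smat <- sapply(seq_len(256), function(i)
    dft_oracle(a$heights[i, ], a$pixel_size_nm)$S)
  sbar <- rowMeans(smat)
  nu_peak <- nus[which.max(sbar)]
  expect_lte(abs(nu_peak - 0.001), 1 / 5000 + 1e-12)
  expect_equal(max(sbar), 1600, tolerance = 0.15 * 1600)
  # Nyquist / field-size preconditions
  expect_error(make_roughness_field(64, 5000, 100, 10, 1),
               class = "afmtopo_invalid_parameter")
  expect_error(make_roughness_field(64, 5000, 3000, 10, 1),
               class = "afmtopo_invalid_parameter")
})

test_that("cell bodies honour height, diameter and lobe structure", {
  ctrl <- scene_preset("control")
  body <- make_cell_body(ctrl)
  expect_equal(max(body$heights), 1200, tolerance = 0.01 * 1200)
  # three lobes -> exactly three summits above half the lobe height
  # (0.5 nm scan tolerance suppresses floating-point micro-plateaus on the
  # analytically flat cap top; lobe summits rise nm-scale above neighbours)
  spread <- scene_preset("spread")
  b3 <- make_cell_body(spread)
  expect_equal(max(b3$heights), 638, tolerance = 0.01 * 638)
  expect_equal(local_maxima_scan(b3$heights, min_height = 638 / 2, tol = 0.1), 3)
  # zero height -> flat field
  expect_true(all(make_cell_body(scene_params(cell_height_nm = 0))$heights == 0))
  expect_error(make_cell_body(scene_params(cell_height_nm = 500,
                                           cell_diameter_nm = 4800,
                                           field_size_nm = 5000)),
               class = "afmtopo_invalid_parameter")
})

test_that("fragment scattering places exact, non-overlapping truth", {
  p0 <- scene_preset("fragment_section", n_fragments = 0L)
  empty <- scatter_fragments(p0)
  expect_true(all(empty$map$heights == 0))
  expect_identical(nrow(empty$fragments), 0L)

  p <- scene_preset("fragment_section", seed = 3)
  fr <- scatter_fragments(p)
  tr <- fr$fragments
  expect_identical(nrow(tr), 26L)
  d <- as.matrix(stats::dist(cbind(tr$center_x_nm, tr$center_y_nm)))
  sep <- outer(tr$diameter_nm / 2, tr$diameter_nm / 2, `+`)
  expect_true(all(d[upper.tri(d)] > sep[upper.tri(sep)]))
  expect_true(all(fr$map$heights >= 0))
  # rendered bumps match the truth one-to-one: local count equals n
  expect_equal(local_maxima_scan(fr$map$heights, min_height = 11), 26)
  # impossible packing reports the placed count
  err <- tryCatch(
    scatter_fragments(scene_params(
      grid_points = 64, field_size_nm = 3000, n_fragments = 40L,
      fragment_size_mixture = list(list(weight = 1, mean_nm = 900, sd_nm = 10)),
      seed = 2)),
    error = function(e) e)
  expect_s3_class(err, "afmtopo_placement_error")
  expect_true(is.numeric(err$placed) && err$placed < 40)
})

test_that("fragment sizes track the requested mixture over seeds", {
  sizes <- unlist(lapply(1:20, function(s)
    scatter_fragments(scene_preset("fragment_section", seed = s))$fragments$diameter_nm))
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 330), 3 * se)
  # two-component truth is recorded for modality recovery
  # 58 fragments of up to ~1 um need a larger region to stay non-overlapping
  bim <- scene_preset("fragment_section", seed = 5, field_size_nm = 12000,
                      fragment_size_mixture = list(
    list(weight = 0.5, mean_nm = 250, sd_nm = 60),
    list(weight = 0.5, mean_nm = 810, sd_nm = 120)), n_fragments = 58L)
  tr <- scatter_fragments(bim)$fragments
  expect_gt(mean(tr$diameter_nm), 350)  # both modes contribute
  expect_gt(max(tr$diameter_nm), 600)
  expect_lt(min(tr$diameter_nm), 400)
})

test_that("NET meshes draw granules from the stated normal, deterministically", {
  p <- scene_preset("granule_mesh")
  expect_true(all(make_net_mesh(scene_preset("granule_mesh",
                                             n_granule_chains = 0L))$map$heights == 0))
  sizes <- unlist(lapply(1:6, function(s)
    make_net_mesh(scene_preset("granule_mesh", seed = s))$granules$size_nm))
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 50), 3 * se)
  m1 <- make_net_mesh(scene_preset("granule_mesh", seed = 8))
  m2 <- make_net_mesh(scene_preset("granule_mesh", seed = 8))
  expect_identical(m1$granules, m2$granules)
  expect_identical(m1$map$heights, m2$map$heights)
  # granules below the resolvable size fail
  coarse <- scene_preset("granule_mesh", grid_points = 64L,
                         field_size_nm = 30000)
  expect_error(make_net_mesh(coarse), class = "afmtopo_invalid_parameter")
})

test_that("scenes are additive, deterministic and truth-labelled by the rule table", {
  p <- scene_preset("spread", seed = 21)
  sc <- make_scene(p)
  expect_equal(Reduce(`+`, sc$components), sc$map$heights, tolerance = 1e-12)
  sc2 <- make_scene(p)
  expect_identical(sc$map$heights, sc2$map$heights)
  # all amplitudes zero -> flat map, zero truth height
  flatp <- scene_params(cell_height_nm = 0, band1_amplitude_nm = 0,
                        band2_amplitude_nm = 0, substrate_noise_sd_nm = 0,
                        grid_points = 64L)
  flat <- make_scene(flatp)
  expect_true(all(flat$map$heights == 0))
  expect_identical(flat$truth$true_cell_height_nm, 0)
  expect_identical(flat$truth$true_type, "4")  # no intact cell body
  # rule table over the presets
  expect_identical(make_scene(scene_preset("control", seed = 2))$truth$true_type, "1")
  expect_identical(sc$truth$true_type, "2")
  expect_identical(make_scene(scene_preset("flat", seed = 2))$truth$true_type, "3")
  expect_identical(make_scene(scene_preset("netosis", seed = 2))$truth$true_type, "4")
  # control round trip: morphometry recovers the drawn height within 5%
  ctrl <- make_scene(scene_preset("control", seed = 13))
  m <- measure_cell(ctrl$map)
  expect_lt(abs(m$h_max_nm - 1200) / 1200, 0.05)
})

test_that("scene params and ground truth serialise round-trip", {
  dir <- withr::local_tempdir()
  p <- scene_preset("spread", seed = 77)
  write_scene_params(p, file.path(dir, "scene.yaml"))
  p2 <- read_scene_params(file.path(dir, "scene.yaml"))
  expect_equal(unclass(p2), unclass(p))
  sc <- make_scene(scene_preset("fragment_section", seed = 2))
  write_ground_truth(sc$truth, file.path(dir, "truth.json"))
  t2 <- read_ground_truth(file.path(dir, "truth.json"))
  expect_equal(t2$true_type, sc$truth$true_type)
  expect_equal(t2$fragments$diameter_nm, sc$truth$fragments$diameter_nm,
               tolerance = 1e-12)
  expect_equal(t2$band_periods_nm, sc$truth$band_periods_nm)
})
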