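test_that("background estimation is unbiased on flat noisy substrates", {
  levels <- sds <- numeric(20)
  for (s in 1:20) {
    bg <- estimate_background(noise_map(n = 64, sd = 1, seed = s))
    levels[s] <- bg$level_nm
    sds[s] <- bg$noise_sd_nm
  }
  expect_lt(max(abs(levels)), 0.2)
  expect_true(all(abs(sds - 1) < 0.2))
  # constant map: zero noise
  const <- heightmap(matrix(5, 16, 16), 10)
  bgc <- estimate_background(const)
  expect_equal(bgc$level_nm, 5)
  expect_equal(bgc$noise_sd_nm, 0)
  # dome on a flat substrate: level stays near the substrate
  sc <- make_scene(scene_preset("control", seed = 6))
  bgd <- estimate_background(sc$map)
  expect_lt(abs(bgd$level_nm), 3 * bgd$noise_sd_nm)
})

test_that("segmentation finds the main cell and flags secondary objects", {
  sc <- make_scene(scene_preset("control", seed = 9))
  bg <- estimate_background(sc$map)
  mask <- segment_cell(sc$map, bg)
  true_area <- pi * (sc$truth$true_diameter_nm / 2)^2
  est_area <- sum(mask) * sc$map$pixel_size_nm^2
  expect_lt(abs(est_area - true_area) / true_area, 0.10)
  # flat noise: nothing above threshold
  expect_error(segment_cell(noise_map(n = 64, sd = 1, seed = 2),
                            estimate_background(noise_map(n = 64, sd = 1, seed = 2))),
               class = "afmtopo_empty_scene")
  # two cells: the largest is selected, the other reported as secondary
  two <- sc$map
  small <- make_cell_body(scene_params(grid_points = 64L, field_size_nm = 7500,
                                       cell_height_nm = 600,
                                       cell_diameter_nm = 4000))
  two$heights[1:64, 1:64] <- two$heights[1:64, 1:64] + small$heights
  mask2 <- segment_cell(two, estimate_background(two))
  expect_gte(attr(mask2, "n_secondary"), 1L)
  expect_false(any(mask2[1:40, 1:40]))  # small dome not in the main mask
})

test_that("cell height and diameter recover ground truth and scale linearly", {
  hs <- ds <- numeric(5)
  for (s in 1:5) {
    sc <- make_scene(scene_preset("control", seed = s))
    m <- measure_cell(sc$map)
    hs[s] <- m$h_max_nm; ds[s] <- m$diameter_um
  }
  expect_lt(median(abs(hs - 1200) / 1200), 0.05)
  expect_lt(median(abs(ds - 9.8) / 9.8), 0.05)
  sp <- make_scene(scene_preset("spread", seed = 3))
  expect_lt(abs(measure_cell(sp$map)$h_max_nm - 638) / 638, 0.05)
  # doubling heights doubles h_max
  sc <- make_scene(scene_preset("control", seed = 2))
  bg <- estimate_background(sc$map)
  mask <- segment_cell(sc$map, bg)
  h1 <- cell_height(sc$map, mask, bg)
  dbl <- sc$map; dbl$heights <- 2 * dbl$heights
  bg2 <- estimate_background(dbl)
  expect_equal(cell_height(dbl, segment_cell(dbl, bg2), bg2), 2 * h1,
               tolerance = 0.02)
  expect_error(cell_height(sc$map, mask & FALSE, bg),
               class = "afmtopo_invalid_input")
})

test_that("equivalent-circle diameter follows closed-form arithmetic", {
  n <- 200
  ctr <- (n + 1) / 2
  disk <- outer(seq_len(n), seq_len(n),
                function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2) <= 4900 / 50)
  expect_equal(cell_diameter(disk, 50), 9.8, tolerance = 0.01)
  single <- matrix(FALSE, 4, 4); single[2, 2] <- TRUE
  expect_equal(cell_diameter(single, 10), 2 * sqrt(100 / pi) / 1000,
               tolerance = 1e-12)  # 0.0113 um
  # same disk sampled at half the pixel size keeps its physical diameter
  n2 <- 400; ctr2 <- (n2 + 1) / 2
  disk2 <- outer(seq_len(n2), seq_len(n2),
                 function(i, j) sqrt((i - ctr2)^2 + (j - ctr2)^2) <= 4900 / 25)
  expect_equal(cell_diameter(disk2, 25), cell_diameter(disk, 50),
               tolerance = 0.01)
  expect_error(cell_diameter(disk & FALSE, 50), class = "afmtopo_invalid_input")
})

test_that("lobe counting respects prominence rules", {
  sp <- make_scene(scene_preset("spread", seed = 4))
  bg <- estimate_background(sp$map)
  mask <- segment_cell(sp$map, bg)
  expect_equal(count_lobes(sp$map, mask, bg), 3L)
  # smooth dome counts a single summit
  ctrl <- make_scene(scene_preset("control", seed = 4))
  bgc <- estimate_background(ctrl$map)
  expect_equal(count_lobes(ctrl$map, segment_cell(ctrl$map, bgc), bgc), 1L)
  # lobes below the prominence floor are not counted
  low <- make_scene(scene_preset("spread", seed = 4, lobe_height_nm = 30))
  bgl <- estimate_background(low$map)
  expect_lt(count_lobes(low$map, segment_cell(low$map, bgl), bgl), 3L)
})

test_that("classification applies the type rules in order", {
  row <- function(h, d, lobes, sol) tibble::tibble(
    h_max_nm = h, diameter_um = d, n_lobes = lobes, solidity = sol)
  expect_identical(classify_type(row(1200, 9.8, 1, 0.9)), "1")
  expect_identical(classify_type(row(638, 16.7, 3, 0.9)), "2")
  expect_identical(classify_type(row(300, 16.7, 1, 0.9)), "3")
  expect_identical(classify_type(row(638, 16.7, 3, 0.4)), "4")  # fragmented
  expect_identical(classify_type(row(638, 16.7, 1, 0.9), mesh_present = TRUE), "4")
  expect_identical(classify_type(row(60, 1, 1, 0.9), particle_cover = 0.9), "4")
  expect_identical(classify_type(row(60, 1, 1, 0.9), particle_cover = 0), "3")
  expect_identical(classify_type(row(1500, 16, 1, 0.9)), "other")
})

test_that("measured types match generator truth across the presets", {
  for (preset in c("control", "spread", "flat", "netosis")) {
    sc <- make_scene(scene_preset(preset, seed = 11))
    m <- measure_cell(sc$map, mesh_present = sc$truth$mesh_present)
    expect_identical(m$type_label, sc$truth$true_type)
  }
})

test_that("type distributions are percentages that sum to 100", {
  td <- type_distribution(c("1", "1", "1", "2"), time_min = 0, activator = "A23187")
  expect_equal(td$fraction_pct[td$type_label == "1"], 75)
  expect_equal(td$fraction_pct[td$type_label == "2"], 25)
  expect_equal(sum(td$fraction_pct), 100)
  all4 <- type_distribution(rep("4", 7))
  expect_equal(all4$fraction_pct, 100)
  expect_error(type_distribution(character(0)), class = "afmtopo_invalid_input")
})

test_that("morphometrics are invariant to in-field translation", {
  sc <- make_scene(scene_preset("control", seed = 15))
  m0 <- measure_cell(sc$map)
  # roll the scene by a few pixels (cell stays fully inside the field)
  roll <- function(z, di, dj) {
    n <- nrow(z)
    z[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(n) - 1 - dj) %% n) + 1]
  }
  shifted <- sc$map
  shifted$heights <- roll(sc$map$heights, 7, -11)
  m1 <- measure_cell(shifted)
  expect_equal(m1$h_max_nm, m0$h_max_nm, tolerance = 1e-9)
  expect_equal(m1$diameter_um, m0$diameter_um, tolerance = 0.01)
  expect_identical(m1$n_lobes, m0$n_lobes)
  expect_identical(m1$type_label, m0$type_label)
})
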