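# Rosette generator and synthetic assay tables.

test_that("phyllotaxis azimuths follow the divergence angle", {
  p <- generate_rosette(plain_rosette_(7, blade_length = 0.05))
  az <- vapply(p$leaves, function(l) l$azimuth_deg, numeric(1))
  expect_equal(az, c(0, 137.5, 275, 52.5, 190, 327.5, 105), tolerance = 1e-9)
})

test_that("leaf areas are conserved and triangles non-degenerate", {
  p <- generate_preset_plant("14DAT", seed = 3)
  areas <- vapply(p$leaves, function(l) l$one_sided_area, numeric(1))
  expect_equal(p$total_leaf_area, sum(areas), tolerance = 1e-12)
  for (l in p$leaves) {
    ta <- uvcanopy:::tri_areas_(l$triangles)
    expect_true(all(ta > 0))
    expect_equal(l$one_sided_area, sum(ta), tolerance = 1e-9)
  }
  ranks <- vapply(p$leaves, function(l) l$rank, integer(1))
  expect_equal(sort(ranks), 1:7)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_preset_plant("28DAT", seed = 11)
  b <- generate_preset_plant("28DAT", seed = 11)
  expect_identical(a$leaves[[5]]$triangles, b$leaves[[5]]$triangles)
  c <- generate_preset_plant("28DAT", seed = 12)
  expect_false(identical(a$leaves[[5]]$triangles, c$leaves[[5]]$triangles))
})

test_that("position classes split youngest-to-oldest and validate counts", {
  p <- generate_rosette(plain_rosette_(7, blade_length = 0.05))
  p <- assign_position_classes(p, c(upper = 3L, middle = 2L, lower = 2L))
  cls <- vapply(p$leaves, function(l) l$position_class, character(1))
  # ranks 7,6,5 are youngest -> upper; 4,3 middle; 2,1 lower
  expect_equal(cls, c("lower", "lower", "middle", "middle",
                      "upper", "upper", "upper"))
  p10 <- generate_rosette(plain_rosette_(10, blade_length = 0.05))
  p10 <- assign_position_classes(p10, c(upper = 4L, middle = 3L, lower = 3L))
  expect_equal(sum(vapply(p10$leaves, function(l)
    l$position_class == "upper", logical(1))), 4L)
  # degenerate: all upper
  pu <- assign_position_classes(p, c(upper = 7L, middle = 0L, lower = 0L))
  expect_true(all(vapply(pu$leaves, function(l)
    l$position_class == "upper", logical(1))))
  expect_error(assign_position_classes(p, c(upper = 3L, middle = 2L,
                                            lower = 3L)), "sum")
})

test_that("presets match the stage class counts and plausible stand LAI", {
  p14 <- generate_preset_plant("14DAT")
  expect_length(p14$leaves, 7)
  expect_equal(table(vapply(p14$leaves, function(l) l$position_class,
                            character(1)))[c("upper", "middle", "lower")],
               c(upper = 3L, middle = 2L, lower = 2L), ignore_attr = TRUE)
  p28 <- generate_preset_plant("28DAT")
  expect_length(p28$leaves, 10)
  expect_equal(sum(vapply(p28$leaves, function(l)
    l$position_class == "upper", logical(1))), 4L)
  # stand-level leaf area index near the two study densities
  expect_equal(leaf_area_index(canopy_scene("14DAT", seed = 2)), 0.40,
               tolerance = 0.1)
  expect_equal(leaf_area_index(canopy_scene("28DAT", seed = 2)), 1.60,
               tolerance = 0.1)
})

test_that("parameter validation rejects impossible rosettes", {
  expect_error(rosette_params(0), "n_leaves")
  expect_error(rosette_params(3, blade_length = -0.1), "blade")
  expect_error(rosette_params(3, elevation_deg = 120), "elevation")
})

make_uv_table_ <- function(n_per_class = 10, max_uv = 60) {
  cls <- rep(c("upper", "middle", "lower"), each = n_per_class)
  data.frame(plant_id = 1L, leaf_id = seq_along(cls), position_class = cls,
             treatment = "3 d 12 h",
             cumulative_absorbed_uv = seq(1, max_uv,
                                          length.out = length(cls)))
}

test_that("zero-noise flat response returns exactly the control values", {
  uv <- make_uv_table_()
  ctrl <- list(TPC = c(upper = 6, middle = 5, lower = 4),
               TFC = c(upper = 2, middle = 1.8, lower = 1.5),
               RSA = c(upper = 50, middle = 45, lower = 40))
  out <- generate_assay_data(uv, yield_model = list(TPC = NULL, TFC = NULL,
                                                    RSA = NULL),
                             control_concentration = ctrl,
                             noise_sd = c(TPC = 0, TFC = 0, RSA = 0))
  expect_equal(out$TPC, unname(ctrl$TPC[out$position_class]))
  expect_equal(out$TFC, unname(ctrl$TFC[out$position_class]))
  # control rows were appended with zero dose
  expect_true(any(out$treatment == "control"))
  expect_true(all(out$cumulative_absorbed_uv[out$treatment == "control"] == 0))
})

test_that("zero-noise linear response round-trips through the linear fitter", {
  uv <- make_uv_table_()
  g <- 0.8  # percent increase per kJ m-2
  ctrl <- list(TPC = c(upper = 100, middle = 100, lower = 100),
               TFC = c(upper = 100, middle = 100, lower = 100),
               RSA = c(upper = 10, middle = 10, lower = 10))
  out <- generate_assay_data(
    uv, yield_model = list(TPC = list(form = "linear", a = g, b = 0),
                           TFC = NULL, RSA = NULL),
    control_concentration = ctrl, noise_sd = c(TPC = 0, TFC = 0, RSA = 0))
  fit <- fit_linear_yield(out$cumulative_absorbed_uv, out$TPC)
  # control = 100, so slope in concentration units equals g exactly
  expect_equal(fit$slope, g, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("hyperbolic generating parameters are recovered from noisy data", {
  ctrl <- list(TPC = c(upper = 100, middle = 100, lower = 100),
               TFC = c(upper = 100, middle = 100, lower = 100),
               RSA = c(upper = 10, middle = 10, lower = 10))
  a <- 60; b <- 20
  est <- sapply(1:3, function(seed) {
    uv <- make_uv_table_(n_per_class = 67, max_uv = 120)  # ~200 leaves
    out <- generate_assay_data(
      uv, yield_model = list(TPC = list(form = "F2", a = a, b = b),
                             TFC = NULL, RSA = NULL),
      control_concentration = ctrl,
      noise_sd = c(TPC = 2, TFC = 0, RSA = 0), rng_seed = seed)
    treated <- out[out$treatment != "control", ]
    rate <- increase_rate(treated$TPC, 100)
    f <- fit_hyperbolic(treated$cumulative_absorbed_uv, rate, form = "F2")
    c(f$a, f$b)
  })
  expect_lt(abs(median(est[1, ]) - a) / a, 0.10)
  expect_lt(abs(median(est[2, ]) - b) / b, 0.10)
})

test_that("assay generator validates inputs and is seed-deterministic", {
  uv <- make_uv_table_()
  ctrl <- list(TPC = c(upper = 6, middle = 5, lower = 4),
               TFC = c(upper = 2, middle = 2, lower = 2),
               RSA = c(upper = 50, middle = 50, lower = 50))
  expect_error(generate_assay_data(uv, list(TPC = NULL, TFC = NULL,
                                            RSA = NULL), ctrl,
                                   noise_sd = c(TPC = -1)), "noise_sd")
  a <- generate_assay_data(uv, list(TPC = NULL, TFC = NULL, RSA = NULL),
                           ctrl, noise_sd = c(TPC = 1, TFC = 1, RSA = 1),
                           rng_seed = 42)
  b <- generate_assay_data(uv, list(TPC = NULL, TFC = NULL, RSA = NULL),
                           ctrl, noise_sd = c(TPC = 1, TFC = 1, RSA = 1),
                           rng_seed = 42)
  expect_identical(a, b)
  expect_true(all(a$TPC >= 0) && all(a$RSA <= 100))
})
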