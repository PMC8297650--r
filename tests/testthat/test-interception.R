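# Aggregation: position summaries, vertical profiles, LAI, cumulative UV.

mock_result_ <- function(flux, class, z = NULL, area = NULL) {
  n <- length(flux)
  if (is.null(z)) z <- seq(0.01, 0.1, length.out = n)
  if (is.null(area)) area <- rep(1e-3, n)
  surf <- data.frame(surface = seq_len(n), kind = "leaf", plant_id = 1L,
                     leaf_id = seq_len(n), rank = seq_len(n),
                     position_class = class, area_m2 = area,
                     centroid_z = z, optics_key = paste0("leaf_", class),
                     absorbed_W = flux * area, mc_se_W = 0,
                     flux_W_m2 = flux, flux_se_W_m2 = 0,
                     flux_umol_m2_s = NA_real_)
  structure(list(surfaces = surf, emitted_W = sum(flux * area),
                 absorbed_total_W = sum(flux * area), escaped_W = 0,
                 n_rays = 1, band = "UV",
                 config = trace_config(1, 0, 1)),
            class = "interception_result")
}

test_that("uniform flux gives equal class means and zero percent differences", {
  r <- mock_result_(rep(2.5, 6), rep(c("upper", "middle", "lower"), 2))
  s <- summarize_by_position(r)
  expect_equal(s$by_class$mean_flux_W_m2, rep(2.5, 3))
  expect_equal(unname(s$percent_above), c(0, 0))
})

test_that("percent difference convention is (upper - x) / x * 100", {
  r <- mock_result_(c(2, 2, 1, 1), c("upper", "upper", "lower", "lower"))
  s <- summarize_by_position(r)
  expect_equal(unname(s$percent_above["lower"]), 100)
})

test_that("vertical profile bins by centroid height and aggregates", {
  r <- mock_result_(c(1, 2, 3), rep("upper", 3), z = c(0.01, 0.05, 0.09))
  p1 <- vertical_profile(r, n_bins = 3)
  expect_equal(p1$mean_flux_W_m2, c(1, 2, 3))
  # single bin equals the overall mean
  p0 <- vertical_profile(r, n_bins = 1)
  expect_equal(p0$mean_flux_W_m2, 2)
  # one leaf occupies exactly one bin
  r1 <- mock_result_(5, "upper", z = 0.05)
  p <- vertical_profile(r1, n_bins = 4)
  expect_equal(sum(p$n), 1)
  expect_equal(p$mean_flux_W_m2[p$n == 1], 5)
})

test_that("overhead-lit canopy profiles decrease from top to bottom", {
  ok <- 0
  for (seed in 1:5) {
    sc <- canopy_scene("28DAT", seed = 300 + seed)
    r <- trace(sc, "UV", trace_config(5e4, 10, seed))
    p <- vertical_profile(r, n_bins = 3)
    f <- p$mean_flux_W_m2[p$n > 0]
    ok <- ok + all(diff(f) >= 0)  # bins are bottom-to-top
  }
  expect_gte(ok, 4)
})

test_that("leaf area index is total leaf area over bed area", {
  expect_equal(leaf_area_index(list(), 0.4), 0)
  p <- plate_plant_(0.4, 0.4, 0.05)  # 0.16 m2
  expect_equal(leaf_area_index(list(p, p, p, p), 0.4), 1.6)
  expect_equal(leaf_area_index(list(p, p), 0.4),
               leaf_area_index(list(p), 0.4) * 2)
  expect_error(leaf_area_index(list(p), 0), "positive")
})

test_that("cumulative absorbed UV integrates flux over the schedule", {
  r <- mock_result_(0.5, "upper", z = 0.05)
  uv <- cumulative_absorbed_uv(r, exposure_schedule(12, 3))
  expect_equal(uv$cumulative_absorbed_uv, 64.8)
  uv0 <- cumulative_absorbed_uv(r, exposure_schedule(12, 0))
  expect_equal(uv0$cumulative_absorbed_uv, 0)
  # proportional to hours x days across the six-treatment grid
  vals <- vapply(treatment_grid(), function(s)
    cumulative_absorbed_uv(r, s)$cumulative_absorbed_uv, numeric(1))
  hd <- vapply(treatment_grid(), function(s)
    s$hours_per_day * s$n_days, numeric(1))
  expect_equal(unname(vals / hd), rep(0.5 * 3.6, 6))
  # invariant under splitting a schedule into sub-schedules
  split2 <- cumulative_absorbed_uv(r, exposure_schedule(12, 1))$cumulative_absorbed_uv +
    cumulative_absorbed_uv(r, exposure_schedule(12, 2))$cumulative_absorbed_uv
  expect_equal(split2, uv$cumulative_absorbed_uv)
})

test_that("class means reconstruct the area-weighted canopy mean", {
  sc <- canopy_scene("14DAT", seed = 77, n_plants = 3)
  r <- trace(sc, "UV", trace_config(3e4, 10, 9))
  lf <- r$surfaces[r$surfaces$kind == "leaf", ]
  canopy_mean <- sum(lf$flux_W_m2 * lf$area_m2) / sum(lf$area_m2)
  parts <- vapply(split(lf, lf$position_class), function(g)
    sum(g$flux_W_m2 * g$area_m2), numeric(1))
  expect_equal(sum(parts) / sum(lf$area_m2), canopy_mean, tolerance = 1e-12)
})
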