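# Aggregation of trace output: per-position means, vertical profiles, leaf
# area index, and per-leaf cumulative absorbed UV over a treatment schedule.

leaf_surfaces_ <- function(result) {
  stopifnot(inherits(result, "interception_result"))
  result$surfaces[result$surfaces$kind == "leaf", , drop = FALSE]
}

#' Mean absorbed flux by leaf position class
#'
#' Class means and standard errors of absorbed flux density across leaves,
#' plus pairwise percent differences of the upper-class mean over each other
#' class (`(upper - x) / x * 100`).
#'
#' @param result an `interception_result` from [trace()].
#' @return List with `by_class` (data.frame: position_class, mean/se flux,
#'   n) and `percent_above` (named numeric: how much the upper mean exceeds
#'   each other class, %).
#' @export
summarize_by_position <- function(result) {
  lf <- leaf_surfaces_(result)
  if (any(is.na(lf$position_class))) stop("leaves without position class")
  cls <- c("upper", "middle", "lower")
  present <- cls[cls %in% lf$position_class]
  by_class <- do.call(rbind, lapply(present, function(cl) {
    x <- lf$flux_W_m2[lf$position_class == cl]
    data.frame(position_class = cl, mean_flux_W_m2 = mean(x),
               se_flux_W_m2 = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
               n = length(x))
  }))
  pa <- NULL
  if ("upper" %in% present) {
    up <- by_class$mean_flux_W_m2[by_class$position_class == "upper"]
    others <- setdiff(present, "upper")
    pa <- vapply(others, function(cl) {
      m <- by_class$mean_flux_W_m2[by_class$position_class == cl]
      (up - m) / m * 100
    }, numeric(1))
  }
  list(by_class = by_class, percent_above = pa, band = result$band)
}

#' Vertical profile of absorbed flux
#'
#' Bins leaves by the area-weighted centroid height of their triangles and
#' reports the mean absorbed flux density per height bin.
#'
#' @param result an `interception_result`.
#' @param n_bins number of equal-width height bins, >= 1.
#' @return data.frame with `bin_centre_m`, `mean_flux_W_m2`, `n`.
#' @export
vertical_profile <- function(result, n_bins = 5) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  lf <- leaf_surfaces_(result)
  z <- lf$centroid_z
  brks <- seq(min(z) - 1e-12, max(z) + 1e-12, length.out = n_bins + 1)
  idx <- cut(z, brks, labels = FALSE)
  centres <- (head(brks, -1) + tail(brks, -1)) / 2
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- idx == b
    data.frame(bin_centre_m = centres[b],
               mean_flux_W_m2 = if (any(sel)) mean(lf$flux_W_m2[sel]) else NA_real_,
               n = sum(sel))
  }))
  out
}

#' Leaf area index of a stand
#'
#' Total one-sided leaf area per unit bed area (m2 m-2).
#'
#' @param plants list of `plant_model` objects (or a `uv_scene`).
#' @param bed_area bed area in m2, > 0; taken from the scene when `plants`
#'   is a scene.
#' @return Dimensionless LAI.
#' @export
leaf_area_index <- function(plants, bed_area = NULL) {
  if (inherits(plants, "uv_scene")) {
    if (is.null(bed_area)) bed_area <- plants$bed$w * plants$bed$l
    plants <- plants$plants
  }
  if (is.null(bed_area) || bed_area <= 0) stop("bed_area must be positive")
  if (length(plants) == 0) return(0)
  sum(vapply(plants, function(p) p$total_leaf_area, numeric(1))) / bed_area
}

#' Per-leaf cumulative absorbed UV over a schedule
#'
#' Integrates each leaf's absorbed UV flux density over the exposure
#' schedule: `deltaUV = flux x hours_per_day x 3600 x n_days / 1000`
#' (kJ m-2); linear in the total exposure time.
#'
#' @param result an `interception_result` traced in the UV band.
#' @param schedule an [exposure_schedule()].
#' @return data.frame with `plant_id`, `leaf_id`, `position_class`,
#'   `treatment` (the schedule label) and `cumulative_absorbed_uv` (kJ m-2).
#' @export
cumulative_absorbed_uv <- function(result, schedule) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  lf <- leaf_surfaces_(result)
  secs <- schedule$hours_per_day * 3600 * schedule$n_days
  data.frame(plant_id = lf$plant_id, leaf_id = lf$leaf_id,
             position_class = lf$position_class,
             treatment = schedule$label,
             cumulative_absorbed_uv = lf$flux_W_m2 * secs / 1000)
}

#' Write a per-position tally table as CSV
#'
#' Mirrors the layout of the interception figures: one row per surface with
#' band, absorbed power, area, flux and Monte Carlo SE.
#'
#' @param result an `interception_result`.
#' @param path file path.
#' @export
write_tally_csv <- function(result, path) {
  lf <- leaf_surfaces_(result)
  out <- data.frame(plant_id = lf$plant_id, leaf_id = lf$leaf_id,
                    position_class = lf$position_class, band = result$band,
                    absorbed_W = lf$absorbed_W, area_m2 = lf$area_m2,
                    flux_W_m2 = lf$flux_W_m2,
                    flux_umol_m2_s = lf$flux_umol_m2_s,
                    mc_se_W = lf$mc_se_W)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
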