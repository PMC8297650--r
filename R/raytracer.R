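# R surface of the Monte Carlo transport engine plus the deterministic
# view-factor oracle used to validate it.

#' Trace configuration
#'
#' @param n_rays number of rays, >= 1.
#' @param max_bounces maximum surface interactions per ray before the ray is
#'   tallied as escaped (default 10).
#' @param seed integer RNG seed; tallies are bit-reproducible given the seed.
#' @return A `trace_config` object.
#' @export
trace_config <- function(n_rays = 1e5, max_bounces = 10L, seed = 1L) {
  if (n_rays < 1) stop("n_rays must be >= 1")
  if (max_bounces < 0) stop("max_bounces must be >= 0")
  structure(list(n_rays = n_rays, max_bounces = as.integer(max_bounces),
                 seed = as.integer(seed)), class = "trace_config")
}

#' Monte Carlo canopy light interception
#'
#' Launches rays from the scene's LED bars (uniform over the emitting faces,
#' cosine-weighted directions), follows them through nearest-triangle
#' intersections (BVH-accelerated), and samples one interaction per hit:
#' absorption with probability alpha, diffuse reflection with probability
#' rho, diffuse transmission with probability tau. Per-leaf absorbed power
#' is `emitted power x (absorbed hits on leaf / n_rays)`; the energy balance
#' emitted = absorbed + escaped holds exactly because every ray's weight
#' lands in exactly one bin.
#'
#' @param scene a `uv_scene` from [build_scene()].
#' @param band_name `"PAR"` or `"UV"`: selects source powers and surface
#'   optics for that band.
#' @param config a [trace_config()].
#' @return An `interception_result`: list with `surfaces` (data.frame with
#'   per-surface absorbed power, flux density, photon flux for PAR, and
#'   Monte Carlo SE), `emitted_W`, `absorbed_total_W`, `escaped_W`, `band`,
#'   `config`.
#' @export
trace <- function(scene, band_name = "PAR", config = trace_config()) {
  stopifnot(inherits(scene, "uv_scene"), inherits(config, "trace_config"))
  if (!band_name %in% names(scene$optics))
    stop("scene has no optics for band ", band_name)
  geo <- scene_geometry_(scene)
  keys <- geo$surfaces$optics_key
  opt <- scene$optics[[band_name]]
  missing_keys <- setdiff(unique(keys), names(opt))
  if (length(missing_keys) > 0)
    stop("missing optics for: ", paste(missing_keys, collapse = ", "))
  om <- t(vapply(keys, function(k) {
    o <- opt[[k]]
    c(o$rho, o$tau, o$alpha)
  }, numeric(3)))
  src <- t(vapply(scene$sources, function(s) {
    p <- if (band_name %in% names(s$power)) s$power[[band_name]] else 0
    c(s$x, s$y, s$z, s$width, s$length, p)
  }, numeric(6)))
  res <- .trace_cpp(geo$tri, as.integer(geo$tri_surface), om, src,
                    config$n_rays, config$max_bounces,
                    as.numeric(config$seed))
  surf <- geo$surfaces
  surf$absorbed_W <- res$absorbed_W
  surf$mc_se_W <- res$mc_se
  surf$flux_W_m2 <- surf$absorbed_W / surf$area_m2
  surf$flux_se_W_m2 <- surf$mc_se_W / surf$area_m2
  surf$flux_umol_m2_s <- if (band_name == "PAR")
    photon_flux(surf$flux_W_m2, 550) else NA_real_
  structure(list(surfaces = surf, emitted_W = res$emitted_W,
                 absorbed_total_W = res$absorbed_total_W,
                 escaped_W = res$escaped_W, n_rays = res$n_rays,
                 band = band_name, config = config),
            class = "interception_result")
}

#' Energy-balance report for a trace
#'
#' Checks that emitted power equals absorbed plus escaped power and that no
#' tally is negative.
#'
#' @param result an `interception_result`.
#' @param tol relative tolerance on the balance residual.
#' @return List with `residual_W`, `relative_residual`, `negative_tallies`,
#'   `ok`.
#' @export
check_conservation <- function(result, tol = 1e-9) {
  stopifnot(inherits(result, "interception_result"))
  resid <- result$emitted_W - result$absorbed_total_W - result$escaped_W
  rel <- if (result$emitted_W > 0) abs(resid) / result$emitted_W else abs(resid)
  neg <- sum(result$surfaces$absorbed_W < 0)
  list(residual_W = resid, relative_residual = rel, negative_tallies = neg,
       ok = rel <= tol && neg == 0L)
}

#' Deterministic plate irradiance under a Lambertian rectangle
#'
#' Numerical view-factor integration: irradiance at a point below a
#' horizontal rectangular Lambertian emitter is
#' `E(p) = integral_source L cos(theta_s) cos(theta_r) / d^2 dA`, with
#' radiance `L = P / (pi A_source)`. For a receiver plate, the point value
#' is averaged over the plate with a tensor Gauss-Legendre rule. Supports
#' horizontal source and horizontal receiver (parallel planes). Serves as
#' the independent oracle for [trace()].
#'
#' @param source a [light_bar()] (power taken from `power[[band_name]]`).
#' @param band_name band whose power to use, default `"PAR"`.
#' @param point numeric `c(x, y, z)` receiver point, or NULL when `plate`
#'   is given.
#' @param plate list `(x, y, z, width, length)` of a horizontal receiver
#'   plate to average over.
#' @param n_quad Gauss-Legendre nodes per dimension.
#' @return Irradiance in W m-2.
#' @export
analytic_plate_irradiance <- function(source, band_name = "PAR",
                                      point = NULL, plate = NULL,
                                      n_quad = 48) {
  stopifnot(inherits(source, "light_bar"))
  P <- source$power[[band_name]]
  A <- source$width * source$length
  L <- P / (pi * A)  # Lambertian radiance
  gx <- pracma::gaussLegendre(n_quad, source$x - source$width / 2,
                              source$x + source$width / 2)
  gy <- pracma::gaussLegendre(n_quad, source$y - source$length / 2,
                              source$y + source$length / 2)
  point_irr <- function(px, py, pz) {
    dz <- source$z - pz
    if (dz <= 0) stop("receiver must lie below the source")
    sx <- outer(gx$x, rep(1, n_quad))
    sy <- outer(rep(1, n_quad), gy$x)
    d2 <- (sx - px)^2 + (sy - py)^2 + dz^2
    integrand <- L * dz^2 / d2^2   # cos_s * cos_r / d^2 = dz^2 / d^4
    as.numeric(t(gx$w) %*% integrand %*% gy$w)
  }
  if (!is.null(point)) {
    return(point_irr(point[1], point[2], point[3]))
  }
  if (is.null(plate)) stop("give either point or plate")
  rx <- pracma::gaussLegendre(n_quad, plate$x - plate$width / 2,
                              plate$x + plate$width / 2)
  ry <- pracma::gaussLegendre(n_quad, plate$y - plate$length / 2,
                              plate$y + plate$length / 2)
  acc <- 0
  for (i in seq_len(n_quad)) for (j in seq_len(n_quad)) {
    acc <- acc + rx$w[i] * ry$w[j] * point_irr(rx$x[i], ry$x[j], plate$z)
  }
  acc / (plate$width * plate$length)
}

#' Single horizontal plate test scene
#'
#' A bare absorbing plate (a one-leaf "plant" made of two triangles) centred
#' below a small Lambertian emitter, with no bed. Used to validate the
#' tracer against [analytic_plate_irradiance()].
#'
#' @param plate_w,plate_l plate extents (m).
#' @param plate_z plate height (m).
#' @param source a [light_bar()].
#' @param absorptance plate absorptance (reflectance fills the remainder,
#'   transmittance 0).
#' @return A `uv_scene` whose only leaf is the plate.
#' @export
plate_scene <- function(plate_w = 0.1, plate_l = 0.1, plate_z = 0,
                        source = light_bar(0, 0, 0.3, 0.02, 0.02,
                                           c(PAR = 1.0, UV = 1.0)),
                        absorptance = 1) {
  w2 <- plate_w / 2
  l2 <- plate_l / 2
  tri <- rbind(c(-w2, -l2, plate_z, w2, -l2, plate_z, w2, l2, plate_z),
               c(-w2, -l2, plate_z, w2, l2, plate_z, -w2, l2, plate_z))
  leaf <- structure(list(leaf_id = 1L, rank = 1L, position_class = "upper",
                         triangles = tri, one_sided_area = plate_w * plate_l,
                         azimuth_deg = NA_real_, elevation_deg = NA_real_),
                    class = "leaf_mesh")
  plant <- structure(list(plant_id = 1L, leaves = list(leaf),
                          height = plate_z, total_leaf_area = plate_w * plate_l),
                     class = "plant_model")
  op <- optical_properties(1 - absorptance, 0)
  optics <- list(PAR = list(leaf_upper = op,
                            bed = optical_properties(0, 0)),
                 UV = list(leaf_upper = op,
                           bed = optical_properties(0, 0)))
  # bed far below and tiny so it never intercepts: use transmitting bed
  build_scene(list(plant), layout = data.frame(x = 0, y = 0),
              bed_w = 1e-6, bed_l = 1e-6, sources = list(source),
              optics = optics)
}
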