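# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

# A horizontal rectangular plate as a one-leaf plant (triangle pair).
plate_plant_ <- function(w, l, z, leaf_id = 1L, rank = 1L,
                         class = "upper", x0 = 0, y0 = 0) {
  w2 <- w / 2
  l2 <- l / 2
  tri <- rbind(c(x0 - w2, y0 - l2, z, x0 + w2, y0 - l2, z, x0 + w2, y0 + l2, z),
               c(x0 - w2, y0 - l2, z, x0 + w2, y0 + l2, z, x0 - w2, y0 + l2, z))
  leaf <- structure(list(leaf_id = leaf_id, rank = rank,
                         position_class = class, triangles = tri,
                         one_sided_area = w * l, azimuth_deg = NA_real_,
                         elevation_deg = NA_real_), class = "leaf_mesh")
  structure(list(plant_id = 1L, leaves = list(leaf), height = z,
                 total_leaf_area = w * l), class = "plant_model")
}

# Two stacked plates (one plant, two leaves): opaque upper, absorbing lower.
stacked_plates_scene_ <- function(upper_w = 1.0, lower_w = 0.1,
                                  z_upper = 0.2, z_lower = 0.1,
                                  source_z = 0.5) {
  up <- plate_plant_(upper_w, upper_w, z_upper)$leaves[[1]]
  up$leaf_id <- 2L; up$rank <- 2L; up$position_class <- "upper"
  lo <- plate_plant_(lower_w, lower_w, z_lower)$leaves[[1]]
  lo$leaf_id <- 1L; lo$rank <- 1L; lo$position_class <- "lower"
  plant <- structure(list(plant_id = 1L, leaves = list(lo, up),
                          height = z_upper,
                          total_leaf_area = up$one_sided_area + lo$one_sided_area),
                     class = "plant_model")
  opaque <- optical_properties(0, 0)  # alpha = 1
  optics <- list(UV = list(leaf_upper = opaque, leaf_lower = opaque,
                           bed = optical_properties(0, 0)))
  src <- light_bar(0, 0, source_z, 0.02, 0.02, c(UV = 1.0))
  build_scene(list(plant), layout = data.frame(x = 0, y = 0),
              bed_w = 1e-6, bed_l = 1e-6, sources = list(src),
              optics = optics)
}

# Closed-form OLS via the normal equations (independent of lm).
ols_oracle_ <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = r2)
}

# Jitter-free rosette parameters for deterministic geometry checks.
plain_rosette_ <- function(n_leaves, ...) {
  rosette_params(n_leaves, azimuth_jitter_deg = 0, elevation_jitter_deg = 0,
                 size_jitter_frac = 0, ...)
}
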