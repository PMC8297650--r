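# Synthetic 3D rosette plants (spiral phyllotaxis) and synthetic per-leaf
# assay tables with linear-in-absorbed-UV structure.  These stand in for 3D
# scans and wet-lab assays so the whole pipeline is testable from code.

with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

tri_areas_ <- function(tri) {
  # tri: n x 9 matrix of (v0, v1, v2) coordinates
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Rosette generation parameters
#'
#' Parameters of the synthetic spiral-phyllotaxis rosette. Per-leaf vectors
#' (`blade_length`, `blade_width`, `elevation_deg`) are recycled to
#' `n_leaves`; leaves are indexed by rank, rank 1 being the oldest (lowest)
#' leaf.
#'
#' @param n_leaves number of leaves, >= 1.
#' @param divergence_angle successive-leaf azimuth step in degrees
#'   (default 137.5, spiral phyllotaxis).
#' @param blade_length,blade_width blade ellipse axes (m), > 0.
#' @param elevation_deg blade pitch above horizontal, in `[0, 90]` degrees.
#' @param internode rise in attachment height per rank (m).
#' @param petiole distance from the stem axis to the blade base (m).
#' @param bend fractional tip droop (blade tip drops `bend * blade_length`
#'   below the blade plane, quadratically).
#' @param n_segments boundary segments of the triangulated blade ellipse.
#' @param azimuth_jitter_deg,elevation_jitter_deg,size_jitter_frac Gaussian
#'   jitter applied per leaf (0 disables).
#' @param rng_seed integer seed; generation is reproducible given the seed.
#' @return A `rosette_params` list.
#' @export
rosette_params <- function(n_leaves, divergence_angle = 137.5,
                           blade_length = 0.05, blade_width = NULL,
                           elevation_deg = 20, internode = 0.008,
                           petiole = 0.02, bend = 0.25, n_segments = 24,
                           azimuth_jitter_deg = 6, elevation_jitter_deg = 3,
                           size_jitter_frac = 0.03, rng_seed = 1L) {
  if (n_leaves < 1) stop("n_leaves must be >= 1")
  if (is.null(blade_width)) blade_width <- 0.45 * blade_length
  if (any(blade_length <= 0) || any(blade_width <= 0))
    stop("blade dimensions must be positive")
  if (any(elevation_deg < 0) || any(elevation_deg > 90))
    stop("elevation must be in [0, 90] degrees")
  structure(list(
    n_leaves = as.integer(n_leaves), divergence_angle = divergence_angle,
    blade_length = rep_len(blade_length, n_leaves),
    blade_width = rep_len(blade_width, n_leaves),
    elevation_deg = rep_len(elevation_deg, n_leaves),
    internode = internode, petiole = petiole, bend = bend,
    n_segments = as.integer(n_segments),
    azimuth_jitter_deg = azimuth_jitter_deg,
    elevation_jitter_deg = elevation_jitter_deg,
    size_jitter_frac = size_jitter_frac,
    rng_seed = as.integer(rng_seed)), class = "rosette_params")
}

make_leaf_mesh_ <- function(leaf_id, rank, azimuth_deg, elevation_deg,
                            base_z, blade_length, blade_width, petiole,
                            bend, n_segments) {
  L <- blade_length; W <- blade_width
  cx <- petiole + L / 2
  th <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  bx <- cx + (L / 2) * cos(th)
  by <- (W / 2) * sin(th)
  px <- c(cx, bx)   # vertex 1 = blade centre, then boundary
  py <- c(0, by)
  u <- pmax(0, (px - petiole) / L)
  pz <- -bend * L * u^2
  e <- elevation_deg * pi / 180
  x1 <- px * cos(e) - pz * sin(e)
  z1 <- px * sin(e) + pz * cos(e)
  a <- azimuth_deg * pi / 180
  x2 <- x1 * cos(a) - py * sin(a)
  y2 <- x1 * sin(a) + py * cos(a)
  z2 <- z1 + base_z
  v <- cbind(x2, y2, z2)
  j <- 2:(n_segments + 1)
  k <- c(3:(n_segments + 1), 2)
  tri <- cbind(v[rep(1, n_segments), , drop = FALSE], v[j, , drop = FALSE],
               v[k, , drop = FALSE])
  dimnames(tri) <- NULL
  areas <- tri_areas_(tri)
  structure(list(leaf_id = as.integer(leaf_id), rank = as.integer(rank),
                 position_class = NA_character_, triangles = tri,
                 one_sided_area = sum(areas), azimuth_deg = azimuth_deg,
                 elevation_deg = elevation_deg), class = "leaf_mesh")
}

#' Generate a synthetic rosette plant
#'
#' Builds a spiral-phyllotaxis rosette: leaf of rank k sits at azimuth
#' `(k - 1) * divergence_angle` (plus jitter), attaches at height
#' `(k - 1) * internode`, and carries a triangulated, gently drooping
#' elliptical blade. Deterministic for a fixed `rng_seed`.
#'
#' @param params a [rosette_params()].
#' @param plant_id integer id recorded on the plant.
#' @return A `plant_model`: list with `plant_id`, `leaves` (list of
#'   `leaf_mesh`), `height` (m), `total_leaf_area` (m2).
#' @export
generate_rosette <- function(params, plant_id = 1L) {
  stopifnot(inherits(params, "rosette_params"))
  n <- params$n_leaves
  with_seed_(params$rng_seed, {
    az_j <- rnorm(n, 0, params$azimuth_jitter_deg)
    el_j <- rnorm(n, 0, params$elevation_jitter_deg)
    sz_j <- 1 + rnorm(n, 0, params$size_jitter_frac)
  })
  sz_j <- pmax(sz_j, 0.5)
  leaves <- vector("list", n)
  for (k in seq_len(n)) {
    az <- ((k - 1) * params$divergence_angle) %% 360 + az_j[k]
    el <- min(max(params$elevation_deg[k] + el_j[k], 0), 90)
    leaves[[k]] <- make_leaf_mesh_(
      leaf_id = k, rank = k, azimuth_deg = az, elevation_deg = el,
      base_z = (k - 1) * params$internode,
      blade_length = params$blade_length[k] * sz_j[k],
      blade_width = params$blade_width[k] * sz_j[k],
      petiole = params$petiole, bend = params$bend,
      n_segments = params$n_segments)
  }
  zmax <- max(vapply(leaves, function(l) max(l$triangles[, c(3, 6, 9)]),
                     numeric(1)))
  structure(list(plant_id = as.integer(plant_id), leaves = leaves,
                 height = zmax,
                 total_leaf_area = sum(vapply(leaves, function(l)
                   l$one_sided_area, numeric(1)))),
            class = "plant_model")
}

#' Label leaves by canopy position
#'
#' Splits the leaves of a plant into upper / middle / lower position classes
#' in rank order from youngest to oldest: the `counts["upper"]`
#' highest-ranked (youngest) leaves are upper, the next block middle, the
#' oldest leaves lower.
#'
#' @param plant a `plant_model`.
#' @param counts named integer vector `c(upper = , middle = , lower = )`
#'   summing to the number of leaves.
#' @return The plant with `position_class` set on every leaf.
#' @export
assign_position_classes <- function(plant, counts) {
  stopifnot(inherits(plant, "plant_model"))
  counts <- counts[c("upper", "middle", "lower")]
  if (anyNA(counts)) stop("counts must be named upper/middle/lower")
  n <- length(plant$leaves)
  if (sum(counts) != n)
    stop(sprintf("class counts sum to %d but plant has %d leaves",
                 sum(counts), n))
  ranks <- vapply(plant$leaves, function(l) l$rank, integer(1))
  ord <- order(ranks, decreasing = TRUE)  # youngest first
  cls <- rep(c("upper", "middle", "lower"), times = counts)
  for (i in seq_len(n)) plant$leaves[[ord[i]]]$position_class <- cls[i]
  plant
}

#' Growth-stage canopy presets
#'
#' Pre-calibrated rosette parameter sets for the two growth stages studied:
#' `"14DAT"` (7 leaves, position classes 3/2/2, ~66 cm2 leaf area per plant)
#' and `"28DAT"` (10 leaves, classes 4/3/3, ~530 cm2 per plant). With the
#' default stand (24 and 12 plants on a 0.40 m2 bed) these give leaf area
#' indices near 0.40 and 1.60.
#'
#' @param stage `"14DAT"` or `"28DAT"`.
#' @param seed integer rng seed for the leaf jitter.
#' @return List with `params` ([rosette_params()]) and `class_counts`.
#' @export
rosette_preset <- function(stage = c("14DAT", "28DAT"), seed = 1L) {
  stage <- match.arg(stage)
  if (stage == "14DAT") {
    lengths <- c(0.056, 0.058, 0.059, 0.058, 0.052, 0.042, 0.029)
    elev <- c(10, 12, 15, 18, 22, 28, 35)
    list(params = rosette_params(7L, blade_length = lengths,
                                 elevation_deg = elev, internode = 0.006,
                                 petiole = 0.015, rng_seed = seed),
         class_counts = c(upper = 3L, middle = 2L, lower = 2L))
  } else {
    lengths <- c(0.135, 0.141, 0.145, 0.145, 0.141, 0.130, 0.115, 0.099,
                 0.083, 0.063)
    elev <- c(12, 15, 18, 22, 26, 30, 35, 40, 45, 50)
    list(params = rosette_params(10L, blade_length = lengths,
                                 elevation_deg = elev, internode = 0.010,
                                 petiole = 0.030, rng_seed = seed),
         class_counts = c(upper = 4L, middle = 3L, lower = 3L))
  }
}

#' @rdname rosette_preset
#' @param plant_id id recorded on the generated plant.
#' @return `generate_preset_plant()`: a classed `plant_model`.
#' @export
generate_preset_plant <- function(stage = c("14DAT", "28DAT"), seed = 1L,
                                  plant_id = 1L) {
  p <- rosette_preset(stage, seed)
  assign_position_classes(generate_rosette(p$params, plant_id),
                          p$class_counts)
}

#' Evaluate a dose-response curve
#'
#' The three parses of the rectangular-hyperbola increase-rate model:
#' `F1: a / (x + b)`, `F2: a * x / (x + b)` (saturating, default elsewhere),
#' `F3: a / x + b`, plus `"linear"` (`a * x + b`) for round-trip testing of
#' the linear yield fitters. `x` is cumulative absorbed UV (kJ m-2), the
#' value an increase rate in percent.
#'
#' @param form `"F1"`, `"F2"`, `"F3"` or `"linear"`.
#' @param x cumulative absorbed UV (kJ m-2).
#' @param a,b curve coefficients.
#' @return Increase rate (%).
#' @export
hyperbolic_response <- function(form, x, a, b) {
  switch(form,
         F1 = a / (x + b),
         F2 = a * x / (x + b),
         F3 = a / x + b,
         linear = a * x + b,
         stop("unknown form: ", form))
}

#' Generate a synthetic per-leaf assay table
#'
#' Emulates the statistical structure the yield analysis assumes: compound
#' concentration = class-matched control concentration times
#' `(1 + f(deltaUV)/100)` plus additive Gaussian noise truncated at zero,
#' where `f` is a [hyperbolic_response()] per compound. RSA is additionally
#' capped at 100%. Control rows (`cumulative_absorbed_uv = 0`, `f = 0`) are
#' appended unless already present.
#'
#' @param uv data.frame with columns `plant_id`, `leaf_id`,
#'   `position_class`, `treatment`, `cumulative_absorbed_uv` (kJ m-2, >= 0).
#' @param yield_model named list per compound (`TPC`, `TFC`, `RSA`), each
#'   `list(form =, a =, b =)`; a compound may instead map to `NULL` for a
#'   flat (f = 0) response.
#' @param control_concentration named list per compound of named numeric
#'   vectors per position class, e.g.
#'   `list(TPC = c(upper = 6, middle = 5, lower = 4), ...)`.
#' @param noise_sd named numeric per compound (same units as the
#'   concentration), >= 0.
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @param add_control append control rows with zero dose (default TRUE).
#' @return data.frame with columns `plant_id`, `leaf_id`, `position_class`,
#'   `treatment`, `cumulative_absorbed_uv`, `TPC`, `TFC`, `RSA`.
#' @export
generate_assay_data <- function(uv, yield_model, control_concentration,
                                noise_sd = c(TPC = 0, TFC = 0, RSA = 0),
                                rng_seed = 1L, add_control = TRUE) {
  need <- c("plant_id", "leaf_id", "position_class", "treatment",
            "cumulative_absorbed_uv")
  if (!all(need %in% names(uv))) stop("uv table missing required columns")
  if (any(uv$cumulative_absorbed_uv < 0)) stop("cumulative absorbed UV must be >= 0")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  df <- uv[, need]
  if (add_control && !any(df$treatment == "control")) {
    leaves <- unique(df[, c("plant_id", "leaf_id", "position_class")])
    ctrl <- data.frame(leaves, treatment = "control",
                       cumulative_absorbed_uv = 0)
    df <- rbind(df, ctrl)
  }
  compounds <- c("TPC", "TFC", "RSA")
  noise_sd <- unlist(noise_sd)
  out <- df
  with_seed_(rng_seed, {
    for (cmp in compounds) {
      ctrl <- unlist(control_concentration[[cmp]])
      if (is.null(ctrl)) stop("missing control concentration for ", cmp)
      base <- unname(ctrl[df$position_class])
      if (anyNA(base)) stop("control concentration missing a position class")
      m <- yield_model[[cmp]]
      x <- df$cumulative_absorbed_uv
      f <- if (is.null(m)) rep(0, nrow(df)) else
        ifelse(x > 0, hyperbolic_response(m$form, x, m$a, m$b), 0)
      sdv <- if (cmp %in% names(noise_sd)) noise_sd[[cmp]] else 0
      conc <- base * (1 + f / 100) + rnorm(nrow(df), 0, sdv)
      conc <- pmax(conc, 0)
      if (cmp == "RSA") conc <- pmin(conc, 100)
      out[[cmp]] <- conc
    }
  })
  out[, c(need, compounds)]
}

#' Read / write assay tables as CSV
#'
#' @param assays an assay data.frame as from [generate_assay_data()].
#' @param path file path.
#' @export
write_assay_csv <- function(assays, path) {
  utils::write.csv(assays, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) utils::read.csv(path)
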