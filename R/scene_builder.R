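# Virtual plant-factory scene: growth bed, LED bars as rectangular Lambertian
# emitters, plants placed at the stand density, and per-band surface optics.

#' Surface optical properties for one band
#'
#' Diffuse reflectance and transmittance; absorptance is the remainder so
#' that rho + tau + alpha = 1 exactly.
#'
#' @param reflectance,transmittance fractions in `[0, 1]` with sum <= 1.
#' @return An `optical_properties` object with fields `rho`, `tau`, `alpha`.
#' @export
optical_properties <- function(reflectance, transmittance) {
  if (reflectance < 0 || transmittance < 0 || reflectance + transmittance > 1)
    stop("need rho >= 0, tau >= 0, rho + tau <= 1")
  structure(list(rho = reflectance, tau = transmittance,
                 alpha = 1 - reflectance - transmittance),
            class = "optical_properties")
}

#' Default per-band surface optics
#'
#' Leaf reflectance/transmittance per position class and band, plus the bed.
#' Leaves absorb strongly in the UV (epidermal screening) and moderately in
#' the PAR band; the bed is a matte white module surface (rho = 0.5). All
#' values are configuration defaults, replaceable by measured ones.
#'
#' @return Nested list `optics[[band]][[surface_key]]`, bands `"PAR"` and
#'   `"UV"`, surface keys `leaf_upper`, `leaf_middle`, `leaf_lower`, `bed`.
#' @export
default_optics <- function() {
  list(
    PAR = list(leaf_upper = optical_properties(0.065, 0.070),
               leaf_middle = optical_properties(0.070, 0.060),
               leaf_lower = optical_properties(0.075, 0.050),
               bed = optical_properties(0.50, 0)),
    UV = list(leaf_upper = optical_properties(0.050, 0.012),
              leaf_middle = optical_properties(0.055, 0.010),
              leaf_lower = optical_properties(0.060, 0.008),
              bed = optical_properties(0.50, 0)))
}

#' Rectangular LED bar source
#'
#' An axis-aligned rectangle at height `z` emitting Lambertian
#' (cosine-weighted) radiation from its lower face toward the bed.
#'
#' @param x,y centre of the bar (m).
#' @param z emitter height above the bed plane (m).
#' @param width,length bar extents along x and y (m).
#' @param power named numeric, total emitted power per band (W), e.g.
#'   `c(PAR = 4.3, UV = 0.1)`.
#' @return A `light_bar` object.
#' @export
light_bar <- function(x, y, z, width, length, power) {
  if (any(power < 0)) stop("source power must be >= 0")
  if (width <= 0 || length <= 0) stop("bar extents must be positive")
  structure(list(x = x, y = y, z = z, width = width, length = length,
                 power = power), class = "light_bar")
}

#' Watts per square metre from PPFD
#'
#' Inverse of [photon_flux()] at a representative wavelength: the irradiance
#' carrying a given photon flux if all photons had that wavelength.
#'
#' @param ppfd photon flux (umol m-2 s-1).
#' @param wavelength_nm representative wavelength (nm), default 550 (centre
#'   of the PAR band).
#' @return Irradiance in W m-2.
#' @export
watts_from_photon_flux <- function(ppfd, wavelength_nm = 550) {
  ppfd / photon_flux(1, wavelength_nm)
}

#' Default overhead LED bar layout
#'
#' `n_bars` parallel bars spanning the bed along y, evenly spaced along x at
#' height `z`. Total power per band equals the target bed-plane irradiance
#' times the bed area, split equally between bars.
#'
#' @param bed_w,bed_l bed extents (m).
#' @param z bar height above the bed (m).
#' @param n_bars number of bars.
#' @param irradiance named numeric, target irradiance per band (W m-2) at
#'   the bed plane, e.g. `c(PAR = 43.5, UV = 1.0)`.
#' @param bar_width emitting width of each bar (m).
#' @return List of [light_bar()] objects.
#' @export
default_led_bars <- function(bed_w = 0.8, bed_l = 0.5, z = 0.35, n_bars = 4,
                             irradiance = c(PAR = watts_from_photon_flux(200),
                                            UV = 1.0),
                             bar_width = 0.04) {
  total <- irradiance * bed_w * bed_l
  xs <- bed_w * (seq_len(n_bars) - 0.5) / n_bars - bed_w / 2
  lapply(xs, function(x)
    light_bar(x, 0, z, bar_width, bed_l, total / n_bars))
}

#' Regular placement grid
#'
#' Centres of an `nx x ny` grid covering the bed with a margin, row-major,
#' truncated to `n` placements. `nx` is chosen to roughly match the bed
#' aspect ratio.
#'
#' @param n number of placements.
#' @param bed_w,bed_l bed extents (m).
#' @param margin distance from bed edge to outermost centres (m).
#' @return data.frame with columns `x`, `y` (bed-centred coordinates).
#' @export
grid_layout <- function(n, bed_w = 0.8, bed_l = 0.5, margin = 0.05) {
  nx <- max(1L, round(sqrt(n * bed_w / bed_l)))
  ny <- ceiling(n / nx)
  xs <- seq(-bed_w / 2 + margin, bed_w / 2 - margin, length.out = nx)
  ys <- seq(-bed_l / 2 + margin, bed_l / 2 - margin, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  g[seq_len(n), , drop = FALSE]
}

#' Assemble a ray-traceable scene
#'
#' Combines plants (placed on the bed), the bed surface, the LED sources and
#' the per-band optics into one scene. Construction is deterministic.
#'
#' @param plants list of `plant_model` objects.
#' @param layout data.frame with columns `x`, `y`, one row per plant;
#'   default a [grid_layout()].
#' @param bed_w,bed_l bed extents (m); the bed top surface lies at z = 0.
#' @param sources list of [light_bar()]; default [default_led_bars()].
#' @param optics per-band optics as from [default_optics()].
#' @param placement_tol minimum allowed distance between placements (m).
#' @return A `uv_scene` object.
#' @export
build_scene <- function(plants, layout = NULL, bed_w = 0.8, bed_l = 0.5,
                        sources = default_led_bars(bed_w, bed_l),
                        optics = default_optics(), placement_tol = 1e-6) {
  n <- length(plants)
  if (is.null(layout)) layout <- grid_layout(n, bed_w, bed_l)
  if (nrow(layout) != n) stop("layout rows must match number of plants")
  if (n > 0) {
    if (any(abs(layout$x) > bed_w / 2) || any(abs(layout$y) > bed_l / 2))
      stop("placement outside bed bounds")
    if (n > 1) {
      d <- as.matrix(dist(layout[, c("x", "y")]))
      diag(d) <- Inf
      if (min(d) < placement_tol) stop("overlapping plant placements")
    }
  }
  for (p in plants) {
    stopifnot(inherits(p, "plant_model"))
    cls <- vapply(p$leaves, function(l) l$position_class, character(1))
    if (anyNA(cls)) stop("all leaves need a position_class before tracing")
  }
  structure(list(bed = list(w = bed_w, l = bed_l), plants = plants,
                 layout = as.data.frame(layout), sources = sources,
                 optics = optics),
            class = "uv_scene")
}

# Flatten a scene into triangle soup + surface bookkeeping for the tracer.
scene_geometry_ <- function(scene) {
  tri_list <- list()
  surf_rows <- list()
  tri_surf <- integer(0)
  sid <- 0L
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    dx <- scene$layout$x[i]
    dy <- scene$layout$y[i]
    for (l in p$leaves) {
      tri <- l$triangles
      tri[, c(1, 4, 7)] <- tri[, c(1, 4, 7)] + dx
      tri[, c(2, 5, 8)] <- tri[, c(2, 5, 8)] + dy
      sid <- sid + 1L
      tri_list[[sid]] <- tri
      tri_surf <- c(tri_surf, rep(sid - 1L, nrow(tri)))
      a <- tri_areas_(tri)
      cz <- rowMeans(tri[, c(3, 6, 9), drop = FALSE])
      surf_rows[[sid]] <- data.frame(
        surface = sid, kind = "leaf", plant_id = p$plant_id,
        leaf_id = l$leaf_id, rank = l$rank,
        position_class = l$position_class, area_m2 = l$one_sided_area,
        centroid_z = sum(a * cz) / sum(a),
        optics_key = paste0("leaf_", l$position_class))
    }
  }
  # bed: two triangles at z = 0
  w2 <- scene$bed$w / 2
  l2 <- scene$bed$l / 2
  bed_tri <- rbind(c(-w2, -l2, 0, w2, -l2, 0, w2, l2, 0),
                   c(-w2, -l2, 0, w2, l2, 0, -w2, l2, 0))
  sid <- sid + 1L
  tri_list[[sid]] <- bed_tri
  tri_surf <- c(tri_surf, rep(sid - 1L, 2L))
  surf_rows[[sid]] <- data.frame(
    surface = sid, kind = "bed", plant_id = NA_integer_,
    leaf_id = NA_integer_, rank = NA_integer_,
    position_class = NA_character_, area_m2 = scene$bed$w * scene$bed$l,
    centroid_z = 0, optics_key = "bed")
  list(tri = do.call(rbind, tri_list), tri_surface = tri_surf,
       surfaces = do.call(rbind, surf_rows))
}

#' Generate a preset canopy scene
#'
#' Convenience wrapper: generates `n_plants` jittered clones of a growth
#' stage preset (seeds `seed`, `seed + 1`, ...) and places them at the stand
#' density on the bed.
#'
#' @param stage `"14DAT"` (default 24 plants) or `"28DAT"` (default 12).
#' @param seed integer; plant k uses seed `seed + k - 1`.
#' @param n_plants number of plants; default by stage.
#' @param ... passed to [build_scene()].
#' @return A `uv_scene`.
#' @export
canopy_scene <- function(stage = c("14DAT", "28DAT"), seed = 1L,
                         n_plants = NULL, ...) {
  stage <- match.arg(stage)
  if (is.null(n_plants)) n_plants <- if (stage == "14DAT") 24L else 12L
  plants <- lapply(seq_len(n_plants), function(k)
    generate_preset_plant(stage, seed = seed + k - 1L, plant_id = k))
  build_scene(plants, ...)
}

# ---------------------------------------------------------------------------
# Mesh input / output (ASCII OBJ and PLY), one named group per leaf.

class_code_ <- c(upper = 0L, middle = 1L, lower = 2L)

#' Save / load a plant mesh
#'
#' Writes a `plant_model` as ASCII OBJ (one `o leaf_<id>_rank_<rank>_<class>`
#' object per leaf) or ASCII PLY (per-face `leaf_id`, `rank` and position
#' class properties), selected by file extension. A sidecar CSV
#' (`<path>.csv`: leaf_id, rank, position_class, area_m2) is written
#' alongside. `load_mesh()` round-trips coordinates to better than 1e-6 m.
#'
#' @param plant a `plant_model`.
#' @param path output path ending in `.obj` or `.ply`.
#' @param sidecar write the metadata CSV (default TRUE).
#' @return `save_mesh()`: the path, invisibly. `load_mesh()`: a
#'   `plant_model`.
#' @export
save_mesh <- function(plant, path, sidecar = TRUE) {
  stopifnot(inherits(plant, "plant_model"))
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("obj", "ply")) stop("unknown mesh format: .", fmt)
  if (fmt == "obj") {
    lines <- c("# uvcanopy plant mesh")
    vcount <- 0L
    for (l in plant$leaves) {
      cls <- if (is.na(l$position_class)) "unassigned" else l$position_class
      lines <- c(lines, sprintf("o leaf_%d_rank_%d_%s", l$leaf_id, l$rank, cls))
      tri <- l$triangles
      for (i in seq_len(nrow(tri))) {
        lines <- c(lines,
                   sprintf("v %.12f %.12f %.12f", tri[i, 1], tri[i, 2], tri[i, 3]),
                   sprintf("v %.12f %.12f %.12f", tri[i, 4], tri[i, 5], tri[i, 6]),
                   sprintf("v %.12f %.12f %.12f", tri[i, 7], tri[i, 8], tri[i, 9]),
                   sprintf("f %d %d %d", vcount + 1L, vcount + 2L, vcount + 3L))
        vcount <- vcount + 3L
      }
    }
    writeLines(lines, path)
  } else {
    nv <- sum(vapply(plant$leaves, function(l) 3L * nrow(l$triangles),
                     integer(1)))
    nf <- nv / 3L
    head_lines <- c("ply", "format ascii 1.0",
                    "comment uvcanopy plant mesh",
                    sprintf("element vertex %d", nv),
                    "property double x", "property double y",
                    "property double z",
                    sprintf("element face %d", nf),
                    "property list uchar int vertex_indices",
                    "property int leaf_id", "property int rank",
                    "property int position_class", "end_header")
    vlines <- character(nv)
    flines <- character(nf)
    vi <- 0L; fi <- 0L
    for (l in plant$leaves) {
      cc <- if (is.na(l$position_class)) -1L else class_code_[[l$position_class]]
      tri <- l$triangles
      for (i in seq_len(nrow(tri))) {
        vlines[vi + 1L] <- sprintf("%.12f %.12f %.12f", tri[i, 1], tri[i, 2], tri[i, 3])
        vlines[vi + 2L] <- sprintf("%.12f %.12f %.12f", tri[i, 4], tri[i, 5], tri[i, 6])
        vlines[vi + 3L] <- sprintf("%.12f %.12f %.12f", tri[i, 7], tri[i, 8], tri[i, 9])
        fi <- fi + 1L
        flines[fi] <- sprintf("3 %d %d %d %d %d %d", vi, vi + 1L, vi + 2L,
                              l$leaf_id, l$rank, cc)
        vi <- vi + 3L
      }
    }
    writeLines(c(head_lines, vlines, flines), path)
  }
  if (sidecar) {
    meta <- data.frame(
      leaf_id = vapply(plant$leaves, function(l) l$leaf_id, integer(1)),
      rank = vapply(plant$leaves, function(l) l$rank, integer(1)),
      position_class = vapply(plant$leaves, function(l) l$position_class,
                              character(1)),
      area_m2 = vapply(plant$leaves, function(l) l$one_sided_area, numeric(1)))
    utils::write.csv(meta, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_mesh
#' @param plant_id id to record on the loaded plant.
#' @export
load_mesh <- function(path, plant_id = 1L) {
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("obj", "ply")) stop("unknown mesh format: .", fmt)
  if (fmt == "obj") plant <- load_obj_(path, plant_id)
  else plant <- load_ply_(path, plant_id)
  plant
}

load_obj_ <- function(path, plant_id) {
  lines <- readLines(path)
  verts <- list()
  groups <- list()          # group name -> list of face index triples
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "v ")) {
      verts[[length(verts) + 1L]] <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4])
    } else if (startsWith(ln, "o ") || startsWith(ln, "g ")) {
      cur <- trimws(sub("^[og] ", "", ln))
      if (is.null(groups[[cur]])) groups[[cur]] <- list()
    } else if (startsWith(ln, "f ")) {
      if (is.null(cur)) stop("leaf segmentation missing (faces outside any group)")
      idx <- as.integer(sub("/.*", "", strsplit(trimws(ln), "\\s+")[[1]][-1]))
      groups[[cur]][[length(groups[[cur]]) + 1L]] <- idx
    }
  }
  if (length(groups) == 0) stop("leaf segmentation missing (no groups in OBJ)")
  V <- do.call(rbind, verts)
  used <- logical(nrow(V))
  leaves <- list()
  for (gname in names(groups)) {
    m <- regmatches(gname, regexec("^leaf_(\\d+)_rank_(\\d+)_(\\w+)$", gname))[[1]]
    if (length(m) == 0) stop("group name not in leaf_<id>_rank_<rank>_<class> form: ", gname)
    fidx <- do.call(rbind, groups[[gname]])
    used[as.vector(fidx)] <- TRUE
    tri <- cbind(V[fidx[, 1], , drop = FALSE], V[fidx[, 2], , drop = FALSE],
                 V[fidx[, 3], , drop = FALSE])
    dimnames(tri) <- NULL
    cls <- m[4]
    leaves[[length(leaves) + 1L]] <- structure(list(
      leaf_id = as.integer(m[2]), rank = as.integer(m[3]),
      position_class = if (cls == "unassigned") NA_character_ else cls,
      triangles = tri, one_sided_area = sum(tri_areas_(tri)),
      azimuth_deg = NA_real_, elevation_deg = NA_real_), class = "leaf_mesh")
  }
  if (any(!used)) warning(sum(!used), " unreferenced vertices dropped")
  finish_plant_(leaves, plant_id)
}

load_ply_ <- function(path, plant_id) {
  lines <- readLines(path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[(endh + 1):(endh + nv)]
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.numeric(x)))
  if (ncol(F) < 7) stop("leaf segmentation missing (no per-face leaf ids in PLY)")
  code_class <- c(`0` = "upper", `1` = "middle", `2` = "lower")
  leaves <- list()
  for (lid in sort(unique(F[, 5]))) {
    rows <- F[F[, 5] == lid, , drop = FALSE]
    idx <- rows[, 2:4] + 1
    tri <- cbind(V[idx[, 1], , drop = FALSE], V[idx[, 2], , drop = FALSE],
                 V[idx[, 3], , drop = FALSE])
    dimnames(tri) <- NULL
    cc <- as.character(rows[1, 7])
    leaves[[length(leaves) + 1L]] <- structure(list(
      leaf_id = as.integer(lid), rank = as.integer(rows[1, 6]),
      position_class = if (cc %in% names(code_class)) code_class[[cc]]
                       else NA_character_,
      triangles = tri, one_sided_area = sum(tri_areas_(tri)),
      azimuth_deg = NA_real_, elevation_deg = NA_real_), class = "leaf_mesh")
  }
  finish_plant_(leaves, plant_id)
}

finish_plant_ <- function(leaves, plant_id) {
  leaves <- leaves[order(vapply(leaves, function(l) l$rank, integer(1)))]
  zmax <- max(vapply(leaves, function(l) max(l$triangles[, c(3, 6, 9)]),
                     numeric(1)))
  structure(list(plant_id = as.integer(plant_id), leaves = leaves,
                 height = zmax,
                 total_leaf_area = sum(vapply(leaves, function(l)
                   l$one_sided_area, numeric(1)))),
            class = "plant_model")
}

#' Save / load a scene as JSON
#'
#' Serializes the full scene (bed, layout, sources, optics and plant
#' geometry) with full numeric precision.
#'
#' @param scene a `uv_scene`.
#' @param path output path.
#' @export
save_scene <- function(scene, path) {
  stopifnot(inherits(scene, "uv_scene"))
  ser <- list(
    bed = scene$bed,
    layout = lapply(seq_len(nrow(scene$layout)), function(i)
      list(x = scene$layout$x[i], y = scene$layout$y[i])),
    sources = lapply(scene$sources, function(s)
      list(x = s$x, y = s$y, z = s$z, width = s$width, length = s$length,
           power = as.list(s$power))),
    optics = lapply(scene$optics, function(bnd)
      lapply(bnd, function(o) list(rho = o$rho, tau = o$tau))),
    plants = lapply(scene$plants, function(p)
      list(plant_id = p$plant_id,
           leaves = lapply(p$leaves, function(l)
             list(leaf_id = l$leaf_id, rank = l$rank,
                  position_class = l$position_class,
                  triangles = l$triangles)))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  sources <- lapply(j$sources, function(s)
    light_bar(s$x, s$y, s$z, s$width, s$length, unlist(s$power)))
  optics <- lapply(j$optics, function(bnd)
    lapply(bnd, function(o) optical_properties(o$rho, o$tau)))
  plants <- lapply(j$plants, function(p) {
    leaves <- lapply(p$leaves, function(l) {
      tri <- do.call(rbind, lapply(l$triangles, function(r) unlist(r)))
      dimnames(tri) <- NULL
      cls <- l$position_class
      structure(list(leaf_id = as.integer(l$leaf_id),
                     rank = as.integer(l$rank),
                     position_class = if (is.null(cls)) NA_character_ else cls,
                     triangles = tri,
                     one_sided_area = sum(tri_areas_(tri)),
                     azimuth_deg = NA_real_, elevation_deg = NA_real_),
                class = "leaf_mesh")
    })
    finish_plant_(leaves, p$plant_id)
  })
  layout <- data.frame(
    x = vapply(j$layout, function(r) as.numeric(r$x), numeric(1)),
    y = vapply(j$layout, function(r) as.numeric(r$y), numeric(1)))
  build_scene(plants, layout = layout, bed_w = j$bed$w, bed_l = j$bed$l,
              sources = sources, optics = optics)
}
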