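# End-to-end run: generate plants -> build scene -> trace PAR and UV ->
# dose/schedule arithmetic -> synthetic assays -> yield fits.  One global
# seed fans out to fixed per-stage seeds so stages can be re-run in
# isolation; reruns with the same config are byte-identical.

stage_seed_ <- function(seed, k) {
  as.integer(((seed %% 65536) * 31397 + k * 9973) %% 2147483647)
}

#' Default pipeline configuration
#'
#' A small, fast configuration (one plant, 1e5 rays per band) used for
#' smoke tests and as a template; amend fields as needed. `full = TRUE`
#' returns the full stand for the growth stage instead.
#'
#' @param stage `"14DAT"` or `"28DAT"`.
#' @param seed global integer seed.
#' @param full use the full stand density (24 or 12 plants) and 1e6 rays.
#' @return A named list understood by [run_pipeline()].
#' @export
smoke_config <- function(stage = "14DAT", seed = 1L, full = FALSE) {
  list(
    stage = stage,
    n_plants = if (full) NULL else 1L,
    seed = as.integer(seed),
    n_rays = if (full) 1e6 else 1e5,
    max_bounces = 10L,
    uv_irradiance = 1.0,
    ppfd = 200,
    photoperiod_h = 16,
    uvb_peak_nm = 310,
    uvb_fwhm_nm = 10,
    schedule = "3 d 12 h",
    form = "F2",
    assay = list(
      yield_model = list(TFC = list(form = "F2", a = 60, b = 20),
                         TPC = list(form = "F2", a = 45, b = 25),
                         RSA = list(form = "F2", a = 30, b = 15)),
      control = list(TFC = list(upper = 2.4, middle = 2.0, lower = 1.7),
                     TPC = list(upper = 6.5, middle = 5.5, lower = 4.5),
                     RSA = list(upper = 55, middle = 50, lower = 45)),
      noise_sd = list(TFC = 0.08, TPC = 0.2, RSA = 1.5)))
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    cfg <- yaml::read_yaml(config)
    # yaml reads named vectors as lists; normalise the assay block
    if (!is.null(cfg$assay)) {
      cfg$assay$control <- lapply(cfg$assay$control, unlist)
      cfg$assay$noise_sd <- unlist(cfg$assay$noise_sd)
    }
    cfg
  } else if (is.list(config)) config
  else stop("config must be a list or a YAML path")
}

log_ <- function(con, ...) {
  writeLines(paste0(format(Sys.time(), "%H:%M:%S"), " ", ...), con)
}

#' Run the full interception-to-yield pipeline
#'
#' Executes every stage in order and writes all outputs into `out_dir`:
#' `tally_PAR.csv` and `tally_UV.csv` (per-leaf absorbed flux),
#' `dose.json` (the six-treatment dose table, unweighted and biologically
#' effective), `uv_per_leaf.csv` (cumulative absorbed UV per leaf and
#' treatment), `assays.csv` (synthetic assay table), `fits.json` and
#' `table1_like.csv` (linear and hyperbolic yield fits per position and
#' stage), `run_meta.json` and `run.log`. Any stage failure aborts with the
#' stage name in the error and the log.
#'
#' @param config list or YAML path; see [smoke_config()] for the schema.
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con))
  seed <- as.integer(cfg$seed %||% 1L)
  run_stage <- function(name, expr) {
    log_(con, "stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  scene <- run_stage("build_scene", {
    canopy_scene(cfg$stage %||% "14DAT", seed = stage_seed_(seed, 1),
                 n_plants = cfg$n_plants,
                 sources = default_led_bars(
                   irradiance = c(PAR = watts_from_photon_flux(cfg$ppfd %||% 200),
                                  UV = cfg$uv_irradiance %||% 1.0)))
  })
  log_(con, sprintf("scene: %d plants, LAI %.3f", length(scene$plants),
                    leaf_area_index(scene)))

  tallies <- list()
  for (bn in c("PAR", "UV")) {
    k <- if (bn == "PAR") 2 else 3
    res <- run_stage(paste0("trace_", bn), {
      r <- trace(scene, bn, trace_config(n_rays = cfg$n_rays %||% 1e5,
                                         max_bounces = cfg$max_bounces %||% 10L,
                                         seed = stage_seed_(seed, k)))
      cons <- check_conservation(r)
      if (!cons$ok) stop("energy balance violated (residual ",
                         cons$residual_W, " W)")
      r
    })
    tallies[[bn]] <- res
    write_tally_csv(res, file.path(out_dir, paste0("tally_", bn, ".csv")))
    log_(con, sprintf("%s: emitted %.4g W, absorbed %.4g W, escaped %.4g W",
                      bn, res$emitted_W, res$absorbed_total_W, res$escaped_W))
  }

  doses <- run_stage("dosimetry", {
    spec <- gaussian_led_spectrum(cfg$uvb_peak_nm %||% 310,
                                  cfg$uvb_fwhm_nm %||% 10,
                                  cfg$uv_irradiance %||% 1.0)
    bef <- be_factor(spec)
    grid <- treatment_grid()
    lapply(grid, function(s)
      dose_summary(cfg$uv_irradiance %||% 1.0, s, bef))
  })
  jsonlite::write_json(doses, file.path(out_dir, "dose.json"),
                       auto_unbox = TRUE, digits = NA)

  uv_tab <- run_stage("cumulative_uv", {
    do.call(rbind, lapply(treatment_grid(), function(s)
      cumulative_absorbed_uv(tallies$UV, s)))
  })
  rownames(uv_tab) <- NULL
  utils::write.csv(uv_tab, file.path(out_dir, "uv_per_leaf.csv"),
                   row.names = FALSE)

  assays <- run_stage("assays", {
    generate_assay_data(uv_tab, cfg$assay$yield_model, cfg$assay$control,
                        cfg$assay$noise_sd, rng_seed = stage_seed_(seed, 4))
  })
  assays$stage <- cfg$stage %||% "14DAT"
  write_assay_csv(assays, file.path(out_dir, "assays.csv"))

  fits <- run_stage("yield_fits", {
    lin <- list(TFC = fit_linear_yield_by(assays, "TFC"),
                TPC = fit_linear_yield_by(assays, "TPC"))
    treated <- assays[assays$treatment != "control", ]
    ctrl <- assays[assays$treatment == "control", ]
    ctrl_mean <- function(cmp) vapply(split(ctrl[[cmp]], ctrl$position_class),
                                      mean, numeric(1))
    nl <- list()
    for (cmp in c("TFC", "TPC")) {
      cm <- ctrl_mean(cmp)
      rate <- increase_rate(treated[[cmp]],
                            unname(cm[treated$position_class]))
      sub <- data.frame(stage = treated$stage,
                        position_class = treated$position_class,
                        cumulative_absorbed_uv = treated$cumulative_absorbed_uv,
                        rate = rate)
      groups <- unique(sub[, c("stage", "position_class")])
      fits_c <- list()
      for (i in seq_len(nrow(groups))) {
        sel <- sub$stage == groups$stage[i] &
          sub$position_class == groups$position_class[i]
        fits_c[[paste(groups$stage[i], groups$position_class[i], sep = ".")]] <-
          fit_hyperbolic(sub$cumulative_absorbed_uv[sel], sub$rate[sel],
                         form = cfg$form %||% "F2",
                         position_class = groups$position_class[i],
                         stage = groups$stage[i])
      }
      nl[[cmp]] <- fits_c
    }
    list(linear = lin, nonlinear = nl)
  })
  jsonlite::write_json(
    lapply(fits, function(grp) lapply(grp, function(fl)
      lapply(fl, unclass))),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA)
  tab1 <- yield_report(fits$linear, fits$nonlinear)
  utils::write.csv(tab1, file.path(out_dir, "table1_like.csv"),
                   row.names = FALSE)

  meta <- list(seed = seed, stage = cfg$stage %||% "14DAT",
               n_plants = length(scene$plants),
               n_rays = cfg$n_rays %||% 1e5,
               stage_seeds = list(plants = stage_seed_(seed, 1),
                                  trace_PAR = stage_seed_(seed, 2),
                                  trace_UV = stage_seed_(seed, 3),
                                  assays = stage_seed_(seed, 4)))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  log_(con, "done")
  invisible(list(scene = scene, tallies = tallies, doses = doses,
                 uv = uv_tab, assays = assays, fits = fits, table1 = tab1,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
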