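# Response statistics: radical scavenging activity, Fv/Fm, linear UV energy
# yield regressions and the rectangular-hyperbola increase-rate model.

#' DPPH radical scavenging activity
#'
#' `RSA% = (A_control - A_sample) / A_control x 100`, from absorbances at
#' 517 nm without and with leaf extract.
#'
#' @param a_control control absorbance at 517 nm, > 0.
#' @param a_sample sample absorbance at 517 nm, >= 0.
#' @return RSA in percent.
#' @export
rsa <- function(a_control, a_sample) {
  if (any(a_control <= 0)) stop("control absorbance must be positive")
  if (any(a_sample < 0)) stop("sample absorbance must be non-negative")
  (a_control - a_sample) / a_control * 100
}

#' Maximal photochemical efficiency of photosystem II
#'
#' `Fv/Fm = (Fm - F0) / Fm` from dark-adapted minimal and maximal
#' fluorescence. Values near 0.82-0.83 indicate unstressed leaves;
#' [fv_fm_status()] flags that range.
#'
#' @param f0 minimal fluorescence, `0 <= f0 <= fm`.
#' @param fm maximal fluorescence, > 0.
#' @return Ratio in `[0, 1]`.
#' @export
fv_fm <- function(f0, fm) {
  if (any(fm <= 0)) stop("fm must be positive")
  if (any(f0 < 0) || any(f0 > fm)) stop("need 0 <= f0 <= fm")
  (fm - f0) / fm
}

#' @rdname fv_fm
#' @param ratio an Fv/Fm value.
#' @param normal_range inclusive range regarded as unstressed.
#' @return `fv_fm_status()`: `"normal"` or `"stressed"`.
#' @export
fv_fm_status <- function(ratio, normal_range = c(0.82, 0.83)) {
  ifelse(ratio >= normal_range[1] & ratio <= normal_range[2],
         "normal", "stressed")
}

#' Concentration increase rate over control
#'
#' `(treated - control) / control x 100`; negative when the treated
#' concentration falls below the control.
#'
#' @param conc_treated treated concentration.
#' @param conc_control control concentration, > 0.
#' @return Increase rate in percent.
#' @export
increase_rate <- function(conc_treated, conc_control) {
  if (any(conc_control <= 0)) stop("control concentration must be positive")
  (conc_treated - conc_control) / conc_control * 100
}

#' Linear UV energy yield regression
#'
#' Ordinary least squares of compound concentration on cumulative absorbed
#' UV energy. The slope is the cumulative UV energy yield (concentration
#' units per kJ m-2), the analogue of radiation use efficiency for
#' UV-induced compounds.
#'
#' @param delta_uv cumulative absorbed UV per leaf (kJ m-2).
#' @param conc compound concentration per leaf.
#' @param position_class,stage optional labels recorded on the fit.
#' @return A `yield_fit`: list with `slope`, `intercept`, `r2`, `n`,
#'   `slope_se`, `position_class`, `stage`.
#' @export
fit_linear_yield <- function(delta_uv, conc, position_class = NA_character_,
                             stage = NA_character_) {
  keep <- is.finite(delta_uv) & is.finite(conc)
  x <- delta_uv[keep]
  y <- conc[keep]
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("degenerate design: all deltaUV equal")
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  s_xx <- sum((x - mean(x))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 n = length(x),
                 slope_se = sqrt(ss_res / (length(x) - 2) / s_xx),
                 position_class = position_class, stage = stage),
            class = "yield_fit")
}

#' Grouped linear yield fits
#'
#' One [fit_linear_yield()] per position class (x stage when present),
#' reproducing the layout of a per-position yield table.
#'
#' @param data data.frame with columns `cumulative_absorbed_uv`,
#'   `position_class`, optionally `stage`, and the compound column.
#' @param compound name of the concentration column.
#' @return List of `yield_fit` objects keyed `"<stage>.<class>"`.
#' @export
fit_linear_yield_by <- function(data, compound) {
  if (!compound %in% names(data)) stop("no column ", compound)
  if (!"stage" %in% names(data)) data$stage <- "all"
  groups <- unique(data[, c("stage", "position_class")])
  fits <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- data$stage == groups$stage[i] &
      data$position_class == groups$position_class[i]
    fits[[paste(groups$stage[i], groups$position_class[i], sep = ".")]] <-
      fit_linear_yield(data$cumulative_absorbed_uv[sel], data[[compound]][sel],
                       position_class = groups$position_class[i],
                       stage = groups$stage[i])
  }
  fits
}

#' Rectangular-hyperbola increase-rate fit
#'
#' Nonlinear least squares of increase rate (%) on cumulative absorbed UV
#' for one of the three hyperbolic forms of [hyperbolic_response()]
#' (default the saturating `F2: a x / (x + b)`), via Levenberg-Marquardt
#' with multi-start initialization. Ties between converged starts are
#' broken by lowest residual sum of squares, then lowest `|b|`.
#'
#' @param delta_uv cumulative absorbed UV (kJ m-2); must be > 0 for forms
#'   containing `1/deltaUV` (F3).
#' @param rate increase rate (%).
#' @param form `"F1"`, `"F2"` or `"F3"`.
#' @param n_starts number of starting points.
#' @param position_class,stage optional labels.
#' @return An `eq_hyperbolic_fit`: list with `form`, `a`, `b`, `r2`, `n`,
#'   `converged`, labels.
#' @export
fit_hyperbolic <- function(delta_uv, rate, form = "F2", n_starts = 5,
                           position_class = NA_character_,
                           stage = NA_character_) {
  keep <- is.finite(delta_uv) & is.finite(rate)
  x <- delta_uv[keep]
  y <- rate[keep]
  if (length(x) < 3) stop("need at least 3 observations")
  if (form == "F3" && any(x <= 0))
    stop("form F3 needs strictly positive deltaUV")
  if (form %in% c("F1", "F2") && any(x < 0))
    stop("deltaUV must be non-negative")
  fn <- switch(form,
               F1 = function(a, b) a / (x + b),
               F2 = function(a, b) a * x / (x + b),
               F3 = function(a, b) a / x + b,
               stop("unknown form: ", form))
  xs <- max(mean(x[x > 0]), .Machine$double.eps)
  ys <- max(abs(y))
  starts <- list()
  scales <- c(0.25, 0.5, 1, 2, 4)[seq_len(n_starts)]
  for (s in scales) {
    starts[[length(starts) + 1L]] <- switch(form,
      F1 = c(a = s * max(ys, 1) * xs, b = s * xs),
      F2 = c(a = s * max(ys, 1), b = s * xs),
      F3 = c(a = s * max(ys, 1) * xs, b = mean(y)))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fn(a, b), start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    ssr <- sum(residuals(fit)^2)
    cand <- list(a = unname(cf["a"]), b = unname(cf["b"]), ssr = ssr)
    if (is.null(best) || cand$ssr < best$ssr - 1e-12 ||
        (abs(cand$ssr - best$ssr) <= 1e-12 && abs(cand$b) < abs(best$b))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(structure(list(form = form, a = NA_real_, b = NA_real_,
                          r2 = NA_real_, n = length(x), converged = FALSE,
                          position_class = position_class, stage = stage),
                     class = "eq_hyperbolic_fit"))
  }
  yhat <- hyperbolic_response(form, x, best$a, best$b)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(form = form, a = best$a, b = best$b,
                 r2 = if (ss_tot > 0) 1 - best$ssr / ss_tot else 1,
                 n = length(x), converged = TRUE,
                 position_class = position_class, stage = stage),
            class = "eq_hyperbolic_fit")
}

#' Per-position, per-stage yield report
#'
#' Assembles linear and nonlinear coefficients of determination per growth
#' stage and leaf position into a wide table with column groups
#' "Linear regression" and "Nonlinear regression" for TFC and TPC.
#'
#' @param linear_fits named list of `yield_fit` objects per compound, e.g.
#'   `list(TFC = fit_linear_yield_by(...), TPC = ...)`.
#' @param nonlinear_fits same structure with `eq_hyperbolic_fit` objects.
#' @return data.frame with columns `growth_stage`, `leaf_position`,
#'   `linear_regression_TFC`, `linear_regression_TPC`,
#'   `nonlinear_regression_TFC`, `nonlinear_regression_TPC`.
#' @export
yield_report <- function(linear_fits, nonlinear_fits) {
  all_fits <- c(unlist(linear_fits, recursive = FALSE),
                unlist(nonlinear_fits, recursive = FALSE))
  if (length(all_fits) == 0) stop("no fits supplied")
  keys <- unique(do.call(rbind, lapply(all_fits, function(f)
    data.frame(stage = f$stage, position = f$position_class))))
  r2_of <- function(fits, stage, pos) {
    key <- paste(stage, pos, sep = ".")
    if (!is.null(fits) && key %in% names(fits)) fits[[key]]$r2 else NA_real_
  }
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    st <- keys$stage[i]
    po <- keys$position[i]
    data.frame(growth_stage = st, leaf_position = po,
               linear_regression_TFC = r2_of(linear_fits$TFC, st, po),
               linear_regression_TPC = r2_of(linear_fits$TPC, st, po),
               nonlinear_regression_TFC = r2_of(nonlinear_fits$TFC, st, po),
               nonlinear_regression_TPC = r2_of(nonlinear_fits$TPC, st, po))
  }))
  ord <- order(out$growth_stage,
               match(out$leaf_position, c("upper", "middle", "lower")))
  out[ord, , drop = FALSE]
}
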