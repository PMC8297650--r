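# Spectra, photon conversions, biologically effective UV weighting and
# cumulative dose arithmetic.

PLANCK_H <- 6.62607015e-34   # J s (exact, SI 2019)
SPEED_C <- 2.99792458e8      # m s-1 (exact)
AVOGADRO <- 6.02214076e23    # mol-1 (exact)

#' Spectral irradiance distribution
#'
#' A spectrum is a wavelength-indexed table of spectral irradiance
#' (W m-2 nm-1) on a strictly increasing wavelength grid in nm.
#'
#' @param wavelength_nm numeric, strictly increasing wavelengths (nm), length >= 2.
#' @param irradiance numeric, non-negative spectral irradiance (W m-2 nm-1).
#' @return An object of class `uv_spectrum` (a data.frame with columns
#'   `wavelength_nm`, `irradiance_W_m2_nm`).
#' @export
spectrum <- function(wavelength_nm, irradiance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  irradiance <- as.numeric(irradiance)
  if (length(wavelength_nm) < 2L) stop("a spectrum needs at least 2 points")
  if (length(irradiance) != length(wavelength_nm))
    stop("wavelength and irradiance lengths differ")
  if (any(diff(wavelength_nm) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(irradiance < 0)) stop("spectral irradiance must be non-negative")
  structure(data.frame(wavelength_nm = wavelength_nm,
                       irradiance_W_m2_nm = irradiance),
            class = c("uv_spectrum", "data.frame"))
}

#' Gaussian LED emission spectrum
#'
#' Models a narrow-band LED as a Gaussian line of given peak wavelength and
#' full width at half maximum, scaled so the trapezoidal integral over the
#' sampled range equals the requested total irradiance.
#'
#' @param peak_nm peak wavelength (nm).
#' @param fwhm_nm full width at half maximum (nm), > 0.
#' @param total_irradiance total band-integrated irradiance (W m-2).
#' @param range sampled wavelength range (nm); default `c(250, 400)`.
#' @param step grid step (nm).
#' @return A [spectrum()] whose integral equals `total_irradiance`.
#' @export
gaussian_led_spectrum <- function(peak_nm, fwhm_nm, total_irradiance,
                                  range = c(250, 400), step = 0.5) {
  if (fwhm_nm <= 0) stop("fwhm must be positive")
  if (total_irradiance < 0) stop("total irradiance must be non-negative")
  wl <- seq(range[1], range[2], by = step)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  v <- exp(-0.5 * ((wl - peak_nm) / sigma)^2)
  raw <- trapz_(wl, v)
  if (raw <= 0) stop("spectrum support does not overlap the sampled range")
  spectrum(wl, v * total_irradiance / raw)
}

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Wavelength band
#'
#' Half-open waveband `[lo, hi)` in nm. `bands()` returns the conventional
#' reporting bands: UV 250-400 nm, UV-B 280-315 nm, PAR 400-700 nm.
#'
#' @param lo,hi band edges in nm, `lo < hi`.
#' @return A `uv_band` object.
#' @export
band <- function(lo, hi) {
  if (!(lo < hi)) stop("band requires lo < hi")
  structure(list(lo = lo, hi = hi), class = "uv_band")
}

#' @rdname band
#' @export
bands <- function() {
  list(UV = band(250, 400), UVB = band(280, 315), PAR = band(400, 700))
}

#' Band-integrated irradiance
#'
#' Trapezoidal integral of spectral irradiance over a waveband, with linear
#' interpolation at the band edges. Returns 0 (with a warning) when the band
#' does not overlap the spectrum support.
#'
#' @param spec a [spectrum()].
#' @param bnd a [band()].
#' @return Irradiance in W m-2.
#' @export
band_integrate <- function(spec, bnd) {
  stopifnot(inherits(spec, "uv_spectrum"), inherits(bnd, "uv_band"))
  wl <- spec$wavelength_nm
  ir <- spec$irradiance_W_m2_nm
  lo <- max(bnd$lo, wl[1])
  hi <- min(bnd$hi, wl[length(wl)])
  if (lo >= hi) {
    warning("band does not overlap spectrum support; returning 0")
    return(0)
  }
  grid <- sort(unique(c(lo, hi, wl[wl > lo & wl < hi])))
  vals <- approx(wl, ir, xout = grid)$y
  trapz_(grid, vals)
}

#' Photon flux from irradiance
#'
#' Converts irradiance to photon flux at a single wavelength via
#' `E * lambda / (h c N_A)`. The spectral version [spectral_photon_flux()]
#' integrates `E(lambda) * lambda / (h c N_A)` over a band.
#'
#' @param irradiance irradiance in W m-2 (>= 0).
#' @param wavelength_nm wavelength in nm (> 0).
#' @return Photon flux in umol m-2 s-1.
#' @export
photon_flux <- function(irradiance, wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  if (any(irradiance < 0)) stop("irradiance must be non-negative")
  irradiance * wavelength_nm * 1e-9 / (PLANCK_H * SPEED_C * AVOGADRO) * 1e6
}

#' @rdname photon_flux
#' @param spec a [spectrum()].
#' @param bnd a [band()].
#' @export
spectral_photon_flux <- function(spec, bnd) {
  stopifnot(inherits(spec, "uv_spectrum"), inherits(bnd, "uv_band"))
  wl <- spec$wavelength_nm
  keep <- wl >= bnd$lo & wl <= bnd$hi
  if (!any(keep)) return(0)
  w <- wl[keep]
  e <- spec$irradiance_W_m2_nm[keep]
  trapz_(w, photon_flux(e, w))
}

#' Generalized plant action spectrum
#'
#' Analytic form of the generalized plant damage action spectrum,
#' `2.618 * (1 - (lambda/313.3)^2) * exp(-(lambda - 300)/31.08)` for
#' `lambda < 313.3` nm and 0 above the cutoff, renormalized so that the
#' weight at 300 nm is exactly 1 (the conventional normalization point).
#'
#' @param wavelength_nm wavelengths in nm (vectorized).
#' @return Dimensionless weights, 0 at and beyond 313.3 nm.
#' @export
plant_action_spectrum <- function(wavelength_nm) {
  raw <- function(l) 2.618 * (1 - (l / 313.3)^2) * exp(-(l - 300) / 31.08)
  w <- ifelse(wavelength_nm < 313.3, raw(wavelength_nm), 0)
  pmax(w, 0) / raw(300)
}

#' Biological effectiveness factor of a spectrum
#'
#' Ratio of action-spectrum-weighted to unweighted irradiance,
#' `be = integral(eps(l) E(l) dl) / integral(E(l) dl)`. The weighted dose is
#' then `be * unweighted dose`. [calibrate_be_factor()] derives the same
#' factor empirically from a printed pair of doses.
#'
#' @param spec a [spectrum()].
#' @param action a weighting function of wavelength (nm); default
#'   [plant_action_spectrum()].
#' @return Dimensionless effectiveness factor.
#' @export
be_factor <- function(spec, action = plant_action_spectrum) {
  stopifnot(inherits(spec, "uv_spectrum"))
  wl <- spec$wavelength_nm
  ir <- spec$irradiance_W_m2_nm
  denom <- trapz_(wl, ir)
  if (denom <= 0) stop("spectrum integrates to zero")
  trapz_(wl, ir * action(wl)) / denom
}

#' @rdname be_factor
#' @param unweighted_dose unweighted dose (kJ m-2), > 0.
#' @param be_dose biologically effective dose (kJ m-2).
#' @export
calibrate_be_factor <- function(unweighted_dose, be_dose) {
  if (any(unweighted_dose <= 0)) stop("unweighted dose must be positive")
  be_dose / unweighted_dose
}

#' Exposure schedule
#'
#' Daily UV exposure duration and number of treatment days.
#'
#' @param hours_per_day hours of exposure per day, in `[0, 24]`.
#' @param n_days number of days, >= 0.
#' @param label optional label; default `"<d> d <h> h"`.
#' @return An `exposure_schedule` object.
#' @export
exposure_schedule <- function(hours_per_day, n_days, label = NULL) {
  if (hours_per_day < 0 || hours_per_day > 24) stop("hours_per_day must be in [0, 24]")
  if (n_days < 0) stop("n_days must be >= 0")
  if (is.null(label)) label <- sprintf("%d d %g h", n_days, hours_per_day)
  structure(list(hours_per_day = hours_per_day, n_days = as.integer(n_days),
                 label = label),
            class = "exposure_schedule")
}

#' The six-treatment exposure grid
#'
#' Cross of 6 and 12 h per day with 1, 2 and 3 treatment days, labelled
#' "1 d 6 h" through "3 d 12 h".
#'
#' @return List of six [exposure_schedule()] objects.
#' @export
treatment_grid <- function() {
  out <- list()
  for (d in 1:3) for (h in c(6, 12)) {
    out[[length(out) + 1L]] <- exposure_schedule(h, d)
  }
  names(out) <- vapply(out, function(s) s$label, character(1))
  out
}

#' Cumulative radiant dose over a schedule
#'
#' `dose = irradiance * hours_per_day * 3600 * n_days / 1000` (kJ m-2);
#' exactly linear in irradiance, hours and days.
#'
#' @param irradiance effective irradiance at the reference plane (W m-2), >= 0.
#' @param schedule an [exposure_schedule()].
#' @return Dose in kJ m-2.
#' @export
cumulative_dose <- function(irradiance, schedule) {
  if (any(irradiance < 0)) stop("irradiance must be non-negative")
  stopifnot(inherits(schedule, "exposure_schedule"))
  irradiance * schedule$hours_per_day * 3600 * schedule$n_days / 1000
}

#' @rdname cumulative_dose
#' @param dose_kj_m2 a cumulative dose in kJ m-2.
#' @return `effective_irradiance()`: the constant irradiance (W m-2) that
#'   yields the given dose over the schedule.
#' @export
effective_irradiance <- function(dose_kj_m2, schedule) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  secs <- schedule$hours_per_day * 3600 * schedule$n_days
  if (secs <= 0) stop("schedule has zero exposure time")
  dose_kj_m2 * 1000 / secs
}

#' Dose summary for a treatment
#'
#' Unweighted and biologically effective cumulative doses for one schedule.
#'
#' @param irradiance effective unweighted irradiance (W m-2).
#' @param schedule an [exposure_schedule()].
#' @param be dimensionless effectiveness factor (from [be_factor()] or
#'   [calibrate_be_factor()]).
#' @return List with `label`, `unweighted_kJ_m2`, `be_kJ_m2`, `be_factor`.
#' @export
dose_summary <- function(irradiance, schedule, be) {
  unw <- cumulative_dose(irradiance, schedule)
  list(label = schedule$label, unweighted_kJ_m2 = unw,
       be_kJ_m2 = be * unw, be_factor = be)
}

#' Daily light integral from a constant photon flux
#'
#' @param ppfd photosynthetic photon flux density (umol m-2 s-1).
#' @param hours photoperiod (h per day).
#' @return DLI in mol m-2 d-1.
#' @export
daily_light_integral <- function(ppfd, hours) {
  if (any(ppfd < 0) || any(hours < 0)) stop("ppfd and hours must be non-negative")
  ppfd * hours * 3600 / 1e6
}

#' Read / write spectra as two-column CSV
#'
#' Columns `wavelength_nm`, `irradiance_W_m2_nm`.
#'
#' @param path file path.
#' @param spec a [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  spectrum(df$wavelength_nm, df$irradiance_W_m2_nm)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "uv_spectrum"))
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}
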