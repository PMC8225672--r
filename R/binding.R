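#' Time-resolved FRET ratio
#'
#' Acceptor-over-donor ratio of the emission intensities measured at the two
#' detection wavelengths of a lanthanide-donor Tr-FRET assay (520 nm
#' acceptor channel over 490 nm donor channel, so the ratio increases with
#' transfer). Invariant to a common rescaling of both channels.
#'
#' @param i_490,i_520 Emission intensities at 490 nm (donor channel) and
#'   520 nm (acceptor channel); both > 0. Vectorized.
#' @return The dimensionless ratio `i_520 / i_490`.
#' @examples
#' tr_fret_ratio(i_490 = 4, i_520 = 2)
#' @export
tr_fret_ratio <- function(i_490, i_520) {
  if (any(i_490 <= 0) || any(i_520 <= 0))
    rlang::abort("Both channel intensities must be positive.")
  i_520 / i_490
}

#' Fit a saturation-plus-nonspecific model to a lipid titration
#'
#' Decomposes a Tr-FRET ratio versus lipid-load series into a hyperbolic
#' specific component and a linear nonspecific background:
#' \eqn{r(x) = \mathrm{offset} + B_{max}\,x/(K_{1/2}+x) + s\,x}.
#' The saturation point is reported as the smallest load at which the
#' specific term reaches 95% of its plateau (\eqn{19 K_{1/2}}). When the
#' fitted plateau is indistinguishable from zero (specific amplitude below
#' `bmax_floor` of the observed dynamic range) the series is classified
#' `"nonspecific"` and refit as a straight line - the control-lipid case.
#'
#' @param data A data frame with numeric columns `x` (lipid load,
#'   non-negative and non-decreasing, at least 4 points) and `ratio`.
#' @param bmax_floor Fraction of the observed ratio range below which the
#'   specific plateau is treated as absent (default 0.05).
#' @return An object of class `binding_fit`: a list with `parameters`
#'   (tibble: `term`, `estimate`, `std_error`), `classification`
#'   (`"specific"` or `"nonspecific"`), `saturation_x` (NA for nonspecific
#'   fits), `fitted`, `residuals`, `data`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' ser <- generate_titration()
#' fit_saturation(ser)
#' @export
fit_saturation <- function(data, bmax_floor = 0.05) {
  stopifnot(all(c("x", "ratio") %in% names(data)))
  x <- data$x; y <- data$ratio
  if (length(x) < 4) rlang::abort("At least 4 titration points are required.")
  if (any(x < 0) || is.unsorted(x))
    rlang::abort("`x` must be non-negative and non-decreasing.")
  rng <- diff(range(y))

  start <- list(offset = min(y),
                bmax = max(rng, 1e-6),
                k_half = max(stats::median(x[x > 0]), 1e-3) / 2,
                ns_slope = 1e-4)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      ratio ~ offset + bmax * x / (k_half + x) + ns_slope * x,
      data = list(x = x, ratio = y), start = start,
      lower = c(offset = -Inf, bmax = 0, k_half = 1e-6, ns_slope = 0),
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14))),
    error = function(e) NULL)
  # a pure-linear (control-lipid) series leaves the hyperbola unidentifiable
  # and the optimizer may fail outright; that IS the nonspecific-only case
  if (is.null(fit)) {
    lin <- stats::lm(y ~ x)
    if (stats::sd(stats::residuals(lin)) > 0.25 * max(rng, 1e-12))
      rlang::abort("Saturation fit did not converge and the series is not linear.")
    cf <- c(bmax = 0)
    nonspecific <- TRUE
  } else {
    cf <- stats::coef(fit)
    fit_se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                       error = function(e) NULL)
    # "indistinguishable from 0": small plateau, plateau within noise, or a
    # half-saturation point beyond the sampled range (the hyperbola has
    # degenerated into a second linear term)
    nonspecific <- rng == 0 ||
      cf[["bmax"]] < bmax_floor * rng ||
      (!is.null(fit_se) && is.finite(fit_se[["bmax"]]) &&
         cf[["bmax"]] < 2 * fit_se[["bmax"]]) ||
      cf[["k_half"]] > max(x)
  }
  if (nonspecific) {
    lin <- stats::lm(y ~ x)
    lcf <- stats::coef(lin)
    lse <- summary(lin)$coefficients[, "Std. Error"]
    params <- tibble::tibble(
      term = c("offset", "bmax", "k_half", "ns_slope"),
      estimate = c(lcf[[1]], 0, NA_real_, max(lcf[[2]], 0)),
      std_error = c(lse[[1]], NA_real_, NA_real_, lse[[2]]))
    fitted <- stats::fitted(lin)
    sat <- NA_real_
  } else {
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 4))
    params <- tibble::tibble(
      term = c("offset", "bmax", "k_half", "ns_slope"),
      estimate = unname(cf[c("offset", "bmax", "k_half", "ns_slope")]),
      std_error = unname(se[c("offset", "bmax", "k_half", "ns_slope")]))
    fitted <- stats::fitted(fit)
    sat <- 19 * cf[["k_half"]]
  }
  structure(list(
    parameters = params,
    classification = if (nonspecific) "nonspecific" else "specific",
    saturation_x = unname(sat),
    fitted = as.numeric(fitted), residuals = y - as.numeric(fitted),
    data = tibble::tibble(x = x, ratio = y)
  ), class = "binding_fit")
}

#' Normalize signals to a reference measurement
#'
#' Expresses each signal as a percentage of a reference: the no-competitor
#' lane of a competition assay, or the receptor-free control of a GTP
#' turnover assay (which then reads exactly 100%).
#'
#' @param values Numeric signals.
#' @param reference The reference signal (> 0).
#' @return `100 * values / reference`.
#' @examples
#' normalize_to_reference(c(0.5, 1, 2), reference = 1)
#' @export
normalize_to_reference <- function(values, reference) {
  if (length(reference) != 1 || reference <= 0)
    rlang::abort("`reference` must be a single positive value.")
  100 * values / reference
}

#' Construct a fluorescent-lipid calibration curve
#'
#' Linear intensity-versus-concentration calibration for a labeled lipid,
#' used to convert nanodisc emission intensities into lipid concentrations
#' (and from there lipid-to-receptor molar ratios). Assumes the fluorophore
#' quantum yield is the same in the calibration micelles and in the bilayer.
#'
#' @param slope Intensity per µM of labeled lipid (> 0).
#' @param intercept Intensity at zero lipid.
#' @param valid_range Length-2 numeric, the concentration range (µM) covered
#'   by the standards.
#' @return A `calibration_curve` list.
#' @export
calibration_curve <- function(slope, intercept = 0, valid_range = c(0, Inf)) {
  stopifnot(slope > 0, length(valid_range) == 2, valid_range[1] < valid_range[2])
  structure(list(slope = slope, intercept = intercept,
                 valid_range = valid_range),
            class = "calibration_curve")
}

#' Fit a calibration curve from standards
#'
#' @param data A data frame with columns `conc_um` (µM) and `intensity`.
#' @return A `calibration_curve` covering the range of the standards.
#' @export
fit_calibration <- function(data) {
  stopifnot(all(c("conc_um", "intensity") %in% names(data)))
  cf <- stats::coef(stats::lm(intensity ~ conc_um, data = data))
  calibration_curve(slope = cf[[2]], intercept = cf[[1]],
                    valid_range = range(data$conc_um))
}

#' Labeled-lipid-to-receptor molar ratio from emission intensity
#'
#' Inverts a [calibration_curve()] to get the labeled-lipid concentration
#' from a measured emission intensity, then divides by the receptor
#' concentration to obtain the lipid-to-receptor molar ratio.
#'
#' @param intensity Measured emission intensity. Vectorized.
#' @param curve A [calibration_curve()].
#' @param receptor_conc_um Receptor concentration in µM (> 0; 0.5 µM is the
#'   typical assay setting).
#' @return Molar ratio (dimensionless). Intensities below the intercept map
#'   to ratio 0 with a warning; concentrations outside the curve's valid
#'   range are flagged via attribute `"extrapolated"`.
#' @examples
#' lipid_per_receptor(35, calibration_curve(slope = 10), 0.5)
#' @export
lipid_per_receptor <- function(intensity, curve, receptor_conc_um = 0.5) {
  stopifnot(inherits(curve, "calibration_curve"), receptor_conc_um > 0)
  conc <- (intensity - curve$intercept) / curve$slope
  below <- conc < 0
  if (any(below)) {
    rlang::warn("Intensity below the calibration intercept; ratio reported as 0.")
    conc[below] <- 0
  }
  out_of_range <- conc < curve$valid_range[1] | conc > curve$valid_range[2]
  structure(conc / receptor_conc_um,
            extrapolated = if (any(out_of_range)) out_of_range else NULL)
}

#' Laurdan general polarization
#'
#' Membrane order/fluidity index of the solvatochromic probe laurdan:
#' \eqn{GP = (I_{440} - I_{490}) / (I_{440} + I_{490})}, bounded in
#' \[-1, 1\] and invariant to common intensity scaling.
#'
#' @param i_440,i_490 Emission intensities at 440 and 490 nm (non-negative,
#'   not both zero). Vectorized.
#' @return The general polarization.
#' @examples
#' laurdan_gp(2, 1)
#' @export
laurdan_gp <- function(i_440, i_490) {
  if (any(i_440 < 0) || any(i_490 < 0) || any(i_440 + i_490 <= 0))
    rlang::abort("Intensities must be non-negative with a positive sum.")
  (i_440 - i_490) / (i_440 + i_490)
}
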