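#' Fit a multi-exponential model to a sensitized-emission decay
#'
#' Fits \eqn{I(t) = b + \sum_{i=1}^{n} \alpha_i e^{-t/\tau_i}} to a decay
#' trace by bounded Levenberg-Marquardt least squares. Because biexponential
#' objectives are multimodal, the fit is multi-started from a log-spaced grid
#' of lifetime combinations (50-3000 µs by default), with amplitudes at each
#' start obtained by a linear solve at fixed lifetimes; the best converged
#' start is refined and kept. Components are returned sorted fast-before-slow.
#'
#' In an LRET experiment each exponential component is one conformational
#' species: its lifetime carries the donor-acceptor distance, its
#' pre-exponential amplitude the species population (see
#' [molecular_fractions()]).
#'
#' @param data A data frame with numeric columns `time_us` (strictly
#'   increasing, first value >= 0) and `intensity`; at least 50 samples.
#' @param n_components Number of exponential components, 1 to 3.
#' @param baseline Logical; include a constant offset term (off by default:
#'   traces are typically reported baseline-free as normalized intensity).
#' @param weights `"none"` (unweighted, the default) or `"poisson"`
#'   (weights \eqn{1/\max(I, \epsilon)}, counting-statistics-like).
#' @param lifetime_grid Lifetime grid (µs) from which multi-start
#'   combinations are drawn.
#' @param merge_tol Relative lifetime separation below which two components
#'   are flagged degenerate (default 0.05: lifetimes within 5%).
#'
#' @return An object of class `decay_fit`: a list with elements
#'   `components` (tibble: `component`, `lifetime_us`, `amplitude`, and
#'   standard errors from the fit covariance), `baseline`, `fitted`,
#'   `residuals`, `reduced_chi_square`, `residual_runs_p` (runs test on
#'   residual signs; high p = random residuals = good fit), `degenerate`,
#'   `n_obs`, `label`. Supports [tidy()], [glance()], and
#'   [ggplot2::autoplot()].
#' @examples
#' tr <- generate_decay(c(294.0, 826.8), c(0.353, 0.647))
#' fit <- fit_decay(tr, 2)
#' tidy(fit)
#' @export
fit_decay <- function(data, n_components = 2, baseline = FALSE,
                      weights = c("none", "poisson"),
                      lifetime_grid = exp(seq(log(50), log(3000), length.out = 6)),
                      merge_tol = 0.05) {
  weights <- rlang::arg_match(weights)
  check_decay_trace(data)
  stopifnot(n_components %in% 1:3)
  t <- data$time_us
  y <- data$intensity
  label <- if ("label" %in% names(data)) data$label[[1]] else "trace"
  n_par <- 2L * n_components + as.integer(baseline)
  if (length(y) < 3L * n_par)
    rlang::abort(sprintf("Trace '%s' has %d samples; at least %d (3 per free parameter) are required.",
                         label, length(y), 3L * n_par))
  w <- if (weights == "poisson") 1 / pmax(y, 1e-6 * max(y)) else rep(1, length(y))

  starts <- utils::combn(sort(lifetime_grid), n_components, simplify = FALSE)
  best <- NULL
  for (tau0 in starts) {
    fit <- try_exp_fit(t, y, w, tau0, baseline)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  # retry schedule: perturbed grid, then unweighted linear-solve start
  if (is.null(best)) {
    for (tau0 in starts) {
      fit <- try_exp_fit(t, y, w, tau0 * 1.5, baseline)
      if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
    }
  }
  if (is.null(best))
    rlang::abort(sprintf("Exponential fit did not converge for trace '%s' after the multi-start retry schedule.", label))

  ord <- order(best$tau)
  tau <- best$tau[ord]; alpha <- best$alpha[ord]
  tau_se <- best$tau_se[ord]; alpha_se <- best$alpha_se[ord]
  fitted <- exp_model(t, tau, alpha, best$b)
  res <- y - fitted
  dof <- length(y) - n_par
  degenerate <- n_components > 1 &&
    any(diff(tau) / tau[-length(tau)] < merge_tol)
  if (degenerate)
    rlang::warn(sprintf("Degenerate fit for trace '%s': two lifetimes within %.0f%%; refit with %d component(s).",
                        label, 100 * merge_tol, n_components - 1L))

  structure(list(
    components = tibble::tibble(
      component = seq_along(tau), lifetime_us = tau, amplitude = alpha,
      lifetime_se = tau_se, amplitude_se = alpha_se),
    baseline = best$b, baseline_se = best$b_se,
    fitted = fitted, residuals = res,
    reduced_chi_square = sum(w * res^2) / dof,
    residual_runs_p = runs_test_p(res, tol = 1e-9 * max(abs(y))),
    degenerate = degenerate, n_obs = length(y), label = label,
    data = tibble::tibble(time_us = t, intensity = y)
  ), class = "decay_fit")
}

# single bounded LM fit from one lifetime start; NULL on failure
try_exp_fit <- function(t, y, w, tau0, baseline) {
  n <- length(tau0)
  E <- exp(outer(t, -1 / tau0))
  X <- if (baseline) cbind(E, 1) else E
  alpha0 <- tryCatch(stats::lm.wfit(X, y, w)$coefficients,
                     error = function(e) NULL)
  if (is.null(alpha0) || anyNA(alpha0)) return(NULL)
  alpha0 <- pmax(alpha0, 1e-8)
  par_names <- c(paste0("a", seq_len(n)), paste0("tau", seq_len(n)),
                 if (baseline) "b")
  start <- stats::setNames(
    as.list(c(alpha0[seq_len(n)], tau0, if (baseline) alpha0[n + 1])),
    par_names)
  rhs <- paste(sprintf("a%d * exp(-t / tau%d)", seq_len(n), seq_len(n)),
               collapse = " + ")
  if (baseline) rhs <- paste(rhs, "+ b")
  fml <- stats::as.formula(paste("y ~", rhs))
  lower <- c(rep(0, n), rep(1e-3, n), if (baseline) 0)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      fml, data = list(t = t, y = y), start = start, weights = w,
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  list(alpha = unname(cf[paste0("a", seq_len(n))]),
       tau = unname(cf[paste0("tau", seq_len(n))]),
       alpha_se = unname(se[paste0("a", seq_len(n))]),
       tau_se = unname(se[paste0("tau", seq_len(n))]),
       b = if (baseline) unname(cf[["b"]]) else 0,
       b_se = if (baseline) unname(se[["b"]]) else NA_real_,
       rss = sum(w * stats::residuals(fit)^2))
}

exp_model <- function(t, tau, alpha, b) {
  b + colSums(alpha * exp(outer(-1 / tau, t)))
}

# Wald-Wolfowitz runs test on residual signs (normal approximation).
# Residuals within `tol` of zero (numerically exact fits) count as neither
# sign; if fewer than 10 signed residuals remain the fit is treated as
# numerically exact and p = 1 is returned.
runs_test_p <- function(res, tol = 0) {
  s <- sign(res[abs(res) > tol])
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 + n2 < 10 || n1 == 0 || n2 == 0) return(1)
  r <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  2 * stats::pnorm(-abs((r - mu) / sqrt(v)))
}

check_decay_trace <- function(data) {
  if (!all(c("time_us", "intensity") %in% names(data)))
    rlang::abort("A decay trace needs columns `time_us` and `intensity`.")
  t <- data$time_us; y <- data$intensity
  if (anyNA(t) || anyNA(y)) rlang::abort("Decay trace contains NA values.")
  if (length(t) < 50) rlang::abort("A decay trace needs at least 50 samples.")
  if (t[1] < 0 || is.unsorted(t, strictly = TRUE))
    rlang::abort("`time_us` must be strictly increasing and start at >= 0.")
  if (all(y == 0)) rlang::abort("Intensity is identically zero.")
  invisible(data)
}

#' Select the number of decay components
#'
#' Chooses the smallest number of exponential components that describes a
#' trace: candidate counts are fitted in increasing order and the first fit
#' that both passes the residual-sign runs test (random residuals at
#' `alpha`) and is preferred over the previous count by the corrected Akaike
#' criterion (AICc) is accepted. If a candidate fit is degenerate (two
#' lifetimes within the merge tolerance) the search stops and the previous
#' count is returned: the extra component is not resolvable.
#'
#' @inheritParams fit_decay
#' @param max_components Largest candidate count (<= 3).
#' @param alpha Runs-test significance threshold (residuals random when
#'   p > `alpha`).
#' @param ... Passed on to [fit_decay()].
#' @return An integer: the selected component count. Attribute `"accepted"`
#'   is `FALSE` (with a warning) when no candidate passed and
#'   `max_components` is returned as a fallback.
#' @examples
#' select_model(generate_decay(500, 1))
#' @export
select_model <- function(data, max_components = 3, alpha = 0.05, ...) {
  stopifnot(max_components >= 1, max_components <= 3)
  aicc_prev <- Inf
  for (n in seq_len(max_components)) {
    fit <- tryCatch(
      withCallingHandlers(fit_decay(data, n_components = n, ...),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$degenerate)
      return(structure(max(n - 1L, 1L), accepted = TRUE, degenerate = TRUE))
    aicc <- aicc_from_fit(fit)
    if (fit$residual_runs_p > alpha && aicc < aicc_prev)
      return(structure(n, accepted = TRUE))
    aicc_prev <- aicc
  }
  rlang::warn(sprintf("No component count up to %d gave random residuals; returning %d.",
                      max_components, max_components))
  structure(as.integer(max_components), accepted = FALSE)
}

aicc_from_fit <- function(fit) {
  n <- fit$n_obs
  p <- nrow(fit$components) * 2 + 1  # +1 for the error variance
  rss <- sum(fit$residuals^2)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Molecular fractions of conformational states from a decay fit
#'
#' Converts the pre-exponential amplitudes of a fitted multi-exponential
#' decay into molecular fractions of the coexisting species. Under the
#' `"amplitude"` convention (default) \eqn{A_i = 100\,\alpha_i / \sum_j
#' \alpha_j}; under `"lifetime"` the amplitudes are weighted by their
#' lifetimes first, \eqn{A_i = 100\,\alpha_i \tau_i / \sum_j \alpha_j
#' \tau_j}, which converts amplitude shares into shares of time-integrated
#' emission. The fractions sum to exactly 100 and are ordered as the fit's
#' components (fast first).
#'
#' @param fit A `decay_fit` object from [fit_decay()], or a data frame with
#'   columns `lifetime_us` and `amplitude`.
#' @param convention `"amplitude"` or `"lifetime"` (see above).
#' @return A tibble with columns `component`, `lifetime_us`, `fraction_pct`
#'   and attribute `"convention"`.
#' @examples
#' fit <- fit_decay(generate_decay(c(294.0, 826.8), c(0.353, 0.647)), 2)
#' molecular_fractions(fit)
#' @export
molecular_fractions <- function(fit, convention = c("amplitude", "lifetime")) {
  convention <- rlang::arg_match(convention)
  comp <- if (inherits(fit, "decay_fit")) fit$components else tibble::as_tibble(fit)
  stopifnot(all(c("lifetime_us", "amplitude") %in% names(comp)))
  if (all(comp$amplitude == 0))
    rlang::abort("All amplitudes are zero; fractions are undefined.")
  w <- switch(convention,
              amplitude = comp$amplitude,
              lifetime  = comp$amplitude * comp$lifetime_us)
  out <- tibble::tibble(
    component = seq_len(nrow(comp)),
    lifetime_us = comp$lifetime_us,
    fraction_pct = 100 * w / sum(w))
  attr(out, "convention") <- convention
  out
}
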