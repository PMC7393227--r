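#' PSII maximal photochemical quantum yield
#'
#' Computes `Fv/Fm = (Fm - F0) / Fm` from basal (`f0`) and maximal (`fm`)
#' fluorescence measured by pulse-amplitude-modulated fluorometry. The
#' result is scale-invariant: multiplying both signals by a positive
#' constant leaves it unchanged.
#'
#' @param f0 Basal fluorescence (arbitrary units, > 0 in practice).
#' @param fm Maximal fluorescence after blocking PSII (same units, > 0).
#' @return The quantum yield, a fraction in [0, 1). Vectorised.
#' @export
#' @examples
#' compute_fvfm(1, 2)      # 0.5
#' compute_fvfm(0.2, 0.5)  # 0.6
compute_fvfm <- function(f0, fm) {
  if (any(fm <= 0)) abort("`fm` must be > 0")
  if (any(f0 > fm)) {
    abort(paste0("signal inversion: f0 > fm (f0 = ",
                 paste(f0[f0 > fm], collapse = ", "),
                 "); check dark acclimation / DCMU addition"))
  }
  (fm - f0) / fm
}

#' Express a fluorescence series as percent of its initial value
#'
#' @param values Numeric series; first element must be > 0.
#' @return `values * 100 / values[1]`; the first element is 100.
#' @export
#' @examples
#' percent_of_initial(c(0.5, 0.25))  # 100 50
percent_of_initial <- function(values) {
  if (length(values) == 0) abort("empty series")
  if (values[1] <= 0) abort("first value must be > 0")
  values * 100 / values[1]
}

#' Fit an exponential decay to a fluorescence time series
#'
#' Fits `y = a * exp(-k * t)` by nonlinear least squares, seeded by a
#' log-linear regression of `log(y)` on `t` where all values are positive,
#' and otherwise by a coarse grid over decay rates. The intercept `a` is
#' free (not pinned to the first observation) for robustness to offset at
#' time zero.
#'
#' @param time_h Time points (hours), at least 3.
#' @param values Observed values at `time_h`.
#' @return An object of class `exp_decay_fit` with elements `k` (per hour),
#'   `a`, `sse`, `converged`, `fitted`, `time_h`, `values`.
#' @export
fit_exp_decay <- function(time_h, values) {
  if (length(time_h) < 3 || length(values) != length(time_h)) {
    abort("need >= 3 (time, value) pairs")
  }
  start <- .decay_start(time_h, values)
  df <- data.frame(t = time_h, y = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-k * t), data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-12,
                                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # grid-seeded retry over a decade of rates
    for (k0 in c(0, 10^seq(-3, 1, length.out = 12))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-k * t), data = df,
                          start = list(a = max(values), k = k0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) abort("exponential fit failed to converge")
  cf <- stats::coef(fit)
  fitted <- cf[["a"]] * exp(-cf[["k"]] * time_h)
  structure(list(k = unname(cf[["k"]]), a = unname(cf[["a"]]),
                 sse = sum((values - fitted)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 fitted = fitted, time_h = time_h, values = values),
            class = "exp_decay_fit")
}

.decay_start <- function(time_h, values) {
  if (all(values > 0)) {
    lf <- stats::lm(log(values) ~ time_h)
    list(a = exp(unname(stats::coef(lf)[1])),
         k = max(0, -unname(stats::coef(lf)[2])))
  } else {
    list(a = max(values, 1e-6), k = 0.1)
  }
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: k = %.4g /h, a = %.4g, SSE = %.3g\n",
              x$k, x$a, x$sse))
  invisible(x)
}

#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble(term = c("k", "a"), estimate = c(x$k, x$a))
}

#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble(sse = x$sse, converged = x$converged, n = length(x$time_h))
}

#' Short-term PSII repair rate from paired decay series
#'
#' During a light/UV stress the quantum yield of a control aliquot decays
#' with a net coefficient (damage minus repair), while an aliquot treated
#' with a protein-synthesis inhibitor (lincomycin) decays with the full
#' damage coefficient. The difference between the two fitted exponential
#' coefficients is the repair-rate proxy.
#'
#' @param control,inhibited Tibbles with `time_h` and `value` columns
#'   spanning the stress window.
#' @return An object of class `repair_rate` with `rate`
#'   (`k_inhibited - k_control`, per hour), both component fits, and
#'   `method = "exponential"`.
#' @export
repair_rate_short <- function(control, inhibited) {
  fc <- fit_exp_decay(control$time_h, control$value)
  fi <- fit_exp_decay(inhibited$time_h, inhibited$value)
  structure(list(rate = fi$k - fc$k, k_control = fc$k, k_inhibited = fi$k,
                 fit_control = fc, fit_inhibited = fi,
                 sse = fc$sse + fi$sse,
                 converged = fc$converged && fi$converged,
                 method = "exponential"),
            class = "repair_rate")
}

#' Long-term PSII repair rate from a one-hour inhibitor assay
#'
#' For multi-day stresses and diel cycles, paired control/inhibited
#' aliquots are monitored over one hour (typically 0, 0.25, 0.5 and 1 h).
#' Each arm's decline rate is the negated slope of a linear regression of
#' quantum yield on time; the repair rate is the difference of decline
#' rates (inhibited minus control), so an active repair cycle gives a
#' positive rate. Three time points under-determine a two-parameter
#' exponential at realistic noise, hence the linear model.
#'
#' @param control,inhibited Tibbles with `time_h` and `value`; replicate
#'   measurements at the same time are supported and pooled in the
#'   regression.
#' @return An object of class `repair_rate` with `rate` (per hour) and the
#'   per-arm slopes; `method = "linear"`.
#' @export
repair_rate_long <- function(control, inhibited) {
  for (arm in list(control, inhibited)) {
    if (length(unique(arm$time_h)) < 3) {
      abort("need >= 3 distinct time points per arm")
    }
  }
  sl <- function(d) unname(stats::coef(stats::lm(value ~ time_h, data = d))[2])
  s_c <- sl(control); s_i <- sl(inhibited)
  structure(list(rate = (-s_i) - (-s_c), k_control = -s_c, k_inhibited = -s_i,
                 slope_control = s_c, slope_inhibited = s_i,
                 converged = TRUE, method = "linear"),
            class = "repair_rate")
}

#' @export
print.repair_rate <- function(x, ...) {
  cat(sprintf("PSII repair rate (%s): %.4g /h (control %.4g, inhibited %.4g)\n",
              x$method, x$rate, x$k_control, x$k_inhibited))
  invisible(x)
}

#' @export
tidy.repair_rate <- function(x, ...) {
  tibble(term = c("k_control", "k_inhibited", "rate"),
         estimate = c(x$k_control, x$k_inhibited, x$rate))
}

#' @export
glance.repair_rate <- function(x, ...) {
  tibble(rate = x$rate, method = x$method, converged = x$converged,
         sse = x$sse %||% NA_real_)
}

#' Phycobilisome emission-peak ratios from a fluorescence spectrum
#'
#' Extracts peak heights as window maxima: phycoerythrin (PE) in
#' 565-575 nm, phycocyanin (PC) in 645-655 nm, and the phycobilisome
#' terminal acceptor (TA) in a 680 +/- 5 nm window. Reports the PE/PC
#' ratio (energy transfer within the rods) and the PC/TA ratio (transfer
#' from the rods to the reaction-center chlorophylls).
#'
#' @param wavelength_nm Wavelength grid (nm) covering all three windows.
#' @param intensity Emission intensities on the grid (>= 0).
#' @param ta_halfwidth Half-width of the TA window in nm (default 5).
#' @return A one-row tibble: `pe_height`, `pc_height`, `ta_height`,
#'   `pe_pc`, `pc_ta`.
#' @export
spectrum_ratios <- function(wavelength_nm, intensity, ta_halfwidth = 5) {
  windows <- list(pe = c(565, 575), pc = c(645, 655),
                  ta = c(680 - ta_halfwidth, 680 + ta_halfwidth))
  h <- purrr::map_dbl(windows, function(w) {
    sel <- wavelength_nm >= w[1] & wavelength_nm <= w[2]
    if (!any(sel)) abort(sprintf("grid does not cover the %g-%g nm window",
                                 w[1], w[2]))
    max(intensity[sel])
  })
  floor_h <- 1e-9 * max(intensity)
  if (h[["pc"]] <= floor_h) {
    abort("phycocyanin window has no signal: PE/PC and PC/TA undefined")
  }
  if (h[["ta"]] <= floor_h) abort("terminal-acceptor window has no signal")
  tibble(pe_height = h[["pe"]], pc_height = h[["pc"]], ta_height = h[["ta"]],
         pe_pc = h[["pe"]] / h[["pc"]], pc_ta = h[["pc"]] / h[["ta"]])
}
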