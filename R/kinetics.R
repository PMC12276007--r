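#' Construct a kinetic trace
#'
#' A time series of CD signal: folding traces (signal vs time) or melting
#' curves (signal vs temperature, `unit = "C"`).
#'
#' @param times Strictly increasing time points (or temperatures).
#' @param signal Signal values (molar CD absorption or raw ellipticity).
#' @param unit Time base: `"min"` (default), `"s"`, `"h"`, or `"C"` for a
#'   temperature axis.
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, unit = c("min", "s", "h", "C")) {
  unit <- match.arg(unit)
  stopifnot(length(times) == length(signal),
            all(is.finite(times)), all(is.finite(signal)))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 unit = unit),
            class = "kinetic_trace")
}

#' Construct an HDX exchange series
#'
#' Normalized imino-proton integrals versus time in D2O. Integrals are
#' normalized to the first recorded point; times are hours since D2O
#' addition.
#'
#' @param times Hours since exchange initiation (non-negative, increasing).
#' @param integrals Normalized absolute integrals.
#' @return Object of class `exchange_series`.
#' @export
exchange_series <- function(times, integrals) {
  stopifnot(length(times) == length(integrals),
            all(is.finite(times)), all(is.finite(integrals)),
            all(times >= 0))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), integrals = as.numeric(integrals)),
            class = "exchange_series")
}

# Robust point-noise estimate from successive differences.
noise_estimate <- function(y) {
  if (length(y) < 3) return(0)
  stats::mad(diff(y)) / sqrt(2)
}

r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

nls_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13, maxiter = 1000,
                             maxfev = 10000)
}

# Levenberg-Marquardt on a model function; returns converged parameters and
# fitted values. Uses the residual-function interface, which stays robust
# on zero-residual (noiseless) data.
lm_fit <- function(model_fn, start, lower, upper, y) {
  res <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) y - model_fn(p),
    control = nls_control())
  if (res$info == 0 || res$info == 5) {
    stop("nonlinear fit did not converge", call. = FALSE)
  }
  p <- as.list(res$par)
  list(par = p, fitted = model_fn(p))
}

#' Fit a single-exponential transition
#'
#' Least-squares fit of \eqn{S(t) = S_\infty + (S_0 - S_\infty) e^{-kt}} to
#' a folding (or relaxation) trace. pUG folding traces are monophasic, with
#' half-lives of 17/13/30 min for chains of 12/15/18 repeats.
#'
#' A trace whose amplitude is indistinguishable from noise returns a
#' "no transition" result (`no_transition = TRUE`, parameters `NA`) rather
#' than an arbitrary fit.
#'
#' @param trace A [kinetic_trace()] with at least 5 points.
#' @return List of class `exp_fit`: `k` (per time unit), `s0`, `s_inf`,
#'   `amplitude` (`s_inf - s0`), `t_half` (`ln 2 / k`), `fit_r2`,
#'   `residuals`, `unit`, `no_transition`.
#' @export
fit_single_exponential <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times; y <- trace$signal
  if (length(t) < 5) stop("need at least 5 points to fit", call. = FALSE)

  amp_obs <- diff(range(y))
  noise <- noise_estimate(y)
  # the range of n i.i.d. Gaussian points grows like sigma * 2*sqrt(2 log n);
  # demand the observed span clear that plus a safety margin
  flat_cutoff <- noise * (2 * sqrt(2 * log(length(y))) + 4)
  if (amp_obs <= max(flat_cutoff, 1e-12 * max(1, max(abs(y))))) {
    return(structure(
      list(k = NA_real_, s0 = NA_real_, s_inf = NA_real_,
           amplitude = NA_real_, t_half = NA_real_, fit_r2 = NA_real_,
           residuals = NULL, unit = trace$unit, no_transition = TRUE),
      class = "exp_fit"))
  }

  n <- length(y)
  s_inf0 <- mean(y[max(1, n - 2):n])
  s00 <- y[1]
  # time at which the remaining amplitude has halved seeds the rate
  half_idx <- which(abs(y - s_inf0) <= abs(s00 - s_inf0) / 2)
  t_half0 <- if (length(half_idx)) max(t[min(half_idx)], diff(range(t)) / 100)
             else diff(range(t)) / 2
  k0 <- log(2) / t_half0

  # offset/amplitude parameterisation: S(t) = s_inf + amp * exp(-k t),
  # amp = s0 - s_inf
  fit <- lm_fit(
    function(p) p$s_inf + p$amp * exp(-p$k * t),
    start = list(s_inf = s_inf0, amp = s00 - s_inf0, k = k0),
    lower = c(-Inf, -Inf, 0), upper = rep(Inf, 3), y = y)
  p <- fit$par
  p$s0 <- p$s_inf + p$amp
  yhat <- fit$fitted
  structure(
    list(k = p$k, s0 = p$s0, s_inf = p$s_inf,
         amplitude = -p$amp, t_half = log(2) / p$k,
         fit_r2 = r_squared(y, yhat), residuals = y - yhat,
         unit = trace$unit, no_transition = FALSE),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (isTRUE(x$no_transition)) {
    cat("single-exponential fit: no transition detected\n")
  } else {
    cat(sprintf(
      "single-exponential fit: k = %.4g per %s, t1/2 = %.4g %s, R2 = %.4f\n",
      x$k, x$unit, x$t_half, x$unit, x$fit_r2))
  }
  invisible(x)
}

#' Fit a mono-exponential HDX decay
#'
#' Fits \eqn{I(t) = [I(0) - I(\infty)] e^{-k_{ex} t} + I(\infty)} to a
#' normalized imino-integral series. By default the fully exchanged floor
#' \eqn{I(\infty)} is constrained to 0 (residual H2O is negligible: no
#' imino signal remains after months in D2O).
#'
#' @param series An [exchange_series()] with at least 5 points.
#' @param constrain_floor_to_zero Fix \eqn{I(\infty) = 0} (default `TRUE`).
#' @return Object of class `exchange_fit` with `model = "mono"`: `I0`,
#'   `Iinf`, `k_ex` (per hour), `t_half` (h), `fit_r2`,
#'   `boundary_zero_rate` (flagged when no decay is resolved).
#' @export
fit_hdx_mono <- function(series, constrain_floor_to_zero = TRUE) {
  stopifnot(inherits(series, "exchange_series"))
  t <- series$times; y <- series$integrals
  if (length(t) < 5) stop("need at least 5 points to fit", call. = FALSE)

  decay <- 1 - min(y) / max(y)
  noise <- noise_estimate(y)
  if (max(y) <= 0 || decay <= max(4 * noise / max(abs(y)), 1e-10)) {
    return(structure(
      list(model = "mono", I0 = mean(y), Iinf = 0, k_ex = 0,
           t_half = Inf, fit_r2 = NA_real_, boundary_zero_rate = TRUE,
           degenerate = FALSE),
      class = "exchange_fit"))
  }

  pos <- y > 0
  lmfit <- stats::lm(log(y[pos]) ~ t[pos])
  k0 <- max(-stats::coef(lmfit)[[2]], 1e-8)
  I00 <- exp(stats::coef(lmfit)[[1]])

  if (constrain_floor_to_zero) {
    fit <- lm_fit(
      function(p) p$I0 * exp(-p$k * t),
      start = list(I0 = I00, k = k0),
      lower = c(0, 0), upper = c(Inf, Inf), y = y)
    p <- fit$par; p$Iinf <- 0
  } else {
    fit <- lm_fit(
      function(p) (p$I0 - p$Iinf) * exp(-p$k * t) + p$Iinf,
      start = list(I0 = I00, Iinf = min(y), k = k0),
      lower = c(0, -Inf, 0), upper = rep(Inf, 3), y = y)
    p <- fit$par
  }
  if (p$k <= 0) stop("fitted exchange rate is non-positive", call. = FALSE)
  yhat <- fit$fitted
  structure(
    list(model = "mono", I0 = p$I0, Iinf = p$Iinf, k_ex = p$k,
         t_half = log(2) / p$k, fit_r2 = r_squared(y, yhat),
         boundary_zero_rate = p$k < 1e-7, degenerate = FALSE),
    class = "exchange_fit")
}

#' Fit a biexponential HDX decay
#'
#' Long pUG chains exchange biphasically: a fast phase (segmental register
#' exchange, half-life ~30 min) superimposed on slow global unfolding
#' (half-lives of days). Fits
#' \deqn{I(t) = I_0 [f e^{-k_{fast} t} + (1-f) e^{-k_{slow} t}]}
#' with floor 0, \eqn{0 \le f \le 1}, and rates ordered
#' \eqn{k_{fast} > k_{slow}} after fitting. The fast-phase amplitude
#' fraction `fast_fraction` corresponds to the reported "ratio fast"
#' (~50% for chains of 13-18 repeats).
#'
#' Rates are seeded by log-linear regression on the late third (slow) and
#' early points (fast) of the decay, with `f` started at 0.5. If the two
#' fitted rates are within a factor of 3 the fit is flagged degenerate and
#' a mono-exponential refit is returned instead.
#'
#' @param series An [exchange_series()] with at least 8 points spanning
#'   both phases.
#' @return Object of class `exchange_fit` with `model = "biexp"`: `I0`,
#'   `k_ex_fast`, `k_ex_slow` (per hour), `fast_fraction`, `t_half_fast`,
#'   `t_half_slow` (h), `fit_r2`, `degenerate`. Degenerate inputs return
#'   the mono refit (`model = "mono"`, `degenerate = TRUE`).
#' @export
fit_hdx_biexponential <- function(series) {
  stopifnot(inherits(series, "exchange_series"))
  t <- series$times; y <- series$integrals
  if (length(t) < 8) {
    stop("need at least 8 points spanning both phases", call. = FALSE)
  }

  # seed slow rate from the late third, fast from the earliest decaying span
  late <- t >= stats::quantile(t, 2 / 3)
  pos <- y > 0
  ks0 <- tryCatch({
    sel <- late & pos
    max(-stats::coef(stats::lm(log(y[sel]) ~ t[sel]))[[2]], 1e-8)
  }, error = function(e) 1e-3)
  early <- seq_len(max(4, ceiling(length(t) / 3)))
  kf0 <- tryCatch({
    sel <- intersect(early, which(pos))
    max(-stats::coef(stats::lm(log(y[sel]) ~ t[sel]))[[2]], 10 * ks0)
  }, error = function(e) 100 * ks0)
  if (kf0 <= ks0) kf0 <- 100 * ks0

  fit <- tryCatch(
    lm_fit(
      function(p) p$I0 * (p$f * exp(-p$kf * t) + (1 - p$f) * exp(-p$ks * t)),
      start = list(I0 = max(y), f = 0.5, kf = kf0, ks = ks0),
      lower = c(0, 0, 0, 0), upper = c(Inf, 1, Inf, Inf), y = y),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- fit_hdx_mono(series)
    out$degenerate <- TRUE
    return(out)
  }
  p <- fit$par
  # enforce rate ordering
  if (p$kf < p$ks) {
    tmp <- p$kf; p$kf <- p$ks; p$ks <- tmp
    p$f <- 1 - p$f
  }
  if (p$ks <= 0 || p$f < 0.005 || p$f > 0.995 || p$kf / p$ks < 3) {
    out <- fit_hdx_mono(series)
    out$degenerate <- TRUE
    return(out)
  }
  yhat <- fit$fitted
  structure(
    list(model = "biexp", I0 = p$I0, Iinf = 0,
         k_ex_fast = p$kf, k_ex_slow = p$ks, fast_fraction = p$f,
         t_half_fast = log(2) / p$kf, t_half_slow = log(2) / p$ks,
         fit_r2 = r_squared(y, yhat), degenerate = FALSE,
         boundary_zero_rate = FALSE),
    class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  if (identical(x$model, "biexp")) {
    cat(sprintf(
      paste0("biexponential HDX fit: k_fast = %.4g /h (t1/2 %.3g h), ",
             "k_slow = %.4g /h (t1/2 %.3g h), ratio fast %.1f%%, R2 = %.4f\n"),
      x$k_ex_fast, x$t_half_fast, x$k_ex_slow, x$t_half_slow,
      100 * x$fast_fraction, x$fit_r2))
  } else {
    flag <- if (isTRUE(x$boundary_zero_rate)) " [k ~ 0 boundary]" else ""
    deg <- if (isTRUE(x$degenerate)) " [degenerate biexp, mono refit]" else ""
    cat(sprintf(
      "mono-exponential HDX fit: k_ex = %.4g /h (t1/2 %.3g h)%s%s\n",
      x$k_ex, x$t_half, flag, deg))
  }
  invisible(x)
}

#' Fit a Boltzmann sigmoidal melting curve
#'
#' Thermal denaturation followed by CD is fit to the two-state Boltzmann
#' sigmoid
#' \deqn{y(T) = A_2 + (A_1 - A_2) / (1 + e^{(T - T_m)/dT})}
#' where \eqn{A_1}, \eqn{A_2} are the folded and unfolded baselines and
#' \eqn{T_m} the midpoint melting temperature. Either monotone direction is
#' accepted (the baselines are free).
#'
#' @param curve A [kinetic_trace()] with `unit = "C"` (temperature axis).
#' @return Object of class `melt_fit`: `Tm` (degrees C), `A1`, `A2`, `dT`,
#'   `fit_r2`, `Tm_in_range`.
#' @export
fit_boltzmann_melt <- function(curve) {
  stopifnot(inherits(curve, "kinetic_trace"))
  if (curve$unit != "C") {
    stop("melting curves must use unit = 'C'", call. = FALSE)
  }
  temp <- curve$times; y <- curve$signal
  if (length(temp) < 5) stop("need at least 5 points to fit", call. = FALSE)

  amp <- diff(range(y))
  if (amp <= max(4 * noise_estimate(y), 1e-12 * max(1, max(abs(y))))) {
    stop("no sigmoidal transition detected (flat curve)", call. = FALSE)
  }

  n <- length(y)
  a10 <- mean(y[1:min(3, n)])
  a20 <- mean(y[max(1, n - 2):n])
  tm0 <- temp[which.min(abs(y - (a10 + a20) / 2))]
  dt0 <- diff(range(temp)) / 10

  # offset/amplitude parameterisation, amp = A1 - A2
  fit <- lm_fit(
    function(p) p$A2 + p$amp / (1 + exp((temp - p$Tm) / p$dT)),
    start = list(A2 = a20, amp = a10 - a20, Tm = tm0, dT = dt0),
    lower = c(-Inf, -Inf, -Inf, 1e-6), upper = rep(Inf, 4), y = y)
  p <- fit$par
  p$A1 <- p$A2 + p$amp
  in_range <- p$Tm >= min(temp) && p$Tm <= max(temp)
  if (!in_range) {
    warning("fitted Tm lies outside the measured temperature range")
  }
  structure(
    list(Tm = p$Tm, A1 = p$A1, A2 = p$A2, dT = p$dT,
         fit_r2 = r_squared(y, fit$fitted), Tm_in_range = in_range),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f C (width %.2f C), R2 = %.4f\n",
              x$Tm, x$dT, x$fit_r2))
  invisible(x)
}

time_unit_seconds <- c(s = 1, min = 60, h = 3600, day = 86400)

#' Rate and half-life conversions
#'
#' First-order kinetics: `t_half = ln(2) / k` in the same time base, and
#' explicit conversions between time bases (s, min, h, day). A 13-min
#' folding half-life corresponds to a rate of `ln(2)/780 s` = 0.0009 per
#' second.
#'
#' @param k First-order rate constant (> 0), in `1/unit`.
#' @param t_half Half-life (> 0), in `unit`.
#' @param x Time value(s) to convert.
#' @param from,to Time units: `"s"`, `"min"`, `"h"`, or `"day"`.
#' @return `halflife_from_rate()` and `rate_from_halflife()` return values
#'   in the same time base as their input; `convert_time()` and
#'   `convert_rate()` convert between bases.
#' @examples
#' rate_from_halflife(convert_time(13, "min", "s"))  # ~0.0009 per s
#' halflife_from_rate(0.0114)                        # ~60.8 h for k in 1/h
#' @name rate_conversions
NULL

#' @rdname rate_conversions
#' @export
halflife_from_rate <- function(k) {
  stopifnot(all(k > 0))
  log(2) / k
}

#' @rdname rate_conversions
#' @export
rate_from_halflife <- function(t_half) {
  stopifnot(all(t_half > 0))
  log(2) / t_half
}

#' @rdname rate_conversions
#' @export
convert_time <- function(x, from, to) {
  from <- match.arg(from, names(time_unit_seconds))
  to <- match.arg(to, names(time_unit_seconds))
  x * time_unit_seconds[[from]] / time_unit_seconds[[to]]
}

#' @rdname rate_conversions
#' @export
convert_rate <- function(k, from, to) {
  from <- match.arg(from, names(time_unit_seconds))
  to <- match.arg(to, names(time_unit_seconds))
  k * time_unit_seconds[[to]] / time_unit_seconds[[from]]
}

#' Regional versus global HDX fit consistency
#'
#' Spectral integrations can be split into regions (e.g. halves of the
#' imino region) and fit separately; the global fit should agree with each
#' regional fit. Fits each region and the global series mono-exponentially
#' and reports the maximum relative discrepancy in `k_ex`.
#'
#' @param series Global [exchange_series()].
#' @param regions List of [exchange_series()] objects, the regional splits.
#' @param threshold Maximum relative discrepancy considered consistent
#'   (default 0.25).
#' @return List of class `split_fit_report`: `k_global`, `k_regions`,
#'   `max_rel_discrepancy`, `consistent`.
#' @export
split_fit_consistency <- function(series, regions, threshold = 0.25) {
  stopifnot(is.list(regions), length(regions) >= 1)
  global_fit <- fit_hdx_mono(series)
  region_fits <- lapply(regions, fit_hdx_mono)
  k_g <- global_fit$k_ex
  k_r <- vapply(region_fits, function(f) f$k_ex, numeric(1))
  if (k_g <= 0) stop("global fit has zero rate; nothing to compare",
                     call. = FALSE)
  max_rel <- max(abs(k_r - k_g) / k_g)
  structure(
    list(k_global = k_g, k_regions = k_r,
         max_rel_discrepancy = max_rel,
         consistent = max_rel <= threshold),
    class = "split_fit_report")
}

#' @export
print.split_fit_report <- function(x, ...) {
  cat(sprintf(
    "split-fit consistency: global k = %.4g /h, max regional discrepancy %.1f%% (%s)\n",
    x$k_global, 100 * x$max_rel_discrepancy,
    if (x$consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}
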