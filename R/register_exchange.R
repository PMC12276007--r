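#' Construct a segmental register-exchange model
#'
#' The pUG fold comprises four 3-repeat segments. When single-stranded
#' repeats flank the fold, the two terminal segments (5' and 3') can swap
#' register with the flanking repeats — transiently opening their quartet
#' hydrogen bonds — much faster than the whole fold unfolds. In D2O this
#' produces biphasic imino-proton exchange: a fast phase whose amplitude is
#' the exchangeable fraction of segments (2/4 = 50% whenever any flank
#' exists), superimposed on slow global unfolding.
#'
#' @param k_flip Register-exchange (terminal-segment opening) rate, per
#'   hour, >= 0.
#' @param k_unfold Global unfolding rate, per hour, >= 0.
#' @param flank_5,flank_3 Flanking single-stranded repeats on each side,
#'   >= 0.
#' @param n_segments Segments per fold (4 for the pUG fold).
#' @param n_exchangeable Exchange-competent terminal segments when a flank
#'   exists (default 2: the 5' and 3' segments).
#' @return Object of class `register_exchange_model`.
#' @export
register_exchange_model <- function(k_flip, k_unfold, flank_5 = 0, flank_3 = 0,
                                    n_segments = 4, n_exchangeable = 2) {
  stopifnot(k_flip >= 0, k_unfold >= 0, flank_5 >= 0, flank_3 >= 0,
            n_segments >= 1, n_exchangeable >= 0,
            n_exchangeable <= n_segments)
  exch <- if (flank_5 + flank_3 > 0) n_exchangeable else 0L
  structure(
    list(k_flip = k_flip, k_unfold = k_unfold,
         flank_5 = flank_5, flank_3 = flank_3,
         n_segments = n_segments, exchangeable_segments = exch),
    class = "register_exchange_model")
}

#' @export
print.register_exchange_model <- function(x, ...) {
  cat(sprintf(
    paste0("register-exchange model: %d/%d exchangeable segments, ",
           "k_flip = %.4g /h, k_unfold = %.4g /h, flanks (%g, %g) repeats\n"),
    x$exchangeable_segments, x$n_segments, x$k_flip, x$k_unfold,
    x$flank_5, x$flank_3))
  invisible(x)
}

#' Exchange-competent segment fraction from flank lengths
#'
#' With no flanking repeats on either side no register exchange is possible
#' (monophasic HDX, as for the minimal (GU)12). With any flanking repeats,
#' both terminal segments participate over the stochastic ensemble of fold
#' positions — folds sit at random registers, so flanks are distributed on
#' both sides across molecules — giving a fast-phase amplitude of
#' `n_exchangeable / n_segments` = 2/4 = 50%, independent of flank length.
#'
#' @param flank_5,flank_3 Flanking repeats (>= 0).
#' @param n_segments,n_exchangeable See [register_exchange_model()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' exchangeable_fraction(0, 0)  # 0: (GU)12, monophasic
#' exchangeable_fraction(3, 0)  # 0.5: e.g. (GU)15 ensemble
#' @export
exchangeable_fraction <- function(flank_5, flank_3, n_segments = 4,
                                  n_exchangeable = 2) {
  stopifnot(flank_5 >= 0, flank_3 >= 0, n_segments >= 1, n_exchangeable >= 0)
  if (flank_5 + flank_3 == 0) return(0)
  min(n_exchangeable / n_segments, 1)
}

#' Analytic HDX survival of the register-exchange model
#'
#' In the EX1 limit (every opening event exchanges the segment's imino
#' protons) with irreversible deuterium labeling, the unexchanged fraction
#' is
#' \deqn{S(t) = a\, e^{-(k_{flip} + k_{unfold}) t} + (1 - a)\, e^{-k_{unfold} t}}
#' where `a` is the exchangeable segment fraction: terminal segments
#' exchange at `k_flip + k_unfold` (register flips plus global unfolding),
#' interior segments only via global unfolding.
#'
#' @param model A [register_exchange_model()].
#' @param times Hours (>= 0) at which to evaluate survival.
#' @return Object of class `hdx_prediction`: `times`, `survival`,
#'   `fast_amplitude`, `k_fast_effective` (`k_flip + k_unfold`),
#'   `k_slow_effective` (`k_unfold`).
#' @export
analytic_hdx <- function(model, times) {
  stopifnot(inherits(model, "register_exchange_model"), all(times >= 0))
  a <- model$exchangeable_segments / model$n_segments
  kf <- model$k_flip + model$k_unfold
  ks <- model$k_unfold
  surv <- a * exp(-kf * times) + (1 - a) * exp(-ks * times)
  structure(
    list(times = as.numeric(times), survival = surv, fast_amplitude = a,
         k_fast_effective = kf, k_slow_effective = ks, mc_se = NULL,
         n_molecules = NULL),
    class = "hdx_prediction")
}

#' Stochastic (Gillespie) realization of the register-exchange model
#'
#' Simulates the continuous-time Markov scheme molecule by molecule: each
#' exchange-competent terminal segment flips at rate `k_flip`
#' (irreversibly marking its imino protons exchanged — deuterium uptake is
#' one-way in excess D2O), and the whole molecule unfolds at rate
#' `k_unfold` (marking all segments exchanged). Waiting times are
#' exponential, so per segment the first marking event occurs at
#' `min(Exp(k_flip), Exp(k_unfold))`. The ensemble-averaged unexchanged
#' fraction is reported at the requested times, with its Monte-Carlo
#' standard error.
#'
#' @param model A [register_exchange_model()].
#' @param n_molecules Ensemble size (>= 1).
#' @param times Hours at which to report survival.
#' @param seed Integer seed.
#' @return Object of class `hdx_prediction` as for [analytic_hdx()], plus
#'   `mc_se` (per-time Monte-Carlo standard error) and `n_molecules`.
#' @export
gillespie_hdx <- function(model, n_molecules, times, seed) {
  stopifnot(inherits(model, "register_exchange_model"),
            n_molecules >= 1, all(times >= 0), is.numeric(seed))
  set.seed(as.integer(seed))
  n_seg <- model$n_segments
  n_ex <- model$exchangeable_segments

  t_unfold <- if (model$k_unfold > 0) {
    stats::rexp(n_molecules, rate = model$k_unfold)
  } else rep(Inf, n_molecules)
  t_flip <- if (n_ex > 0 && model$k_flip > 0) {
    matrix(stats::rexp(n_molecules * n_ex, rate = model$k_flip),
           nrow = n_molecules)
  } else matrix(Inf, nrow = n_molecules, ncol = max(n_ex, 1))

  surv <- numeric(length(times))
  se <- numeric(length(times))
  for (i in seq_along(times)) {
    tt <- times[i]
    # per molecule: count of segments still protonated at tt
    n_interior <- n_seg - n_ex
    interior_alive <- n_interior * (t_unfold > tt)
    exch_alive <- if (n_ex > 0) {
      rowSums(pmin(t_flip[, seq_len(n_ex), drop = FALSE], t_unfold) > tt)
    } else 0
    frac <- (interior_alive + exch_alive) / n_seg
    surv[i] <- mean(frac)
    se[i] <- stats::sd(frac) / sqrt(n_molecules)
  }
  structure(
    list(times = as.numeric(times), survival = surv,
         fast_amplitude = n_ex / n_seg,
         k_fast_effective = model$k_flip + model$k_unfold,
         k_slow_effective = model$k_unfold,
         mc_se = se, n_molecules = n_molecules),
    class = "hdx_prediction")
}

#' @export
print.hdx_prediction <- function(x, ...) {
  kind <- if (is.null(x$n_molecules)) "analytic" else
    sprintf("stochastic (%d molecules)", x$n_molecules)
  cat(sprintf(
    paste0("HDX prediction (%s): fast amplitude %.0f%%, ",
           "k_fast = %.4g /h, k_slow = %.4g /h, %d time points\n"),
    kind, 100 * x$fast_amplitude, x$k_fast_effective, x$k_slow_effective,
    length(x$times)))
  invisible(x)
}

#' Convert an HDX prediction to an exchange series
#'
#' Convenience bridge to the fitting functions: wraps the predicted
#' survival curve as an [exchange_series()] (dropping any `t = 0` anchor is
#' not needed; survival at 0 is 1).
#'
#' @param prediction An `hdx_prediction`.
#' @return An [exchange_series()].
#' @export
as_exchange_series <- function(prediction) {
  stopifnot(inherits(prediction, "hdx_prediction"))
  exchange_series(prediction$times, prediction$survival)
}
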