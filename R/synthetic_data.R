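#' @title Seeded synthetic-data generators
#' @description Generators that emulate every data type the analysis
#'   consumes — CD spectra with the pUG fold's four characteristic peaks,
#'   single-exponential folding traces, mono/biexponential HDX decays,
#'   Boltzmann melting curves, and RNase digest fragment tables — with
#'   additive Gaussian noise and full seed determinism.
#' @name synthetic_data
NULL

# Gaussian band parameters of the synthetic pUG fold basis spectrum:
# centers/signs follow the four characteristic peaks (negative 245 nm,
# positive 260 nm, positive 281 nm, negative 304 nm); width 6 nm; relative
# amplitudes are package constants (all analyses are ratio-based).
pug_cd_bands <- data.frame(
  center = c(245, 260, 281, 304),
  amplitude = c(-6, 8, 5, -4),
  sigma = 6
)

# Default acquisition conditions for generated spectra (20 uM RNA, 1 mm
# path), matching typical CD practice for these RNAs.
default_cd_concentration <- 20e-6
default_cd_path <- 0.1

# Noiseless basis: delta_eps of the canonical (GU)12 reference at scale 1.
pug_basis_delta_eps <- function(wavelengths) {
  rowSums(vapply(seq_len(nrow(pug_cd_bands)), function(i) {
    b <- pug_cd_bands[i, ]
    b$amplitude * exp(-((wavelengths - b$center)^2) / (2 * b$sigma^2))
  }, numeric(length(wavelengths))))
}

#' The canonical (GU)12 reference spectrum
#'
#' Noiseless molar CD absorption of the (GU)12 reference against which
#' fraction-folded measurements are normalized. The real (GU)12 is 95%
#' folded (its 3' terminal U is unstructured), which is why measurements
#' against this reference carry the 0.95 factor; the reference basis is at
#' scale 1 by construction, so a sample measured against it returns its
#' model folded fraction.
#'
#' @param wavelengths Wavelength grid in nm (default 210-340, 1 nm step).
#' @return A `molar_cd` object.
#' @export
reference_gu12 <- function(wavelengths = 210:340) {
  structure(
    list(wavelengths = as.numeric(wavelengths),
         delta_eps = pug_basis_delta_eps(wavelengths)),
    class = "molar_cd")
}

#' Generate a synthetic CD spectrum
#'
#' Emulates the CD spectrum of an `n_nt`-nucleotide pUG chain carrying
#' `n_folds` pUG folds (fractional fold counts describe ensemble averages).
#' The basis spectrum is a sum of Gaussian bands at the four characteristic
#' peaks, scaled by `expected_fraction_folded(n_nt, n_folds) / 0.95`
#' relative to the [reference_gu12()] basis, so that
#' [fraction_folded()] of the generated spectrum against the canonical
#' reference recovers the model folded fraction. Gaussian noise is added to
#' the raw ellipticity.
#'
#' @param n_nt Chain length in nucleotides.
#' @param n_folds Number of folds (capacity `n_folds * 24 <= n_nt`; may be
#'   fractional).
#' @param noise_sd Noise standard deviation as a fraction of the dynamic
#'   range of the raw signal (default 0.02).
#' @param seed Integer seed.
#' @param wavelengths Grid in nm (default 210-340, step 1).
#' @param concentration,path_length Acquisition metadata stored in the
#'   spectrum (defaults 20 uM, 0.1 cm).
#' @return A [cd_spectrum()] (raw ellipticity plus metadata).
#' @export
generate_cd_spectrum <- function(n_nt, n_folds, noise_sd = 0.02, seed = 1,
                                 wavelengths = 210:340,
                                 concentration = default_cd_concentration,
                                 path_length = default_cd_path) {
  frac <- expected_fraction_folded(n_nt, n_folds)  # validates capacity
  set.seed(as.integer(seed))
  delta_eps <- pug_basis_delta_eps(wavelengths) * frac / 0.95
  theta <- delta_eps * 32980 * concentration * path_length * n_nt
  dynamic_range <- diff(range(theta))
  if (dynamic_range == 0) {
    # unfolded chain: scale noise to what a folded chain of this length
    # would span, so "flat + noise" is realistic
    ref_theta <- pug_basis_delta_eps(wavelengths) * 32980 * concentration *
      path_length * n_nt
    dynamic_range <- diff(range(ref_theta))
  }
  theta <- theta + stats::rnorm(length(theta), sd = noise_sd * dynamic_range)
  cd_spectrum(wavelengths, theta, concentration, path_length, n_nt)
}

#' Generate a synthetic folding trace
#'
#' Single-exponential approach to the folded signal with the given
#' half-life, emulating CD-monitored folding after salt addition
#' (default: 180 points over 330 min). `t_half_min = Inf` gives a flat
#' (non-folding) trace.
#'
#' @param t_half_min Folding half-life in minutes (> 0, may be `Inf`).
#' @param duration_min Total observation time (default 330 min).
#' @param n_points Number of samples (default 180).
#' @param noise_sd Noise SD as a fraction of the folding amplitude
#'   (default 0.02).
#' @param seed Integer seed.
#' @param s0,s_inf Start and plateau signal (defaults 0 and 1).
#' @return A [kinetic_trace()] in minutes.
#' @export
generate_folding_trace <- function(t_half_min, duration_min = 330,
                                   n_points = 180, noise_sd = 0.02, seed = 1,
                                   s0 = 0, s_inf = 1) {
  stopifnot(t_half_min > 0, duration_min > 0, n_points >= 2)
  set.seed(as.integer(seed))
  times <- seq(0, duration_min, length.out = n_points)
  k <- if (is.infinite(t_half_min)) 0 else log(2) / t_half_min
  signal <- s_inf + (s0 - s_inf) * exp(-k * times)
  amp <- abs(s_inf - s0)
  signal <- signal + stats::rnorm(n_points, sd = noise_sd * amp)
  kinetic_trace(times, signal, unit = "min")
}

#' Default HDX sampling schedule
#'
#' First point at 0.3 h (spectra start within ~20 min of D2O addition),
#' dense sampling every 0.25 h out to 72 h of continuous acquisition, then
#' daily points to 3 weeks.
#'
#' @return Numeric vector of times in hours.
#' @export
hdx_default_schedule <- function() {
  c(seq(0.3, 72, by = 0.25), seq(96, 504, by = 24))
}

#' Generate a synthetic HDX decay series
#'
#' Mono-exponential (`I0 * exp(-k t)`) or biexponential
#' (`I0 * (f * exp(-k_fast t) + (1 - f) * exp(-k_slow t))`) imino-integral
#' decay with floor 0 and additive Gaussian noise.
#'
#' @param mode `"mono"` or `"biexp"`.
#' @param parameters Named list: mono needs `I0`, `k`; biexp needs `I0`,
#'   `f`, `k_fast`, `k_slow`.
#' @param schedule Times in hours (default [hdx_default_schedule()]).
#' @param noise_sd Absolute noise SD on the normalized integrals
#'   (default 0.02).
#' @param seed Integer seed.
#' @return An [exchange_series()].
#' @export
generate_hdx_series <- function(mode = c("mono", "biexp"), parameters,
                                schedule = hdx_default_schedule(),
                                noise_sd = 0.02, seed = 1) {
  mode <- match.arg(mode)
  p <- parameters
  set.seed(as.integer(seed))
  if (mode == "mono") {
    stopifnot(p$I0 > 0, p$k >= 0)
    ideal <- p$I0 * exp(-p$k * schedule)
  } else {
    stopifnot(p$I0 > 0, p$k_fast >= 0, p$k_slow >= 0,
              p$f >= 0, p$f <= 1)
    ideal <- p$I0 * (p$f * exp(-p$k_fast * schedule) +
                       (1 - p$f) * exp(-p$k_slow * schedule))
  }
  exchange_series(schedule, ideal + stats::rnorm(length(schedule),
                                                 sd = noise_sd))
}

#' Generate a synthetic melting curve
#'
#' Boltzmann sigmoid sampled over the standard temperature ramp
#' (20 to 81.5 degrees C in 1.5-degree steps, 42 points) with additive
#' Gaussian noise. A `Tm` outside the ramp is permitted but flagged with a
#' warning, since the transition midpoint is then unobserved.
#'
#' @param Tm_C Midpoint temperature (degrees C).
#' @param dT_C Transition width (> 0, default 3).
#' @param A1,A2 Folded / unfolded baselines (defaults -4, 0).
#' @param noise_sd Noise SD as a fraction of `|A1 - A2|` (default 0.02).
#' @param seed Integer seed.
#' @param temperatures Ramp (default `seq(20, 81.5, by = 1.5)`).
#' @return A [kinetic_trace()] with `unit = "C"`.
#' @export
generate_melt_curve <- function(Tm_C, dT_C = 3, A1 = -4, A2 = 0,
                                noise_sd = 0.02, seed = 1,
                                temperatures = seq(20, 81.5, by = 1.5)) {
  stopifnot(dT_C > 0)
  if (Tm_C < min(temperatures) || Tm_C > max(temperatures)) {
    warning("Tm lies outside the temperature ramp; transition midpoint unobserved")
  }
  set.seed(as.integer(seed))
  y <- A2 + (A1 - A2) / (1 + exp((temperatures - Tm_C) / dT_C))
  y <- y + stats::rnorm(length(temperatures), sd = noise_sd * abs(A1 - A2))
  kinetic_trace(temperatures, y, unit = "C")
}

#' Aggregate an ensemble of configurations into a digest fragment table
#'
#' Applies [predict_t1_fragments()] to every configuration in an ensemble
#' (e.g. from [simulate_sequential_folding()]) and aggregates fragments by
#' (repeat length, fold count, termini). Reported intensities emulate a
#' length-proportional nucleic-acid stain: intensity is proportional to
#' count times fragment length in nucleotides.
#'
#' @param ensemble Non-empty list of [fold_configuration()] objects (those
#'   without placements contribute nothing).
#' @param five_prime_chemistry `"PPP"` or `"HO"`.
#' @param seed Accepted for interface symmetry with the other generators;
#'   the aggregation itself is deterministic given the ensemble.
#' @return data.frame with columns `length_repeats`, `n_folds`,
#'   `five_prime`, `three_prime`, `count`, `intensity`,
#'   `intensity_fraction`.
#' @export
generate_digest_table <- function(ensemble, five_prime_chemistry = c("PPP", "HO"),
                                  seed = NULL) {
  five_prime_chemistry <- match.arg(five_prime_chemistry)
  if (!is.list(ensemble) || length(ensemble) == 0) {
    stop("ensemble must be a non-empty list of fold configurations",
         call. = FALSE)
  }
  frags <- lapply(ensemble, function(cf) {
    if (cf$n_folds == 0) return(NULL)
    predict_t1_fragments(cf, five_prime_chemistry)
  })
  frags <- do.call(rbind, frags[!vapply(frags, is.null, logical(1))])
  if (is.null(frags) || nrow(frags) == 0) {
    stop("ensemble contains no fold placements", call. = FALSE)
  }
  frags$length_repeats <- frags$end_repeat - frags$start_repeat + 1L
  key <- interaction(frags$length_repeats, frags$n_folds, frags$five_prime,
                     frags$three_prime, drop = TRUE)
  agg <- lapply(split(frags, key), function(g) {
    data.frame(length_repeats = g$length_repeats[1], n_folds = g$n_folds[1],
               five_prime = g$five_prime[1], three_prime = g$three_prime[1],
               count = nrow(g), intensity = nrow(g) * g$length_nt[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$intensity_fraction <- out$intensity / sum(out$intensity)
  out <- out[order(out$length_repeats, out$five_prime, out$three_prime), ]
  rownames(out) <- NULL
  out
}
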