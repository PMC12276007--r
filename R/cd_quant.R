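#' Construct a CD spectrum
#'
#' Holds raw ellipticity versus wavelength together with the metadata needed
#' to convert to molar CD absorption: RNA concentration, cuvette path
#' length, and chain length in nucleotides.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param theta Raw ellipticity (millidegrees), one value per wavelength.
#' @param concentration RNA concentration (molar), > 0.
#' @param path_length Cuvette path length (cm), > 0.
#' @param n_nt Number of nucleotides in the chain, >= 1.
#' @return Object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, theta, concentration, path_length, n_nt) {
  stopifnot(length(wavelengths) == length(theta),
            length(wavelengths) >= 1,
            all(is.finite(wavelengths)), all(is.finite(theta)))
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!isTRUE(concentration > 0)) stop("concentration must be > 0", call. = FALSE)
  if (!isTRUE(path_length > 0)) stop("path_length must be > 0", call. = FALSE)
  if (!isTRUE(n_nt >= 1)) stop("n_nt must be >= 1", call. = FALSE)
  structure(
    list(wavelengths = as.numeric(wavelengths), theta = as.numeric(theta),
         concentration = concentration, path_length = path_length,
         n_nt = n_nt),
    class = "cd_spectrum"
  )
}

#' Convert raw ellipticity to molar CD absorption
#'
#' Applies the standard conversion
#' \deqn{\Delta\varepsilon(\lambda) = \theta(\lambda) / (32980 \cdot C \cdot L \cdot N)}
#' where \eqn{\theta} is raw ellipticity in millidegrees, \eqn{C} the molar
#' RNA concentration, \eqn{L} the path length in cm and \eqn{N} the number
#' of nucleotides, giving per-nucleotide molar CD absorption
#' (M^-1 cm^-1).
#'
#' @param spectrum A [cd_spectrum()].
#' @return Object of class `molar_cd`: list with `wavelengths` and
#'   `delta_eps` on the same grid.
#' @export
molar_cd <- function(spectrum) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  denom <- 32980 * spectrum$concentration * spectrum$path_length * spectrum$n_nt
  structure(
    list(wavelengths = spectrum$wavelengths,
         delta_eps = spectrum$theta / denom),
    class = "molar_cd"
  )
}

# Read delta_eps at requested wavelengths: nearest grid point when the grid
# step is <= 2 nm (instrument scans are 1 nm), linear interpolation otherwise.
delta_eps_at <- function(mcd, wavelengths) {
  stopifnot(inherits(mcd, "molar_cd"))
  grid <- mcd$wavelengths
  if (any(wavelengths < min(grid) | wavelengths > max(grid))) {
    stop("requested wavelength outside spectrum range", call. = FALSE)
  }
  step <- if (length(grid) > 1) max(diff(grid)) else 0
  if (step <= 2) {
    idx <- vapply(wavelengths, function(w) which.min(abs(grid - w)), integer(1))
    mcd$delta_eps[idx]
  } else {
    stats::approx(grid, mcd$delta_eps, xout = wavelengths)$y
  }
}

#' Fraction folded from CD peak magnitudes
#'
#' The fraction of a pUG chain engaged in pUG folds is measured as the
#' ratio of its molar CD absorption to that of the minimal (GU)12 fold at
#' the characteristic peaks, scaled by 0.95 — the (GU)12 reference is
#' itself 95% folded because its 3' terminal U is unstructured:
#' \deqn{f = 0.95 \cdot \Delta\varepsilon_{sample} / \Delta\varepsilon_{(GU)_{12}}}
#' Ratios are signed; sample and reference share peak signs, so each peak's
#' ratio is positive for a folded sample.
#'
#' @param sample,reference_gu12 [molar_cd()] objects covering the requested
#'   wavelengths; `reference_gu12` is the (GU)12 reference spectrum.
#' @param wavelengths Analysis peaks in nm (default `c(245, 281, 304)`).
#' @param scale Reference normalisation (default 0.95).
#' @return Object of class `folded_fraction`: list with `per_peak` (named
#'   numeric), `mean_fraction`, and `wavelengths_used`.
#' @export
fraction_folded <- function(sample, reference_gu12,
                            wavelengths = c(245, 281, 304), scale = 0.95) {
  eps_s <- delta_eps_at(sample, wavelengths)
  eps_r <- delta_eps_at(reference_gu12, wavelengths)
  if (any(abs(eps_r) < .Machine$double.eps^0.5)) {
    stop("reference molar CD absorption is ~0 at a requested wavelength",
         call. = FALSE)
  }
  per_peak <- (eps_s / eps_r) * scale
  names(per_peak) <- paste0(wavelengths, "nm")
  structure(
    list(per_peak = per_peak, mean_fraction = mean(per_peak),
         wavelengths_used = wavelengths),
    class = "folded_fraction"
  )
}

#' @export
print.folded_fraction <- function(x, ...) {
  cat("fraction folded (vs (GU)12 reference):\n")
  cat(paste(sprintf("  %s: %.3f", names(x$per_peak), x$per_peak),
            collapse = "\n"), "\n")
  cat(sprintf("  mean: %.3f\n", x$mean_fraction))
  invisible(x)
}

#' Model fraction folded for a given fold count
#'
#' Each pUG fold engages `nt_per_fold` nucleotides (24 for the 12-repeat
#' fold), so `n_folds` folds on an `n_nt`-nucleotide chain correspond to a
#' folded fraction of `n_folds * nt_per_fold / n_nt` — e.g. two folds on
#' the 58-nt (GU)29 engage 48/58 = 83% of the chain, one fold 41%.
#'
#' @param n_nt Chain length in nucleotides.
#' @param n_folds Number of folds (may be fractional for ensemble means).
#' @param nt_per_fold Nucleotides per fold (default 24).
#' @return Fraction in `[0, 1]`.
#' @export
expected_fraction_folded <- function(n_nt, n_folds, nt_per_fold = 24) {
  stopifnot(n_nt >= 1, n_folds >= 0)
  if (n_folds * nt_per_fold > n_nt) {
    stop("fold capacity exceeded: n_folds * nt_per_fold > n_nt", call. = FALSE)
  }
  n_folds * nt_per_fold / n_nt
}

#' Mean fold count implied by a measured folded fraction
#'
#' Inverse of [expected_fraction_folded()]: a chain measured `fraction`
#' folded carries on average `fraction * n_nt / nt_per_fold` folds — e.g.
#' (GU)29 at 73% folded carries ~1.76 folds per 58 nucleotides.
#'
#' @param fraction Measured folded fraction in `[0, 1]`.
#' @param n_nt Chain length in nucleotides.
#' @param nt_per_fold Nucleotides per fold (default 24).
#' @return Mean number of folds (real).
#' @export
mean_folds_from_fraction <- function(fraction, n_nt, nt_per_fold = 24) {
  stopifnot(fraction >= 0, fraction <= 1, n_nt >= 1)
  fraction * n_nt / nt_per_fold
}
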