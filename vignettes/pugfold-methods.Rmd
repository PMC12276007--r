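---
title: "Models and methods behind pugfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pugfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pugfold)
```

## The system

Poly(UG) ("pUG") RNAs are dinucleotide repeats of alternating G and U.
Twelve consecutive UG repeats (24 nt, 12 guanosines) can fold into the pUG
fold, a left-handed RNA G-quadruplex built from four 3-repeat segments
stacked as three G-quartets and one U-quartet around potassium ions. Long
pUG chains (24 or more repeats) can host two or more folds at once, and
the placement, kinetics, and internal dynamics of those folds are what this
package models quantitatively. All placement arithmetic is done at *repeat*
granularity (1 repeat = 2 nt), because every fold-count statement about
these chains is naturally repeat-denominated; nucleotide coordinates are
1-based and inclusive where they appear (the sequence scanner).

## Fold placement combinatorics

A fold occupies 12 consecutive repeats, so a chain of $n$ full repeats has
legal start positions $1 \dots n - 11$. A *configuration* is any
non-empty set of pairwise non-overlapping placements; it is *maximal* when
no further fold fits in any gap or flank; two placements are *adjacent*
when zero repeats intervene. `enumerate_configurations()` enumerates these
by depth-first extension, and the test suite verifies it against an
independent subset-enumeration oracle for every chain length up to 40
repeats.

Two distinct ensembles over configurations are provided, and they answer
different questions:

* **Uniform-over-maximal** (`enumerate_configurations(..., maximal_only
  = TRUE)` + `adjacency_stats()`): all maximal configurations counted with
  equal weight. On a 29-repeat chain this gives 27 configurations — 6
  maximal singles (starts 7–12) and 21 doubles — of which the 6 adjacent
  doubles are 22%. This is the measure behind the stochastic-folding
  prediction that ~22% of configurations carry an adjacent double fold,
  and it is the quantity `scripts/acceptance.R` recomputes. We note this
  uniform-measure reading is a reconstruction: it is the simplest
  enumeration that defines "all possible folds" coherently, and we document
  it as such rather than as the only possible choice.
* **Sequential kinetic placement** (`simulate_sequential_folding()`):
  folds nucleate one at a time at a start drawn uniformly among currently
  legal positions until the chain is saturated. Every outcome is maximal,
  but outcomes are weighted by nucleation order; for the 29-repeat chain
  the adjacent-double probability is
  $\tfrac{1}{18} \cdot 2 (1 + \tfrac12 + \dots + \tfrac16) \approx 27\%$
  and the mean fold count is $30/18 \approx 1.67$. The tests check the
  simulator against this closed form and against an exhaustive recursion
  over placement orders. The two ensembles are deliberately kept separate;
  the sequential model is never used for the 22% figure.

`predict_t1_fragments()` translates a configuration into the fragments an
exhaustive RNase T1 digest would leave: T1 cuts 3' of single-stranded
guanosines, so unstructured repeats are destroyed, isolated folds survive
as 12-repeat blocks, and adjacent folds survive as merged blocks. Terminal
chemistry follows transcript logic: a block starting at repeat 1 keeps the
transcript's 5' end (triphosphate or hydroxyl); any internal cut leaves a
5' hydroxyl downstream and a 2',3'-cyclic phosphate upstream; a block
reaching the 3' end keeps the 3'-OH.

## CD quantification

Raw ellipticity $\theta$ (millidegrees) is converted to per-nucleotide
molar CD absorption with the standard normalisation
$$\Delta\varepsilon = \frac{\theta}{32980 \cdot C \cdot L \cdot N}$$
($C$ molar concentration, $L$ path length in cm, $N$ nucleotides).

Fraction folded is measured against the minimal (GU)$_{12}$ fold at the
three analysis peaks 245, 281 and 304 nm as
$0.95\,\Delta\varepsilon_{sample}/\Delta\varepsilon_{(GU)_{12}}$. The 0.95
enters because (GU)$_{12}$ is itself only 95% folded — its 3'-terminal U is
unstructured — so a sample identical to the reference reads 95%, not 100%.
The model arithmetic works in whole folds of 24 nt: two folds on a 58-nt
chain engage $48/58 = 83\%$ of it, one fold $41\%$, and a chain measured
73% folded carries $0.73 \cdot 58/24 \approx 1.76$ folds on average. The
24 nt/fold convention and the 0.95 normalisation are kept strictly apart so
the terminal-U correction is never double-counted. Peak values are read at
the nearest grid wavelength when the scan step is 1–2 nm (instrument scans
are 1 nm) and linearly interpolated on coarser grids. A second, slightly
different wavelength set (243, 264, 284, 304 nm) is used by convention for
kinetic monitoring; both sets are plain function arguments.

For chains between 12 and 18 repeats the one-fold model tracks the
measurement closely but the terminal-U handling is ambiguous in principle
(e.g. an 18-repeat chain is 64% or 67% folded depending on whether the
engaged fold counts 23 or 24 nt); the package therefore reports measured
and model values side by side and never asserts their equality.

## Kinetic and thermodynamic fits

All nonlinear fits use Levenberg–Marquardt through the residual-function
interface of `minpack.lm::nls.lm` (cost tolerance $10^{-13}$, up to $10^4$
evaluations). Offset/amplitude parameterisations are used throughout
(e.g. $S(t) = S_\infty + A e^{-kt}$) because endpoint parameterisations
leave the gradient ill-conditioned on clean data. Half-lives are always
$\ln 2 / k$; folding traces are in minutes, exchange series in hours,
melting curves in degrees Celsius, with explicit converters
(`convert_time()`, `convert_rate()`) rather than implicit unit guessing.

* **Folding** (`fit_single_exponential()`): monophasic exponential; the
  rate is seeded from the half-amplitude crossing time. A trace whose span
  does not clear the expected extreme range of its own noise
  ($\sigma \cdot 2\sqrt{2\log n}$ plus margin) returns an explicit
  "no transition" result instead of a fit.
* **HDX, mono** (`fit_hdx_mono()`): $I(t) = [I(0)-I(\infty)]e^{-k_{ex}t} +
  I(\infty)$ with the floor constrained to 0 by default (no imino signal
  survives long-term D$_2$O incubation, so residual H$_2$O is negligible);
  an unresolved decay is flagged as a $k_{ex} \approx 0$ boundary.
* **HDX, biexponential** (`fit_hdx_biexponential()`):
  $I(t) = I_0[f e^{-k_{fast}t} + (1-f)e^{-k_{slow}t}]$, floor 0, $f$
  bounded to $[0,1]$, rates ordered after fitting. Rates are seeded by
  log-linear regression on the late third (slow) and early points (fast)
  of the decay, $f$ at 0.5 — robust across the ~100-fold rate separations
  seen in practice. If the fitted rates are within a factor of 3, or $f$
  collapses to a boundary, the series is declared effectively monophasic:
  the fit is flagged degenerate and a mono refit is returned. $I_0$ is
  left free (measured series can normalise slightly above 1 when the fast
  phase begins before the first point).
* **Melting** (`fit_boltzmann_melt()`): Boltzmann sigmoid
  $y(T) = A_2 + (A_1 - A_2)/(1 + e^{(T-T_m)/dT})$ with free baselines, so
  both melt directions fit; a flat curve raises an explicit
  "no sigmoidal transition" error, and a fitted $T_m$ outside the measured
  ramp is flagged.
* **Consistency** (`split_fit_consistency()`): regional integrations are
  fit separately and compared to the global fit; relative rate
  discrepancies above 25% (default) are flagged.

## The segmental register-exchange model

Long chains show biphasic HDX: a fast phase with half-life around 30 min
and ~50% amplitude on top of global unfolding with half-lives of days. The
model: of the fold's four segments, exactly the two terminal ones (5' and
3') can swap register with flanking single-stranded repeats, transiently
opening their quartet hydrogen bonds; interior segments open only when the
whole fold unfolds. Over the stochastic ensemble of fold positions, any
chain with at least one flanking repeat has both terminal segments
exchange-competent — which is why the fast amplitude sits at
$2/4 = 50\%$ *independent of chain length*, while the minimal 12-repeat
chain (no flanks) is strictly monophasic.

Two further assumptions close the model. First, the EX1 limit: every
opening event exchanges the segment's imino protons, so the observed fast
rate is $k_{flip} + k_{unfold}$ (no intrinsic-chemistry correction is
attempted; none is identifiable from these data). Second, labeling is
irreversible: in excess D$_2$O a re-protected segment does not recover
signal. The survival curve is then exactly biexponential,
$$S(t) = a\,e^{-(k_{flip}+k_{unfold})t} + (1-a)\,e^{-k_{unfold}t},
\qquad a = \text{exchangeable fraction},$$
implemented in `analytic_hdx()`, with `gillespie_hdx()` providing the
matching stochastic realisation (exponential waiting times per segment and
per molecule). The tests require the ensemble mean to match the analytic
curve within three Monte-Carlo standard errors and a biexponential fit of
either curve to recover the 50% amplitude. A 50% amplitude cannot
distinguish "half the signal in every molecule" from "all the signal in
half the molecules"; the simulator implements the former, and the ensemble
curves of the two readings are identical by construction.

## Synthetic data

The generators produce data with the statistical structure the analysis
assumes, so every stage is testable without instrument files:

* **CD spectra**: sums of Gaussian bands (width 6 nm) at 245(−), 260(+),
  281(+) and 304(−) nm, the characteristic sign pattern of the fold.
  Absolute band amplitudes are package constants — every analysis is
  ratio-based — and a generated chain is scaled by
  `expected_fraction_folded(n_nt, n_folds) / 0.95` relative to the
  canonical reference `reference_gu12()`, so measuring a generated
  spectrum against that reference returns the model folded fraction.
  Fractional `n_folds` values generate ensemble-average spectra.
* **Folding traces**: single-exponential rises, default 180 points over
  330 min, matching typical acquisition.
* **HDX series**: mono- or biexponential decays on a realistic schedule
  (first point 0.3 h after D$_2$O addition, 15-min sampling to 72 h, then
  daily to 3 weeks).
* **Melting curves**: Boltzmann sigmoids on the standard ramp, 20 to
  81.5 °C in 1.5 °C steps (42 points).
* **Digest tables**: per-molecule T1 fragment prediction aggregated by
  (length, termini), with stain-weighted intensities proportional to
  count × fragment length, emulating a nucleic-acid stain.

Noise is additive i.i.d. Gaussian at σ = 2% of the dynamic range by
default — the papers in this area do not publish their noise models, and
2% keeps seeded parameter-recovery spreads comparable to the uncertainties
such measurements report. All randomness flows through one `set.seed()`
per generator call with an explicit `seed` argument, making every output
byte-reproducible. What the generators deliberately do **not** emulate:
baseline drift, correlated noise, incomplete folding at $t = 0$,
intermolecular species, or line-broadening effects — so passing recovery
tests demonstrate correctness of the estimators under the stated model,
not robustness to every pathology of real instrument data.

## Problem sizes and numerical choices

The shipped tests enumerate placements up to 40-repeat chains (the
brute-force oracle is combinatorial in chain length), simulate $2$–$4
\times 10^4$ molecules for sequential-placement statistics, use $10^4$
molecules for Gillespie-vs-analytic comparisons, and 50 replicates for the
seeded biexponential recovery study — sizes chosen so the Monte-Carlo
standard errors sit well below the effect sizes being checked. Noiseless
recovery is asserted to a relative error of $10^{-6}$; stochastic checks
are asserted at 3–4 standard errors under fixed seeds.

## Limitations

* The 22% adjacent-double figure depends on the uniform-over-maximal
  measure discussed above; alternative measures (e.g. the sequential
  kinetic ensemble) give different numbers, which the package exposes
  rather than hides.
* Placement works at repeat granularity; G-start versus U-start phase is
  tracked by the scanner but not enumerated as distinct placements, and
  folds with expanded loops (AA insertions) are characterised only through
  their melting behaviour, not as placements.
* The register-exchange model has no intrinsic-exchange chemistry and no
  µs–ms dynamics; it describes the hours-to-weeks HDX window only.
* The CD fraction-folded statistic assumes the four-band pUG spectrum;
  competing conformations (e.g. A-form duplex content in Mg$^{2+}$) would
  bias it and are not modelled.
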