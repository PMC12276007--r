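# pugfold

Quantitative analysis of long poly(UG) ("pUG") repeat RNAs. Twelve
consecutive UG repeats (24 nt) can fold into the pUG fold, a left-handed
RNA G-quadruplex; chains of 24 or more repeats can carry several folds at
once. `pugfold` is for people studying these RNAs by circular dichroism
(CD), nuclease mapping, and hydrogen/deuterium exchange (HDX) NMR — it
implements the arithmetic and the models those experiments are interpreted
with:

* **Sequence scanning** — locate maximal GU/UG repeat runs (either phase,
  half-repeat granularity) in plain strings or FASTA records
  (`parse_pug`, `find_pug_runs`, `scan_fasta`).
* **Fold placement combinatorics** — enumerate all configurations of
  non-overlapping 12-repeat folds on a chain, classify adjacent double
  folds, simulate sequential stochastic folding, and predict the fragments
  an exhaustive RNase T1 digest would leave
  (`enumerate_configurations`, `adjacency_stats`,
  `simulate_sequential_folding`, `predict_t1_fragments`).
* **CD quantification** — convert ellipticity to molar CD absorption,
  Δε = θ / (32980 · C · L · N), and derive fraction folded
  (0.95 · Δε/Δε<sub>(GU)12</sub> at 245/281/304 nm) and mean fold counts
  (`molar_cd`, `fraction_folded`, `expected_fraction_folded`,
  `mean_folds_from_fraction`).
* **Kinetic and thermodynamic fitting** — single-exponential folding,
  mono/biexponential HDX decays with floor 0, Boltzmann sigmoidal melting
  curves, and explicit rate/half-life unit conversions
  (`fit_single_exponential`, `fit_hdx_mono`, `fit_hdx_biexponential`,
  `fit_boltzmann_melt`, `halflife_from_rate`).
* **Segmental register exchange** — the four-segment model in which the
  two terminal segments of an internal fold swap register with flanking
  repeats (fast, ~50% amplitude) on top of slow global unfolding, both as
  a closed-form survival curve and as a Gillespie simulation
  (`register_exchange_model`, `analytic_hdx`, `gillespie_hdx`).
* **Synthetic data** — seeded generators for every supported data type, so
  the full pipeline is testable without instrument files
  (`generate_cd_spectrum`, `generate_folding_trace`,
  `generate_hdx_series`, `generate_melt_curve`, `generate_digest_table`).
* **Pipeline & I/O** — schema-validated multi-stage runs with JSON/TSV
  outputs and reproducibility hashes (`run_pipeline`, `read_table`,
  `write_report`).

See `vignettes/pugfold-methods.Rmd` for the models, assumptions, and
numerical choices.

## Worked example

```r
library(pugfold)

# Two repeat runs in the 50-nt pUG tract of the human HO-1 5'UTR
ho1 <- paste0(strrep("GU", 12), "AU", strrep("GU", 12))
find_pug_runs(ho1, min_repeats = 10)
#>   start end n_repeats n_g phase
#> 1     1  24      12.0  12     G
#> 2    26  50      12.5  12     U

# All maximal placements of 12-repeat folds on a 29-repeat chain
adjacency_stats(enumerate_configurations(29, maximal_only = TRUE))
#> placement ensemble: 27 configurations (6 single / 21 double / 0 triple+)
#>   with adjacent double fold: 6 (22.2%); mean folds 1.778

# CD fraction folded of a synthetic (GU)29 spectrum carrying 1.76 folds
spec <- generate_cd_spectrum(n_nt = 58, n_folds = 1.76, noise_sd = 0.02, seed = 1)
ff <- fraction_folded(molar_cd(spec), reference_gu12())
ff
#> fraction folded (vs (GU)12 reference):
#>   245nm: 0.743
#>   281nm: 0.701
#>   304nm: 0.651
#>   mean: 0.698
mean_folds_from_fraction(ff$mean_fraction, 58)   # ~1.7 folds per chain
#> [1] 1.686965

# Folding kinetics: 17-min half-life recovered from a noisy trace
fit_single_exponential(generate_folding_trace(17, noise_sd = 0.02, seed = 2))
#> single-exponential fit: k = 0.04122 per min, t1/2 = 16.82 min, R2 = 0.9860

# Register exchange: fast phase ~30 min at 50% amplitude over slow unfolding
m <- register_exchange_model(k_flip = log(2) / 0.5, k_unfold = log(2) / 120,
                             flank_5 = 3)
pred <- gillespie_hdx(m, n_molecules = 10000, times = hdx_default_schedule(),
                      seed = 3)
fit_hdx_biexponential(as_exchange_series(pred))
#> biexponential HDX fit: k_fast = 1.342 /h (t1/2 0.516 h),
#>   k_slow = 0.005802 /h (t1/2 119 h), ratio fast 49.7%, R2 = 0.9998
```

The numbers mean: the 29-repeat chain supports 27 distinct saturated fold
arrangements of which 22% are compact adjacent doubles; a spectrum
generated at 1.76 folds measures ~70% folded (0.73 expected, within the
2% noise); and a simulated internal fold with 3 flanking repeats exchanges
half its imino protons with a ~30-minute half-life while the rest decay
only through global unfolding (half-life of days).

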