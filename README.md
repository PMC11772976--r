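# braggdna

DNA damage complexity, microdosimetry and cell survival along a proton
Bragg curve — a desk-scale radiobiology pipeline in R.

## What it is for

Proton radiotherapy delivers its dose in a Bragg peak, and the *quality* of
that dose changes with depth: at the distal edge of the peak the protons are
slow, energy deposition is locally dense (high dose-averaged mean lineal
energy, ȳ_D = Σw·y²/Σw·y), and the DNA double-strand breaks (DSBs) they
induce are more clustered and harder to repair. `braggdna` is for
radiobiologists and modellers who want to reproduce and probe this chain of
reasoning quantitatively, end to end, without a full track-structure Monte
Carlo:

* a **seeded synthetic lesion generator** — Poisson track arrival scaling
  with dose and inversely with lineal energy, per-track lesion clusters that
  tighten with lineal energy, direct/indirect lesion labelling;
* the standard **damage classification scheme** — sites by 10 bp clustering;
  SSB; DSB (opposite-strand breaks within 10 bp, greedy nearest pairing);
  DSB+ (a DSB with a companion lesion within 10 bp); DSB++ (≥2 DSBs within
  100 bp); source types direct / indirect / hybrid / mixed; yields per Gy
  per Gbps — verified against an exhaustive brute-force evaluator;
* **microdosimetry** — lineal-energy spectra, ȳ_D, exact lognormal
  calibration to a target ȳ_D;
* **linear-quadratic survival** — S(D) = exp(−αD − βD²) fitted by weighted
  least squares on log survival with α, β ≥ 0 solved exactly, interpolated
  D37%/D10% and fold changes;
* **53BP1 focus kinetics** — N(t) = C₁e^(−t/τ₁) − C₂e^(−t/τ₂) + C₃ with
  C₁, C₂ > 0, multi-start bounded least squares, resolution half-life by
  bisection from the curve peak;
* **image quantification** — synthetic two-channel nucleus images with
  ground truth; DAPI segmentation (Otsu, hole fill, watershed option),
  per-nucleus focus detection at mean + k·SD, second-moment ellipse fitting.

The bundled profiles describe the three studied positions of a passively
scattered 150 MeV beam: P36, P80 (proximal 36%/80% of the peak; ȳ_D = 1.10
and 1.80 keV/µm) and D20 (distal 20%; ȳ_D = 7.25 keV/µm).

## Worked example

```r
library(braggdna)
cfg <- experiment_config(n_nuclei = 20, master_seed = 42)
res <- run_experiment(cfg)
res$summary[, c("position", "yd_bar_keV_um", "d37_Gy", "d10_Gy", "t_half_h",
                "ssb_per_Gy_Gbps", "dsb_per_Gy_Gbps", "ssb_over_dsb",
                "complex_frac_of_sb_pct")]
#>   position yd_bar_keV_um d37_Gy d10_Gy t_half_h ssb_per_Gy_Gbps dsb_per_Gy_Gbps
#> 1      P36          1.10   3.09   5.27     2.42             295            11.4
#> 2      P80          1.80   2.88   4.82     3.14             269            18.3
#> 3      D20          7.25   1.60   3.41     4.58             148            50.2
#>   ssb_over_dsb complex_frac_of_sb_pct
#> 1        25.86                   1.23
#> 2        14.72                   2.69
#> 3         2.96                   9.47
```

Each row is one Bragg-curve position: 20 simulated nuclei at 2 Gy were
classified for damage (SSB/DSB yields per Gy per Gbps, SSB/DSB ratio,
complex-DSB fraction of strand breaks), a simulated clonogenic assay was
fitted with the LQ model (D37/D10 in Gy), and a simulated 53BP1 time series
was fitted with the biexponential model (half-life in hours). Reading down
the rows: at the distal position the dose needed for 37% survival roughly
halves, foci resolve almost twice as slowly, and damage shifts from single
toward complex double-strand breaks — the SSB/DSB ratio falls while the DSB
and complex-DSB fractions rise.

Fold-change claims derive from any such summary (here, from the bundled
reference table of the underlying experiments):

```r
report_fractions(reference_summary())
#> $per_position
#>   position d37_fold d10_fold complex_share_of_dsb_pct
#> 1      P36     1.00     1.00                 14.54545
#> 2      P80     1.03     1.08                 15.71429
#> 3      D20     1.88     1.53                 19.55556
#>
#> $distal_complex_ratio
#> [1] 1.71
```

i.e. a 1.88-fold (D37) and 1.53-fold (D10) dose reduction at the distal
position, complex DSBs rising from ~15% to ~20% of all DSBs, a 1.7-fold
distal increase of the complex fraction of strand breaks.

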