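---
title: "Modelling DNA damage complexity and cell survival along a proton Bragg curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA damage complexity and cell survival along a proton Bragg curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggdna)
```

## The problem

Protons deposit most of their dose at the end of their range (the Bragg
peak). Along the depth axis the *radiation quality* changes: at the distal
edge the protons are slow, their energy deposition is dense, and the DNA
damage they induce is more clustered and harder to repair. The standard
microdosimetric summary of quality is the dose-averaged mean lineal energy

$$\bar{y}_D = \frac{\sum_i w_i y_i^2}{\sum_i w_i y_i},$$

the second-over-first moment of the single-event lineal-energy distribution
$f(y)$. `braggdna` models a three-position experiment on a passively
scattered 150 MeV proton beam — plateau/proximal positions P36 and P80
($\bar{y}_D$ = 1.10 and 1.80 keV/µm) and the distal D20 position
($\bar{y}_D$ = 7.25 keV/µm) — and links position to:

* yields of single- and double-strand breaks (SSB, DSB) and of *complex*
  DSBs (DSB+, DSB++), from a synthetic lesion generator plus the standard
  clustering classifier;
* clonogenic survival through the linear-quadratic (LQ) model
  $S(D) = e^{-\alpha D - \beta D^2}$ with interpolated $D_{37\%}$ and
  $D_{10\%}$ doses;
* 53BP1 repair-focus kinetics through the biexponential model
  $N(t) = C_1 e^{-t/\tau_1} - C_2 e^{-t/\tau_2} + C_3$ and its resolution
  half-life;
* quantification of two-channel (DNA stain + focus stain) microscopy images.

Full track-structure Monte Carlo is out of scope: the lesion generator is a
parametric, seeded stand-in that preserves the microdosimetric backbone of
such simulations at desk scale.

## The synthetic lesion generator

One exposure of one nucleus at dose $D$ proceeds as:

1. **Track count.** The energy one Gy deposits in the nucleus is
   $E_{Gy} = 6.2415\,V$ keV for an ellipsoidal nucleus of volume $V$ µm³
   (unit density). A track with lineal energy $y$ deposits $y\,\bar{\ell}$
   keV, with $\bar{\ell} = 4V/S$ the Cauchy mean chord length. The number of
   traversals is Poisson with mean $D\,E_{Gy} / (\bar{y}_F\,\bar\ell)$ —
   proportional to dose and, at fixed spectrum shape, inversely proportional
   to $\bar{y}_D$: a fixed dose is delivered by fewer, denser tracks at high
   lineal energy.
2. **Lesions per track.** Each track draws $y$ from the position's spectrum
   and deposits $\mathrm{Poisson}(\kappa\, y\, \bar\ell)$ lesions, with
   $\kappa$ = `lesions_per_keV`.
3. **Genomic placement.** The genome is 6.4 Gbps in 1 Mbp chromatin
   segments. A track's first lesion lands uniformly; subsequent lesions
   follow at geometric (memoryless) offsets with scale
   `cluster_scale_bp / y`, so clustering tightens as $y$ grows. Positions
   wrap within their segment; segments never share sites.
4. **Attributes.** Strand is fair Bernoulli; a lesion is a base lesion with
   probability `p_base_lesion` (default 0.5), else a strand break; it is
   radical-mediated ("indirect") with probability `p_indirect` (default
   0.65 — the indirect channel dominates strand breakage, but no measured
   per-position split exists, so this is an explicitly free parameter).

Spectra are lognormal frequency distributions calibrated so that
$\bar{y}_D$ matches each position exactly (`calibrate_lognormal()`:
$\sigma^2 = \log(1+cv^2)$, $\mu = \log \bar{y}_D - 3\sigma^2/2$). The full
measured spectrum shapes are not tabulated anywhere usable, so the bundled
profiles pin only $\bar{y}_D$, with a common coefficient of variation 0.8.

**Calibration.** `lesions_per_keV = 1.2` and `cluster_scale_bp = 60` were
fixed once so that a P36-like run (2 Gy, default nucleus of semi-axes
9 × 6 × 2.5 µm) lands in the reference range: SSB yield ≈ 293 /Gy/Gbps and
SSB/DSB ≈ 26 (reference values 291.7 and 20–30). This is a packaged
calibration fixture, not a claim of physical fidelity.

**Known limitation.** With the prescribed $1/y$ spacing the position
contrast is exaggerated relative to a full track-structure code: at D20 the
simulated SSB/DSB ratio falls to ≈ 3 (reference ≈ 21) and the complex-DSB
share of DSBs at P36 is ≈ 35% (reference 15%). Only the *qualitative*
P36 → P80 → D20 ordering of DSB fraction, complex fraction and SSB/DSB
ratio is claimed, and that is what the test suite asserts.

## Damage classification

Classification follows the standard clustering scheme:

* **Sites.** A left-to-right sweep per segment: a new site opens when the
  next lesion lies more than `dsb_window_bp` (default 10 bp) past the
  current site's rightmost lesion. This equals single-linkage clustering at
  the 10 bp threshold.
* **DSBs.** Within a site, strand breaks on opposite strands within 10 bp
  pair into a DSB. When several pairings are possible the nearest pair wins,
  ties leftmost-first (then by source label, making the outcome invariant to
  input order); each break is consumed by at most one DSB. Greedy
  nearest-first pairing is maximum-cardinality here (candidate pairs are
  processed in ascending distance, and enlarging the window only appends
  longer candidates), so the DSB count is monotone in the window.
* **DSB+**: a DSB with at least one additional lesion (break or base
  lesion) within 10 bp of the paired breaks.
* **DSB++**: at least two DSBs within `dsbpp_segment_bp` (default 100 bp).
  Read as proximity, not fixed genome tiling: pair midpoints are chained
  transitively (`dsbpp_tiling = "fixed"` offers the tiling alternative).
  A merged DSB++ entity counts once in the complex tally but contributes its
  constituent pairings to the DSB total (`dsbpp_counts = "once"` switches to
  entity counting — the reference tables do not state which convention they
  use, and their printed SSB/DSB ratios differ by ~1 from the quotient of
  their printed yields, so both are provided).
* Classes are mutually exclusive with hierarchy DSB++ > DSB+ > DSB > SSB;
  sites carrying only base lesions are never scored (kept as diagnostics).
* **Source typing** per DSB-bearing site: *direct* / *indirect* when every
  lesion agrees; *hybrid* when the two paired breaks disagree; *mixed* when
  the paired breaks agree but an accompanying lesion differs. (The rule set
  named only the direct-pair-plus-indirect-companion case; the symmetric
  indirect-pair-plus-direct-companion case is also classified *mixed*.)

The tally normalizes yields per Gy per Gbps and uses SSB sites + total DSBs
as the strand-break denominator of the fraction columns. The whole rule set
is verified, pairing and all, against an exhaustive $O(n^2)$ brute-force
evaluator on thousands of random lesion sets.

## Survival and kinetics fitting

`fit_lq()` fits on log survival, where the LQ model is linear in
$(D, D^2)$: a weighted linear least-squares problem under
$\alpha, \beta \ge 0$, solved exactly by enumerating the active sets (no
iterative optimiser to fail). Weights are $1/\mathrm{SEM}^2$ when standard
errors are supplied. Zero-dose points only normalize plating efficiency and
never enter the residuals. Flat data fit to $\alpha = \beta = 0$ with
$D_{37\%}/D_{10\%}$ reported `NA` (unattainable). `dose_at_survival()` uses
the stable quadratic root $2L/(\alpha + \sqrt{\alpha^2 + 4\beta L})$,
$L = -\log s$, which degrades gracefully to $L/\alpha$ as $\beta \to 0$.

`fit_biexp()` is bounded least squares ($C_1, C_2 > 0$, $\tau_i > 0$,
$C_3 \ge 0$) on per-time means, weighted by $1/\mathrm{SEM}^2$ when
available, multi-started over the deterministic grid
$\tau \in \{0.5, 1, 2, 4, 8\}^2$ h with amplitudes initialised by a linear
solve at fixed time constants; the best start wins, so fits are
reproducible. Fits with $|\tau_1 - \tau_2|$ below 0.1% are flagged
ill-identified rather than relabelled: the two exponentials enter with
opposite signs, so swapping the time constants changes the model and is not
a symmetry.

**Half-life definition.** The source assays report a 53BP1 resolution
half-life without defining it relative to the rising phase. Here it is
defined relative to the plateau and the curve peak: the elapsed time from
the peak $t_{peak}$ until $N(t) - C_3$ has halved, located by bracketing and
bisection to $10^{-6}$ h within $[t_{peak},\, t_{peak} + 10\max\tau]$. This
is invariant to baseline foci and to the early rising phase, and reduces to
$\tau_1 \log 2$ for a single-exponential decay. Curves that never decay
below half amplitude return `NA` with a warning.

## Image quantification

The synthetic renderer draws non-overlapping elliptical nuclei (DNA
channel) with diffuse nucleoplasmic signal plus Gaussian foci (focus
channel) over Gaussian noise; ground truth (nucleus ellipses, focus
centers) is returned alongside. Foci of one nucleus keep a minimum
separation (default 6 px) so they are optically resolvable, as counted foci
are; the ground-truth table records what was actually placed.

Quantification mirrors the ImageJ-style pipeline: Otsu threshold on the DNA
channel, hole filling, area filter, optional watershed split, optional
border exclusion; focus detection per nucleus at mean + $k\cdot$SD of the
in-nucleus signal (default $k = 2$; the upstream method leaves the factor
unspecified, so it is exposed in the config) with a minimum focus size of
4 px; nucleus semi-axes from the second-moment (inertia-equivalent) ellipse,
$a = 2\sqrt{\lambda_1}$, $b = 2\sqrt{\lambda_2}$ of the pixel-coordinate
covariance (population moments plus the 1/12 pixel-extent correction).
Analysis is 2D on projections throughout. Per-nucleus thresholds make
detection robust to staining gradients, but they are contaminated by the
foci themselves: beyond roughly 20 foci per nucleus the in-nucleus SD
inflates and recall degrades — a property of mean + $k\cdot$SD thresholding,
documented rather than patched.

## The pipeline

`run_experiment()` chains simulate → classify → tally → fit per position
and assembles a summary table (one row per position: $D_{37\%}$,
$D_{10\%}$, $t_{1/2}$, $\bar{y}_D$, yields, fractions).
`report_fractions()` derives the headline claims: fold reductions of
$D_{37\%}/D_{10\%}$ versus the plateau row, the complex-DSB share of all
DSBs, and the distal-over-proximal complex-fraction ratio. Survival and
kinetics generators are parameterised from the bundled reference summary
(D37/D10 solved for $\alpha, \beta$ by `lq_from_doses()`; biexponential
parameters calibrated to the reference half-lives by `calibrate_biexp()`,
which also rescales amplitudes to a requested peak height — legitimate
because the half-life is amplitude-invariant).

All randomness fans out from one master seed through `stage_seed()`, a
string-hash counter scheme, so adding replicates never perturbs existing
ones and identical configurations replay byte-identically.

```{r example}
cfg <- experiment_config(n_nuclei = 6, master_seed = 1,
                         genome = genome_model(0.8, 1e6),
                         nucleus = nucleus_geometry(6, 4, 2))
res <- run_experiment(cfg)
res$summary[, c("position", "yd_bar_keV_um", "d37_Gy", "t_half_h",
                "ssb_over_dsb", "complex_frac_of_sb_pct")]
report_fractions(reference_summary())
```

## Problem sizes and numerical choices

The shipped tests run the three-position damage simulation at 50 nuclei ×
2 Gy on the full 6.4 Gbps genome (the scale at which the qualitative
ordering is asserted), 1000 random lesion sets for the classifier-oracle
equivalence, 1000 noisy survival replicates and 500 kinetics trials for
parameter-recovery checks — sizes chosen so every stochastic margin is wide
(ordering gaps of several fold, recovery errors ~1% against 5% bounds).
Smaller-scale versions of the same properties run in the per-module tests.

Degenerate inputs are defined, not patched: zero dose gives an empty lesion
set; an empty lesion table tallies zero counts with `NA` ratios; flat
survival fits to (0, 0) with `NA` quantile doses; monotone-increasing focus
curves have no half-life (`NA` + warning); sub-5-pixel nuclei are flagged
degenerate in the ellipse fit.

## What passing tests do and do not show

The generators emulate Poisson track arrival, dose linearity,
lineal-energy-driven clustering, lognormal assay noise, Poisson counting
noise and resolvable Gaussian foci. They do not emulate chromatin
architecture, repair-pathway kinetics, lineal-energy spectrum shapes beyond
their first two moments, chromatic aberration or staining artefacts.
Passing tests therefore certify the *statistical machinery* — classifier
correctness against brute force, fit identifiability and recovery,
detection on resolvable foci — not the biological accuracy of any
particular yield at any particular beam position.
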