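---
title: "Quantifying meniscus response to loading with serial qMRI: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meniscus response to loading with serial qMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meniscusqmri)
```

## The problem

The meniscus transmits and disperses load in the knee; degeneration of its
extracellular matrix degrades that function long before gross tears appear.
Quantitative MRI maps — T1 (inversion recovery), T1&rho; (spin lock) and T2
(multi-echo) — are sensitive to matrix composition, and their *change under
standardized compression* ("response to loading") is a candidate functional
biomarker. This package implements the complete ex-vivo analysis: meniscus
body cross-sections are imaged at three loading positions
(&delta;<sub>0</sub> unloaded, &delta;<sub>1</sub> at 2 bar &asymp; 37 N,
&delta;<sub>2</sub> at 4 bar &asymp; 69 N), relaxation maps are fitted
voxelwise, the segmented cross-section is split into apex (I), intermediate
(II) and base (III) thirds, and per-sample relative changes

$$\Delta_k = \left(\frac{\mathrm{median}(\delta_k)}{\mathrm{median}(\delta_0)} - 1\right)\times 100\ [\%],\quad k = 1, 2$$

are compared across histological degeneration subgroups (Pauli Grade I /
II / &ge;III). Because no raw images from such experiments are publicly
deposited, the package ships a synthetic-cohort generator with full ground
truth; every pipeline stage is exercised and scored against that truth.

## Signal models and fitting

The three mapping sequences are modelled mono-exponentially:

* **T2 / T1&rho;**: $S(t) = A\,e^{-t/T}$ along the echo-time grid
  $TE = 8.4\,n$ ms ($n = 1..6$) or the spin-lock grid
  $TSL \in \{0, 10, 20, 30, 40\}$ ms.
* **T1 (magnitude IR)**: $S(TI) = |a + b\,e^{-TI/T1}|$ on
  $TI \in \{150, 300, 500, 800, 1000, 1500\}$ ms. The three-parameter form
  absorbs imperfect inversion; magnitude reconstruction loses polarity,
  which is restored by enumerating the "first $k$ inversion times negative"
  sign patterns and keeping the lowest-residual solution.

Fitting choices, frozen for reproducibility:

* Bounded least squares with bounds T2, T1&rho; &isin; [1, 500] ms and
  T1 &isin; [50, 5000] ms. T2/T1&rho; fits start from a signal-weighted
  log-linear regression and are refined by damped Gauss–Newton steps run
  simultaneously over all pixels (stopping when the relative residual
  change falls below 10<sup>-8</sup>, or after 200 iterations). T1 uses a
  coarse logarithmic grid with the linear parameters profiled in closed
  form, followed by a vectorized golden-section refinement of T1.
* Pixels with non-positive signal everywhere, fits pinned at a bound, or
  non-converged iterations are flagged and excluded from every ROI
  summary; a constant signal across echoes yields the upper bound with
  `converged = FALSE`, never a silent value.
* No saturation correction is applied for finite TR (1500/3000 ms are
  treated as long). This is an approximation shared with routine clinical
  mapping.
* Tests verify exact noiseless recovery (&le;0.1%), scale equivariance,
  agreement with two-point closed forms, and agreement with an
  independent per-pixel Levenberg–Marquardt fit (`minpack.lm`) and with
  dense grid-search oracles under Rician noise.

## Zonal geometry

Masks are first eroded by one pixel (8-connectivity) to suppress partial
volume effects at the tissue boundary; a mask emptied by erosion is an
error, not a silent drop. The eroded outline's extreme columns define the
maximum mediolateral diameter; this interval is divided into thirds and
pixels are classified by the column of their centre, apex side taken from
explicit orientation metadata (never inferred from image content). Pixel
centres of integer-width masks can never coincide with a cut, so the
partition is deterministic, exactly conservative
($|I|+|II|+|III| = |\text{mask}|$) and exactly mirror-equivariant — all
three properties are tested against brute-force per-pixel classifiers.
The erosion depth (one pixel) is a package choice; the emulated procedure
states only that boundary pixels were excluded.

## Response statistics

ROI summaries are medians with type-6 linear-interpolation quartiles (the
rule used by the common biostatistics packages; frozen and documented).
Cohort-level tables summarize *per-sample* medians — the cohort median of
ROI medians, and means &plusmn; SD of per-sample &Delta; values — rather
than pooling pixels across samples. Whether the emulated study pooled
pixels or summarized per sample first is not stated; per-sample-first is
the defensible choice (samples are the experimental unit) and is used
throughout. Maps at different loading positions are summarized
independently, with no inter-load registration, matching the per-position
re-segmentation procedure.

## Biomechanics

Unconfined-compression stress–strain curves are fitted to the
two-parameter exponential model in its stress form

$$\sigma(\varepsilon) = c\,[\exp(b\varepsilon) - 1],$$

whose tangent stiffness is the Elastic Modulus
$EM(\varepsilon) = c\,b\,e^{b\varepsilon}$, evaluated at 20% and 80%
engineering strain. The associated energy expression
$\Psi = \tfrac{c}{2b}[e^{b\varepsilon}-1]^2$ is provided as a documented
evaluator (`strain_energy`), but note that it is not the antiderivative
chain of the EM expression — the two printed forms of this classical model
are mutually inconsistent, and the package treats the stress model whose
derivative is exactly the EM formula as primary. Likewise, the customary
prose describing `b` as the stress scale and `c` as the nonlinearity has
the roles reversed relative to the equations; the equations govern here.
Fitting is Levenberg–Marquardt with a multi-start over
$b \in \{1, 3, 5, 8, 12\}$, tare offset removed so $\sigma(0)=0$.
$EM(0.8)/EM(0.2) = e^{0.6b}$ holds algebraically and is tested to machine
precision.

## Statistical plan

All omnibus tests run at $\alpha = 0.005$:

* grade-wise: Kruskal–Wallis (tie-corrected) with Dunn's pairwise
  post-hoc, reported in the order I vs II, I vs &ge;III, II vs &ge;III;
* load-wise: Friedman over complete per-sample triplets with Dunn's
  post-hoc in the order &delta;<sub>0</sub> vs &delta;<sub>1</sub>,
  &delta;<sub>0</sub> vs &delta;<sub>2</sub>, &delta;<sub>1</sub> vs
  &delta;<sub>2</sub>;
* &Delta; statistics: unpaired pooled-variance t-test
  (&Delta;<sub>1</sub> vs &Delta;<sub>2</sub>) and one-way ANOVA across
  subgroups, screened by the D'Agostino–Pearson omnibus normality test
  (implemented from the standard skewness/kurtosis z transforms — no
  installed R package provides it — and validated against an independent
  reference implementation);
* pixel counts: repeated-measures ANOVA;
* qMRI–stiffness association: tie-aware Spearman &rho;.

Design decisions worth stating explicitly: Dunn's procedure carries its
own familywise (Bonferroni-over-three) adjustment and no further
correction is layered on top; the Dunn variant is tie-corrected (the
emulated plan does not specify); and the omnibus p-values are asymptotic
by default (matching the commercial software the plan was run in), with a
Monte-Carlo permutation option (`p_method = "permutation"`) that the test
suite validates against exhaustive enumeration oracles — at toy sample
sizes the chi-square approximation and the exact permutation distribution
differ visibly, so only the permutation path is compared with exact
enumerations.

## The synthetic cohort: what it emulates, and what it does not

`phantom_spec()` / `generate_cohort()` produce a cohort of 45 samples
split 14/16/15 across the degeneration subgroups, with:

* **Geometry** — a right-triangular wedge cross-section on a 64&times;64
  grid at 0.25 mm/pixel; width 8.4 &plusmn; 1.3 mm, height 11.9 &plusmn;
  2.4 mm (truncated normals), giving roughly 800 unloaded mask pixels
  with a realistic between-sample spread. Loading is emulated as pure
  height compression with area-retention factors (1, 718/801, 604/801),
  so mean pixel counts fall roughly 800 &rarr; 710 &rarr; 600 with the
  wedge flattening as observed. Truth zones follow the segmentation
  convention: thirds of the boundary-excluded outline, with the boundary
  ring inheriting its column's zone.
* **Relaxation truths** — per (subgroup, zone, load, contrast) central
  values taken from published cohort medians, encoding the qualitative
  response patterns the statistics stage must detect: T1 falls everywhere
  under loading; apex T1&rho; rises in Grade I/II but falls in &ge;III;
  apex T2 falls in degenerative tissue. A per-sample log-normal factor
  (sd 0.12–0.15) and a small per-(zone, load) jitter (sd 0.04) supply
  biological spread; the published tables report only IQRs, so these
  spreads are package choices, exposed as parameters.
* **Signal** — noiseless stacks from the fitting models above, amplitude
  100, degraded by Rician noise (modulus of complex Gaussian, sd 2),
  which is what magnitude reconstruction produces.
* **Biomechanics** — exponential curves with
  $b \sim N(4.9, 0.4)$ (coupled), $c \approx 1.3$ MPa log-normal and 2%
  stress noise, calibrated so cohort EM means sit near 16 MPa (20%
  strain) and 350 MPa (80%); a shared latent factor couples high
  relaxation times to low stiffness, reproducing the inverse Spearman
  correlations (roughly &minus;0.4 to &minus;0.7) reported for such
  tissue.
* **Histology** — Pauli sum scores drawn per subgroup (3.4 &plusmn; 0.9,
  8.0 &plusmn; 0.9, 12.3 &plusmn; 1.5, clipped to the grade bins) and
  decomposed uniformly into the four components under their caps, then
  re-scored and trichotomized downstream exactly as real scores would be.

The generator does **not** simulate acquisition physics (no Bloch
dynamics, B<sub>0</sub>/B<sub>1</sub> inhomogeneity, slice profiles or
partial volume), 3-D anatomy, biomechanical deformation fields (loading
is geometric, and per-load maps are generated independently — matching
the per-position re-segmentation of the emulated procedure, but not
tissue-level strain), or spatial heterogeneity within zones beyond the
piecewise-constant truths. Passing tests therefore demonstrate that the
*computational pipeline* is correct and that the statistical plan detects
effects of the encoded size under realistic noise — not that the models
are adequate for any particular scanner's raw data.

## Numerical and degenerate-input choices

* Quartiles: type 6; medians: `stats::median`.
* A pixel column exactly on a zonal cut would go to the more apical zone;
  with integer mask widths this cannot occur.
* Empty ROIs produce missing summary rows with a message; missing loading
  triplets drop the sample from the Friedman test with a message;
  constant inputs yield missing correlations; fully tied samples yield
  omnibus statistic 0 with p = 1.
* Stress curves are tare-shifted so &sigma;(0) = 0; non-monotonicity
  warnings fire only beyond 2% of the stress range, since noise at low
  stress routinely produces tiny local decreases.
* All cohort randomness flows through one seed in `phantom_spec`; two
  generations with the same spec are bit-identical.

## Problem sizes used in the shipped analyses and tests

The `analysis/` drivers run the full default cohort (45 samples, three
contrasts, three loads, 64&times;64 grid), about half a minute end to
end. The test suite uses the same code paths at reduced sizes chosen for
desk-scale iteration: noiseless recovery on 3-sample cohorts at
48&times;48, detection-rate checks on ten seeded 45-sample replicates at
48&times;48 with 0.35 mm pixels and the T1/T1&rho; contrasts, 200-replicate
noise studies for the biomechanical fit, and 10<sup>4</sup>-pixel Monte
Carlo panels for relaxometry bias. Detection of the encoded
response-to-loading patterns at &alpha; = 0.005 succeeds in &ge;90% of
the seeded replicates; with the default effect sizes the omnibus
p-values are typically orders of magnitude below the threshold.

## Known limitations

* Mono-exponential models only; multi-component relaxation, dictionary
  fitting and B<sub>1</sub>-corrected spin-lock models are out of scope.
* The vendor's proprietary map-generation algorithms are unknown, so
  numerical equality with scanner-produced maps cannot be asserted — only
  model-level recovery.
* The zonal partition assumes the imaging plane is oriented with the
  mediolateral axis horizontal; masks from other orientations must be
  rotated first.
* Cohort-level values from any specific real experiment are not
  reproducible from synthetic data; the package's claims are recovery of
  known truth and calibrated detection power, not replication of any
  particular cohort's tables.
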