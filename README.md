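# meniscusqmri

Response-to-loading analysis of human meniscus quantitative MRI.

Meniscus degeneration alters how the tissue bears and disperses load.
This package implements an ex-vivo *stress MRI* analysis for meniscus
body samples compressed in an MRI-compatible loading device: serial T1,
T1ρ and T2 mapping at three loading positions (δ₀ unloaded, δ₁ ≈ 37 N,
δ₂ ≈ 69 N), zonal analysis of the cross-section, and the statistical
plan that relates loading-induced changes to histological degeneration
(Pauli grading) and compressive stiffness (exponential hyperelastic
model). It is aimed at researchers in quantitative musculoskeletal MRI
who want a tested, reproducible reference implementation of this
workflow — including a synthetic-cohort generator with full ground
truth, since raw data from such experiments are not publicly deposited.

## What it computes

* **Voxelwise relaxometry** — mono-exponential fits
  S(TE) = A·exp(−TE/T2) and S(TSL) = A·exp(−TSL/T1ρ), and the
  three-parameter magnitude inversion-recovery model
  S(TI) = |a + b·exp(−TI/T1)| with sign-pattern polarity restoration;
  flagged-pixel diagnostics throughout.
* **Zonal partition** — one-pixel boundary erosion, then division of the
  maximum mediolateral diameter into thirds: apex (I), intermediate
  (II), base (III); exactly conservative and mirror-equivariant.
* **Response to loading** — per-sample ROI medians (type-6 quartiles)
  and the relative change Δₖ = ((median(δₖ)/median(δ₀)) − 1)·100 [%].
* **Biomechanics** — fit of σ(ε) = c·(exp(bε) − 1) to
  unconfined-compression curves; tangent Elastic Modulus
  EM(ε) = c·b·exp(bε) at 20% and 80% strain.
* **Histology** — Pauli sum score (0–18) from the four component scores,
  grade bins I–IV, and the I / II / ≥III trichotomy.
* **Statistics** — Friedman + Dunn across loading states,
  Kruskal–Wallis + Dunn across grades, t-test/ANOVA for Δ with a
  D'Agostino–Pearson normality screen, repeated-measures ANOVA for pixel
  counts, Spearman correlations with stiffness; all at α = 0.005.

## Worked example

```r
library(meniscusqmri)

# contact pressure of the loading device on a standard sample footprint
pressure_from_force(c(38, 69), length = 15, width = 8.4)
#> [1] 0.30 0.55            # MPa over the 126 mm^2 contact area

# Pauli scoring: surface total 7, hypercellularity 1, collagen 2, staining 2
pauli_score(7, 1, 2, 2)[, c("sum", "grade", "group")]
#>   sum grade group
#> 1  12   III >=III

# a small synthetic cohort, analysed end to end
spec   <- phantom_spec(n = 6, grade_fractions = c(2, 2, 2)/6, seed = 1)
cohort <- generate_cohort(spec)
an     <- run_cohort_analysis(cohort)
subset(an$deltas, contrast == "T1" & roi == "entire" & delta == "Delta2")
#>           sample group contrast    roi  delta     value
#> delta2.1     S01     I       T1 entire Delta2 -26.21031
#> delta2.13    S02     I       T1 entire Delta2 -27.41912
#> delta2.25    S03    II       T1 entire Delta2 -22.66710
#> delta2.37    S04    II       T1 entire Delta2 -29.21642
#> delta2.49    S05 >=III       T1 entire Delta2 -28.21512
#> delta2.61    S06 >=III       T1 entire Delta2 -27.55597
```

Negative Δ₂ values of −20 to −30% are the hallmark T1 response: loading
expresses water from the tissue and shortens T1 in every zone.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `06_stats.R`): simulate the default 45-sample cohort,
fit all maps, compute response statistics, fit the biomechanical
reference, tabulate histology, and run the statistical plan. Each writes
its tables under `results/` and prints what it found:

```sh
Rscript analysis/01_simulate.R   # mean mask pixels per load: 794 > 712 > 599
Rscript analysis/02_fit_maps.R   # cohort entire-sample T1 medians: 675 > 559 > 505 ms
Rscript analysis/06_stats.R      # T1 loading effect significant in 4 of 4 ROIs ...
```

## Layout

```
R/                  implementation (generator, relaxometry, geometry,
                    response, biomechanics, histology, statistics, I/O)
analysis/           numbered workflow drivers
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests with
                    brute-force/enumeration oracles
vignettes/          methods vignette (models, assumptions, design choices)
```
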