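---
title: "Quantifying test-retest reliability of resting-state networks with netretest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying test-retest reliability of resting-state networks with netretest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netretest)
```

## The problem

Before resting-state fMRI connectivity can serve as a longitudinal biomarker
— for instance to monitor disease progression in multiple sclerosis — the
measurements must be reproducible across scanning sessions in the absence of
real change. `netretest` implements the standard template-based workflow for
quantifying that between-session reliability in a two-group (healthy
control / patient), two-session (baseline BL, follow-up FU) design, and
pairs it with a synthetic 4D BOLD generator with known ground truth so every
stage of the pipeline can be validated end to end.

Two complementary reliability statistics are produced per network and group:

* **ICC(3,1)** of a per-subject summary connectivity value — consistency of
  the *magnitude* of connectivity across sessions;
* **R12**, the Dice ratio of overlapping suprathreshold voxels — stability
  of the *spatial extent* of the network across sessions.

## Dual regression

Given a stack of $p$ template network maps $T \in \mathbb{R}^{V \times p}$
and one subject-session 4D series $Y \in \mathbb{R}^{V \times t}$ on the
same grid, the subject-specific maps are estimated in two joint OLS stages:

1. **Spatial stage.** Each time point's volume (each voxel's series
   demeaned over time, each volume demeaned over the mask) is regressed on
   the voxel-demeaned templates, all networks simultaneously, giving one
   time course per network.
2. **Temporal stage.** Each time course is scaled to unit sample variance,
   then every voxel's demeaned series is regressed jointly on all demeaned
   time courses. The coefficients are the subject's beta maps; dividing by
   the coefficient standard error (residual variance times the inverse Gram
   diagonal, residual df $t - p - 1$) gives the Z maps.

Both stages are *joint* multiple regressions; running one network at a time
would let variance shared between spatially correlated networks leak into
each map. The "Z" is the OLS t-statistic used directly: at 150 time points
the t and normal deviates are essentially identical, and the sign threshold
Z > 0 used downstream is exactly invariant to the conversion
(`convert_to_z = TRUE` applies the exact t-to-normal quantile map for users
who want calibrated magnitudes).

Numerical conventions, chosen so that threshold masks stay well defined on
degenerate input:

* voxels with a constant time series get beta = Z = 0, never `NaN`;
* residual variance is floored at a denormal-scale constant so Z is finite
  wherever the voxel varies;
* coefficients indistinguishable from zero at double precision (below
  $10^{-10}$ of the network's largest coefficient) are reported as exact
  zeros — a strict sign threshold must not pick up floating-point noise;
* variance normalisation makes Z maps exactly invariant to affine rescaling
  of the raw data.

## Masks and summary values

Two mask types feed the ICC:

* the **entire-network (EN) mask** — template voxels strictly above a
  cutoff (default 0, i.e. the template's whole footprint);
* the **subject-overlap ROI** — voxels with Z strictly positive in *both*
  of a subject's sessions, that individual's reproducible network core.

The per-subject summary value is the arithmetic mean over the mask, taken
from the Z maps by default (`use = "beta"` switches to the raw
coefficients; which scale the reference workflow used is not defined
operationally, so both are exposed). Thresholds are strict everywhere: a
voxel exactly at the cutoff is excluded. An empty overlap ROI contributes a
missing value that is dropped pairwise — imputing zero would conflate
"network absent" with "connectivity low".

## ICC(3,1)

From the $n \times k$ subjects-by-sessions table ($k = 2$ here), the
two-way ANOVA with random subject and fixed session effects gives the
between-subject mean square BMS, the session mean square JMS and the error
mean square EMS, and

$$\mathrm{ICC}(3,1) = \frac{\mathrm{BMS} - \mathrm{EMS}}
                            {\mathrm{BMS} + (k-1)\,\mathrm{EMS}}.$$

Because the session term is removed from the error, a constant session
offset (a global drift between visits) does not lower the ICC — the
statistic measures *consistency*, not absolute agreement. The
implementation removes the column means before decomposing, which makes
that invariance exact in floating point even for session offsets of $10^4$.
Negative raw estimates are clamped to 0 for reporting (the convention
behind printed "0.00" table entries) with the raw value returned alongside;
an all-equal table is the statistic's own 0/0 worst case and is reported as
0 with a warning. Sessions are labelled strings (BL/FU), never inferred
from file order: a silent session swap would leave every symmetric
statistic unchanged and corrupt only the session-effect decomposition,
invisibly.

## R12 and threshold sensitivity

With $V_1, V_2$ the suprathreshold voxel counts of the two sessions and
$V_\mathrm{ov}$ the count suprathreshold in both,
$R_{12} = 2V_\mathrm{ov} / (V_1 + V_2) \in [0, 1]$. Both-empty sessions are
an error, deliberately distinct from $R_{12} = 0$ (disjoint but present).
`threshold_sweep()` evaluates the ratio over a ladder of cutoffs: overlap
of thresholded maps is known to be threshold-sensitive, and on the
synthetic studies below the mean R12 drops substantially when the cutoff
rises from 0 to 1.5 while the ROI ICC moves far less — the sweep makes that
dependence visible instead of hiding it in a convention.

## Group-level statistics

Between-group comparisons of per-subject reliability scores use two-sided
pooled-variance t-tests with a Bonferroni-adjusted significance level
$0.05/m$ ($0.0056$ for nine networks), applied as a fixed level rather
than by multiplying p-values. Demographic tables are recomputable from
printed summaries alone: `ttest_from_summary()` implements the pooled
t-test from (mean, SD, n) triples and `chisq_2x2()` the Pearson chi-square
without continuity correction. Those two conventions — pooling rather than
Welch, no Yates correction — are the ones under which published
demographic p-values of this design reproduce from their printed cells
(recomputing the standard worked examples gives p = 0.246, 0.169 and 0.273
against printed values of .24, .17 and .27; the small age discrepancy is
what rounding the summaries to one decimal costs).

## The synthetic generator

No suitable public two-session dataset exists at desk scale, so the
generator produces the *minimal* structure under which dual regression is
the correct estimator — a low-rank spatial-map-by-time-course mixture:

$$\mathrm{map}_{ijs} = T_j \,(1 + b_{ij} + w_{ijs} + \delta\,[s = FU]),
\qquad
Y_{is}(v, t) = \sum_j \mathrm{map}_{ijs}(v)\, c_{ijs,j}(t) + \varepsilon$$

with $b \sim N(0, \sigma_b^2)$ per subject-network (between-subject),
$w \sim N(0, \sigma_w^2)$ per subject-session-network (between-session),
$c$ independent unit-normal time courses, and
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$ sensor noise. Templates are
Gaussian blobs truncated at three radii — compact support makes "the
entire network" well defined and the zero-noise degenerate cases exact —
placed on a lattice with at least three-radius spacing, which keeps every
pairwise template correlation below 0.5.

Default study conditions mirror the two-session design the package is
built for: 14 HC and 20 MS subjects, nine networks, 150 volumes at
TR = 3 s. Where the design gives no number, the defaults are one-time
choices a practitioner would call realistic, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `sigma_between` | 0.5 | ~50% between-subject amplitude CV, enough spread for ICCs in the high-reliability band |
| `sigma_within` | HC 0.05, MS 0.1 | within far below between (stable disease, 3-month interval); patients get the larger value, encoding the greater session-to-session variability expected in a patient group |
| `sigma_noise` | 6 | calibrated so single-subject network Z maps peak around 5–10 at 150 volumes, the magnitude real dual-regression Z maps show |
| `session_shift` | 0 | no systematic session effect; nonzero values exercise the fixed-session-effect term of the ICC ANOVA |
| `z_peak` | 4 | template maps in Z-like units |

Determinism: a config plus seed reproduces every array bit-for-bit, and
each subject-session BOLD series is seeded individually so any single
series can be regenerated without simulating the study.

### What the generator does and does not emulate

It emulates the variance structure that the two reliability statistics
measure — and that is all. No hemodynamic response, physiological noise,
motion, drift, spatial autocorrelation of noise, or registration error. A
consequence worth knowing: because within-session variability enters as a
*multiplicative amplitude* perturbation and stage 1 recovers each time
course with the amplitude's sign and scale absorbed, the Z-map sign
pattern — all that a Z > 0 mask sees — is nearly invariant to
`sigma_within`. On synthetic studies the ROI ICC therefore falls
monotonically as `sigma_within` grows while R12 barely moves; R12 degrades
with *sensor noise* instead. Real data destabilise spatial extent through
mechanisms (motion, registration, physiological noise) this generator
deliberately omits, so passing tests demonstrate correctness of the
estimators, not that real-world R12 will behave like the simulation.

Similarly, with `sigma_within = sigma_noise = 0` each subject's two
sessions share identical maps, so R12 is exactly 1; the ROI ICC is near
but not exactly 1 (about 0.99 at 150 volumes) because each session's
realised time courses carry their own sample variance into the stage-2
coefficients — and with zero noise the Z statistic itself is
0/0-degenerate, so that check is meaningful on beta maps only.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- simulation_config(seed = 1)      # the default two-group design
res <- run_pipeline(cfg, out_dir = "results")
subset(as.data.frame(res$repro), group == "MS")[1:4, ]
#>     network group  n icc_en icc_roi r12_mean r12_sd
#>   visual_00    MS 20   0.96    0.94     0.53  0.023
#>   visual_01    MS 20   0.91    0.92     0.54  0.012
#>   visual_02    MS 20   0.90    0.89     0.54  0.012
#>         dmn    MS 20   0.96    0.97     0.53  0.018
```

(The chunk is not evaluated at build time; the output shown is from a run
of exactly this code.) Test-suite problem sizes are deliberately
desk-scale — grids of $8^3$–$16^3$ voxels, 20–150 volumes, 3–9 networks,
up to 40 subjects — chosen so that the whole validation suite, including a
200-replicate null-calibration study of the Bonferroni flag, runs on a
single CPU in a couple of minutes.

## Known limitations

* The EN/ROI summary is the mean over the mask; median or peak summaries
  are not implemented.
* ICC(3,1) is the only headline ICC form; absolute-agreement forms
  (ICC(2,1)) and bootstrap confidence intervals are out of scope.
* The generator's group difference is purely a variance-component
  difference; it cannot represent topographic reorganisation of networks.
* Voxel-wise ICC maps (`voxelwise_icc()`) are provided for exploration but
  are not part of the headline tables.
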