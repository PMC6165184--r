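---
title: "Methods: two-sample Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summaryMR)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of
an exposure X on an outcome Y using J genetic variants as instruments,
with only per-SNP summary statistics from two non-overlapping GWAS: the
per-allele effect on the exposure, $\hat\beta_{Xj}$ with standard error
$\sigma_{Xj}$, and the per-allele effect on the outcome,
$\hat\beta_{Yj}$ (a log odds ratio here) with $\sigma_{Yj}$. Under the
instrumental-variable assumptions (the variant is associated with X, is
independent of confounders, and affects Y only through X), each SNP
yields a Wald ratio estimate of the causal effect per unit of X:

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj},
\qquad \mathrm{se}(\hat\theta_j) \approx \sigma_{Yj}/|\hat\beta_{Xj}|.$$

The first-order (delta-method) ratio SE ignores $\sigma_{Xj}$; this is
the standard choice for inverse-variance weighting and the package
default (a second-order SE would add
$\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$; at the instrument
strengths of the bundled data the difference is negligible — it moves
the weighted median point estimate in the fifth decimal).

### Pooled estimators

**IVW.** With weights $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2 =
1/\mathrm{se}(\hat\theta_j)^2$,

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
\qquad \mathrm{se} = \Big(\sum_j w_j\Big)^{-1/2},$$

which is algebraically the weighted least-squares slope of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin (a test asserts
the equivalence to 1e-12 relative against an `lm` oracle). The
fixed-effect SE above is the default; a multiplicative random-effects
option inflates it by $\max(1, \sqrt{Q/(J-1)})$. Fixed-effect, z-based
inference is the default because it reproduces the bundled study's
printed intervals and p-values. Inference is two-sided normal.

**Weighted median.** Sort the ratios $\hat\theta_{(1)} \le \dots \le
\hat\theta_{(J)}$ with weights $w_{(j)}$; form standardized midpoint
cumulative weights $s_j = (\sum_{i \le j} w_{(i)} - w_{(j)}/2)/\sum_i
w_i$ and linearly interpolate $\hat\theta$ at $s = 0.5$. The estimator
is consistent when valid instruments carry at least 50% of the weight.
Its SE has no closed form; the package uses a parametric bootstrap —
resample $\hat\beta_{Xj}^* \sim N(\hat\beta_{Xj}, \sigma_{Xj}^2)$ and
$\hat\beta_{Yj}^* \sim N(\hat\beta_{Yj}, \sigma_{Yj}^2)$ independently,
recompute the weighted median, and take the SD over replicates
(default 10,000, seeded, bit-reproducible; the seed and replicate
count are recorded in the result's metadata).

**MR-Egger.** Weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$ and a free intercept,
fitted by explicit normal equations. The intercept estimates the
average directional pleiotropic effect (a per-allele log-OR offset);
the slope estimates the causal effect under the InSIDE condition
(pleiotropic effects uncorrelated with instrument strength).
Coefficient SEs are the WLS SEs times $\max(1, s)$, where $s^2$ is the
weighted residual mean square on $J-2$ degrees of freedom — residual
underdispersion is not allowed to shrink the SEs. Normal-theory CIs
are the default, with a $t_{J-2}$ option; the intercept's point
estimate is insensitive to this choice but its p-value is not, and
software conventions differ, so only intercept point estimates are
treated as exactly reproducible. The Egger intercept is *not*
invariant to per-SNP allele re-orientation (IVW is; a test asserts
both), which is why harmonization orients every instrument to its
exposure-increasing allele first.

**Heterogeneity.** Cochran's
$Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2$ with the fixed
IVW weights, referred to $\chi^2_{J-1}$. Q is dimensionless (invariant
to the SD rescaling below) and zero exactly when all ratios coincide.
Note that Q does **not** vanish in the small-noise limit: as the
sampling noise shrinks, the deviations fall exactly as fast as the
weights grow, so Q remains $\chi^2$-distributed at every noise scale —
what converges is each ratio to the true effect.

### Units and SD scaling

Exposure effects are per-allele effects on the natural-log-transformed
trait. Estimates are reported per one standard deviation of the ln
exposure by multiplying the log-OR estimate, its SE and CI bounds by
`sdScale` (0.33 ln-units per SD for both bundled exposures); z-scores
and p-values are unchanged, and scaling before or after pooling is
algebraically identical for every estimator (asserted by test). One
bundled 25OHD instrument (rs117913124) is published in SD-of-ln-trait
units and is converted to ln-units by the same factor before
harmonization — `convertUnits()` multiplies beta and SE alike, leaving
the z-score invariant. Using the analysis's own 0.33 SD rather than
the source GWAS's SD is an assumption; it is the convention that
reproduces the bundled study's pooled OR, and it is applied
prominently in the run log.

## Harmonization

`harmonize()` orients each exposure record to its trait-increasing
allele (negating beta, swapping alleles, complementing the allele
frequency), then aligns the outcome effect to that allele, attempting
a strand-complement match before declaring an allele pair
irreconcilable. Palindromic (A/T, C/G) variants cannot be resolved
from alleles alone; the default policy `eaf_infer` aligns them by
which side of 0.5 the two studies' allele frequencies fall, and fails
loudly when either frequency is within `eafTolerance` (default 0.08, a
conservative community convention) of 0.5. `drop` and `trust` policies
are available.

Published instrument tables often print only the effect allele. Such
records are treated as *pre-oriented*: the outcome beta is taken to
refer to the printed exposure allele (and follows its sign if the
exposure record is flipped). The bundled tables are of this form, and
their printed effect alleles are already exposure-increasing, so
harmonization reproduces them verbatim — the internal consistency of
the reproduced results supports that reading.

Proxy substitution (`substituteProxy()`) replaces a missing outcome
record by a high-LD proxy's record (refusing below `minR2`, default
0.8) and stamps `proxied_by`. LD pruning in `filterInstruments()`
keeps, within any pair at or above the r² threshold, the SNP with the
smaller exposure p-value (ties: smaller SE, then lexicographic rsid —
the bundled data never exercise the tie-break; it is a package
convention). The significance filter is strict (`p < 5e-8`), matching
the genome-wide convention. One bundled p-value (4.74e-343) lies below
the smallest representable double and parses to 0; the container
therefore admits p = 0 as "below double precision", which a strict
threshold handles correctly.

## The simulator

`SimulationSpec()`/`simulateInstruments()` generate the two-sample
summary-statistic structure the estimators assume: true per-allele
effects $\gamma_j \sim U(0.02, 0.10)$, pleiotropic effects $\alpha_j$
(none; balanced $N(0, \tau^2)$; directional $N(\mu_\alpha, \tau^2)$,
drawn independently of $\gamma_j$ so InSIDE holds), SEs
$\sigma_{Xj} \sim U(0.002, 0.02)$ and $\sigma_{Yj} \sim U(0.016,
0.022)$, and observed effects $\hat\beta_{Xj} \sim N(\gamma_j,
\sigma_{Xj}^2)$, $\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j,
\sigma_{Yj}^2)$. The default ranges and J = 12 mirror the magnitudes
of the bundled instrument tables, so the simulator stresses the
estimators in the regime of the actual analysis. What it does *not*
emulate: LD between instruments, sample overlap, winner's curse, and
allele-level bookkeeping (simulated alleles are placeholders); passing
tests therefore validate the estimators' statistical behaviour under
the stated generative model, not robustness to those artefacts of real
data.

Observed $\hat\beta_{Xj}$ can be negative by sampling noise for weak
instruments. The simulator deliberately does not re-orient such SNPs:
truth is defined on the $\gamma_j > 0$ orientation, and flipping by
the observed sign would flip $\alpha_j$'s sign and corrupt
directional-pleiotropy recovery. For the same reason the
`InstrumentSet` container does not hard-enforce non-negative exposure
betas; `harmonize()` output satisfies it by construction (tested).

`runReplicates()` derives one sub-seed per replicate by drawing
`sample.int(2^31 - 2, nReps)` under the spec's seed, making whole
performance tables bit-reproducible. Monte-Carlo checks in the test
suite use 2000 replicates for null calibration (type-I error within
three binomial SDs of 0.05, coverage in [0.93, 0.97], estimated SE
tracking the empirical SD within 10%) and 1000 for
directional-pleiotropy recovery; both run in seconds.

## Numerical and design notes

* All file I/O keeps full double precision (`%.17g`); rounding is done
  only for display and for comparison against published values.
* The weighted-median interpolation returns the extreme ratio when
  half the total weight lies beyond the first or last midpoint
  (degenerate, heavily skewed weight configurations).
* Reproduction of the bundled study is exact at published rounding for
  13 of 15 printed quantities. Two sit half a unit in the last printed
  place away — the 25OHD weighted-median OR (computed 0.8751, printed
  0.87) and the 25OHD IVW upper CI (computed 0.9465, printed 0.94) —
  an irreducible artefact of recomputing from the 2–3-decimal printed
  inputs; `reproduceStudy()` flags them honestly, and no interpolation
  or weighting variant examined moves them across the boundary.
* The pipeline order is read → filter (significance, LD) → proxy →
  unit conversion → harmonize → estimate: filtering needs p-values,
  which belong to the per-study association tables, not to harmonized
  instruments.
* The Egger intercept is reported per ln-unit orientation and never
  rescaled by `sdScale` (it is a per-allele offset, not an effect per
  exposure unit).
* `cochranQ`, `mrIVW`, `mrEgger` and `mrWeightedMedian` are
  implemented as explicit closed forms; `lm`/WLS fits appear only as
  independent oracles in the test suite.

## Known limitations

No correlated-instrument (generalized) IVW — instruments are assumed
LD-independent, which the filtering step enforces from user-supplied
r² only (the package never computes LD from genotypes). No mode-based
estimators, MR-PRESSO, multivariable or bidirectional MR. Weak
instruments bias the Egger slope toward the null (visible in the
simulation tests as a small residual slope bias); no NOME/I²
correction is applied.
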