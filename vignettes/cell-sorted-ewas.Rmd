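---
title: "Designing and analysing cell-sorted DNA methylation association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing cell-sorted DNA methylation association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortedmeth)
```

# The problem

Epigenome-wide association studies (EWAS) of bulk tissue cannot say which
cell type carries a disease-associated methylation difference. Sorting
nuclei into purified fractions (for instance NeuN+ neuronal, SOX10+
oligodendrocyte and double-negative populations from cortex) solves that,
but changes the statistics of the study in three ways:

1. **Multiple samples per donor.** Each individual contributes one sample
   per sorted fraction, so observations are no longer independent across
   the pooled dataset.
2. **Cell-type-specific effects.** A true difference may be common to all
   fractions or confined to one; the analysis must both detect and
   attribute it.
3. **Cell-type-specific variance.** Purified fractions have their own
   site-wise variance distributions; some (neuronal) are markedly less
   variable than bulk tissue, others (double-negative glia) more.

`sortedmeth` implements the full design-to-analysis arc for such studies:
a synthetic cohort generator, principal-component quality control for the
sort itself, normalization-strategy scoring, binned power calculations,
four per-site regression frameworks, a false/true-positive simulation
benchmark, and the recommended two-stage discovery/characterization
pipeline.

# The synthetic cohort generator

Everything downstream is testable because the generator reproduces the
statistical structure that the analyses assume. Per cell type $c$ and site
$s$ the model is

$$ y_{s,i,c} = m_{s,c} + u_{s,i} + \varepsilon_{s,i,c}, \qquad
   u_{s,i} \sim N(0,\, \rho\,\sigma^2_{s,c}), \quad
   \varepsilon \sim N(0,\, (1-\rho)\,\sigma^2_{s,c}), $$

truncated to $[0,1]$, where $u_{s,i}$ is a donor intercept shared across
all of that donor's fractions (implemented as a shared standard-normal
factor scaled by $\sqrt{\rho}\,\sigma_{s,c}$, so the within-cell-type
variance is exactly $\sigma^2_{s,c}$ and the cross-fraction residual
correlation is exactly $\rho$).

Key choices, all settable through `cohort_config()`:

* **Sample structure.** Defaults: 200 donors; 182 NeuNPos, 168 Sox10Pos
  and 164 DoubleNeg samples (at most one per donor and fraction); age
  18–100 years, two sexes, eight brain banks. Covariates enter every model
  but have no effect on methylation unless `covariate_effects = TRUE`
  (which adds small age/sex effects at 1% of sites for confounding
  experiments).
* **Site-SD distributions.** Site SDs are drawn from a log-normal matched
  by moments to per-cell-type targets (defaults 0.036/0.023 for NeuNPos,
  0.038/0.024 for Sox10Pos, 0.057/0.033 for DoubleNeg, on the beta scale).
  The log-normal was chosen because empirical site-SD distributions are
  strongly right-skewed; a symmetric choice would misstate the fraction of
  high-variance sites that dominate power losses.
* **Variance–mean coupling.** The SD draws are rank-coupled (with jitter)
  to the baseline means so that sites near the 0/1 boundary receive the
  smaller SDs. This reproduces the variance–mean relationship of bounded
  methylation data, keeps boundary clamping rare (< 1% of values under
  defaults), and leaves the marginal SD distribution exactly the
  moment-matched log-normal because the coupling is a permutation of the
  draws.
* **Baseline means.** A three-component mixture (35% hypomethylated around
  0.06–0.16, 30% intermediate, 35% hypermethylated around 0.84–0.94).
  These weights are plumbing: they shape clamping frequency and nothing
  else that the benchmarks measure.
* **Cell-type structure.** 20% of autosomal sites get a mean offset in one
  cell type. The NeuN analogue receives the largest share (60%), the
  biggest offsets (|0.20–0.50| versus |0.18–0.40| for the glial
  fractions), and a hypomethylation-skewed direction, so that its marginal
  value distribution — not just individual sites — is the most distinct.
  This mirrors sorted cortex, where the NeuN+/NeuN− contrast is the
  primary axis of variation, and is what makes joint quantile
  normalization transform the neuronal fraction hardest.
* **Special site classes** for the normalization metrics: imprinted-region
  sites at 0.5 in everyone (SD 0.02), SNP-like probes with per-donor
  genotype bands at {0.03, 0.5, 0.97}, and X-linked sites of which a third
  are strongly sex-differential (females ≈ 0.5, males ≈ 0.15). The
  sex-differential subset is deliberately small: sex must be a visible
  axis (so the seabird metric has signal) without outranking the glial
  separation in the leading principal components, matching real arrays
  where cell identity dominates the methylome.
* **Spikes and failures.** `spike_dmps()` adds a case–control difference
  `delta` at randomly chosen sites, each either common to all fractions or
  specific to one uniformly chosen fraction; `inject_sort_failures()`
  creates mislabelled samples (within-donor label swaps) and mixture
  samples (convex combinations with another fraction's mean profile).

What the generator does **not** emulate: probe-type chemistry, batch and
position effects, missing values, cross-site correlation beyond the donor
intercept, and the long-range correlation structure of real residuals.
The last point matters for interpretation: in real data a chance imbalance
of the case labels against a latent donor-level factor inflates thousands
of sites at once, producing the very heavy upper tail of false-positive
counts that pooled uncorrected models show on real cohorts. The parametric
generator reproduces the *ordering* of that inflation (through
heteroskedasticity across cell types and the shared donor intercept) but
not its extreme magnitude. Passing benchmarks here therefore demonstrate
calibration and ranking claims, not the exact false-positive counts of any
real study. It is also unknown whether the original simulation studies in
this area resampled observed arrays with permuted labels rather than
simulating parametrically; this generator is a parametric stand-in.

# Quality control of the sort (stage 3)

Cell-type identity dominates methylome variation, so the leading principal
components of the site-centered beta matrix should cluster samples by
fraction. Two metrics are computed on the PC scores:

* **Isolation efficiency score** (per donor): for each cell type, the
  centroid and per-PC SD of its labelled samples are computed over the
  first `n_pcs` components (default 2); each sample's z-distance is the
  Euclidean norm of its per-PC z-scores, and the donor's score is the
  *maximum* over the donor's samples — max rather than mean, so that a
  single failed fraction flags the sort. Donors above the threshold
  (default 5) are flagged.
* **Cell-type distance filter** (per sample): a sample is retained iff it
  lies within 2 SDs of its labelled cell type's mean on each of the first
  two PCs separately. The statistics are computed once on the full sample
  set; iterating would shrink the SDs and over-exclude.

One consequence deserves emphasis: with approximately normal within-type
PC scores, a per-PC 2-SD rule retains about $0.9545^2 \approx 91\%$ of
clean samples by construction. On real data the retained fraction is
higher because genuine outliers inflate the SD estimate. Interpreting
"everything retained" as the clean-data expectation would be wrong; the
package's tests assert the theoretical retention band and zero flagged
donors on clean cohorts.

Stages 1 (array quality) and 2 (donor concordance) of a full pipeline need
raw array channels and are reported as "not evaluated" placeholders.

# Normalization strategy scoring

Between-sample quantile normalization can be applied jointly to all
fractions or separately within each. Forcing distinct cell types onto one
common distribution moves samples far more than within-type normalization
does, and the package scores both strategies (plus raw data) with three
signal-to-noise metrics, all "lower is better": imprinted-region
stability (the SE of per-sample means over imprinted sites), SNP-probe
genotype clustering (mean squared deviation from the nearest of 0, 0.5,
1), and sex separation on X-linked summaries (1 − the Mann–Whitney AUC,
oriented into $[0, 0.5]$; a per-sample-mean AUC is used rather than
averaging per-site AUCs because it is simpler and monotone-equivalent for
a strategy comparison). The rank transformation itself is delegated to
`limma::normalizeQuantiles` (ties averaged), which is exactly the
order-statistic-mean definition used here. Probe-type-stratified,
background-adjusted normalization of raw arrays is out of scope, so the
absolute metric values of any real-data pipeline are not reproduced —
only the joint-versus-per-cell-type comparison is meaningful, along with
the per-sample transformation magnitude (mean and SD of
|normalized − raw|).

# Power calculations

Per-site power for a case–control comparison is the exact two-sided
two-sample t-test power from the noncentral t distribution with $2n-2$
degrees of freedom and noncentrality $\delta\sqrt{n/2}/\sigma_s$, at the
experiment-wide threshold $\alpha = 9\times10^{-8}$. Genome-wide summaries
bin the site-SD distribution into 500 equal-count bins (sorted by SD) and
apply each bin's mean-SD power to all its sites; on 10,000-site profiles
the binning error is below one percentage point of coverage. Sample-size
search brackets by doubling and then bisects to the exact minimal integer
(a `paper_grid` option reproduces a coarse 100-point grid for
comparability with grid-based reports); minimal detectable differences are
searched on the fixed grid 0.001–0.100 in steps of 0.001 and reported in
percentage points at the command line. Tests are two-sided by default; a
one-sided option exists but is not the default because the two-sample
formulation of the underlying calculators is conventionally two-sided.

# The four regression frameworks

All frameworks adjust for age, sex and brain bank and are vectorized
across sites.

* **ctLR** — within-cell-type linear regression, one sample per donor, a
  classical t test on the case term. Independent observations by design.
* **allLR** — pooled OLS, `beta ~ case * cell_type + covariates`, with
  classical standard errors. Deliberately anticonservative with multiple
  samples per donor; the benchmark quantifies exactly that bias, so the
  implementation must not "fix" it.
* **MER** — the same fixed effects plus a random intercept per donor.
  Estimated per site by profiled REML over the variance ratio
  $\lambda = \sigma^2_u/\sigma^2_e$: the regression is rotated once per
  design into the eigenbasis of the cluster structure (block-wise known
  analytically), making the criterion a one-dimensional function of
  $\lambda$ whose site-dependent part is just $(N-p)\log \mathrm{RSS}_w$.
  A 44-point log-spaced grid (including the $\lambda = 0$ boundary) is
  evaluated for all sites simultaneously; the per-site optimum is refined
  by quadratic interpolation on the grid by default, or by exact Brent
  search (`refine = "brent"`) when per-site precision matters more than
  speed. Inference is Wald with a normal reference; Satterthwaite degrees
  of freedom are deliberately omitted (they would shift extreme-tail
  p-values slightly, and the choice is recorded here because of that).
  REML is the default; maximum likelihood is available.
* **CRR** — pooled OLS point estimates (identical to allLR by
  construction) with a cluster-robust sandwich covariance over donors,
  CR1 small-sample scaling $G/(G-1)\cdot(N-1)/(N-k)$ chosen to match the
  common sandwich implementations, and a t reference with $G-1$ degrees
  of freedom.

The cell-type factor uses treatment coding with the alphabetically first
label as reference (DoubleNeg under the default labels), configurable via
`reference`. This matters: the "main" case effect of the pooled models is
the case–control contrast *in the reference cell type*, and the
interactions are contrasts against it. With an above-average-variance
reference, the pooled models' classical main-effect tests are
anticonservative (pooled residual variance understates the reference
cell's), which is precisely the miscalibration the null benchmark
documents. Results tables therefore also carry the implied per-cell-type
case effects (`eff_<ct>_*`), which are coding-invariant.

Calls are made by a recorded policy: "any-term" (main effect or any
interaction; the default, since either may carry a DMP's signal depending
on which cell types it affects), "main-only", or "joint-test" (main
effect or the joint Wald interaction test). Zero-variance or
clamp-saturated sites are flagged non-converged, keep their rows, and are
never called.

# The simulation benchmark

Null benchmarks fix a cohort and repeatedly assign case/control labels at
the donor level (about 50/50), fit the requested frameworks and count
significant calls at 9e-8, 1e-7, 1e-6 and 1e-5; spiked benchmarks
additionally introduce 1,000 DMPs per study with a 5% mean difference,
half specific to one fraction and half common, and score detections
against the truth table. Two accounting decisions are prominent enough to
state:

* **ctLR denominators.** A within-cell-type model is scored over the DMPs
  that *affect its cell type*; counting DMPs confined to other fractions
  against it would conflate attribution with detection.
* **FWER calibration.** "The threshold controlling the family-wise error
  rate at 5%" is read as the empirical 5th percentile (linear
  interpolation) of the per-simulation minimum p-values — the standard
  permutation estimator. An alternative reading (the mean of
  per-simulation 5% p-value quantiles) is available behind
  `method = "mean-quantile"`.

Per-simulation seeds are derived deterministically from the master seed,
so benchmarks are reproducible and parallelizable. Fitting errors are
recorded per simulation without aborting the run. The problem sizes used
by the package's own reproduction runs are 100 null studies of 50,000
sites (ctLR and CRR, fully vectorized) and 100 spiked studies of 6,000
sites (1,000 spiked + 5,000 null), with the mixed model fitted on the
spiked sites, whose true-positive accounting is the quantity of interest.
Benchmark cohorts are generated without the special site classes — the
analysis set of a real study is QC'd autosomal probes, and a spike landing
on a genotype-band probe is undetectable for reasons that have nothing to
do with the frameworks under comparison.

# The two-stage analysis

Stage 1 discovers DMPs with ctLR per cell type at 9e-8 (well-calibrated
false-positive control); a relaxed discovery threshold is supported but
deliberately capped at 1e-6, beyond which false positives accumulate
faster than true ones. Stage 2 refits only the discovered sites with the
mixed model and tests heterogeneity across cell types by the joint Wald
test on all interaction terms (a per-term option exists), Bonferroni
adjusted over the discovered set at level 0.05 — the stage-2 multiplicity
rule is the package's choice, as is the joint-versus-per-term default.
Non-significant heterogeneity yields the label "common", which is
explicitly a non-rejection — absence of detected heterogeneity, not proof
of a shared effect; significant heterogeneity yields "cell-specific" with
the affected fractions taken from the per-cell-type contrasts at a nominal
0.05. Stage 2 never adds sites absent from stage 1, and refits only
discovered sites rather than the genome.

# Numerical notes and degenerate inputs

* Boundary clamping makes quantile normalization only approximately
  idempotent (tie-averaging at clamped 0/1 values); away from boundary
  ties it is exactly idempotent.
* `two_sample_t_power()` computes the critical value with
  `lower.tail = FALSE` to keep the extreme tail ($\alpha = 9\times10^{-8}$)
  at full precision, and uses the central t at $\delta = 0$ where the
  noncentral algorithm is less accurate than the identity "power = size".
* Under a true zero variance ratio, per-site REML estimates land at the
  $\lambda = 0$ boundary only about half the time; sites estimated at the
  boundary match the pooled OLS fit exactly, the rest differ by
  $O(10^{-4})$ in the coefficients. This is a property of per-site REML,
  not a solver artifact.
* Constant beta matrices, singleton normalization groups, single-sex
  cohorts, cell types with fewer than 3 samples, rank-deficient designs
  (reported with the offending columns) and empty discovery lists all
  raise typed errors or produce explicit empty results rather than
  silently degrading.

# Limitations

Synthetic benchmarks bound what the package can claim: real cohorts add
batch structure, probe chemistry, cellular contamination gradients and
cross-site dependence that the generator does not model, so false-positive
counts and true-positive rates on real data will differ from the synthetic
ones even when the qualitative conclusions (framework ranking, threshold
calibration, normalization strategy) carry over. The mixed model fits a
single random intercept; random slopes and multiple variance components
are out of scope, as are M-value analyses, inflation-correction
procedures, and raw-array (IDAT) processing.
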