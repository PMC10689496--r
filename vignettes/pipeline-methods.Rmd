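---
title: "Models, priors and design choices in the urheimat pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, priors and design choices in the urheimat pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters with their defaults and units,
what the synthetic-data generator does and does not emulate, the numerical
conventions, and the choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The scientific problem

The pipeline dates the divergences of a small language family — four living
South Caucasian languages plus historically attested Old Georgian — from a
binary matrix of cognate sets grouped into meaning concepts, and then
triangulates the family's homeland from three independent lines of
evidence: the reconstructed past ranges of taxa whose names descend from
proto-roots, the biome associations of dated archaeological cultures, and
the placement of ancient genomes in the principal-component space of modern
populations. Every stage consumes and produces ordinary tabular data
(tibbles), dated `phylo` trees, or small raster matrices.

## 2. Cognate likelihoods

Characters are binary with `?` treated as missing-at-random: the pruning
partial for a `?` tip allows both states. Columns with no observed cell
carry no information and are skipped entirely.

* **CTMC.** Reversible two-state generator with stationary presence
  frequency $\pi_1$, normalized so the expected substitution rate at
  stationarity is 1. Transition probabilities are closed-form.
* **Covarion.** Four states (0/1 visible × slow/fast hidden). Within-slow
  substitutions run at relative rate $\alpha \in (0,1]$, within-fast at 1,
  hidden switches at rate $s$ preserve the visible state, hidden equilibrium
  frequencies are equal, and the generator is normalized to unit expected
  *visible* substitution rate. At $\alpha = 1$ the model collapses exactly
  to the CTMC (a unit test asserts this), and as $s \to 0$ it becomes the
  equal-weights mixture of a slow and a fast CTMC.
  Visible-state frequencies are estimated (uniform prior) rather than
  fixed; the source description of the model is agnostic on this point, and
  estimating them nests the fixed case.
* **Stochastic Dollo.** Each cognate set is born exactly once — uniformly in
  tree time over the branches plus an infinite root stem on which only
  births surviving to the root register — and is lost at rate $\mu_D$
  (per unit of clock-scaled time). The per-branch birth-position integral
  has the closed form $A\,(1-e^{-\mu t})/\mu + B\,(t-(1-e^{-\mu t})/\mu)$,
  where $A$ and $B$ are the subtree likelihoods given presence/absence at
  the branch's child. Observability conditioning is applied per column
  (the birth intensity cancels), so Dollo fits skip the ascertainment dummy
  columns instead of correcting with them.

**Ascertainment.** For CTMC/covarion fits each concept carries one flagged
all-zero column, and the concept log-likelihood is corrected by
$-n_c \log(1 - P_c(\text{all absent}))$ with $P_c$ evaluated under the same
concept rate and gamma mixture. This is the conditional likelihood of
observing only attested cognate sets, and a property test asserts it always
increases the log-likelihood.

**Rate variation.** Two independent switches, because the source design is
ambiguous about their joint use: 4-category discrete gamma across cognate
sets (mean-one quantile-mean categories) and mean-one per-concept rate
multipliers sampled under an additive delta-exchange constraint with a
lognormal(0, 0.5) prior.

## 3. Tree prior, clocks, calibrations

The fossilized birth–death prior is implemented conditioned on the root age
with no survival conditioning, which makes the $\mu=\psi=0,\rho=1$ case
reduce *exactly* to the Yule closed form (unit-tested, plus a quadrature
check of the node-age normalization). A dated non-extant tip requires
$\psi > 0$ and contributes the $\psi\,p_0(y)/q(y)$ fossil factor.

Hyperpriors (all configurable via `phylo_priors()`):

| parameter | default | rationale |
|---|---|---|
| diversification $\lambda-\mu$ (1/yr) | lognormal(log 2e-4, 1.5) | the ~1e-4/yr scale of language families; a biological-speciation scale (median ~7e-3/yr) was tried first and squeezes the weakly identified root toward the present |
| turnover $\mu/\lambda$ | Uniform(0,1) | uninformative on [0,1) |
| fossil-sampling proportion $\psi/(\psi+\mu)$ | Beta(1,1) | uninformative |
| extant sampling $\rho$ | fixed 1 | all four living languages are sampled |
| clock rate (subst/yr) | lognormal(log 2.5e-4, 1.5) | broad, centred on typical lexical replacement rates |
| UCLN log-sd | Exponential(mean 1/3) | the usual weakly informative choice |
| covarion switch rate | lognormal(log 0.1, 1.5) | occasional switching is the covarion's defining regime, so the prior is centred well below the substitution rate and kept broad |

Calibrations: Old Georgian enters as a fixed tip age of 900 BP (no tip-age
sampling); the Megrelian–Laz node carries a Normal(1200, 10) years BP prior
whose clade is held monophyletic (topology proposals that would break a
calibrated clade are rejected, the standard treatment of
monophyly-constrained calibrations). The sigma is configurable (50/100/200)
for sensitivity runs.

## 4. The sampler

One proposal per generation, drawn by weight: bounded-uniform and local
Gaussian node-age moves, a root-gap multiplier, an up–down move that
stretches all uncalibrated internal ages while compressing the clock rate
(the critical move along the tree-height/rate ridge of tip-dated designs),
narrow exchange on the topology, scale moves on rates and model parameters,
a targeted independence proposal for calibrated node ages, and slide moves
for bounded parameters. Trees and the scalar trace are sampled every `thin`
generations; the first `burnin_fraction` of samples is discarded, so the
study configuration (2e8 generations, thin 5000, 10% burn-in) retains
36,000 trees.

Posterior summaries: ESS by the initial monotone positive-pair-sum rule;
HPD as the shortest contiguous sample window (leftmost on ties); the MCC
tree maximizes the product of sampled-clade frequencies with node heights
summarized as per-clade mean MRCA ages (not common-ancestor heights) — the
choice is recorded in the output metadata.

## 5. Nested sampling

Classic single-run nested sampling with the deterministic shrinkage
schedule $X_i = e^{-i/N}$, a prior-constrained MCMC kernel built from the
same proposals as the main sampler (default subchain length 100 in the API;
reduced lengths are used in the shipped analyses, stated below), an sd
estimate of $\sqrt{H/N}$ from the information $H$, and termination when the
remaining prior mass can contribute less than `tol` (default 1e-6) of the
accumulated evidence. A conjugate-normal toy (through the same generic
engine) is tested against its analytic evidence, and the estimator's
particle-count scaling is checked empirically.

## 6. The synthetic-data generator

One root seed determines every output; each generator draws from a
sub-stream derived deterministically from the seed and a stage tag.

* **Trees.** Forward birth–death (defaults: birth 1.5e-4/yr, death
  2e-5/yr) run until four lineages are alive, observed at a memoryless
  instant, extinct side-branches pruned, and one dated tip grafted at
  900 BP. `kartvelian_reference_tree()` instead fixes the canonical node
  ages (root 7641, Georgian–Zan 2617, Megrelian–Laz 1200 BP) for
  recovery experiments.
* **Cognates.** Shifted-Poisson cognate sets per concept, *conditioned on
  the configured total* (251 concepts × mean 736/251 → exactly 736 sets, as
  in the attested matrix); simulation down the tree under the chosen model;
  columns with no attested presence are redrawn (the observability filter);
  `?` inserted completely at random (default 3%; the attested matrix does
  not state how its uncertain cells arose, so both readings are treated as
  missing-at-random). Covarion defaults are switch rate 0.02 and slow
  fraction 0.05 — occasional regime switching with strong slow/fast
  contrast. This was calibrated once so the hidden-regime signature is
  actually present in the generated data: fast switching makes the marginal
  visible process statistically indistinguishable from a CTMC, whereas in
  the chosen regime the covarion model carries a clear evidence margin over
  the CTMC at full scale (the acceptance script recomputes this margin as
  `log_bf_covarion_vs_ctmc`).
* **Climate.** Gaussian random fields (smoothed white noise, kernel sd 4
  cells) with AR(1) drift 0.85 between slices, mapped into −15..30 °C and
  100..2500 mm. Once the kernel spans the grid the field is flat at the
  range midpoint. These are caricatures: no topography, no spatial
  covariance between temperature and precipitation.
* **Species.** Gaussian response surfaces in the two climate variables;
  presences sampled proportional to true suitability.
* **Pollen and cultures.** Sites uniform over valid cells and slices; biome
  labels from a true softmax model in standardized climate (8 classes);
  arboreal-pollen percentages drawn consistently with the label. The
  default coefficient sharpness is set so a fitted classifier lands in the
  mid-seventies percent accuracy regime reported for real pollen-biome
  classifications. Culture sites are placed only in biomes their culture is
  associated with in the given window.
* **Genotypes.** Balding–Nichols population frequencies at the configured
  FST, diploid binomial genotypes, 969 modern reference individuals (three
  populations) and 563 projected individuals with 50%
  missing-completely-at-random calls; optional 50/50 admixture. Real
  pseudo-haploid calling conventions are *not* emulated.

Passing tests on these data demonstrate internal consistency of the
pipeline — correct likelihoods, calibrated inference, recoverable truths —
not that real cognate codings, pollen counts or ancient genomes satisfy the
generators' independence assumptions.

## 7. Niche and biome conventions

MaxEnt: linear + quadratic terms and 30 forward plus 30 reverse hinge knots
per variable (evenly spaced over the background range; the reference tool
derives knot placement from data, which is version-internal), features
standardized over the background, per-feature penalties
$\beta_j/\sqrt{m}$ with the quadratic-class multiplier interpolated from
1.0 (≤10 presences) to 0.25 (≥100) and hinge 0.5, optimized by proximal
gradient with backtracking (the penalized objective is non-increasing by
construction; tolerance 1e-7, cap 2500 iterations). Output is the cloglog
transform $1-\exp(-e^{\eta-\log Z+H})$ with features clamped to the
training range; logistic is available by flag. maxSSS thresholds use
background points as absence stand-ins, candidate thresholds are the
distinct presence suitabilities, ties break to the lowest maximizer
(ranges err inclusive), and binarization uses ≥ so a presence at the
threshold is predicted present. Per-period combination of co-occurrence
slices defaults to union — the source description ("combined") is
ambiguous, so intersection and frequency rules are provided as options.

Biome bins are lower-inclusive at 5/25/50 with 75 belonging to the 50–75%
class and only strictly greater values to the top class; sub-5% sites take
their supplied low-arboreal label (Desert/Steppe/Tundra/Glacier — the
labels are inputs, not inferred). The stated class arithmetic ("three of
these biomes", "the rest, i.e. 5") is internally inconsistent; the
implementation uses 4 + 4 = 8. The multinomial fit is by maximum likelihood
(nnet) without regularization; coefficients beyond |30| on the standardized
scale trigger a separation warning and are capped. The final association
window runs to 2000 BP with an optional extension flag to 1500 BP; in the
6000–4000 BP window the Copper Age shares the Bronze Age's
steppe-to-75%-forest association (the tabulated source row is truncated in
extraction; the accompanying text supports the shared reading).

## 8. PCA projection conventions

Per-SNP frequency uses the shrinkage form $(1+\sum g)/(2+2n)$ (plain mean/2
behind a flag); calls are centered by $2\hat p$ and scaled by
$\sqrt{\hat p(1-\hat p)}$; missing reference calls are mean-imputed (zero
after centering); SNPs monomorphic in the reference panel are dropped with
a reported count. Ten components are computed and two reported by default.
No outlier-removal iterations are run. Projection solves the least-squares
fit of the individual's observed normalized calls against the loadings
restricted to those SNPs; with complete data this equals the plain dot
product. PC signs are fixed by making each component's largest-magnitude
loading positive.

## 9. Problem sizes in the shipped analyses

The test suite and `scripts/acceptance.R` choose these sizes as the
package's own balance of fidelity and turnaround:

* split-date inference: the full 251-concept stand-in matrix with a
  1,500,000-generation chain (thin 750) in the acceptance script and a
  900,000-generation chain in the tests;
* nested sampling: 20 particles / subchain 25 in the acceptance script
  (the study's particle count), 10 / 12 in the tests;
* coverage: 12 simulation-based-calibration replicates at 40 concepts and
  40,000 generations. Truths are drawn from the inference prior via
  prior-only chains because, with five tips and two dating anchors, the
  root age lies on a height–rate ridge where the posterior remains
  prior-dominated — fixed-truth frequentist coverage of credible intervals
  is not nominal in this regime (the design's own reported root interval
  spans some seventeen thousand years), while prior-drawn truths make the
  95% interval property exact up to sampler error.

## 10. Known limitations

* The sampler is a straightforward single-chain Metropolis–Hastings; no
  Metropolis-coupling, no adaptive tuning. Tree-height ESS per generation
  is modest, which is why the shipped chains are long.
* The stochastic Dollo implementation integrates single births exactly but
  does not implement the missing-data-aware variants needed for partially
  sampled cognate classes beyond the `?` convention described above.
* The MaxEnt optimizer reproduces the published feature classes and
  penalty structure, not any particular binary's iteration-for-iteration
  behaviour.
* Synthetic climate fields and Balding–Nichols panels are deliberately
  minimal; conclusions about real rasters or genotype panels require the
  real data, which the pipeline reads through the same interfaces
  (ASCII-grid rasters, occurrence/site CSVs, EIGENSTRAT triplets).
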