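---
title: "Comparative analysis of cytoplasmic-incompatibility strength: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of cytoplasmic-incompatibility strength: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciphylo)
```

## The scientific problem

*Wolbachia* are maternally inherited bacterial symbionts of insects. Many
strains induce cytoplasmic incompatibility (CI): when an infected male mates
with an uninfected female, a fraction of the resulting eggs die; infection in
the female rescues them. CI strength varies enormously among strains, and the
leading mechanistic candidates for that variation are symbiont density in the
testes, transcript levels of the CI factor genes *cifA*/*cifB*, and host
development time. Because strains are related by a phylogeny, naive
regressions of CI strength on these predictors confound mechanistic
association with shared ancestry. `ciphylo` implements the full comparative
workflow: phenotype estimation, qPCR quantification, phylogenetically
corrected regression, and phylogenetic-signal testing, plus a synthetic-study
generator so that every stage can be validated against known ground truth.

## CI strength from hatch data

The unit of observation is a vial: one female crossed to one male, with eggs
laid and eggs hatched counted. Four cross types are distinguished by the
infection status of female x male (`UU`, `UI`, `IU`, `II`); `UI` is the CI
cross. For each CI vial $i$ of a strain,

$$ s_{h,i} \;=\; 1 - \frac{h_i}{\bar h_{\mathrm{compat}}}, $$

where $h_i$ is the vial's hatch rate and $\bar h_{\mathrm{compat}}$ is the
unweighted mean of per-vial hatch rates over the strain's compatible cross
types. $s_h = 1$ means no CI-cross egg hatched, $s_h = 0$ no deviation from
compatibility; negative values occur when a CI vial out-hatches the baseline.
Vials with fewer than ten eggs laid are excluded before any computation: a
nine-egg vial constrains a proportion so weakly that it mostly adds noise.

Choices worth making explicit:

* **Baseline is a mean over vials, not over eggs.** "Mean hatch of compatible
  crosses" is read as a mean over samples; egg-weighted averaging would let a
  single fecund female dominate the baseline.
* **Bootstrap unit.** The BCa interval for mean $s_h$ resamples the per-vial
  $s_h$ values with the compatible-cross mean held fixed. Resampling baseline
  vials jointly is a defensible alternative; we hold the baseline fixed
  because $s_h$ is defined per CI vial against the strain's fixed baseline,
  and the residual baseline uncertainty is an order of magnitude smaller than
  the CI-vial spread at realistic designs (30 baseline vials of ~40 eggs).
  The per-vial values are sorted before resampling so results do not depend
  on row order.
* **Classification.** A strain is `none` when the Mann–Whitney test of
  CI-cross vs compatible-cross hatch rates is not significant at 0.05;
  otherwise `strong` when mean CI-cross hatch is below 20%, else `weak`.
* **Mann–Whitney variant.** Exact enumeration of all group-label assignments
  when both groups have at most eight vials (valid under ties); otherwise a
  tie-corrected normal approximation without continuity correction.
* **Cross-type omnibus.** Kruskal–Wallis (tie-corrected) with Dunn's pairwise
  z tests on pooled ranks; pairwise adjustment defaults to Holm and is
  configurable (Bonferroni, BH, ...), since the omnibus literature names no
  single convention.

### The BCa interval

With bootstrap replicates $\theta^*_1,\dots,\theta^*_B$ of the statistic
$\hat\theta$, the bias correction is
$z_0 = \Phi^{-1}(\#\{\theta^*_b < \hat\theta\}/B)$ and the acceleration
$a = \sum_i (\bar\theta_{(.)} - \theta_{(i)})^3 / \{6[\sum_i(\bar\theta_{(.)}
- \theta_{(i)})^2]^{3/2}\}$ from the jackknife. Endpoints are the empirical
$\Phi\!\left(z_0 + \frac{z_0 + z_\alpha}{1 - a(z_0+z_\alpha)}\right)$
percentiles (quantile type 7). With $z_0 = a = 0$ this is exactly the
percentile interval. Degenerate inputs (all values identical) return a
zero-width interval with a warning rather than an error, because constant
$s_h = 1$ genuinely occurs for fully incompatible strains. When the bootstrap
distribution falls entirely on one side of $\hat\theta$ the bias proportion is
clamped to $[1/(B+1),\,B/(B+1)]$ to keep $z_0$ finite. Default $B$ is 10,000,
seedable.

## Relative quantification (2^−ΔΔCt)

Symbiont density is quantified as the relative abundance of a single-copy
bacterial gene to a conserved single-copy host gene; *cif* transcript levels
as the relative abundance of the *cif* target to an exogenous RNA spike-in
added before reverse transcription. Samples run in triplicate per channel; a
sample is excluded whole when either channel's triplicate standard deviation
(n−1 denominator) exceeds 0.4 cycles — a one-channel failure makes the
sample's ΔCt unreliable regardless of the other channel. Then

$$ \Delta Ct = \overline{Cq}_{\mathrm{target}} -
   \overline{Cq}_{\mathrm{normalizer}}, \qquad
   FC = 2^{-(\Delta Ct - \Delta Ct_{\mathrm{ref}})} , $$

so `log2_fc` is exactly −ΔΔCt and fold changes are invariant to any constant
Cq offset applied to both channels. The density calibrator is one randomly
selected sample of the reference strain (seeded, and recorded in the output's
`reference_sample` attribute). The transcript calibrator is the unweighted
mean ΔCt over the designated reference assay groups — averaging in ΔCt (log)
space, because fold changes are ratios and the arithmetic mean of ratios
overweights high expressors. Primer efficiency is assumed to be exactly 2;
efficiency calibration is out of scope. Strain contrasts use Welch t tests on
log2 fold changes against the reference strain with Benjamini–Hochberg
adjustment; "pairwise t test" and "FDR" are underdetermined phrases, and
Welch + BH are the defaults a practitioner would reach for when group
variances and test counts are both modest.

## Phylogenetic regression with Pagel's λ

Strain-level traits live on a rooted, ultrametric phylogeny with branch
lengths. Under Brownian trait evolution the expected covariance of tips $i,j$
is proportional to $C_{ij}$, the root-to-MRCA shared path length. Pagel's λ
multiplies the off-diagonal of $C$, interpolating between no phylogenetic
signal (λ = 0) and pure Brownian motion (λ = 1). The regression
$y = \beta_0 + \beta_1 x + \varepsilon$, $\varepsilon \sim N(0, \sigma^2
V(\lambda))$ is fitted by generalized least squares; λ is profiled by maximum
likelihood over $[0, 1]$ with a bounded scalar optimiser (tolerance $10^{-6}$)
plus explicit evaluation of both boundaries, since `optimize()` alone can
miss a boundary optimum.

Conventions, stated because they change p-values slightly:

* Inference on β uses $\hat\sigma^2 = RSS_V/(n-2)$ with $t_{n-2}$, while λ
  itself is profiled by ML — the common hybrid in comparative methods.
* $R^2 = 1 - RSS_V / RSS_{V,0}$ with both residual sums in the V-whitened
  space (intercept-only null), the convention of the comparative-methods
  tooling this field uses. It is invariant to affine rescaling of $x$.
* AIC counts the β entries, σ², and one more parameter when λ is estimated;
  so two fits with identical likelihood and $\hat\lambda = 1$ differ by
  exactly 2. `pgls_model_choice()` reports the λ-estimated and λ = 1 fits and
  marks the lower-AIC fit preferred.
* A flat profile (star-like tree, tiny n) is flagged (`flat_likelihood`) and
  λ reported as 1 with a warning rather than an arbitrary interior value.
* The λ transform applied to a non-ultrametric covariance emits a warning:
  the transform is canonically defined for ultrametric trees, but the same
  off-diagonal multiplier is applied so that consumers can proceed
  deliberately.

`pagel_lambda_signal()` reuses the same machinery with an intercept-only
design to test phylogenetic signal in a continuous trait, comparing
$\hat\lambda$ to λ = 0 by likelihood ratio against $\chi^2_1$. Because λ = 0
is a boundary value, the $\chi^2_1$ reference is conservative; the
calibration suite checks that the realised type-I error at nominal 5% stays
at or below 7%.

## Fritz–Purvis D for binary traits

For a binary trait on a fully bifurcating tree, nodal values are assigned
root-ward: each internal node takes the branch-length-weighted average of its
two daughters (inverse-length weights — Felsenstein's ancestral estimate —
which reduce to the simple average under equal branch lengths; a zero-length
daughter takes all the weight, and two zero-length daughters average
equally). The sister-clade sum $\Sigma d$ adds $|v_L - v_R|$ over internal
nodes. D locates the observed sum between two simulated expectations:

$$ D = \frac{\Sigma d_{obs} - \overline{\Sigma d_{BM}}}
            {\overline{\Sigma d_{rand}} - \overline{\Sigma d_{BM}}} $$

with the random null built from B tip-label shuffles and the Brownian null
from B Brownian simulations thresholded at the observed prevalence (ties in
the threshold broken by tip-label order, so runs are reproducible). B
defaults to 1,000 per null. Because both nulls pass through the same
$\Sigma d$ operator, the calibration $E[D] \approx 1$ (random) and
$E[D] \approx 0$ (Brownian) holds for any fixed nodal-estimator rule; the
acceptance suite verifies both to within 0.15 over 500 replicate datasets of
50-taxon trees at prevalence 0.5. $P_1$ is the fraction of random-null sums
at or below the observed sum, $P_0$ the fraction of Brownian-null sums at or
above it — a one-tailed reading of "differs from D = 1 / D = 0" in the
direction of clumping, chosen because the substantive question is always
whether a trait is *more clumped* than random and *no more dispersed* than
Brownian. Both tails are reported so users can fold them as they prefer.
The implementation precomputes the contrast matrix of the root-ward pass
(the pass is linear in tip values), so each null costs one matrix product;
an exhaustive test checks the operator against an independent recursion on
every bifurcating topology with up to six tips and every two-state
assignment. Polytomies are rejected by the sister-clade sum (they are
accepted by the covariance and simulation code).

### Tree-size power simulation

How large a phylogeny is needed before D separates a random trait from a
Brownian-threshold one? For taxon counts 10, 25, 50 and 100 (100 replicates
per cell by default), a unit-height pure-birth (Yule) tree is simulated per
replicate — pure birth because nothing in the question involves extinction,
and unit height because D is invariant to uniform branch-length rescaling
(also verified by test). Under λ = 1 the trait is thresholded Brownian
motion at the target prevalence; under λ = 0 the same number of 1s is placed
uniformly at random. The per-size overlap of the two D distributions is
summarised with a histogram overlap coefficient (20 shared bins); the
calibration suite checks it shrinks from 10 to 100 taxa.

## Sequence divergence and structure concordance

Pairwise percent identity between two rows of one protein alignment is
computed over *shared sites* — columns where both sequences have a residue —
not alignment-wide complete columns, so a third sequence's insertions cannot
dilute a pair's identity. The CifA-vs-CifB conservation contrast collapses
identities to unordered strain pairs first (strains with multiple gene copies
contribute the mean over their copies), joins the two families on strain
pair, and applies a two-sided Wilcoxon matched-pairs signed-rank test. The
signed-rank p-value is exact for up to 25 non-zero pairs via the full
sign-flip distribution computed by dynamic programming — exactness survives
ties, which matters because identity values repeat. Each family's median
identity gets a BCa bootstrap interval. TM scores are averaged over the two
template/experiment orientations before Pearson correlation with percent
identity (p from the t transform with N − 2 df).

## The synthetic-study generator

`make_study()` emulates the statistical structure the analysis assumes, with
every generating parameter recorded for recovery testing:

* a unit-height Yule strain tree; log2 *cifB* level under λ-scaled Brownian
  motion (rate σ² = 1); CI strength linked through
  $s^* = \mathrm{logistic}(a + b \cdot \mathrm{level})$, which keeps $s^*$ in
  $[0,1]$ while leaving the association monotone;
* vials: eggs ~ Poisson(40) truncated at 1 (so the <10-egg filter exercises
  naturally), hatched ~ Binomial with p = 0.9 in compatible crosses and
  $0.9(1 - s^*)$ in the CI cross, 30 vials per cross;
* Cq triplicates ~ Normal(true Cq, 0.2 cycles) around true
  ΔCt = −log2(true FC); per-strain normal development times.

The defaults (30 vials/cross, ~40 eggs/vial, 90% compatible hatch, 0.2-cycle
Cq noise, 10 strains) are the design a well-powered single-male-pair hatch
assay in *Drosophila* produces. What the generator deliberately does *not*
emulate: male-age and rearing-density effects on CI strength, temperature,
primer-efficiency deviations from 2, qPCR outliers beyond Gaussian noise,
among-vial overdispersion beyond binomial sampling, and any sequence or
structure evolution. Passing recovery tests therefore demonstrate the
*estimators* are correct under the stated model, not that real data meet the
model.

## Reproducibility and the pipeline

All randomness is seedable. `run_all()` fans one master seed out through
stable string-hash child seeds per stage (and per strain within the
CI-strength stage), so adding a stage — or reordering strains — never
perturbs another stage's stream, and a rerun with the same config and seed is
numerically identical. Sensitivity subsets (e.g. dropping non-CI inducers or
low-density strains) are config lists of strain names validated before any
computation, never hard-coded.

## Problem sizes in the calibration suite

The test suite and acceptance script use: 500 replicate datasets of 50-taxon
trees (B = 1,000 per null) for D calibration; 500 datasets of 100-taxon trees
for slope recovery and coverage; 500 shuffled datasets (n = 100) and 200
Brownian datasets (n = 200) for λ recovery and LRT size; 1,000 synthetic
hatch datasets (30 vials/cross) for BCa coverage; 100 replicates per cell at
prevalence 0.4 for the power simulation. These sizes put Monte-Carlo error
comfortably inside each check's tolerance while keeping a full run at desk
scale.

## Known limitations

* Single-predictor PGLS only; no multi-predictor models, phylogenetic ANOVA,
  or measurement-error ("errors-in-variables") correction, although the
  response is itself an estimate.
* λ is constrained to $[0, 1]$; estimators that allow λ slightly above 1 on
  some trees will differ at that boundary.
* The D statistic requires a fully bifurcating tree; resolve polytomies
  (e.g. `ape::multi2di()`, zero-length branches) deliberately before use.
* The 2^−ΔΔCt model assumes perfect doubling per cycle; efficiency-corrected
  quantification would need standard curves the pipeline does not consume.
* P₁/P₀ tail conventions are one-tailed as described; other packages may
  report differently folded probabilities.
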