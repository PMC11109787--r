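---
title: "Clustered Mendelian randomization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered Mendelian randomization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustmr)
```

## The problem

Two-sample Mendelian randomization (MR) uses genetic variants robustly
associated with an exposure (say, adiposity) as natural randomizers to
estimate the causal effect of that exposure on an outcome (say, type 2
diabetes). A single pooled estimate, however, assumes one causal
mechanism. When the exposure can act through several biological pathways
with different — even opposite — effects on the outcome, the per-variant
causal estimates are heterogeneous in a structured way: variants acting
through the same pathway share a slope. `clustmr` recovers that structure
by clustering the per-variant estimates, then characterizes each cluster
with a suite of MR estimators and genetic-risk-score (GRS) trait
profiles.

## The model

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and
$\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) be its estimated associations with
exposure and outcome from two non-overlapping GWAS samples. The
per-variant causal estimate is the Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ with first-order
delta-method SE $\sigma_j = \sigma_{Yj} / |\hat\beta_{Xj}|$ (a
second-order form adding the exposure uncertainty is available by flag;
the first-order form is the default because instruments are selected to
be strong, where the correction is negligible).

The $\hat\theta_j$ are modelled as a mixture of normals with *known,
variant-specific* variances:

$$
\hat\theta_j \sim \pi_0\, N(0, \sigma_j^2)
  + \pi_\mathrm{junk}\, N(0, \sigma_j^2 + s_\mathrm{junk}^2)
  + \sum_{k=1}^{K} \pi_k\, N(\mu_k, \sigma_j^2).
$$

* The **null** component (mean fixed at 0, variance $\sigma_j^2$)
  represents "no causal effect through any pathway".
* The **junk** component absorbs variants with idiosyncratic
  (pleiotropic) effects that belong to no shared mechanism. Its form is
  a broad zero-mean normal with variance $\sigma_j^2 + s_\mathrm{junk}^2$;
  by default $s_\mathrm{junk}$ is twice the sample standard deviation of
  the $\hat\theta_j$, wide enough to catch outliers without competing
  with tight clusters. The scale is configurable
  (`em_fit(junk_scale = )`), since the exact junk density is a modelling
  choice, not something the mixture likelihood itself dictates.
* Each **substantive cluster** $k$ has an unknown mean $\mu_k$ — the
  causal effect of the exposure on the outcome through that mechanism —
  and no extra within-cluster variance by default. We considered a
  per-cluster variance $\tau_k^2$ and decided against enabling it by
  default: with known per-variant variances the fixed-effect cluster is
  identifiable and testable in closed form, while free $\tau_k^2$ terms
  compete with the junk component and destabilize small clusters.

Fitting is by EM. The E-step computes responsibilities
$r_{jc} \propto \pi_c f_c(\hat\theta_j)$ in log space (log-sum-exp, so a
variant far from every component never underflows to a zero density).
The M-step updates $\pi_c$ as mean responsibilities and each cluster
mean as the precision-weighted average
$\mu_k = \sum_j r_{jk}\hat\theta_j/\sigma_j^2 \,/\, \sum_j r_{jk}/\sigma_j^2$.
The log-likelihood is non-decreasing by construction; every fit records
its trace and a `monotone` flag, and the tests assert it. Convergence is
an absolute log-likelihood change below `1e-8` with a 2,000-iteration
cap; initialization takes the $K$-quantiles of $\hat\theta$, and 10
jittered restarts (configurable) keep the best final likelihood under a
fixed seed. Fitted means are reported sorted ascending, so labels are
canonical regardless of initialization order.

**Choosing $K$.** The number of mechanisms is selected by BIC over
$K = 0, \dots, K_{\max}$ with $K + (K+1)$ free parameters ($K$ means and
the free mixture proportions), ties toward smaller $K$. BIC is a design
choice: the clustering literature offers several rules, and BIC's
penalty keeps spurious micro-clusters out at the sample sizes involved
here (a couple hundred instruments).

**Assignment.** A variant is assigned to its highest-probability
component only when that probability is at least 0.8 — the conventional
80% membership rule; otherwise it stays unassigned and is excluded from
all downstream per-cluster analyses. Null and junk are reported as their
own labels, never merged with substantive clusters.

## Harmonization and proxies

All effects are aligned to the *exposure-increasing allele*: the
exposure record is flipped to a positive beta and the outcome (or trait)
record is flipped to report the same allele, complementing strands where
the labels only match by reverse complement. Palindromic pairs (A/T,
C/G) are strand-ambiguous; the default policy infers strand from allele
frequency when both frequencies are clearly away from 0.5
(`min(eaf, 1-eaf) <= 0.42`) and drops the pair otherwise. The 0.42
window is the package's own default — common two-sample MR practice —
and is configurable; the policy can also be set to drop all palindromes
or to trust the labels.

Variants missing from an outcome or trait table may be replaced by LD
proxies from a user-supplied table at $r^2 \ge 0.8$ (highest $r^2$ wins,
ties broken lexicographically, so substitution is deterministic). The
proxy table must carry an explicit allele correspondence between target
and proxy; the pipeline never infers it from LD sign, and proxy
discovery itself (reference panels, clumping) is out of scope.

## The estimator suite

Per cluster (and for the full instrument set), against each validation
outcome:

* **IVW** (main estimator): precision-weighted mean of the Wald ratios,
  identical to the zero-intercept weighted regression of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$.
  The default variance model is *multiplicative random effects* — the
  fixed-effect SE inflated by $\max(1, \sqrt{Q/(J-1)})$ — because
  residual heterogeneity within clusters cannot be excluded; the
  fixed-effect model is a flag away.
* **MR-Egger**: weighted regression with a free intercept; the intercept
  tests directional pleiotropy. Inference uses $t_{J-2}$; coefficient
  SEs are floored at the fixed-effect ones (division by
  $\min(1, \hat\sigma)$). Requires the positive-$\beta_X$ orientation
  that harmonization guarantees.
* **Weighted median**: interpolation where cumulative normalized IVW
  weights cross 0.5; SE by a seeded parametric bootstrap (1,000
  resamples of $\hat\theta_j \sim N(\hat\theta_j, \sigma_j^2)$ by
  default).
* **Simple and weighted mode**: argmax of a normal-kernel density of the
  ratios on a 512-point grid spanning the range plus three bandwidths;
  bandwidth is $\varphi \times 0.9\,\mathrm{mad}(\hat\theta)\,J^{-1/5}$
  (modified Silverman rule on the median absolute deviation,
  $\varphi = 1$ by default). If all ratios coincide, that value is
  returned with SE 0.
* **Diagnostics**: Cochran's $Q$ with $\chi^2_{J-1}$ p-value and $I^2$;
  mean instrument F, $\mathrm{mean}_j(\hat\beta_{Xj}/\sigma_{Xj})^2$.
  For binary outcomes on the log-odds scale, estimates are also reported
  as odds ratios per SD of exposure, $e^{\hat\beta}$ with normal-theory
  CIs.

## Trait profiling

Each cluster's GRS effect on a secondary trait pools the member
variants' aligned per-allele trait effects with a DerSimonian–Laird
random-effects meta-analysis:
$\tau^2 = \max\{0, (Q - (J-1)) / (\sum w - \sum w^2/\sum w)\}$, random
weights $1/(s_j^2 + \tau^2)$. DL was chosen over REML as the default
because it is closed-form and exactly testable against a step-by-step
oracle; REML (the default of the usual meta-analysis software) is
available via `dl_meta(method = "REML")` and cross-checked against
the metafor package in the tests. P-values are Benjamini–Hochberg-adjusted
*within each cluster across traits* — the multiple-testing family is the
trait panel of one cluster, never pooled across clusters. For display,
z-scores are divided by $\sqrt{n_\mathrm{variants}}$: cluster GRS
z-scores grow mechanically with cluster size, and the square-root
standardization removes exactly that growth. The transform is
display-only; inference always uses the raw z. (Other standardizations
are conceivable; this one is recorded as the package's choice.)
Cells with zero resolvable variants are flagged missing, never imputed.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the generative model the analysis assumes:
variants are partitioned into mechanism clusters (true slope
$\theta_k$), a null fraction ($\beta_Y = 0$) and a junk fraction
($\beta_Y$ an idiosyncratic pleiotropic offset, mean-zero by default,
with a directional option for Egger power studies). True exposure
effects are gamma(shape 2) magnitudes scaled to a configured mean
(default 0.05 exposure-SD per allele) and bounded below at three
exposure SEs, so simulated instruments look genome-wide-significant,
mirroring how instruments are selected in practice. Observed effects add
independent Gaussian noise with SE $1/\sqrt{2p(1-p)n}$ from allele
frequency and sample size; p-values come from the Wald z; outcome and
trait records are stored on a randomly flipped allele orientation for
half the variants so that harmonization is genuinely exercised, and a
configurable fraction of variants gets palindromic alleles. Default
sample sizes (exposure 450,000; outcome 250,000) mimic large-biobank
scale; the packaged fixture scales them to 50,000 to keep test runtimes
in seconds.

The generator deliberately omits: LD between variants (instruments are
independent by construction, as after clumping), sample overlap between
the two GWAS, allele-frequency differences between datasets, population
stratification, and winner's-curse bias in the exposure effects. Passing
recovery tests therefore show the estimators and the clustering are
correct *under the stated model*; they do not certify behavior under
correlated instruments or overlapping samples.

## Numerical choices and degenerate inputs

* Mixture densities are evaluated in log space; responsibilities come
  from log-sum-exp, never raw density ratios.
* Mixture proportions are floored at `1e-12` before renormalization so a
  component can empty without producing `log(0)` in the next E-step; a
  cluster whose effective weight vanishes keeps its last mean.
* A zero exposure beta cannot be aligned (the Wald ratio is undefined);
  such variants are dropped with reason `zero_exposure_beta`.
* All-identical ratios give a zero kernel bandwidth; the mode estimators
  return the common value with SE 0 rather than dividing by zero.
* Junk scale defaults to twice the sd of the ratios, so the whole model
  is scale-equivariant: multiplying all $(\hat\theta_j, \sigma_j)$ by
  $c$ multiplies every fitted mean by $c$ (asserted in the tests).
* Every stochastic step (restart jitter, bootstraps, simulation) derives
  its seed deterministically from one master seed; pipeline reruns are
  byte-identical.

## Problem sizes used in validation

The packaged fixture runs 200 variants (clusters at 0.4 and −0.6,
weights 0.35/0.25, null 0.3, junk 0.1), three traits and one validation
outcome at sample size 50,000 per GWAS — chosen so a full pipeline run
takes seconds while cluster separation relative to the ratio SEs
(roughly 0.05–0.3 at these sizes) matches the regime the method is meant
for. Selection-stability checks use 100 seed-varied replicates of that
fixture; calibration checks use 500 replicates of 30 instruments
(Cochran's Q against $\chi^2_{29}$) and 100 replicates of 50 instruments
(Egger intercept type-I error under balanced pleiotropy, sd 0.02).
BIC selection, mean recovery and assignment accuracy under these
conditions are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The junk density, the BIC selection rule and the absence of
  within-cluster variance are documented modelling choices; other
  clustered-MR implementations make different ones, and results can
  differ near the identifiability boundary (junk variants whose ratio
  happens to coincide with a cluster slope are indistinguishable from
  cluster members by any method).
* First-order Wald SEs understate uncertainty for weak instruments;
  keep instruments at F ≳ 10 (the generator enforces this regime) or
  switch to second-order SEs.
* The pipeline consumes a proxy table; it cannot discover proxies, lift
  over positions, or resolve rsIDs.
* Trait tables are assumed to be on the same strand convention as the
  exposure table up to explicit complement matches; palindromic trait
  records are aligned by label.

## A minimal run

```{r, eval = FALSE}
cfg <- read_pipeline_config(
  system.file("extdata", "fixture_config.yaml", package = "clustmr"),
  seed = 7)
report <- run_pipeline(cfg, out_dir = "clustmr_out")
print(report)
render_report(report, "clustmr_out/figures")
```
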