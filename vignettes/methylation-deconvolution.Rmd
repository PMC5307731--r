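---
title: "Reference-based deconvolution of DNA methylation profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based deconvolution of DNA methylation profiles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdeconv)
```

## The problem

Bulk DNA methylation profiles of complex tissues such as whole blood are
averages over many cell types. Because cell-type composition shifts with age,
disease and exposures, an epigenome-wide association study (EWAS) that
ignores composition will attribute composition changes to individual CpGs.
`methdeconv` estimates the cellular composition of each sample from its
methylation profile and a reference database of purified cell-type profiles,
and feeds those estimates back into the association model as covariates.

## The mixture model

Let $y$ be the beta-value profile of a sample over a set of CpGs (each beta
value is the methylated fraction at a CpG, in $[0,1]$) and let
$b_1, \dots, b_C$ be reference profiles of the $C$ constituent cell types
over the same CpGs. The model is the linear mixture

$$ y = \sum_{c=1}^{C} w_c\, b_c + \varepsilon, \qquad
   w_c \ge 0, \quad \sum_c w_c \le 1, $$

with no intercept: a tissue that is fully described by the reference has
weights summing to one, and the inequality leaves room for unmodelled cell
types. Mixing is linear on the beta scale because cell populations contribute
methylated alleles in proportion to their abundance.

Four estimators of $w$ are provided, differing in how the simplex constraint
enters:

* **LR** — ordinary least squares; constraints applied afterwards.
* **RPC** — robust partial correlations: a Huber M-estimator fitted by
  iteratively reweighted least squares, constraints afterwards. This is the
  package's default, and the most reliable method at realistic noise levels.
* **SVR** — linear-kernel $\nu$-support-vector regression, constraints
  afterwards; the CIBERSORT-style procedure, fitted for
  $\nu \in \{0.25, 0.5, 0.75\}$ with the minimum-RMSE fit retained.
* **CP** — constrained projection: the least-squares problem solved by
  quadratic programming with $w \ge 0$ and $\sum_c w_c \le 1$ imposed
  *during* optimisation (the classical reference-based approach).

The a-posteriori constraint (`project_to_simplex()`) zeroes negative raw
weights and rescales the remaining positive ones to sum to one. If no weight
is positive the row is returned as all zeros and flagged — a sign the
reference does not describe the sample at all.

### Numerical choices

* The Huber tuning constant defaults to $c = 1.345$ (95% efficiency at the
  Gaussian model, the conventional choice in robust regression). The residual
  scale is re-estimated each iteration as $\mathrm{median}(|r|)/0.6745$;
  iteration stops when no coefficient moves by more than `rpc_tol` ($10^{-6}$)
  or after 50 iterations. A zero median absolute residual (an exact fit)
  stops iteration immediately.
* SVR is fitted unstandardised on the beta scale, so the primal coefficients
  are directly interpretable as cell-type weights; the intercept (offset) is
  not part of the reported weights. This deviates from CIBERSORT's z-scoring,
  deliberately: z-scoring destroys the fractional interpretation of the
  coefficients, and the simplex projection applied afterwards assumes it.
* The CP quadratic program is solved with an active-set solver
  (`pracma::quadprog`). The feasible set contains the origin, so the program
  is always feasible; solutions are clipped at zero only to absorb round-off.
* Estimation is per sample, so results do not depend on sample order, and
  permuting reference columns permutes the output identically.

## Building the reference database

The reference is constructed from purified-cell profiles in two modes:

* **`fdr` mode** (replicates available): each cell type is compared against
  all remaining samples pooled, per CpG, with an empirical-Bayes moderated
  t-statistic. The per-CpG pooled variance $s^2$ (on $d$ residual df) is
  shrunk towards a prior $(d_0, s_0^2)$ estimated by moment matching on log
  variances across CpGs, giving $\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0+d)$
  and $d_0 + d$ degrees of freedom. CpGs significant at FDR < 0.05
  (Benjamini–Hochberg) are retained.
* **`pairwise` mode** (single profiles): for every pair of cell types, CpGs
  whose absolute beta difference exceeds 0.9 are retained. This extremely
  stringent rule is what single-replicate data supports.

Optionally, candidate CpGs are restricted to those falling in a DNase
hypersensitive site (DHS) of *any* of the cell types under consideration
(the union rule): DHSs are highly cell-type specific open-chromatin regions,
so this injects prior biological knowledge about where genuine cell-type
differences live. Omitting the DHS inputs reproduces the unrestricted
("non-DHS") database through the identical code path.

Surviving CpGs are ranked by absolute mean beta difference — the quantity
that matters for the conditioning of the regression — and the top 50 per
cell type are kept. Ties are broken lexicographically by CpG identifier so
builds are deterministic. The final reference holds, for each cell type, the
arithmetic mean over its replicates at the union of all picks. Two open
choices are resolved as follows: ranking uses the *absolute* mean difference
(hypo- and hypermethylated markers are equally useful), and the one-vs-rest
mean difference is the ranking statistic in `fdr` mode.

Coordinate conventions: BED intervals are 0-based half-open, CpG positions
1-based; a CpG at position $p$ overlaps $[s, e)$ iff $s \le p - 1 < e$.
Strand is ignored (DHS are strand-symmetric). Rows with missing values are
dropped at load time with a logged count, because all downstream algebra
assumes complete matrices.

## Beta and M scales, and the noise model

The M-value is the log2 odds of methylation, $M = \log_2(\beta/(1-\beta))$;
betas are clipped into $[\epsilon, 1-\epsilon]$ with $\epsilon = 10^{-6}$
before the transform so boundary values stay finite. Measurement noise is
modelled as additive Gaussian on the M scale — the variance-stabilised scale
on which array noise is approximately homoscedastic — and transformed back.
A unit M-shift changes a beta value $b$ by exactly $b(1-b)/(1+b)$: about 5
percentage points for an unmethylated CpG ($b = 0.05$) and about 16–17
points for a partially methylated one ($b = 0.4$), so `sd = 1` is a
realistic array-level noise scenario. Two strongly discriminative cell-type
states ($\beta$ 0.1 vs 0.9) are about 6 M-units apart, so `sd = 6` noise is
comparable to the biological signal itself and represents an extreme regime.

## The synthetic-data generator

Real purified-cell resources cannot ship with the package, so
`synth_purified_dataset()` generates data with the statistical structure the
methods assume. Its defaults mirror the canonical whole-blood design: 7 cell
types with 6 replicates each; 50 planted cell-type-specific DMCs per type
with beta differences drawn from 0.5–0.9 (strong marker CpGs, as favoured by
the top-$k$ ranking); a background of mostly bimodal CpGs (methylation is
predominantly near 0 or 1); replicate noise of SD 0.3 on the M scale and an
independent test study with a per-CpG lab shift of SD 0.3 shared across its
replicates (typical between-study variation for methylation arrays); and a
synthetic genome in which DHS intervals cover a cell type's own planted DMCs
with probability 0.8 against a background rate of 0.1. Mixture weights are
$C$ independent Uniform(0,1) draws normalised to sum to one — deliberately
the normalised-uniform construction, not a flat Dirichlet. Test-set mixtures
are built from the test study's per-cell-type mean profiles.

What this emulates: cell-type-specific differential methylation, replicate
and between-lab noise on the correct scale, DHS enrichment at true marker
CpGs, and train/test independence. What it does not emulate: Illumina
probe-type chemistry and its type-2 bias, probe cross-hybridisation,
genome-scale correlation structure, or realistic genomic clustering of DMCs.
Passing tests therefore demonstrate correctness of the algorithms under the
model's assumptions, not performance on any particular array product.

## Benchmarking and comparison

`run_benchmark()` reproduces the standard in-silico evaluation design: per
Monte-Carlo run, 100 fresh simplex-weight mixtures are built from held-out
profiles, Gaussian M-scale noise at SD 0–6 is added, and every method is
applied to the identical noisy matrix; per-cell-type RMSE and $R^2$
(squared Pearson correlation; defined 0 for a constant estimate so averages
stay computable) are averaged over cell types, and the whole procedure is
repeated for 25 runs. Method pairs are compared on run-level average scores
with a one-tailed paired Wilcoxon *signed-rank* test (the paired form of the
rank test), exact when there are no ties, with zero differences dropped.

At the package's own desk scale (7 cell types, a ~330-CpG reference built on
the training study, mixtures from the test study), robust regression attains
a mean RMSE of about 0.02 at SD = 1 and is at least as accurate as
constrained projection in most paired runs at that noise level, while the
constrained method closes the gap and overtakes it as noise grows — the
characteristic low-noise/high-noise crossover of constrained versus
unconstrained inference. Error increases monotonically with noise for every
method. The heavier grid reported by the tests and the acceptance script
uses 100 mixtures × 25 runs at SD = 1 and 50 mixtures × 5 runs across the
full SD 0–6 sweep; these sizes are the package's chosen desk-scale design.

## Composition-adjusted association scans

`fit_ewas()` fits, per CpG, ordinary least squares of beta on a numeric
(ordinal) phenotype plus optional technical covariates and, when supplied,
the estimated cell fractions. Because estimated fractions sum to one, one
cell type must be dropped when an intercept is present; by default the cell
type with the smallest mean fraction goes (in whole blood that is typically
a population whose weights are effectively zero). P-values are two-sided
t-tests of the phenotype coefficient; multiplicity is handled by plain
Benjamini–Hochberg across all tested CpGs, with no genomic-control
inflation adjustment. `score_calls()` evaluates a call set against curated
true-positive and true-negative CpG lists, reporting sensitivity,
specificity and the empirical FDR (fraction of calls that are known true
negatives).

The confounding mechanism this guards against is generated explicitly by
`synth_ewas_dataset()`: when a phenotype shifts one cell type's abundance,
every marker CpG of that cell type becomes spuriously phenotype-associated
in an unadjusted scan; including estimated fractions as covariates removes
those calls while leaving directly planted effects detectable.

## Known limitations

* The reference must contain the major cell types actually present;
  weights of missing cell types are absorbed by the modelled ones (the
  inequality constraint mitigates but does not solve this).
* Exact numerical parity with any particular published implementation of
  robust or support-vector regression is not claimed; the contracts are the
  limit behaviours (e.g. RPC equals LR when no residual is flagged) and the
  oracle agreements verified in the test suite.
* The moderated-t prior is estimated by the standard moments method; with
  very few CpGs the prior is noisy and the code falls back to the ordinary
  t-test if estimation fails.
* Normalisation of raw array data (probe-type correction, background
  subtraction) is out of scope; inputs are assumed to be cleaned beta
  matrices.
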