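---
title: "Projection scoring of cell-type identity: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection scoring of cell-type identity: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapscore)
```

## The problem and the model

Given a query transcriptome (for example, an in vitro derived lung
progenitor population) and a labeled reference basis of K in vivo cell-type
expression profiles, we want one number per reference type measuring how
much of that type's expression program the query carries. Correlating the
query against each reference column separately does not work well: real
cell types share most of their transcriptome, so a query resembling one
type automatically correlates with all of its relatives.

The projection model resolves this by treating the K reference profiles as
the columns of a gene × K matrix $B$ and expressing the query $q$ in the
*coordinates of the basis*: the scores are the least-squares solution
$s = P q$ with $P = (B^\top B)^{-1} B^\top$, the Moore–Penrose
pseudoinverse. Since $P B = I_K$, each reference type scores exactly 1 with
itself and exactly 0 with every other type, however correlated the columns
are — the Gram matrix inverse is precisely what subtracts the shared
signal. Geometrically, $B s$ is the orthogonal projection of $q$ onto the
span of the basis, and the residual $q - Bs$ is orthogonal to every
reference column. Both facts are enforced as test invariants.

The dual-coordinate reading of "projection score" is the unique linear
score satisfying the self = 1 / cross = 0 contract; alternatives (e.g.
cosines against orthogonalized references) would rescale the scores
type-by-type and break the interpretation of a score as a mixture
coordinate, which the recovery tests rely on.

## Cross-platform rank-quantile normalization

Reference bases mix microarray intensities with RNA-Seq counts. Absolute
values are not comparable across those platforms, but ranks are. Each
sample is normalized independently:

1. genes are ranked ascending, ties receiving average (fractional) ranks —
   the standard convention, which keeps the percentile grid symmetric;
2. rank $r$ becomes percentile $r / (N + 1)$ for $N$ genes, so percentiles
   stay strictly inside $(0, 1)$;
3. percentiles map through the standard-normal quantile function
   $\Phi^{-1}$;
4. the sample vector is rescaled so its **squared** Euclidean norm equals
   $N$ exactly.

Step 4 deserves a note. The convention we adopt is squared norm $= N$: the
quantile grid already has per-gene variance close to 1, so the squared norm
is close to $N$ by construction and the rescale merely makes it exact,
giving every sample an identical length in z-space. Reading the convention
as unsquared norm $= N$ would inflate every sample by a factor
$\sqrt{N}$ and make the self-projection contract fail by that factor, so
the squared-norm reading is the one consistent with scores of order 1.

Because only ranks enter, the output is invariant to any strictly
increasing per-sample transform (log, scaling, exponentiation) — the
property the cross-platform claim rests on — and normalization is
idempotent in rank space. A constant sample has no usable ranks and is
rejected.

**High-expression filter.** After pooling all reference columns on the
common gene universe, only genes with z > 1 in at least one reference type
are kept (strict inequality). The retained z-scores are *not* recomputed on
the reduced universe: the filter selects informative genes for the
projection geometry, and re-ranking on the survivors would distort the
profiles that justified their selection in the first place. A consequence,
recorded deliberately: post-filter columns have squared norm slightly below
the pre-filter $N$, which the basis object tracks by storing both the
normalization universe size `n` and the retained gene count.

**Query normalization.** Queries are rank-normalized on the basis gene
universe, since the projection geometry assumes a shared universe. Queries
measuring fewer than 95% of basis genes are rejected; a missing tail of up
to 5% is tolerated with the absent genes set to the rank-neutral z = 0 and
a warning, a pragmatic compromise between refusing usable data and
silently projecting on the wrong universe.

## Null calibration

Projection scores come with no analytic p-value. Significance is instead
calibrated against random profiles: R vectors of iid standard-normal
entries, rescaled to squared norm $N$ so they are distribution-matched to
rank-normalized samples (fresh Gaussian draws, not permutations of real
samples — the null should model *random expression*, not a shuffled real
cell). Their scores have mean 0 by symmetry; the pooled standard deviation
over all $R \times K$ scores sets the threshold at `multiplier` (default 5)
standard deviations, exceeded *strictly* in magnitude for a significance
call. The SD is pooled rather than per-type because the null is a single
global yardstick; per-type SDs differ only through basis conditioning and
would turn one interpretable threshold into K.

On an exactly orthogonal basis the null SD is analytically
$1/\sqrt{N}$ (each coordinate of a random direction scaled to length
$\sqrt N$), and it scales as $N^{-1/2}$; both are test targets. On
realistic, correlated bases the SD is *larger* — collinearity inflates the
dual coordinates — which is why a basis of 91 strongly related in vivo cell
types on ~9000 genes can plausibly show an SD of 0.04, four times the
orthogonal value of $1/\sqrt{9035} \approx 0.0105$. Defaults: R = 10000
(SD estimated to about 1% relative error), seed 0, multiplier 5.

## The gene-set route

An independent check on projection scores, sharing no machinery with them.

**Preprocessing** (RNA-Seq counts): per-sample counts-per-million, then
$\log_2(\mathrm{CPM} + 0.5)$ — the prior count of 0.5 avoids log of zero,
and adding it *after* the per-million scaling keeps the transform exactly
invariant to library-size scaling; genes whose summed log-scale expression
across samples is below 2 are dropped (applied before centering — after
centering every gene would sum to about 0 and the filter would be
vacuous); genes are centered at 0; finally each sample is winsorized to
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ with quartiles by
linear interpolation, taming heavy-tailed outliers. The variance pool for
signatures is computed after this full chain, so outliers cannot buy a
gene into the pool.

**Signatures**: the 3000 highest-variance genes across all samples form
the pool (biological signal); per condition, the 100 most expressed pool
genes (mean over that condition's samples) form its signature. Both
rankings break ties lexicographically by gene id, making construction
bit-reproducible.

**Enrichment score**: genes are ranked by a sample's value, descending
(ties again lexicographic). Walking down the ranking, the weighted ECDF of
signature genes (weight $|v|^\tau$, $\tau = 1$) and the unweighted ECDF of
the remaining genes are accumulated, and the score is the sum of their
differences over all rank positions — the running-sum *integral* variant,
not the maximum-deviation (Kolmogorov–Smirnov) one: the integral uses the
whole ranking and is smoother on small signatures. $\tau = 1$ weights each
signature gene by the magnitude of its (centered) expression, the default
of the single-sample enrichment lineage this score belongs to.

## The synthetic-data generator

The generator replaces the original study data with instruments whose
truth is known, and its defaults are fixed study conditions, not tuning
dials.

* `simulate_reference`: K latent profiles from an equicorrelated Gaussian
  factor model (pairwise correlation `rho`), a shared gene-level baseline
  (real cell types share most expression, so readout profiles are more
  correlated than the latent ones), read out as lognormal intensities for
  half the types and negative-binomial counts (dispersion 0.2) for the
  other half, each platform with ~5% private genes so basis assembly must
  exercise the gene-intersection step.
* `simulate_query_mixture`: $q = Bw + \varepsilon$ in z-space (exact
  recovery: $Pq = w + P\varepsilon$, unbiased), plus the same profile
  pushed through a monotone lognormal readout so the full
  re-normalization path is tested end to end. The default dominant weight
  used in end-to-end recovery is 0.7 with the remainder spread evenly — a
  differentiated population carrying a clear majority identity plus
  background lineages.
* `simulate_single_cell`: per-cluster lognormal latent profiles, per-cell
  negative-binomial counts with a lognormal library-size factor, and
  uniform random dropout; cluster labels are returned as ground truth
  (clustering itself is consumed, not computed, matching the pipeline's
  contract).

What the generator does **not** emulate: batch effects, ambient RNA and
doublets in single-cell data, gene-length biases, platform-specific probe
saturation. Passing tests therefore certify the algebra, the normalization
contracts and the recovery behaviour under idealized noise — not
robustness to every artifact of real data.

## Numerical choices

* Inverse-normal quantiles via `qnorm` (absolute accuracy well below
  1e-9, the tolerance the worked normalization example is checked at).
* Pseudoinverse via SVD with a relative singular-value cutoff of 1e-10;
  below it the basis is declared rank-deficient and the error names the
  most collinear type pair (largest pairwise cosine) so the user knows
  what to drop. The Gram condition number is stored on every basis.
* Per-sample squared norm enforced to relative 1e-9; the dual identity
  $PB = I$ verified to 1e-8 max absolute deviation.
* Strict inequalities at both decision boundaries (z > 1 filter,
  |score| > threshold).
* Quartiles by linear interpolation (type 7), the R default.
* Cell-type label collisions across source data sets are suffixed with
  the data-set name.

## Problem sizes used by the test suite

The suite works at desk scale, chosen so the full run completes in well
under a minute while keeping Monte-Carlo error far from the asserted
tolerances: identity and oracle checks at K ≤ 10, G ≤ 500; null
calibrations at R = 10000 on bases up to G = 4000; mixture-recovery and
end-to-end dominance checks at K = 8, G = 3000 with 200 queries at noise
SD 0.2. The reference data set scale (91 types, ~11,000 common genes,
~9000 post-filter) is not reproduced: those numbers depend on the original
archived data, and the package's claims are the structural ones — the
identity contract, the null behaviour, and recovery of known truth.

## Known limitations

* Scores are least-squares coordinates: they need not lie in [0, 1], do
  not sum to 1, and are not a formal deconvolution; negative scores mean
  anti-correlated patterns, not negative abundance.
* An ill-conditioned basis (near-duplicate reference types) inflates both
  scores and the null SD; the stored condition number should be inspected
  when adding closely related types.
* The null calibrates against random profiles only; it does not control
  error rates across K types or across many queries (no multiplicity
  correction, by design).
* Gene matching is exact symbol equality — upstream identifier
  harmonization is the user's responsibility.
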