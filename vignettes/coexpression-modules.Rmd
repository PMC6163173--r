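---
title: "Co-expression network modules with coexpnet: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression network modules with coexpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpnet)
```

## The model

coexpnet implements the weighted gene co-expression analysis workflow for a
positive-valued (MAS5-like) expression compendium, genes in rows and samples
in columns. The chain of transformations is:

1. **Correlation.** Pairwise Pearson correlation between gene profiles,
   by default on the `log2` scale. MAS5-scale intensities are heavily
   right-skewed, so the log scale is the better substrate for a linear
   association measure; `log_transform = FALSE` is available for data that
   are already symmetric (the eigengene meta-network uses it).
2. **Signed adjacency.** $a_{ij} = ((1 + \mathrm{cor}_{ij})/2)^\beta$.
   Anti-correlated genes get weight near 0, uncorrelated genes
   $0.5^\beta$, co-regulated genes weight near 1. The soft-threshold
   power $\beta$ suppresses weak edges without a hard cutoff and is chosen
   by the scale-free topology criterion: the smallest candidate power whose
   connectivity distribution fits a power law with signed
   $R^2 \ge 0.8$ (`pick_soft_threshold()`). On compendium-scale real data
   this criterion typically selects a power around 14; on planted-block
   synthetic data, which is deliberately *not* scale-free, no candidate
   reaches the cutoff and the documented argmax fallback fires with a
   warning flag.
3. **Topological overlap.**
   $\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
   with $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$ and connectivity
   $k_i = \sum_{j \ne i} a_{ij}$. TOM credits shared neighborhoods as well
   as the direct edge, which makes module boundaries much crisper than raw
   correlation.
4. **Clustering and cutting.** Average-linkage (UPGMA) clustering of
   $1 - \mathrm{TOM}$, then the dynamic tree cut variant described below.
5. **Eigengenes.** Each module is summarized by the first right singular
   vector of its standardized (zero mean, unit variance per gene)
   expression submatrix — the module's first principal component over
   samples — with the sign flipped to correlate non-negatively with the
   module's mean profile, and `variance_explained`
   $= d_1^2 / \sum_r d_r^2$.

Downstream, modules are profiled by within-module connectivity and hub
genes, half-sample connectivity stability, expression relative standard
deviation (RSD), condition association, an eigengene meta-network
(the same pipeline applied to eigengenes at power 3 with minimum module
size 2), and log-space hypergeometric enrichment statistics.

## The dynamic tree cut variant

The exact reference tree-cut algorithm is not re-implemented here; the
package defines its own deterministic variant and validates it by
planted-module recovery rather than by equivalence with any external
implementation:

1. a static cut at `cut_height_fraction` (default 0.995) times the top
   merge height yields candidate branches;
2. branches with at least `min_module_size` (default 30) leaves become
   modules; everything else is `"grey"`;
3. with `deep_split` > 0 (default 2), a module splits at its top merge
   when both children hold `min_module_size` leaves *and* the merge height
   exceeds each child's internal maximum by `gap_threshold` (default
   0.05), recursively up to `deep_split` levels;
4. **membership shedding** (`shed_low_membership()`): each assigned gene's
   correlation with its module eigengene (kME) is computed once, and genes
   below `kme_threshold` (default 0.5) are returned to grey; modules
   falling below the minimum size dissolve.

Step 4 exists because steps 1–3, like any pure height cut, cannot tell a
branch's core from weakly attached stragglers: on planted-module benchmark
data, a few dozen background genes join each module branch just below the
cutoff and cap the adjusted Rand index near 0.6 even though the planted
modules themselves are perfectly separated. A kME filter is the standard
practice for this in the field's workflows. The threshold 0.5 sits midway
between the membership of genuine module genes at the benchmark
signal-to-noise ratio (kME about 0.9) and the chance correlations of
background genes (|kME| about 0.1); with it, recovery on the benchmark is
exact. The filter is one-pass — eigengenes are not recomputed after
shedding — and is intentionally *not* a PAM-style reassignment: genes are
only ever demoted to grey, never moved between modules.

Module labels are color-style names assigned by decreasing module size
(ties by smallest leaf index), with `"grey"` reserved for unassigned genes
and excluded from every per-module statistic.

## What the synthetic generator emulates — and what it does not

`generate_expression()` draws from a latent-factor block model: module $m$
has a factor $f_m \sim N(0, 1)$ per sample (centered per module), and
member gene $g$ has expression
$x_{gs} = \exp(\mu_g + \beta_g f_m(s) + \varepsilon_{gs})$ with
$\varepsilon \sim N(0, \sigma)$; background genes are baseline plus noise.
The factor model was chosen over a copula or explicit covariance
construction because the module eigengene then has a known ground truth —
the factor itself — enabling parameter-recovery tests
(|cor(eigengene, factor)| is asserted, not just cluster agreement).

Defaults, with rationale:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 120 | enough for stable correlations at desk scale |
| `module_sizes` | 40–120 | the benchmark module-size range |
| `n_background` | 200 | unstructured genes to challenge the cut |
| `factor_strength` | 0.9 | with `noise_sd = 0.3`, signal-to-noise 3: comfortable but not trivial detection |
| `noise_sd` | 0.3 | natural-log residual spread |
| `loading_jitter` | 0.3 | $\beta_g = 0.9 \cdot U(0.7, 1.3)$; see below |
| baseline $\mu_g$ | log-uniform on [log 50, log 5000] | mimics MAS5 intensity spread |

`loading_jitter` deserves a note. With identical loadings every module gene
is statistically interchangeable, within-module connectivity is a constant
vector plus sampling noise, and both connectivity-stability and hub-gene
statistics become meaningless (their values correlate with nothing).
Real modules have internal hub structure, so the generator's default gives
loadings a modest spread while keeping their mean at `factor_strength`.
All correlation-level properties (noise-free correlation 1 within modules,
monotone decay with noise) are unaffected.

The generator does **not** emulate probe-level data, MAS5 summarization
itself, batch structure across GEO series, heteroskedastic array noise, or
realistic gene-gene correlation beyond the block factors. A green
recovery test therefore establishes that the pipeline's machinery is
correct on data satisfying its assumptions — not that it would recover the
published module catalog from the real compendium, which would require the
2,101-array download that is out of scope here.

Matched annotations: `generate_gene_sets()` emits each planted module as a
"true" gene set plus size-matched random decoys (a stand-in for GO-style
collections); `generate_positions()` places a configurable fraction of each
module's genes in one contiguous chromosomal run (gene ranks map to
disjoint intervals), so positional enrichment has a planted positive and a
uniform-scatter null.

## Statistics and conventions

**Hypergeometric tails are computed in log space** (`hypergeom_log_tail()`),
via log-gamma binomial terms and log-sum-exp: the headline overlap
statistics this machinery must reproduce sit near $10^{-300}$, beyond what
naive tail summation survives. The *at-least* convention $P(X \ge k)$ is
used everywhere: the p-value of an observed overlap counts outcomes at
least as extreme, including the observation. A numerical note: for the
published 518/912/1421/14068 cuticle-module overlap, the exact at-least
tail is $5.261 \times 10^{-302}$, a whisker *above* the printed bound of
$5 \times 10^{-302}$ (which the strictly-greater tail,
$\approx 3 \times 10^{-303}$, does satisfy). The package reports the
at-least value; the corresponding acceptance assertion is deliberately
left failing rather than silently switching conventions, since the two
agree at the printed one-significant-digit precision.

**Benjamini–Hochberg** (`bh_adjust()`) is the step-up rule implemented
directly: sort ascending, $p_{(i)} m / i$, enforce monotonicity from the
top, cap at 1, restore order. "Benjamini method" is interpreted as BH FDR
(the common default of annotation servers); the EASE-style modified
Fisher variant is documented as out of scope — plain hypergeometric tails
are reported.

**Positional enrichment** slides windows of 50 consecutive genes
(gene-rank coordinates, step 25) along each chromosome plus a
whole-chromosome test, with background = all positioned genes; overlapping
windows below the threshold (default $7 \times 10^{-7}$) merge into
regions. Window and step sizes are this package's choice — the web tool
they stand in for does not document its windows.

**Stability resampling** draws $\lfloor n/2 \rfloor$ samples without
replacement (1000 times by default), recomputes within-module connectivity
per module, and correlates it with the full-data connectivity.
"Per module" means adjacency among the module's genes only, not a global
network restricted afterwards — the resampling protocol is explicitly run
for every module, and reported values are per-module. Conventions for
degenerate cases: two (near-)constant connectivity vectors (relative
spread below $10^{-8}$, e.g. noise-free data) correlate at 1 by
definition — the pattern is exactly preserved, and Pearson on
floating-point dust would otherwise return noise; one constant vector
gives 0; modules under 3 genes are flagged and skipped.

**RSD** is sample SD over mean on the positive scale (log-scale input is
rejected, since RSD of logs is mean-shift sensitive); module RSD is the
unweighted mean over member genes.

**Welch's t-test** (`connectivity_group_test()`) compares connectivity
between module groups without an equal-variance assumption (the variance
assumption is otherwise unstated in this setting); both-groups-constant
input returns $t = 0, p = 1$ on equal means by convention.

**Meta-network.** Eigengenes are treated as genes and pushed through the
*same* correlation → signed adjacency (power 3) → TOM → UPGMA → tree-cut
code path, with `min_module_size = 2` and no log transform (eigengenes are
centered, signed quantities). Top edges are ranked by adjacency (not TOM)
— the choice is a package convention, deterministic ties by label pair.

## Determinism

Every stochastic step is seeded. The pipeline derives stage seeds
deterministically from one root seed, and reruns are byte-identical
(asserted on MD5 checksums of every output table in the test suite).
UPGMA ties break by smallest cluster index (the `hclust` convention);
sub-epsilon height inversions from tied merges are repaired by a running
maximum before cutting, while genuine non-monotonicity still errors.

## Known limitations

- Only signed networks with Pearson correlation: no unsigned or "signed
  hybrid" variants, no biweight midcorrelation or Spearman option.
- Dense matrices throughout; intended scale is up to ~5,000 genes.
- No module merging by eigengene similarity, no PAM reassignment of grey
  genes, no multi-dataset consensus or preservation statistics.
- Enrichment is set-based only: no GO-graph propagation, no live
  annotation-service queries.
- The scale-free fit uses 10 equal-width connectivity bins; binning is a
  convention, and very skewed connectivity distributions may deserve
  log-spaced bins.
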