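# coexpnet

Weighted gene co-expression network module analysis for positive-valued
expression compendia (MAS5-style microarray intensities), written for
transcriptomics researchers who want the full module workflow — network,
modules, eigengenes, stability, meta-network, enrichment — as plain,
testable R with no external services.

## What it computes

Given a genes × samples expression matrix, coexpnet builds a **signed
weighted network**

&nbsp;&nbsp;&nbsp;&nbsp;*a<sub>ij</sub> = ((1 + cor<sub>ij</sub>)/2)<sup>β</sup>*

with β chosen by the scale-free topology criterion, converts it to
**topological overlap**

&nbsp;&nbsp;&nbsp;&nbsp;*TOM<sub>ij</sub> = (ℓ<sub>ij</sub> + a<sub>ij</sub>) / (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>)*,&nbsp;&nbsp;
*ℓ<sub>ij</sub> = Σ<sub>u≠i,j</sub> a<sub>iu</sub>a<sub>uj</sub>*,

clusters genes by average linkage on 1 − TOM, cuts the dendrogram with a
documented dynamic tree cut variant (static cut + gap-based deep split +
eigengene-membership shedding; unassigned genes are `"grey"`), and
summarizes each module by its **eigengene** (first principal component of
the standardized module submatrix). Modules are then profiled by:

- within-module connectivity *k<sub>i</sub> = Σ<sub>j≠i</sub> a<sub>ij</sub>* and hub genes,
- **half-sample stability**: correlation of module connectivity between the
  full data and (by default) 1000 random half-samples,
- expression **relative standard deviation** (sd/mean) per gene and module,
- module–condition association via mean eigengene per condition,
- a higher-order **eigengene meta-network** (same pipeline at power 3,
  minimum module size 2) with meta-modules, module global connectivity,
  and top-edge export,
- **log-space hypergeometric enrichment**: gene-set over-representation
  with Benjamini–Hochberg adjustment, sliding-window positional
  (chromosome-region) enrichment, and set-overlap tests that stay exact
  far below the double-precision underflow limit (p ≈ 10⁻³⁰⁰).

A planted-module synthetic generator (latent-factor block model with
matched GMT gene sets and BED positions) makes every stage testable end to
end, and a packaged catalog of 48 annotated *C. elegans* co-expression
modules supports annotation counting queries. Formats: TSV, GMT, BED —
all round-trip through the package's own readers.

## Worked example

Five planted modules (40–120 genes), 200 background genes, 120 samples,
signal-to-noise 3 — then the full detection chain:

```r
library(coexpnet)

cfg <- synthetic_config(n_samples = 120, module_sizes = c(40, 60, 80, 100, 120),
                        n_background = 200, factor_strength = 0.9,
                        noise_sd = 0.3, seed = 7)
sim  <- generate_expression(cfg)
cc   <- correlation_matrix(sim$expr)              # log2 scale by default
tom  <- topological_overlap(signed_adjacency(cc, 12))
part <- cut_modules(coexp_dendrogram(tom_dissimilarity(tom)))
part <- shed_low_membership(sim$expr, part)
table(part)
#> part
#>      blue     brown     green      grey turquoise    yellow
#>       100        80        40       200       120        60

truth <- sim$truth$partition
a <- part != "grey"
adjusted_rand_index(part[a], truth[names(part)[a]])
#> [1] 1
```

All five planted modules are recovered exactly; the 200 grey genes are
precisely the unstructured background. The eigengenes explain ~89% of
module variance and correlate with the planted factors at |r| > 0.99:

```r
eig <- module_eigengenes(sim$expr, part)
round(eig$variance_explained, 3)
#> turquoise      blue     brown    yellow     green
#>     0.890     0.876     0.906     0.895     0.900

st <- stability_resampling(sim$expr, part, beta = 12,
                           stability_params(n_iterations = 200, seed = 11))
as.data.frame(st)[, 1:4]
#>      module n_genes mean_correlation sd_correlation
#> 1 turquoise     120            0.930        0.01040
#> 2      blue     100            0.941        0.00934
#> 3     brown      80            0.924        0.01521
#> 4    yellow      60            0.922        0.01501
#> 5     green      40            0.929        0.01758
```

Every module's connectivity pattern survives half-sampling at mean
correlation > 0.9 — the behavior expected of robust modules. Finally, the
log-space overlap statistic on a published cuticle-module comparison
(518 shared genes between a 912- and a 1,421-gene set on a 14,068-gene
background):

```r
ov <- overlap_from_counts(N = 14068, n_a = 912, n_b = 1421, k = 518)
ov$log10_p        # -301.2789  (p ~ 5.26e-302)
ov$fraction_of_a  # 0.568      (about 57% of the 912-gene set shared)
```

The whole pipeline, driven by one config with one root seed and fully
deterministic outputs:

```r
run_pipeline(demo_config("demo_out", seed = 3))   # ~1 s, 20 output files
```

or from the command line:

```sh
Rscript inst/cli/coexpnet.R run --config config.json --out demo_out --seed 3
```

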