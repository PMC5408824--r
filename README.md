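# leanet — local enrichment analysis of gene interaction networks

`leanet` finds *local subnetworks* — a center gene together with its direct
interaction partners — whose member genes are jointly enriched for low
P-values. It is aimed at anyone with a genome-wide score table (differential
expression, GWAS, proteomics, ...) and an interaction network (STRING-style
edge lists, SIF, plain TSV) who wants calibrated, exhaustively computed
per-gene subnetwork significance instead of heuristic module search: the
method is exact, parameter-free and fast, and every hit names one center
gene to follow up.

## The statistic

For a center gene *g* with neighborhood P-values sorted as
*p*₍₁₎ ≤ … ≤ *p*₍ₘ₎, each prefix length *k* is scored with the binomial
tail

> p̃(k) = Σᵢ₌ₖᵐ C(m, i) · p₍ₖ₎ⁱ · (1 − p₍ₖ₎)^(m−i),

the probability under the null (i.i.d. uniform P-values) that at least *k*
of the *m* neighborhood values fall at or below *p*₍ₖ₎. The enrichment score
is

> ES_g = −log₁₀ min₍ₖ₎ p̃(k).

Because ES grows with *m*, it is calibrated against an empirical null: ES
values of random same-size gene sets drawn from the pooled input P-values
(10 000 samples per size by default), giving

> p\*_g = Pr(ES_BG ≥ ES_g), estimated as (r + 1)/(n + 1).

The p\* of all candidate centers are Benjamini–Hochberg corrected ("LEAN
P-values"). The package also ships the simulation harness used to benchmark
the method (scale-free fixture networks with triadic closure, planted
deregulated subnetworks under a `p_enr`/`p_scale` redraw model, edge
rewiring), ROC/partial-AUC evaluation, a local GSEA comparator, a
hypergeometric list test and a command-line interface.

## Worked example

Simulate a 500-gene network with two planted deregulated pathways (half of
the pathway genes get P-values below 0.1), run the analysis, and compare
gene ranking quality against using the raw P-values alone:

```r
library(leanet)

net <- generate_fixture_network(500, attachment = 3, seed = 7)
cfg <- simulation_config(n_pathways = 2, pathway_size = 20,
                        p_enr = 0.5, p_scale = 0.1, seed = 3)
sim <- plant_deregulation(net, cfg)
sim
#> Simulated deregulation dataset: 500 genes, 2 planted pathway(s) of size 20
#>   radii: 2, 3 | redrawn genes: 16 (p_enr = 0.50, p_scale = 0.1)

fit <- lean(net, sim$scores, n_samples = 2000, seed = 11)

genes <- names(sim$scores)
lab <- genes %in% sim$pathway_genes
round(c(lean        = roc_auc(roc_points(lean_ranking(fit, genes), lab)),
        single_gene = roc_auc(roc_points(as.numeric(sim$scores), lab))), 4)
#>        lean single_gene
#>      0.7109      0.6629
```

The planted genes are ranked markedly better by the neighborhood statistic
(AUC 0.71) than by their own P-values (0.66): with `p_enr = 0.5`, half the
pathway genes carry no individual signal and can only be recovered through
their neighbors. At this moderate signal strength no single center passes
the BH 0.05 cutoff (`summary(fit)` reports 0 significant centers) — the
gain is in the ranking; stronger signal (`p_scale = 0.01`) yields
significant centers outright.

Real data goes through the readers instead of the simulator:

```r
net <- read_edge_list("string_links.txt", format = "string-links",
                      min_score = 0.9)
scores <- read_scores("limma_pvalues.tsv")
fit <- lean(net, scores, seed = 1)
significant_centers(fit, alpha = 0.05)
write_results(fit, "lean_results.tsv")
```

The same pipeline is scriptable via the CLI (`inst/exec/lean`):
`lean simulate`, `lean run`, `lean evaluate`, `lean compare`; see
`?lean_cli`.

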