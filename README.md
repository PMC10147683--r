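# cobindep

Cofactor-dependent transcription factor (TF) target discovery from
factorial expression contrasts, ChIP-seq peak co-occupancy and
multiplexed interactome proteomics.

## The problem

Oncogenic programs such as the epithelial–mesenchymal transition (EMT)
are driven by TFs whose activating function can depend on chromatin
cofactors. Given a 2×2 factorial experiment — control vs cofactor
knockdown (`SCR`/`KD`) crossed with untreated vs induced (`Con`/`Dox`)
— plus peak sets for the TF and cofactor, `cobindep` identifies the
genes whose induction requires the cofactor. The core statistic is the
per-gene **knockdown impact score**

    IS = lfc(KD: Dox vs Con) − lfc(SCR: Dox vs Con)

in log2 units; IS ≤ −log2(1.5) marks at least a 1.5-fold reduction in
activation. Direct targets are genes that are (i) significantly
upregulated on induction (adj. p ≤ 0.05, FC ≥ 1.5), (ii) impaired by
the knockdown (IS ≤ −log2(1.5)), and (iii) carry a TF–cofactor
co-bound peak within 10 kb of their TSS.

Around this sit the supporting statistics the analysis needs: an exact
multi-set intersection test (iterated hypergeometric convolution),
observed/expected chi-square for preferential peak loss at co-bound
sites, hypergeometric over-representation, preranked GSEA with a
permutation null, Spearman correlation, BH adjustment, and a
TMT interactome stage (total-intensity channel normalization plus
moderated bait-vs-IgG and condition contrasts). A synthetic-data
generator with recorded ground truth makes the whole pipeline testable
without any external download.

## Worked example

```r
library(cobindep)

res <- run_pipeline(pipeline_config(sim_config(seed = 7)))
round(res$summary[c("n_up", "n_down", "n_impaired",
                    "n_cobound_genes", "n_targets",
                    "chi2_oe_ratio", "chi2_log10p")], 3)
#>           n_up          n_down      n_impaired n_cobound_genes
#>        485.000         462.000          44.000          40.000
#>      n_targets   chi2_oe_ratio     chi2_log10p
#>         40.000           4.153         -11.725

head(res$targets, 5)
#> [1] "g04926" "g00191" "g02105" "g01719" "g02350"
```

Reading: of 5000 simulated genes, 485 are called UP on induction; 44
have impaired activation under knockdown (IS ≤ −log2(1.5)); 40 genes
carry a co-bound promoter peak; their intersection — the 40 reported
targets, ordered most-impaired first — exactly recovers the 40 planted
dependent genes (`res$summary["target_sensitivity"]` and
`..._precision` are both 1). The chi-square block shows TF peaks at
co-bound sites are lost ~4.2× more often than expected under
independence after knockdown (p ≈ 10⁻¹²), and the interactome stage
(`res$qplex_enrich`, `res$qplex_contrast`) recovers all 30 planted
bait-enriched proteins and the 10 condition-rewired ones.

Every stage is also usable standalone on files: `read_bed()` /
`read_counts()` / `read_contrast_table()` / `read_gmt()` /
`read_tmt()` feed `de_contrast()`, `categorize_genes()`,
`impact_score()`, `filter_impaired_activation()`,
`intersect_unique()`, `annotate_peaks()`, `cobound_gene_set()`,
`multiset_intersection_test()`, `gsea_preranked()`,
`normalize_channels()`, `enrichment_call()` and friends; see the
vignette in `vignettes/` for the methods.

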