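# preservenet

Weighted gene co-expression network analysis across two cohorts: which
co-expression modules of one condition fail to replicate in the other, and
which genes hub those disrupted modules. The package implements the full
pipeline — per-cohort network construction, module detection, a
seven-statistic permutation test of module preservation, a five-metric
label-permutation hub test, and downstream enrichment / variant statistics —
together with a synthetic two-cohort generator with planted ground truth, so
every stage is testable without any external download.

It is written for systems-biology analysts who compare disease and control
transcriptomes (blood microarray panels are the motivating case) and want a
self-contained, reproducible implementation of this analysis style.

## The model in brief

Per cohort, Pearson correlations are soft-thresholded into an adjacency
`a_ij = |r_ij|^β` with β the smallest power achieving scale-free fit
`−sign(slope)·R² ≥ 0.85`, then converted to the topological overlap matrix

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),   l_ij = Σ_u a_iu a_uj
```

Modules are branches of the average-linkage tree of `1 − TOM` (dynamic
hybrid cut: deepSplit 3, minimum size 10), merged at eigengene correlation
> 0.95 and polished by a k-means step with eigengene centroids.

A module of the discovery cohort is scored in the test cohort by seven
preservation statistics (mean adjacency, eigengene coherence, correlation of
correlation / degree / eigengene-contribution vectors, and two
sign-corrected means). Their null distribution comes from random same-size
gene sets (10,000 permutations by convention, alternative "less",
`p = (s+1)/(n+1)`); a module is **non-preserved** when all seven p-values
fall below 0.05. Hubs of non-preserved modules are scored by module
membership, betweenness, closeness, PageRank and the Kleinberg score; a
relabelling permutation null (1,000 relabellings, `p = #(higher)/n_perm`)
declares a gene a hub when any score has p < 0.01. Enrichment uses the
one-sided hypergeometric test over GMT libraries; GWAS enrichment uses the
two-sided Fisher exact test; variant joins keep SNPs with eQTL p < 1e-4 and
frequency > 0.10 (both strict).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data; `analysis/01_simulate.R` plants four modules (320/100/90/120 genes,
170 background genes, 150 samples per cohort) with one hub per module and
destroys the 120-gene module ("M4", hub `g0625`) in cohort B. Running the
stages prints:

```
$ Rscript analysis/02_network.R
[cohort a] soft power 18 (signed R^2 = 0.856)
[cohort a] 4 modules (M1=318, M2=100, M3=90, M4=111), 181 genes unassigned
[cohort b] soft power 18 (signed R^2 = 0.864)
[cohort b] 3 modules (M1=320, M2=100, M3=90), 290 genes unassigned

$ Rscript analysis/03_preservation.R
[ab] modules tested: 4; non-preserved: M4
 module size max_p_printed nonpreserved
     M1  318             1        FALSE
     M4  111       9.99E-4         TRUE
     M2  100             1        FALSE
     M3   90             1        FALSE
[ba] modules tested: 3; non-preserved: none

$ Rscript analysis/04_hubs.R
[ab] module M4 (111 genes): 2 significant hubs: g0554, g0625

$ Rscript analysis/05_annotation.R
module M4: 2/20 sets enriched at p < 0.05; top: SET008 (p = 1.26E-7, 9/10 overlap)
GWAS enrichment in non-preserved modules: OR = 9.74, 95% CI 2.27~47.72, p = 0.0008235
cross-disease SNP overlap: |A| = 3, |B| = 3, shared = 1
```

Reading this: the destroyed module is invisible as a module in cohort B, is
the unique module flagged non-preserved (its maximum permutation p-value
9.99E-4 is the floor at 1,000 permutations), its planted hub `g0625` is
recovered among the significant hubs, the gene sets planted to overlap it
are enriched, and the synthetic "GWAS" genes concentrate in the
non-preserved stratum (odds ratio 9.7). The same pipeline runs from one
configuration object:

```r
library(preservenet)
cfg <- pipeline_config(synthetic = synthetic_config(seed = 1),
                       preservation_n_perm = 1000, seed = 1)
bundle <- run_pipeline(cfg)
bundle$directions$ab$nonpreserved
significant_hubs(bundle$directions$ab$hubs[[1]])
```

File-based cohorts work the same way (`cohort_a_path`/`cohort_b_path`,
TSV with a `gene_id` column), with MAD probe collapse
(`collapse_probes_by_mad()`) and the bottom-5% mean-expression filter
available for probe-level input.

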