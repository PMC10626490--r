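# stemwax

Gene-regulatory-network (GRN) inference for cell-type-resolved plant stem
transcriptomes, together with the morphometric calculations used in
cuticular-wax studies (internode surface area, wax load, wax-class
composition).

The package is aimed at plant molecular biologists asking *which
transcription factors drive a pathway that is active in one cell type* —
the motivating case being epicuticular wax biosynthesis in the stem
epidermis, where pathway genes are strongly epidermis-enriched and their
regulators must be found among epidermis-upregulated TFs.

## The method

Starting from gene-level counts and TPM for several cell types × replicates
(e.g. laser-capture microdissection RNA-seq), the pipeline:

1. **Selects epidermis-enriched genes.** Genes are kept when the mean TPM of
   at least one cell type is ≥ 5; counts are TMM-normalized and
   epidermis-vs-all-other-cell-types differential expression is computed
   with a conditional negative-binomial exact test (method-of-moments common
   dispersion). Selection rule: fold change ≥ 5 and FDR < 0.05
   (Benjamini–Hochberg).
2. **Computes coexpression.** Over the selected genes, all-pairs Pearson
   correlation *r* of log2(TPM+1) profiles, two-sided p-values from
   *t = r√((n−2)/(1−r²))*, BH q-values, and the **Mutual Rank**
   MR(i,j) = √(rank_i(j) · rank_j(i)) — the geometric mean of the positions
   the two genes occupy in each other's correlation-sorted partner lists.
3. **Scans promoters.** 1-kb strand-aware promoters upstream of each TSS are
   scanned on both strands with log-odds position weight matrices (relative
   score ≥ 0.85 of the attainable range); per motif, cis-regulatory-element
   enrichment in the selected genes versus all promoters is tested with a
   one-sided Fisher exact test (BH across motifs).
4. **Assembles the network.** A directed TF → partner edge requires
   PCC ≥ 0.9, correlation FDR ≤ 0.05, and an enriched motif of the TF in the
   partner's promoter — so every edge has at least one TF endpoint. The
   network is exported as edge/node TSV and Cytoscape-loadable GraphML, and
   is scored (precision/recall/F1) against planted truth when available.

A **synthetic-data module** generates the whole study offline: six stem cell
types × 3 replicates of negative-binomial counts with a planted 8-fold
epidermis-upregulated module, TF regulons whose targets track their TF's
profile, and promoters carrying the corresponding motif instances — so every
stage is verifiable against known ground truth.

Morphometric helpers implement the two-truncated-cone internode
surface-area model

    SA = (h/2)(D_top + D_mid)(π/2) + (h/2)(D_mid + D_base)(π/2)

wax load (summed wash masses / surface area, µg/cm²), and %TIC wax-class
composition with Welch-test group comparisons.

## Worked example

```r
library(stemwax)

fixture <- file.path(tempdir(), "fixture")
sim <- simulate_fixture(sim_config(seed = 1), fixture)   # 2000 genes, 10 TFs x 5 targets
res <- run_pipeline(fixture, file.path(tempdir(), "out"))
```

```
stemwax pipeline
thresholds: TPM>=5 fold>=5 deFDR<0.05 PCC>=0.9 edgeQ<=0.05 sign=positive scoreFrac=0.85 enrichQ<0.05
input: 2000 genes x 18 samples
expression filter: 1995 genes with cell-type mean TPM >= 5
differential expression: 200 genes with fold >= 5, FDR < 0.05 (up)
coexpression: 200 genes, 359 pairs with PCC >= 0.9
motif scan: 160 hits of 10 motifs in 2000 promoters
CRE enrichment: 10 of 10 motifs enriched at q < 0.05
binding map: 60 TF-target promoter-binding pairs
network: 56 nodes, 46 edges
recovery vs planted truth: precision 1.000 recall 0.920 F1 0.958
```

The log is the attrition report: of 2000 genes, 1995 pass the expression
filter, 200 (exactly the planted module) pass the DE selection, and the edge
rule keeps 46 directed TF → target edges — all of them planted (precision
1.000), covering 92% of the 50 true regulatory pairs. The missed edges are
pairs whose observed correlation fell just under the 0.9 cutoff, the
expected cost of a high-precision threshold.

Morphometrics:

```r
internode_surface_area(10, 2, 1, 2)   # h = 10 cm, diameters 2/1/2 cm
#> [1] 47.12389
wax_load(c(60, 30, 10), internode_surface_area(10, 2, 1, 2))
#> [1] 2.122066                        # ug/cm^2 from three summed washes
```

A thin CLI over the same functions is installed at
`system.file("scripts/stemwax", package = "stemwax")` with `simulate`,
`pipeline` and `morpho` subcommands.

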