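# statemi

State-space and mutual-information analysis of factorial RNA-seq designs.

## The problem

In a 2x2 factorial expression study — here the cross of leukemic status
(non-CML vs CML) with a genotype (wt vs knockout), giving the four conditions
`wt`, `KO`, `CP` (chronic-phase-like CML) and `BC` (blast-crisis-like CML) —
one often wants to know whether a *specific gene set* carries the information
that places samples in their disease states, or whether that information is
spread across the remaining transcriptome.  `statemi` answers this with two
complementary analyses:

**State-space geometry.**  For the centered log2-CPM matrix `M` (genes x
samples), the thin SVD `M = U D Vᵀ` defines sample coordinates `V D`.  The
components best separating leukemic status and genotype (by one-way ANOVA
R² of the coordinates) form a 2-D plane, rotated so the non-leukemic-to-
leukemic centroid direction lies along +x.  Fitting the same space from the
gene set alone and correlating coordinates axis-by-axis gives per-axis
R² — high values mean the set alone reconstructs the transcriptome-wide
state-space.

**MI density.**  Expression is discretized into three bins at the global
tertiles of the pooled centered values (equal-frequency = maximum-entropy
binning), and per gene the plug-in mutual information

    I(X:Y) = H(X) + H(Y) − H(X,Y)   [bits]

is computed against the condition label for three contrasts (all four
conditions; CP vs BC; wt vs KO).  A one-sided Wilcoxon rank-sum test (exact
enumeration under ties for small problems, tie-corrected normal
approximation otherwise) asks whether the set's MI values are stochastically
greater than the rest's.  An upper-tail hypergeometric test on DEG counts
(stand-in Welch caller at BH FDR < 0.05, or an externally supplied DEG
table) then checks whether any MI advantage is explained by simple DEG
over-representation.

A negative-binomial simulator (`var = mu + phi mu²`) of the full design —
5 replicates per condition, a dominant leukemic axis, a secondary genotype
axis, and a planted 655-gene informative set with bidirectional effects —
makes every stage testable without external data.

## Worked example

```r
library(statemi)

ds     <- simulate_counts(sim_config(seed = 1))          # 2000 genes x 20 samples
sets   <- generate_gene_sets(ds, n_decoys = 1, seed = 2) # planted set + 1 decoy
report <- run_pipeline(pipeline_config(ds, gene_sets = sets, seed = 1))
print(report)
```

```
run_report (statemi 1.0.0, seed 1)
  full space: elbow 3, disease axis PC1, genotype axis PC2, rotation -173.9 deg
  set planted    R2 = 0.998 / 0.998; p[condition4] = 0.979; p[CP_vs_BC] = 1.51e-14; p[wt_vs_KO] = 5.4e-11; DEG-balance p = 5.97e-14
  set decoy_01   R2 = 0.998 / 0.998; p[condition4] = 0.483; p[CP_vs_BC] = 0.567; p[wt_vs_KO] = 0.873; DEG-balance p = 0.675
  DEGs (standin_welch, CP_vs_BC): 237 of 2000 genes at FDR < 0.05
```

Reading the output: the disease axis is PC1 and genotype PC2, as planted.
The planted set reconstructs both state-space axes almost perfectly
(R² = 0.998) — but so does the decoy, because with 655 of 2000 genes a
random set still samples the dominant axes; the discriminating readout is MI
density.  The planted set is strongly MI-denser than the rest for the
CP-vs-BC and wt-vs-KO contrasts (its genes respond to the genotype axis),
while the decoy is not (p ≈ 0.5).  Under the four-condition contrast the
planted set is *not* denser — the 400 leukemic-responsive background genes
sit in the "rest" by design.  In this simulation the planted set's MI
advantage comes with DEG over-representation (balance p = 6e-14); the test
suite also constructs the converse situation, where heterogeneous
bidirectional responses give the set higher MI density with *balanced* DEG
counts.

Artifacts (coordinates, scree, per-gene MI tables, DEG table, JSON report)
are written when `pipeline_config(out_dir = ...)` is set.

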