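# amlsig

Sparse multi-omic signatures of ex vivo drug response in acute myeloid
leukemia (AML), with phosphosite-aware network contextualization.

## The problem

Ex vivo drug screens expose freshly isolated patient leukemia cells to a
drug panel and summarize each dose-response curve as an AUC (low AUC =
sensitive, high AUC = resistant). Given matched molecular profiles of the
same samples — somatic mutations (binary), transcript abundance (CPM),
protein and phosphosite abundance (log-ratios) — the question is which
molecular layer, alone or in combination, best predicts response to each
drug, and which features make up the predictive signature. The package is
aimed at computational biologists working with small proteogenomic cohorts
(tens of samples, 10^2–10^4 features per modality), where honest
cross-validation and feature-selection discipline matter more than model
complexity.

`amlsig` implements that workflow end to end:

1. **Drug filtering** — a drug is retained when at least
   `max(ceil(0.10 · n), 2)` of its `n` measured samples are sensitive
   (AUC < 100).
2. **Sparse regression** — for response `y` (AUC, or its binarization at
   100 for logistic models) and standardized features `X`, all three model
   families solve the elastic net

   min over (b0, b) of  f(b0, b) + lambda · [ (1−a)·||b||²₂/2 + a·||b||₁ ]

   with `f` the mean squared error (lasso `a = 1`, elastic net `a = 0.5`)
   or the average binomial deviance (logistic). The penalty `lambda` is
   tuned by leave-one-out cross-validation inside each of K = 5 outer
   folds; performance is the Spearman correlation between held-out
   predictions and observations, averaged over folds. Models that select
   zero features, or whose fold score is undefined, are flagged excluded.
3. **Signatures** — the model is refit on all samples at the
   LOO-selected penalty; the nonzero coefficients are the drug's signature.
4. **Network contextualization** — signatures are mapped onto a
   protein-protein interaction graph augmented with one node per
   phosphosite: substrate→site edges cost `m/4` and site→kinase edges
   `3m/2`, where `m` is the mean base edge cost (`1 − confidence`,
   clipped). A randomized prize-collecting Steiner forest (PCSF) connects
   signature members; per-node selection frequencies over 100 noisy
   replicates define a consensus subnetwork.
5. **Enrichment** — hypergeometric over-representation of signature genes
   in gene sets (GMT) and of selected phosphosites per kinase, with
   Benjamini-Hochberg correction at q < 0.01.
6. **Cell-line validation** — signatures are tested on
   parental/early-resistant/late-resistant cultures by average-linkage
   hierarchical clustering, scored by the adjusted Rand index and by
   cophenetic proximity of early-resistant cells to parental ones.

A first-class synthetic-data module generates cohorts with the statistical
structure this analysis assumes — 38 samples, AUC spanning 14.7–186.3,
pooled mRNA–protein Spearman 0.25 and phosphosite–protein 0.15, sparse
planted signatures with recorded ground truth — so every stage can be
tested against known answers.

## Worked example

```r
library(amlsig)

sim <- generate_cohort(cohort_config(n_genes = 120, n_drugs = 8, seed = 42))
sim$response
#> <drug_response> 8 drugs x 38 samples (15% missing)
filter_drugs(sim$response)
#> [1] "Drug01" "Drug02" "Drug03" "Drug04" "Drug05" "Drug06" "Drug07" "Drug08"

mp <- modality_correlation(sim$cohort$transcript, sim$cohort$protein, "pooled")
sprintf("pooled mRNA-protein Spearman: %.3f over %d pairs", mp$rho, mp$n)
#> "pooled mRNA-protein Spearman: 0.255 over 4560 pairs"

auc  <- sim$response$auc["Drug03", ]
have <- names(auc)[!is.na(auc)]
X <- assemble_features(sim$cohort, "protein", have)
y <- unname(auc[rownames(X)])

evaluate_nested_cv(X, y, model_spec("lasso", "protein"), cv_config(seed = 1))
#> <fit_result> lasso on protein, n=33: mean held-out Spearman = 0.371

sig <- extract_signature(X, y, model_spec("lasso", "protein"), drug = "Drug03")
sig
#> <drug_signature> Drug03: 10 features (lasso, lambda=4.959)
head(sig$features[order(-abs(sig$features$coefficient)), ], 3)
#>    feature modality coefficient
#> 6    G0060  protein    9.094151
#> 5    G0051  protein   -6.779960
#> 3    G0036  protein    4.445954
sim$truth$signatures$Drug03$feature   # planted ground truth
#> [1] "G0077" "G0060" "G0051" "G0116" "G0061"
```

The nested-CV score of 0.37 is typical for a planted signal explaining
~70% of response variance at n = 38: the signature recovers the strong
planted features (G0060, G0051, G0116) and misses the weakest ones, which
individually explain a few percent of variance.

Network contextualization and cell-line validation continue from the
signature:

```r
net <- generate_network(features(sim$cohort$protein), edge_density = 0.05,
                        sites = features(sim$cohort$phosphosite), seed = 7)
g  <- build_augmented_graph(net$edges, net$ks, features(sim$cohort$phosphosite))
res <- randomized_pcsf(g, assign_prizes(sig, g), pcsf_config(beta = 2, seed = 9))
igraph::V(res$consensus)$name
#> [1] "G0036" "G0051" "G0060" "G0116"

cl <- generate_cell_lines(sim$truth, drug = "Drug03",
                          shift_early = 1.5, shift_late = 3, seed = 5)
prox <- resistance_stage_proximity(cl, cl$signature)
sprintf("cophenetic parental-early %.2f vs parental-late %.2f",
        prox$d_parental_early, prox$d_parental_late)
#> "cophenetic parental-early 1.94 vs parental-late 4.05"
```

In this random network the stable signature members are retained as
separate trees (no interaction path is cheaper than the per-tree cost), and
the early-resistant cultures cluster closer to parental cells than the
late-resistant ones do — the expected two-step resistance geometry.

The whole analysis can also be driven by one configuration:

```r
run_pipeline(default_pipeline_config(seed = 1, out_dir = "amlsig_run"))
```

which writes every intermediate artifact (TSV/GMT/JSON) plus a run
manifest, and is byte-identical on rerun with the same seed. A thin
command-line wrapper lives at `inst/scripts/amlsig.R`.

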