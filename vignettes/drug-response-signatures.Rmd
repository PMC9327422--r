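---
title: "Modeling ex vivo drug response from multi-omic profiles"
author: "amlsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ex vivo drug response from multi-omic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models it fits,
the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The modeling problem

An ex vivo drug screen measures, for each patient sample and each drug, the
area under a dose-response viability curve (AUC). Low AUC means the
patient's cells died at low drug concentration (sensitive); high AUC means
they survived (resistant). Matched molecular profiles come in four
modalities: somatic mutations (binary gene x sample matrix), transcript
abundance (counts per million), and protein and phosphosite abundances
(log-ratios to a common reference channel, so values are centered and
approximately symmetric).

With only a few dozen samples and hundreds to tens of thousands of
features, the only defensible regression models are heavily penalized
linear ones, and the only defensible performance estimate is nested
cross-validation in which feature selection and penalty tuning happen
strictly inside each training fold.

## Drug filtering and binarization

A drug whose panel shows no sensitive samples supports no discrimination,
so drugs are filtered first: a drug is kept when at least
`max(ceiling(0.10 * n), 2)` of its `n` non-missing samples have AUC below
100. Two reading choices are deliberate and configurable:

* the 10% is rounded **up** ("at least" semantics), and `n` counts
  non-missing measurements for that drug, because panel coverage varies by
  drug;
* an AUC exactly at the threshold is classified **resistant**, because
  sensitivity is defined strictly as AUC *below* the cutoff.

Logistic models binarize AUC the same way (1 = resistant at or above 100).

## Penalized regression and nested cross-validation

All three families minimize

$$\min_{\beta_0, \beta}\; f(\beta_0, \beta)
  + \lambda\left[\tfrac{1-a}{2}\lVert\beta\rVert_2^2
  + a\lVert\beta\rVert_1\right]$$

where $f$ is the mean squared error over $2$ (lasso $a=1$, elastic net
$a=0.5$) or the average binomial deviance (logistic, $a=1$), with an
unpenalized intercept. Fits are delegated to glmnet; every returned
solution is required to satisfy the subgradient (KKT) conditions of this
objective to $10^{-6}$, which the test suite checks against an independent
proximal-gradient minimizer.

One numerical subtlety deserves a note: for gaussian responses glmnet
internally rescales `y` by its standard deviation, which silently divides
the *ridge* part of the penalty by that factor. The package reparametrizes
each call (with $c = a + (1-a)\,\mathrm{sd}(y)$, mixing $a/c$ and penalty
$\lambda c$) so that the solution minimizes the objective exactly as
written above, uniformly along the penalty path.

The penalty path holds 50 log-spaced values from $\lambda_{\max}$ (the
smallest penalty at which all coefficients are zero,
$\max_j |x_j^\top (y-\bar y)| / (n a)$) down to $10^{-3}\lambda_{\max}$.
Within each of $K = 5$ seeded outer folds (stratified by class for
logistic models, since unstratified folds on ~38 samples frequently
produce single-class training sets), the penalty is chosen by
leave-one-out cross-validation minimizing squared error (gaussian) or
deviance (logistic), with ties broken toward the larger, sparser penalty.
The fold score is the Spearman correlation between held-out predictions
and observations; the model score averages the five folds. Models for
which any refit selects zero features, or any fold score is undefined
(constant predictions, constant held-out response, or fewer than two
held-out samples), are flagged *excluded* and carry no score — they are
reported, never silently dropped.

The phrase "tuning the penalty" is a deliberate reading: the mixing
parameter is what distinguishes the lasso and elastic-net families, so the
quantity tuned per fold is the penalty strength $\lambda$; the mixing
value is fixed per family and configurable.

Signatures are obtained by re-running the selection on **all** samples
(leave-one-out over the same path) and refitting; the nonzero coefficients
with their modality tags are the drug's signature. Because a signature
uses all the data, its features must not be read as validated predictors —
validation is what the nested CV score and the cell-line module are for.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked.

* **Cross-modality correlation.** Each gene has a latent standard-normal
  protein score; the transcript score shares it with mixing weight
  $r = 2\sin(\pi\rho_s/6)$, the exact bivariate-Gaussian relation between
  Pearson $r$ and Spearman $\rho_s$. Phosphosites repeat the construction
  against their parent protein. Defaults target the weak couplings seen in
  patient cohorts: 0.25 (mRNA-protein) and 0.15 (site-protein), and the
  pooled Spearman over all (gene, sample) pairs recovers the target within
  about 0.05 once more than 10^4 pairs are pooled.
* **Abundance scales.** Transcripts are `exp(latent)` scaled to one
  million per sample (CPM semantics without read simulation); protein and
  site matrices are column-centered log-ratios. Between-gene baseline
  differences are deliberately **not** modeled: identical per-gene
  marginals are what make the pooled Spearman equal the per-gene target.
  Real data pool within- and between-gene variation; passing these tests
  therefore says nothing about between-gene effects.
* **Drug response.** Each drug gets `signature_size` features drawn from
  the configured modalities with coefficients `sign * Uniform(0.5, 1.5)`;
  AUC is intercept + signal + Gaussian noise. The default noise (SD 1.5)
  gives a generative $R^2$ of about 0.7 on average; `target_r2` instead
  calibrates the noise per drug from the realized signal variance when an
  exact $R^2$ is wanted. After optional completely-at-random missingness
  (default 15%), the pooled observed values are affinely mapped so their
  min and max equal the configured range (14.7–186.3 by default), and the
  recorded ground-truth coefficients are rescaled by the same map — so
  with zero noise an oracle regression on the true features reproduces the
  table exactly.
* **Networks and annotations.** Interaction networks have a
  preferential-attachment spanning backbone (always connected) plus random
  extra edges, confidences in (0, 1), a designated kinase subset, and
  kinase annotations on only a configurable fraction of phosphosites —
  mirroring how sparsely kinase-substrate databases cover real
  phosphoproteomes. Gene-set collections are random draws with an optional
  planted set for enrichment power checks.
* **Cell lines.** Parental, early-resistant and late-resistant groups
  shift the signature features by 0, `shift_early` and `shift_late`. The
  early shift touches only a fraction (default half) of the signature:
  early, ligand-mediated resistance is extrinsic and perturbs part of the
  intrinsic late-resistance program. This choice matters: if the early
  state were a uniform half-strength shift of *all* signature features, it
  would sit exactly equidistant between parental and late states and the
  expected clustering order would be a coin flip; the partial-shift
  geometry makes "early clusters closer to parental" a property of the
  generative model rather than of noise.

What the generator does not emulate: batch effects, missingness in the
omics matrices (only the drug table), heavy-tailed abundance
distributions, correlated mutation co-occurrence, and dose-level response
curves. Conclusions from passing tests are correspondingly scoped.

## Network contextualization

The interaction graph converts edge confidence to cost as
`1 - confidence`, clipped to [0.01, 1] — monotone and strictly positive.
With `m` the mean cost of the base edges (computed before augmentation, to
avoid a self-referential definition), each phosphosite becomes a node tied
to its parent protein at cost `m/4` and to each annotated kinase at cost
`3m/2`: attaching a site to its own protein is cheap, reaching through a
kinase is expensive, so kinases enter a solution only when they connect
several selected sites.

Signature members receive prizes `|coefficient| / max|coefficient|`
(mutations and transcripts map to their gene's protein node, phosphosites
to their site node). The prize-collecting Steiner forest then selects a
node set $S$ minimizing

$$\beta \sum_{v \notin S} p(v) \;+\; \sum_{e \in F} c(e)
  \;+\; \omega\,(\#\text{trees}),$$

where $F$ is the minimum spanning forest of the subgraph induced by $S$ —
trees are the connected components of $G[S]$, so two selected neighbors
always share a tree. A model constraint keeps solutions interpretable: a
phosphosite may only be selected together with its parent protein, hence a
selected site always carries its substrate edge (being the cheapest edge
class, a spanning forest always retains it).

Two solvers are provided. The exact solver enumerates node subsets (up to
15 nodes) and is the oracle in the test suite. The production heuristic
runs Goemans-Williamson moat growth against a dummy root connected to
every positive-prize node at cost $\omega$, strong-prunes the root tree,
and polishes the resulting node set by local search (add a prize node or a
potential Steiner point, add a prize node through one intermediate,
remove a node), started from both the GW set and the empty set. On random
8-node instances the heuristic matches the exact optimum in ~98% of cases
and has never been observed above 1.01x the optimum in the acceptance runs.

Robustness is assessed by re-solving 100 times (the default) with every
edge cost multiplied by an independent Uniform(1±0.05) draw; the fraction
of runs selecting each node is its frequency, and the consensus subgraph
keeps nodes at frequency ≥ 0.5. The prize values, β, ω, the noise model
and the aggregation rule are all package decisions — standard conventions
of prize-collecting network tools — and all are configurable.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for an overlap of $k$ selected genes with a $K$-member set in
a universe of $N$, with Benjamini-Hochberg correction across sets and a
q < 0.01 significance flag. The universe is the measured features of the
relevant modality, not the whole genome — enrichment against an inflated
universe is the classic way to manufacture significance. Kinase
over-representation treats each kinase's annotated substrate sites as a
set; sites without any annotation stay in the universe (they can never
overlap) and their share of the selection is reported, since sparse kinase
annotation otherwise silently weakens the test.

## Cell-line validation

Signature features are z-scored per feature, samples are clustered by
average-linkage agglomeration on Euclidean distance (columns sorted by
sample id first, so input order is irrelevant), and the tree is cut at
k = 2. Separation from group labels is scored by the adjusted Rand index;
the degenerate single-block-vs-single-block case is defined as 1. The
two-step resistance claim is quantified by mean cophenetic distances:
early resistance should sit closer to parental than late resistance does.
Distance, linkage and scaling are package defaults, not reconstructions of
any particular study's (unstated) choices; signature members missing from
the measured features (e.g. transcripts in a protein-only dataset) are
dropped with a logged count and the protein-level sub-signature is used.

## Numerical choices and degenerate inputs

* Solver thresholds: final fits at glmnet `thresh = 1e-12` (KKT residuals
  ≤ 1e-6 enforced in tests); the leave-one-out selection loop at `1e-9`,
  since it only compares prediction errors across the path.
* Penalty ties break toward the larger penalty; PCSF subset ties toward
  the first subset in enumeration order; local-search moves require strict
  improvement (1e-11).
* Constant feature columns are dropped with a warning before
  standardization; constant responses raise a degenerate-path error;
  single-class logistic folds raise a non-discretizable-fold error, and
  leave-one-out iterations that would be single-class are skipped.
* Spearman correlations use average ranks and are reported missing for
  fewer than 3 complete pairs or zero-variance series.
* All randomness flows from explicit integer seeds; the pipeline derives
  per-stage seeds from the global seed by stage-name hashing, so stages
  are individually reproducible and mutually independent.

## Problem sizes in the test suite

The suite exercises the pipeline at the cohort scale it models: 38
samples throughout; 200 protein features with 5 planted features at
generative $R^2 = 0.7$ for recovery runs (20 seeds); 100 pure-noise
repetitions at 50 features for the null; 50 random 8-node instances for
the Steiner-forest oracle comparison; 100 seeds for cell-line separation;
and two full pipeline runs for byte-level determinism. Under these
conditions the nested-CV held-out Spearman averages ≈ 0.4 and planted
support recall ≈ 0.75 — indistinguishable from what glmnet's own
cross-validation attains on the same data, and well below the oracle
ceiling (≈ 0.68) obtained by choosing the penalty with access to the
held-out fold. Those two numbers are worth keeping in mind when reading
any small-cohort drug-response study: with n = 38 and weak planted
effects, even a correct procedure recovers only the strong features.

## Known limitations

* Modality correlation targets hold for pooled statistics by
  construction; per-gene correlation *heterogeneity* (real cohorts show a
  wide per-gene distribution) is not modeled.
* The PCSF heuristic has no approximation guarantee under the
  induced-subgraph semantics; its quality is established empirically
  against the exact solver on small instances.
* Enrichment assumes exchangeable genes under the null; correlated
  features (e.g. co-regulated sites on one protein) make the
  hypergeometric p-values anti-conservative.
* The logistic family on small cohorts is fragile by nature — many folds
  are excluded — which is reported, not patched.
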