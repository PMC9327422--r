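#' Configuration for the synthetic multi-omic cohort generator
#'
#' Defaults emulate the statistical structure of an ex vivo AML
#' proteogenomics cohort: 38 patient samples, a 26-drug panel with AUC values
#' spanning 14.7-186.3, weak mRNA-protein coupling (pooled Spearman 0.25) and
#' weaker phosphosite-protein coupling (0.15), sparse planted drug
#' signatures, and ~15% missingness in the drug table.
#'
#' Cross-modality correlation is induced through a shared latent Gaussian
#' factor per gene. The latent Pearson correlation is solved from the target
#' Spearman via the bivariate-Gaussian relation `r = 2*sin(pi*rho/6)`, so the
#' pooled Spearman over all (gene, sample) pairs equals the target.
#'
#' @param n_samples number of samples (>= 6 so that 5-fold CV is feasible).
#' @param n_genes number of genes (each gene yields one mutation, transcript
#'   and protein feature).
#' @param n_sites_per_gene mean number of phosphosites per gene (Poisson).
#' @param n_drugs number of drugs in the panel.
#' @param signature_size number of ground-truth features per drug.
#' @param signature_modalities modalities the planted features are drawn
#'   from.
#' @param noise_sd response noise SD on the generative (pre-mapping) scale.
#'   The default 1.5, with 5 planted coefficients drawn from
#'   +/-Uniform(0.5, 1.5) on unit-variance features, gives a generative
#'   R-squared of about 0.7 on average (the realized value varies with the
#'   drawn coefficients).
#' @param target_r2 optional generative R-squared target in (0, 1); when
#'   set, it overrides `noise_sd` and the response noise is calibrated per
#'   drug from the realized signal variance, so every drug's generative
#'   R-squared equals the target.
#' @param rho_mrna_protein target pooled Spearman between transcript and
#'   protein levels, in `[0, 1)`.
#' @param rho_site_protein target pooled Spearman between phosphosite and
#'   parent-protein levels, in `[0, 1)`.
#' @param auc_range length-2 numeric `(low, high)`; the pooled observed AUC
#'   distribution is affinely mapped so its min/max equal this range exactly.
#' @param mutation_rate per-gene, per-sample Bernoulli mutation probability.
#' @param missing_rate fraction of drug-table entries masked completely at
#'   random.
#' @param seed integer seed; fixing it makes every output byte-identical.
#' @return validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 38L, n_genes = 200L,
                          n_sites_per_gene = 2, n_drugs = 26L,
                          signature_size = 5L,
                          signature_modalities = "protein",
                          noise_sd = 1.5, target_r2 = NULL,
                          rho_mrna_protein = 0.25,
                          rho_site_protein = 0.15,
                          auc_range = c(14.7, 186.3),
                          mutation_rate = 0.1,
                          missing_rate = 0.15,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_sites_per_gene = n_sites_per_gene,
              n_drugs = as.integer(n_drugs),
              signature_size = as.integer(signature_size),
              signature_modalities = signature_modalities,
              noise_sd = noise_sd, target_r2 = target_r2,
              rho_mrna_protein = rho_mrna_protein,
              rho_site_protein = rho_site_protein, auc_range = auc_range,
              mutation_rate = mutation_rate, missing_rate = missing_rate,
              seed = as.integer(seed))
  if (cfg$n_samples < 6L)
    stop_field("n_samples", "must be >= 6 (outer 5-fold CV must be feasible)")
  for (f in c("rho_mrna_protein", "rho_site_protein"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) stop_field(f, "must lie in [0, 1)")
  if (length(cfg$auc_range) != 2L || cfg$auc_range[1] >= cfg$auc_range[2])
    stop_field("auc_range", "must be (low, high) with low < high")
  if (cfg$noise_sd < 0) stop_field("noise_sd", "must be nonnegative")
  if (!is.null(cfg$target_r2) && (cfg$target_r2 <= 0 || cfg$target_r2 >= 1))
    stop_field("target_r2", "must lie in (0, 1)")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop_field("mutation_rate", "must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  if (!all(cfg$signature_modalities %in% MODALITIES))
    stop_field("signature_modalities", "unknown modality")
  if (cfg$signature_size < 1L) stop_field("signature_size", "must be >= 1")
  class(cfg) <- "cohort_config"
  cfg
}

# Spearman target -> Pearson correlation of the latent bivariate Gaussian
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Generate a synthetic multi-omic cohort with known ground truth
#'
#' Produces four modality matrices sharing a sample index, a drug x sample
#' AUC table, and the generative ground truth (planted signature features,
#' their post-mapping coefficients and intercepts) needed for recovery tests.
#'
#' Per-drug AUC is an intercept plus a sparse linear combination of planted
#' features plus Gaussian noise; the pooled observed values are then affinely
#' mapped so their min/max equal `config$auc_range` exactly, and the recorded
#' coefficients are rescaled by the same map, so a noiseless oracle fit on
#' the ground-truth features reproduces the table exactly.
#'
#' @param config a [cohort_config()].
#' @return list with elements `cohort` (named list of [omics_matrix()], class
#'   `multi_omic_cohort`), `response` (a [drug_response()]), and `truth`
#'   (class `ground_truth`: per-drug signature data.frames with `feature`,
#'   `modality`, `coefficient`; per-drug `intercept`; the affine map; the
#'   full feature universe per modality).
#' @examples
#' sim <- generate_cohort(cohort_config(n_genes = 50, n_drugs = 4, seed = 7))
#' range(sim$response$auc, na.rm = TRUE)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ns <- config$n_samples; ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  samp <- sprintf("S%02d", seq_len(ns))

  # latent protein scores, standard normal per gene
  P <- matrix(stats::rnorm(ng * ns), ng, ns, dimnames = list(genes, samp))

  # transcripts: latent score correlated with protein at the target Spearman,
  # exponentiated and scaled per sample to counts-per-million
  r1 <- spearman_to_pearson(config$rho_mrna_protein)
  Tlat <- r1 * P + sqrt(1 - r1^2) * matrix(stats::rnorm(ng * ns), ng, ns)
  cpm <- exp(Tlat)
  cpm <- sweep(cpm, 2, colSums(cpm), "/") * 1e6
  dimnames(cpm) <- list(genes, samp)

  # phosphosites: per-site scores correlated with the parent protein
  nsites <- stats::rpois(ng, config$n_sites_per_gene)
  parent <- rep(seq_len(ng), nsites)
  site_ids <- character(0)
  if (length(parent)) {
    res <- sample(c("S", "T", "Y"), length(parent), replace = TRUE,
                  prob = c(0.8, 0.15, 0.05))
    pos <- unlist(lapply(nsites[nsites > 0], function(k)
      sort(sample(1:999, k))), use.names = FALSE)
    site_ids <- sprintf("%s-p%s%d", genes[parent], res, pos)
  }
  r2 <- spearman_to_pearson(config$rho_site_protein)
  S <- r2 * P[parent, , drop = FALSE] +
    sqrt(1 - r2^2) * matrix(stats::rnorm(length(parent) * ns),
                            length(parent), ns)
  dimnames(S) <- list(site_ids, samp)

  # log2-ratio matrices are column-centered (ratio to a common reference)
  prot <- sweep(P, 2, colMeans(P))
  S <- sweep(S, 2, colMeans(S))

  mut <- matrix(stats::rbinom(ng * ns, 1L, config$mutation_rate), ng, ns,
                dimnames = list(genes, samp))

  cohort <- structure(list(
    mutation = omics_matrix(mut, "mutation"),
    transcript = omics_matrix(cpm, "transcript"),
    protein = omics_matrix(prot, "protein"),
    phosphosite = omics_matrix(S, "phosphosite")),
    class = "multi_omic_cohort")

  # planted sparse signatures and raw response
  drugs <- sprintf("Drug%02d", seq_len(config$n_drugs))
  universe <- lapply(cohort, features)
  sig_pool <- do.call(rbind, lapply(config$signature_modalities, function(m)
    data.frame(feature = universe[[m]], modality = m,
               stringsAsFactors = FALSE)))
  if (nrow(sig_pool) < config$signature_size)
    stop_field("signature_size", "exceeds available signature-pool features")
  raw <- matrix(NA_real_, config$n_drugs, ns, dimnames = list(drugs, samp))
  sigs <- vector("list", config$n_drugs)
  names(sigs) <- drugs
  for (d in seq_len(config$n_drugs)) {
    pick <- sig_pool[sample(nrow(sig_pool), config$signature_size), ]
    pick$coefficient <- sample(c(-1, 1), config$signature_size, TRUE) *
      stats::runif(config$signature_size, 0.5, 1.5)
    vals <- t(vapply(seq_len(nrow(pick)), function(i)
      cohort[[pick$modality[i]]]$values[pick$feature[i], ], numeric(ns)))
    signal <- colSums(vals * pick$coefficient)
    sd_d <- if (is.null(config$target_r2)) config$noise_sd else
      sqrt(stats::var(signal) * (1 - config$target_r2) / config$target_r2)
    raw[d, ] <- signal + stats::rnorm(ns, sd = sd_d)
    rownames(pick) <- NULL
    sigs[[d]] <- pick
  }

  # MCAR missingness, then exact affine mapping of the observed pool
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(raw)) < config$missing_rate,
                   nrow(raw), ncol(raw))
    # never blank out a whole drug
    for (d in which(rowSums(!mask) == 0L)) mask[d, sample(ns, 1L)] <- FALSE
    raw[mask] <- NA_real_
  }
  obs <- range(raw, na.rm = TRUE)
  if (obs[1] == obs[2])
    stop("degenerate response: all generated AUC values identical", call. = FALSE)
  b <- diff(config$auc_range) / diff(obs)
  a <- config$auc_range[1] - b * obs[1]
  auc <- a + b * raw
  for (d in seq_along(sigs)) sigs[[d]]$coefficient <- b * sigs[[d]]$coefficient

  truth <- structure(list(
    signatures = sigs,
    intercepts = stats::setNames(rep(a, config$n_drugs), drugs),
    noise_sd = b * config$noise_sd,
    affine = c(offset = a, scale = b),
    features = universe), class = "ground_truth")

  list(cohort = cohort, response = drug_response(auc), truth = truth)
}

#' @export
print.multi_omic_cohort <- function(x, ...) {
  cat("<multi_omic_cohort>\n")
  for (m in names(x))
    cat(sprintf("  %-11s %5d features x %d samples\n", m,
                nrow(x[[m]]$values), ncol(x[[m]]$values)))
  invisible(x)
}

#' Write all cohort matrices as TSV files
#' @param cohort a `multi_omic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(cohort), function(m) {
    p <- file.path(dir, paste0(m, ".tsv"))
    write_matrix(cohort[[m]], p)
    p
  }, "")
  invisible(paths)
}

#' Generate a synthetic protein interaction network and kinase-substrate map
#'
#' The network has a preferential-attachment spanning backbone (so it is
#' always connected) plus uniform random extra edges up to the requested
#' density, with per-edge confidences in (0, 1). A random subset of proteins
#' is designated as kinases, and only `site_annotation_fraction` of the
#' supplied phosphosites receive kinase annotations, emulating the sparse
#' coverage of kinase-substrate databases.
#'
#' @param proteins character vector of protein names, or an integer count.
#' @param edge_density target fraction of all possible edges, in (0, 1].
#' @param kinase_fraction fraction of proteins designated kinases, in (0, 1].
#' @param site_annotation_fraction probability that a site gets >= 1 kinase
#'   annotation, in (0, 1].
#' @param sites character vector of phosphosite ids (`GENE-pS123` style);
#'   defaults to one synthetic site per protein.
#' @param seed integer seed.
#' @return list with `edges` (a [ppi_edges()] data.frame), `ks` (a
#'   [ks_map()]), and `kinases` (character vector).
#' @export
generate_network <- function(proteins, edge_density = 0.02,
                             kinase_fraction = 0.1,
                             site_annotation_fraction = 0.2,
                             sites = NULL, seed = 1L) {
  if (is.numeric(proteins) && length(proteins) == 1L)
    proteins <- sprintf("G%04d", seq_len(proteins))
  n <- length(proteins)
  if (n < 3L) stop("need at least 3 proteins", call. = FALSE)
  for (f in c("edge_density", "kinase_fraction", "site_annotation_fraction")) {
    v <- get(f)
    if (v <= 0 || v > 1) stop_field(f, "must lie in (0, 1]")
  }
  set.seed(seed)
  g <- igraph::sample_pa(n, m = 1, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  target <- max(nrow(el), round(edge_density * n * (n - 1) / 2))
  extra <- target - nrow(el)
  if (extra > 0) {
    have <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    cand <- cbind(sample(n, 4L * extra, TRUE), sample(n, 4L * extra, TRUE))
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    key <- paste(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
    keep <- !duplicated(key) & !(key %in% have)
    cand <- cand[keep, , drop = FALSE]
    el <- rbind(el, cand[seq_len(min(extra, nrow(cand))), , drop = FALSE])
  }
  edges <- ppi_edges(data.frame(
    node_a = proteins[el[, 1]], node_b = proteins[el[, 2]],
    confidence = stats::runif(nrow(el), 0.1, 0.99),
    stringsAsFactors = FALSE))

  kinases <- sort(sample(proteins, max(1L, ceiling(kinase_fraction * n))))
  if (is.null(sites))
    sites <- sprintf("%s-pS%d", proteins, sample(1:999, n, replace = TRUE))
  annotated <- sites[stats::runif(length(sites)) < site_annotation_fraction]
  ks <- data.frame(kinase = character(0), site = character(0),
                   stringsAsFactors = FALSE)
  if (length(annotated)) {
    nk <- 1L + stats::rpois(length(annotated), 0.5)
    nk <- pmin(nk, length(kinases))
    ks <- do.call(rbind, lapply(seq_along(annotated), function(i)
      data.frame(kinase = sample(kinases, nk[i]), site = annotated[i],
                 stringsAsFactors = FALSE)))
  }
  list(edges = edges, ks = ks_map(ks), kinases = kinases)
}

#' Generate synthetic cell-line profiles for signature validation
#'
#' Emulates parental / early-resistant / late-resistant cell-line cultures:
#' planted signature features are shifted by `shift_early` in the early group
#' and `shift_late` in the late group (zero in parental); all other features
#' are pure noise. With `shift_early` between 0 and `shift_late` this
#' reproduces the two-step resistance geometry in which early-resistant
#' cultures sit between parental and late-resistant ones.
#'
#' @param truth a `ground_truth` object from [generate_cohort()].
#' @param drug drug id (or index) whose signature is planted; default first.
#' @param n_per_group samples per group (default 3, typical of cell-line
#'   replicates).
#' @param shift_early,shift_late additive shifts on signature features;
#'   require `0 <= shift_early <= shift_late`.
#' @param early_fraction fraction of signature features the early shift
#'   touches (default 0.5). Early, ligand-mediated resistance is extrinsic
#'   and perturbs only part of the intrinsic late-resistance signature; this
#'   keeps early cultures geometrically closer to parental than to late
#'   ones whenever `shift_early < shift_late`.
#' @param noise_sd residual feature noise SD.
#' @param groups which of `parental`, `early`, `late` to generate.
#' @param seed integer seed.
#' @return `cell_line_dataset`: list with `values` (feature x sample matrix
#'   over the protein and phosphosite feature universe), `groups` (named
#'   factor), and `signature` (planted feature ids).
#' @export
generate_cell_lines <- function(truth, drug = 1L, n_per_group = 3L,
                                shift_early = 0, shift_late = 3,
                                early_fraction = 0.5, noise_sd = 1,
                                groups = c("parental", "early", "late"),
                                seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (shift_early < 0 || shift_early > shift_late)
    stop("require 0 <= shift_early <= shift_late", call. = FALSE)
  sig <- truth$signatures[[drug]]
  sig <- sig[sig$modality %in% c("protein", "phosphosite"), , drop = FALSE]
  if (is.null(sig) || nrow(sig) == 0L)
    stop("signature has no protein/phosphosite features to plant", call. = FALSE)
  groups <- match.arg(groups, several.ok = TRUE)
  set.seed(seed)
  feats <- unlist(truth$features[c("protein", "phosphosite")], use.names = FALSE)
  shift_of <- c(parental = 0, early = shift_early, late = shift_late)
  lab <- rep(groups, each = n_per_group)
  ids <- sprintf("%s_%d", lab, sequence(rep(n_per_group, length(groups))))
  vals <- matrix(stats::rnorm(length(feats) * length(ids), sd = noise_sd),
                 length(feats), length(ids), dimnames = list(feats, ids))
  # the early shift touches only a sub-portion of the signature
  early_idx <- sort(sample(nrow(sig), max(1L, round(early_fraction * nrow(sig)))))
  for (j in seq_along(ids)) {
    idx <- if (lab[j] == "early") early_idx else seq_len(nrow(sig))
    vals[sig$feature[idx], j] <- vals[sig$feature[idx], j] +
      shift_of[lab[j]] * sign(sig$coefficient[idx])
  }
  structure(list(values = vals,
                 groups = stats::setNames(factor(lab, levels = groups), ids),
                 signature = sig$feature),
            class = "cell_line_dataset")
}

#' Generate random gene-set annotations (GMT-writable)
#'
#' Random sets drawn from the supplied gene universe, optionally with one
#' planted set (e.g. a drug signature) prepended for enrichment power tests.
#'
#' @param genes gene universe.
#' @param n_sets number of random sets.
#' @param set_size length-2 integer range of set sizes (inclusive).
#' @param enriched_set optional character vector planted verbatim as set
#'   `"planted"`.
#' @param seed integer seed.
#' @return a `gene_sets` named list.
#' @export
generate_annotations <- function(genes, n_sets = 20L, set_size = c(5L, 15L),
                                 enriched_set = NULL, seed = 1L) {
  if (max(set_size) > length(genes))
    stop("set sizes must not exceed the number of genes", call. = FALSE)
  set.seed(seed)
  sets <- list()
  if (!is.null(enriched_set)) {
    if (!all(enriched_set %in% genes))
      stop("enriched_set members must be in `genes`", call. = FALSE)
    sets$planted <- enriched_set
  }
  if (n_sets > 0L) {
    sizes <- if (set_size[1] == set_size[2]) rep(set_size[1], n_sets) else
      sample(set_size[1]:set_size[2], n_sets, replace = TRUE)
    rand <- lapply(sizes, function(k) sort(sample(genes, k)))
    names(rand) <- sprintf("RandomSet%03d", seq_len(n_sets))
    sets <- c(sets, rand)
  }
  structure(sets, class = "gene_sets")
}
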