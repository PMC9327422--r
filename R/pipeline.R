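#' Default pipeline configuration
#'
#' A fully synthetic end-to-end configuration sized for desk-scale runs:
#' a 38-sample cohort with 60 genes, a 6-drug panel with planted protein
#' signatures, a matched interaction network and random gene sets, two model
#' specifications (lasso and elastic net on proteins), and synthetic
#' parental/early/late cell lines. Every stage seed is derived
#' deterministically from the single global `seed` by stage-name hashing.
#'
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "amlsig_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(
      cohort = list(n_samples = 38L, n_genes = 60L, n_drugs = 6L,
                    signature_size = 5L, noise_sd = 1.5),
      network = list(edge_density = 0.05, kinase_fraction = 0.1,
                     site_annotation_fraction = 0.2),
      annotations = list(n_sets = 15L, set_size = c(5L, 15L))
    ),
    filter = list(auc_threshold = 100, min_fraction = 0.10, min_count = 2L),
    models = list(list(family = "lasso", modalities = "protein"),
                  list(family = "elasticnet", modalities = "protein")),
    cv = list(outer_k = 5L),
    pcsf = list(beta = 1, n_randomizations = 100L, noise_delta = 0.05,
                consensus_fraction = 0.5),
    enrichment = list(q_threshold = 0.01),
    validation = list(n_per_group = 3L, shift_early = 1.5, shift_late = 3,
                      noise_sd = 1)
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error: `seed` must be set", call. = FALSE)
  has_synth <- !is.null(cfg$synthetic)
  has_paths <- !is.null(cfg$paths)
  if (!has_synth && !has_paths)
    stop("config error: need a `synthetic` block or input `paths`",
         call. = FALSE)
  if (has_paths) {
    need <- c("mutation", "transcript", "protein", "phosphosite", "response",
              "ppi", "ks", "gmt")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop(sprintf("config error: missing input path(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    gone <- cfg$paths[!vapply(unlist(cfg$paths), file.exists, logical(1))]
    if (length(gone))
      stop(sprintf("config error: input file(s) not found: %s",
                   paste(unlist(gone), collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), drug filtering, model
#' comparison under nested cross-validation, signature extraction for the
#' best-scoring model, randomized PCSF network contextualization, gene-set
#' and kinase enrichment, and cell-line validation. Every intermediate
#' artifact is written under `out_dir` together with a JSON manifest
#' (inputs, per-stage seeds and summaries). Reruns with the same
#' configuration and seed are byte-identical. A stage error aborts the run,
#' naming the stage; the manifest written so far is kept.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out <- config$out_dir %||% "amlsig_run"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "amlsig",
                   version = as.character(utils::packageVersion("amlsig")),
                   seed = config$seed, stages = list())
  finish_stage <- function(name, summary) {
    manifest$stages[[name]] <<- summary
    write_json_stable(manifest, file.path(out, "manifest.json"))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_json_stable(manifest, file.path(out, "manifest.json"))
      stop(sprintf("stage '%s' failed: %s (artifacts so far in %s)",
                   name, conditionMessage(e), out), call. = FALSE)
    })
  }

  # -- stage 1: simulate or load ------------------------------------------
  sim <- run_stage("simulate", {
    if (!is.null(config$synthetic)) {
      ca <- config$synthetic$cohort %||% list()
      ca$seed <- derive_seed(config$seed, "cohort")
      cc <- do.call(cohort_config, ca)
      s <- generate_cohort(cc)
      na <- config$synthetic$network %||% list()
      na$proteins <- features(s$cohort$protein)
      na$sites <- features(s$cohort$phosphosite)
      na$seed <- derive_seed(config$seed, "network")
      net <- do.call(generate_network, na)
      aa <- config$synthetic$annotations %||% list()
      aa$genes <- features(s$cohort$protein)
      aa$seed <- derive_seed(config$seed, "annotations")
      sets <- do.call(generate_annotations, aa)
      write_cohort(s$cohort, out)
      write_response(s$response, file.path(out, "response.tsv"))
      write_edgelist(net$edges, file.path(out, "ppi.tsv"))
      write_ks(net$ks, file.path(out, "kinase_substrate.tsv"))
      write_gmt(sets, file.path(out, "gene_sets.gmt"))
      write_json_stable(lapply(s$truth$signatures, function(x)
        as.list(x)), file.path(out, "ground_truth.json"))
      list(cohort = s$cohort, response = s$response, truth = s$truth,
           net = net, sets = sets)
    } else {
      p <- config$paths
      list(cohort = structure(lapply(stats::setNames(nm = MODALITIES),
                                     function(m) read_matrix(p[[m]], m)),
                              class = "multi_omic_cohort"),
           response = read_response(p$response), truth = NULL,
           net = list(edges = read_edgelist(p$ppi), ks = read_ks(p$ks)),
           sets = read_gmt(p$gmt))
    }
  })
  finish_stage("simulate", list(
    n_samples = length(samples(sim$cohort$protein)),
    n_drugs = nrow(sim$response$auc),
    n_sites = length(features(sim$cohort$phosphosite)),
    synthetic = !is.null(sim$truth)))

  # -- stage 2: drug filter -----------------------------------------------
  retained <- run_stage("filter", {
    fc <- do.call(filter_config, config$filter %||% list())
    r <- filter_drugs(sim$response, fc)
    writeLines(r, file.path(out, "retained_drugs.txt"))
    r
  })
  finish_stage("filter", list(n_retained = length(retained),
                              drugs = retained))
  if (length(retained) == 0L)
    stop("stage 'filter' failed: no drug passes the filter", call. = FALSE)

  # -- stage 3: model comparison ------------------------------------------
  comparison <- run_stage("compare", {
    specs <- lapply(config$models, function(m)
      model_spec(m$family, unlist(m$modalities), a = m$a %||% NULL))
    cv <- cv_config(outer_k = config$cv$outer_k %||% 5L,
                    seed = derive_seed(config$seed, "cv"))
    tbl <- compare_models(sim$cohort, sim$response, retained, specs, cv)
    utils::write.table(tbl, file.path(out, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tbl
  })
  med <- summarize_comparison(comparison)
  finish_stage("compare", list(
    n_models = nrow(comparison), n_excluded = sum(comparison$excluded),
    median_by_family = med$by_family))

  # -- stage 4: signature -------------------------------------------------
  signature <- run_stage("signature", {
    ok <- comparison[!comparison$excluded, , drop = FALSE]
    if (nrow(ok) == 0L) stop("all models excluded; no signature to extract")
    pick <- ok[order(-ok$mean_score, ok$drug)[1L], ]
    drug <- config$signature_drug %||% pick$drug
    smod <- strsplit(pick$modalities, "+", fixed = TRUE)[[1L]]
    spec <- model_spec(pick$family, smod)
    auc <- sim$response$auc[drug, ]
    have <- names(auc)[!is.na(auc)]
    X <- suppressWarnings(assemble_features(sim$cohort, smod, have))
    yv <- auc[rownames(X)]
    y <- if (spec$family == "logistic") binarize_response(yv) else unname(yv)
    sg <- extract_signature(X, y, spec, drug = drug)
    write_json_stable(list(drug = sg$drug, family = sg$spec$family,
                           lambda = sg$lambda, intercept = sg$intercept,
                           features = sg$features),
                      file.path(out, "signature.json"))
    sg
  })
  finish_stage("signature", list(drug = signature$drug,
                                 n_features = nrow(signature$features)))

  # -- stage 5: network ---------------------------------------------------
  netres <- run_stage("network", {
    graph <- build_augmented_graph(sim$net$edges, sim$net$ks,
                                   features(sim$cohort$phosphosite))
    prizes <- assign_prizes(signature, graph)
    pa <- config$pcsf %||% list()
    pa$seed <- derive_seed(config$seed, "pcsf")
    pc <- do.call(pcsf_config, pa)
    res <- randomized_pcsf(graph, prizes, pc)
    write_forest(res, graph, prizes, file.path(out, "network"))
    list(graph = graph, prizes = prizes, result = res)
  })
  finish_stage("network", list(
    n_selected = length(netres$result$nodes),
    n_consensus = igraph::vcount(netres$result$consensus),
    objective = netres$result$objective))

  # -- stage 6: enrichment ------------------------------------------------
  enr <- run_stage("enrich", {
    qthr <- config$enrichment$q_threshold %||% 0.01
    sel_nodes <- igraph::V(netres$result$consensus)$name
    sel_genes <- unique(c(
      signature$features$feature[signature$features$modality != "phosphosite"],
      sel_nodes[igraph::V(netres$result$consensus)$type == "protein"]))
    g_tab <- enrich_sets(sel_genes, sim$sets,
                         features(sim$cohort$protein), qthr)
    sel_sites <- unique(c(
      signature$features$feature[signature$features$modality == "phosphosite"],
      sel_nodes[igraph::V(netres$result$consensus)$type == "phosphosite"]))
    k_tab <- enrich_kinases(sel_sites, sim$net$ks,
                            features(sim$cohort$phosphosite), qthr)
    utils::write.table(g_tab, file.path(out, "enrichment_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(k_tab, file.path(out, "enrichment_kinases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(sets = g_tab, kinases = k_tab)
  })
  finish_stage("enrich", list(
    n_significant_sets = sum(enr$sets$significant),
    n_significant_kinases = sum(enr$kinases$significant),
    unannotated_fraction = attr(enr$kinases, "unannotated_fraction")))

  # -- stage 7: validation ------------------------------------------------
  val <- run_stage("validate", {
    if (is.null(sim$truth))
      stop("cell-line validation requires the synthetic ground truth")
    va <- config$validation %||% list()
    va$truth <- sim$truth
    va$drug <- signature$drug
    va$seed <- derive_seed(config$seed, "celllines")
    cl_data <- do.call(generate_cell_lines, va)
    cl <- cluster_signature(cl_data, signature, k = 2L)
    # parental-vs-late separation is scored on those two groups' samples
    pl <- names(cl_data$groups)[cl_data$groups %in% c("parental", "late")]
    cl_pl <- cluster_signature(list(values = cl_data$values[, pl]),
                               signature, k = 2L)
    ari <- separation_score(cl_pl$labels[pl],
                            as.character(cl_data$groups[pl]))
    prox <- resistance_stage_proximity(cl_data, signature)
    df <- data.frame(sample = names(cl$labels), cluster = cl$labels,
                     group = as.character(cl_data$groups[names(cl$labels)]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(out, "validation_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(ari_parental_late = ari,
         d_parental_early = prox$d_parental_early,
         d_parental_late = prox$d_parental_late,
         early_closer = prox$early_closer)
  })
  finish_stage("validate", val)

  invisible(manifest)
}
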