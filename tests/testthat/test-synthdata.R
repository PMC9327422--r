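test_that("cohort config rejects invalid fields by name", {
  expect_error(cohort_config(n_samples = 4), "n_samples")
  expect_error(cohort_config(rho_mrna_protein = 1), "rho_mrna_protein")
  expect_error(cohort_config(rho_site_protein = -0.1), "rho_site_protein")
  expect_error(cohort_config(auc_range = c(100, 50)), "auc_range")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
})

test_that("generated matrices satisfy modality invariants and share samples", {
  sim <- small_sim()
  expect_true(all(sim$cohort$mutation$values %in% c(0, 1)))
  expect_true(all(sim$cohort$transcript$values >= 0))
  expect_equal(unname(colSums(sim$cohort$transcript$values)),
               rep(1e6, 38), tolerance = 1e-9)
  sm <- lapply(sim$cohort, samples)
  expect_true(all(vapply(sm, identical, logical(1), sm[[1]])))
  # every phosphosite parses to a generated gene
  parents <- parse_site_ids(features(sim$cohort$phosphosite))$gene
  expect_true(all(parents %in% features(sim$cohort$protein)))
})

test_that("fixed seed reproduces identical cohorts", {
  a <- generate_cohort(cohort_config(n_genes = 30, n_drugs = 3, seed = 9))
  b <- generate_cohort(cohort_config(n_genes = 30, n_drugs = 3, seed = 9))
  expect_identical(a$cohort$protein$values, b$cohort$protein$values)
  expect_identical(a$response$auc, b$response$auc)
  expect_identical(a$truth$signatures, b$truth$signatures)
})

test_that("pooled cross-modality correlations hit their targets", {
  sim <- generate_cohort(cohort_config(n_genes = 300, n_drugs = 2, seed = 5))
  mp <- modality_correlation(sim$cohort$transcript, sim$cohort$protein,
                             "pooled")
  expect_gt(mp$n, 1e4)
  expect_lt(abs(mp$rho - 0.25), 0.05)
  sp <- modality_correlation(sim$cohort$phosphosite, sim$cohort$protein,
                             "pooled")
  expect_lt(abs(sp$rho - 0.15), 0.05)

  indep <- generate_cohort(cohort_config(n_genes = 300, n_drugs = 2,
                                         rho_mrna_protein = 0, seed = 6))
  mi <- modality_correlation(indep$cohort$transcript, indep$cohort$protein,
                             "pooled")
  expect_lt(abs(mi$rho), 0.05)
})

test_that("AUC table spans the configured range exactly", {
  sim <- small_sim()
  expect_equal(unname(range(sim$response$auc, na.rm = TRUE)), c(14.7, 186.3))
  wide <- generate_cohort(cohort_config(n_genes = 30, n_drugs = 3,
                                        auc_range = c(5, 50), seed = 2))
  expect_equal(unname(range(wide$response$auc, na.rm = TRUE)), c(5, 50))
})

test_that("noiseless response is an exact affine function of its signature", {
  sim <- generate_cohort(cohort_config(n_genes = 40, n_drugs = 1,
                                       signature_size = 1, noise_sd = 0,
                                       missing_rate = 0, seed = 3))
  sig <- sim$truth$signatures[[1]]
  feat <- sim$cohort[[sig$modality]]$values[sig$feature, ]
  expect_equal(abs(cor(sim$response$auc[1, ], feat, method = "spearman")), 1)
  # the recorded ground truth reproduces the table to machine precision
  pred <- sim$truth$intercepts[1] + sig$coefficient * feat
  expect_equal(unname(sim$response$auc[1, ]), unname(pred), tolerance = 1e-10)
})

test_that("ground-truth features suffice for an exact oracle regression", {
  sim <- generate_cohort(cohort_config(n_genes = 50, n_drugs = 3,
                                       signature_size = 4, noise_sd = 0,
                                       missing_rate = 0, seed = 13))
  for (d in names(sim$truth$signatures)) {
    sig <- sim$truth$signatures[[d]]
    Xg <- t(vapply(seq_len(nrow(sig)), function(i)
      sim$cohort[[sig$modality[i]]]$values[sig$feature[i], ],
      numeric(38)))
    fit <- lm(sim$response$auc[d, ] ~ t(Xg))
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
})

test_that("synthetic network is connected with sparse kinase annotation", {
  expect_error(generate_network(2), "3 proteins")
  net <- generate_network(100, edge_density = 0.001, seed = 7)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_true(all(net$edges$confidence > 0 & net$edges$confidence < 1))

  sites <- sprintf("G%04d-pS%d", sample(1:100, 1000, TRUE), 1:1000)
  full <- generate_network(100, site_annotation_fraction = 1,
                           sites = sites, seed = 8)
  expect_setequal(unique(full$ks$site), sites)

  part <- generate_network(100, site_annotation_fraction = 0.2,
                           sites = sites, seed = 9)
  n_annot <- length(unique(part$ks$site))
  ci <- qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(n_annot, ci[1])
  expect_lte(n_annot, ci[2])
})

test_that("cell-line groups reflect the planted shifts", {
  truth <- small_sim()$truth
  expect_error(generate_cell_lines(truth, shift_early = 2, shift_late = 1),
               "shift_early")
  # no shift: group means indistinguishable on signature features
  flat <- generate_cell_lines(truth, shift_early = 0, shift_late = 0,
                              n_per_group = 10, seed = 21)
  sig <- flat$signature
  gm <- sapply(levels(flat$groups), function(g)
    mean(flat$values[sig, flat$groups == g]))
  expect_lt(max(gm) - min(gm), 0.5)

  # graded shifts: parental-early closer than parental-late
  shifted <- generate_cell_lines(truth, shift_early = 1.5, shift_late = 3,
                                 seed = 22)
  centroid <- function(g) rowMeans(shifted$values[sig, shifted$groups == g])
  d_pe <- sqrt(sum((centroid("parental") - centroid("early"))^2))
  d_pl <- sqrt(sum((centroid("parental") - centroid("late"))^2))
  expect_lt(d_pe, d_pl)

  # strong shift: k-means cleanly separates parental from late
  strong <- generate_cell_lines(truth, shift_early = 0, shift_late = 10,
                                groups = c("parental", "late"), seed = 23)
  km <- kmeans(t(strong$values[sig, ]), centers = 2, nstart = 5)
  expect_equal(oracle_ari(km$cluster, as.character(strong$groups)), 1)
})

test_that("generated annotations honor size bounds and planting", {
  genes <- sprintf("G%03d", 1:60)
  expect_error(generate_annotations(genes, set_size = c(10, 100)), "exceed")
  empty <- generate_annotations(genes, n_sets = 0)
  expect_length(empty, 0)
  fixed <- generate_annotations(genes, n_sets = 10, set_size = c(5, 5),
                                seed = 2)
  expect_true(all(lengths(fixed) == 5))
  planted <- generate_annotations(genes, n_sets = 20,
                                  enriched_set = genes[1:6], seed = 3)
  tab <- enrich_sets(genes[1:6], planted, genes)
  expect_equal(tab$set[1], "planted")
  expect_lt(tab$q[1], 0.01)
})
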