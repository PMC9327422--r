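make_response <- function(mat) {
  dimnames(mat) <- list(sprintf("d%02d", seq_len(nrow(mat))),
                        sprintf("s%02d", seq_len(ncol(mat))))
  drug_response(mat)
}

test_that("drug filter applies the max(ceil(10% n), 2) sensitive-count rule", {
  # 38 non-missing samples -> ceiling(3.8) = 4 sensitive samples required
  base <- matrix(150, 3, 38)
  base[1, 1:4] <- 50   # exactly 4 sensitive: retained
  base[2, 1:3] <- 50   # 3 sensitive: dropped
  base[3, ] <- 150     # none sensitive: dropped
  expect_equal(filter_drugs(make_response(base)), "d01")

  # with 12 non-missing samples the floor of 2 dominates: ceil(1.2) = 2
  small <- matrix(150, 2, 12)
  small[1, 1:2] <- 99
  small[2, 1] <- 99
  expect_equal(filter_drugs(make_response(small)), "d01")

  # all-missing drug excluded with a warning
  miss <- matrix(c(rep(50, 12), rep(NA_real_, 12)), 2, 12, byrow = TRUE)
  expect_warning(kept <- filter_drugs(make_response(miss)), "no non-missing")
  expect_equal(kept, "d01")
})

test_that("drug filter matches a brute-force oracle on random tables", {
  cfg <- filter_config()
  for (rep in 1:10) {
    set.seed(rep)
    auc <- matrix(runif(120, 20, 180), 10, 12)
    auc[runif(120) < 0.2] <- NA
    auc[rowSums(!is.na(auc)) == 0, 1] <- 100  # keep every drug measured
    r <- make_response(auc)
    expected <- sort(rownames(r$auc)[vapply(seq_len(10), function(d) {
      v <- r$auc[d, ]
      n <- sum(!is.na(v))
      sum(v < 100, na.rm = TRUE) >= max(ceiling(0.1 * n), 2)
    }, logical(1))])
    expect_identical(filter_drugs(r, cfg), expected)
  }
})

test_that("drug filter is monotone in threshold and min_count", {
  set.seed(42)
  auc <- matrix(runif(200, 20, 180), 10, 20)
  r <- make_response(auc)
  kept_100 <- filter_drugs(r, filter_config(auc_threshold = 100))
  kept_120 <- filter_drugs(r, filter_config(auc_threshold = 120))
  expect_true(all(kept_100 %in% kept_120))
  kept_c2 <- filter_drugs(r, filter_config(min_count = 2))
  kept_c5 <- filter_drugs(r, filter_config(min_count = 5))
  expect_true(all(kept_c5 %in% kept_c2))
})

test_that("binarization codes resistance as 1 with ties resistant", {
  expect_equal(binarize_response(c(150, 50)), c(1L, 0L))
  expect_equal(binarize_response(100), 1L)
  expect_equal(binarize_response(c(10, NA, 99.99)), c(0L, NA, 0L))
  expect_equal(binarize_response(rep(50, 5)), rep(0L, 5))
})

test_that("per-feature correlation is exact on monotone transforms", {
  set.seed(1)
  a <- toy_omics(matrix(rnorm(20), 4, 5))
  ident <- modality_correlation(a, a, "per_feature")
  expect_equal(ident$rho, rep(1, 4))
  neg <- toy_omics(-a$values)
  expect_equal(modality_correlation(a, neg, "per_feature")$rho, rep(-1, 4))
  expect_equal(modality_correlation(a, a, "pooled")$rho, 1)
})

test_that("correlation with ties matches the rank-then-Pearson oracle", {
  set.seed(3)
  va <- matrix(sample(1:3, 20, TRUE) + 0, 5, 4)
  vb <- matrix(sample(1:3, 20, TRUE) + 0, 5, 4)
  a <- toy_omics(va); b <- toy_omics(vb)
  got <- modality_correlation(a, b, "per_feature")
  for (i in seq_len(5)) {
    if (sd(va[i, ]) == 0 || sd(vb[i, ]) == 0) {
      expect_true(is.na(got$rho[i]))  # constant series: undefined, not 0/0
    } else {
      expect_equal(got$rho[i], oracle_spearman(va[i, ], vb[i, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("phosphosites match to parent proteins and short series go missing", {
  prot <- toy_omics(matrix(rnorm(8), 2, 4), "protein",
                    features = c("AKT1", "TP53"))
  site <- toy_omics(rbind(prot$values[1, ] * 2, rnorm(4)), "phosphosite",
                    features = c("AKT1-pS473", "TP53-pS15"))
  cc <- modality_correlation(site, prot, "per_feature")
  expect_equal(nrow(cc), 2)
  expect_equal(cc$rho[cc$feature_a == "AKT1-pS473"], 1)

  # a feature with < 3 complete pairs is reported missing, not dropped
  holey <- prot
  holey$values[1, 1:2] <- NA
  ch <- modality_correlation(site, holey, "per_feature")
  expect_true(is.na(ch$rho[ch$feature_a == "AKT1-pS473"]))
  expect_equal(ch$n[ch$feature_a == "AKT1-pS473"], 2L)
})
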