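test_that("model specs validate families and modality combinations", {
  expect_silent(model_spec("lasso", "mutation"))
  expect_silent(model_spec("elasticnet", c("transcript", "protein")))
  expect_silent(model_spec("logistic", c("mutation", "transcript", "protein",
                                         "phosphosite")))
  expect_error(model_spec("lasso", c("mutation", "protein")), "combination")
  expect_error(model_spec("lasso", "protein", a = 0.5), "lasso")
  expect_equal(model_spec("elasticnet", "protein")$a, 0.5)
})

test_that("feature assembly standardizes and drops constant columns", {
  sim <- small_sim()
  X <- assemble_features(sim$cohort, c("transcript", "protein"))
  expect_equal(ncol(X), 120)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, ncol(X)), tolerance = 1e-12)
  expect_equal(as.vector(table(attr(X, "modality"))[c("transcript", "protein")]),
               c(60L, 60L))

  flat <- sim$cohort
  flat$mutation$values[, ] <- 0
  expect_warning(Xm <- assemble_features(flat, "mutation"), "constant")
  expect_equal(ncol(Xm), 0)
  expect_error(assemble_features(sim$cohort, "protein", use_samples = "nope"),
               "empty sample intersection")
})

test_that("penalty at or above lambda_max yields the exact null model", {
  pr <- planted_problem(n = 20, p = 10, noise = 0.5, seed = 2)
  n <- nrow(pr$X)
  lmax <- max(abs(crossprod(pr$X, pr$y - mean(pr$y)))) / n
  fit <- fit_penalized(pr$X, pr$y, "gaussian", a = 1, lambda = lmax * 1.001)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, mean(pr$y), tolerance = 1e-8)
})

test_that("the unpenalized limit matches ordinary least squares", {
  pr <- planted_problem(n = 30, p = 6, noise = 1, seed = 3)
  fit <- fit_penalized(pr$X, pr$y, "gaussian", a = 1, lambda = 0)
  ls <- lm(pr$y ~ pr$X)
  expect_equal(unname(fit$beta), unname(coef(ls)[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ls)[1]), tolerance = 1e-6)
})

test_that("penalized fits match the independent proximal-gradient oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(12 * 6), 12, 6))
    y <- rnorm(12)
    a <- sample(c(0.5, 1), 1)
    lam <- runif(1, 0.05, 0.5)
    fit <- fit_penalized(X, y, "gaussian", a, lam)
    obj <- enet_objective(X, y, fit$intercept, fit$beta, "gaussian", a, lam)
    oracle <- oracle_ista(X, y, a, lam)
    expect_lt(abs(obj - oracle$objective), 1e-5)
    expect_lt(kkt_residual(X, y, fit$intercept, fit$beta, "gaussian", a, lam),
              1e-6)
  }
})

test_that("logistic fits satisfy KKT and refuse single-class folds", {
  set.seed(4)
  X <- scale(matrix(rnorm(30 * 5), 30, 5))
  y <- rbinom(30, 1, 0.5)
  fit <- fit_penalized(X, y, "binomial", a = 1, lambda = 0.05)
  expect_lt(kkt_residual(X, y, fit$intercept, fit$beta, "binomial", 1, 0.05),
            1e-6)
  expect_error(fit_penalized(X, rep(1, 30), "binomial", 1, 0.1),
               "single-class")
})

test_that("LOO penalty selection matches the brute-force oracle on a grid", {
  set.seed(5)
  X <- scale(matrix(rnorm(8 * 4), 8, 4))
  y <- drop(X[, 1] * 2 + rnorm(8, sd = 0.3))
  grid <- c(1, 0.5, 0.2, 0.05, 0.01)
  sel <- select_penalty_loo(X, y, "gaussian", a = 1, lambda = grid)
  expect_equal(sel$lambda, oracle_loo_select(X, y, 1, grid))
})

test_that("LOO selection recovers a noiseless single-column signal", {
  set.seed(6)
  X <- scale(matrix(rnorm(15 * 5), 15, 5))
  y <- drop(X[, 3])
  sel <- select_penalty_loo(X, y, "gaussian", a = 1)
  expect_lt(min(sel$cv_error), 1e-3)
  fit <- fit_penalized(X, y, "gaussian", 1, sel$lambda)
  expect_equal(which(abs(fit$beta) > 0.1), c(col3 = 3L), ignore_attr = TRUE)
})

test_that("pure-noise responses mostly select the sparsest end of the path", {
  wins <- 0
  for (seed in 1:50) {
    set.seed(seed + 1000)
    X <- scale(matrix(rnorm(10 * 40), 10, 40))
    y <- rnorm(10)
    sel <- select_penalty_loo(X, y, "gaussian", a = 1)
    # null model wins: selected penalty in the top quarter of the path
    if (sel$lambda >= sel$path[ceiling(length(sel$path) / 4)])
      wins <- wins + 1
  }
  expect_gt(wins, 25)
})

test_that("nested CV recovers planted signal and is deterministic", {
  pr <- planted_problem(n = 38, p = 200, k = 3, noise = 0, seed = 7)
  spec <- model_spec("lasso", "protein")
  fr <- evaluate_nested_cv(pr$X, pr$y, spec, cv_config(seed = 11))
  expect_false(fr$excluded)
  expect_gte(fr$mean_score, 0.9)
  expect_true(all(fr$fold_scores >= -1 & fr$fold_scores <= 1))
  fr2 <- evaluate_nested_cv(pr$X, pr$y, spec, cv_config(seed = 11))
  expect_identical(fr$fold_scores, fr2$fold_scores)
})

test_that("degenerate designs are excluded, never a crash", {
  X <- matrix(0, 20, 1, dimnames = list(NULL, "flat"))
  attr(X, "modality") <- "protein"; attr(X, "feature") <- "flat"
  y <- rnorm(20)
  fr <- evaluate_nested_cv(X, y, model_spec("lasso", "protein"),
                           cv_config(seed = 1))
  expect_true(fr$excluded)
  expect_true(is.na(fr$mean_score))
  expect_match(fr$reason, "fold")
})

test_that("signature extraction returns nonzero coefficients or errors", {
  pr <- planted_problem(n = 38, p = 100, k = 5, noise = 0.8, seed = 8)
  sig <- extract_signature(pr$X, pr$y, model_spec("lasso", "protein"), "drugX")
  expect_true(all(sig$features$coefficient != 0))
  recall <- mean(pr$support %in% sig$features$feature)
  expect_gte(recall, 0.8)
  # a penalty at the top of the path selects nothing
  spec0 <- model_spec("lasso", "protein",
                      lambda = max(abs(crossprod(pr$X, pr$y))) / 38 * 2)
  expect_error(extract_signature(pr$X, pr$y, spec0), "empty signature")
})

test_that("duplicated feature columns stay deterministic under the lasso", {
  set.seed(9)
  base <- scale(matrix(rnorm(30 * 4), 30, 4))
  X <- cbind(base, dup = base[, 1])
  colnames(X) <- c(paste0("f", 1:4), "f1dup")
  attr(X, "modality") <- rep("protein", 5)
  attr(X, "feature") <- colnames(X)
  y <- drop(base[, 1] + rnorm(30, sd = 0.2))
  s1 <- extract_signature(X, y, model_spec("lasso", "protein"))
  s2 <- extract_signature(X, y, model_spec("lasso", "protein"))
  expect_identical(s1$features, s2$features)
})

test_that("model comparison keeps excluded rows flagged and is reproducible", {
  sim <- small_sim()
  drugs <- filter_drugs(sim$response)[1:2]
  specs <- list(model_spec("lasso", "protein"),
                model_spec("lasso", "mutation"))
  cv <- cv_config(seed = 31)
  tbl <- compare_models(sim$cohort, sim$response, drugs, specs, cv)
  expect_equal(nrow(tbl), 4)
  expect_true(all(c("drug", "family", "modalities", "mean_score",
                    "excluded") %in% names(tbl)))
  expect_true(all(is.na(tbl$mean_score) == tbl$excluded))
  tbl2 <- compare_models(sim$cohort, sim$response, drugs, specs, cv)
  expect_identical(tbl, tbl2)
})
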