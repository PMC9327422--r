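# Independent numerical oracles, kept free of the package's solver paths.

# Elastic-net objective evaluated from its definition.
oracle_enet_objective <- function(X, y, b0, b, a, lambda) {
  n <- nrow(X)
  r <- y - b0 - drop(X %*% b)
  sum(r^2) / (2 * n) + lambda * ((1 - a) * sum(b^2) / 2 + a * sum(abs(b)))
}

# Proximal-gradient (ISTA) minimizer of the gaussian elastic net with an
# unpenalized intercept; step size from the Lipschitz constant.
oracle_ista <- function(X, y, a, lambda, iters = 50000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - a) + 1
  eta <- 1 / L
  b0 <- mean(y); b <- rep(0, p)
  obj <- oracle_enet_objective(X, y, b0, b, a, lambda)
  for (it in seq_len(iters)) {
    r <- y - b0 - drop(X %*% b)
    gb <- -drop(crossprod(X, r)) / n + lambda * (1 - a) * b
    b_new <- b - eta * gb
    thr <- eta * lambda * a
    b_new <- sign(b_new) * pmax(abs(b_new) - thr, 0)
    b0_new <- b0 + eta * mean(y - b0 - drop(X %*% b_new))
    obj_new <- oracle_enet_objective(X, y, b0_new, b_new, a, lambda)
    conv <- abs(obj - obj_new) < tol
    b <- b_new; b0 <- b0_new; obj <- obj_new
    if (conv && it > 100) break
  }
  list(intercept = b0, beta = b, objective = obj)
}

# Exhaustive leave-one-out evaluation of a penalty grid, using squared
# prediction error, mirroring the stated selection procedure directly.
oracle_loo_select <- function(X, y, a, grid) {
  n <- nrow(X)
  errs <- sapply(grid, function(lam) {
    mean(sapply(seq_len(n), function(i) {
      f <- amlsig::fit_penalized(X[-i, , drop = FALSE], y[-i], "gaussian",
                                 a, lam)
      (y[i] - (f$intercept + sum(X[i, ] * f$beta)))^2
    }))
  })
  grid[which(errs <= min(errs) + 1e-12)[1L]]
}

# Adjusted Rand index straight from the contingency-table formula.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Benjamini-Hochberg step-up from its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Spearman correlation as rank-then-Pearson with average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Random PCSF instance on n nodes (plain PPI-style graph).
random_pcsf_instance <- function(n = 8, density = 0.45, cost_range = c(0.1, 2),
                                 prize_prob = 0.5, prize_range = c(0, 3)) {
  el <- t(utils::combn(n, 2))
  el <- el[stats::runif(nrow(el)) < density, , drop = FALSE]
  if (nrow(el) == 0L) el <- matrix(c(1, 2), 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("n", el[, 1]), to = paste0("n", el[, 2]),
               cost = stats::runif(nrow(el), cost_range[1], cost_range[2]),
               kind = "ppi"),
    directed = FALSE, vertices = data.frame(name = paste0("n", seq_len(n))))
  prizes <- stats::setNames(
    ifelse(stats::runif(n) < prize_prob,
           stats::runif(n, prize_range[1], prize_range[2]), 0),
    paste0("n", seq_len(n)))
  list(graph = g, prizes = prizes)
}

# An edge set is a forest iff every connected component it spans satisfies
# |E| = |V| - 1 (checked component-wise via igraph).
expect_forest <- function(result) {
  if (nrow(result$edges) == 0L) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(result$edges[, c("from", "to")],
                                     directed = FALSE)
  testthat::expect_false(igraph::any_loop(g))
  testthat::expect_equal(igraph::ecount(g),
                         igraph::vcount(g) - igraph::count_components(g))
  invisible(TRUE)
}
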