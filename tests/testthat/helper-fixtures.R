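# Small shared fixtures, built in code at test time.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(n_genes = 60, n_drugs = 4,
                                              seed = 101))
    cache
  }
})

toy_omics <- function(vals, modality = "protein",
                      features = sprintf("G%02d", seq_len(nrow(vals))),
                      samples = sprintf("S%02d", seq_len(ncol(vals)))) {
  dimnames(vals) <- list(features, samples)
  omics_matrix(vals, modality)
}

# planted linear problem: y depends on the first k columns only
planted_problem <- function(n = 38, p = 200, k = 5, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  X <- scale(X)
  beta <- c(runif(k, 1, 2) * sample(c(-1, 1), k, TRUE), rep(0, p - k))
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  attr(X, "modality") <- rep("protein", p)
  attr(X, "feature") <- colnames(X)
  list(X = X, y = y, support = colnames(X)[seq_len(k)], beta = beta)
}
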