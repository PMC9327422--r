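#' Model specification for penalized drug-response regression
#'
#' Three model families are supported, all solving the elastic-net problem
#' \deqn{\min_{\beta_0,\beta} f(\beta_0,\beta) +
#'   \lambda[(1-a)\|\beta\|_2^2/2 + a\|\beta\|_1]}
#' where `f` is the mean squared error over `2` (lasso, elastic net) or the
#' average binomial deviance (logistic, on AUC binarized at 100). The mixing
#' parameter `a` is fixed per family (lasso 1, elastic net 0.5, logistic 1)
#' and the penalty strength `lambda` is tuned by inner leave-one-out
#' cross-validation over a log-spaced path. Allowed modality combinations
#' are each singleton, transcript+protein, protein+phosphosite, and all
#' four.
#'
#' @param family `"lasso"`, `"elasticnet"`, or `"logistic"`.
#' @param modalities character vector of modalities to combine.
#' @param a elastic-net mixing in (0, 1]; defaults by family.
#' @param lambda optional decreasing penalty grid; computed from the data
#'   when absent.
#' @return validated `model_spec` list.
#' @export
model_spec <- function(family = c("lasso", "elasticnet", "logistic"),
                       modalities = "protein", a = NULL, lambda = NULL) {
  family <- match.arg(family)
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  allowed <- c(lapply(MODALITIES, identity),
               list(c("transcript", "protein"),
                    c("protein", "phosphosite"),
                    MODALITIES))
  if (!any(vapply(allowed, function(x) setequal(x, modalities), logical(1))))
    stop_field("modalities", paste("unsupported combination:",
                                   paste(modalities, collapse = "+")))
  if (is.null(a)) a <- switch(family, lasso = 1, elasticnet = 0.5, logistic = 1)
  if (family == "lasso" && a != 1) stop_field("a", "lasso forces a = 1")
  if (a <= 0 || a > 1) stop_field("a", "must lie in (0, 1]")
  if (!is.null(lambda) && (any(lambda < 0) || is.unsorted(rev(lambda))))
    stop_field("lambda", "must be a decreasing nonnegative grid")
  structure(list(family = family,
                 modalities = MODALITIES[MODALITIES %in% modalities],
                 a = a, lambda = lambda),
            class = "model_spec")
}

#' Cross-validation configuration
#'
#' Outer K-fold cross-validation (default K = 5) with a fixed leave-one-out
#' inner loop for penalty selection; held-out performance is the Spearman
#' correlation between predicted and observed response (for logistic,
#' between predicted probability and observed label).
#'
#' @param outer_k number of outer folds (>= 2).
#' @param seed integer seed controlling the outer fold partition.
#' @return validated `cv_config` list.
#' @export
cv_config <- function(outer_k = 5L, seed = 1L) {
  if (outer_k < 2L) stop_field("outer_k", "must be >= 2")
  structure(list(outer_k = as.integer(outer_k), metric = "spearman",
                 seed = as.integer(seed)),
            class = "cv_config")
}

glmnet_family <- function(family)
  switch(family, lasso = , elasticnet = "gaussian", logistic = "binomial",
         gaussian = "gaussian", binomial = "binomial",
         stop("unknown family: ", family))

#' Assemble a standardized multi-modality design matrix
#'
#' Stacks the requested modality matrices (samples as rows), restricted to
#' the samples shared by all of them (optionally intersected with
#' `use_samples`), and standardizes every column to mean 0, unit sample
#' variance. Constant columns cannot be standardized and are dropped with a
#' warning. Column names are prefixed `modality:feature`; the per-column
#' modality and bare feature id are retained as attributes.
#'
#' @param cohort a `multi_omic_cohort`.
#' @param modalities modalities to include.
#' @param use_samples optional sample ids to restrict to (e.g. samples with
#'   a response measurement for the modeled drug).
#' @return numeric matrix with attributes `modality` and `feature`.
#' @export
assemble_features <- function(cohort, modalities, use_samples = NULL) {
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  stopifnot(all(modalities %in% names(cohort)))
  shared <- Reduce(intersect, lapply(cohort[modalities], samples))
  if (!is.null(use_samples)) shared <- intersect(shared, use_samples)
  if (length(shared) == 0L) stop("empty sample intersection", call. = FALSE)
  blocks <- lapply(modalities, function(m) {
    v <- t(cohort[[m]]$values[, shared, drop = FALSE])
    colnames(v) <- paste(m, colnames(v), sep = ":")
    v
  })
  X <- do.call(cbind, blocks)
  mod <- rep(modalities, vapply(blocks, ncol, integer(1)))
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(const)))
    X <- X[, !const, drop = FALSE]
    mod <- mod[!const]
  }
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  attr(X, "modality") <- mod
  attr(X, "feature") <- sub("^[a-z]+:", "", colnames(X))
  X
}

# For gaussian fits glmnet internally rescales the response by its
# population SD, which silently divides the ridge part of the penalty by
# that SD. Reparametrizing with c = a + (1 - a) * sd_n(y), alpha' = a / c
# and lambda' = lambda * c makes the returned solution minimize the
# documented objective (1/2n)RSS + lambda[(1-a)/2 |b|_2^2 + a |b|_1]
# exactly, uniformly along the path (c does not depend on lambda).
enet_reparam <- function(y, family, a) {
  if (family != "gaussian" || a == 1) return(list(scale = 1, alpha = a))
  ys <- sqrt(mean((y - mean(y))^2))
  if (ys == 0) return(list(scale = 1, alpha = a))
  cc <- a + (1 - a) * ys
  list(scale = cc, alpha = a / cc)
}

# glmnet refuses single-column x; pad with an all-zero dummy column that can
# never be selected, and strip it from the returned coefficients.
glmnet_fit <- function(X, y, family, a, lambda = NULL, thresh = 1e-12, ...) {
  pad <- ncol(X) < 2L
  if (pad) X <- cbind(X, `.pad.` = 0)
  rp <- enet_reparam(y, family, a)
  fit <- glmnet::glmnet(X, y, family = family, alpha = rp$alpha,
                        lambda = if (is.null(lambda)) NULL
                        else lambda * rp$scale,
                        standardize = FALSE, thresh = thresh, maxit = 1e6, ...)
  attr(fit, "padded") <- pad
  attr(fit, "reparam") <- rp
  fit
}

#' Fit one penalized regression at a fixed penalty
#'
#' Thin wrapper around glmnet solving the elastic-net objective stated in
#' [model_spec()], with an unpenalized intercept and no internal
#' re-standardization (the design is standardized by
#' [assemble_features()]). Coefficients are computed exactly at the
#' requested penalty.
#'
#' @param X design matrix (samples x features).
#' @param y response vector; for `"binomial"`, 0/1 with both classes
#'   present.
#' @param family `"gaussian"` or `"binomial"` (model-spec families map via
#'   lasso/elasticnet -> gaussian, logistic -> binomial).
#' @param a elastic-net mixing in (0, 1].
#' @param lambda penalty strength (>= 0).
#' @return list with `intercept` and named `beta` (all columns, zeros
#'   included).
#' @export
fit_penalized <- function(X, y, family = c("gaussian", "binomial"),
                          a = 1, lambda) {
  family <- match.arg(family)
  stopifnot(lambda >= 0, length(y) == nrow(X))
  if (family == "binomial" && length(unique(y)) < 2L)
    stop("single-class response: fold is not discretizable", call. = FALSE)
  fit <- glmnet_fit(X, y, family, a)
  rp <- attr(fit, "reparam")
  # suppressWarnings: approx() inside coef.glmnet chatters about collapsing
  # duplicated path values before the exact refit; harmless
  cf <- suppressWarnings(
    glmnet::coef.glmnet(fit, s = lambda * rp$scale, exact = TRUE,
                        x = if (attr(fit, "padded")) cbind(X, `.pad.` = 0) else X,
                        y = y, family = family, alpha = rp$alpha,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e6))
  beta <- as.numeric(cf)[-1L]
  names(beta) <- rownames(cf)[-1L]
  beta <- beta[names(beta) != ".pad."]
  list(intercept = as.numeric(cf)[1L], beta = beta)
}

#' Elastic-net objective and KKT residual
#'
#' `enet_objective` evaluates the penalized objective; `kkt_residual`
#' returns the maximum violation of the subgradient optimality conditions
#' (a correct solution has residual ~0). Both are used to verify fits
#' against independent minimizers.
#'
#' @inheritParams fit_penalized
#' @param intercept,beta fitted coefficients.
#' @return a single number.
#' @export
enet_objective <- function(X, y, intercept, beta, family = "gaussian",
                           a = 1, lambda = 0) {
  n <- nrow(X)
  eta <- drop(intercept + X %*% beta)
  loss <- if (family == "gaussian") sum((y - eta)^2) / (2 * n)
  else sum(log1p(exp(eta)) - y * eta) / n
  loss + lambda * ((1 - a) * sum(beta^2) / 2 + a * sum(abs(beta)))
}

#' @rdname enet_objective
#' @export
kkt_residual <- function(X, y, intercept, beta, family = "gaussian",
                         a = 1, lambda = 0) {
  n <- nrow(X)
  eta <- drop(intercept + X %*% beta)
  resid <- if (family == "gaussian") eta - y else 1 / (1 + exp(-eta)) - y
  g <- drop(crossprod(X, resid)) / n + lambda * (1 - a) * beta
  nz <- beta != 0
  viol <- numeric(length(beta))
  viol[nz] <- abs(g[nz] + lambda * a * sign(beta[nz]))
  viol[!nz] <- pmax(0, abs(g[!nz]) - lambda * a)
  max(abs(mean(resid)), viol)
}

#' Construct the default penalty path
#'
#' 50 log-spaced values from the null-model threshold `lambda_max` (above
#' which every coefficient is zero) down to `1e-3 * lambda_max`.
#'
#' @inheritParams fit_penalized
#' @param nlambda path length.
#' @param ratio smallest-to-largest penalty ratio.
#' @return decreasing numeric vector.
#' @export
lambda_path <- function(X, y, family = "gaussian", a = 1, nlambda = 50L,
                        ratio = 1e-3) {
  n <- nrow(X)
  r <- if (family == "gaussian") y - mean(y) else y - mean(y)
  lmax <- max(abs(crossprod(X, r))) / (n * max(a, 1e-3))
  if (!is.finite(lmax) || lmax <= 0)
    stop("degenerate penalty path (constant response?)", call. = FALSE)
  exp(seq(log(lmax), log(ratio * lmax), length.out = nlambda))
}

#' Select the penalty by leave-one-out cross-validation
#'
#' Evaluates the full penalty path by leave-one-out prediction error
#' (squared error for gaussian, binomial deviance for logistic) on the
#' training set and returns the error-minimizing penalty, with ties broken
#' toward the larger (sparser) penalty. Leave-one-out iterations whose
#' training response is single-class (logistic) are skipped.
#'
#' @inheritParams fit_penalized
#' @param lambda optional penalty grid; defaults to [lambda_path()].
#' @return list with `lambda` (selected), `path`, and `cv_error` (mean LOO
#'   error per path value).
#' @export
select_penalty_loo <- function(X, y, family = c("gaussian", "binomial"),
                               a = 1, lambda = NULL) {
  family <- match.arg(family)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 training samples", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_path(X, y, family, a)
  err <- matrix(NA_real_, n, length(lambda))
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (family == "binomial" && length(unique(yi)) < 2L) next
    # selection only compares prediction errors across the path; a looser
    # solver threshold than the final fits use is ample here
    fit <- glmnet_fit(X[-i, , drop = FALSE], yi, family, a, lambda = lambda,
                      thresh = 1e-9)
    newx <- X[i, , drop = FALSE]
    if (attr(fit, "padded")) newx <- cbind(newx, `.pad.` = 0)
    # suppress approx()'s tie-collapsing chatter when glmnet stops the
    # path early and interpolates the remaining penalty values
    pred <- drop(suppressWarnings(
      stats::predict(fit, newx = newx,
                     s = lambda * attr(fit, "reparam")$scale,
                     type = "response")))
    err[i, ] <- if (family == "gaussian") (y[i] - pred)^2 else {
      p <- pmin(pmax(pred, 1e-10), 1 - 1e-10)
      -2 * (y[i] * log(p) + (1 - y[i]) * log(1 - p))
    }
  }
  if (all(is.na(err)))
    stop("no valid leave-one-out iteration (all single-class)", call. = FALSE)
  cv <- colMeans(err, na.rm = TRUE)
  best <- which(cv <= min(cv) + 1e-12)[1L]  # path decreasing: first = largest
  list(lambda = lambda[best], path = lambda, cv_error = cv)
}

fold_assignment <- function(y, k, stratify, seed) {
  set.seed(seed)
  n <- length(y)
  folds <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

#' Nested cross-validation of one model specification
#'
#' Outer K-fold cross-validation with a seeded partition (stratified by
#' class for logistic models); within each outer training set the penalty is
#' selected by leave-one-out, the model refit, and the held-out Spearman
#' correlation between predictions and observations recorded. Models for
#' which any refit selects zero features, or any fold score is undefined
#' (fewer than 2 held-out samples, zero-variance held-out response or
#' constant predictions), are flagged excluded and carry no mean score.
#'
#' @param X design matrix from [assemble_features()].
#' @param y response (already binarized for logistic).
#' @param spec a [model_spec()].
#' @param cv a [cv_config()].
#' @return `fit_result`: list with `fold_scores`, `fold_lambdas`,
#'   `mean_score`, `excluded`, `reason`, `n`, `spec`.
#' @export
evaluate_nested_cv <- function(X, y, spec, cv = cv_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(cv, "cv_config"))
  fam <- glmnet_family(spec$family)
  n <- length(y)
  res <- list(fold_scores = rep(NA_real_, cv$outer_k),
              fold_lambdas = rep(NA_real_, cv$outer_k),
              mean_score = NA_real_, excluded = TRUE, reason = NA_character_,
              n = n, spec = spec)
  class(res) <- "fit_result"
  if (n < cv$outer_k) {
    res$reason <- "fewer samples than outer folds"
    return(res)
  }
  folds <- fold_assignment(y, cv$outer_k, fam == "binomial", cv$seed)
  reasons <- character(0)
  for (f in seq_len(cv$outer_k)) {
    tr <- folds != f
    score <- tryCatch({
      sel <- select_penalty_loo(X[tr, , drop = FALSE], y[tr], fam, spec$a,
                                spec$lambda)
      fit <- fit_penalized(X[tr, , drop = FALSE], y[tr], fam, spec$a,
                           sel$lambda)
      res$fold_lambdas[f] <- sel$lambda
      if (all(fit$beta == 0)) {
        reasons <- c(reasons, sprintf("fold %d selected zero features", f))
        NA_real_
      } else if (sum(!tr) < 2L) {
        reasons <- c(reasons, sprintf("fold %d has < 2 held-out samples", f))
        NA_real_
      } else {
        pred <- drop(fit$intercept + X[!tr, , drop = FALSE] %*% fit$beta)
        if (fam == "binomial") pred <- 1 / (1 + exp(-pred))
        s <- spearman(pred, y[!tr])
        if (is.na(s))
          reasons <- c(reasons,
                       sprintf("fold %d score undefined (constant values)", f))
        s
      }
    }, error = function(e) {
      reasons <<- c(reasons, sprintf("fold %d: %s", f, conditionMessage(e)))
      NA_real_
    })
    res$fold_scores[f] <- score
  }
  if (anyNA(res$fold_scores)) {
    res$excluded <- TRUE
    res$reason <- paste(reasons, collapse = "; ")
  } else {
    res$excluded <- FALSE
    res$mean_score <- mean(res$fold_scores)
  }
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s on %s, n=%d: %s\n", x$spec$family,
              paste(x$spec$modalities, collapse = "+"), x$n,
              if (x$excluded) paste("excluded -", x$reason)
              else sprintf("mean held-out Spearman = %.3f", x$mean_score)))
  invisible(x)
}

#' Extract a drug signature by refitting on all samples
#'
#' The penalty is selected by leave-one-out on all samples, the model refit
#' on all samples, and the nonzero coefficients returned with their modality
#' tags — the feature set the model uses for this drug.
#'
#' @inheritParams evaluate_nested_cv
#' @param drug optional drug id recorded in the signature.
#' @return `signature` object: list with `drug`, `spec`, `lambda`,
#'   `intercept`, and `features` (data.frame `feature`, `modality`,
#'   `coefficient`, all nonzero).
#' @export
extract_signature <- function(X, y, spec, drug = NA_character_) {
  stopifnot(inherits(spec, "model_spec"))
  fam <- glmnet_family(spec$family)
  sel <- select_penalty_loo(X, y, fam, spec$a, spec$lambda)
  fit <- fit_penalized(X, y, fam, spec$a, sel$lambda)
  nz <- which(fit$beta != 0)
  if (length(nz) == 0L)
    stop("empty signature: model selected zero features", call. = FALSE)
  structure(list(
    drug = drug, spec = spec, lambda = sel$lambda, intercept = fit$intercept,
    features = data.frame(feature = attr(X, "feature")[nz],
                          modality = attr(X, "modality")[nz],
                          coefficient = unname(fit$beta[nz]),
                          stringsAsFactors = FALSE)),
    class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("<drug_signature> %s: %d features (%s, lambda=%.4g)\n",
              x$drug, nrow(x$features), x$spec$family, x$lambda))
  invisible(x)
}

#' Compare model families and modality combinations across drugs
#'
#' Runs [evaluate_nested_cv()] for every (drug, spec) pair and tabulates the
#' mean held-out Spearman scores. Excluded models appear flagged, never
#' silently dropped. Samples missing the drug's AUC are dropped for that
#' drug only.
#'
#' @param cohort a `multi_omic_cohort`.
#' @param response a [drug_response()].
#' @param drugs drug ids to model (pre-filter with [filter_drugs()]).
#' @param specs list of [model_spec()] objects.
#' @param cv a [cv_config()].
#' @param auc_threshold binarization cutoff for logistic models.
#' @return data.frame with one row per (drug, family, modalities):
#'   `mean_score`, per-fold scores (semicolon-joined), `n_samples`,
#'   `excluded`, `reason`.
#' @export
compare_models <- function(cohort, response, drugs, specs, cv = cv_config(),
                           auc_threshold = 100) {
  stopifnot(inherits(response, "drug_response"))
  rows <- list()
  for (d in drugs) {
    auc <- response$auc[d, ]
    have <- names(auc)[!is.na(auc)]
    for (spec in specs) {
      X <- suppressWarnings(
        assemble_features(cohort, spec$modalities, use_samples = have))
      yv <- auc[rownames(X)]
      y <- if (spec$family == "logistic")
        binarize_response(yv, auc_threshold) else unname(yv)
      fit <- evaluate_nested_cv(X, y, spec, cv)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, family = spec$family,
        modalities = paste(spec$modalities, collapse = "+"),
        mean_score = fit$mean_score,
        fold_scores = paste(sprintf("%.4f", fit$fold_scores), collapse = ";"),
        n_samples = fit$n, excluded = fit$excluded,
        reason = fit$reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median held-out score by family and by modality combination
#'
#' @param tbl output of [compare_models()].
#' @return list of two data.frames: `by_family` and `by_modalities`, median
#'   `mean_score` over non-excluded models plus counts.
#' @export
summarize_comparison <- function(tbl) {
  ok <- tbl[!tbl$excluded & !is.na(tbl$mean_score), , drop = FALSE]
  agg <- function(key) {
    med <- tapply(ok$mean_score, ok[[key]], stats::median)
    data.frame(group = names(med), median_score = as.numeric(med),
               n_models = as.integer(table(ok[[key]])[names(med)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(by_family = agg("family"), by_modalities = agg("modalities"))
}
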