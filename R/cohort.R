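#' Drug retention filter configuration
#'
#' A drug is kept when enough samples respond to it: at least
#' `max(ceiling(min_fraction * n), min_count)` of its `n` non-missing samples
#' must show an AUC below `auc_threshold`. With the defaults this is the
#' "at least 10% or 2 samples, whichever is greater, with AUC below 100"
#' rule; `n` counts non-missing measurements because panel coverage varies
#' by drug. The 10% is rounded up ("at least" semantics) — both choices are
#' configurable.
#'
#' @param auc_threshold AUC below which a sample counts as sensitive
#'   (default 100).
#' @param min_fraction minimum fraction of non-missing samples that must be
#'   sensitive (default 0.10).
#' @param min_count minimum absolute number of sensitive samples (default 2).
#' @return validated `filter_config` list.
#' @export
filter_config <- function(auc_threshold = 100, min_fraction = 0.10,
                          min_count = 2L) {
  if (auc_threshold <= 0) stop_field("auc_threshold", "must be > 0")
  if (min_fraction <= 0 || min_fraction >= 1)
    stop_field("min_fraction", "must lie in (0, 1)")
  if (min_count < 1L) stop_field("min_count", "must be >= 1")
  structure(list(auc_threshold = auc_threshold, min_fraction = min_fraction,
                 min_count = as.integer(min_count)),
            class = "filter_config")
}

#' Filter the drug panel by response prevalence
#'
#' @param response a [drug_response()] table.
#' @param cfg a [filter_config()].
#' @return sorted character vector of retained drug ids. Drugs with zero
#'   non-missing measurements are excluded with a warning.
#' @examples
#' auc <- matrix(c(50, 60, 150, 150, 150, 150), 2, 3, byrow = TRUE,
#'               dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' filter_drugs(drug_response(auc), filter_config())
#' @export
filter_drugs <- function(response, cfg = filter_config()) {
  stopifnot(inherits(response, "drug_response"))
  if (nrow(response$auc) == 0L) stop("empty response table", call. = FALSE)
  keep <- vapply(rownames(response$auc), function(d) {
    v <- response$auc[d, ]
    n <- sum(!is.na(v))
    if (n == 0L) {
      warning(sprintf("drug %s has no non-missing AUC values; excluded", d))
      return(FALSE)
    }
    need <- max(ceiling(cfg$min_fraction * n), cfg$min_count)
    sum(v < cfg$auc_threshold, na.rm = TRUE) >= need
  }, logical(1))
  sort(rownames(response$auc)[keep])
}

#' Binarize drug response for logistic models
#'
#' AUC above the threshold is coded 1 (resistant), below 0 (sensitive).
#' A value exactly at the threshold is coded resistant, because "sensitive"
#' is defined strictly as AUC below the threshold. Missing stays missing.
#'
#' @param auc numeric vector of AUC values (NA allowed).
#' @param threshold resistance cutoff (default 100).
#' @return integer vector of 0/1 (NA preserved).
#' @export
binarize_response <- function(auc, threshold = 100) {
  stopifnot(all(is.finite(auc) | is.na(auc)))
  as.integer(auc >= threshold)
}

#' Cross-modality correlation summaries
#'
#' Matches the features of two omics matrices by gene (phosphosites are
#' matched to their parent protein via the `GENE-pS123` id prefix) and
#' computes Spearman correlations over the shared samples, either per
#' matched feature or pooled over all matched (feature, sample) pairs
#' jointly. Spearman uses average ranks for ties throughout.
#'
#' @param a,b [omics_matrix()] objects sharing at least 3 samples.
#' @param level `"per_feature"` or `"pooled"`.
#' @return for `per_feature`, a data.frame with one row per matched feature
#'   pair (`feature_a`, `feature_b`, `rho`, `n`); features with fewer than 3
#'   complete pairs get `NA` rho. For `pooled`, a one-row data.frame with
#'   `rho` and `n` (total pairs used).
#' @export
modality_correlation <- function(a, b, level = c("per_feature", "pooled")) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  level <- match.arg(level)
  shared <- intersect(samples(a), samples(b))
  if (length(shared) < 3L) stop("matrices share fewer than 3 samples", call. = FALSE)
  ga <- feature_gene(features(a), a$modality)
  gb <- feature_gene(features(b), b$modality)
  # all (feature_a, feature_b) pairs mapping to the same gene
  ib <- split(seq_along(gb), gb)
  hits <- which(ga %in% names(ib) & !is.na(ga))
  pairs <- do.call(rbind, lapply(hits, function(i)
    cbind(i, ib[[ga[i]]])))
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no features could be matched by gene id", call. = FALSE)
  va <- a$values[pairs[, 1], shared, drop = FALSE]
  vb <- b$values[pairs[, 2], shared, drop = FALSE]
  if (level == "pooled") {
    ok <- is.finite(va) & is.finite(vb)
    data.frame(rho = spearman(va[ok], vb[ok]), n = sum(ok))
  } else {
    rho <- vapply(seq_len(nrow(pairs)), function(k)
      spearman(va[k, ], vb[k, ]), numeric(1))
    n <- vapply(seq_len(nrow(pairs)), function(k)
      sum(is.finite(va[k, ]) & is.finite(vb[k, ])), integer(1))
    data.frame(feature_a = features(a)[pairs[, 1]],
               feature_b = features(b)[pairs[, 2]],
               rho = rho, n = n, stringsAsFactors = FALSE, row.names = NULL)
  }
}
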