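#' @keywords internal
"_PACKAGE"

MODALITIES <- c("mutation", "transcript", "protein", "phosphosite")

#' Parse phosphosite identifiers
#'
#' Site ids follow the `"GENE-pS123"` convention: parent gene symbol, a dash,
#' `p`, the residue letter (S/T/Y) and the position. The parent protein of a
#' site is recovered by parsing this prefix.
#'
#' @param ids character vector of site ids.
#' @return data.frame with columns `site`, `gene`, `residue`, `position`;
#'   rows with unparseable ids carry `NA` in the derived columns.
#' @examples
#' parse_site_ids(c("TP53-pS15", "FLT3-pY589"))
#' @export
parse_site_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)-p([STY])([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  gene <- residue <- rep(NA_character_, length(ids))
  pos <- rep(NA_integer_, length(ids))
  ok <- which(!bad)
  if (length(ok)) {
    gene[ok] <- vapply(m[ok], `[`, "", 2L)
    residue[ok] <- vapply(m[ok], `[`, "", 3L)
    pos[ok] <- as.integer(vapply(m[ok], `[`, "", 4L))
  }
  data.frame(site = ids, gene = gene, residue = residue, position = pos,
             stringsAsFactors = FALSE)
}

#' Map a feature id to its gene symbol
#'
#' Phosphosite ids are reduced to their parent gene; all other modalities use
#' the feature id as the gene symbol directly.
#' @param ids feature ids.
#' @param modality one of `mutation`, `transcript`, `protein`, `phosphosite`.
#' @return character vector of gene symbols (`NA` for unparseable sites).
#' @export
feature_gene <- function(ids, modality) {
  if (identical(modality, "phosphosite")) parse_site_ids(ids)$gene else ids
}

# Deterministic per-stage seed derived from a global seed and a stage name.
# Polynomial string hash folded into the positive 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# Spearman correlation with average ranks; NA if fewer than 3 complete pairs
# or either side is constant.
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
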