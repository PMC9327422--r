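#' Omics matrix container
#'
#' A single-modality measurement matrix with features as rows and samples as
#' columns, the orientation used by all on-disk TSVs. Modality-specific
#' invariants are enforced at construction: mutation matrices must be strictly
#' 0/1 and transcript matrices nonnegative; duplicate sample or feature ids
#' are rejected for every modality.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param modality one of `"mutation"`, `"transcript"`, `"protein"`,
#'   `"phosphosite"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, modality) {
  modality <- match.arg(modality, MODALITIES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  obs <- values[!is.na(values)]
  if (modality == "mutation" && !all(obs %in% c(0, 1)))
    stop("mutation matrix must contain only 0/1 values", call. = FALSE)
  if (modality == "transcript" && any(obs < 0))
    stop("transcript matrix must be nonnegative", call. = FALSE)
  structure(list(modality = modality, values = values),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d samples\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample and feature ids of an omics matrix
#' @param x an `omics_matrix`.
#' @return character vector of ids.
#' @export
samples <- function(x) UseMethod("samples")
#' @export
samples.omics_matrix <- function(x) colnames(x$values)
#' @rdname samples
#' @export
features <- function(x) UseMethod("features")
#' @export
features.omics_matrix <- function(x) rownames(x$values)

#' Drug response (AUC) table
#'
#' Drug x sample matrix of dose-response AUC values. Low AUC means the sample
#' is sensitive to the drug, high AUC resistant. Missing entries (`NA`) mark
#' drug/sample combinations that were not assayed; present values must be
#' finite and nonnegative.
#'
#' @param auc numeric matrix, drugs x samples, with dimnames.
#' @return an object of class `drug_response`.
#' @export
drug_response <- function(auc) {
  if (!is.matrix(auc) || !is.numeric(auc))
    stop("`auc` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(auc)) || is.null(colnames(auc)))
    stop("`auc` must have drug rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(auc)) || anyDuplicated(colnames(auc)))
    stop("duplicate drug or sample ids", call. = FALSE)
  obs <- auc[!is.na(auc)]
  if (any(!is.finite(obs))) stop("AUC values must be finite where present", call. = FALSE)
  if (any(obs < 0)) stop("AUC values must be nonnegative", call. = FALSE)
  structure(list(auc = auc), class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("<drug_response> %d drugs x %d samples (%.0f%% missing)\n",
              nrow(x$auc), ncol(x$auc), 100 * mean(is.na(x$auc))))
  invisible(x)
}

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop(sprintf("%s: need a header and at least one feature row", path),
         call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ids <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n <- length(ids)
  vals <- matrix(NA_real_, length(rows), n)
  rn <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != n + 1L)
      stop(sprintf("%s: line %d has %d fields, expected %d", path, i + 1L,
                   length(r), n + 1L), call. = FALSE)
    rn[i] <- r[1L]
    v <- suppressWarnings(as.numeric(r[-1L]))
    bad <- which(is.na(v) & !(r[-1L] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("%s: line %d: non-numeric value '%s'", path, i + 1L,
                   r[-1L][bad[1L]]), call. = FALSE)
    vals[i, ] <- v
  }
  dimnames(vals) <- list(rn, ids)
  vals
}

#' Read / write an omics matrix as TSV
#'
#' TSV layout: first column holds feature ids, remaining columns one sample
#' each, header row carries the sample ids. `read_matrix(write_matrix(m))`
#' round-trips exactly. Invalid input (duplicate ids, non-numeric cells,
#' modality-invariant violations) raises a descriptive error with the
#' offending line, never a silently coerced matrix.
#'
#' @param path TSV file path.
#' @param modality matrix modality (see [omics_matrix()]).
#' @return `read_matrix` returns an `omics_matrix`; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, modality) {
  omics_matrix(read_tsv_matrix(path), modality)
}

#' @rdname read_matrix
#' @param m an `omics_matrix` (or `drug_response` for [write_response()]).
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  write_tsv_matrix(m$values, path, "feature")
}

write_tsv_matrix <- function(vals, path, id_col) {
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a drug response table as TSV
#'
#' Same layout as [read_matrix()] with drugs as rows; empty or `NA` cells are
#' missing measurements.
#' @inheritParams read_matrix
#' @param r a `drug_response` object.
#' @return `read_response` returns a `drug_response`.
#' @export
read_response <- function(path) {
  drug_response(read_tsv_matrix(path))
}

#' @rdname read_response
#' @export
write_response <- function(r, path) {
  stopifnot(inherits(r, "drug_response"))
  write_tsv_matrix(r$auc, path, "drug")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Sets with zero members are skipped with a warning. Parsing is
#' delegated to `fgsea::gmtPathways` when fgsea is installed (with
#' post-validation, since fgsea keeps empty sets silently); otherwise a
#' built-in parser is used.
#'
#' @param path GMT file.
#' @return named list of character vectors (class `gene_sets`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
    names(sets) <- vapply(parts, `[`, "", 1L)
  }
  sets <- lapply(sets, function(s) unique(s[nzchar(s)]))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("skipping %d gene set(s) with no members: %s",
                    sum(empty), paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  structure(sets, class = "gene_sets")
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a protein-protein interaction edge list
#'
#' Three-column TSV (`node_a`, `node_b`, `confidence`) describing an
#' undirected graph. Self-loops are rejected; duplicate edges (in either
#' orientation) are collapsed keeping the maximum confidence; confidences
#' must lie strictly in (0, 1).
#'
#' @param path TSV file with a header row.
#' @return data.frame with columns `node_a`, `node_b`, `confidence`
#'   (class `ppi_edges`).
#' @export
read_edgelist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs 3 columns", call. = FALSE)
  names(df)[1:3] <- c("node_a", "node_b", "confidence")
  ppi_edges(df[, 1:3])
}

#' @rdname read_edgelist
#' @param edges data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
ppi_edges <- function(edges) {
  edges$confidence <- as.numeric(edges$confidence)
  if (any(!is.finite(edges$confidence)) ||
      any(edges$confidence <= 0 | edges$confidence >= 1))
    stop("edge confidence must lie strictly in (0, 1)", call. = FALSE)
  if (any(edges$node_a == edges$node_b))
    stop("self-loop edges are not allowed", call. = FALSE)
  # canonical orientation, then collapse duplicates keeping max confidence
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(edges$confidence, key, max)
  keys <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(keys, `[`, "", 1L),
                    node_b = vapply(keys, `[`, "", 2L),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_edges", "data.frame")
  out
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a kinase-substrate map
#'
#' Two-column TSV (`kinase`, `site`): each row annotates one phosphosite with
#' one upstream kinase. Site ids must parse as `GENE-pS123`-style strings.
#'
#' @param path TSV file with a header row.
#' @return data.frame with columns `kinase`, `site` (class `ks_map`).
#' @export
read_ks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("kinase-substrate map needs 2 columns", call. = FALSE)
  names(df)[1:2] <- c("kinase", "site")
  ks_map(df[, 1:2])
}

#' @rdname read_ks
#' @param ks data.frame with columns `kinase`, `site`.
#' @export
ks_map <- function(ks) {
  parsed <- parse_site_ids(ks$site)
  if (anyNA(parsed$gene))
    stop(sprintf("unparseable site id(s): %s",
                 paste(utils::head(ks$site[is.na(parsed$gene)], 3L),
                       collapse = ", ")), call. = FALSE)
  ks <- unique(ks[, c("kinase", "site")])
  ks <- ks[order(ks$kinase, ks$site), , drop = FALSE]
  rownames(ks) <- NULL
  class(ks) <- c("ks_map", "data.frame")
  ks
}

#' @rdname read_ks
#' @export
write_ks <- function(ks, path) {
  utils::write.table(ks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
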