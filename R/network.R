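#' Build the phosphosite-augmented interaction graph
#'
#' Starts from a protein-protein interaction network with per-edge
#' confidences, converts confidence to cost (`1 - confidence`, clipped to
#' `[0.01, 1]`), and augments it with one node per phosphosite. Each site is
#' tied to its parent protein by a `substrate_site` edge of cost `m/4` and to
#' each of its annotated kinases by a `site_kinase` edge of cost `3m/2`,
#' where `m` is the mean cost of the base PPI edges (computed before
#' augmentation, so the definition is not self-referential). Sites whose
#' parent protein is absent from the network (or whose id does not parse)
#' are dropped with a warning.
#'
#' @param ppi a [ppi_edges()] data.frame.
#' @param ks a [ks_map()] (may have zero rows).
#' @param sites character vector of phosphosite ids to add as nodes.
#' @return igraph object with vertex attribute `type`
#'   (`protein`/`phosphosite`), edge attributes `cost` and `kind`
#'   (`ppi`/`substrate_site`/`site_kinase`), and graph attribute `m`.
#' @export
build_augmented_graph <- function(ppi, ks, sites = character(0)) {
  if (is.null(ppi) || nrow(ppi) == 0L) stop("empty PPI network", call. = FALSE)
  cost <- pmin(pmax(1 - ppi$confidence, 0.01), 1)
  m <- mean(cost)
  proteins <- sort(unique(c(ppi$node_a, ppi$node_b)))
  parsed <- parse_site_ids(sites)
  ok <- !is.na(parsed$gene) & parsed$gene %in% proteins
  if (any(!ok))
    warning(sprintf("dropping %d site(s) with no parent protein in the network",
                    sum(!ok)))
  sites <- sites[ok]
  parent <- parsed$gene[ok]

  edges <- data.frame(from = ppi$node_a, to = ppi$node_b, cost = cost,
                      kind = "ppi", stringsAsFactors = FALSE)
  if (length(sites))
    edges <- rbind(edges, data.frame(from = parent, to = sites,
                                     cost = m / 4, kind = "substrate_site",
                                     stringsAsFactors = FALSE))
  if (!is.null(ks) && nrow(ks) > 0L && length(sites)) {
    kk <- ks[ks$site %in% sites & ks$kinase %in% proteins, , drop = FALSE]
    if (nrow(kk))
      edges <- rbind(edges, data.frame(from = kk$site, to = kk$kinase,
                                       cost = 3 * m / 2, kind = "site_kinase",
                                       stringsAsFactors = FALSE))
  }
  verts <- data.frame(name = c(proteins, sites),
                      type = rep(c("protein", "phosphosite"),
                                 c(length(proteins), length(sites))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  g <- igraph::set_graph_attr(g, "m", m)
  g
}

#' Assign node prizes from a drug signature
#'
#' Prizes are the absolute model coefficients normalized by the largest one,
#' so the strongest feature gets prize 1. Mutation and transcript features
#' map to the protein node of their gene, proteins to their own node, and
#' phosphosites to their site node. Members absent from the graph are
#' skipped with a warning; if none map, an error is raised.
#'
#' @param signature a `drug_signature` (or its `features` data.frame).
#' @param graph the augmented graph from [build_augmented_graph()].
#' @return named numeric vector of prizes over all graph nodes (zero for
#'   non-members).
#' @export
assign_prizes <- function(signature, graph) {
  feats <- if (inherits(signature, "drug_signature")) signature$features
  else signature
  if (is.null(feats) || nrow(feats) == 0L)
    stop("empty signature", call. = FALSE)
  nodes <- igraph::V(graph)$name
  # mutations/transcripts/proteins share the gene-named protein node;
  # phosphosites have their own node under the site id, which is the
  # feature id in both cases
  target <- feats$feature
  hit <- target %in% nodes
  if (any(!hit))
    warning(sprintf("%d signature feature(s) absent from the graph, skipped",
                    sum(!hit)))
  if (!any(hit)) stop("no signature feature maps into the graph", call. = FALSE)
  p <- stats::setNames(rep(0, length(nodes)), nodes)
  w <- abs(feats$coefficient[hit])
  for (i in seq_along(w)) {
    v <- target[hit][i]
    p[v] <- max(p[v], w[i])
  }
  p / max(p)
}
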