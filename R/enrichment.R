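#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test per set: with universe size `N`, set size
#' `K`, selection size `n` and overlap `k`, the p-value is `P(X >= k)` for
#' `X` hypergeometric `(N, K, n)`. Multiple testing is corrected by
#' Benjamini-Hochberg FDR across all tested sets; sets are flagged
#' significant at `q < q_threshold` (default 0.01). Selected members
#' outside the universe are dropped with a warning; the universe should be
#' the measured features of the relevant modality, not the whole genome.
#'
#' @param selected character vector of selected genes.
#' @param sets a `gene_sets` collection (named list).
#' @param universe character vector of background genes.
#' @param q_threshold significance cutoff on the adjusted p-value.
#' @return data.frame sorted by `q` then `p`, one row per set: `set`, `k`
#'   (overlap), `K` (set size in universe), `n` (selection size), `N`
#'   (universe size), `p`, `q`, `significant`. Empty selection gives an
#'   empty table.
#' @export
enrich_sets <- function(selected, sets, universe, q_threshold = 0.01) {
  universe <- unique(universe)
  selected <- unique(selected)
  out_of_universe <- setdiff(selected, universe)
  if (length(out_of_universe)) {
    warning(sprintf("%d selected gene(s) outside the universe dropped",
                    length(out_of_universe)))
    selected <- intersect(selected, universe)
  }
  N <- length(universe)
  n <- length(selected)
  if (n == 0L || length(sets) == 0L)
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  rows <- lapply(names(sets), function(s) {
    members <- intersect(sets[[s]], universe)
    K <- length(members)
    k <- length(intersect(selected, members))
    # upper tail P(X >= k); phyper gives P(X > k-1)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < q_threshold
  tab <- tab[order(tab$q, tab$p, tab$set), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Kinase over-representation among selected phosphosites
#'
#' Treats each kinase's annotated substrate sites (within the site universe)
#' as a gene set and applies the same hypergeometric + BH machinery as
#' [enrich_sets()]. Sites without any kinase annotation stay in the universe
#' but can never overlap a kinase set; their share of the selection is
#' reported as the `unannotated_fraction` attribute. Kinases with no
#' annotated site in the universe are skipped.
#'
#' @param selected_sites character vector of selected phosphosite ids.
#' @param ks a [ks_map()].
#' @param universe_sites character vector of all measured site ids.
#' @param q_threshold significance cutoff on the adjusted p-value.
#' @return data.frame as in [enrich_sets()] with column `set` holding the
#'   kinase, plus attribute `unannotated_fraction`.
#' @export
enrich_kinases <- function(selected_sites, ks, universe_sites,
                           q_threshold = 0.01) {
  kin_sets <- split(ks$site, ks$kinase)
  kin_sets <- lapply(kin_sets, intersect, universe_sites)
  kin_sets <- kin_sets[lengths(kin_sets) > 0L]
  tab <- enrich_sets(selected_sites, kin_sets, universe_sites, q_threshold)
  annotated <- unique(unlist(kin_sets, use.names = FALSE))
  sel <- intersect(unique(selected_sites), unique(universe_sites))
  attr(tab, "unannotated_fraction") <-
    if (length(sel)) mean(!(sel %in% annotated)) else NA_real_
  tab
}
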