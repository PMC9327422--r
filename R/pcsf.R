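#' Prize-collecting Steiner forest configuration
#'
#' The solver selects a node set `S`; the solution forest is the minimum
#' spanning forest of the subgraph induced by `S` (one tree per connected
#' component), and the objective is
#' \deqn{\beta \sum_{v \notin S} p(v) + \sum_{e \in F} c(e) + \omega \cdot
#'   (\textrm{number of trees})}
#' `omega` defaults to the mean base PPI edge cost `m` of the graph being
#' solved. Randomized runs multiply every edge cost by an independent
#' Uniform(1-delta, 1+delta) draw and aggregate per-node selection
#' frequencies; the consensus subgraph keeps nodes selected in at least
#' `consensus_fraction` of runs.
#'
#' @param beta prize scale (> 0).
#' @param omega per-tree cost (> 0); `NULL` means the graph's `m`.
#' @param n_randomizations number of noisy replicate runs (default 100).
#' @param noise_delta edge-cost noise half-width in `[0, 1)`.
#' @param consensus_fraction node frequency threshold in (0, 1].
#' @param seed integer seed.
#' @return validated `pcsf_config` list.
#' @export
pcsf_config <- function(beta = 1, omega = NULL, n_randomizations = 100L,
                        noise_delta = 0.05, consensus_fraction = 0.5,
                        seed = 1L) {
  if (beta <= 0) stop_field("beta", "must be > 0")
  if (!is.null(omega) && omega <= 0) stop_field("omega", "must be > 0")
  if (n_randomizations < 1L) stop_field("n_randomizations", "must be >= 1")
  if (noise_delta < 0 || noise_delta >= 1)
    stop_field("noise_delta", "must lie in [0, 1)")
  if (consensus_fraction <= 0 || consensus_fraction > 1)
    stop_field("consensus_fraction", "must lie in (0, 1]")
  structure(list(beta = beta, omega = omega,
                 n_randomizations = as.integer(n_randomizations),
                 noise_delta = noise_delta,
                 consensus_fraction = consensus_fraction,
                 seed = as.integer(seed)),
            class = "pcsf_config")
}

# internal flat representation of a weighted graph
graph_arrays <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  ga <- list(u = as.integer(el[, 1]), v = as.integer(el[, 2]),
             cost = igraph::E(graph)$cost,
             kind = igraph::E(graph)$kind %||% rep("ppi", nrow(el)),
             names = igraph::V(graph)$name,
             type = igraph::vertex_attr(graph, "type"),
             n = igraph::vcount(graph))
  inc <- vector("list", ga$n)
  for (i in seq_along(ga$u)) {
    inc[[ga$u[i]]] <- c(inc[[ga$u[i]]], i)
    inc[[ga$v[i]]] <- c(inc[[ga$v[i]]], i)
  }
  ga$inc <- inc
  # model constraint bookkeeping: parent protein of each phosphosite
  ga$site_parent <- rep(NA_integer_, ga$n)
  if (!is.null(ga$type)) {
    sub <- which(ga$kind == "substrate_site")
    s <- ifelse(ga$type[ga$u[sub]] == "phosphosite", ga$u[sub], ga$v[sub])
    p <- ifelse(ga$type[ga$u[sub]] == "phosphosite", ga$v[sub], ga$u[sub])
    ga$site_parent[s] <- p
  }
  ga
}

# a selected phosphosite takes part in the network only through its parent
# protein: close the node set under site -> parent
close_parents <- function(ga, S) {
  par <- ga$site_parent[S]
  union(S, par[!is.na(par)])
}

# Evaluate a node set under the model: minimum spanning forest of the
# induced subgraph (Kruskal), one tree per component.
ns_solution <- function(ga, pi_v, omega, S) {
  S <- sort(unique(S))
  if (length(S) == 0L)
    return(list(nodes = integer(0), edges = integer(0), n_trees = 0L,
                objective = sum(pi_v)))
  insel <- rep(FALSE, ga$n); insel[S] <- TRUE
  ei <- as.integer(unique(unlist(ga$inc[S], use.names = FALSE)))
  ei <- ei[insel[ga$u[ei]] & insel[ga$v[ei]]]
  comp <- seq_len(ga$n)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  keep <- integer(0)
  for (i in ei[order(ga$cost[ei], ei)]) {
    a <- find(ga$u[i]); b <- find(ga$v[i])
    if (a != b) {
      comp[a] <- b
      keep <- c(keep, i)
    }
  }
  nt <- length(unique(vapply(S, find, integer(1))))
  list(nodes = S, edges = sort(keep), n_trees = nt,
       objective = sum(pi_v[-S]) + sum(ga$cost[keep]) + omega * nt)
}

#' Recompute the PCSF objective of a solution
#'
#' @param prizes named prize vector over graph nodes.
#' @param result a `forest_result`.
#' @param beta,omega objective parameters used for the solve.
#' @return the objective value (excluded prizes + edge costs + per-tree
#'   cost).
#' @export
pcsf_objective <- function(prizes, result, beta, omega) {
  excluded <- setdiff(names(prizes), result$nodes)
  beta * sum(prizes[excluded]) + sum(result$edges$cost) +
    omega * result$n_trees
}

forest_result <- function(ga, sol, beta, omega, prizes) {
  edges <- data.frame(from = ga$names[ga$u[sol$edges]],
                      to = ga$names[ga$v[sol$edges]],
                      cost = ga$cost[sol$edges],
                      kind = ga$kind[sol$edges],
                      stringsAsFactors = FALSE, row.names = NULL)
  res <- structure(list(nodes = ga$names[sol$nodes], edges = edges,
                        n_trees = sol$n_trees, objective = NA_real_,
                        frequencies = NULL, consensus = NULL),
                   class = "forest_result")
  res$objective <- pcsf_objective(prizes, res, beta, omega)
  res
}

#' @export
print.forest_result <- function(x, ...) {
  cat(sprintf("<forest_result> %d nodes, %d edges, %d tree(s), objective %.4g\n",
              length(x$nodes), nrow(x$edges), x$n_trees, x$objective))
  invisible(x)
}

# Local search with exact objective evaluation: repeatedly apply the best of
#   add a node (prize node, or a potential Steiner point adjacent to >= 2
#   selected nodes), add a prize node together with one intermediate
#   neighbor, or remove a node (with its dependent phosphosites),
# while any move strictly lowers the objective. Candidate sets stay closed
# under the site -> parent constraint.
polish_nodeset <- function(ga, pi_v, omega, S, eps = 1e-11) {
  S <- close_parents(ga, S)
  cur <- ns_solution(ga, pi_v, omega, S)
  for (iter in seq_len(10L * (ga$n + 1L))) {
    sel <- rep(FALSE, ga$n); sel[cur$nodes] <- TRUE
    nsel_nbr <- integer(ga$n)
    for (i in seq_along(ga$u)) {
      if (sel[ga$v[i]]) nsel_nbr[ga$u[i]] <- nsel_nbr[ga$u[i]] + 1L
      if (sel[ga$u[i]]) nsel_nbr[ga$v[i]] <- nsel_nbr[ga$v[i]] + 1L
    }
    cands <- list()
    for (v in which(!sel & (pi_v > 0 | nsel_nbr >= 2L)))
      cands[[length(cands) + 1L]] <- c(cur$nodes, v)
    for (v in which(!sel & pi_v > 0)) {
      for (i in ga$inc[[v]]) {
        w <- if (ga$u[i] == v) ga$v[i] else ga$u[i]
        if (!sel[w]) cands[[length(cands) + 1L]] <- c(cur$nodes, v, w)
      }
    }
    for (v in cur$nodes) {
      drop <- c(v, which(ga$site_parent == v))
      kept <- setdiff(cur$nodes, drop)
      cands[[length(cands) + 1L]] <- kept
    }
    best <- cur
    for (S2 in cands) {
      s2 <- ns_solution(ga, pi_v, omega, close_parents(ga, S2))
      if (s2$objective < best$objective - eps) best <- s2
    }
    if (best$objective >= cur$objective - eps) break
    cur <- best
  }
  cur
}

# ---- Goemans-Williamson moat growth --------------------------------------
#
# Unrooted PCSF is reduced to rooted prize-collecting Steiner tree by adding
# a dummy root connected to every positive-prize node at cost omega.
# Clusters not containing the root stay active while they hold residual
# prize; duals grow uniformly on active clusters, edges go tight and merge
# clusters, clusters deactivate when their prize budget is exhausted.
# Afterwards the root tree is strong-pruned; the surviving node set is then
# scored under the induced-subgraph model and polished by local search
# (from both the GW start and an empty start; the better result wins).
gw_pcsf <- function(ga, prizes, beta, omega, eps = 1e-11) {
  n <- ga$n
  pi_v <- beta * prizes
  pos <- which(pi_v > 0)
  if (!length(pos))
    return(list(nodes = integer(0), edges = integer(0), n_trees = 0L,
                objective = 0))
  root <- n + 1L
  eu <- c(ga$u, rep(root, length(pos)))
  ev <- c(ga$v, pos)
  ecost <- c(ga$cost, rep(omega, length(pos)))
  ne <- length(eu)

  clust <- seq_len(n + 1L)           # node -> cluster label
  W <- c(pi_v, 0)                    # residual prize budget per cluster label
  active <- c(pi_v > eps, FALSE)
  has_root <- c(rep(FALSE, n), TRUE)
  slack <- ecost
  forest <- integer(0)

  repeat {
    if (!any(active)) break
    cu <- clust[eu]; cv <- clust[ev]
    na_sides <- (active[cu] + active[cv]) * (cu != cv)
    t_edge <- ifelse(na_sides > 0, slack / na_sides, Inf)
    act_ids <- which(active)
    t_clust <- W[act_ids]
    dt <- min(min(t_edge), min(t_clust))
    if (!is.finite(dt)) break
    slack <- slack - dt * na_sides
    W[act_ids] <- W[act_ids] - dt
    ie <- which(na_sides > 0 & slack <= eps)
    if (length(ie)) {
      # merge along the first tight edge; other ties resolve next iteration
      i <- ie[1L]
      a <- clust[eu[i]]; b <- clust[ev[i]]
      forest <- c(forest, i)
      clust[clust == b] <- a
      W[a] <- W[a] + W[b]
      has_root[a] <- has_root[a] || has_root[b]
      active[a] <- !has_root[a] && W[a] > eps
      active[b] <- FALSE
    } else {
      done <- act_ids[W[act_ids] <= eps]
      active[done] <- FALSE
    }
  }

  # BFS over forest edges from the root; only its component is kept
  adj <- vector("list", n + 1L)
  for (i in forest) {
    adj[[eu[i]]] <- c(adj[[eu[i]]], i)
    adj[[ev[i]]] <- c(adj[[ev[i]]], i)
  }
  parent_edge <- rep(NA_integer_, n + 1L)
  visited <- rep(FALSE, n + 1L)
  visited[root] <- TRUE
  queue <- root
  order_v <- integer(0)
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    order_v <- c(order_v, x)
    for (i in adj[[x]]) {
      y <- if (eu[i] == x) ev[i] else eu[i]
      if (!visited[y]) {
        visited[y] <- TRUE
        parent_edge[y] <- i
        queue <- c(queue, y)
      }
    }
  }
  # strong pruning bottom-up: keep a child subtree only if its net prize
  # strictly exceeds the cost of the edge attaching it
  net <- c(pi_v, 0)[seq_len(n + 1L)]
  keep_edge <- rep(FALSE, ne)
  for (x in rev(order_v)) {
    i <- parent_edge[x]
    if (is.na(i)) next
    p <- if (eu[i] == x) ev[i] else eu[i]
    gain <- net[x] - ecost[i]
    if (gain > eps) {
      net[p] <- net[p] + gain
      keep_edge[i] <- TRUE
    }
  }
  sel_nodes <- logical(n + 1L)
  for (x in order_v) {
    if (x == root) { sel_nodes[x] <- TRUE; next }
    i <- parent_edge[x]
    p <- if (eu[i] == x) ev[i] else eu[i]
    sel_nodes[x] <- keep_edge[i] && sel_nodes[p]
  }
  start <- which(sel_nodes[seq_len(n)])

  a <- polish_nodeset(ga, pi_v, omega, start)
  b <- polish_nodeset(ga, pi_v, omega, integer(0))
  if (a$objective <= b$objective) a else b
}

# exact solver: enumerate node subsets (respecting the site -> parent
# constraint), minimum spanning forest of each induced subgraph
exact_pcsf <- function(ga, prizes, beta, omega) {
  n <- ga$n
  if (n > 15L)
    stop("exact mode is limited to graphs with <= 15 nodes", call. = FALSE)
  pi_v <- beta * prizes
  best <- ns_solution(ga, pi_v, omega, integer(0))
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in seq_len(2^n - 1L)) {
    inset <- which(bitwAnd(mask, bits) != 0L)
    par <- ga$site_parent[inset]
    if (any(!is.na(par) & !(par %in% inset))) next
    sol <- ns_solution(ga, pi_v, omega, inset)
    if (sol$objective < best$objective - 1e-12) best <- sol
  }
  best
}

#' Solve the prize-collecting Steiner forest
#'
#' `mode = "heuristic"` runs a Goemans-Williamson-style primal-dual moat
#' growth with a dummy root (joined to every positive-prize node at cost
#' `omega`), followed by strong pruning and a local-search polish.
#' `mode = "exact"` enumerates all node subsets, scoring excluded prizes
#' plus the minimum spanning forest of the induced subgraph plus `omega`
#' per tree, and returns the optimum; it is restricted to graphs with at
#' most 15 nodes and serves as the oracle for the heuristic.
#'
#' On augmented graphs (with typed phosphosite nodes), both modes enforce
#' the model constraint that a phosphosite may only be selected together
#' with its parent protein, so a selected site always carries its
#' substrate_site edge (the cheapest edge class, m/4, which a minimum
#' spanning forest therefore always retains).
#'
#' @param graph igraph with edge attribute `cost` (> 0), e.g. from
#'   [build_augmented_graph()].
#' @param prizes named nonnegative prize vector (nodes absent from it get
#'   prize 0), e.g. from [assign_prizes()].
#' @param cfg a [pcsf_config()].
#' @param mode `"heuristic"` or `"exact"`.
#' @return a `forest_result`: selected `nodes`, `edges` (with cost and
#'   kind), `n_trees`, and the recomputed `objective`.
#' @export
solve_pcsf <- function(graph, prizes, cfg = pcsf_config(),
                       mode = c("heuristic", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "pcsf_config"))
  ga <- graph_arrays(graph)
  if (any(ga$cost <= 0)) stop("edge costs must be positive", call. = FALSE)
  p <- stats::setNames(rep(0, ga$n), ga$names)
  if (!is.null(prizes) && length(prizes)) {
    if (any(prizes < 0)) stop("prizes must be nonnegative", call. = FALSE)
    common <- intersect(names(prizes), ga$names)
    p[common] <- prizes[common]
  }
  omega <- cfg$omega %||% igraph::graph_attr(graph, "m") %||% mean(ga$cost)
  sol <- if (mode == "exact") exact_pcsf(ga, p, cfg$beta, omega)
  else gw_pcsf(ga, p, cfg$beta, omega)
  forest_result(ga, sol, cfg$beta, omega, p)
}

#' Randomized PCSF with per-node selection frequencies
#'
#' Re-solves the instance `n_randomizations` times, each time multiplying
#' every edge cost by an independent Uniform(1-delta, 1+delta) draw (seeded,
#' so runs are reproducible), and records the fraction of runs in which each
#' node was selected. The consensus subgraph is the induced subgraph on
#' nodes with frequency at least `consensus_fraction`. The returned solution
#' itself is the unperturbed base run.
#'
#' @inheritParams solve_pcsf
#' @return a `forest_result` with `frequencies` (named, all graph nodes) and
#'   `consensus` (igraph) filled in.
#' @export
randomized_pcsf <- function(graph, prizes, cfg = pcsf_config()) {
  stopifnot(inherits(cfg, "pcsf_config"))
  ga <- graph_arrays(graph)
  base <- solve_pcsf(graph, prizes, cfg, mode = "heuristic")
  p <- stats::setNames(rep(0, ga$n), ga$names)
  common <- intersect(names(prizes), ga$names)
  p[common] <- prizes[common]
  omega <- cfg$omega %||% igraph::graph_attr(graph, "m") %||% mean(ga$cost)
  counts <- stats::setNames(rep(0L, ga$n), ga$names)
  for (k in seq_len(cfg$n_randomizations)) {
    set.seed(derive_seed(cfg$seed, paste0("pcsf_rand_", k)))
    gk <- ga
    gk$cost <- ga$cost * stats::runif(length(ga$cost),
                                      1 - cfg$noise_delta,
                                      1 + cfg$noise_delta)
    sol <- gw_pcsf(gk, p, cfg$beta, omega)
    counts[sol$nodes] <- counts[sol$nodes] + 1L
  }
  base$frequencies <- counts / cfg$n_randomizations
  keep <- names(counts)[base$frequencies >= cfg$consensus_fraction]
  base$consensus <- igraph::induced_subgraph(graph, keep)
  base
}

#' Write a forest result as TSV files
#'
#' Writes the consensus (or selected) network as an edge-list TSV plus a
#' node-attribute TSV (`node`, `type`, `prize`, `frequency`) loadable by
#' standard graph viewers.
#'
#' @param result a `forest_result`.
#' @param graph the solved graph (for node types).
#' @param prizes the prize vector used.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @return invisibly, the two paths.
#' @export
write_forest <- function(result, graph, prizes, prefix) {
  edges <- if (!is.null(result$consensus))
    cbind(igraph::as_data_frame(result$consensus, "edges"))
  else result$edges
  ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- igraph::V(graph)$name
  nd <- data.frame(node = nodes,
                   type = igraph::V(graph)$type,
                   prize = as.numeric(prizes[nodes]),
                   frequency = if (!is.null(result$frequencies))
                     as.numeric(result$frequencies[nodes]) else
                       as.numeric(nodes %in% result$nodes),
                   stringsAsFactors = FALSE)
  np <- paste0(prefix, "_nodes.tsv")
  utils::write.table(nd, np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ep, np))
}
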