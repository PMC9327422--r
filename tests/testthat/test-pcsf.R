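two_node_graph <- function(cost = 1) {
  igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", cost = cost, kind = "ppi"),
    directed = FALSE)
}

test_that("the two-node instance is solved optimally by both modes", {
  # prizes 10 each, edge 1, beta 1, omega 0.5: connect both in one tree;
  # alternatives cost 20 (drop both) or 11 (one singleton) or 1+2*0.5 split
  cfg <- pcsf_config(beta = 1, omega = 0.5)
  for (mode in c("exact", "heuristic")) {
    res <- solve_pcsf(two_node_graph(), c(A = 10, B = 10), cfg, mode)
    expect_setequal(res$nodes, c("A", "B"))
    expect_equal(res$objective, 1.5)
    expect_equal(res$n_trees, 1)
  }
})

test_that("zero prizes give an empty forest with objective zero", {
  cfg <- pcsf_config(beta = 1, omega = 0.5)
  for (mode in c("exact", "heuristic")) {
    res <- solve_pcsf(two_node_graph(), c(A = 0, B = 0), cfg, mode)
    expect_length(res$nodes, 0)
    expect_equal(res$objective, 0)
  }
  expect_error(solve_pcsf(two_node_graph(cost = -1), c(A = 1, B = 1), cfg),
               "positive")
  expect_error(solve_pcsf(two_node_graph(), c(A = -1, B = 1), cfg),
               "nonnegative")
})

test_that("returned edge sets are forests and objectives recompute exactly", {
  set.seed(77)
  for (i in 1:15) {
    inst <- random_pcsf_instance(n = 9, density = 0.5)
    cfg <- pcsf_config(beta = 1, omega = runif(1, 0.2, 1.2))
    for (mode in c("heuristic", "exact")) {
      if (mode == "exact" && i > 5) next
      res <- solve_pcsf(inst$graph, inst$prizes, cfg, mode)
      expect_forest(res)
      p <- setNames(rep(0, igraph::vcount(inst$graph)),
                    igraph::V(inst$graph)$name)
      p[names(inst$prizes)] <- inst$prizes
      expect_equal(res$objective,
                   cfg$beta * sum(p[setdiff(names(p), res$nodes)]) +
                     sum(res$edges$cost) + cfg$omega * res$n_trees,
                   tolerance = 1e-10)
    }
  }
})

test_that("the exact solver never scores above any sampled valid forest", {
  set.seed(12)
  for (rep in 1:5) {
    inst <- random_pcsf_instance(n = 7, density = 0.6)
    cfg <- pcsf_config(beta = 1, omega = 0.6)
    ex <- solve_pcsf(inst$graph, inst$prizes, cfg, "exact")
    vs <- igraph::V(inst$graph)$name
    # random candidate solutions: node subset + spanning forest via MST
    for (k in 1:40) {
      sub <- sample(vs, sample(0:length(vs), 1))
      if (length(sub) == 0) {
        cand_obj <- sum(inst$prizes)
      } else {
        gi <- igraph::induced_subgraph(inst$graph, sub)
        mst <- igraph::mst(gi, weights = igraph::E(gi)$cost)
        cand_obj <- sum(inst$prizes[setdiff(vs, sub)]) +
          sum(igraph::E(mst)$cost) + cfg$omega * igraph::count_components(mst)
      }
      expect_lte(ex$objective, cand_obj + 1e-9)
    }
  }
})

test_that("noiseless randomization is degenerate and seeded runs repeat", {
  inst <- random_pcsf_instance(n = 8, density = 0.5)
  cfg0 <- pcsf_config(noise_delta = 0, n_randomizations = 10, seed = 5)
  r0 <- randomized_pcsf(inst$graph, inst$prizes, cfg0)
  expect_true(all(r0$frequencies %in% c(0, 1)))

  cfg <- pcsf_config(noise_delta = 0.05, n_randomizations = 25, seed = 6)
  r1 <- randomized_pcsf(inst$graph, inst$prizes, cfg)
  r2 <- randomized_pcsf(inst$graph, inst$prizes, cfg)
  expect_identical(r1$frequencies, r2$frequencies)

  # consensus shrinks (weakly) as the threshold rises
  n50 <- sum(r1$frequencies >= 0.5)
  n80 <- sum(r1$frequencies >= 0.8)
  expect_lte(n80, n50)
})

test_that("a planted cheap path is selected in nearly all randomizations", {
  # two high-prize endpoints joined by a cheap 3-hop path amid pricey decoys
  path_nodes <- c("P1", "I1", "I2", "P2")
  decoys <- sprintf("D%d", 1:6)
  edges <- rbind(
    data.frame(from = c("P1", "I1", "I2"), to = c("I1", "I2", "P2"),
               cost = 0.05, kind = "ppi"),
    data.frame(from = rep(c("P1", "P2"), each = 3), to = rep(decoys[1:3], 2),
               cost = 2, kind = "ppi"),
    data.frame(from = decoys[1:3], to = decoys[4:6], cost = 2, kind = "ppi"))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(path_nodes, decoys)))
  prizes <- c(P1 = 1, P2 = 1)
  cfg <- pcsf_config(beta = 5, omega = 1, n_randomizations = 100,
                     noise_delta = 0.05, seed = 9)
  res <- randomized_pcsf(g, prizes, cfg)
  expect_gte(res$frequencies[["I1"]], 0.9)
  expect_gte(res$frequencies[["I2"]], 0.9)
  expect_lt(max(res$frequencies[decoys]), 0.5)
})

test_that("selected phosphosites always carry their substrate edge", {
  # site S prize-bearing; its kinase is on the cheap side, the parent not
  edges <- data.frame(
    from = c("PAR", "KIN", "PAR"),
    to = c("KIN", "X", "X"),
    cost = c(0.5, 0.3, 0.4), kind = "ppi")
  ppi <- ppi_edges(data.frame(node_a = edges$from, node_b = edges$to,
                              confidence = 1 - edges$cost))
  ks <- ks_map(data.frame(kinase = "KIN", site = "PAR-pS1"))
  g <- build_augmented_graph(ppi, ks, sites = "PAR-pS1")
  prizes <- c("PAR-pS1" = 1, "KIN" = 1)
  for (mode in c("heuristic", "exact")) {
    res <- solve_pcsf(g, prizes, pcsf_config(beta = 5, omega = 0.5), mode)
    if ("PAR-pS1" %in% res$nodes && nrow(res$edges) > 0) {
      touching <- res$edges$from == "PAR-pS1" | res$edges$to == "PAR-pS1"
      expect_true(any(res$edges$kind[touching] == "substrate_site"))
    }
    expect_forest(res)
  }
})
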