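test_that("shortest paths match exhaustive enumeration on small graphs", {
  checked <- 0
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    rg <- random_small_graph(n, p_edge = 0.4, seed = 7000 + rep)
    if (nrow(rg$edges) == 0) next
    scores <- stats::setNames(
      sample(c(1, 0.8, 0.6), n, replace = TRUE), rg$nodes
    )
    st <- sample(rg$nodes, 2)
    oracle <- path_oracle(rg$edges, rg$nodes, st[1], st[2], scores)
    sp <- shortest_path(rg$graph, st[1], st[2], scores)
    expect_equal(sp$unweighted_len, oracle$unweighted)
    expect_equal(sp$weighted_len, oracle$weighted, tolerance = 1e-12)
    if (is.finite(sp$weighted_len)) {
      # the reported node sequence realizes the reported weighted length
      expect_identical(sp$nodes[1], st[1])
      expect_identical(sp$nodes[length(sp$nodes)], st[2])
      expect_equal(sum(scores[sp$nodes[-1]]), sp$weighted_len,
                   tolerance = 1e-12)
    }
    checked <- checked + 1
  }
  expect_gt(checked, 150)
})

test_that("weighted and unweighted lengths coincide when all scores are 1", {
  for (rep in 1:20) {
    rg <- random_small_graph(7, p_edge = 0.4, seed = 7500 + rep)
    if (nrow(rg$edges) == 0) next
    st <- sample(rg$nodes, 2)
    sp <- shortest_path(rg$graph, st[1], st[2])
    expect_equal(sp$weighted_len, sp$unweighted_len)
  }
})

test_that("a strong mediator makes a 2-hop route cheaper than its hop count", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "M"), b = c("M", "T")), directed = FALSE
  )
  sp <- shortest_path(g, "A", "T", c(M = 0.6, T = 1))
  expect_equal(sp$unweighted_len, 2)
  expect_equal(sp$weighted_len, 1.6)
  expect_identical(sp$nodes, c("A", "M", "T"))

  # direct edge with all scores 1
  g2 <- igraph::graph_from_data_frame(
    data.frame(a = "A", b = "T"), directed = FALSE
  )
  sp2 <- shortest_path(g2, "A", "T")
  expect_equal(sp2$unweighted_len, 1)
  expect_equal(sp2$weighted_len, 1)
})

test_that("disconnection yields Inf while unknown vertices are an error", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = "A", b = "B"), directed = FALSE,
    vertices = data.frame(name = c("A", "B", "C"))
  )
  sp <- shortest_path(g, "A", "C")
  expect_identical(sp$unweighted_len, Inf)
  expect_identical(sp$weighted_len, Inf)
  expect_error(shortest_path(g, "A", "Z"), "absent")
  expect_error(shortest_path(g, "A", "A"), "differ")
  expect_error(path_permutation_p(g, NULL, "A", "C", n_perm = 10, seed = 1),
               "infinite")
})

test_that("lowering an intermediate score can only shorten the weighted path", {
  for (rep in 1:20) {
    rg <- random_small_graph(8, p_edge = 0.5, seed = 7700 + rep)
    if (nrow(rg$edges) == 0) next
    st <- sample(rg$nodes, 2)
    mid <- setdiff(rg$nodes, st)[1]
    sc1 <- stats::setNames(rep(1, 8), rg$nodes)
    sc2 <- sc1; sc2[mid] <- 0.6
    w1 <- shortest_path(rg$graph, st[1], st[2], sc1)$weighted_len
    w2 <- shortest_path(rg$graph, st[1], st[2], sc2)$weighted_len
    expect_lte(w2, w1)
  }
})

test_that("rewiring preserves the degree sequence and is seed-deterministic", {
  net <- simulate_network(paste0("g", 1:80), m_attach = 2, seed = 71)
  rw <- rewire_network(net, seed = 72)
  expect_identical(igraph::degree(rw), igraph::degree(net))
  expect_identical(sort(igraph::E(rw)$confidence),
                   sort(igraph::E(net)$confidence))
  rw2 <- rewire_network(net, seed = 72)
  expect_identical(igraph::as_edgelist(rw), igraph::as_edgelist(rw2))
  rw3 <- rewire_network(net, seed = 73)
  expect_false(identical(igraph::as_edgelist(rw), igraph::as_edgelist(rw3)))
})

test_that("rewiring a 4-cycle only reaches degree-consistent simple graphs", {
  cyc <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "A")),
    directed = FALSE
  )
  # all 2-regular simple graphs on 4 labelled vertices are 4-cycles;
  # enumerate the 3 possible ones by their edge sets
  allowed <- list(
    c("A-B", "B-C", "C-D", "A-D"),
    c("A-B", "A-C", "B-D", "C-D"),
    c("A-C", "B-C", "A-D", "B-D")
  )
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
  }
  seen <- character(0)
  for (s in 1:30) {
    rw <- rewire_network(cyc, seed = s)
    expect_identical(unname(igraph::degree(rw)), rep(2, 4))
    key <- paste(canon(rw), collapse = ",")
    expect_true(key %in% vapply(allowed,
                                function(a) paste(sort(a), collapse = ","),
                                character(1)))
    seen <- union(seen, key)
  }
  expect_gt(length(seen), 1)  # the swap chain actually moves
})

test_that("a sub-2-edge network is returned unchanged", {
  g <- igraph::graph_from_data_frame(data.frame(a = "A", b = "B"),
                                     directed = FALSE)
  expect_identical(igraph::as_edgelist(rewire_network(g, seed = 1)),
                   igraph::as_edgelist(g))
})

test_that("permutation p is deterministic, batch-consistent and estimator-aware", {
  net <- simulate_network(c(paste0("g", 1:60), "S", "T"), m_attach = 2,
                          planted_edges = tibble::tibble(
                            geneA = "S", geneB = "T", confidence = 900L),
                          seed = 74)
  sc <- stats::setNames(sample(c(1, 0.8), 62, replace = TRUE),
                        igraph::V(net)$name)
  p1 <- path_permutation_p(net, sc, "S", "T", n_perm = 50, seed = 75)
  p2 <- path_permutation_p(net, sc, "S", "T", n_perm = 50, seed = 75)
  expect_identical(p1, p2)
  pb <- path_permutation_batch(net, sc, tibble::tibble(source = "S",
                                                       target = "T"),
                               n_perm = 50, seed = 75)
  expect_identical(pb$perm_p[1], p1)

  # a direct edge cannot be strictly beaten: strict-count p is exactly 0
  ps <- path_permutation_p(net, NULL, "S", "T", n_perm = 50, seed = 76,
                           weighted = FALSE, ties = "strict")
  expect_identical(ps, 0)
  # the mid-p estimator counts tied (also-direct) replicates half
  pm <- path_permutation_p(net, NULL, "S", "T", n_perm = 50, seed = 76,
                           weighted = FALSE, ties = "half")
  pl <- path_permutation_p(net, NULL, "S", "T", n_perm = 50, seed = 76,
                           weighted = FALSE, ties = "leq")
  expect_gte(pm, ps)
  expect_gte(pl, pm)
  expect_equal(pl, 2 * pm)  # no strictly-shorter replicates, only ties
})

test_that("permutation p is invariant to relabeling of the nodes", {
  net <- simulate_network(paste0("g", 1:50), m_attach = 2, seed = 77)
  sc <- stats::setNames(sample(c(1, 0.8, 0.6), 50, replace = TRUE),
                        igraph::V(net)$name)
  p_before <- path_permutation_p(net, sc, "g10", "g40", n_perm = 40, seed = 78)
  perm <- sample(igraph::V(net)$name)
  relabel <- stats::setNames(perm, igraph::V(net)$name)
  net2 <- igraph::set_vertex_attr(net, "name",
                                  value = relabel[igraph::V(net)$name])
  sc2 <- stats::setNames(sc, relabel[names(sc)])
  p_after <- path_permutation_p(net2, sc2, relabel[["g10"]], relabel[["g40"]],
                                n_perm = 40, seed = 78)
  expect_identical(p_before, p_after)
})
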