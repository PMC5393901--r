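#' Shortest path between a cis-gene and a trait gene
#'
#' Computes both path lengths used to judge whether a candidate mediator
#' gene plausibly connects a trans locus to its trait protein:
#'
#' * unweighted — minimum number of edges (breadth-first search);
#' * weighted — minimum over paths of the sum of node scores over every node
#'   the path enters (the source node's own score is excluded, so a direct
#'   edge costs `score(target)` and a two-hop path costs
#'   `score(intermediate) + score(target)`). With all scores 1 the two
#'   lengths coincide. Scores come from [trans_eqtl_scores()], so a strong
#'   trans-eQTL mediator (score 0.6) can undercut paths of equal hop count.
#'
#' @param network an undirected igraph with named vertices.
#' @param source,target distinct vertex names; an error (distinct from mere
#'   disconnection, which yields `Inf` lengths) if either is absent.
#' @param scores named numeric score vector (values in `{1, 0.8, 0.6}`);
#'   genes not named score 1. `NULL` means all scores 1.
#' @return A list of class `path_result`: `source`, `target`,
#'   `unweighted_len`, `weighted_len`, `nodes` (vertex sequence of the
#'   weighted optimum; of the unweighted one when no scores were given),
#'   both lengths `Inf` when disconnected.
#' @export
shortest_path <- function(network, source, target, scores = NULL) {
  nms <- igraph::V(network)$name
  missing_v <- setdiff(c(source, target), nms)
  if (length(missing_v) > 0) {
    abort(paste0("vertex absent from network: ",
                 paste(missing_v, collapse = ", ")))
  }
  if (identical(source, target)) abort("source and target must differ")
  du <- suppressWarnings(
    igraph::distances(network, v = source, to = target)[1, 1]
  )
  res <- list(source = source, target = target,
              unweighted_len = du, weighted_len = du, nodes = character(0))
  sc <- .full_scores(scores, nms)
  dir_g <- .directed_scored(network, sc)
  dw <- suppressWarnings(
    igraph::distances(dir_g$graph, v = source, to = target,
                      mode = "out", weights = dir_g$weights)[1, 1]
  )
  res$weighted_len <- dw
  if (is.finite(dw)) {
    vp <- suppressWarnings(igraph::shortest_paths(
      dir_g$graph, from = source, to = target, mode = "out",
      weights = dir_g$weights, output = "vpath"
    )$vpath[[1]])
    res$nodes <- igraph::V(dir_g$graph)$name[as.integer(vp)]
  }
  structure(res, class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf(
    "<path_result> %s -> %s: unweighted %s, weighted %s%s\n",
    x$source, x$target, format(x$unweighted_len), format(x$weighted_len),
    if (length(x$nodes) > 0) paste0(" via [", paste(x$nodes, collapse = " - "), "]") else ""
  ))
  invisible(x)
}

.full_scores <- function(scores, vertex_names) {
  sc <- setNames(rep(1, length(vertex_names)), vertex_names)
  if (!is.null(scores)) {
    if (inherits(scores, "data.frame")) {
      scores <- setNames(scores$score, scores$gene)
    }
    known <- intersect(names(scores), vertex_names)
    sc[known] <- scores[known]
  }
  sc
}

# expand an undirected graph to a directed one where each arc costs the
# score of the node it enters
.directed_scored <- function(network, sc) {
  el <- igraph::as_edgelist(network, names = FALSE)
  nv <- igraph::vcount(network)
  del <- rbind(el, el[, 2:1, drop = FALSE])
  g <- igraph::make_empty_graph(nv, directed = TRUE)
  g <- igraph::add_edges(g, t(del))
  igraph::V(g)$name <- igraph::V(network)$name
  list(graph = g, weights = sc[del[, 2]])
}

#' Degree-preserving rewiring of a network
#'
#' Configuration-model null for the path permutation tests: repeated double
#' edge swaps — two random edges (a,b), (c,d) become (a,d), (c,b) whenever
#' the result creates no self-loop or duplicate edge — preserve every node's
#' degree exactly. `10 * |E|` swaps are attempted. Edge confidences are
#' carried by edge-list position. Deterministic given `seed`.
#'
#' @param network an undirected igraph.
#' @param seed integer seed.
#' @return The rewired igraph (unchanged if fewer than 2 edges).
#' @export
rewire_network <- function(network, seed) {
  if (missing(seed) || is.na(seed)) abort("seed is required for rewiring")
  m <- igraph::ecount(network)
  if (m < 2) return(network)
  set.seed(as.integer(seed))
  el <- igraph::as_edgelist(network, names = FALSE)
  storage.mode(el) <- "integer"
  el2 <- rewire_edges_cpp(el, 10L * m)
  g <- igraph::make_empty_graph(igraph::vcount(network), directed = FALSE)
  g <- igraph::add_edges(g, t(el2))
  igraph::V(g)$name <- igraph::V(network)$name
  conf <- igraph::E(network)$confidence
  if (!is.null(conf)) igraph::E(g)$confidence <- conf
  g
}

#' Permutation significance of shortest paths
#'
#' For each permutation replicate `b` in `1..n_perm`, the network is rewired
#' degree-preservingly and the node-score map is permuted over nodes (both
#' from the replicate's own seed `seed + b`), and the source-target shortest
#' length is recomputed. Replicates where the pair is disconnected count as
#' not shorter. The p-value counts replicates achieving a shorter length
#' than the observed one, with the handling of exact ties set by `ties`:
#'
#' * `"half"` (default) — ties count half (the mid-p estimator). Path
#'   lengths are coarsely discrete (hop counts; sums of scores from
#'   \{1, 0.8, 0.6\}), and the plain strict count degenerates: any observed
#'   multi-hop path is "beaten" by every rewired direct edge, so all
#'   length-2 paths get the same tiny p regardless of their weighting and
#'   the test loses both calibration and its ability to distinguish a
#'   cheap weighted path from an ordinary one. Counting ties half restores
#'   both (it is the standard discreteness correction for permutation
#'   tests).
#' * `"strict"` — the plain strictly-shorter fraction.
#' * `"leq"` — shorter-or-equal count (most conservative).
#'
#' With `plus_one = TRUE` the count is shifted to (k+1)/(B+1).
#'
#' `path_permutation_p()` tests a single pair and errors when the observed
#' path is already infinite (the caller must skip such pairs);
#' `path_permutation_batch()` shares one replicate stream across many pairs
#' (identical to the single-pair value at equal `seed`) and returns `NA`
#' for pairs disconnected in the observed network.
#'
#' @param network an undirected igraph with named vertices.
#' @param scores named score vector or [trans_eqtl_scores()] tibble; ignored
#'   when `weighted = FALSE`.
#' @param source,target vertex names (single pair).
#' @param n_perm number of permutation replicates (default 1000).
#' @param seed integer base seed; replicate `b` uses `seed + b`.
#' @param weighted use the score-weighted length (default) or the plain
#'   hop count.
#' @param ties tie handling: `"half"` (default), `"strict"`, or `"leq"`.
#' @param plus_one use the (k+1)/(B+1) shift.
#' @return A p-value in `[0, 1]` (`path_permutation_p`), or a tibble with
#'   columns `source`, `target`, `observed_len`, `perm_p`
#'   (`path_permutation_batch`).
#' @export
path_permutation_p <- function(network, scores, source, target,
                               n_perm = 1000, seed, weighted = TRUE,
                               ties = c("half", "strict", "leq"),
                               plus_one = FALSE) {
  res <- path_permutation_batch(
    network, scores, tibble(source = source, target = target),
    n_perm = n_perm, seed = seed, weighted = weighted, ties = ties,
    plus_one = plus_one
  )
  if (is.na(res$perm_p[1])) {
    abort("observed path is infinite; nothing to test")
  }
  res$perm_p[1]
}

#' @rdname path_permutation_p
#' @param pairs tibble with columns `source`, `target`.
#' @export
path_permutation_batch <- function(network, scores, pairs, n_perm = 1000,
                                   seed, weighted = TRUE,
                                   ties = c("half", "strict", "leq"),
                                   plus_one = FALSE) {
  if (missing(seed) || is.na(seed)) abort("seed is required for permutation")
  ties <- match.arg(ties)
  pairs <- as_tibble(pairs)
  nms <- igraph::V(network)$name
  missing_v <- setdiff(unique(c(pairs$source, pairs$target)), nms)
  if (length(missing_v) > 0) {
    abort(paste0("vertex absent from network: ",
                 paste(missing_v, collapse = ", ")))
  }
  if (any(pairs$source == pairs$target)) {
    abort("source and target must differ")
  }
  nv <- igraph::vcount(network)
  sc <- .full_scores(if (weighted) scores else NULL, nms)
  el <- igraph::as_edgelist(network, names = FALSE)
  storage.mode(el) <- "integer"
  src_idx <- match(pairs$source, nms)
  tgt_idx <- match(pairs$target, nms)

  obs <- .pair_lengths(el, nv, sc, src_idx, tgt_idx, weighted)
  shorter <- numeric(nrow(pairs))
  tied <- numeric(nrow(pairs))
  m <- nrow(el)
  tol <- 1e-9
  for (b in seq_len(n_perm)) {
    set.seed(as.integer(seed) + b)
    el_b <- rewire_edges_cpp(el, 10L * m)
    sc_b <- if (weighted) sc[sample.int(nv)] else sc
    perm_len <- .pair_lengths(el_b, nv, sc_b, src_idx, tgt_idx, weighted)
    fin <- !is.na(perm_len) & is.finite(perm_len)
    shorter <- shorter + (fin & perm_len < obs - tol)
    tied <- tied + (fin & abs(perm_len - obs) <= tol)
  }
  k <- switch(ties,
    half = shorter + 0.5 * tied,
    strict = shorter,
    leq = shorter + tied
  )
  perm_p <- if (plus_one) (k + 1) / (n_perm + 1) else k / n_perm
  perm_p[!is.finite(obs)] <- NA_real_
  tibble(source = pairs$source, target = pairs$target,
         observed_len = obs, perm_p = perm_p)
}

# shortest lengths for index pairs on an edge matrix (1-based vertex ids)
.pair_lengths <- function(el, nv, sc, src_idx, tgt_idx, weighted) {
  if (weighted) {
    del <- rbind(el, el[, 2:1, drop = FALSE])
    g <- igraph::make_empty_graph(nv, directed = TRUE)
    g <- igraph::add_edges(g, t(del))
    w <- sc[del[, 2]]
  } else {
    g <- igraph::make_empty_graph(nv, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    w <- NULL
  }
  us <- unique(src_idx)
  ut <- unique(tgt_idx)
  d <- suppressWarnings(
    igraph::distances(g, v = us, to = ut,
                      mode = if (weighted) "out" else "all", weights = w)
  )
  d[cbind(match(src_idx, us), match(tgt_idx, ut))]
}
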