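# shared builders and independent oracles

# quick genotype matrix from a dosage matrix and minimal metadata
make_gm <- function(dosage, chrom = NULL, pos = NULL, missense = NULL,
                    coded = NULL, other = NULL) {
  m <- ncol(dosage)
  ids <- colnames(dosage)
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  variants <- tibble::tibble(
    id = ids,
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    pos = if (is.null(pos)) as.integer(seq_len(m) * 1000) else as.integer(pos),
    coded_allele = if (is.null(coded)) rep("A", m) else coded,
    other_allele = if (is.null(other)) rep("G", m) else other,
    missense = if (is.null(missense)) rep(FALSE, m) else missense
  )
  colnames(dosage) <- ids
  genotype_matrix(dosage, variants)
}

# independent HWE oracle: direct log-choose enumeration of the conditional
# distribution of heterozygote counts given allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_Aa
  nm <- min(n_a, 2 * n - n_a)
  hets <- seq(nm %% 2, nm, by = 2)
  # P(h) proportional to choose(n, h) * choose(n - h, n_aa) * 2^h;
  # normalising within the support avoids the allele-count constant
  lp <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    lchoose(n, h) + lchoose(n - h, naa) + h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# exhaustive simple-path enumeration oracle for small graphs
# edges: data.frame(a, b); scores: named vector (entered-node costs)
path_oracle <- function(edges, nodes, source, target, scores = NULL) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  if (is.null(scores)) scores <- stats::setNames(rep(1, length(nodes)), nodes)
  best_u <- Inf
  best_w <- Inf
  walk <- function(node, visited, hops, cost) {
    if (node == target) {
      best_u <<- min(best_u, hops)
      best_w <<- min(best_w, cost)
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (!(nb %in% visited)) {
        walk(nb, c(visited, nb), hops + 1, cost + scores[[nb]])
      }
    }
  }
  walk(source, source, 0, 0)
  list(unweighted = best_u, weighted = best_w)
}

# brute-force BH step-up oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * q)
  flags <- rep(FALSE, m)
  if (length(k) > 0) flags[o[seq_len(max(k))]] <- TRUE
  flags
}

# random small graph as an igraph plus its edge list
random_small_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  list(graph = g, edges = edges, nodes = nodes)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
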