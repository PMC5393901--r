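#' Simulate a confidence-scored interaction network
#'
#' Grows a scale-free graph by preferential attachment: starting from
#' `m_attach` isolated seed nodes, each new node attaches to `m_attach`
#' distinct existing nodes sampled with probability proportional to degree
#' plus one, giving exactly `m_attach * (length(genes) - m_attach)` grown
#' edges. Edge confidences are drawn uniformly from 401-1000 (all above the
#' default network confidence floor); planted edges are then added, or have
#' their confidence overwritten when the growth step already created them.
#'
#' @param genes character vector of node (gene) names.
#' @param m_attach integer >= 1, edges added per new node.
#' @param planted_edges optional tibble `geneA`, `geneB`, `confidence`
#'   (confidence must exceed 400 so planted structure survives filtering).
#' @param seed integer seed.
#' @return An undirected igraph with edge attribute `confidence`.
#' @export
simulate_network <- function(genes, m_attach = 2, planted_edges = NULL, seed) {
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  m_attach <- as.integer(m_attach)
  if (is.na(m_attach) || m_attach < 1) abort("m_attach must be >= 1")
  n <- length(genes)
  if (n <= m_attach) abort("need more genes than m_attach")
  if (anyDuplicated(genes)) abort("gene names must be unique")
  if (!is.null(planted_edges)) {
    planted_edges <- as_tibble(planted_edges)
    unknown <- setdiff(c(planted_edges$geneA, planted_edges$geneB), genes)
    if (length(unknown) > 0) {
      abort(paste0("planted edge references unknown gene(s): ",
                   paste(unique(unknown), collapse = ", ")))
    }
    if (any(planted_edges$confidence <= 400)) {
      abort("planted edge confidences must exceed the confidence floor (400)")
    }
    if (any(planted_edges$geneA == planted_edges$geneB)) {
      abort("planted self-loops are not allowed")
    }
  }
  set.seed(as.integer(seed))

  deg <- integer(n)
  from <- integer(0)
  to <- integer(0)
  for (v in (m_attach + 1L):n) {
    existing <- seq_len(v - 1L)
    w <- deg[existing] + 1
    targets <- sample(existing, m_attach, prob = w)
    from <- c(from, rep.int(v, m_attach))
    to <- c(to, targets)
    deg[v] <- deg[v] + m_attach
    deg[targets] <- deg[targets] + 1L
  }
  edges <- tibble(
    a = genes[pmin(from, to)],
    b = genes[pmax(from, to)],
    confidence = sample(401:1000, length(from), replace = TRUE)
  )
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    pl <- tibble(
      a = pmin(planted_edges$geneA, planted_edges$geneB),
      b = pmax(planted_edges$geneA, planted_edges$geneB),
      confidence = as.integer(planted_edges$confidence)
    )
    # planted edges overwrite grown duplicates
    key <- paste(edges$a, edges$b, sep = "\r")
    pkey <- paste(pl$a, pl$b, sep = "\r")
    edges <- bind_rows(edges[!key %in% pkey, , drop = FALSE], pl)
  }
  edges <- distinct(edges, .data$a, .data$b, .keep_all = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b, confidence = edges$confidence),
    directed = FALSE,
    vertices = data.frame(name = genes)
  )
}
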