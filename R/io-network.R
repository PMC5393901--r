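#' Read an interaction network edge list
#'
#' Parses a STRING-database-dialect edge list: whitespace- or tab-separated
#' lines of `node node combined_score` with scores on the 0-1000 scale and an
#' optional header line. Edges at or below `min_confidence` are dropped
#' (strictly-greater filter); duplicate pairs (in either order) keep the
#' maximum confidence; nodes whose every edge was filtered out remain in the
#' graph as isolated nodes.
#'
#' @param path file path.
#' @param min_confidence integer confidence floor (default 400, the
#'   medium-confidence STRING cutoff).
#' @return An undirected [igraph::igraph] with vertex attribute `name` and
#'   edge attribute `confidence`.
#' @export
read_network <- function(path, min_confidence = 400) {
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- stringr::str_split(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 3)) {
    abort(sprintf("network format error: line %d does not have 3 fields",
                  which(nf != 3)[1]))
  }
  m <- do.call(rbind, fields)
  score_chr <- m[, 3]
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(score_chr[1])))) {
    start <- 2L  # header line
    if (length(lines) == 1) {
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
  }
  m <- m[start:nrow(m), , drop = FALSE]
  score_chr <- m[, 3]
  score_num <- suppressWarnings(as.numeric(score_chr))
  bad <- is.na(score_num) | score_num != round(score_num)
  if (any(bad)) {
    abort(sprintf(
      "network format error: non-integer score '%s' at line %d",
      score_chr[which(bad)[1]], which(bad)[1] + start - 1L
    ))
  }
  score <- as.integer(score_num)
  if (any(score < 0 | score > 1000)) {
    abort("network format error: confidence scores must lie in [0, 1000]")
  }
  edges <- tibble(
    a = pmin(m[, 1], m[, 2]),
    b = pmax(m[, 1], m[, 2]),
    confidence = score
  )
  loops <- edges$a == edges$b
  if (any(loops)) edges <- edges[!loops, , drop = FALSE]
  edges <- edges %>%
    group_by(.data$a, .data$b) %>%
    summarise(confidence = max(.data$confidence), .groups = "drop")
  all_nodes <- sort(unique(c(m[, 1], m[, 2])))
  keep <- edges$confidence > min_confidence
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b, confidence = edges$confidence),
    directed = FALSE,
    vertices = data.frame(name = all_nodes)
  )
  g
}

#' Write an interaction network edge list
#'
#' Serializes a confidence-scored graph back to the STRING edge-list dialect
#' (tab-separated `node node combined_score`, with header). Isolated nodes
#' cannot be represented in an edge list and are dropped on write.
#'
#' @param network an igraph with edge attribute `confidence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  conf <- igraph::E(network)$confidence
  if (is.null(conf)) conf <- rep(1000L, nrow(el))
  tab <- tibble(node1 = el[, 1], node2 = el[, 2],
                combined_score = as.integer(conf))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
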