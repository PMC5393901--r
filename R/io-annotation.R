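#' Read gene annotation
#'
#' Reads a BED-like TSV of gene models into the 1-based inclusive coordinate
#' convention used internally (distances in kb are computed from 1-based
#' positions). A dialect flag states whether the file's start coordinates are
#' 0-based half-open (`"bed"`, the UCSC convention) or already 1-based
#' inclusive (`"one_based"`).
#'
#' Expected columns (no header for `"bed"`): chrom, start, end, gene symbol,
#' and optionally gene id and strand. For `"one_based"` a header with columns
#' `chrom`, `start`, `end`, `symbol` (optionally `gene_id`, `strand`) is
#' accepted.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"one_based"`.
#' @return A tibble of gene models with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand`, start <= end, 1-based inclusive.
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (dialect == "bed") {
    tab <- readr::read_tsv(
      path,
      col_names = FALSE, show_col_types = FALSE, progress = FALSE
    )
    if (ncol(tab) < 4) {
      abort("BED format error: need at least chrom, start, end, name columns")
    }
    genes <- tibble(
      gene_id = if (ncol(tab) >= 5) as.character(tab[[5]]) else as.character(tab[[4]]),
      symbol = as.character(tab[[4]]),
      chrom = as.character(tab[[1]]),
      start = as.integer(tab[[2]]) + 1L,  # 0-based half-open -> 1-based inclusive
      end = as.integer(tab[[3]]),
      strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+"
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("chrom", "start", "end", "symbol")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      abort(paste0("annotation lacks column(s): ", paste(miss, collapse = ", ")))
    }
    genes <- tibble(
      gene_id = if ("gene_id" %in% names(tab)) as.character(tab$gene_id) else as.character(tab$symbol),
      symbol = as.character(tab$symbol),
      chrom = as.character(tab$chrom),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      strand = if ("strand" %in% names(tab)) as.character(tab$strand) else "+"
    )
  }
  bad <- genes$start > genes$end
  if (any(bad)) {
    abort(sprintf(
      "annotation validation error: start > end for gene '%s' after normalization",
      genes$symbol[which(bad)[1]]
    ))
  }
  if (any(genes$start < 1)) {
    abort("annotation validation error: coordinates must be >= 1 after normalization")
  }
  genes
}

#' Write gene annotation as a 1-based TSV
#'
#' @param genes tibble as returned by [read_gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  readr::write_tsv(
    genes[, c("gene_id", "symbol", "chrom", "start", "end", "strand")],
    path, progress = FALSE
  )
  invisible(path)
}
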