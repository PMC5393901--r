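#' Read a summary-statistics table
#'
#' Reads a GWAS summary-statistics TSV in the deposited-table shape: one row
#' per variant with columns `id`, `chrom`, `pos`, `coded_allele`,
#' `other_allele`, `beta` (per copy of the coded allele), `se`, `p`, `n`.
#' Extra columns are preserved untouched.
#'
#' @param path file path.
#' @param check_consistency if `TRUE`, verify that `p` is consistent with the
#'   two-sided normal tail of `beta/se` (20% relative tolerance, to absorb
#'   rounding in published tables) and warn on rows that disagree.
#' @return A tibble. `se <= 0` or `p` outside `(0, 1]` raise validation
#'   errors; p-value underflow must be stored as the smallest positive
#'   representable double, never 0.
#' @export
read_sumstats <- function(path, check_consistency = FALSE) {
  if (!file.exists(path)) abort(paste0("sumstats file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "chrom", "pos", "coded_allele", "other_allele",
            "beta", "se", "p", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("sumstats lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_sumstats(tab)
  if (check_consistency) {
    z <- abs(tab$beta / tab$se)
    expect_p <- 2 * pnorm(-z)
    ok <- expect_p == 0 | abs(tab$p - expect_p) <= 0.2 * pmax(tab$p, expect_p)
    if (any(!ok)) {
      warn(sprintf(
        "%d row(s) have p inconsistent with |beta/se| under the normal law (first: '%s')",
        sum(!ok), tab$id[which(!ok)[1]]
      ))
    }
  }
  tab
}

#' @rdname read_sumstats
#' @param tab a sumstats tibble.
#' @export
validate_sumstats <- function(tab) {
  if (any(!is.na(tab$se) & tab$se <= 0)) {
    abort(sprintf("sumstats validation error: se <= 0 for variant '%s'",
                  tab$id[which(tab$se <= 0)[1]]))
  }
  bad_p <- !is.na(tab$p) & (tab$p <= 0 | tab$p > 1)
  if (any(bad_p)) {
    abort(sprintf(
      paste0("sumstats validation error: p outside (0, 1] for variant '%s' ",
             "(store underflow as the smallest positive double, not 0)"),
      tab$id[which(bad_p)[1]]
    ))
  }
  invisible(tab)
}

#' Write a summary-statistics table
#'
#' Writes the TSV shape read by [read_sumstats()]; `write_sumstats()` then
#' `read_sumstats()` round-trips the table (floats at full printed
#' precision). Extra columns are written as-is.
#'
#' @param tab a sumstats tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tab, path) {
  validate_sumstats(tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
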