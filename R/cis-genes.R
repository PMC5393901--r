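#' Enumerate candidate cis-genes around an index SNP
#'
#' Lists every gene whose body lies within `window_kb` of the SNP position
#' (distance 0 when the SNP overlaps the gene), with the signed distance of
#' [signed_distance_kb()] and the 1-based rank of |distance| (ties broken by
#' gene start). These are the candidate mediator genes scored by the five
#' evidence tracks of [integrate_evidence()].
#'
#' @param chrom,pos index SNP coordinates.
#' @param annotation gene-model tibble.
#' @param window_kb search window (default 500).
#' @return A tibble of gene models with `distance_kb` and `dist_rank`,
#'   ordered by rank; empty when no gene is in range.
#' @export
enumerate_cis_genes <- function(chrom, pos, annotation, window_kb = 500) {
  annotation <- as_tibble(annotation)
  if (nrow(annotation) == 0) abort("annotation must be nonempty")
  hits <- annotation %>%
    filter(.data$chrom == !!as.character(chrom)) %>%
    mutate(distance_kb = signed_distance_kb(!!pos, .data$start, .data$end)) %>%
    filter(abs(.data$distance_kb) <= window_kb) %>%
    arrange(abs(.data$distance_kb), .data$start) %>%
    mutate(dist_rank = row_number())
  hits
}

#' Coding-proxy evidence for an index SNP
#'
#' Searches the missense-flagged variants within 500 kb of the index SNP
#' for the one in strongest LD; it is reported when r-squared strictly
#' exceeds `coding_r2`. An index SNP that is itself missense is its own
#' proxy with r-squared 1.
#'
#' @param snp_id index SNP id.
#' @param ld_ref a [genotype_matrix()] whose variant metadata carries the
#'   `missense` flag.
#' @param coding_r2 LD threshold (strict >; default 0.6).
#' @param window_kb search radius (default 500).
#' @return A one-row tibble `id`, `r2`, `chrom`, `pos`, or `NULL`.
#' @export
coding_proxy_evidence <- function(snp_id, ld_ref, coding_r2 = 0.6,
                                  window_kb = 500) {
  stopifnot(inherits(ld_ref, "genotype_matrix"))
  vmeta <- ld_ref$variants
  j <- match(snp_id, vmeta$id)
  if (is.na(j)) abort(paste0("variant '", snp_id, "' absent from LD reference"))
  if (isTRUE(vmeta$missense[j])) {
    return(tibble(id = snp_id, r2 = 1,
                  chrom = vmeta$chrom[j], pos = vmeta$pos[j]))
  }
  cand <- vmeta %>%
    filter(.data$missense,
           .data$chrom == vmeta$chrom[j],
           abs(.data$pos - vmeta$pos[j]) <= window_kb * 1000)
  if (nrow(cand) == 0) return(NULL)
  r2s <- vapply(cand$id, function(v) .r2_or_zero(ld_r2(ld_ref, snp_id, v)),
                numeric(1))
  best <- which.max(r2s)
  if (r2s[best] <= coding_r2) return(NULL)
  tibble(id = cand$id[best], r2 = unname(r2s[best]),
         chrom = cand$chrom[best], pos = cand$pos[best])
}
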