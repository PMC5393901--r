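#' Assay quality control for a protein panel
#'
#' Removes assays with more than `lod_frac` of samples below the lower
#' detection limit, or with inter-plate coefficient of variation above
#' `cv_max` (both comparisons strict, so an assay exactly at a threshold is
#' retained). With the defaults this is the rule under which 83 of 92 panel
#' assays survive in a typical CVD panel.
#'
#' @param panel a [protein_panel()] with complete QC metadata.
#' @param lod_frac maximum tolerated below-LOD fraction (default 0.20).
#' @param cv_max maximum tolerated inter-plate CV (default 0.25).
#' @return The filtered `protein_panel`, with attribute `"removed"`: a tibble
#'   of dropped assays and which rule fired (`"lod"`, `"cv"`, or both).
#' @export
qc_proteins <- function(panel, lod_frac = 0.20, cv_max = 0.25) {
  stopifnot(inherits(panel, "protein_panel"))
  meta <- panel$assays
  if (anyNA(meta$frac_below_lod) || anyNA(meta$cv_interplate)) {
    abort("QC metadata must be present for every assay")
  }
  fail_lod <- meta$frac_below_lod > lod_frac
  fail_cv <- meta$cv_interplate > cv_max
  drop <- fail_lod | fail_cv
  removed <- tibble(
    assay = meta$assay[drop],
    reason = dplyr::case_when(
      fail_lod[drop] & fail_cv[drop] ~ "lod+cv",
      fail_lod[drop] ~ "lod",
      TRUE ~ "cv"
    )
  )
  keep <- which(!drop)
  out <- protein_panel(
    panel$values[, keep, drop = FALSE],
    meta[keep, , drop = FALSE],
    samples = panel$samples,
    plate_of = panel$plate_of
  )
  attr(out, "removed") <- removed
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg equilibrium from genotype counts:
#' the p-value is the sum, over all heterozygote counts compatible with the
#' observed allele counts, of the conditional probabilities not exceeding the
#' probability of the observed heterozygote count (the standard exact HWE
#' test). All counts zero returns 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa nonnegative integer genotype counts.
#' @return The exact p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_Aa   # rarer-or-either allele count works symmetrically
  n_A <- 2 * n_AA + n_Aa
  nm <- min(n_A, n_a)      # minor allele count
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(nm %% 2, nm, by = 2)
  # conditional pmf given allele counts:
  # P(h) = n! 2^h / (nAA! h! naa!) * nA! na! / (2n)!
  n_AA_h <- (n_A - hets) / 2
  n_aa_h <- (n_a - hets) / 2
  logp <- lgamma(n + 1) + hets * log(2) -
    lgamma(n_AA_h + 1) - lgamma(hets + 1) - lgamma(n_aa_h + 1) +
    lgamma(n_A + 1) + lgamma(n_a + 1) - lgamma(2 * n + 1)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  # numeric slack so ties with the observed probability are included
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Variant quality control for a genotype matrix
#'
#' Removes variants failing either the call-rate filter (fraction of
#' non-missing dosages below `call_rate`) or the Hardy-Weinberg exact test
#' (p strictly below `hwe_p`). Genotype counts for the HWE test are obtained
#' by rounding dosages to hard calls, mirroring QC on directly genotyped
#' calls.
#'
#' @param gm a [genotype_matrix()].
#' @param hwe_p HWE exact-test floor (default 1e-6).
#' @param call_rate minimum call rate (default 0.95).
#' @return The filtered `genotype_matrix`, with attribute `"removed"`: a
#'   tibble of dropped variants and the rule that fired.
#' @export
qc_genotypes <- function(gm, hwe_p = 1e-6, call_rate = 0.95) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- nrow(gm$variants)
  cr <- colMeans(!is.na(gm$dosage))
  hwe <- vapply(seq_len(m), function(j) {
    hard <- round(gm$dosage[, j])
    hard <- hard[!is.na(hard)]
    hwe_exact_test(sum(hard == 0), sum(hard == 1), sum(hard == 2))
  }, numeric(1))
  fail_cr <- cr < call_rate
  fail_hwe <- hwe < hwe_p
  drop <- fail_cr | fail_hwe
  removed <- tibble(
    id = gm$variants$id[drop],
    reason = dplyr::case_when(
      fail_cr[drop] & fail_hwe[drop] ~ "call_rate+hwe",
      fail_cr[drop] ~ "call_rate",
      TRUE ~ "hwe"
    ),
    call_rate = cr[drop],
    hwe_p = hwe[drop]
  )
  out <- gm_subset(gm, variants = which(!drop))
  attr(out, "removed") <- removed
  out
}
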