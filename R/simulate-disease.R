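#' Simulate disease GWAS summary statistics
#'
#' Emulates an external disease GWAS lookup table over the pQTL index
#' variants. For variants whose protein is disease-causal, the disease beta
#' is proportional to the protein beta (shared direction,
#' `beta_cad = proportionality * beta_protein`); all other variants draw
#' their beta from the null `N(0, se_scale)`. Standard errors are constant
#' at `se_scale` and p-values come from the two-sided normal tail.
#'
#' @param pqtl_truth tibble of planted pQTLs with columns `variant`,
#'   `protein`, `beta` (per coded allele).
#' @param variants variant metadata tibble (columns `id`, `chrom`, `pos`,
#'   `coded_allele`, `other_allele`) covering every truth variant.
#' @param causal_proteins character vector of disease-causal proteins; must
#'   all appear in `pqtl_truth`.
#' @param se_scale constant per-variant standard error.
#' @param proportionality scaling from protein beta to disease beta.
#' @param n reported GWAS sample size.
#' @param seed integer seed.
#' @return A sumstats tibble in the shape of [read_sumstats()].
#' @export
simulate_disease_sumstats <- function(pqtl_truth, variants, causal_proteins,
                                      se_scale = 0.01, proportionality = 0.5,
                                      n = 184305, seed) {
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  pqtl_truth <- as_tibble(pqtl_truth)
  variants <- as_tibble(variants)
  unknown <- setdiff(causal_proteins, pqtl_truth$protein)
  if (length(unknown) > 0) {
    abort(paste0("unknown causal protein(s): ", paste(unknown, collapse = ", ")))
  }
  if (!all(pqtl_truth$variant %in% variants$id)) {
    abort("variant metadata missing for some truth variants")
  }
  set.seed(as.integer(seed))
  meta <- variants[match(pqtl_truth$variant, variants$id), , drop = FALSE]
  causal <- pqtl_truth$protein %in% causal_proteins
  beta <- ifelse(causal,
                 proportionality * pqtl_truth$beta,
                 rnorm(nrow(pqtl_truth), 0, se_scale))
  p <- 2 * pnorm(-abs(beta / se_scale))
  p <- pmax(p, .Machine$double.xmin)
  tibble(
    id = pqtl_truth$variant,
    chrom = meta$chrom,
    pos = meta$pos,
    coded_allele = meta$coded_allele,
    other_allele = meta$other_allele,
    beta = beta,
    se = se_scale,
    p = p,
    n = as.integer(n),
    protein = pqtl_truth$protein
  )
}
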