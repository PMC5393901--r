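#' Harmonize disease records to the risk-increasing allele
#'
#' Aligns external disease-GWAS records to the pQTL allele coding and then
#' re-codes each variant so its coded allele increases disease risk
#' (disease beta >= 0), regardless of the direction of the protein effect —
#' the coding under which pooled per-protein scores have uniform risk
#' directionality. Variants whose allele pair matches in neither order, and
#' strand-ambiguous palindromic pairs (A/T, C/G), are excluded with a
#' warning. The operation is idempotent.
#'
#' @param pqtl tibble of pQTL records, columns `id`, `coded_allele`,
#'   `other_allele` (plus anything else, preserved).
#' @param disease disease sumstats tibble, columns `id`, `coded_allele`,
#'   `other_allele`, `beta`, `se`.
#' @return The matched disease records, one row per shared variant, with
#'   `beta` (now `beta_cad >= 0` coding), `se`, `coded_allele`,
#'   `other_allele`, and a `flipped` log column noting allele swaps and risk
#'   flips.
#' @export
harmonize_to_risk <- function(pqtl, disease) {
  pqtl <- as_tibble(pqtl)
  disease <- as_tibble(disease)
  out <- list()
  for (i in seq_len(nrow(pqtl))) {
    d <- disease[disease$id == pqtl$id[i], , drop = FALSE]
    if (nrow(d) == 0) next
    d <- d[1, ]
    pa <- toupper(c(pqtl$coded_allele[i], pqtl$other_allele[i]))
    da <- toupper(c(d$coded_allele, d$other_allele))
    if (.palindromic(pa)) {
      warn(paste0("variant '", d$id,
                  "' has a strand-ambiguous allele pair; excluded"))
      next
    }
    flips <- character(0)
    if (identical(da, pa)) {
      beta <- d$beta
    } else if (identical(da, rev(pa))) {
      beta <- -d$beta  # allele swap flips the effect sign
      flips <- "allele_swap"
      da <- rev(da)
    } else {
      warn(paste0("variant '", d$id,
                  "' alleles do not match the pQTL record; excluded"))
      next
    }
    if (beta < 0) {
      beta <- -beta
      da <- rev(da)
      flips <- c(flips, "risk_flip")
    }
    out[[length(out) + 1]] <- tibble(
      id = d$id, coded_allele = da[1], other_allele = da[2],
      beta = beta, se = d$se,
      p = if ("p" %in% names(d)) d$p else 2 * pnorm(-abs(beta / d$se)),
      flipped = paste(flips, collapse = "+")
    )
  }
  if (length(out) == 0) {
    return(tibble(id = character(), coded_allele = character(),
                  other_allele = character(), beta = numeric(),
                  se = numeric(), p = numeric(), flipped = character()))
  }
  bind_rows(out)
}

.palindromic <- function(alleles) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  a1 <- alleles[1]; a2 <- alleles[2]
  a1 %in% names(comp) && identical(unname(comp[a1]), a2)
}

#' Pooled disease risk score for one protein
#'
#' Inverse-variance pooling of risk-aligned disease betas over a protein's
#' independent index SNPs — the summary-statistic genetic risk score used to
#' judge whether a protein's loci jointly associate with disease. Records
#' must be harmonized ([harmonize_to_risk()]) so all betas are nonnegative.
#'
#' @param aligned harmonized disease records for one protein (columns
#'   `beta`, `se`; at least one row).
#' @param protein protein name, carried into the result.
#' @return A one-row tibble: `protein`, `n_snps`, `pooled_beta`,
#'   `pooled_se`, `pooled_p`.
#' @export
pooled_score <- function(aligned, protein = NA_character_) {
  aligned <- as_tibble(aligned)
  if (nrow(aligned) == 0) abort("pooled_score needs at least one record")
  if (any(aligned$beta < 0)) {
    abort("records must be risk-aligned (all betas >= 0) before pooling")
  }
  m <- ivw_meta(aligned)
  tibble(
    protein = protein, n_snps = nrow(aligned),
    pooled_beta = m$pooled_beta, pooled_se = m$pooled_se,
    pooled_p = m$pooled_p
  )
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false-discovery-rate control at level `q`: flags are monotone in
#' p (every p below a flagged one is flagged).
#'
#' @param p vector of p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble `p`, `p_adj` (BH-adjusted), `significant`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble(p = numeric(), p_adj = numeric(), significant = logical()))
  }
  if (any(is.na(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, p_adj = adj, significant = adj <= q)
}

#' Disease risk-score lookup over all proteins
#'
#' Runs the full downstream disease stage: harmonizes each protein's index
#' SNPs against the disease GWAS, computes per-SNP associations and the
#' pooled per-protein score, and flags proteins significant after BH-FDR
#' correction across all lookups in the run.
#'
#' @param loci classified locus tibble with `trait`, `index_id`.
#' @param gm discovery [genotype_matrix()] (allele metadata for the index
#'   SNPs).
#' @param disease disease sumstats tibble.
#' @param q FDR level (default 0.05).
#' @return A tibble, one row per protein: `protein`, `n_snps`,
#'   `pooled_beta`, `pooled_se`, `pooled_p`, `p_adj`, `fdr_significant`.
#' @export
risk_score_lookup <- function(loci, gm, disease, q = 0.05) {
  loci <- as_tibble(loci)
  vmeta <- gm$variants
  per_protein <- loci %>%
    mutate(coded_allele = vmeta$coded_allele[match(.data$index_id, vmeta$id)],
           other_allele = vmeta$other_allele[match(.data$index_id, vmeta$id)]) %>%
    rename(id = "index_id") %>%
    group_by(.data$trait) %>%
    dplyr::group_map(function(rows, key) {
      aligned <- harmonize_to_risk(rows, disease)
      if (nrow(aligned) == 0) return(NULL)
      pooled_score(aligned, protein = key$trait)
    })
  res <- bind_rows(per_protein)
  if (nrow(res) == 0) return(res)
  fdr <- bh_fdr(res$pooled_p, q = q)
  res$p_adj <- fdr$p_adj
  res$fdr_significant <- fdr$significant
  res
}
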