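#' Scan one gene for cis-eQTL evidence across datasets
#'
#' In each expression dataset where both the gene and the SNP are measured,
#' fits the linear additive model of log2 expression on dosage and reports
#' the uncorrected p-value when it is strictly below `eqtl_cis_p` (5e-4 by
#' default, corresponding to roughly FDR 5% in a multi-dataset lookup).
#' Datasets lacking the gene or the SNP are skipped silently and recorded in
#' the `"skipped"` attribute.
#'
#' @param snp_id variant id.
#' @param gene gene symbol.
#' @param datasets list of [eqtl_dataset()] objects.
#' @param eqtl_cis_p report threshold (strict <).
#' @return A tibble `dataset`, `beta`, `p` of reporting datasets (possibly
#'   empty).
#' @export
cis_eqtl_scan <- function(snp_id, gene, datasets, eqtl_cis_p = 5e-4) {
  skipped <- character(0)
  rows <- list()
  for (ds in datasets) {
    if (!(gene %in% colnames(ds$expr)) ||
        !(snp_id %in% ds$genotypes$variants$id)) {
      skipped <- c(skipped, ds$name)
      next
    }
    fit <- .simple_reg(gm_dosage(ds$genotypes, snp_id), ds$expr[, gene])
    if (is.na(fit[1]) || fit[2] <= 0) {
      skipped <- c(skipped, ds$name)
      next
    }
    p <- 2 * pt(-abs(fit[1] / fit[2]), fit[4] - 2)
    if (p < eqtl_cis_p) {
      rows[[length(rows) + 1]] <- tibble(dataset = ds$name,
                                         beta = fit[1], p = p)
    }
  }
  out <- if (length(rows) > 0) bind_rows(rows) else
    tibble(dataset = character(), beta = numeric(), p = numeric())
  attr(out, "skipped") <- skipped
  out
}

#' Trans-eQTL node scores for path weighting
#'
#' For every network gene, takes the best (minimum) p-value of the
#' expression-on-dosage regression of the index SNP across all datasets
#' where the gene is measurable, and maps it to a path weight: 0.6 when the
#' best p < 0.005, 0.8 when 0.005 <= p < 0.05, and 1 otherwise. Genes never
#' measured score 1.
#'
#' @param snp_id variant id (the trans locus's index SNP).
#' @param datasets list of [eqtl_dataset()] objects.
#' @param network_genes character vector of genes to score.
#' @param w1_p,w2_p the 0.8 and 0.6 score thresholds (defaults 0.05, 0.005).
#' @return A tibble `gene`, `score`, `best_p`, `dataset` (dataset attaining
#'   the best p; `NA` for unmeasured genes).
#' @export
trans_eqtl_scores <- function(snp_id, datasets, network_genes,
                              w1_p = 0.05, w2_p = 0.005) {
  best_p <- setNames(rep(NA_real_, length(network_genes)), network_genes)
  best_ds <- setNames(rep(NA_character_, length(network_genes)), network_genes)
  for (ds in datasets) {
    if (!(snp_id %in% ds$genotypes$variants$id)) next
    g <- gm_dosage(ds$genotypes, snp_id)
    genes_here <- intersect(network_genes, colnames(ds$expr))
    if (length(genes_here) == 0) next
    ok <- !is.na(g)
    gv <- g[ok]
    n <- length(gv)
    if (n < 3 || sd(gv) == 0) next
    E <- ds$expr[ok, genes_here, drop = FALSE]
    gc <- gv - mean(gv)
    sgg <- sum(gc^2)
    ec <- sweep(E, 2, colMeans(E))
    sgy <- drop(crossprod(gc, ec))
    syy <- colSums(ec^2)
    beta <- sgy / sgg
    sse <- pmax(syy - sgy^2 / sgg, 0)
    se <- sqrt(sse / (n - 2) / sgg)
    p <- 2 * pt(-abs(beta / se), n - 2)
    upd <- is.na(best_p[genes_here]) | p < best_p[genes_here]
    best_p[genes_here][upd] <- p[upd]
    best_ds[genes_here][upd] <- ds$name
  }
  score <- dplyr::case_when(
    is.na(best_p) ~ 1,
    best_p < w2_p ~ 0.6,
    best_p < w1_p ~ 0.8,
    TRUE ~ 1
  )
  tibble(gene = network_genes, score = score,
         best_p = unname(best_p), dataset = unname(best_ds))
}
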