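#' Heatmap of a clustered pleiotropy matrix
#'
#' @param object a `pleiotropy_matrix` (clustered or not; unclustered
#'   matrices are drawn in input order).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pleiotropy_matrix <- function(object, ...) {
  long <- tidy(object)
  rn <- rownames(object$matrix)
  cn <- colnames(object$matrix)
  if (!is.null(object$row_order)) rn <- rn[object$row_order]
  if (!is.null(object$col_order)) cn <- cn[object$col_order]
  long$snp <- factor(long$snp, levels = rn)
  long$protein <- factor(long$protein, levels = cn)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$protein, y = .data$snp,
                                     fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 name = expression(-log[10](P))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Forest plot of a replication meta-analysis
#'
#' @param object an [ivw_meta()] result.
#' @param ... unused.
#' @return A ggplot showing per-cohort estimates with 95% intervals and the
#'   pooled estimate.
#' @export
autoplot.ivw_meta <- function(object, ...) {
  est <- tidy(object)
  pooled <- tibble(cohort = "pooled", beta = object$pooled_beta,
                   se = object$pooled_se)
  dat <- bind_rows(est[, c("cohort", "beta", "se")], pooled) %>%
    mutate(lo = .data$beta - 1.96 * .data$se,
           hi = .data$beta + 1.96 * .data$se,
           cohort = factor(.data$cohort, levels = rev(unique(.data$cohort))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, y = .data$cohort)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$cohort == "pooled"),
                        size = 2.5, show.legend = FALSE) +
    ggplot2::labs(x = "effect per coded allele", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-trait association overview
#'
#' Plots -log10 p against genomic position for every tested variant,
#' faceted by trait, with the genome-wide threshold drawn as a line — the
#' quick visual check on a scan's output.
#'
#' @param scan association tibble from [wald_scan()].
#' @param gm the [genotype_matrix()] used in the scan (positions).
#' @param p_gw threshold to draw (default 5e-8).
#' @param traits optional subset of traits to show.
#' @return A ggplot.
#' @export
plot_scan <- function(scan, gm, p_gw = 5e-8, traits = NULL) {
  vmeta <- gm$variants
  dat <- as_tibble(scan) %>%
    mutate(chrom = vmeta$chrom[match(.data$variant, vmeta$id)],
           pos = vmeta$pos[match(.data$variant, vmeta$id)])
  if (!is.null(traits)) dat <- dat %>% filter(.data$trait %in% traits)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6,
                                    y = -log10(.data$p),
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_gw), linetype = "dashed") +
    ggplot2::facet_grid(trait ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](P))) +
    ggplot2::theme_minimal()
}
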