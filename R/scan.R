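#' Genome-wide Wald scan of residualized proteins
#'
#' For every (assay, variant) pair, fits the simple regression of the
#' standardized protein residual on the dosage: `beta = cov(g, y) / var(g)`,
#' standard error from the residual variance on `n - 2` degrees of freedom,
#' and a two-sided p-value from the t distribution with `n - 2` df.
#' Covariates are assumed already projected out by [residualize()], so this
#' is the two-step scan of the standard protocol. P-values that underflow
#' are clamped to the smallest positive normal double and flagged in the
#' `p_underflow` column.
#'
#' @param residuals samples-by-assays matrix from [residualize()].
#' @param gm a [genotype_matrix()] with the same samples, same order.
#' @param p_gw genome-wide significance threshold; associations with
#'   `p < p_gw` (strict) are marked in the `flagged` column.
#' @return A tibble with one row per tested pair: `variant`, `trait`,
#'   `beta`, `se`, `p`, `n`, `r2_explained`, `flagged`, `p_underflow`.
#'   Monomorphic variants are skipped (recorded in attribute `"skipped"`),
#'   never an error.
#' @export
wald_scan <- function(residuals, gm, p_gw = 5e-8) {
  stopifnot(inherits(gm, "genotype_matrix"))
  residuals <- as.matrix(residuals)
  if (nrow(residuals) != length(gm$samples)) {
    abort("residuals and genotypes must cover the same samples")
  }
  if (!is.null(rownames(residuals)) &&
      !identical(rownames(residuals), gm$samples)) {
    abort("residual rows must align exactly with genotype samples")
  }
  traits <- colnames(residuals)
  if (is.null(traits)) traits <- paste0("T", seq_len(ncol(residuals)))
  G <- gm$dosage
  res <- vector("list", ncol(residuals))
  skipped <- character(0)
  for (k in seq_len(ncol(residuals))) {
    y <- residuals[, k]
    ok <- !is.na(y)
    g_ok <- G[ok, , drop = FALSE]
    miss_g <- anyNA(g_ok)
    if (miss_g) {
      # per-variant pairwise masks; fall back to a per-variant loop
      stats_k <- vapply(seq_len(ncol(g_ok)), function(j) {
        .simple_reg(g_ok[, j], y[ok])
      }, numeric(4))
    } else {
      yv <- y[ok]
      n <- length(yv)
      gc <- sweep(g_ok, 2, colMeans(g_ok))
      yc <- yv - mean(yv)
      sgg <- colSums(gc^2)
      sgy <- drop(crossprod(gc, yc))
      syy <- sum(yc^2)
      beta <- ifelse(sgg > 0, sgy / sgg, NA_real_)
      sse <- syy - ifelse(sgg > 0, sgy^2 / sgg, 0)
      se <- sqrt(pmax(sse, 0) / (n - 2) / sgg)
      r2 <- ifelse(sgg > 0 & syy > 0, sgy^2 / (sgg * syy), NA_real_)
      stats_k <- rbind(beta, se, r2, n)
    }
    beta <- stats_k[1, ]; se <- stats_k[2, ]
    r2 <- stats_k[3, ]; nn <- stats_k[4, ]
    tt <- beta / se
    p <- 2 * pt(-abs(tt), nn - 2)
    underflow <- !is.na(p) & p < .Machine$double.xmin
    p[underflow] <- .Machine$double.xmin
    keep <- !is.na(beta) & is.finite(beta)
    skipped <- c(skipped, gm$variants$id[!keep])
    res[[k]] <- tibble(
      variant = gm$variants$id[keep],
      trait = traits[k],
      beta = unname(beta[keep]),
      se = unname(se[keep]),
      p = unname(p[keep]),
      n = as.integer(nn[keep]),
      r2_explained = unname(r2[keep]),
      flagged = unname(p[keep] < p_gw),
      p_underflow = unname(underflow[keep])
    )
  }
  out <- bind_rows(res)
  attr(out, "skipped") <- unique(skipped)
  out
}

.simple_reg <- function(g, y) {
  ok <- !is.na(g)
  g <- g[ok]; y <- y[ok]
  n <- length(g)
  if (n < 3) return(c(NA_real_, NA_real_, NA_real_, n))
  gc <- g - mean(g); yc <- y - mean(y)
  sgg <- sum(gc^2)
  if (sgg == 0) return(c(NA_real_, NA_real_, NA_real_, n))
  sgy <- sum(gc * yc)
  syy <- sum(yc^2)
  beta <- sgy / sgg
  sse <- max(syy - sgy^2 / sgg, 0)
  se <- sqrt(sse / (n - 2) / sgg)
  r2 <- if (syy > 0) sgy^2 / (sgg * syy) else NA_real_
  c(beta, se, r2, n)
}

#' Linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of dosages over the samples non-missing for
#' both variants. Symmetric in its arguments and invariant to allele coding
#' (flipping `g` to `2 - g` leaves r-squared unchanged). When either variant
#' is monomorphic over the shared samples the value is undefined and `NA` is
#' returned; callers treat that as 0.
#'
#' @param gm a [genotype_matrix()].
#' @param v1,v2 variant ids.
#' @return r-squared in `[0, 1]`, or `NA` when undefined.
#' @export
ld_r2 <- function(gm, v1, v2) {
  g1 <- gm_dosage(gm, v1)
  g2 <- gm_dosage(gm, v2)
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2 || sd(g1) == 0 || sd(g2) == 0) return(NA_real_)
  cor(g1, g2)^2
}

.r2_or_zero <- function(r2) {
  if (is.na(r2)) 0 else r2
}
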