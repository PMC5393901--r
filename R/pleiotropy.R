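#' Select index SNPs with pleiotropic protein associations
#'
#' Builds the SNP-by-protein matrix of -log10 p-values restricted to index
#' SNPs showing at least 2 protein associations below the conservative
#' cross-testing cutoff `alpha = 0.05 / (n_proteins * n_snps)` (7.7e-6 for
#' 83 proteins and 79 SNPs). Proteins with no retained association are
#' dropped from the columns.
#'
#' @param assoc tibble of all (index SNP, protein) association p-values,
#'   columns `snp`, `protein`, `p`.
#' @param n_snps,n_proteins the multiple-testing burden: number of index
#'   SNPs and of tested proteins.
#' @return An object of class `pleiotropy_matrix`: list with `matrix`
#'   (-log10 p, rows SNPs, columns proteins), `alpha`, and empty orderings
#'   until [cluster_matrix()] is applied.
#' @export
pleiotropy_select <- function(assoc, n_snps, n_proteins) {
  if (n_snps < 1 || n_proteins < 1) {
    abort("n_snps and n_proteins must be >= 1")
  }
  assoc <- as_tibble(assoc)
  alpha <- 0.05 / (n_proteins * n_snps)
  sig <- assoc %>% filter(.data$p < alpha)
  keep_snps <- sig %>%
    distinct(.data$snp, .data$protein) %>%
    dplyr::count(.data$snp) %>%
    filter(.data$n >= 2) %>%
    pull(.data$snp)
  sig_kept <- sig %>% filter(.data$snp %in% keep_snps)
  keep_prot <- unique(sig_kept$protein)
  sub <- assoc %>%
    filter(.data$snp %in% keep_snps, .data$protein %in% keep_prot)
  mat <- matrix(0, length(keep_snps), length(keep_prot),
                dimnames = list(keep_snps, keep_prot))
  if (nrow(sub) > 0) {
    mat[cbind(match(sub$snp, keep_snps), match(sub$protein, keep_prot))] <-
      -log10(sub$p)
  }
  structure(
    list(matrix = mat, alpha = alpha, row_order = NULL, col_order = NULL,
         row_hclust = NULL, col_hclust = NULL),
    class = "pleiotropy_matrix"
  )
}

#' Cluster a pleiotropy matrix
#'
#' Complete-linkage hierarchical clustering of rows and, separately,
#' columns, with distance `1 - Pearson correlation` between the -log10 p
#' profiles. A zero-variance profile has its correlations defined as 0
#' (distance 1), with a warning. Deterministic; ties resolved by input
#' order through the agglomeration implementation.
#'
#' @param m a `pleiotropy_matrix` with at least 2 rows and 2 columns.
#' @return The matrix object with `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust` filled in.
#' @export
cluster_matrix <- function(m) {
  stopifnot(inherits(m, "pleiotropy_matrix"))
  if (nrow(m$matrix) < 2 || ncol(m$matrix) < 2) {
    abort("clustering needs at least 2 rows and 2 columns")
  }
  m$row_hclust <- hclust(.cor_dist(m$matrix), method = "complete")
  m$col_hclust <- hclust(.cor_dist(t(m$matrix)), method = "complete")
  m$row_order <- m$row_hclust$order
  m$col_order <- m$col_hclust$order
  m
}

.cor_dist <- function(x) {
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warn("zero-variance profile(s); their correlations are defined as 0")
  }
  cc <- suppressWarnings(cor(t(x)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  as.dist(1 - cc)
}

#' @export
print.pleiotropy_matrix <- function(x, ...) {
  cat(sprintf(
    "<pleiotropy_matrix> %d SNPs x %d proteins (alpha = %.2g)%s\n",
    nrow(x$matrix), ncol(x$matrix), x$alpha,
    if (is.null(x$row_order)) "" else ", clustered"
  ))
  invisible(x)
}

#' @rdname pleiotropy_select
#' @param x a `pleiotropy_matrix`.
#' @param ... unused.
#' @export
tidy.pleiotropy_matrix <- function(x, ...) {
  as_tibble(x$matrix, rownames = "snp") %>%
    tidyr::pivot_longer(-"snp", names_to = "protein",
                        values_to = "neg_log10_p")
}
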