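#' Genotype dosage container
#'
#' Builds the samples-by-variants dosage container used throughout the
#' pipeline. Dosages are expected allele counts of the coded allele, in
#' `[0, 2]`; missing dosages are `NA` (never a numeric sentinel).
#'
#' @param dosage numeric matrix, samples in rows and variants in columns.
#' @param variants tibble of variant metadata with columns `id`, `chrom`,
#'   `pos` (1-based), `coded_allele`, `other_allele`, and optionally
#'   `coded_freq`, `missense`, `impute_rsq`.
#' @param samples character vector of sample identifiers; defaults to the
#'   matrix rownames.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  variants <- as_tibble(variants)
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(dosage)))
  }
  variants <- .complete_variants(variants)
  if (ncol(dosage) != nrow(variants)) {
    abort(sprintf(
      "dosage has %d columns but %d variants are described",
      ncol(dosage), nrow(variants)
    ))
  }
  if (nrow(dosage) != length(samples)) {
    abort("number of dosage rows must equal number of samples")
  }
  .validate_variants(variants)
  bad <- which(!is.na(dosage) & (dosage < 0 | dosage > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf(
      "dosage out of [0, 2]: value %.4g for variant '%s', sample '%s'",
      dosage[i, j], variants$id[j], samples[i]
    ))
  }
  dimnames(dosage) <- list(samples, variants$id)
  structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

.complete_variants <- function(variants) {
  if (!"coded_freq" %in% names(variants)) variants$coded_freq <- NA_real_
  if (!"missense" %in% names(variants)) variants$missense <- FALSE
  if (!"impute_rsq" %in% names(variants)) variants$impute_rsq <- NA_real_
  variants$missense[is.na(variants$missense)] <- FALSE
  variants
}

.validate_variants <- function(variants) {
  need <- c("id", "chrom", "pos", "coded_allele", "other_allele")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    abort(paste0("variant table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(variants$id)) {
    abort("variant ids must be unique")
  }
  if (any(variants$pos < 1, na.rm = TRUE)) {
    abort("variant positions must be 1-based (>= 1)")
  }
  same <- variants$coded_allele == variants$other_allele
  if (any(same, na.rm = TRUE)) {
    abort(paste0(
      "coded and other allele identical for variant '",
      variants$id[which(same)[1]], "'"
    ))
  }
  bad_f <- !is.na(variants$coded_freq) &
    (variants$coded_freq < 0 | variants$coded_freq > 1)
  if (any(bad_f)) {
    abort(paste0("coded_freq outside [0, 1] for variant '",
                 variants$id[which(bad_f)[1]], "'"))
  }
  invisible(variants)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.1f%% missing)\n",
    length(x$samples), nrow(x$variants),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples sample identifiers (or indices) to keep; `NULL` keeps all.
#' @param variants variant ids (or indices) to keep; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
gm_subset <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$samples) else {
    if (is.character(samples)) match(samples, x$samples) else samples
  }
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else {
    if (is.character(variants)) match(variants, x$variants$id) else variants
  }
  if (anyNA(si)) abort("unknown sample identifier in subset")
  if (anyNA(vi)) abort("unknown variant identifier in subset")
  genotype_matrix(
    x$dosage[si, vi, drop = FALSE],
    x$variants[vi, , drop = FALSE],
    samples = x$samples[si]
  )
}

#' Extract one variant's dosage vector
#' @param x a `genotype_matrix`.
#' @param id variant id.
#' @return Named numeric vector of dosages.
#' @export
gm_dosage <- function(x, id) {
  stopifnot(inherits(x, "genotype_matrix"))
  j <- match(id, x$variants$id)
  if (is.na(j)) abort(paste0("variant '", id, "' not present"))
  x$dosage[, j]
}
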