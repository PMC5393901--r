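#' Protein panel container
#'
#' Samples-by-assays matrix of log10-scale protein measurements with the QC
#' metadata needed by [qc_proteins()]: the fraction of samples below the
#' assay's lower limit of detection and the inter-plate coefficient of
#' variation, plus the plate assignment of every sample.
#'
#' @param values numeric matrix (samples x assays) on the log10 scale.
#' @param assays tibble with columns `assay`, `frac_below_lod`,
#'   `cv_interplate` (both fractions in `[0, 1]`).
#' @param samples sample identifiers; defaults to rownames.
#' @param plate_of named character vector mapping sample to plate; defaults to
#'   a single plate.
#' @return An object of class `protein_panel`.
#' @export
protein_panel <- function(values, assays, samples = rownames(values),
                          plate_of = NULL) {
  values <- as.matrix(values)
  assays <- as_tibble(assays)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(values)))
  need <- c("assay", "frac_below_lod", "cv_interplate")
  miss <- setdiff(need, names(assays))
  if (length(miss) > 0) {
    abort(paste0("assay table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (ncol(values) != nrow(assays)) {
    abort("number of value columns must equal number of assays")
  }
  if (nrow(values) != length(samples)) {
    abort("number of value rows must equal number of samples")
  }
  for (nm in c("frac_below_lod", "cv_interplate")) {
    x <- assays[[nm]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      abort(paste0(nm, " must lie in [0, 1]"))
    }
  }
  if (any(is.infinite(values))) {
    abort("protein values must be finite or NA")
  }
  if (is.null(plate_of)) {
    plate_of <- setNames(rep("plate1", length(samples)), samples)
  }
  dimnames(values) <- list(samples, assays$assay)
  structure(
    list(values = values, assays = assays, samples = samples,
         plate_of = plate_of),
    class = "protein_panel"
  )
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf(
    "<protein_panel> %d samples x %d assays on %d plate(s)\n",
    length(x$samples), nrow(x$assays), length(unique(x$plate_of))
  ))
  invisible(x)
}

#' @export
dim.protein_panel <- function(x) dim(x$values)

#' eQTL dataset container
#'
#' One expression dataset: log2 expression (samples x genes) aligned to a
#' genotype matrix over the same samples.
#'
#' @param name dataset label.
#' @param expr numeric matrix of log2 expression, samples x genes.
#' @param genotypes a [genotype_matrix()] for the same samples, same order.
#' @return An object of class `eqtl_dataset` with elements `name`, `expr`,
#'   `genotypes`, `n`.
#' @export
eqtl_dataset <- function(name, expr, genotypes) {
  expr <- as.matrix(expr)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(expr) != length(genotypes$samples)) {
    abort("expression and genotype sample counts differ")
  }
  if (!is.null(rownames(expr)) &&
      !identical(rownames(expr), genotypes$samples)) {
    abort("expression rows must align exactly with genotype samples")
  }
  if (nrow(expr) < 30) {
    abort("eQTL datasets need at least 30 samples")
  }
  structure(
    list(name = name, expr = expr, genotypes = genotypes, n = nrow(expr)),
    class = "eqtl_dataset"
  )
}

#' @export
print.eqtl_dataset <- function(x, ...) {
  cat(sprintf("<eqtl_dataset> '%s': %d samples x %d genes\n",
              x$name, x$n, ncol(x$expr)))
  invisible(x)
}
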