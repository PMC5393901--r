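#' Simulate eQTL expression datasets
#'
#' Builds a collection of expression datasets of the kind used for eQTL
#' lookups: each dataset independently subsamples subjects from the genotyped
#' cohort and generates log2 expression with planted additive genetic effects
#' and independent noise. The default sizes emulate a panel of 11 microarray
#' datasets with sample sizes between 89 and 367 (mean ~223).
#'
#' @param gm a [genotype_matrix()] providing the subject pool.
#' @param genes character vector of gene symbols to simulate.
#' @param eqtl_spec tibble of planted effects: `variant`, `gene`, `dataset`,
#'   `variance_explained` in `(0, 1)`. Use dataset `"*"` to plant the effect
#'   in every dataset.
#' @param dataset_sizes named integer vector of per-dataset sample sizes.
#' @param measurable_frac probability that a gene is measured (present on
#'   the array) in any given dataset; genes carrying a planted effect in a
#'   dataset are always measured there. The default 1 measures every gene
#'   everywhere; values below 1 emulate tissue- and platform-restricted
#'   coverage.
#' @param seed integer seed.
#' @return A named list of [eqtl_dataset()] objects.
#' @export
simulate_expression <- function(gm, genes, eqtl_spec = NULL,
                                dataset_sizes = default_eqtl_sizes(),
                                measurable_frac = 1, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  if (any(dataset_sizes < 30)) abort("dataset sample sizes must be >= 30")
  if (is.null(names(dataset_sizes)) || any(names(dataset_sizes) == "")) {
    abort("dataset_sizes must be named")
  }
  if (is.null(eqtl_spec)) {
    eqtl_spec <- tibble(variant = character(), gene = character(),
                        dataset = character(), variance_explained = numeric())
  }
  eqtl_spec <- as_tibble(eqtl_spec)
  if (nrow(eqtl_spec) > 0) {
    if (!all(eqtl_spec$variant %in% gm$variants$id)) {
      abort("planted eQTL references a variant absent from the genotypes")
    }
    if (!all(eqtl_spec$gene %in% genes)) {
      abort("planted eQTL references a gene absent from the gene list")
    }
    known <- c(names(dataset_sizes), "*")
    if (!all(eqtl_spec$dataset %in% known)) {
      abort("planted eQTL references an unknown dataset")
    }
  }
  set.seed(as.integer(seed))
  n_pool <- length(gm$samples)

  out <- list()
  for (d in names(dataset_sizes)) {
    nd <- dataset_sizes[[d]]
    if (nd > n_pool) abort("dataset size exceeds the genotyped pool")
    idx <- sample.int(n_pool, nd)
    sub <- gm_subset(gm, samples = idx)
    spec_d <- eqtl_spec[eqtl_spec$dataset %in% c(d, "*"), , drop = FALSE]
    measured <- genes[runif(length(genes)) <= measurable_frac]
    measured <- union(measured, spec_d$gene)
    measured <- genes[genes %in% measured]
    expr <- matrix(rnorm(nd * length(measured)), nd, length(measured),
                   dimnames = list(sub$samples, measured))
    for (r in seq_len(nrow(spec_d))) {
      g <- gm_dosage(sub, spec_d$variant[r])
      vg <- stats::var(g)
      if (vg == 0) next  # monomorphic in this subsample; effect unplantable
      ve <- spec_d$variance_explained[r]
      b <- sqrt(ve / (1 - ve) / vg)
      expr[, spec_d$gene[r]] <- expr[, spec_d$gene[r]] + b * g
    }
    out[[d]] <- eqtl_dataset(d, expr, sub)
  }
  out
}

#' Default eQTL dataset sizes
#'
#' Eleven datasets spanning 89-367 subjects (mean ~223), the size profile of
#' a multi-tissue cardiovascular eQTL collection.
#'
#' @return Named integer vector of length 11.
#' @export
default_eqtl_sizes <- function() {
  c(
    aorta_media = 89, aorta_adventitia = 133, liver = 206,
    mammary_artery = 89, heart = 127, monocytes = 367, b_cells = 283,
    monocytes_lps2 = 261, monocytes_lps24 = 322, monocytes_ifn = 235,
    whole_blood = 341
  )
}
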