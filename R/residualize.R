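#' Residualize a protein panel on covariates
#'
#' For each assay, fits an ordinary least-squares model of the (log10)
#' protein values on the covariates — age, sex, recruitment centre, analysis
#' batch, smoking, diabetes and hypertension in the standard protocol — and
#' returns the standardized residuals (residuals divided by their standard
#' deviation). Categorical covariates are expanded to indicator contrasts.
#' Samples with a missing protein value are excluded pairwise per assay;
#' missing covariates for included samples are an error.
#'
#' @param panel a [protein_panel()] (typically after [qc_proteins()]).
#' @param covariates tibble with a `sample` column and one column per
#'   covariate; every panel sample must appear.
#' @return A samples-by-assays matrix of standardized residuals (mean 0,
#'   sd 1 per assay), `NA` where the protein value was missing.
#' @export
residualize <- function(panel, covariates) {
  stopifnot(inherits(panel, "protein_panel"))
  covariates <- as_tibble(covariates)
  if (!"sample" %in% names(covariates)) {
    abort("covariates need a 'sample' column")
  }
  idx <- match(panel$samples, covariates$sample)
  if (anyNA(idx)) abort("covariates missing for some panel samples")
  covs <- covariates[idx, setdiff(names(covariates), "sample"), drop = FALSE]
  if (anyNA(covs)) abort("missing covariate values for included samples")
  covs <- as.data.frame(lapply(covs, function(x) {
    if (is.character(x) || is.logical(x)) factor(x) else x
  }))
  X <- model.matrix(~ ., data = covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient covariate design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  out <- matrix(NA_real_, nrow(panel$values), ncol(panel$values),
                dimnames = dimnames(panel$values))
  for (k in seq_len(ncol(panel$values))) {
    y <- panel$values[, k]
    ok <- !is.na(y)
    if (sum(ok) <= ncol(X)) {
      abort(sprintf("too few non-missing samples for assay '%s'",
                    panel$assays$assay[k]))
    }
    r <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])$residuals
    s <- sd(r)
    if (s < 1e-12) {
      abort(sprintf("assay '%s' is constant after covariate adjustment",
                    panel$assays$assay[k]))
    }
    out[ok, k] <- r / s
  }
  out
}
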