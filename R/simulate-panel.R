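#' Simulate covariates for a cohort
#'
#' Generates the covariate structure adjusted for in the discovery scan:
#' age (years), sex, recruitment centre, analysis batch (one batch per
#' measurement plate), current smoking, diabetes and hypertension.
#'
#' @param samples character vector of sample ids.
#' @param n_centres number of recruitment centres.
#' @param plate_size samples per measurement plate.
#' @param seed integer seed.
#' @return A tibble with one row per sample; `batch` equals the plate label.
#' @export
simulate_covariates <- function(samples, n_centres = 7, plate_size = 88, seed) {
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  set.seed(as.integer(seed))
  n <- length(samples)
  plates <- paste0("plate", ceiling(seq_len(n) / plate_size))
  tibble(
    sample = samples,
    age = round(runif(n, 55, 79), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    centre = sample(paste0("centre", seq_len(n_centres)), n, replace = TRUE),
    batch = plates,
    smoking = rbinom(n, 1, 0.25),
    diabetes = rbinom(n, 1, 0.20),
    hypertension = rbinom(n, 1, 0.55)
  )
}

#' Simulate a protein panel with planted genetic effects
#'
#' Builds log10-scale protein measurements as the sum of planted genetic
#' effects, covariate effects, a per-plate random intercept and independent
#' noise, scaled so that each planted effect explains its stated fraction of
#' the protein's variance. Values falling below each assay's detection limit
#' (placed at the `lod_censor_frac` quantile) are censored to the limit, the
#' way multiplexed immunoassay panels report them. The inter-plate CV is
#' computed from a simulated pooled control sample measured once per plate.
#'
#' @param gm a [genotype_matrix()] for the cohort.
#' @param proteins character vector of assay names.
#' @param effects tibble of planted effects: `variant`, `protein`,
#'   `variance_explained` in `(0, 1)`, optional `sign` (+1/-1, default +1).
#'   The summed variance per protein must stay below 1.
#' @param covariates covariate tibble from [simulate_covariates()]; generated
#'   automatically when `NULL`.
#' @param lod_censor_frac named numeric vector (per assay) of censoring
#'   fractions; unnamed scalar recycles. Default 0.02.
#' @param plate_cv named numeric vector (per assay) of target inter-plate
#'   coefficients of variation; unnamed scalar recycles. Default 0.08.
#' @param covar_var fraction of variance from covariates (default 0.15).
#' @param seed integer seed.
#' @return A list with elements `panel` (a [protein_panel()]), `covariates`
#'   (tibble) and `truth` (tibble of planted effects with realized beta).
#' @export
simulate_protein_panel <- function(gm, proteins, effects = NULL,
                                   covariates = NULL,
                                   lod_censor_frac = 0.02, plate_cv = 0.08,
                                   covar_var = 0.15, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  set.seed(as.integer(seed))
  n <- length(gm$samples)
  p <- length(proteins)
  if (is.null(effects)) {
    effects <- tibble(variant = character(), protein = character(),
                      variance_explained = numeric())
  }
  effects <- as_tibble(effects)
  if (nrow(effects) > 0) {
    if (!all(effects$variant %in% gm$variants$id)) {
      abort("planted effect references a variant absent from the genotypes")
    }
    if (!all(effects$protein %in% proteins)) {
      abort("planted effect references an unknown protein")
    }
    if (!"sign" %in% names(effects)) effects$sign <- 1
    budget <- tapply(effects$variance_explained, effects$protein, sum)
    if (any(budget >= 1)) {
      abort("variance budget >= 1 for at least one protein")
    }
    if (any(effects$variance_explained <= 0)) {
      abort("variance_explained must be positive")
    }
  }

  lodf <- .per_assay(lod_censor_frac, proteins, "lod_censor_frac")
  pcv <- .per_assay(plate_cv, proteins, "plate_cv")
  if (is.null(covariates)) {
    covariates <- simulate_covariates(gm$samples, seed = seed + 1L)
  }
  plates <- covariates$batch[match(gm$samples, covariates$sample)]
  plate_levels <- unique(plates)

  # fixed covariate coefficients, rescaled per protein to hit covar_var
  cov_num <- cbind(
    scale(covariates$age),
    covariates$sex == "M",
    covariates$smoking,
    covariates$diabetes,
    covariates$hypertension,
    scale(as.integer(factor(covariates$centre)))
  )

  values <- matrix(NA_real_, n, p, dimnames = list(gm$samples, proteins))
  truth <- effects
  if (nrow(truth) > 0) truth$beta <- NA_real_
  assay_meta <- tibble(
    assay = proteins,
    frac_below_lod = NA_real_,
    cv_interplate = NA_real_
  )

  for (k in seq_len(p)) {
    prot <- proteins[k]
    eff_k <- if (nrow(effects) > 0) effects[effects$protein == prot, ] else effects
    ve_g <- if (nrow(eff_k) > 0) sum(eff_k$variance_explained) else 0

    # log10-scale plate intercepts sized so the raw-scale pooled-control CV
    # approximates the target: cv ~ sigma_log10 * ln(10) for small sigma
    sigma_plate <- pcv[k] / log(10)
    plate_int <- setNames(rnorm(length(plate_levels), 0, sigma_plate),
                          plate_levels)
    var_plate <- sigma_plate^2

    cov_beta <- c(0.5, 0.3, 0.25, 0.25, 0.2, 0.15)
    cov_part <- drop(cov_num %*% cov_beta)
    cov_part <- cov_part / sd(cov_part) * sqrt(covar_var)

    var_noise <- 1 - ve_g - covar_var - var_plate
    if (var_noise <= 0) {
      abort(sprintf("variance budget exceeds 1 for protein '%s'", prot))
    }
    y <- cov_part + plate_int[plates] + rnorm(n, 0, sqrt(var_noise))
    if (nrow(eff_k) > 0) {
      for (r in seq_len(nrow(eff_k))) {
        g <- gm_dosage(gm, eff_k$variant[r])
        vg <- stats::var(g)
        if (vg == 0) abort("planted effect on a monomorphic variant")
        b <- eff_k$sign[r] * sqrt(eff_k$variance_explained[r] / vg)
        y <- y + b * g
        truth$beta[truth$protein == prot &
                     truth$variant == eff_k$variant[r]] <- b
      }
    }
    if (sd(y) < 1e-12) {
      abort(sprintf("degenerate (constant) measurements for protein '%s'", prot))
    }

    # LOD censoring: everything below the lod quantile is reported at the LOD
    if (lodf[k] > 0) {
      lod <- quantile(y, lodf[k], names = FALSE)
      y[y < lod] <- lod
      frac <- mean(y <= lod)
    } else {
      frac <- 0
    }

    # pooled plasma control measured once per plate; CV on the raw scale
    ctrl <- plate_int + rnorm(length(plate_levels), 0, 0.005)
    ctrl_raw <- 10^ctrl
    cvk <- sd(ctrl_raw) / mean(ctrl_raw)

    values[, k] <- y
    assay_meta$frac_below_lod[k] <- frac
    assay_meta$cv_interplate[k] <- cvk
  }

  panel <- protein_panel(
    values, assay_meta, samples = gm$samples,
    plate_of = setNames(plates, gm$samples)
  )
  list(panel = panel, covariates = covariates, truth = truth)
}

.per_assay <- function(x, proteins, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(x, length(proteins)), proteins))
  }
  if (is.null(names(x)) || !all(proteins %in% names(x))) {
    abort(paste0(what, " must be a scalar or named per assay"))
  }
  x[proteins]
}
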