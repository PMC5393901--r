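#' Default analysis configuration
#'
#' Every threshold used by the pipeline, with the defaults of the published
#' protocol this package implements. All comparisons against these thresholds
#' are strict unless a function documents otherwise.
#'
#' @details
#' * `p_gw` — genome-wide significance for the discovery Wald scan (5e-8).
#' * `cis_window_kb` — maximum index-SNP-to-gene distance for a cis call (500).
#' * `trans_min_mb` — minimum same-chromosome distance for a trans call (100).
#' * `merge_r2`, `merge_window_kb` — LD and distance conditions (both required)
#'   under which flagged signals collapse into one locus (0.1, 250).
#' * `proxy_r2` — minimum LD for a replication proxy SNP (0.8).
#' * `coding_r2` — minimum LD between index SNP and a missense coding proxy (0.6).
#' * `eqtl_cis_p` — report threshold for cis-eQTL associations (5e-4, ~FDR 5%).
#' * `eqtl_w1_p`, `eqtl_w2_p` — trans-eQTL p cutoffs mapping genes to path
#'   weights 0.8 and 0.6 (0.05, 0.005).
#' * `net_min_conf` — interaction-network confidence floor, edges kept if
#'   strictly above (400 on the 0-1000 scale).
#' * `n_perm`, `perm_alpha` — permutation replicates and significance level for
#'   the path tests (1000, 0.05).
#' * `lit_min` — literature co-occurrence count above which the literature
#'   criterion fires (50).
#' * `lod_frac`, `cv_max` — assay QC: maximum fraction of samples below the
#'   detection limit (0.20) and maximum inter-plate CV (0.25), strict >.
#' * `hwe_p`, `call_rate` — genotype QC: Hardy-Weinberg exact-test floor (1e-6)
#'   and minimum variant call rate (0.95).
#' * `perm_ties` — tie handling in the permutation count: `"half"` (mid-p,
#'   the default), `"strict"`, or `"leq"`; see [path_permutation_p()].
#' * `perm_plus_one` — if `TRUE`, permutation p uses the (k+1)/(B+1) shift
#'   instead of the plain fraction k/B.
#' * `seed` — integer seed; required for any stochastic run.
#'
#' @param ... named overrides of individual defaults.
#' @return A named list of class `pqtl_config`.
#' @export
#' @examples
#' cfg <- pqtl_config(seed = 1)
#' cfg$p_gw
pqtl_config <- function(...) {
  defaults <- list(
    p_gw = 5e-8,
    cis_window_kb = 500,
    trans_min_mb = 100,
    merge_r2 = 0.1,
    merge_window_kb = 250,
    proxy_r2 = 0.8,
    coding_r2 = 0.6,
    eqtl_cis_p = 5e-4,
    eqtl_w1_p = 0.05,
    eqtl_w2_p = 0.005,
    net_min_conf = 400,
    n_perm = 1000,
    perm_alpha = 0.05,
    lit_min = 50,
    lod_frac = 0.20,
    cv_max = 0.25,
    hwe_p = 1e-6,
    call_rate = 0.95,
    perm_ties = "half",
    perm_plus_one = FALSE,
    seed = NA_integer_
  )
  overrides <- list(...)
  cfg <- .merge_config(defaults, overrides)
  validate_config(cfg)
}

.merge_config <- function(defaults, overrides) {
  if (length(overrides) == 0) {
    return(structure(defaults, class = "pqtl_config"))
  }
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    abort("all configuration overrides must be named")
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown configuration key(s): ", paste(unknown, collapse = ", "),
      "\nvalid keys: ", paste(names(defaults), collapse = ", ")
    ))
  }
  structure(modifyList(defaults, overrides), class = "pqtl_config")
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pqtl_config"))
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0("config key '", nm, "' must be a single value in [0, 1]"))
    }
  }
  for (nm in c("merge_r2", "proxy_r2", "coding_r2", "perm_alpha",
               "lod_frac", "cv_max", "call_rate")) {
    chk_frac(cfg[[nm]], nm)
  }
  for (nm in c("p_gw", "eqtl_cis_p", "eqtl_w1_p", "eqtl_w2_p", "hwe_p")) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1) {
      abort(paste0("config key '", nm, "' must be a p-value threshold in (0, 1]"))
    }
  }
  if (!cfg$perm_ties %in% c("half", "strict", "leq")) {
    abort("config key 'perm_ties' must be one of half, strict, leq")
  }
  for (nm in c("cis_window_kb", "trans_min_mb", "merge_window_kb",
               "net_min_conf", "n_perm", "lit_min")) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      abort(paste0("config key '", nm, "' must be a single nonnegative number"))
    }
  }
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML key-value file of threshold overrides. Keys absent from the
#' file keep the defaults documented in [pqtl_config()]; unknown keys are an
#' error (no silent typo tolerance).
#'
#' @param path path to a YAML file; an empty file yields all defaults.
#' @param seed optional integer seed, overriding any `seed` key in the file.
#' @return A `pqtl_config` list.
#' @export
load_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    abort("config file must contain a key-value mapping")
  }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(pqtl_config, raw)
}

#' @export
print.pqtl_config <- function(x, ...) {
  cat("<pqtl_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
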