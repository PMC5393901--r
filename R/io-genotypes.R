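#' Read genotype dosages
#'
#' Reads a genotype dosage file into a [genotype_matrix()]. Two dialects are
#' supported:
#'
#' * `"vcf_dosage"` — a VCF 4.x file carrying a per-genotype `DS` FORMAT
#'   field. The coded allele is the VCF ALT allele, so every downstream beta
#'   is per copy of ALT. A variant is flagged missense when its INFO field
#'   contains the token `missense` (e.g. a `MISSENSE` flag or an annotation
#'   string); imputation quality is taken from an `R2=` or `RSQ=` INFO key
#'   when present.
#' * `"tsv_dosage"` — a tab-separated table whose header names the variants,
#'   with a leading `sample` column and one row per sample. Variant metadata
#'   (positions, alleles, missense flags) is supplied via `variant_info`.
#'
#' @param path file path.
#' @param dialect `"vcf_dosage"` or `"tsv_dosage"`.
#' @param variant_info optional tibble of variant metadata (columns as in
#'   [genotype_matrix()]) for the TSV dialect; matched by `id`.
#' @return A `genotype_matrix`. Dosages outside `[0, 2]` raise a validation
#'   error naming the offending variant and sample.
#' @export
read_genotypes <- function(path, dialect = c("vcf_dosage", "tsv_dosage"),
                           variant_info = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  switch(dialect,
    vcf_dosage = .read_genotypes_vcf(path),
    tsv_dosage = .read_genotypes_tsv(path, variant_info)
  )
}

.read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || all(is.na(ds))) {
    abort("VCF format error: no per-genotype DS (dosage) field found")
  }
  info <- fix$INFO
  if (is.null(info)) info <- rep("", nrow(fix))
  rsq <- stringr::str_match(info, "(?:^|;)R(?:SQ|2)=([0-9.eE+-]+)")[, 2]
  variants <- tibble(
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    coded_allele = fix$ALT,
    other_allele = fix$REF,
    coded_freq = NA_real_,
    missense = stringr::str_detect(tolower(info), "missense"),
    impute_rsq = suppressWarnings(as.numeric(rsq))
  )
  # vcfR returns variants x samples; pipeline convention is samples x variants
  dosage <- t(ds)
  variants$coded_freq <- colMeans(dosage, na.rm = TRUE) / 2
  .check_dosage_range(dosage, variants$id)
  genotype_matrix(dosage, variants, samples = rownames(dosage))
}

.read_genotypes_tsv <- function(path, variant_info) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2 || !identical(tolower(names(tab)[1]), "sample")) {
    abort("TSV dosage format error: expected header 'sample<TAB>id1<TAB>id2...'")
  }
  samples <- as.character(tab[[1]])
  ids <- names(tab)[-1]
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(dosage)) {
    abort("TSV dosage format error: non-numeric dosage entries")
  }
  .check_dosage_range(dosage, ids)
  if (is.null(variant_info)) {
    variants <- tibble(
      id = ids, chrom = NA_character_, pos = NA_integer_,
      coded_allele = "A", other_allele = "B",
      coded_freq = colMeans(dosage, na.rm = TRUE) / 2
    )
  } else {
    variants <- as_tibble(variant_info)
    variants <- variants[match(ids, variants$id), , drop = FALSE]
    if (anyNA(variants$id)) {
      abort("variant_info lacks metadata for some TSV columns")
    }
  }
  rownames(dosage) <- samples
  genotype_matrix(dosage, variants, samples = samples)
}

.check_dosage_range <- function(dosage, ids) {
  bad <- which(!is.na(dosage) & (dosage < 0 | dosage > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "dosage validation error: value %.4g outside [0, 2] for variant '%s' (row %d)",
      dosage[bad[1, 1], bad[1, 2]], ids[bad[1, 2]], bad[1, 1]
    ))
  }
  invisible(TRUE)
}

#' Write genotype dosages as TSV
#'
#' Inverse of the `tsv_dosage` dialect of [read_genotypes()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tab <- as_tibble(gm$dosage)
  tab <- dplyr::bind_cols(tibble(sample = gm$samples), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
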