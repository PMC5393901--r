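#' Simulate genotype dosages
#'
#' Draws dosages as the sum of two independent Bernoulli haplotypes per
#' sample. Linkage disequilibrium within a chromosome is induced by a latent
#' order-1 autoregressive Gaussian across adjacent variants (correlation
#' `ld_rho`), thresholded at each variant's allele-frequency quantile, so
#' pairwise dosage r-squared increases monotonically with `ld_rho`. Variants
#' on different chromosomes are independent. Deterministic given `seed`.
#'
#' @param n_samples number of samples.
#' @param variant_spec tibble with columns `chrom`, `pos`, `maf` (minor/coded
#'   allele frequency in `(0, 0.5]`) and optionally `id`, `missense`.
#' @param ld_rho latent AR(1) correlation in `[0, 1)`.
#' @param seed integer seed.
#' @return A [genotype_matrix()] whose coded allele is the simulated minor
#'   allele (`coded_freq` is the realized sample frequency).
#' @export
simulate_genotypes <- function(n_samples, variant_spec, ld_rho = 0, seed) {
  variant_spec <- as_tibble(variant_spec)
  if (!all(c("chrom", "pos", "maf") %in% names(variant_spec))) {
    abort("variant_spec needs columns chrom, pos, maf")
  }
  if (any(variant_spec$maf <= 0 | variant_spec$maf > 0.5)) {
    abort("maf must lie in (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must lie in [0, 1)")
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  set.seed(as.integer(seed))

  m <- nrow(variant_spec)
  if (!"id" %in% names(variant_spec)) {
    variant_spec$id <- sprintf("rs%06d", seq_len(m))
  }
  ord <- order(variant_spec$chrom, variant_spec$pos)
  spec <- variant_spec[ord, , drop = FALSE]

  thr <- qnorm(spec$maf)
  hap <- function() {
    z <- matrix(0, n_samples, m)
    for (chrom in unique(spec$chrom)) {
      idx <- which(spec$chrom == chrom)
      e <- matrix(rnorm(n_samples * length(idx)), n_samples, length(idx))
      zc <- e
      if (length(idx) > 1 && ld_rho > 0) {
        for (j in 2:length(idx)) {
          zc[, j] <- ld_rho * zc[, j - 1] + sqrt(1 - ld_rho^2) * e[, j]
        }
      }
      z[, idx] <- zc
    }
    # allele carried when the latent variable falls below the maf quantile
    sweep(z, 2, thr, "<") * 1
  }
  dosage <- hap() + hap()

  variants <- tibble(
    id = spec$id,
    chrom = as.character(spec$chrom),
    pos = as.integer(spec$pos),
    coded_allele = "A",
    other_allele = "G",
    coded_freq = colMeans(dosage) / 2,
    missense = if ("missense" %in% names(spec)) spec$missense else FALSE
  )
  rownames(dosage) <- sprintf("S%05d", seq_len(n_samples))
  genotype_matrix(dosage, variants, samples = rownames(dosage))
}
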