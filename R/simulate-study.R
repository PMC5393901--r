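#' Simulate a complete pQTL study with recorded truth
#'
#' Generates every input the pipeline consumes, with planted and recorded
#' ground truth so each downstream stage can be validated by recovery:
#'
#' * a discovery cohort (default 3,394 samples) genotyped at blocks of three
#'   LD-linked variants, with a 92-assay protein panel of which 9 assays are
#'   constructed to violate QC (5 by below-detection-limit fraction, 4 by
#'   inter-plate CV), leaving 83 analysable proteins;
#' * planted cis effects (index variant inside the protein's own gene) and
#'   trans effects (index variant inside another protein's gene on a
#'   different chromosome), each explaining a stated variance fraction;
#' * three replication cohorts (defaults 976, 933, 730 samples) measured on
#'   the same variants and clean assays;
#' * eleven eQTL expression datasets carrying a planted cis-eQTL on each
#'   trans locus's host gene and a planted trans-eQTL on its mediator gene;
#' * a scale-free interaction network with planted
#'   host-gene -> mediator -> trait-gene paths;
#' * a disease GWAS lookup table in which a subset of proteins is causal.
#'
#' Protein names double as their encoding gene symbols, so the trait-to-gene
#' map is the identity.
#'
#' @param n_samples discovery cohort size.
#' @param n_proteins number of analysable proteins (assays passing QC).
#' @param n_cis,n_trans number of proteins given a planted cis / trans locus.
#' @param n_null_blocks number of variant blocks with no planted effect.
#' @param ve variance explained by each planted pQTL effect.
#' @param ld_rho latent AR(1) LD parameter within a variant block.
#' @param replication_sizes named vector of replication cohort sizes.
#' @param causal_proteins proteins causal for disease in the GWAS table
#'   (default: the first three cis proteins).
#' @param components which optional blocks to generate; the discovery cohort
#'   is always generated.
#' @param seed integer seed; every derived seed stays below 2^31.
#' @return A list: `genotypes`, `panel`, `covariates`, `annotation`,
#'   `trait_genes` (protein -> gene symbol map), `replication` (named list of
#'   cohorts, each `genotypes`/`panel`/`covariates`), `eqtl` (list of
#'   [eqtl_dataset()]), `network`, `disease` (sumstats tibble), and `truth`
#'   (list with `pqtl`, `eqtl`, `mediators`, `causal_proteins`).
#' @export
simulate_study <- function(n_samples = 3394,
                           n_proteins = 83,
                           n_cis = 12, n_trans = 8,
                           n_null_blocks = 10,
                           ve = 0.03,
                           ld_rho = 0.6,
                           replication_sizes = c(repA = 976, repB = 933,
                                                 repC = 730),
                           causal_proteins = NULL,
                           components = c("replication", "eqtl", "network",
                                          "disease"),
                           seed) {
  if (missing(seed) || is.na(seed)) abort("seed is required for simulation")
  seed <- as.integer(seed)
  if (n_cis + n_trans > n_proteins) abort("more planted loci than proteins")
  set.seed(seed)

  proteins <- sprintf("P%02d", seq_len(n_proteins))
  chroms <- as.character(1:6)
  k <- seq_len(n_proteins)
  gene_chrom <- chroms[((k - 1) %% length(chroms)) + 1]
  gene_start <- 4e6 + ((k - 1) %/% length(chroms)) * 4e6
  annotation <- tibble(
    gene_id = proteins, symbol = proteins, chrom = gene_chrom,
    start = as.integer(gene_start), end = as.integer(gene_start + 20000),
    strand = "+"
  )
  trait_genes <- setNames(proteins, proteins)

  # planted loci: three-variant LD blocks, 50 kb apart, index in the middle
  block <- function(chrom, center, tag) {
    tibble(
      id = paste0(tag, c("_l", "", "_r")),
      chrom = chrom,
      pos = as.integer(center + c(-50000, 0, 50000)),
      maf = runif(3, 0.15, 0.5)
    )
  }
  cis_idx <- seq_len(n_cis)
  trans_idx <- n_cis + seq_len(n_trans)
  blocks <- list()
  truth_pqtl <- list()
  mediators <- list()
  for (i in cis_idx) {
    tag <- paste0("rsC", i)
    blocks[[tag]] <- block(annotation$chrom[i], annotation$start[i] + 10000, tag)
    truth_pqtl[[tag]] <- tibble(
      variant = tag, protein = proteins[i], class = "cis",
      variance_explained = ve
    )
  }
  for (j in seq_along(trans_idx)) {
    i <- trans_idx[j]
    # host gene: another protein's gene on a different chromosome
    host <- which(annotation$chrom != annotation$chrom[i])[j]
    tag <- paste0("rsT", j)
    blocks[[tag]] <- block(annotation$chrom[host],
                           annotation$start[host] + 10000, tag)
    truth_pqtl[[tag]] <- tibble(
      variant = tag, protein = proteins[i], class = "trans",
      variance_explained = ve
    )
    mediators[[tag]] <- tibble(
      variant = tag, cis_gene = proteins[host],
      mediator = paste0("MED", j), trait_gene = proteins[i]
    )
  }
  for (b in seq_len(n_null_blocks)) {
    tag <- paste0("rsN", b)
    chrom <- chroms[((b - 1) %% length(chroms)) + 1]
    blocks[[tag]] <- block(chrom, 8e7 + b * 1e6, tag)
  }
  variant_spec <- bind_rows(blocks)
  truth_pqtl <- bind_rows(truth_pqtl)
  mediators <- if (length(mediators) > 0) bind_rows(mediators) else
    tibble(variant = character(), cis_gene = character(),
           mediator = character(), trait_gene = character())

  gm <- simulate_genotypes(n_samples, variant_spec, ld_rho = ld_rho,
                           seed = seed + 11L)

  # 92-assay panel: clean assays first, then the 9 QC-violating ones
  lod_fail <- sprintf("QLOD%d", 1:5)
  cv_fail <- sprintf("QCV%d", 1:4)
  all_assays <- c(proteins, lod_fail, cv_fail)
  lodf <- setNames(rep(0.02, length(all_assays)), all_assays)
  lodf[lod_fail] <- 0.30
  pcv <- setNames(rep(0.08, length(all_assays)), all_assays)
  pcv[cv_fail] <- 0.40
  effects <- truth_pqtl %>%
    select(variant, protein, variance_explained)
  sim_panel <- simulate_protein_panel(
    gm, all_assays, effects = effects,
    lod_censor_frac = lodf, plate_cv = pcv, seed = seed + 23L
  )
  truth_pqtl$beta <- sim_panel$truth$beta[
    match(paste(truth_pqtl$variant, truth_pqtl$protein),
          paste(sim_panel$truth$variant, sim_panel$truth$protein))]

  out <- list(
    genotypes = gm,
    panel = sim_panel$panel,
    covariates = sim_panel$covariates,
    annotation = annotation,
    trait_genes = trait_genes,
    truth = list(pqtl = truth_pqtl, mediators = mediators)
  )

  if ("replication" %in% components) {
    reps <- list()
    for (r in seq_along(replication_sizes)) {
      nm <- names(replication_sizes)[r]
      gmr <- simulate_genotypes(replication_sizes[[r]], variant_spec,
                                ld_rho = ld_rho, seed = seed + 100L + r)
      pr <- simulate_protein_panel(
        gmr, proteins, effects = effects, seed = seed + 200L + r
      )
      reps[[nm]] <- list(genotypes = gmr, panel = pr$panel,
                         covariates = pr$covariates)
    }
    out$replication <- reps
  }

  # filler genes enter the preferential-attachment growth first, so the
  # trait/mediator genes join late and carry typical (low) degrees
  net_genes <- c(sprintf("NWK%03d", 1:150), proteins,
                 unique(mediators$mediator))
  if ("eqtl" %in% components) {
    eqtl_spec <- bind_rows(
      # cis-eQTL of each trans index SNP on its host gene
      tibble(variant = mediators$variant, gene = mediators$cis_gene,
             dataset = "*", variance_explained = 0.20),
      # trans-eQTL of each trans index SNP on its mediator gene
      tibble(variant = mediators$variant, gene = mediators$mediator,
             dataset = "*", variance_explained = 0.06)
    )
    out$eqtl <- simulate_expression(gm, net_genes, eqtl_spec,
                                    measurable_frac = 0.3,
                                    seed = seed + 301L)
    out$truth$eqtl <- eqtl_spec
  }

  if ("network" %in% components) {
    planted_edges <- bind_rows(
      tibble(geneA = mediators$cis_gene, geneB = mediators$mediator,
             confidence = 900L),
      tibble(geneA = mediators$mediator, geneB = mediators$trait_gene,
             confidence = 900L)
    )
    if (nrow(planted_edges) == 0) planted_edges <- NULL
    out$network <- simulate_network(net_genes, m_attach = 3,
                                    planted_edges = planted_edges,
                                    seed = seed + 401L)
  }

  if ("disease" %in% components) {
    if (is.null(causal_proteins)) {
      causal_proteins <- proteins[head(cis_idx, 3)]
    }
    out$disease <- simulate_disease_sumstats(
      truth_pqtl, gm$variants, causal_proteins, seed = seed + 501L
    )
    out$truth$causal_proteins <- causal_proteins
  }

  out
}

#' Summarise recovery of planted pQTLs
#'
#' Joins discovered loci back to the planted truth: a planted effect counts
#' as recovered when some locus for its protein has an index SNP within
#' `window_kb` of the planted index variant, and a discovered locus counts
#' as a false discovery when it cannot be attributed to any planted effect
#' for that protein.
#'
#' @param loci classified locus tibble (see [classify_loci()]).
#' @param truth_pqtl truth tibble from [simulate_study()] (`$truth$pqtl`).
#' @param gm the discovery [genotype_matrix()] (for variant positions).
#' @param window_kb attribution window around the planted index variant.
#' @return A list: `per_effect` tibble (planted effect, recovered flag,
#'   class_correct flag), `n_false` count of unattributable loci.
#' @export
recovery_summary <- function(loci, truth_pqtl, gm, window_kb = 250) {
  vmeta <- gm$variants
  truth <- as_tibble(truth_pqtl) %>%
    mutate(
      chrom = vmeta$chrom[match(.data$variant, vmeta$id)],
      pos = vmeta$pos[match(.data$variant, vmeta$id)]
    )
  loci <- as_tibble(loci) %>%
    mutate(
      idx_chrom = vmeta$chrom[match(.data$index_id, vmeta$id)],
      idx_pos = vmeta$pos[match(.data$index_id, vmeta$id)]
    )
  per_effect <- truth %>%
    mutate(recovered = FALSE, class_correct = NA)
  attributed <- rep(FALSE, nrow(loci))
  for (r in seq_len(nrow(truth))) {
    hit <- which(
      loci$trait == truth$protein[r] &
        loci$idx_chrom == truth$chrom[r] &
        abs(loci$idx_pos - truth$pos[r]) <= window_kb * 1000
    )
    if (length(hit) > 0) {
      per_effect$recovered[r] <- TRUE
      per_effect$class_correct[r] <-
        any(loci$locus_class[hit] == truth$class[r])
      attributed[hit] <- TRUE
    }
  }
  list(per_effect = per_effect, n_false = sum(!attributed))
}
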