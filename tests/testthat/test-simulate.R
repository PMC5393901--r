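test_that("simulated genotypes hit their allele frequency and obey HWE", {
  spec <- tibble::tibble(chrom = "1", pos = c(1e6, 2e6), maf = 0.3)
  gm <- simulate_genotypes(5000, spec, ld_rho = 0, seed = 51)
  freq <- colMeans(gm$dosage) / 2
  expect_true(all(abs(freq - 0.3) < 0.02))
  for (j in 1:2) {
    g <- gm$dosage[, j]
    expect_gt(hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)), 1e-6)
  }
  expect_error(simulate_genotypes(100, dplyr::mutate(spec, maf = 0.6), seed = 1),
               "maf")
})

test_that("the AR(1) latent structure induces LD between adjacent variants", {
  # Gaussian-copula oracle: thresholding a rho = 0.9 latent pair at the
  # maf = 0.5 quantile gives indicator correlation 2*asin(0.9)/pi + ... ,
  # a dosage r2 of ~0.51; at n = 5000 the estimate stays above 0.5
  spec <- tibble::tibble(chrom = "1", pos = c(1e6, 1.01e6), maf = 0.5)
  gm <- simulate_genotypes(5000, spec, ld_rho = 0.9, seed = 52)
  expect_gt(ld_r2(gm, gm$variants$id[1], gm$variants$id[2]), 0.5)
  # and pairwise r2 grows monotonically with ld_rho
  r2_at <- function(rho) {
    gmr <- simulate_genotypes(5000, spec, ld_rho = rho, seed = 152)
    ld_r2(gmr, gmr$variants$id[1], gmr$variants$id[2])
  }
  expect_gt(r2_at(0.9), r2_at(0.5))
  expect_gt(r2_at(0.5), r2_at(0))
  # variants on different chromosomes stay independent
  spec2 <- tibble::tibble(chrom = c("1", "2"), pos = c(1e6, 1e6), maf = 0.3)
  gm2 <- simulate_genotypes(5000, spec2, ld_rho = 0.9, seed = 53)
  expect_lt(ld_r2(gm2, gm2$variants$id[1], gm2$variants$id[2]), 0.01)
})

test_that("generators are pure functions of their seed", {
  spec <- tibble::tibble(chrom = "1", pos = c(1e6, 2e6, 3e6), maf = 0.25)
  g1 <- simulate_genotypes(200, spec, ld_rho = 0.5, seed = 54)
  g2 <- simulate_genotypes(200, spec, ld_rho = 0.5, seed = 54)
  expect_identical(g1$dosage, g2$dosage)

  net1 <- simulate_network(paste0("g", 1:50), seed = 55)
  net2 <- simulate_network(paste0("g", 1:50), seed = 55)
  expect_identical(igraph::as_edgelist(net1), igraph::as_edgelist(net2))

  truth <- tibble::tibble(variant = "v1", protein = "P", beta = 0.2)
  vmeta <- tibble::tibble(id = "v1", chrom = "1", pos = 1L,
                          coded_allele = "A", other_allele = "G")
  d1 <- simulate_disease_sumstats(truth, vmeta, "P", seed = 56)
  d2 <- simulate_disease_sumstats(truth, vmeta, "P", seed = 56)
  expect_identical(d1, d2)
})

test_that("planted protein effects realize their variance fraction", {
  spec <- tibble::tibble(chrom = "1", pos = 1e6, maf = 0.3, id = "v1")
  gm <- simulate_genotypes(3394, spec, seed = 57)
  sim <- simulate_protein_panel(
    gm, "P1",
    effects = tibble::tibble(variant = "v1", protein = "P1",
                             variance_explained = 0.05),
    seed = 58
  )
  r2 <- cor(gm$dosage[, 1], sim$panel$values[, 1])^2
  expect_gt(r2, 0.03)
  expect_lt(r2, 0.07)
  expect_error(
    simulate_protein_panel(
      gm, "P1",
      effects = tibble::tibble(variant = "v1", protein = "P1",
                               variance_explained = 1.2),
      seed = 58
    ),
    "variance"
  )
})

test_that("below-LOD censoring is recorded and caught by assay QC", {
  spec <- tibble::tibble(chrom = "1", pos = 1e6, maf = 0.3, id = "v1")
  gm <- simulate_genotypes(2000, spec, seed = 59)
  sim <- simulate_protein_panel(gm, c("X", "Y"),
                                lod_censor_frac = c(X = 0.25, Y = 0.02),
                                plate_cv = 0.08, seed = 60)
  meta <- sim$panel$assays
  expect_gt(meta$frac_below_lod[meta$assay == "X"], 0.20)
  expect_equal(meta$frac_below_lod[meta$assay == "X"], 0.25, tolerance = 0.02)
  kept <- qc_proteins(sim$panel)
  expect_identical(kept$assays$assay, "Y")
  expect_identical(attr(kept, "removed")$reason, "lod")
})

test_that("planted cis-eQTLs are detected at the report threshold", {
  spec <- tibble::tibble(chrom = "1", pos = 1e6, maf = 0.3, id = "v1")
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    gm <- simulate_genotypes(500, spec, seed = 6000 + r)
    eq <- simulate_expression(
      gm, c("G1", "G2"),
      eqtl_spec = tibble::tibble(variant = "v1", gene = "G1", dataset = "d",
                                 variance_explained = 0.20),
      dataset_sizes = c(d = 223), seed = 6100 + r
    )
    res <- cis_eqtl_scan("v1", "G1", eq)
    if (nrow(res) == 1 && res$p < 5e-4) hits <- hits + 1
  }
  # noncentrality n * R2 / (1 - R2) ~ 56 makes detection near-certain
  expect_gte(hits / n_rep, 0.95)
})

test_that("expression without planted effects is uncorrelated with genotype", {
  spec <- tibble::tibble(chrom = "1", pos = 1e6, maf = 0.3, id = "v1")
  gm <- simulate_genotypes(500, spec, seed = 61)
  eq <- simulate_expression(gm, paste0("G", 1:100),
                            dataset_sizes = c(d = 89), seed = 62)
  g <- gm_dosage(eq$d$genotypes, "v1")
  rs <- apply(eq$d$expr, 2, function(e) cor(g, e))
  # null bound: the largest of 100 null correlations at n = 89 stays below
  # the z = 4.4 / sqrt(n) envelope (99.9% level for the maximum)
  expect_lt(max(abs(rs)), 0.47)
  expect_lt(median(abs(rs)), 0.15)
})

test_that("network growth yields the attachment edge count and planted paths", {
  net <- simulate_network(paste0("g", 1:200), m_attach = 2, seed = 63)
  expect_equal(igraph::ecount(net), 2 * (200 - 2))
  expect_error(simulate_network(paste0("g", 1:10), m_attach = 0, seed = 1),
               "m_attach")
  expect_error(
    simulate_network(paste0("g", 1:10),
                     planted_edges = tibble::tibble(geneA = "g1",
                                                    geneB = "nope",
                                                    confidence = 900L),
                     seed = 1),
    "unknown gene"
  )

  genes <- c(paste0("g", 1:40), "CISG", "MED", "TRAIT")
  net2 <- simulate_network(
    genes, m_attach = 2,
    planted_edges = tibble::tibble(geneA = c("CISG", "MED"),
                                   geneB = c("MED", "TRAIT"),
                                   confidence = 900L),
    seed = 64
  )
  if (igraph::are_adjacent(net2, "CISG", "TRAIT")) {
    net2 <- igraph::delete_edges(net2,
                                 igraph::get_edge_ids(net2, c("CISG", "TRAIT")))
  }
  sp <- shortest_path(net2, "CISG", "TRAIT")
  expect_equal(sp$unweighted_len, 2)
})

test_that("disease sumstats reflect causal proteins through the shared-direction rule", {
  truth <- tibble::tibble(
    variant = paste0("v", 1:3), protein = "CAUS", beta = c(0.12, -0.15, 0.2)
  )
  vmeta <- tibble::tibble(id = paste0("v", 1:3), chrom = "1",
                          pos = 1:3, coded_allele = "A", other_allele = "G")
  d <- simulate_disease_sumstats(truth, vmeta, "CAUS", se_scale = 0.01,
                                 proportionality = 0.5, seed = 65)
  # z = 0.5 * beta / se gives |z| >= 5 whenever |protein beta| >= 0.1
  expect_true(all(d$p < 0.05))
  expect_equal(d$beta, 0.5 * truth$beta)

  null_truth <- tibble::tibble(variant = paste0("n", 1:1000),
                               protein = "NULLP", beta = 0.2)
  null_meta <- tibble::tibble(id = paste0("n", 1:1000), chrom = "1",
                              pos = seq_len(1000), coded_allele = "A",
                              other_allele = "G")
  dn <- simulate_disease_sumstats(null_truth, null_meta,
                                  character(0), seed = 66)
  expect_equal(mean(dn$p < 0.05), 0.05, tolerance = 0.025)
  expect_error(
    simulate_disease_sumstats(truth, vmeta, "UNKNOWN", seed = 1),
    "unknown causal"
  )
})

test_that("the assembled study records closed truth references", {
  st <- simulate_study(n_samples = 400, n_proteins = 10, n_cis = 2,
                       n_trans = 2, n_null_blocks = 2,
                       replication_sizes = c(rA = 100),
                       seed = 67)
  expect_true(all(st$truth$pqtl$variant %in% st$genotypes$variants$id))
  expect_true(all(st$truth$pqtl$protein %in% st$panel$assays$assay))
  expect_true(all(st$truth$mediators$mediator %in%
                    igraph::V(st$network)$name))
  expect_true(all(st$truth$mediators$cis_gene %in% st$annotation$symbol))
  expect_true(all(st$truth$causal_proteins %in% st$truth$pqtl$protein))
  expect_true(all(st$truth$eqtl$gene %in%
                    unique(unlist(purrr::map(st$eqtl, ~ colnames(.x$expr))))))
  # 92-assay design: 9 QC-violating assays on top of the analysable panel
  expect_equal(nrow(st$panel$assays), 10 + 9)
})
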