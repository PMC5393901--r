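pq <- function(id, ca = "A", oa = "G") {
  tibble::tibble(id = id, coded_allele = ca, other_allele = oa)
}
dz <- function(id, beta, ca = "A", oa = "G", se = 0.01) {
  tibble::tibble(id = id, coded_allele = ca, other_allele = oa,
                 beta = beta, se = se)
}

test_that("harmonization aligns alleles and flips to the risk direction", {
  # already aligned, positive: unchanged
  out <- harmonize_to_risk(pq("rs1"), dz("rs1", 0.08))
  expect_equal(out$beta, 0.08)
  expect_identical(out$coded_allele, "A")

  # negative beta: flipped so the coded allele raises risk
  out2 <- harmonize_to_risk(pq("rs2"), dz("rs2", -0.05))
  expect_equal(out2$beta, 0.05)
  expect_identical(out2$coded_allele, "G")
  expect_match(out2$flipped, "risk_flip")

  # swapped allele order in the disease file: sign flips on matching
  out3 <- harmonize_to_risk(pq("rs3"), dz("rs3", 0.05, ca = "G", oa = "A"))
  expect_equal(out3$beta, 0.05)  # -0.05 after swap, then risk-flipped
  expect_match(out3$flipped, "allele_swap")

  # palindromic and mismatched pairs are excluded with warnings
  expect_warning(
    none <- harmonize_to_risk(pq("rs4", ca = "A", oa = "T"),
                              dz("rs4", 0.05, ca = "A", oa = "T")),
    "strand-ambiguous"
  )
  expect_equal(nrow(none), 0)
  expect_warning(
    none2 <- harmonize_to_risk(pq("rs5"), dz("rs5", 0.05, ca = "C", oa = "T")),
    "do not match"
  )
  expect_equal(nrow(none2), 0)
})

test_that("harmonization is idempotent", {
  aligned <- harmonize_to_risk(pq("rs1"), dz("rs1", -0.07))
  again <- harmonize_to_risk(aligned[, c("id", "coded_allele", "other_allele")],
                             aligned)
  expect_equal(again$beta, aligned$beta)
  expect_identical(again$coded_allele, aligned$coded_allele)
})

test_that("pooled scores follow the inverse-variance closed form", {
  single <- pooled_score(tibble::tibble(beta = 0.08, se = 0.01), "P")
  expect_equal(single$pooled_beta, 0.08)
  expect_equal(single$pooled_se, 0.01)

  two <- pooled_score(tibble::tibble(beta = c(0.05, 0.03),
                                     se = c(0.01, 0.015)), "P")
  w <- c(1 / 1e-4, 1 / 2.25e-4)
  expect_equal(two$pooled_beta, sum(c(0.05, 0.03) * w) / sum(w),
               tolerance = 1e-12)
  expect_equal(two$pooled_beta, 0.0438, tolerance = 2e-3)
  expect_equal(two$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(two$pooled_se, 0.00832, tolerance = 1e-4)

  for (k in c(2, 5)) {
    rep_k <- pooled_score(tibble::tibble(beta = rep(0.04, k),
                                         se = rep(0.012, k)), "P")
    expect_equal(rep_k$pooled_se, 0.012 / sqrt(k))
  }
  expect_error(pooled_score(tibble::tibble(beta = -0.1, se = 0.01)),
               "risk-aligned")
})

test_that("pooling several weak concordant signals can beat the best single p", {
  # per-SNP p from 5.7e-4 to 0.52, all risk-aligned
  recs <- tibble::tibble(
    beta = c(0.031, 0.020, 0.012, 0.006),
    se = c(0.009, 0.009, 0.009, 0.0093)
  )
  ps <- 2 * pnorm(-recs$beta / recs$se)
  expect_equal(min(ps), 5.7e-4, tolerance = 0.05)
  expect_equal(max(ps), 0.52, tolerance = 0.05)
  pooled <- pooled_score(recs, "LG")
  expect_lt(pooled$pooled_p, min(ps))
})

test_that("BH flags match the brute-force step-up rule", {
  flags <- bh_fdr(c(0.001, 0.011, 0.02, 0.8), q = 0.05)
  expect_identical(flags$significant, bh_oracle(c(0.001, 0.011, 0.02, 0.8), 0.05))

  expect_identical(bh_fdr(rep(1, 5))$significant, rep(FALSE, 5))
  expect_true(bh_fdr(0.04, q = 0.05)$significant)

  set.seed(111)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)$significant
    expect_identical(got, bh_oracle(p, q))
    # monotone: everything below a flagged p is flagged
    if (any(got)) expect_true(all(got[p <= max(p[got])]))
  }
  expect_equal(nrow(bh_fdr(numeric(0))), 0)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
})

test_that("the disease lookup flags planted causal proteins", {
  st <- simulate_study(n_samples = 1500, n_proteins = 10, n_cis = 4,
                       n_trans = 0, n_null_blocks = 2, ve = 0.05,
                       components = "disease", seed = 115)
  pan <- qc_proteins(st$panel)
  res <- residualize(pan, st$covariates)
  res <- res[, intersect(colnames(res), names(st$trait_genes)), drop = FALSE]
  sc <- wald_scan(res, st$genotypes)
  loci <- classify_loci(merge_loci(dplyr::filter(sc, flagged), st$genotypes),
                        st$annotation, st$trait_genes, st$genotypes)
  rs <- risk_score_lookup(loci, st$genotypes, st$disease)
  expect_true(all(st$truth$causal_proteins %in%
                    rs$protein[rs$fdr_significant]))
})
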