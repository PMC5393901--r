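test_that("IVW pooling reproduces its closed forms", {
  m1 <- ivw_meta(tibble::tibble(beta = 0.1, se = 0.02))
  expect_equal(m1$pooled_beta, 0.1)
  expect_equal(m1$pooled_se, 0.02)
  expect_equal(m1$pooled_p, 2 * pnorm(-5))

  m2 <- ivw_meta(tibble::tibble(beta = c(0.1, 0.1), se = c(0.02, 0.02)))
  expect_equal(m2$pooled_beta, 0.1)
  expect_equal(m2$pooled_se, 0.02 / sqrt(2))

  m3 <- ivw_meta(tibble::tibble(beta = c(0.1, -0.1), se = c(0.02, 0.02)))
  expect_equal(m3$pooled_beta, 0)
  expect_identical(m3$direction, "+-")
})

test_that("IVW matches an independent fixed-effects implementation", {
  set.seed(13)
  for (i in 1:100) {
    k <- sample(1:8, 1)
    est <- tibble::tibble(beta = rnorm(k, 0, 0.2),
                          se = runif(k, 0.01, 0.3))
    m <- ivw_meta(est)
    fe <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
    expect_equal(m$pooled_beta, as.numeric(fe$beta), tolerance = 1e-12)
    expect_equal(m$pooled_se, as.numeric(fe$se), tolerance = 1e-12)
  }
})

test_that("pooling k identical cohorts scales the se by k^(-1/2) exactly", {
  for (k in c(2, 3, 7)) {
    m <- ivw_meta(tibble::tibble(beta = rep(0.07, k), se = rep(0.015, k)))
    expect_equal(m$pooled_se, 0.015 / sqrt(k))
    expect_equal(m$pooled_beta, 0.07)
  }
})

test_that("tidy and glance expose per-cohort and pooled views", {
  m <- ivw_meta(tibble::tibble(cohort = c("a", "b"), beta = c(0.1, 0.2),
                               se = c(0.02, 0.04), n = c(100L, 50L)))
  td <- tidy(m)
  expect_identical(td$cohort, c("a", "b"))
  expect_equal(td$weight, 1 / c(0.02, 0.04)^2)
  gl <- glance(m)
  expect_identical(names(gl),
                   c("pooled_beta", "pooled_se", "pooled_p", "direction",
                     "n_cohorts"))
  expect_identical(gl$direction, "++")
})

test_that("proxy search prefers exact matches and applies the LD threshold", {
  set.seed(14)
  n <- 2000
  v1 <- rbinom(n, 2, 0.4)
  strong <- v1; flip <- sample.int(n, 60); strong[flip] <- rbinom(60, 2, 0.4)
  weak <- v1; flip <- sample.int(n, 900); weak[flip] <- rbinom(900, 2, 0.4)
  ld_ref <- make_gm(cbind(index = v1, strong = strong, weak = weak,
                          anti = 2 - strong),
                    pos = c(1e6, 1.2e6, 1.3e6, 1.25e6))
  expect_gt(ld_r2(ld_ref, "index", "strong"), 0.8)
  expect_lt(ld_r2(ld_ref, "index", "weak"), 0.8)

  self <- find_proxy("index", c("index", "strong"), ld_ref)
  expect_identical(self$id, "index")
  expect_equal(self$r2, 1)

  prox <- find_proxy("index", c("strong", "weak"), ld_ref)
  expect_identical(prox$id, "strong")
  expect_gt(prox$r2, 0.8)
  expect_identical(prox$sign, 1)

  # anti-correlated proxy carries the harmonizing sign
  anti <- find_proxy("index", c("anti", "weak"), ld_ref)
  expect_identical(anti$id, "anti")
  expect_identical(anti$sign, -1)

  none <- find_proxy("index", "weak", ld_ref)
  expect_null(none)
})

test_that("replication status applies the rounded Bonferroni rule and sign concordance", {
  expect_identical(replication_status(0.1, NULL, 71), "not_measured")
  expect_equal(bonferroni_threshold(71), 0.0007)
  m_bonf <- ivw_meta(tibble::tibble(beta = 0.09, se = 0.025))  # p ~ 3e-4
  expect_identical(replication_status(0.1, m_bonf, 71), "replicated_bonferroni")
  m_nom <- ivw_meta(tibble::tibble(beta = 0.05, se = 0.02))    # p ~ 0.012
  expect_identical(replication_status(0.1, m_nom, 71), "replicated_nominal")
  # concordant sign is required for either replicated status
  expect_identical(replication_status(-0.1, m_bonf, 71), "not_replicated")
  m_null <- ivw_meta(tibble::tibble(beta = 0.01, se = 0.02))
  expect_identical(replication_status(0.1, m_null, 71), "not_replicated")
})

test_that("planted effects replicate across synthetic cohorts", {
  st <- simulate_study(n_samples = 1200, n_proteins = 8, n_cis = 2,
                       n_trans = 1, n_null_blocks = 2, ve = 0.05,
                       replication_sizes = c(rA = 400, rB = 350, rC = 300),
                       components = "replication", seed = 401)
  pan <- qc_proteins(st$panel)
  res <- residualize(pan, st$covariates)
  res <- res[, intersect(colnames(res), names(st$trait_genes)), drop = FALSE]
  sc <- wald_scan(res, st$genotypes)
  loci <- classify_loci(merge_loci(dplyr::filter(sc, flagged), st$genotypes),
                        st$annotation, st$trait_genes, st$genotypes)
  rep <- replicate_loci(loci, st$replication, st$genotypes)
  planted <- rep[rep$index_id %in% st$truth$pqtl$variant, ]
  expect_true(all(planted$status %in%
                    c("replicated_bonferroni", "replicated_nominal")))
  expect_true(all(nchar(planted$direction) == 3))
})
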