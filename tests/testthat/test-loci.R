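# genotypes with controlled LD: v2 is a noisy copy of v1 (high r2),
# v3 independent
make_ld_gm <- function(n = 2000, seed = 31, pos = c(1e6, 1.1e6, 1.11e6)) {
  set.seed(seed)
  v1 <- rbinom(n, 2, 0.4)
  v2 <- v1
  flip <- sample.int(n, round(0.15 * n))
  v2[flip] <- rbinom(length(flip), 2, 0.4)
  v3 <- rbinom(n, 2, 0.4)
  make_gm(cbind(v1 = v1, v2 = v2, v3 = v3), pos = pos)
}

flag_row <- function(variant, trait, p, beta = 0.1) {
  tibble::tibble(variant = variant, trait = trait, beta = beta, se = 0.01,
                 p = p, n = 1000L, r2_explained = 0.02, flagged = TRUE)
}

test_that("a single flagged signal forms its own locus", {
  gm <- make_ld_gm()
  loci <- merge_loci(flag_row("v1", "T", 1e-10), gm)
  expect_equal(nrow(loci), 1)
  expect_identical(loci$index_id, "v1")
  expect_equal(loci$n_members, 1L)
})

test_that("signals merge only when both LD and distance conditions hold", {
  gm <- make_ld_gm()
  expect_gt(ld_r2(gm, "v1", "v2"), 0.1)
  expect_lt(ld_r2(gm, "v1", "v3"), 0.1)

  # linked and within 250 kb: one locus, index is the stronger p
  loci <- merge_loci(dplyr::bind_rows(flag_row("v2", "T", 1e-9),
                                      flag_row("v1", "T", 1e-10)), gm)
  expect_equal(nrow(loci), 1)
  expect_identical(loci$index_id, "v1")
  expect_equal(loci$n_members, 2L)

  # unlinked though nearby: two loci (AND semantics)
  loci2 <- merge_loci(dplyr::bind_rows(flag_row("v1", "T", 1e-10),
                                       flag_row("v3", "T", 1e-9)), gm)
  expect_equal(nrow(loci2), 2)

  # linked but far apart: two loci
  gm_far <- make_ld_gm(pos = c(1e6, 2e6, 2.1e6))
  loci3 <- merge_loci(dplyr::bind_rows(flag_row("v1", "T", 1e-10),
                                       flag_row("v2", "T", 1e-9)), gm_far)
  expect_equal(nrow(loci3), 2)
})

test_that("merging preserves all records and is idempotent", {
  gm <- make_ld_gm()
  flagged <- dplyr::bind_rows(
    flag_row("v1", "T", 1e-10), flag_row("v2", "T", 1e-9),
    flag_row("v3", "T", 1e-8), flag_row("v1", "U", 1e-12)
  )
  loci <- merge_loci(flagged, gm)
  members <- dplyr::bind_rows(loci$members)
  expect_setequal(paste(members$variant, members$trait),
                  paste(flagged$variant, flagged$trait))
  # indices of distinct loci must pairwise fail the merge condition
  for (tr in unique(loci$trait)) {
    idx <- loci$index_id[loci$trait == tr]
    if (length(idx) > 1) {
      for (i in seq_along(idx)) for (j in seq_len(i - 1)) {
        d <- abs(gm$variants$pos[match(idx[i], gm$variants$id)] -
                   gm$variants$pos[match(idx[j], gm$variants$id)])
        linked <- ld_r2(gm, idx[i], idx[j]) > 0.1 && d <= 250000
        expect_false(linked)
      }
    }
  }
  # re-merging the index records reproduces the loci
  again <- merge_loci(dplyr::bind_rows(purrr::map(loci$members, ~ .x[1, ])), gm)
  expect_setequal(paste(again$trait, again$index_id),
                  paste(loci$trait, loci$index_id))
})

test_that("locus classification follows window, override and chromosome rules", {
  annotation <- tibble::tibble(
    gene_id = c("G1", "G2"), symbol = c("G1", "G2"), chrom = c("1", "1"),
    start = c(1000000L, 150000000L), end = c(1020000L, 150020000L),
    strand = "+"
  )
  gm <- make_gm(
    cbind(inside = rbinom(50, 2, 0.4), far = rbinom(50, 2, 0.4),
          border = rbinom(50, 2, 0.4), other = rbinom(50, 2, 0.4)),
    chrom = c("1", "1", "1", "9"),
    pos = c(1010000, 115e6, 1020000 + 530700, 5e6)
  )
  trait_genes <- c(A = "G1", B = "G1", C = "G1", D = "G1")
  mk_locus <- function(id, trait) {
    tibble::tibble(trait = trait, index_id = id, beta = 0.1, se = 0.01,
                   p = 1e-10, n = 100L, r2_explained = 0.1, n_members = 1L)
  }
  inside <- classify_loci(mk_locus("inside", "A"), annotation, trait_genes, gm)
  expect_identical(inside$locus_class, "cis")
  expect_identical(inside$distance_kb, 0)

  # same chromosome, >=100 Mb away: trans with a signed distance
  far <- classify_loci(mk_locus("far", "B"), annotation, trait_genes, gm)
  expect_identical(far$locus_class, "trans")
  expect_equal(far$distance_kb, (115e6 - 1020000) / 1000)

  # 530.7 kb: outside the 500 kb window unless the curated override names it
  expect_warning(
    amb <- classify_loci(mk_locus("border", "C"), annotation, trait_genes, gm),
    "ambiguous"
  )
  expect_identical(amb$locus_class, "ambiguous")
  ovr <- classify_loci(mk_locus("border", "C"), annotation, trait_genes, gm,
                       overrides = "C:border")
  expect_identical(ovr$locus_class, "cis")
  expect_equal(ovr$distance_kb, 530.7)

  # different chromosome: trans, distance undefined
  tr <- classify_loci(mk_locus("other", "D"), annotation, trait_genes, gm)
  expect_identical(tr$locus_class, "trans")
  expect_true(is.na(tr$distance_kb))
})

test_that("signed distances are negative on the lower-coordinate side", {
  expect_equal(signed_distance_kb(900000, 1000000, 1020000), -100)
  expect_equal(signed_distance_kb(1120000, 1000000, 1020000), 100)
  expect_equal(signed_distance_kb(1010000, 1000000, 1020000), 0)
})
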