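#' Merge flagged associations into loci
#'
#' Greedy per-trait merging of genome-wide-significant signals: the
#' strongest remaining record (smallest p) becomes an index SNP, and every
#' remaining record with LD r-squared strictly above `merge_r2` AND distance
#' at most `merge_window_kb` from it is absorbed into that locus (both
#' conditions required; variants on different chromosomes never merge). The
#' procedure repeats until no flagged record remains; it is deterministic
#' (p ties broken by variant id) and idempotent.
#'
#' @param flagged tibble of flagged association records from [wald_scan()]
#'   (columns `variant`, `trait`, `beta`, `se`, `p`, `n`, `r2_explained`).
#' @param gm the [genotype_matrix()] used for LD and positions.
#' @param merge_r2 LD threshold (strict >; default 0.1).
#' @param merge_window_kb distance threshold in kb (default 250).
#' @return A tibble with one row per locus: `trait`, `index_id`, index-SNP
#'   statistics (`beta`, `se`, `p`, `n`, `r2_explained`), `n_members`, and a
#'   `members` list-column holding the absorbed records.
#' @export
merge_loci <- function(flagged, gm, merge_r2 = 0.1, merge_window_kb = 250) {
  stopifnot(inherits(gm, "genotype_matrix"))
  flagged <- as_tibble(flagged)
  if (nrow(flagged) == 0) {
    return(tibble(trait = character(), index_id = character(),
                  beta = numeric(), se = numeric(), p = numeric(),
                  n = integer(), r2_explained = numeric(),
                  n_members = integer(), members = list()))
  }
  vmeta <- gm$variants
  out <- list()
  for (tr in unique(flagged$trait)) {
    rec <- flagged %>%
      filter(.data$trait == tr) %>%
      arrange(.data$p, .data$variant)
    rec$chrom <- vmeta$chrom[match(rec$variant, vmeta$id)]
    rec$pos <- vmeta$pos[match(rec$variant, vmeta$id)]
    while (nrow(rec) > 0) {
      index <- rec[1, ]
      rest <- rec[-1, , drop = FALSE]
      if (nrow(rest) > 0) {
        same_chrom <- !is.na(rest$chrom) & rest$chrom == index$chrom
        near <- same_chrom &
          abs(rest$pos - index$pos) <= merge_window_kb * 1000
        linked <- vapply(seq_len(nrow(rest)), function(i) {
          if (!near[i]) return(FALSE)
          .r2_or_zero(ld_r2(gm, index$variant, rest$variant[i])) > merge_r2
        }, logical(1))
      } else {
        linked <- logical(0)
      }
      members <- bind_rows(index, rest[linked, , drop = FALSE])
      out[[length(out) + 1]] <- tibble(
        trait = tr,
        index_id = index$variant,
        beta = index$beta, se = index$se, p = index$p,
        n = index$n, r2_explained = index$r2_explained,
        n_members = nrow(members),
        members = list(select(members, -"chrom", -"pos"))
      )
      rec <- rest[!linked, , drop = FALSE]
    }
  }
  bind_rows(out)
}

#' Classify loci as cis or trans
#'
#' Computes the signed distance between each locus's index SNP and the gene
#' encoding its trait protein, and assigns the locus class:
#'
#' * distance 0 when the SNP lies inside the gene body; otherwise the signed
#'   distance in kb to the nearest gene boundary, negative when the SNP lies
#'   on the lower-coordinate (5' on the reference + strand) side;
#' * `cis` when |distance| <= `cis_window_kb`, or when the locus is named in
#'   `overrides` (for curated borderline cases just outside the window);
#' * `trans` when the SNP sits on a different chromosome (distance reported
#'   `NA`) or at least `trans_min_mb` Mb away on the same chromosome;
#' * `ambiguous` (with a warning) for same-chromosome distances between the
#'   cis window and the trans floor, a configuration the protocol's rules do
#'   not cover.
#'
#' @param loci locus tibble from [merge_loci()].
#' @param annotation gene-model tibble (see [read_gene_annotation()]).
#' @param trait_genes named character vector mapping trait (protein) to the
#'   symbol of its encoding gene; every trait must map to exactly one gene.
#' @param gm the [genotype_matrix()] (for index positions).
#' @param cis_window_kb cis window (default 500).
#' @param trans_min_mb trans floor in Mb (default 100).
#' @param overrides character vector of `"<trait>:<index_id>"` locus ids to
#'   force-classify as cis.
#' @return The locus tibble with added `locus_class` and `distance_kb`.
#' @export
classify_loci <- function(loci, annotation, trait_genes, gm,
                          cis_window_kb = 500, trans_min_mb = 100,
                          overrides = character(0)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- as_tibble(loci)
  annotation <- as_tibble(annotation)
  vmeta <- gm$variants
  n <- nrow(loci)
  cls <- character(n)
  dist_kb <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sym <- trait_genes[[loci$trait[i]]]
    if (is.null(sym) || is.na(sym)) {
      abort(paste0("no trait gene known for '", loci$trait[i], "'"))
    }
    gene <- annotation[annotation$symbol == sym, , drop = FALSE]
    if (nrow(gene) != 1) {
      abort(paste0("trait '", loci$trait[i],
                   "' must map to exactly one gene model ('", sym, "')"))
    }
    j <- match(loci$index_id[i], vmeta$id)
    if (is.na(j)) abort(paste0("index SNP '", loci$index_id[i],
                               "' absent from genotype metadata"))
    pos <- vmeta$pos[j]
    same_chrom <- identical(as.character(vmeta$chrom[j]),
                            as.character(gene$chrom))
    lid <- paste0(loci$trait[i], ":", loci$index_id[i])
    if (!same_chrom) {
      cls[i] <- "trans"  # distance undefined across chromosomes
      next
    }
    d <- signed_distance_kb(pos, gene$start, gene$end)
    dist_kb[i] <- d
    if (abs(d) <= cis_window_kb || lid %in% overrides) {
      cls[i] <- "cis"
    } else if (abs(d) >= trans_min_mb * 1000) {
      cls[i] <- "trans"
    } else {
      cls[i] <- "ambiguous"
      warn(sprintf(
        "locus %s at %.1f kb falls between the cis window and the trans floor; classified 'ambiguous'",
        lid, d
      ))
    }
  }
  loci$locus_class <- cls
  loci$distance_kb <- dist_kb
  loci
}

#' Signed SNP-to-gene distance in kb
#'
#' Zero inside the gene body; otherwise the distance to the nearest gene
#' boundary, negative on the lower-coordinate side of the gene.
#'
#' @param pos SNP position (1-based).
#' @param start,end gene body, 1-based inclusive.
#' @return Signed distance in kb.
#' @export
signed_distance_kb <- function(pos, start, end) {
  dplyr::case_when(
    pos >= start & pos <= end ~ 0,
    pos < start ~ (pos - start) / 1000,
    TRUE ~ (pos - end) / 1000
  )
}
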