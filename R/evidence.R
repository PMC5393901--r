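#' Integrate mediator-gene evidence for trans loci
#'
#' For every trans locus, enumerates the candidate cis-genes within the cis
#' window of its index SNP and scores the five evidence tracks used to
#' nominate a mediator gene:
#'
#' 1. a missense coding proxy in LD with the index SNP (r-squared > 0.6),
#'    attributed to the cis-gene whose body contains the proxy variant;
#' 2. a cis-eQTL of the index SNP on the cis-gene at the FDR-5% report
#'    threshold, in any expression dataset;
#' 3. an unweighted shortest path from cis-gene to trait gene shorter than
#'    in 95% of degree-preservingly rewired networks;
#' 4. the same test on the trans-eQTL-weighted path length;
#' 5. a literature co-occurrence count above `lit_min`.
#'
#' One row is produced per (index SNP, cis-gene) pair; the `retained` column
#' marks rows where at least one criterion fires (the headline-table rule),
#' while the full table is always returned.
#'
#' @param loci classified locus tibble; only rows with
#'   `locus_class == "trans"` are analysed.
#' @param annotation gene-model tibble.
#' @param gm discovery [genotype_matrix()] (LD reference; missense flags).
#' @param datasets list of [eqtl_dataset()] objects.
#' @param network undirected igraph of gene interactions.
#' @param trait_genes named map from trait protein to gene symbol.
#' @param literature_counts optional tibble `gene`, `trait`, `count` of
#'   abstract co-occurrences.
#' @param config a [pqtl_config()]; `n_perm`, `perm_alpha`, thresholds and
#'   the permutation seed are taken from it.
#' @return A tibble with one row per (locus, cis-gene) pair carrying all
#'   five evidence tracks and the `retained` flag.
#' @export
integrate_evidence <- function(loci, annotation, gm, datasets, network,
                               trait_genes, literature_counts = NULL,
                               config = pqtl_config()) {
  loci <- as_tibble(loci) %>% filter(.data$locus_class == "trans")
  if (nrow(loci) == 0) {
    inform("no trans loci to analyse")
    return(tibble())
  }
  if (is.na(config$seed)) abort("config$seed is required for permutation tests")
  vmeta <- gm$variants
  net_genes <- igraph::V(network)$name
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    snp <- loci$index_id[i]
    trait <- loci$trait[i]
    trait_gene <- trait_genes[[trait]]
    j <- match(snp, vmeta$id)
    if (is.na(j)) abort(paste0("index SNP '", snp, "' absent from genotypes"))
    cis <- enumerate_cis_genes(vmeta$chrom[j], vmeta$pos[j], annotation,
                               window_kb = config$cis_window_kb)
    if (nrow(cis) == 0) next
    proxy <- coding_proxy_evidence(snp, gm, coding_r2 = config$coding_r2)
    scores <- trans_eqtl_scores(snp, datasets, net_genes,
                                w1_p = config$eqtl_w1_p,
                                w2_p = config$eqtl_w2_p)

    trait_gene_in_net <- !is.null(trait_gene) && trait_gene %in% net_genes
    if (!trait_gene_in_net) {
      inform(paste0("trait gene for '", trait,
                    "' absent from network; pathway tracks skipped"))
    }
    path_cands <- cis$symbol[cis$symbol %in% net_genes &
                               cis$symbol != trait_gene]
    path_res_u <- path_res_w <- NULL
    if (trait_gene_in_net && length(path_cands) > 0) {
      pairs <- tibble(source = path_cands, target = trait_gene)
      path_res_u <- path_permutation_batch(
        network, NULL, pairs, n_perm = config$n_perm,
        seed = config$seed + 1000L * i, weighted = FALSE,
        ties = config$perm_ties, plus_one = config$perm_plus_one
      )
      path_res_w <- path_permutation_batch(
        network, scores, pairs, n_perm = config$n_perm,
        seed = config$seed + 1000L * i, weighted = TRUE,
        ties = config$perm_ties, plus_one = config$perm_plus_one
      )
    }

    for (k in seq_len(nrow(cis))) {
      gene <- cis$symbol[k]
      # track 1: coding proxy inside this cis-gene
      has_proxy <- !is.null(proxy) &&
        proxy$chrom == cis$chrom[k] &&
        proxy$pos >= cis$start[k] && proxy$pos <= cis$end[k]
      # track 2: cis-eQTL on this gene
      eqtl_hits <- cis_eqtl_scan(snp, gene, datasets,
                                 eqtl_cis_p = config$eqtl_cis_p)
      # tracks 3-4: path permutation tests
      u_len <- w_len <- NA_real_
      u_p <- w_p <- NA_real_
      w_via <- NA_character_
      if (!is.null(path_res_u) && gene %in% path_res_u$source) {
        r <- match(gene, path_res_u$source)
        u_len <- path_res_u$observed_len[r]
        u_p <- path_res_u$perm_p[r]
        w_len <- path_res_w$observed_len[r]
        w_p <- path_res_w$perm_p[r]
        if (!is.na(w_p) && w_p < config$perm_alpha) {
          sp <- shortest_path(network, gene, trait_gene, scores)
          mid <- setdiff(sp$nodes, c(gene, trait_gene))
          w_via <- if (length(mid) > 0) paste(mid, collapse = ",") else "direct"
        }
      }
      # track 5: literature co-occurrence
      lit <- NA_integer_
      if (!is.null(literature_counts)) {
        hit <- literature_counts$gene == gene & literature_counts$trait == trait
        if (any(hit)) lit <- as.integer(max(literature_counts$count[hit]))
      }
      crit <- c(
        coding = has_proxy,
        eqtl = nrow(eqtl_hits) > 0,
        path_unweighted = !is.na(u_p) && u_p < config$perm_alpha,
        path_weighted = !is.na(w_p) && w_p < config$perm_alpha,
        literature = !is.na(lit) && lit > config$lit_min
      )
      rows[[length(rows) + 1]] <- tibble(
        trait = trait, index_id = snp, cis_gene = gene,
        distance_kb = cis$distance_kb[k], dist_rank = cis$dist_rank[k],
        coding_proxy_id = if (has_proxy) proxy$id else NA_character_,
        coding_proxy_r2 = if (has_proxy) proxy$r2 else NA_real_,
        cis_eqtl = if (nrow(eqtl_hits) > 0) {
          paste(sprintf("%s (P = %.3g)", eqtl_hits$dataset, eqtl_hits$p),
                collapse = ", ")
        } else NA_character_,
        n_cis_eqtl = nrow(eqtl_hits),
        unweighted_len = u_len, unweighted_perm_p = u_p,
        weighted_len = w_len, weighted_perm_p = w_p,
        weighted_via = w_via,
        literature_score = lit,
        n_criteria = sum(crit),
        retained = any(crit)
      )
    }
  }
  bind_rows(rows)
}
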