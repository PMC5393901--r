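# pqtlpath

Mapping plasma-protein quantitative trait loci (pQTLs) and weighing the
evidence for the mediator genes behind trans-acting signals.

Multiplexed immunoassay panels make it routine to measure dozens of
circulating proteins in genotyped cohorts. Scanning those measurements
genome-wide yields two kinds of loci: **cis** signals, where the index SNP
lies within 500 kb of the gene encoding the protein, and **trans** signals
acting from another chromosome (or from more than 100 Mb away). A cis signal
largely explains itself; a trans signal poses a question — *which gene near
the SNP conveys the effect to the distant protein?* `pqtlpath` implements the
full inference chain for studies of this design:

1. **QC** — assays are dropped when more than 20% of samples fall below the
   detection limit or the inter-plate CV exceeds 25%; variants are dropped at
   call rate < 95% or Hardy-Weinberg exact-test p < 1e-6.
2. **Discovery scan** — log10 protein values are residualized on age, sex,
   centre, batch, smoking, diabetes and hypertension; standardized residuals
   are Wald-tested against dosages (`p < 5e-8`); signals with LD r² > 0.1
   within 250 kb merge into loci; loci are classified cis/trans by the 500
   kb / 100 Mb rules.
3. **Replication** — index SNPs are matched into replication cohorts directly
   or through an LD proxy (r² > 0.8), per-cohort estimates are pooled by
   inverse-variance fixed-effects meta-analysis
   (`se_pool = (Σ se_i⁻²)^(-1/2)`, `β_pool = Σ(β_i/se_i²)·se_pool²`), and each
   locus gets a replication status against the one-significant-figure
   Bonferroni threshold `0.05/n_measurable`.
4. **Mediator evidence** — for every trans locus, each gene within 500 kb of
   the index SNP is scored on five tracks: a missense coding proxy in LD
   (r² > 0.6); a cis-eQTL of the index SNP on the gene (p < 5e-4) in any of
   the expression datasets; an unweighted shortest path to the trait gene
   shorter than expected under a degree-preserving rewiring null; the same
   test on the **trans-eQTL-weighted** path length, where entering a gene
   costs its score (1, or 0.8 when the index SNP's trans-eQTL p < 0.05, or
   0.6 when p < 0.005) — so a strong trans-eQTL mediator makes a two-hop
   route cheaper than an ordinary one; and a literature co-occurrence count
   above 50.
5. **Downstream** — a pleiotropy matrix of index SNPs with ≥ 2 protein
   associations at `0.05/(83·79)`, clustered by complete linkage on
   1 − Pearson correlation of −log10 p profiles; and disease risk-score
   lookups in which each protein's SNPs are aligned to the risk-increasing
   allele, pooled by inverse variance, and flagged by Benjamini-Hochberg FDR.

A synthetic-data generator (`simulate_study()` and the individual
`simulate_*()` functions) emulates every input — cohorts with LD-linked
dosage blocks, covariate structure, below-LOD censoring and plate CV, eleven
eQTL datasets of 89–367 subjects, a scale-free interaction network with
planted cis-gene → mediator → trait-gene paths, and a disease GWAS table —
with recorded truth, so every stage is validated by recovery.

## Worked example

```r
library(pqtlpath)
library(dplyr)

st <- simulate_study(n_samples = 800, n_proteins = 12, n_cis = 3,
                     n_trans = 2, ve = 0.05,
                     replication_sizes = c(repA = 300, repB = 250),
                     seed = 7)

panel <- qc_proteins(st$panel)
ncol(panel$values)
#> [1] 12            # the 9 QC-violating extra assays are gone

res  <- residualize(panel, st$covariates)
scan <- wald_scan(res[, names(st$trait_genes)], st$genotypes)
loci <- merge_loci(filter(scan, flagged), st$genotypes) |>
  classify_loci(st$annotation, st$trait_genes, st$genotypes)
loci[, c("trait", "index_id", "p", "locus_class", "distance_kb")]
#> # A tibble: 5 × 5
#>   trait index_id        p locus_class distance_kb
#> 1 P01   rsC1     1.05e- 8 cis                   0
#> 2 P02   rsC2     4.60e-10 cis                   0
#> 3 P03   rsC3     1.37e-12 cis                   0
#> 4 P04   rsT1     2.26e-11 trans                NA
#> 5 P05   rsT2     2.33e-14 trans                NA
```

All five planted loci come back: three cis hits sitting inside their own
trait genes (distance 0 kb) and two trans hits on other chromosomes (distance
undefined). Replication pools the two cohorts per locus:

```r
rep <- replicate_loci(loci, st$replication, st$genotypes)
rep[, c("trait", "index_id", "pooled_p", "direction", "status")]
#>   trait index_id     pooled_p direction                status
#> 1   P01     rsC1 6.926394e-11        ++ replicated_bonferroni
#> 2   P02     rsC2 8.845815e-05        ++ replicated_bonferroni
#> 3   P03     rsC3 2.293758e-10        ++ replicated_bonferroni
#> 4   P04     rsT1 2.167831e-13        ++ replicated_bonferroni
#> 5   P05     rsT2 1.793510e-12        ++ replicated_bonferroni
```

Every locus replicates with concordant direction in both cohorts
(`direction "++"`) below the Bonferroni threshold. For the trans loci,
`integrate_evidence()` then produces the per-(SNP, cis-gene) evidence table
— coding proxies, cis-eQTL hits, both permutation path tests with the
mediator gene named (`weighted_via`), and literature counts — with
`retained` marking pairs satisfying at least one track.

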