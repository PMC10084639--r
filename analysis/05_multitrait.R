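#!/usr/bin/env Rscript
# Stage 5: the three multi-trait strategies per trait group.
#
# For each trait group (and the pooled set): the complete-case multivariate
# LMM scan (mtGWAS) against the complete-case meta-analysis of matched
# single-trait scans (metaGWAS1, the unbiased comparison), and the
# all-available-records meta-analysis (metaGWAS2, the power configuration).
# Writes per-group significant counts, QTL tables, overlap decompositions
# and paired lead signals.

library(pleioscan)

phen <- read_pheno_tsv("results/cohort/phenotypes.tsv")
geno <- read_geno_tsv("results/qc/genotypes_qc")
G <- read_grm_tsv("results/qc/cohort")

dir.create("results/multitrait", recursive = TRUE, showWarnings = FALSE)
thr <- bonferroni_threshold(0.05, nrow(geno$map))

stg <- lapply(phen$trait_names, function(tr) {
  read_summary_stats(file.path("results/stgwas",
                               paste0("stgwas_", tr, ".tsv")))
})
names(stg) <- phen$trait_names

group_rows <- NULL
for (gp in c(unique(unname(phen$group_of)), "all")) {
  traits <- if (gp == "all") phen$trait_names else
    phen$trait_names[phen$group_of == gp]
  if (length(traits) < 2) next
  cc <- complete_case_subset(phen, gp)
  Y <- cc$values
  rownames(Y) <- cc$sample_ids
  Gcc <- G
  Gcc <- pleioscan::grm(G$matrix[cc$sample_ids, cc$sample_ids],
                        cc$sample_ids, G$n_variants_used)

  vc <- estimate_mt_vc(Y, Gcc)
  mt <- mv_scan(Y, geno, Gcc, vc)

  st_cc <- lapply(traits, function(tr) {
    null <- fit_null(stats::setNames(Y[, tr], cc$sample_ids), Gcc, trait = tr)
    score_scan(null, geno)
  })
  tm1 <- assemble_t(st_cc)
  meta1 <- meta_chi2(tm1, estimate_v(tm1))
  tm2 <- assemble_t(stg[traits])
  meta2 <- meta_chi2(tm2, estimate_v(tm2))

  results <- list(
    mtGWAS = mt[c("variant_id", "chrom", "pos", "p")],
    metaGWAS1 = data.frame(variant_id = meta1$id, chrom = meta1$chrom,
                           pos = meta1$pos, p = meta1$p),
    metaGWAS2 = data.frame(variant_id = meta2$id, chrom = meta2$chrom,
                           pos = meta2$pos, p = meta2$p))
  cmp <- compare_methods(results, thr)

  for (m in names(cmp$qtl)) {
    if (nrow(cmp$qtl[[m]])) {
      q <- cmp$qtl[[m]]; q$group <- gp; q$method <- m
      data.table::fwrite(q, sprintf("results/multitrait/qtl_%s_%s.tsv",
                                    gp, m), sep = "\t")
    }
  }
  ov <- as.data.frame(cmp$subset_counts)
  if (nrow(ov)) {
    names(ov) <- c("methods", "n_variants")
    ov$group <- gp
    data.table::fwrite(ov, sprintf("results/multitrait/overlap_%s.tsv", gp),
                       sep = "\t")
  }
  pair <- cmp$pairs[["mtGWAS|metaGWAS1"]]
  group_rows <- rbind(group_rows, data.frame(
    group = gp, d = length(traits), n_complete = nrow(Y),
    sig_mt = length(cmp$significant$mtGWAS),
    sig_meta1 = length(cmp$significant$metaGWAS1),
    sig_meta2 = length(cmp$significant$metaGWAS2),
    qtl_mt = nrow(cmp$qtl$mtGWAS), qtl_meta1 = nrow(cmp$qtl$metaGWAS1),
    qtl_meta2 = nrow(cmp$qtl$metaGWAS2),
    logp_cor_mt_meta1 = pair$cor))
}
data.table::fwrite(group_rows, "results/multitrait/group_summary.tsv",
                   sep = "\t")
print(group_rows, digits = 3)
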