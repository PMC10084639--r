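#!/usr/bin/env Rscript
# Stage 6: QTL fine-mapping from the pooled meta-analysis.
#
# Calls QTL from the all-traits metaGWAS2, reports per-lead LD
# neighbourhoods, jointly fitted per-trait variance explained for the traits
# in which each lead is significant, and verifies that conditioning on the
# leads removes the peaks.

library(pleioscan)

phen <- read_pheno_tsv("results/cohort/phenotypes.tsv")
geno <- read_geno_tsv("results/qc/genotypes_qc")
G <- read_grm_tsv("results/qc/cohort")
truth <- data.table::fread("results/cohort/truth_causal.tsv")

dir.create("results/finemap", recursive = TRUE, showWarnings = FALSE)
thr <- bonferroni_threshold(0.05, nrow(geno$map))

stg <- lapply(phen$trait_names, function(tr) {
  read_summary_stats(file.path("results/stgwas",
                               paste0("stgwas_", tr, ".tsv")))
})
names(stg) <- phen$trait_names

tm <- assemble_t(stg)
meta <- meta_chi2(tm, estimate_v(tm))
qtl <- call_qtl(data.frame(variant_id = meta$id, chrom = meta$chrom,
                           pos = meta$pos, p = meta$p), thr)
data.table::fwrite(qtl, "results/finemap/qtl_meta_all.tsv", sep = "\t")
cat(sprintf("%d QTL called from the pooled meta-analysis (threshold %.3g)\n",
            nrow(qtl), thr))
print(qtl)

if (nrow(qtl)) {
  # LD neighbourhood of each lead
  ld_rows <- NULL
  for (i in seq_len(nrow(qtl))) {
    r2 <- ld_r2(geno, qtl$lead_variant[i])
    high <- r2[!is.na(r2) & r2 > 0.8]
    ld_rows <- rbind(ld_rows, data.frame(
      qtl = qtl$qtl[i], lead = qtl$lead_variant[i],
      n_r2_above_0.8 = length(high) - 1,
      nearest_truth_bp = min(abs(truth$pos[truth$chrom == qtl$chrom[i]] -
                                   qtl[i, ]$stop_bp), Inf)))
  }
  data.table::fwrite(ld_rows, "results/finemap/ld_neighbourhoods.tsv",
                     sep = "\t")

  # per-trait variance explained by the leads significant for that trait,
  # fitted jointly, plus the conditional scan
  ve_rows <- NULL
  for (tr in phen$trait_names) {
    st <- stg[[tr]]$records
    leads <- qtl$lead_variant[qtl$lead_variant %in%
                                st$variant_id[st$p < thr]]
    if (!length(leads)) next
    y <- phen$values[, tr]
    keep <- !is.na(y)
    yk <- stats::setNames(y[keep], phen$sample_ids[keep])
    ve <- suppressWarnings(
      variance_explained(yk, subset_geno(geno, phen$sample_ids[keep]), leads))
    ve$trait <- tr
    ve_rows <- rbind(ve_rows, ve)

    null <- fit_null(yk, G, trait = tr)
    cond <- suppressWarnings(conditional_scan(null, geno, leads))
    n_before <- sum(st$p < thr)
    n_after <- sum(cond$records$p < thr)
    cat(sprintf("  %s: %d leads, %d significant before / %d after conditioning\n",
                tr, length(leads), n_before, n_after))
  }
  if (!is.null(ve_rows)) {
    data.table::fwrite(ve_rows, "results/finemap/variance_explained.tsv",
                       sep = "\t")
    print(ve_rows, digits = 3)
  }
}
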