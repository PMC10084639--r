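#!/usr/bin/env Rscript
# Stage 2: genotype QC, centred GRM, and PCA of the GRM.
#
# Applies the GWAS preset (MAF > 5%, HWE exact P >= 1e-5, call rates >= 80%)
# to the raw panel, builds the centred genomic relationship matrix from the
# retained variants, and records the leading principal components.

library(pleioscan)

geno <- read_geno_tsv("results/cohort/genotypes_raw")
pr <- qc_preset("gwas")
qc <- qc_filter(geno, maf_min = pr$maf_min, hwe_p_min = pr$hwe_p_min,
                var_call_min = pr$var_call_min,
                sample_call_min = pr$sample_call_min)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
data.table::fwrite(qc$report, "results/qc/qc_report.tsv", sep = "\t")
write_geno_tsv(qc$geno, "results/qc/genotypes_qc")

G <- compute_grm_centered(qc$geno)
write_grm_tsv(G, "results/qc/cohort")

pc <- pca_grm(G, k = 10)
data.table::fwrite(
  cbind(data.frame(sample_id = G$sample_ids), as.data.frame(pc$coords)),
  "results/qc/grm_pca.tsv", sep = "\t")
data.table::fwrite(
  data.frame(component = seq_along(pc$fractions),
             variance_fraction = pc$fractions),
  "results/qc/grm_pca_fractions.tsv", sep = "\t")

print(qc$report)
cat(sprintf("GRM built from %d variants; PC1 captures %.2f%% of variance\n",
            G$n_variants_used, 100 * pc$fractions[1]))
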