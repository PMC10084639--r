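#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the default synthetic breeding cohort (1,000 animals, ~10,000
# array-density SNPs on 5 autosomes, 6 drEBV-like traits in three groups
# with heritabilities 0.07-0.67, three pleiotropic QTL, per-trait
# missingness up to 37%) and writes the raw genotype/phenotype/truth tables.

library(pleioscan)

outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260922)
write_sim_config(cfg, file.path(outdir, "config.yaml"))

geno <- simulate_genotypes(cfg)
sim <- simulate_phenotypes(geno, cfg)

# record-eligibility filters on the raw drEBV (reliability > 0.3, 5 SD,
# minimum record count scaled to the cohort)
phen <- apply_drebv_filters(sim$phen, min_records = round(cfg$n_samples / 4))

write_geno_tsv(geno, file.path(outdir, "genotypes_raw"))
write_pheno_tsv(phen, file.path(outdir, "phenotypes.tsv"))
data.table::fwrite(sim$truth$causal, file.path(outdir, "truth_causal.tsv"),
                   sep = "\t")
data.table::fwrite(
  data.frame(trait = names(sim$truth$realized_h2),
             realized_h2 = sim$truth$realized_h2),
  file.path(outdir, "truth_h2.tsv"), sep = "\t")

print(geno)
print(phen)
cat("Cohort written to", outdir, "\n")
cat("QTL truth:\n")
print(sim$truth$causal[c("variant_id", "trait", "target_frac")])
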