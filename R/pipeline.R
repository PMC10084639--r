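#' Run the full simulation-and-comparison experiment
#'
#' Orchestrates the stages of the study design on one simulated cohort:
#' simulate genotypes and drEBV-like phenotypes, apply record-eligibility
#' filters, genotype QC at the GWAS preset, centred GRM, per-trait REML
#' heritability, per-trait single-trait scans with all available records,
#' and then the three multi-trait experiment modes on each trait group:
#' complete-case comparison (multivariate scan vs meta-analysis of
#' group-restricted single-trait scans on identical samples), all-available
#' meta-analysis from the full single-trait scans, and conditional
#' fine-mapping of the meta-analysis QTL (lead variants fitted as fixed
#' effects per affected trait).
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSV and a manifest of file digests is produced.
#' @param groups trait groups to run the multi-trait modes on (default: all
#'   configured groups plus the pooled `"all"` group).
#' @param alpha family-wise error rate for Bonferroni thresholds.
#' @param maf_min scan MAF threshold.
#' @param df_mode degrees of freedom convention for the meta-analysis.
#' @param min_records eligibility threshold on records per trait; the
#'   default of [apply_drebv_filters()] targets real cohort sizes, so scale
#'   it with `cfg$n_samples`.
#' @return list of class `pipeline_run` with elements `cohort`, `qc`,
#'   `heritability`, `stgwas`, `groups` (per group: mtGWAS, metaGWAS1,
#'   metaGWAS2, comparison, QTL tables), `finemap`, `manifest`.
#' @export
run_pipeline <- function(cfg, outdir = NULL,
                         groups = c(names(cfg$trait_groups), "all"),
                         alpha = 0.05, maf_min = 0.05,
                         df_mode = "d_minus_1",
                         min_records = max(50, round(cfg$n_samples / 4))) {
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s (%.1fs)", stage, sprintf(...),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  geno_raw <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno_raw, cfg)
  log_stage("simulate", "%d samples, %d variants, %d traits",
            cfg$n_samples, nrow(geno_raw$map), cfg$n_traits)

  phen <- apply_drebv_filters(sim$phen, min_records = min_records)
  qc <- qc_filter(geno_raw, maf_min = maf_min, hwe_p_min = 1e-5,
                  var_call_min = 0.8, sample_call_min = 0.8)
  geno <- qc$geno
  log_stage("qc", "%d -> %d variants", qc$report$n_input_variants,
            qc$report$n_output_variants)

  G <- compute_grm_centered(geno)
  n_tests <- nrow(geno$map)
  thr <- bonferroni_threshold(alpha, n_tests)

  heritability <- lapply(phen$trait_names, function(tr) {
    y <- phen$values[, tr]
    w <- phen$weight[, tr]
    keep <- !is.na(y)
    reml_single(stats::setNames(y[keep], phen$sample_ids[keep]), G,
                weights = w[keep])
  })
  names(heritability) <- phen$trait_names
  log_stage("reml", "h2: %s",
            paste(sprintf("%s=%.2f", phen$trait_names,
                          vapply(heritability, `[[`, numeric(1), "h2")),
                  collapse = " "))

  # stGWAS per trait with all available records (feeds metaGWAS2)
  stgwas <- lapply(phen$trait_names, function(tr) {
    y <- phen$values[, tr]
    keep <- !is.na(y)
    null <- fit_null(stats::setNames(y[keep], phen$sample_ids[keep]), G,
                     trait = tr)
    score_scan(null, geno, maf_min)
  })
  names(stgwas) <- phen$trait_names
  log_stage("stgwas", "%d traits scanned", length(stgwas))

  group_results <- list()
  for (gp in groups) {
    gp_traits <- if (identical(gp, "all")) phen$trait_names else
      phen$trait_names[phen$group_of == gp]
    if (length(gp_traits) < 1) next
    if (length(gp_traits) == 1) {
      group_results[[gp]] <- list(
        note = "single-trait group: multivariate scan reduces to the single-trait scan",
        stgwas = stgwas[[gp_traits]]
      )
      next
    }
    cc <- complete_case_subset(phen, gp)
    Ycc <- cc$values
    rownames(Ycc) <- cc$sample_ids
    Gcc <- subset_grm(G, cc$sample_ids)

    vc <- estimate_mt_vc(Ycc, Gcc)
    mt <- mv_scan(Ycc, geno, Gcc, vc, maf_min)

    # metaGWAS1: group-restricted single-trait scans on the complete cases
    st_cc <- lapply(gp_traits, function(tr) {
      null <- fit_null(stats::setNames(Ycc[, tr], cc$sample_ids), Gcc, trait = tr)
      score_scan(null, geno, maf_min)
    })
    tm1 <- assemble_t(st_cc)
    v1 <- estimate_v(tm1)
    meta1 <- meta_chi2(tm1, v1, df_mode)

    # metaGWAS2: all-available single-trait scans
    tm2 <- assemble_t(stgwas[gp_traits])
    v2 <- estimate_v(tm2)
    meta2 <- meta_chi2(tm2, v2, df_mode)

    mt_df <- mt[c("variant_id", "chrom", "pos", "p")]
    meta1_df <- data.frame(variant_id = meta1$id, chrom = meta1$chrom,
                           pos = meta1$pos, p = meta1$p)
    meta2_df <- data.frame(variant_id = meta2$id, chrom = meta2$chrom,
                           pos = meta2$pos, p = meta2$p)
    cmp <- compare_methods(
      list(mtGWAS = mt_df, metaGWAS1 = meta1_df, metaGWAS2 = meta2_df), thr)
    group_results[[gp]] <- list(
      traits = gp_traits, n_complete = nrow(Ycc), vc = vc, mtgwas = mt,
      metagwas1 = meta1, metagwas2 = meta2, comparison = cmp,
      qtl = cmp$qtl
    )
    log_stage("group", "%s: n_cc=%d, QTL mt/meta1/meta2 = %d/%d/%d", gp,
              nrow(Ycc), nrow(cmp$qtl$mtGWAS), nrow(cmp$qtl$metaGWAS1),
              nrow(cmp$qtl$metaGWAS2))
  }

  # conditional fine-mapping: metaGWAS2 QTL of the pooled group (or first)
  finemap <- NULL
  fm_gp <- if ("all" %in% names(group_results)) "all" else names(group_results)[1]
  if (!is.null(group_results[[fm_gp]]$metagwas2)) {
    meta2 <- group_results[[fm_gp]]$metagwas2
    qtl <- call_qtl(data.frame(variant_id = meta2$id, chrom = meta2$chrom,
                               pos = meta2$pos, p = meta2$p), thr)
    per_trait <- list()
    if (nrow(qtl)) {
      leads <- qtl$lead_variant
      for (tr in phen$trait_names) {
        st <- stgwas[[tr]]$records
        sig_leads <- leads[leads %in% st$variant_id[st$p < thr]]
        if (!length(sig_leads)) next
        y <- phen$values[, tr]
        keep <- !is.na(y)
        ve <- variance_explained(stats::setNames(y[keep], phen$sample_ids[keep]),
                                 subset_geno(geno, phen$sample_ids[keep]),
                                 sig_leads)
        null <- fit_null(stats::setNames(y[keep], phen$sample_ids[keep]), G,
                         trait = tr)
        cond <- conditional_scan(null, geno, sig_leads, maf_min)
        per_trait[[tr]] <- list(variance_explained = ve, conditional = cond)
      }
    }
    finemap <- list(group = fm_gp, qtl = qtl, per_trait = per_trait)
    log_stage("finemap", "%d QTL in group '%s'", nrow(qtl), fm_gp)
  }

  manifest <- list(
    config = unclass(cfg), version = as.character(utils::packageVersion("pleioscan")),
    seed = cfg$seed, threshold = thr, n_tests = n_tests,
    started = format(t0), finished = format(Sys.time()), files = NULL
  )
  out <- list(cohort = list(geno = geno_raw, phen = phen, truth = sim$truth),
              qc = qc$report, grm = G, heritability = heritability,
              stgwas = stgwas, groups = group_results, finemap = finemap,
              threshold = thr, manifest = manifest)
  class(out) <- "pipeline_run"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_geno_tsv(geno, file.path(outdir, "genotypes_qc"))
    write_pheno_tsv(phen, file.path(outdir, "phenotypes.tsv"))
    write_grm_tsv(G, file.path(outdir, "cohort"))
    for (tr in names(stgwas)) {
      write_summary_stats(stgwas[[tr]], file.path(outdir, paste0("stgwas_", tr, ".tsv")))
    }
    h2df <- data.frame(
      trait = names(heritability),
      h2 = vapply(heritability, `[[`, numeric(1), "h2"),
      h2_se = vapply(heritability, `[[`, numeric(1), "h2_se"),
      sigma_a2 = vapply(heritability, `[[`, numeric(1), "sigma_a2"),
      sigma_e2 = vapply(heritability, `[[`, numeric(1), "sigma_e2")
    )
    data.table::fwrite(h2df, file.path(outdir, "heritability.tsv"), sep = "\t")
    if (!is.null(finemap) && nrow(finemap$qtl)) {
      data.table::fwrite(finemap$qtl, file.path(outdir, "qtl_meta2.tsv"), sep = "\t")
    }
    files <- list.files(outdir, full.names = TRUE)
    manifest$files <- data.frame(file = basename(files),
                                 md5 = unname(tools::md5sum(files)))
    out$manifest <- manifest
    yaml::write_yaml(list(version = manifest$version, seed = manifest$seed,
                          threshold = manifest$threshold,
                          files = manifest$files$md5,
                          names = manifest$files$file),
                     file.path(outdir, "manifest.yaml"))
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d traits, %d QC'd variants, threshold %.3g\n",
              length(x$heritability), x$qc$n_output_variants, x$threshold))
  for (gp in names(x$groups)) {
    g <- x$groups[[gp]]
    if (!is.null(g$note)) next
    cat(sprintf("  %s: n_cc=%d, QTL mt/meta1/meta2 = %d/%d/%d\n", gp,
                g$n_complete, nrow(g$qtl$mtGWAS), nrow(g$qtl$metaGWAS1),
                nrow(g$qtl$metaGWAS2)))
  }
  invisible(x)
}
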