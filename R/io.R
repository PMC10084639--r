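#' Write genotypes as a TSV dosage matrix plus variant map
#'
#' @param geno a [geno_matrix()].
#' @param prefix output path prefix; writes `<prefix>.dosage.tsv`
#'   (sample_id x variant) and `<prefix>.map.tsv`.
#' @return The two paths, invisibly.
#' @export
write_geno_tsv <- function(geno, prefix) {
  dpath <- paste0(prefix, ".dosage.tsv")
  mpath <- paste0(prefix, ".map.tsv")
  dt <- data.table::data.table(sample_id = geno$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(geno$dosages))
  data.table::fwrite(dt, dpath, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(geno$map, mpath, sep = "\t", na = "NA", quote = FALSE)
  invisible(c(dpath, mpath))
}

#' Read genotypes written by [write_geno_tsv()]
#'
#' @param prefix path prefix used at write time.
#' @return A [geno_matrix()].
#' @export
read_geno_tsv <- function(prefix) {
  dt <- data.table::fread(paste0(prefix, ".dosage.tsv"), sep = "\t")
  map <- as.data.frame(data.table::fread(paste0(prefix, ".map.tsv"), sep = "\t",
                                         colClasses = list(character = "chrom")))
  samples <- dt$sample_id
  dos <- as.matrix(dt[, -1])
  geno_matrix(dos, map, samples)
}

#' Write genotypes as VCF
#'
#' Hard genotypes (all dosages integral) are written as GT; otherwise both GT
#' (best guess) and DS (dosage) are emitted. A `dr2` column of the map, when
#' present, is written as an INFO `DR2` field.
#'
#' @param geno a [geno_matrix()].
#' @param path output `.vcf` path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  dos <- geno$dosages
  hard <- all(is.na(dos) | dos == round(dos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pleioscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!hard) '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
    if (!is.null(geno$map$dr2)) '##INFO=<ID=DR2,Number=1,Type=Float,Description="Imputation accuracy">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  ), con)
  gt_of <- function(d) {
    ifelse(is.na(d), "./.",
           ifelse(d < 0.5, "0/0", ifelse(d <= 1.5, "0/1", "1/1")))
  }
  fmt <- if (hard) "GT" else "GT:DS"
  for (j in seq_len(nrow(geno$map))) {
    d <- dos[, j]
    cells <- if (hard) gt_of(d) else {
      paste0(gt_of(d), ":", ifelse(is.na(d), ".", formatC(d, digits = 4, format = "g")))
    }
    info <- if (!is.null(geno$map$dr2) && !is.na(geno$map$dr2[j])) {
      paste0("DR2=", formatC(geno$map$dr2[j], digits = 4, format = "g"))
    } else "."
    writeLines(paste(c(geno$map$chrom[j], geno$map$pos[j], geno$map$id[j],
                       geno$map$ref[j], geno$map$alt[j], ".", "PASS", info,
                       fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses the DS FORMAT field when present, otherwise counts alternate alleles
#' from GT. INFO DR2 values, when present, populate the map's `dr2` column.
#' Requires the `vcfR` package.
#'
#' @param path a `.vcf` / `.vcf.gz` path.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  fmt_fields <- strsplit(v@gt[1, "FORMAT"], ":")[[1]]
  if ("DS" %in% fmt_fields) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    cnt[clean == "0/0"] <- 0
    cnt[clean %in% c("0/1", "1/0")] <- 1
    cnt[clean == "1/1"] <- 2
    dos <- t(cnt)
  }
  dr2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DR2")))
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  if (any(!is.na(dr2))) map$dr2 <- dr2
  geno_matrix(dos, map, samples)
}

#' Write phenotypes as long-format TSV
#'
#' Columns: sample_id, trait, group, value, reliability, weight; missing
#' records are omitted (their reliabilities are retained only for present
#' records).
#'
#' @param phen a [pheno_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(phen, path) {
  long <- do.call(rbind, lapply(seq_along(phen$trait_names), function(j) {
    tr <- phen$trait_names[j]
    keep <- !is.na(phen$values[, j])
    data.frame(sample_id = phen$sample_ids[keep], trait = tr,
               group = unname(phen$group_of[tr]),
               value = phen$values[keep, j],
               reliability = phen$reliability[keep, j],
               weight = phen$weight[keep, j], stringsAsFactors = FALSE)
  }))
  data.table::fwrite(long, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read phenotypes written by [write_pheno_tsv()]
#'
#' @param path TSV path.
#' @return A [pheno_set()] (records absent from the file are missing).
#' @export
read_pheno_tsv <- function(path) {
  long <- as.data.frame(data.table::fread(path, sep = "\t"))
  samples <- unique(long$sample_id)
  traits <- unique(long$trait)
  shape <- function(col, fill = NA_real_) {
    M <- matrix(fill, length(samples), length(traits),
                dimnames = list(samples, traits))
    M[cbind(match(long$sample_id, samples), match(long$trait, traits))] <- long[[col]]
    M
  }
  group_of <- stats::setNames(long$group[!duplicated(long$trait)],
                              long$trait[!duplicated(long$trait)])
  W <- shape("weight")
  W[is.na(W)] <- 1  # weights only matter where values are present
  pheno_set(shape("value"), shape("reliability"), W, samples, traits,
            group_of[traits])
}

#' Write single-trait summary statistics as TSV
#'
#' Fixed column order: trait, variant_id, chrom, pos, effect_allele,
#' other_allele, af, beta, se, p, n.
#'
#' @param stats a `summary_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- c("trait", "variant_id", "chrom", "pos", "effect_allele",
            "other_allele", "af", "beta", "se", "p", "n")
  data.table::fwrite(stats$records[cols], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_summary_stats()]
#'
#' @param path TSV path.
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path) {
  rec <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = list(character = "chrom")))
  rec <- rec[order(rec$chrom, rec$pos), ]
  rownames(rec) <- NULL
  structure(
    list(trait = rec$trait[1], records = rec, n_variants = nrow(rec),
         n_skipped = NA_integer_, threshold_used = NA_real_),
    class = "summary_stats"
  )
}

#' Write a GRM as symmetric TSV plus sample list
#'
#' @param g a [grm()].
#' @param prefix writes `<prefix>.grm.tsv` and `<prefix>.grm.ids`.
#' @return The two paths, invisibly.
#' @export
write_grm_tsv <- function(g, prefix) {
  mpath <- paste0(prefix, ".grm.tsv")
  ipath <- paste0(prefix, ".grm.ids")
  data.table::fwrite(data.table::as.data.table(g$matrix), mpath, sep = "\t",
                     col.names = FALSE)
  writeLines(g$sample_ids, ipath)
  invisible(c(mpath, ipath))
}

#' Read a GRM written by [write_grm_tsv()]
#'
#' @param prefix path prefix.
#' @param n_variants_used optional variant count to restore.
#' @return A [grm()].
#' @export
read_grm_tsv <- function(prefix, n_variants_used = NA_integer_) {
  M <- as.matrix(data.table::fread(paste0(prefix, ".grm.tsv"), sep = "\t",
                                   header = FALSE))
  ids <- readLines(paste0(prefix, ".grm.ids"))
  dimnames(M) <- NULL
  grm((M + t(M)) / 2, ids, n_variants_used)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a [sim_config()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$genetic_corr <- as.vector(cfg$genetic_corr)
  obj$chrom_lengths <- as.list(cfg$chrom_lengths)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  d <- obj$n_traits
  obj$genetic_corr <- matrix(unlist(obj$genetic_corr), d, d)
  obj$chrom_lengths <- unlist(obj$chrom_lengths)
  obj$trait_groups <- lapply(obj$trait_groups, unlist)
  do.call(sim_config, obj[setdiff(names(obj), c("n_founders2"))])
}
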