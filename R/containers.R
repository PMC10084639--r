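#' Genotype matrix container
#'
#' Holds an n x m allele-dosage matrix together with its variant map and
#' sample identifiers. Dosages count copies of the alternate (effect) allele:
#' hard genotypes are 0/1/2, imputed dosages live in \[0, 2\], and missing
#' genotypes are `NA`.
#'
#' @param dosages numeric n x m matrix; rows are samples, columns variants.
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt` and optionally `dr2` (model-based imputation accuracy in
#'   \[0, 1\]), one row per variant, in column order of `dosages`.
#' @param sample_ids character vector of length n.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, map, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(nrow(map) == ncol(dosages), length(sample_ids) == nrow(dosages))
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(map))) {
    stop("variant map must have columns: ", paste(req, collapse = ", "))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$chrom <- as.character(map$chrom)
  if (anyDuplicated(map$id)) stop("variant ids must be unique")
  # positions strictly increasing within each chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (length(dosages)) {
    rng <- suppressWarnings(range(dosages, na.rm = TRUE))
    if (all(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
      stop("dosages must lie in [0, 2] or be NA")
    }
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- map$id
  structure(
    list(sample_ids = sample_ids, map = map, dosages = dosages),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d samples x %d variants on %d chromosome(s); %.2f%% missing\n",
    length(x$sample_ids), nrow(x$map), length(unique(x$map$chrom)),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param geno a [geno_matrix()].
#' @param samples character vector of sample ids to keep (default all).
#' @param variants character vector of variant ids to keep (default all).
#' @return A `geno_matrix` restricted to the requested rows/columns, in the
#'   requested sample order and the original variant (position) order.
#' @export
subset_geno <- function(geno, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(geno$sample_ids) else {
    idx <- match(samples, geno$sample_ids)
    if (anyNA(idx)) stop("unknown sample ids: ", paste(samples[is.na(idx)], collapse = ", "))
    idx
  }
  vi <- if (is.null(variants)) seq_len(nrow(geno$map)) else {
    idx <- match(variants, geno$map$id)
    if (anyNA(idx)) stop("unknown variant ids: ", paste(variants[is.na(idx)], collapse = ", "))
    sort(idx)
  }
  geno_matrix(geno$dosages[si, vi, drop = FALSE],
              geno$map[vi, , drop = FALSE],
              geno$sample_ids[si])
}

#' Phenotype set container
#'
#' Deregressed-breeding-value (drEBV) style phenotypes: an n x d value matrix
#' with per-record reliabilities and weights, and a grouping of traits.
#'
#' @param values numeric n x d matrix (NA = missing record).
#' @param reliability numeric n x d matrix of drEBV reliabilities in \[0, 1\].
#' @param weight numeric n x d matrix of positive record weights; must be
#'   present (non-NA) wherever `values` is present.
#' @param sample_ids character vector, length n.
#' @param trait_names character vector, length d.
#' @param group_of named character vector mapping trait name -> group name.
#'
#' @return An object of class `pheno_set`.
#' @export
pheno_set <- function(values, reliability, weight, sample_ids = rownames(values),
                      trait_names = colnames(values), group_of = NULL) {
  values <- as.matrix(values)
  reliability <- as.matrix(reliability)
  weight <- as.matrix(weight)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(trait_names)) trait_names <- paste0("T", seq_len(ncol(values)))
  stopifnot(
    all(dim(values) == dim(reliability)), all(dim(values) == dim(weight)),
    length(sample_ids) == nrow(values), length(trait_names) == ncol(values)
  )
  if (any(!is.na(values) & (is.na(weight) | weight <= 0))) {
    stop("every non-missing value needs a positive weight")
  }
  if (is.null(group_of)) {
    group_of <- stats::setNames(rep("all", length(trait_names)), trait_names)
  }
  if (!all(trait_names %in% names(group_of))) stop("group_of must cover every trait")
  dimnames(values) <- dimnames(reliability) <- dimnames(weight) <-
    list(sample_ids, trait_names)
  structure(
    list(sample_ids = sample_ids, trait_names = trait_names, values = values,
         reliability = reliability, weight = weight,
         group_of = group_of[trait_names]),
    class = "pheno_set"
  )
}

#' @export
print.pheno_set <- function(x, ...) {
  cat(sprintf(
    "pheno_set: %d samples x %d traits (%s); %.1f%% missing records\n",
    length(x$sample_ids), length(x$trait_names),
    paste(unique(x$group_of), collapse = ", "), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' Genomic relationship matrix container
#'
#' @param matrix symmetric n x n numeric matrix.
#' @param sample_ids character vector of length n.
#' @param n_variants_used number of variants that entered the construction.
#' @return An object of class `grm`.
#' @export
grm <- function(matrix, sample_ids = rownames(matrix), n_variants_used = NA_integer_) {
  matrix <- as.matrix(matrix)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(matrix)))
  stopifnot(nrow(matrix) == ncol(matrix), length(sample_ids) == nrow(matrix))
  if (max(abs(matrix - t(matrix))) > 1e-8) stop("GRM must be symmetric")
  dimnames(matrix) <- list(sample_ids, sample_ids)
  structure(
    list(sample_ids = sample_ids, matrix = matrix,
         n_variants_used = as.integer(n_variants_used)),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, built from %s variants\n",
              length(x$sample_ids),
              ifelse(is.na(x$n_variants_used), "?", x$n_variants_used)))
  invisible(x)
}

# Align a grm to a sample subset (order preserved as requested).
subset_grm <- function(g, samples) {
  idx <- match(samples, g$sample_ids)
  if (anyNA(idx)) stop("samples absent from GRM: ", paste(samples[is.na(idx)], collapse = ", "))
  grm(g$matrix[idx, idx, drop = FALSE], g$sample_ids[idx], g$n_variants_used)
}
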