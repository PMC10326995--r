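#' Genotype dosage matrix with variant metadata
#'
#' @param dosages numeric matrix, samples in rows, variants in columns; column
#'   names are variant ids, row names are sample ids. Entries in \[0, 2\].
#' @param meta data.frame with one row per variant: `variant_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `af` (alternate-allele frequency).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, meta) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(ncol(dosages) == nrow(meta))
  need <- c("variant_id", "chrom", "pos")
  if (!all(need %in% names(meta)))
    stop("variant metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$variant_id))
    stop("duplicated variant ids: ",
         paste(unique(meta$variant_id[duplicated(meta$variant_id)]), collapse = ", "))
  if (is.null(rownames(dosages)))
    stop("dosage matrix must carry sample ids as row names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated sample ids in genotype matrix")
  colnames(dosages) <- meta$variant_id
  if (!"af" %in% names(meta)) meta$af <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages, meta = as.data.frame(meta)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$meta$chrom), collapse = ",")))
  invisible(x)
}

#' Molecular phenotype set (expression or methylation)
#'
#' Values are stored samples x phenotypes; each phenotype carries a single
#' 1-based anchor coordinate (gene TSS or CpG position) that defines its cis
#' window. Strand is ignored.
#'
#' @param values numeric matrix, samples in rows (row names = sample ids),
#'   phenotypes in columns (column names = phenotype ids).
#' @param meta data.frame with `phenotype_id`, `chrom`, `anchor` (1-based),
#'   and optionally `kind` ("gene" or "cpg").
#' @return object of class `phenotype_set`.
#' @export
phenotype_set <- function(values, meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(ncol(values) == nrow(meta))
  need <- c("phenotype_id", "chrom", "anchor")
  if (!all(need %in% names(meta)))
    stop("phenotype metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$phenotype_id))
    stop("duplicated phenotype ids: ",
         paste(unique(meta$phenotype_id[duplicated(meta$phenotype_id)]), collapse = ", "))
  if (is.null(rownames(values)))
    stop("phenotype matrix must carry sample ids as row names")
  if (!"kind" %in% names(meta)) meta$kind <- "gene"
  colnames(values) <- meta$phenotype_id
  structure(list(values = values, meta = as.data.frame(meta)),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("<phenotype_set> %d samples x %d phenotypes (kind: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$kind), collapse = ",")))
  invisible(x)
}

#' Aligned dataset bundle
#'
#' Aligns genotypes, phenotypes, interaction variables and covariates on a
#' shared, ordered set of sample ids. Alignment happens once, here; all
#' downstream functions assume positional alignment.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_set()].
#' @param interactions named list of per-sample vectors (or a data.frame /
#'   matrix with sample row names), e.g. cell-type proportions, age, sex.
#' @param covariates sample-by-covariate numeric matrix with sample row names,
#'   or NULL.
#' @param sample_ids optional explicit sample order; defaults to the
#'   intersection of ids across components, in genotype order.
#' @return object of class `dataset_bundle` with positionally aligned parts.
#' @export
dataset_bundle <- function(genotypes, phenotypes, interactions = list(),
                           covariates = NULL, sample_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(phenotypes, "phenotype_set"))
  if (is.data.frame(interactions) || is.matrix(interactions)) {
    im <- as.matrix(interactions)
    interactions <- stats::setNames(
      lapply(seq_len(ncol(im)), function(j) stats::setNames(im[, j], rownames(im))),
      colnames(im))
  }
  ids_g <- rownames(genotypes$dosages)
  ids_p <- rownames(phenotypes$values)
  if (is.null(sample_ids)) {
    sample_ids <- ids_g[ids_g %in% ids_p]
    for (v in interactions) sample_ids <- sample_ids[sample_ids %in% names(v)]
    if (!is.null(covariates)) sample_ids <- sample_ids[sample_ids %in% rownames(covariates)]
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (length(sample_ids) < 2) stop("fewer than 2 shared samples across components")
  miss <- setdiff(sample_ids, ids_g)
  if (length(miss)) stop("samples missing from genotypes: ", paste(miss, collapse = ", "))
  miss <- setdiff(sample_ids, ids_p)
  if (length(miss)) stop("samples missing from phenotypes: ", paste(miss, collapse = ", "))
  genotypes$dosages <- genotypes$dosages[sample_ids, , drop = FALSE]
  phenotypes$values <- phenotypes$values[sample_ids, , drop = FALSE]
  interactions <- lapply(interactions, function(v) {
    miss <- setdiff(sample_ids, names(v))
    if (length(miss)) stop("samples missing from interaction variable: ",
                           paste(miss, collapse = ", "))
    v[sample_ids]
  })
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    miss <- setdiff(sample_ids, rownames(covariates))
    if (length(miss)) stop("samples missing from covariates: ", paste(miss, collapse = ", "))
    covariates <- covariates[sample_ids, , drop = FALSE]
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 interactions = interactions, covariates = covariates,
                 sample_ids = sample_ids),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(paste0("<dataset_bundle> %d samples | %d variants | %d phenotypes",
                     " | interactions: %s | %d covariates\n"),
              length(x$sample_ids), ncol(x$genotypes$dosages),
              ncol(x$phenotypes$values),
              paste(names(x$interactions), collapse = ","),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}
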