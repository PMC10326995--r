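#' Read a phenotype BED file (tensorQTL convention)
#'
#' The file has a header line and at least four leading columns
#' `chrom`, `start`, `end`, `phenotype_id`, followed by one numeric column per
#' sample. On disk coordinates follow the 0-based half-open BED convention;
#' internally the `end` column is kept as the 1-based anchor (TSS or CpG
#' position) that defines the cis window.
#'
#' @param path path to the (uncompressed) BED file.
#' @param kind phenotype kind stored in the metadata, "gene" or "cpg".
#' @return a [phenotype_set()].
#' @export
read_phenotype_bed <- function(path, kind = c("gene", "cpg")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (ncol(dt) < 5)
    stop("malformed phenotype BED '", path,
         "': need chrom/start/end/phenotype_id plus >=1 sample column")
  names(dt)[1] <- sub("^#", "", names(dt)[1])
  ids <- as.character(dt[[4]])
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1L
    stop("duplicate phenotype_id '", ids[duplicated(ids)][1],
         "' in '", path, "' (line ", line, ")")
  }
  svals <- dt[, -(1:4), drop = FALSE]
  for (j in seq_along(svals)) {
    if (!is.numeric(svals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(svals[[j]]))) &
                     !is.na(svals[[j]]) & svals[[j]] != "NA")[1]
      stop("non-numeric value in sample column '", names(svals)[j],
           "' of '", path, "' (line ", if (is.na(bad)) "?" else bad + 1L, ")")
    }
  }
  values <- t(as.matrix(svals))              # samples x phenotypes
  colnames(values) <- ids
  meta <- data.frame(phenotype_id = ids, chrom = as.character(dt[[1]]),
                     anchor = as.integer(dt[[3]]), kind = kind,
                     stringsAsFactors = FALSE)
  phenotype_set(values, meta)
}

#' Write a phenotype set as a tensorQTL-style BED file
#'
#' @param phenotypes a [phenotype_set()].
#' @param path output path.
#' @export
write_phenotype_bed <- function(phenotypes, path) {
  stopifnot(inherits(phenotypes, "phenotype_set"))
  m <- phenotypes$meta
  out <- data.frame(`#chr` = m$chrom, start = m$anchor - 1L, end = m$anchor,
                    phenotype_id = m$phenotype_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  vals <- as.data.frame(t(phenotypes$values))
  names(vals) <- rownames(phenotypes$values)
  data.table::fwrite(cbind(out, vals), path, sep = "\t", quote = FALSE)
  invisible(path)
}

parse_gt_dosage <- function(gt) {
  # "0/0", "0|1", "1/1", "./." (or half-missing) -> alt-allele count or NA
  out <- rep(NA_real_, length(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gt[known], "[/|]")
  out[known] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
  out
}

#' Read genotype dosages from VCF or a plain dosage TSV
#'
#' For VCF input, biallelic records only: multi-allelic records are skipped
#' with a warning. Dosage comes from the DS field when present, otherwise from
#' GT as the count of alternate alleles; missing genotypes become missing
#' entries. Allele frequency is computed from non-missing entries. Missing
#' dosages are then mean-imputed per variant (the common QTL-scan convention),
#' unless `impute = FALSE`.
#'
#' The dosage TSV has columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#' then one column per sample.
#'
#' @param path input file.
#' @param format "vcf" or "dosage_tsv"; default guesses from the extension.
#' @param impute mean-impute missing dosages per variant (default TRUE).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = NULL, impute = TRUE) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  format <- match.arg(format, c("vcf", "dosage_tsv"))
  if (format == "vcf") gm <- read_genotypes_vcf(path) else gm <- read_genotypes_tsv(path)
  if (impute) {
    d <- gm$dosages
    if (anyNA(d)) {
      for (j in which(colSums(is.na(d)) > 0L)) {
        mu <- mean(d[, j], na.rm = TRUE)
        d[is.na(d[, j]), j] <- mu
      }
      gm$dosages <- d
    }
  }
  gm
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  multi <- nalt != 1L
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped in '", path, "'")
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  gen <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  if ("DS" %in% names(gen)) {
    dos <- t(matrix(as.numeric(gen$DS), nrow = nrow(vcf)))
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    dos <- t(matrix(parse_gt_dosage(as.character(gt)), nrow = nrow(vcf)))
  } else stop("VCF '", path, "' has neither DS nor GT genotype fields")
  rownames(dos) <- samples
  af <- colMeans(dos, na.rm = TRUE) / 2
  meta <- data.frame(variant_id = names(rr),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     ref = as.character(VariantAnnotation::ref(vcf)),
                     alt = as.character(unlist(alt)),
                     af = unname(af), stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(dt)))
    stop("dosage TSV '", path, "' must have columns ", paste(need, collapse = ", "),
         " followed by sample columns")
  svals <- dt[, setdiff(names(dt), need), drop = FALSE]
  dos <- t(as.matrix(svals))
  rownames(dos) <- names(svals)
  af <- colMeans(dos, na.rm = TRUE) / 2
  meta <- data.frame(variant_id = dt$variant_id, chrom = as.character(dt$chrom),
                     pos = as.integer(dt$pos), ref = dt$ref, alt = dt$alt,
                     af = unname(af), stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

#' Write genotypes as a dosage TSV
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  m <- genotypes$meta
  out <- data.frame(variant_id = m$variant_id, chrom = m$chrom, pos = m$pos,
                    ref = if ("ref" %in% names(m)) m$ref else "A",
                    alt = if ("alt" %in% names(m)) m$alt else "G",
                    stringsAsFactors = FALSE)
  vals <- as.data.frame(t(genotypes$dosages))
  names(vals) <- rownames(genotypes$dosages)
  data.table::fwrite(cbind(out, vals), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF v4.2 (GT when integral dosages, else DS)
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  m <- genotypes$meta
  samples <- rownames(d)
  integral <- all(is.na(d) | d == round(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               if (integral)
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
               else
                 '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    field <- if (integral) {
      ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    } else {
      ifelse(is.na(d[, j]), ".", format(d[, j], digits = 10, trim = TRUE))
    }
    writeLines(paste(c(m$chrom[j], m$pos[j], m$variant_id[j],
                       if ("ref" %in% names(m)) m$ref[j] else "A",
                       if ("alt" %in% names(m)) m$alt[j] else "G",
                       ".", "PASS", ".", if (integral) "GT" else "DS", field),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a covariate (or interaction-variable) TSV
#'
#' First column holds the sample id; remaining columns must be numeric.
#'
#' @param path input TSV.
#' @param sample_ids optional requested sample order; rows are reordered to
#'   match, and samples missing from the file raise an error listing the ids.
#' @return numeric matrix with sample row names.
#' @export
read_covariates <- function(path, sample_ids = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample ids in '", path, "'")
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]))
      stop("non-numeric value in covariate column '", names(vals)[j],
           "' of '", path, "'")
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, ids)
    if (length(miss))
      stop("samples missing from '", path, "': ", paste(miss, collapse = ", "))
    m <- m[sample_ids, , drop = FALSE]
  }
  m
}

result_columns <- c("phenotype_id", "variant_id", "chrom", "pos", "maf",
                    "maf_lower_half", "maf_upper_half", "b_g", "se_g", "p_g",
                    "b_gxe", "se_gxe", "p_gxe", "p_eigenmt", "q_bh", "direction")

#' Write iQTL records to a TSV with a stable column order
#'
#' Columns: phenotype_id, variant_id, chrom, pos, maf, maf_lower_half,
#' maf_upper_half, b_g, se_g, p_g, b_gxe, se_gxe, p_gxe, p_eigenmt, q_bh,
#' direction. Absent fields are written as NA; any extra columns follow the
#' stable block. Floating values keep full (>= 10 significant digit)
#' precision.
#'
#' @param records data.frame of iQTL records.
#' @param path output path.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  for (cc in setdiff(result_columns, names(records)))
    records[[cc]] <- rep(NA, nrow(records))
  extra <- setdiff(names(records), result_columns)
  records <- records[, c(result_columns, extra), drop = FALSE]
  data.table::fwrite(records, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an iQTL results TSV written by [write_results()]
#' @param path input path.
#' @return data.frame of records.
#' @export
read_results <- function(path) {
  data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                    na.strings = "NA")
}
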