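#' Enumerate cis phenotype-variant pairs
#'
#' A pair is included when the variant lies on the phenotype's chromosome and
#' within `half_width_bp` of its anchor, boundary inclusive. Conventional
#' windows are +/-1 Mb of a gene's TSS and +/-500 kb of a CpG site.
#'
#' @param phenotypes a [phenotype_set()] (or its `meta` data.frame).
#' @param variants variant metadata data.frame with `variant_id`, `chrom`, `pos`.
#' @param half_width_bp window half-width; if NULL, taken from the phenotype
#'   kind (gene: 1e6, cpg: 5e5).
#' @return data.frame with `phenotype_id`, `variant_id` and the matched
#'   integer indices `phenotype_idx`, `variant_idx`.
#' @export
cis_pairs <- function(phenotypes, variants, half_width_bp = NULL) {
  pm <- if (inherits(phenotypes, "phenotype_set")) phenotypes$meta else as.data.frame(phenotypes)
  vm <- as.data.frame(variants)
  if (is.null(half_width_bp)) {
    kind <- if ("kind" %in% names(pm)) pm$kind else "gene"
    half_width_bp <- ifelse(kind == "cpg", 5e5, 1e6)
  }
  if (length(half_width_bp) == 1L) half_width_bp <- rep(half_width_bp, nrow(pm))
  stopifnot(all(half_width_bp > 0))
  out <- vector("list", nrow(pm))
  for (chr in unique(pm$chrom)) {
    vsel <- which(vm$chrom == chr)
    if (!length(vsel)) next
    vord <- vsel[order(vm$pos[vsel])]
    vpos <- vm$pos[vord]
    for (i in which(pm$chrom == chr)) {
      lo <- findInterval(pm$anchor[i] - half_width_bp[i] - 0.5, vpos) + 1L
      hi <- findInterval(pm$anchor[i] + half_width_bp[i] + 0.5, vpos)
      if (hi >= lo) {
        idx <- vord[lo:hi]
        out[[i]] <- data.frame(phenotype_id = pm$phenotype_id[i],
                               variant_id = vm$variant_id[idx],
                               phenotype_idx = i, variant_idx = idx,
                               stringsAsFactors = FALSE)
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(phenotype_id = character(), variant_id = character(),
                      phenotype_idx = integer(), variant_idx = integer()))
  do.call(rbind, out)
}

#' Fit the interaction linear model for one phenotype-variant pair
#'
#' Ordinary least squares for `Y ~ 1 + G + E + GxE + C`, where the `GxE`
#' column is the elementwise product of the dosage and the (centered)
#' interaction variable. Two-sided p-values come from the t distribution on
#' the residual degrees of freedom. The genotype column is deliberately not
#' centered, so with centered E the genotype main effect is the QTL effect at
#' the mean of the interaction variable.
#'
#' @param y phenotype vector (no missing values).
#' @param g dosage vector.
#' @param e centered interaction vector.
#' @param C covariate matrix or NULL.
#' @return one-row data.frame (an iQTL record) with coefficient, SE, t and p
#'   for the G, E and GxE terms, `n`, `df_resid` and a `degenerate` flag; a
#'   rank-deficient design yields a flagged record with missing estimates.
#' @export
fit_interaction_model <- function(y, g, e, C = NULL) {
  n <- length(y)
  stopifnot(length(g) == n, length(e) == n)
  C <- as_covariate_matrix(C, n)
  X <- cbind(`(Intercept)` = 1, g = g, e = e, gxe = g * e, C)
  f <- ols_fit(X, y)
  grab <- function(fld, term) unname(f[[fld]][term])
  data.frame(b_g = grab("coef", "g"), se_g = grab("se", "g"),
             t_g = grab("t", "g"), p_g = grab("p", "g"),
             b_e = grab("coef", "e"), se_e = grab("se", "e"), p_e = grab("p", "e"),
             b_gxe = grab("coef", "gxe"), se_gxe = grab("se", "gxe"),
             t_gxe = grab("t", "gxe"), p_gxe = grab("p", "gxe"),
             n = n, df_resid = n - ncol(X), degenerate = !f$ok)
}

#' Per-group genotype effect (binary interaction variables)
#'
#' OLS of `y ~ 1 + g + C` restricted to the samples in the group, used by the
#' four-category direction rule for binary interaction variables.
#'
#' @param y phenotype vector.
#' @param g dosage vector.
#' @param C covariate matrix or NULL.
#' @param group_mask logical vector selecting the group's samples.
#' @return one-row data.frame with `b_g`, `se_g`, `t_g`, `p_g`, `n`, `df_resid`.
#' @export
fit_group_model <- function(y, g, C = NULL, group_mask = NULL) {
  n <- length(y)
  if (is.null(group_mask)) group_mask <- rep(TRUE, n)
  stopifnot(length(g) == n, length(group_mask) == n)
  C <- as_covariate_matrix(C, n)
  idx <- which(group_mask)
  ncols <- 2L + ncol(C)
  if (length(idx) < ncols + 3L)
    stop("degenerate group: needs at least ", ncols + 3L, " samples, has ",
         length(idx))
  X <- cbind(`(Intercept)` = 1, g = g[idx], C[idx, , drop = FALSE])
  f <- ols_fit(X, y[idx])
  if (!f$ok) stop("rank-deficient design in group fit")
  data.frame(b_g = unname(f$coef["g"]), se_g = unname(f$se["g"]),
             t_g = unname(f$t["g"]), p_g = unname(f$p["g"]),
             n = length(idx), df_resid = f$df_resid)
}

#' Scan all cis pairs with the interaction model
#'
#' Applies the global MAF filter, then the interaction-aware MAF filter (MAF
#' above threshold in both halves of the interaction variable's
#' distribution), enumerates cis pairs among surviving variants, fits the
#' interaction model for each pair, and reports the top association (smallest
#' interaction p-value; ties broken by smaller position then variant id) per
#' phenotype.
#'
#' @param bundle a [dataset_bundle()].
#' @param e_name name of the interaction variable in `bundle$interactions`.
#' @param half_width_bp cis window half-width; NULL = by phenotype kind
#'   (gene 1e6, cpg 5e5).
#' @param maf_global minor allele frequency floor over all samples (default
#'   0.01).
#' @param maf_interaction per-half MAF floor (default 0.05; 0.1 is the
#'   conventional stricter choice for trait interactions).
#' @param transform "none" (default) fits phenotypes as stored; "int" applies
#'   the rank-based inverse normal transform per phenotype first.
#' @param seed seed for the INT tie-breaking noise when `transform = "int"`.
#' @return object of class `iqtl_scan`: list with `pairs` (all fitted
#'   records), `top` (one record per phenotype), `skipped` (phenotypes with no
#'   surviving variant), `tested` (pair index after filtering), `e_name`.
#' @export
iqtl_scan <- function(bundle, e_name, half_width_bp = NULL,
                      maf_global = 0.01, maf_interaction = 0.05,
                      transform = c("none", "int"), seed = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  transform <- match.arg(transform)
  if (!e_name %in% names(bundle$interactions))
    stop("unknown interaction variable '", e_name, "'")
  e <- center_vector(as.numeric(bundle$interactions[[e_name]]))
  if (anyNA(e)) stop("interaction variable '", e_name, "' has missing values")
  d <- bundle$genotypes$dosages
  vm <- bundle$genotypes$meta
  C <- bundle$covariates

  f_all <- colMeans(d) / 2
  maf_all <- pmin(f_all, 1 - f_all)
  imf <- interaction_maf_filter(d, e, maf_interaction)
  keep <- maf_all > maf_global & imf$keep

  Y <- bundle$phenotypes$values
  if (transform == "int") {
    if (!is.null(seed)) set.seed(seed)
    Y <- apply(Y, 2, inverse_normal_transform)
  }

  pairs_idx <- cis_pairs(bundle$phenotypes, vm[keep, , drop = FALSE],
                         half_width_bp = half_width_bp)
  # map back to full-matrix variant indices
  kept_idx <- which(keep)
  pairs_idx$variant_idx <- kept_idx[pairs_idx$variant_idx]

  skipped <- setdiff(bundle$phenotypes$meta$phenotype_id,
                     unique(pairs_idx$phenotype_id))
  recs <- vector("list", nrow(pairs_idx))
  for (k in seq_len(nrow(pairs_idx))) {
    pi_ <- pairs_idx$phenotype_idx[k]
    vi <- pairs_idx$variant_idx[k]
    rec <- fit_interaction_model(Y[, pi_], d[, vi], e, C)
    recs[[k]] <- cbind(
      data.frame(phenotype_id = pairs_idx$phenotype_id[k],
                 variant_id = pairs_idx$variant_id[k],
                 chrom = vm$chrom[vi], pos = vm$pos[vi],
                 maf = unname(maf_all[vi]),
                 maf_lower_half = unname(imf$maf_lower[vi]),
                 maf_upper_half = unname(imf$maf_upper[vi]),
                 stringsAsFactors = FALSE),
      rec)
  }
  pairs <- if (length(recs)) do.call(rbind, recs) else
    cbind(data.frame(phenotype_id = character(), variant_id = character(),
                     chrom = character(), pos = integer(), maf = numeric(),
                     maf_lower_half = numeric(), maf_upper_half = numeric()),
          fit_interaction_model(c(0, 1, 2, 3, 2, 1), c(0, 1, 2, 0, 1, 2),
                                c(-1, 0, 1, -1, 0, 1))[0, ])
  top <- top_per_phenotype(pairs)
  structure(list(pairs = pairs, top = top, skipped = skipped,
                 tested = pairs_idx, e_name = e_name),
            class = "iqtl_scan")
}

# smallest p_gxe per phenotype; ties -> smaller pos, then variant id;
# degenerate records lose to any finite p
top_per_phenotype <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  p <- pairs$p_gxe
  p[is.na(p)] <- Inf
  ord <- order(pairs$phenotype_id, p, pairs$pos, pairs$variant_id)
  pairs <- pairs[ord, , drop = FALSE]
  out <- pairs[!duplicated(pairs$phenotype_id), , drop = FALSE]
  # count of variants tested per phenotype, needed for eigenMT capping
  out$n_variants <- as.integer(table(pairs$phenotype_id)[out$phenotype_id])
  rownames(out) <- NULL
  out
}

#' @export
print.iqtl_scan <- function(x, ...) {
  cat(sprintf("<iqtl_scan> E = %s | %d pairs fitted | %d phenotypes | %d skipped\n",
              x$e_name, nrow(x$pairs), nrow(x$top), length(x$skipped)))
  invisible(x)
}
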