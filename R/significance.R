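#' Effective number of tests from local genotype correlation
#'
#' Variants are partitioned into consecutive windows of at most `window_size`;
#' within each window the variant-variant Pearson correlation matrix of
#' dosages is eigendecomposed and the window's effective test count is the
#' smallest k such that the top-k eigenvalues sum to at least
#' `var_threshold` of the trace. The total, summed over windows, is capped at
#' the variant count.
#'
#' @param genotype_block sample-by-variant dosage matrix (each variant must
#'   have positive variance).
#' @param window_size maximum variants per window (default 200, the tool's
#'   published default).
#' @param var_threshold fraction of variance to capture (default 0.99).
#' @return integer effective number of tests, between 1 and `ncol`.
#' @export
eigenmt_meff <- function(genotype_block, window_size = 200, var_threshold = 0.99) {
  G <- as.matrix(genotype_block)
  V <- ncol(G)
  stopifnot(V >= 1)
  vars <- apply(G, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance variant(s) in eigenMT block: ",
         paste(which(vars == 0), collapse = ", "))
  starts <- seq(1L, V, by = window_size)
  meff <- 0L
  for (s in starts) {
    idx <- s:min(s + window_size - 1L, V)
    if (length(idx) == 1L) { meff <- meff + 1L; next }
    R <- stats::cor(G[, idx, drop = FALSE])
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) >= var_threshold * sum(ev))[1]
    meff <- meff + k
  }
  min(meff, V)
}

#' Benjamini-Hochberg adjusted values (step-up)
#'
#' @param p vector of p-values in \[0, 1\] (NA passed through).
#' @return adjusted q-values, monotone in the p-value ranks.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- order(p[ok], decreasing = TRUE)
  ranked <- p[ok][ord] * m / seq(m, 1)
  q <- pmin(1, cummin(ranked))
  out[ok][ord] <- q
  out
}

#' Hierarchical significance calls (per-phenotype correction, then BH)
#'
#' For each phenotype the top nominal interaction p-value is corrected by its
#' effective number of tests (p_eigenmt = min(1, p_top * m_eff), computed from
#' the dosage correlation of the variants actually tested for that
#' phenotype), then the Benjamini-Hochberg procedure is applied across
#' phenotypes.
#'
#' @param scan an `iqtl_scan` result (or a list with `top` and `tested`).
#' @param genotypes the [genotype_matrix()] used in the scan.
#' @param fdr FDR threshold for the `significant` flag (0.05 is conventional
#'   for cell-type interactions, 0.25 for trait interactions).
#' @param window_size,var_threshold passed to [eigenmt_meff()].
#' @return data.frame: the top records plus `m_eff`, `p_eigenmt`, `q_bh`,
#'   `significant`.
#' @export
significance_calls <- function(scan, genotypes, fdr = 0.05,
                               window_size = 200, var_threshold = 0.99) {
  top <- scan$top
  tested <- scan$tested
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  m_eff <- integer(nrow(top))
  for (i in seq_len(nrow(top))) {
    vidx <- tested$variant_idx[tested$phenotype_id == top$phenotype_id[i]]
    m_eff[i] <- eigenmt_meff(d[, vidx, drop = FALSE],
                             window_size = window_size,
                             var_threshold = var_threshold)
  }
  top$m_eff <- m_eff
  top$p_eigenmt <- pmin(1, top$p_gxe * m_eff)
  top$q_bh <- bh_adjust(top$p_eigenmt)
  top$significant <- !is.na(top$q_bh) & top$q_bh < fdr
  top
}

#' Combine significance calls across two exams
#'
#' Takes the union of phenotypes significant in either exam; for phenotypes
#' significant in both, the record with the smaller interaction p-value is
#' kept (ties keep the earlier exam). Provenance is retained in an `exam`
#' column.
#'
#' @param calls_exam1,calls_exam2 data.frames from [significance_calls()]
#'   (must have `phenotype_id`, `p_gxe`, `significant`).
#' @param labels exam labels, in order.
#' @return combined data.frame with one record per phenotype.
#' @export
combine_exams <- function(calls_exam1, calls_exam2,
                          labels = c("exam1", "exam2")) {
  a <- as.data.frame(calls_exam1)
  b <- as.data.frame(calls_exam2)
  a$exam <- labels[1]
  b$exam <- labels[2]
  a <- a[a$significant %in% TRUE, , drop = FALSE]
  b <- b[b$significant %in% TRUE, , drop = FALSE]
  common <- intersect(names(a), names(b))
  both <- rbind(a[, common, drop = FALSE], b[, common, drop = FALSE])
  if (nrow(both) == 0) return(both)
  # order: phenotype, then smaller p, then exam label order (earlier wins tie)
  ord <- order(both$phenotype_id, both$p_gxe, match(both$exam, labels))
  both <- both[ord, , drop = FALSE]
  out <- both[!duplicated(both$phenotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
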