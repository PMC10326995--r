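#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles at
#' `(rank - rank_offset) / (n - 2 * rank_offset + 1)` over the non-missing
#' entries. Ties are broken by adding Gaussian noise with a tiny standard
#' deviation before ranking (variance 1e-16, i.e. SD 1e-8, by default), so the
#' transform is a strictly monotone function of the perturbed ranks. Missing
#' values stay missing.
#'
#' @param x numeric vector with at least 3 non-missing values.
#' @param tie_noise_sd SD of the tie-breaking noise; 0 disables it.
#' @param rank_offset offset in \[0, 0.5\] for the rank-to-quantile mapping
#'   (default 0.5, i.e. quantiles at (rank - 0.5)/n).
#' @param seed optional integer seed for the tie-breaking noise.
#' @return transformed vector, same length and names as `x`.
#' @export
inverse_normal_transform <- function(x, tie_noise_sd = 1e-8, rank_offset = 0.5,
                                     seed = NULL) {
  stopifnot(tie_noise_sd >= 0, rank_offset >= 0, rank_offset <= 0.5)
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("inverse normal transform needs >= 3 non-missing values")
  v <- x[ok]
  if (tie_noise_sd == 0 && length(unique(v)) == 1L)
    stop("all values identical and tie_noise_sd = 0: ranks undefined")
  if (tie_noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    v <- v + stats::rnorm(n, 0, tie_noise_sd)
  }
  r <- rank(v, ties.method = "first")
  q <- stats::qnorm((r - rank_offset) / (n - 2 * rank_offset + 1))
  out <- x
  out[ok] <- q
  out
}

#' Outlier exclusion mask at k standard deviations
#'
#' A value is excluded when it lies more than `k` sample standard deviations
#' from the mean, both computed over the non-missing values.
#'
#' @param x numeric vector with >= 2 non-missing values.
#' @param k SD multiple (default 3). `Inf` keeps everything.
#' @return logical mask, TRUE = keep; NA where `x` is missing.
#' @export
exclude_outliers <- function(x, k = 3) {
  stopifnot(k > 0)
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need >= 2 non-missing values")
  mu <- mean(x[ok])
  s <- stats::sd(x[ok])
  keep <- rep(NA, length(x))
  keep[ok] <- if (s == 0 || is.infinite(k)) TRUE else abs(x[ok] - mu) <= k * s
  keep
}

#' Mean-center a vector (missing values preserved)
#' @param x numeric vector with >= 1 non-missing value.
#' @return centered vector with mean 0 over non-missing entries.
#' @export
center_vector <- function(x) {
  if (all(is.na(x))) stop("cannot center an all-missing vector")
  x - mean(x, na.rm = TRUE)
}

#' Split samples into lower/upper halves by rank of the interaction variable
#'
#' Deterministic rule: samples are ordered by value with original sample order
#' as the tie-break; with odd n the median sample goes to the lower half.
#'
#' @param e interaction vector without missing values.
#' @return logical vector, TRUE = lower half.
#' @export
half_split <- function(e) {
  if (anyNA(e)) stop("interaction variable has missing values")
  n <- length(e)
  ord <- order(e, seq_len(n))
  lower <- logical(n)
  lower[ord[seq_len(ceiling(n / 2))]] <- TRUE
  lower
}

#' Interaction-aware MAF filter
#'
#' Samples are split into lower and upper halves of the interaction variable's
#' distribution; a variant is kept only when its minor allele frequency
#' exceeds `threshold` in both halves. Guards against interaction estimates
#' driven by a handful of carriers concentrated at one end of the interaction
#' variable.
#'
#' @param dosages sample-by-variant dosage matrix (no missing values).
#' @param e interaction vector, no missing values among scanned samples.
#' @param threshold MAF threshold (0.05 for cell-type interactions, 0.1 for
#'   trait interactions).
#' @return list with `keep` (logical per variant), `maf_lower`, `maf_upper`.
#' @export
interaction_maf_filter <- function(dosages, e, threshold = 0.05) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(e))
  lower <- half_split(e)
  if (sum(lower) < 2 || sum(!lower) < 2)
    stop("fewer than 2 samples per half of the interaction distribution")
  f_lo <- colMeans(dosages[lower, , drop = FALSE]) / 2
  f_hi <- colMeans(dosages[!lower, , drop = FALSE]) / 2
  maf_lo <- pmin(f_lo, 1 - f_lo)
  maf_hi <- pmin(f_hi, 1 - f_hi)
  list(keep = maf_lo > threshold & maf_hi > threshold,
       maf_lower = maf_lo, maf_upper = maf_hi)
}

#' Collapse CpG-variant records to sentinel sites
#'
#' Greedy selection used to de-correlate co-methylated CpG sites: repeatedly
#' take the remaining record with the smallest interaction p-value, emit it as
#' a sentinel, and discard every record whose CpG anchor lies within
#' `window_bp` of it on the same chromosome. Ties in p-value break by smaller
#' anchor position, then lexicographic variant id, so the output does not
#' depend on input order.
#'
#' @param records data.frame with at least `chrom`, `pos` (CpG anchor) and
#'   `p_gxe`; typically the top record per CpG from a scan.
#' @param window_bp half-width of the exclusion window (default 1000, i.e. a
#'   2 kb window centered on each sentinel).
#' @return the sentinel subset of `records`, pairwise > `window_bp` apart.
#' @export
collapse_sentinels <- function(records, window_bp = 1000) {
  records <- as.data.frame(records)
  stopifnot(all(c("chrom", "pos", "p_gxe") %in% names(records)))
  if (nrow(records) == 0) return(records)
  vid <- if ("variant_id" %in% names(records)) as.character(records$variant_id)
         else rep("", nrow(records))
  ord <- order(records$p_gxe, records$pos, vid)
  records <- records[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(records))
  sentinel <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!alive[i]) next
    sentinel[i] <- TRUE
    hit <- alive & records$chrom == records$chrom[i] &
      abs(records$pos - records$pos[i]) <= window_bp
    alive[hit] <- FALSE
  }
  out <- records[sentinel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
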