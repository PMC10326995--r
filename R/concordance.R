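#' Storey's pi0 at a fixed lambda
#'
#' Point estimator `pi0 = #\{p > lambda\} / (n * (1 - lambda))`, clamped to
#' \[0, 1\]. The smoother-based estimator is deliberately not provided; the
#' replication workflow fixes lambda by sample-size rule (see
#' [pi1_reproducibility()]).
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda tuning value in (0, 1).
#' @return list with `pi0` and `pi1 = 1 - pi0`.
#' @export
storey_pi0 <- function(p, lambda = 0.5) {
  if (length(p) == 0) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1), lambda > 0, lambda < 1)
  pi0 <- sum(p > lambda) / (length(p) * (1 - lambda))
  pi0 <- min(max(pi0, 0), 1)
  list(pi0 = pi0, pi1 = 1 - pi0)
}

#' Proportion of true positives (pi1) with sample-size lambda rule
#'
#' Reproducibility/replication convention: the estimate is reported only when
#' more than 20 validation pairs are available; lambda = 0.5 for more than 20
#' and up to 100 pairs, lambda = 0.85 for more than 100 pairs.
#'
#' @param validation_p interaction p-values observed in the validation data.
#' @return list with `pi1`, `pi0`, `lambda_used`, `n_pairs`, `defined` and a
#'   `reason` when undefined.
#' @export
pi1_reproducibility <- function(validation_p) {
  n <- length(validation_p)
  if (n <= 20)
    return(list(pi1 = NA_real_, pi0 = NA_real_, lambda_used = NA_real_,
                n_pairs = n, defined = FALSE,
                reason = "too few validation pairs (need > 20)"))
  lambda <- if (n > 100) 0.85 else 0.5
  s <- storey_pi0(validation_p, lambda)
  list(pi1 = s$pi1, pi0 = s$pi0, lambda_used = lambda, n_pairs = n,
       defined = TRUE, reason = NA_character_)
}

#' Fraction of validation pairs with nominally significant interaction
#' @param validation_p p-values in the validation data.
#' @param alpha nominal level (default 0.05).
#' @return fraction in \[0, 1\].
#' @export
nominal_replication_rate <- function(validation_p, alpha = 0.05) {
  if (length(validation_p) == 0) stop("empty p-value vector")
  mean(validation_p < alpha)
}

#' Genomic inflation factor lambda
#'
#' Ratio of the median observed chi-squared statistic (1 df, from the
#' upper-tail transform of the p-values) to the median of the null
#' chi-squared(1) distribution.
#'
#' @param p vector of p-values in (0, 1\].
#' @return lambda (1 under the null, > 1 indicates enrichment of signal).
#' @export
inflation_lambda <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  stopifnot(all(p > 0 & p <= 1))
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' @param genotypes a [genotype_matrix()] (or bare dosage matrix).
#' @param pairs two-column matrix/data.frame of variant ids or column indices.
#' @return numeric vector of r-squared per pair; NA (with a warning) when a
#'   variant is constant.
#' @export
ld_r2 <- function(genotypes, pairs) {
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  out <- numeric(nrow(pairs))
  warned <- FALSE
  for (i in seq_len(nrow(pairs))) {
    a <- d[, pairs[i, 1]]
    b <- d[, pairs[i, 2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out[i] <- NA_real_
      warned <- TRUE
    } else out[i] <- stats::cor(a, b)^2
  }
  if (warned) warning("constant variant(s): r2 undefined for some pair(s)")
  out
}

#' Normalized LD overlap between two variant sets
#'
#' Counts query variants tagged by (in LD with, r2 >= `r2_min` within
#' `window_bp`; a variant always tags itself) at least one validation
#' variant, divided by the size of the smaller set, capped at 1.
#'
#' @param query,validation character vectors of variant ids (non-empty).
#' @param genotypes [genotype_matrix()] holding dosages and positions for all
#'   involved variants (the LD reference).
#' @param r2_min LD threshold (default 0.5).
#' @param window_bp maximum distance for an LD match (default 1e6).
#' @return list with `normalized_overlap`, `n_tagged`, `n_query`,
#'   `n_validation`.
#' @export
normalized_overlap <- function(query, validation, genotypes,
                               r2_min = 0.5, window_bp = 1e6) {
  if (length(query) == 0 || length(validation) == 0)
    stop("empty variant set")
  stopifnot(inherits(genotypes, "genotype_matrix"))
  m <- genotypes$meta
  d <- genotypes$dosages
  idx <- function(v) {
    i <- match(v, m$variant_id)
    if (anyNA(i)) stop("variants absent from LD reference: ",
                       paste(v[is.na(i)], collapse = ", "))
    i
  }
  qi <- idx(unique(query))
  vi <- idx(unique(validation))
  tagged <- 0L
  for (q in qi) {
    if (q %in% vi) { tagged <- tagged + 1L; next }   # self-match
    cand <- vi[m$chrom[vi] == m$chrom[q] & abs(m$pos[vi] - m$pos[q]) <= window_bp]
    hit <- FALSE
    for (v in cand) {
      if (stats::sd(d[, q]) == 0 || stats::sd(d[, v]) == 0) next
      if (stats::cor(d[, q], d[, v])^2 >= r2_min) { hit <- TRUE; break }
    }
    if (hit) tagged <- tagged + 1L
  }
  denom <- min(length(qi), length(vi))
  list(normalized_overlap = min(tagged / denom, 1),
       n_tagged = tagged, n_query = length(qi), n_validation = length(vi))
}

#' Odds ratio with Haldane-Anscombe correction and exact p-value
#'
#' When any cell of the 2x2 table is zero, 0.5 is added to all cells before
#' computing the odds ratio `(a*d)/(b*c)`. The p-value comes from a two-sided
#' exact conditional test on the original, uncorrected counts.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major a, b, c, d) of
#'   non-negative integer counts.
#' @return list with `odds_ratio`, `p_value`, `table` (original counts),
#'   `corrected` flag.
#' @export
haldane_anscombe_or <- function(table) {
  tb <- matrix(as.numeric(table), nrow = 2, byrow = !is.matrix(table))
  if (is.matrix(table)) tb <- matrix(as.numeric(table), nrow = 2)
  stopifnot(all(tb >= 0), all(tb == round(tb)))
  corrected <- any(tb == 0)
  tb2 <- if (corrected) tb + 0.5 else tb
  or <- (tb2[1, 1] * tb2[2, 2]) / (tb2[1, 2] * tb2[2, 1])
  pv <- stats::fisher.test(matrix(as.integer(tb), 2, 2))$p.value
  list(odds_ratio = or, p_value = pv, table = tb, corrected = corrected)
}

#' Allelic concordance between discovery and replication effects
#'
#' Proportion of pairs whose effect estimates agree in sign; pairs where
#' either effect is exactly zero (or missing) are excluded.
#'
#' @param query_b,validation_b aligned effect-size vectors (harmonized to the
#'   same effect allele).
#' @return fraction in \[0, 1\].
#' @export
allelic_concordance <- function(query_b, validation_b) {
  stopifnot(length(query_b) == length(validation_b))
  ok <- !is.na(query_b) & !is.na(validation_b) & query_b != 0 & validation_b != 0
  if (!any(ok)) stop("no nonzero, non-missing pairs")
  mean(sign(query_b[ok]) == sign(validation_b[ok]))
}

#' Absolute value of the median replication effect size
#' @param validation_b effect-size vector (non-empty).
#' @return `abs(median(validation_b))`.
#' @export
median_abs_effect <- function(validation_b) {
  if (length(validation_b) == 0) stop("empty effect vector")
  abs(stats::median(validation_b, na.rm = TRUE))
}
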