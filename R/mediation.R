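# Mediated moderation: does a moderator's effect on a QTL (G x W, e.g.
# genotype-by-age) travel through a mediator's interaction (G x M, e.g.
# genotype-by-cell-proportion)? The moderation path is X*W -> X*M -> Y, so
# the "treatment" in mediation terms is the product term G x W and the
# "mediator" is G x M. For linear models the product-of-coefficients
# estimator (a * b) coincides with the simulation-based ACME, so point
# estimates use the closed form and all inference comes from a nonparametric
# bootstrap with BCa intervals.

mediation_design <- function(g, w, m, C, n) {
  C <- as_covariate_matrix(C, n)
  g <- g - mean(g); w <- w - mean(w); m <- m - mean(m)
  list(g = g, w = w, m = m, C = C,
       Xmed = cbind(`(Intercept)` = 1, g = g, w = w, gxw = g * w, m = m, C),
       Xout = cbind(`(Intercept)` = 1, g = g, w = w, gxw = g * w, m = m,
                    gxm = g * m, C))
}

#' Mediator model of the mediated-moderation analysis
#'
#' OLS of `G*M ~ 1 + G + W + G*W + M + C` on mean-centered G, W, M. The path
#' coefficient `a` is the coefficient of the G*W column: how strongly the
#' moderator interaction predicts the mediator interaction.
#'
#' @param g dosage vector; @param w moderator (e.g. age); @param m mediator
#'   (e.g. cell-type proportion); @param C covariate matrix or NULL.
#' @return list with `a`, full `fit` (see [ols_fit()]).
#' @export
fit_mediator_model <- function(g, w, m, C = NULL) {
  n <- length(g)
  stopifnot(length(w) == n, length(m) == n)
  dd <- mediation_design(g, w, m, C, n)
  f <- ols_fit(dd$Xmed, dd$g * dd$m)
  if (!f$ok) stop("rank-deficient design in mediator model")
  list(a = unname(f$coef["gxw"]), fit = f)
}

#' Outcome model of the mediated-moderation analysis
#'
#' OLS of `Y ~ 1 + G + W + G*W + M + G*M + C` on mean-centered G, W, M.
#' Returns `b` (coefficient of G*M, the mediator path into the outcome) and
#' `direct` (coefficient of G*W, the direct moderation effect).
#'
#' @param y outcome (molecular phenotype); @param g,w,m,C as in
#'   [fit_mediator_model()].
#' @return list with `b`, `direct`, full `fit`.
#' @export
fit_outcome_model <- function(y, g, w, m, C = NULL) {
  n <- length(y)
  stopifnot(length(g) == n, length(w) == n, length(m) == n)
  dd <- mediation_design(g, w, m, C, n)
  f <- ols_fit(dd$Xout, y)
  if (!f$ok) stop("rank-deficient design in outcome model")
  list(b = unname(f$coef["gxm"]), direct = unname(f$coef["gxw"]), fit = f)
}

# point estimates for one (possibly resampled) dataset; NULL if degenerate
mediation_point <- function(y, g, w, m, C) {
  dd <- mediation_design(g, w, m, C, length(y))
  fm <- ols_fit(dd$Xmed, dd$g * dd$m)
  fo <- ols_fit(dd$Xout, y)
  if (!fm$ok || !fo$ok) return(NULL)
  a <- unname(fm$coef["gxw"])
  b <- unname(fo$coef["gxm"])
  direct <- unname(fo$coef["gxw"])
  acme <- a * b
  total <- acme + direct
  c(acme = acme, ade = direct, total = total,
    prop = if (total != 0) acme / total else NA_real_)
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval: the bias term z0 is the normal
#' quantile of the fraction of bootstrap draws below the point estimate; the
#' acceleration comes from the jackknife third-moment formula.
#'
#' @param boot vector of bootstrap estimates (length >= 100 recommended).
#' @param point the point estimate on the full data.
#' @param jackknife vector of leave-one-out estimates.
#' @param level confidence level (default 0.95).
#' @return numeric length-2 vector (lower, upper).
#' @export
bca_interval <- function(boot, point, jackknife, level = 0.95) {
  boot <- boot[!is.na(boot)]
  B <- length(boot)
  stopifnot(B >= 1)
  if (all(boot == point)) return(c(point, point))
  prop <- mean(boot < point)
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  jk <- jackknife[!is.na(jackknife)]
  dj <- mean(jk) - jk
  denom <- 6 * sum(dj^2)^1.5
  a_hat <- if (denom == 0) 0 else sum(dj^3) / denom
  alpha <- (1 - level) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a_hat * (z0 + zq)))
  unname(stats::quantile(boot, probs = adj, type = 7))
}

boot_pvalue <- function(draws, n_boot) {
  draws <- draws[!is.na(draws)]
  if (!length(draws)) return(NA_real_)
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  min(max(p, 1 / n_boot), 1)
}

#' Mediated moderation with nonparametric bootstrap and BCa intervals
#'
#' Point estimates are the product-of-coefficients decomposition:
#' ACME = a * b (mediator-model G*W coefficient times outcome-model G*M
#' coefficient), ADE = the outcome-model G*W coefficient, total = ACME + ADE,
#' proportion mediated = ACME / total. Inference resamples whole sample rows
#' with replacement (keeping y, g, w, m and covariates linked), refits both
#' models per draw, and forms BCa intervals and two-sided bootstrap p-values
#' (floored at 1/n_boot).
#'
#' @param y outcome vector; @param g dosage; @param w moderator; @param m
#'   mediator; @param C covariates or NULL.
#' @param n_boot bootstrap draws (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @param prop_truncate if TRUE, the proportion mediated is truncated to
#'   \[0, 1\] (used when ACME and total disagree in sign); default FALSE
#'   reports the raw ratio.
#' @param compute_ci if FALSE, skip the jackknife and BCa intervals (they
#'   become NA) and return bootstrap p-values only; useful when screening
#'   many pairs.
#' @return list of class `mediation_result`: `acme`, `ade`, `total`,
#'   `prop_mediated`, `ci_acme`, `ci_ade`, `ci_total`, `ci_prop`, `p_acme`,
#'   `p_ade`, `p_total`, `n_boot`, `n`, `seed`.
#' @export
mediated_moderation <- function(y, g, w, m, C = NULL, n_boot = 1000,
                                level = 0.95, seed = NULL,
                                prop_truncate = FALSE, compute_ci = TRUE) {
  n <- length(y)
  stopifnot(length(g) == n, length(w) == n, length(m) == n, n_boot >= 10)
  if (!is.null(seed)) set.seed(seed)
  Cm <- as_covariate_matrix(C, n)
  point <- mediation_point(y, g, w, m, Cm)
  if (is.null(point)) stop("rank-deficient design on the full data")

  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("acme", "ade", "total", "prop")))
  draws <- 0L
  attempts <- 0L
  while (draws < n_boot) {
    attempts <- attempts + 1L
    if (attempts > 10L * n_boot)
      stop("too many rank-deficient bootstrap draws (", attempts, " attempts)")
    idx <- sample.int(n, n, replace = TRUE)
    est <- mediation_point(y[idx], g[idx], w[idx], m[idx],
                           Cm[idx, , drop = FALSE])
    if (is.null(est)) next
    draws <- draws + 1L
    boot[draws, ] <- est
  }

  if (compute_ci) {
    jack <- matrix(NA_real_, n, 4)
    for (i in seq_len(n)) {
      est <- mediation_point(y[-i], g[-i], w[-i], m[-i], Cm[-i, , drop = FALSE])
      if (!is.null(est)) jack[i, ] <- est
    }
    ci <- lapply(1:4, function(j)
      bca_interval(boot[, j], point[j], jack[, j], level = level))
  } else {
    ci <- rep(list(c(NA_real_, NA_real_)), 4)
  }
  prop_point <- point["prop"]
  if (prop_truncate && !is.na(prop_point))
    prop_point <- min(max(prop_point, 0), 1)
  structure(list(
    acme = unname(point["acme"]), ade = unname(point["ade"]),
    total = unname(point["total"]), prop_mediated = unname(prop_point),
    prop_defined = !is.na(point["prop"]),
    ci_acme = ci[[1]], ci_ade = ci[[2]], ci_total = ci[[3]], ci_prop = ci[[4]],
    p_acme = boot_pvalue(boot[, "acme"], n_boot),
    p_ade = boot_pvalue(boot[, "ade"], n_boot),
    p_total = boot_pvalue(boot[, "total"], n_boot),
    n_boot = n_boot, n = n, seed = seed, boot = boot),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n=%d, n_boot=%d\n", x$n, x$n_boot))
  cat(sprintf("  ACME  %.4g [%.4g, %.4g]  p=%.3g\n", x$acme,
              x$ci_acme[1], x$ci_acme[2], x$p_acme))
  cat(sprintf("  ADE   %.4g [%.4g, %.4g]  p=%.3g\n", x$ade,
              x$ci_ade[1], x$ci_ade[2], x$p_ade))
  cat(sprintf("  total %.4g [%.4g, %.4g]  p=%.3g\n", x$total,
              x$ci_total[1], x$ci_total[2], x$p_total))
  cat(sprintf("  prop mediated %.4g\n", x$prop_mediated))
  invisible(x)
}

#' Inflation of genotype-by-cell interaction p-values by direction group
#'
#' For each trait-iQTL record, refits the interaction model with a cell-type
#' proportion as the interaction variable, collects the interaction p-values,
#' and computes the genomic inflation lambda separately for records with a
#' positive/negative direction call and for the uncertain group. Strong
#' inflation in the directed group and none in the uncertain group is the
#' signature of trait interactions transmitted through cell composition.
#'
#' @param records iQTL records with a `direction` column (plus
#'   `phenotype_id`, `variant_id`).
#' @param bundle the [dataset_bundle()].
#' @param cell_name name of the cell-proportion interaction variable in
#'   `bundle$interactions`.
#' @param min_pairs groups smaller than this are flagged low-confidence
#'   (default 10).
#' @return data.frame with one row per group: `group`, `lambda`, `n_pairs`,
#'   `low_confidence`.
#' @export
screen_gxm_inflation <- function(records, bundle, cell_name, min_pairs = 10) {
  stopifnot(inherits(bundle, "dataset_bundle"),
            "direction" %in% names(records))
  records <- as.data.frame(records)
  e <- center_vector(as.numeric(bundle$interactions[[cell_name]]))
  pvals <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- fit_interaction_model(
      bundle$phenotypes$values[, records$phenotype_id[i]],
      bundle$genotypes$dosages[, records$variant_id[i]],
      e, bundle$covariates)
    pvals[i] <- rec$p_gxe
  }
  grp <- ifelse(records$direction %in% c("positive", "negative"),
                "directed", "uncertain")
  res <- lapply(c("directed", "uncertain"), function(gname) {
    pv <- pvals[grp == gname & !is.na(pvals)]
    data.frame(group = gname,
               lambda = if (length(pv)) inflation_lambda(pv) else NA_real_,
               n_pairs = length(pv),
               low_confidence = length(pv) < min_pairs)
  })
  do.call(rbind, res)
}
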