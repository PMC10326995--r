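# Independent brute-force OLS oracle: plain normal equations, no QR, kept
# deliberately separate from the package's fitting path.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  coef <- drop(XtXinv %*% t(X) %*% y)
  res <- y - drop(X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXinv))
  tt <- coef / se
  list(coef = coef, se = se, t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE), df = df)
}

# oracle for the interaction design: y ~ 1 + g + e + g*e + C
oracle_interaction <- function(y, g, e, C = NULL) {
  X <- cbind(1, g, e, g * e)
  if (!is.null(C)) X <- cbind(X, as.matrix(C))
  colnames(X) <- c("(Intercept)", "g", "e", "gxe",
                   if (!is.null(C)) paste0("c", seq_len(ncol(as.matrix(C)))))
  oracle_ols(X, y)
}

# small random regression instance
random_instance <- function(n = 50, n_cov = 2, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.3)
  e <- rnorm(n)
  e <- e - mean(e)
  C <- if (n_cov > 0) matrix(rnorm(n * n_cov), n) else NULL
  y <- 0.5 + 0.8 * g - 0.3 * e + 0.6 * g * e +
    (if (is.null(C)) 0 else drop(C %*% rep(0.2, n_cov))) + rnorm(n)
  list(y = y, g = g, e = e, C = C)
}

# quick aligned bundle built from raw pieces (single chromosome)
make_bundle <- function(dosages, pos, Y, anchors, interactions,
                        covariates = NULL, kind = "gene") {
  n <- nrow(dosages)
  ids <- sprintf("S%03d", seq_len(n))
  rownames(dosages) <- ids
  vm <- data.frame(variant_id = sprintf("v%03d", seq_len(ncol(dosages))),
                   chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "G")
  geno <- genotype_matrix(dosages, vm)
  rownames(Y) <- ids
  pm <- data.frame(phenotype_id = sprintf("ph%03d", seq_len(ncol(Y))),
                   chrom = "chr1", anchor = as.integer(anchors), kind = kind)
  phen <- phenotype_set(Y, pm)
  inter <- lapply(interactions, function(v) setNames(v, ids))
  if (!is.null(covariates)) rownames(covariates) <- ids
  dataset_bundle(geno, phen, interactions = inter, covariates = covariates,
                 sample_ids = ids)
}
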