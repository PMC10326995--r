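#' @keywords internal
"_PACKAGE"

#' Ordinary least squares with per-coefficient inference
#'
#' QR-based OLS used by every model-fitting routine in the package. Returns
#' coefficient estimates, standard errors, t statistics and two-sided p-values
#' from the t distribution on the residual degrees of freedom.
#'
#' @param X design matrix (including the intercept column if wanted).
#' @param y response vector, no missing values.
#' @return list with `coef`, `se`, `t`, `p` (named by `colnames(X)`),
#'   `df_resid`, `sigma2`, `rank`, `ok` (FALSE when the design is
#'   rank-deficient, in which case the inference fields are NA).
#' @keywords internal
ols_fit <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  nc <- ncol(X)
  nms <- colnames(X)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < nc) {
    na <- stats::setNames(rep(NA_real_, nc), nms)
    return(list(coef = na, se = na, t = na, p = na,
                df_resid = length(y) - fit$rank, sigma2 = NA_real_,
                rank = fit$rank, ok = FALSE))
  }
  df <- length(y) - nc
  if (df <= 0) stop("no residual degrees of freedom (n <= number of columns)")
  res <- fit$residuals
  sigma2 <- sum(res^2) / df
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  piv <- fit$qr$pivot
  v <- numeric(nc)
  v[piv] <- diag(XtXinv)
  se <- sqrt(sigma2 * v)
  cf <- fit$coefficients
  tt <- cf / se
  pp <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  list(coef = stats::setNames(cf, nms), se = stats::setNames(se, nms),
       t = stats::setNames(tt, nms), p = stats::setNames(pp, nms),
       df_resid = df, sigma2 = sigma2, rank = fit$rank, ok = TRUE)
}

# Drops covariate columns that are constant (zero variance) — an all-ones
# covariate would collide with the intercept. Returns a matrix, possibly with
# zero columns.
as_covariate_matrix <- function(C, n) {
  if (is.null(C)) return(matrix(numeric(0), nrow = n, ncol = 0))
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  stopifnot(nrow(C) == n)
  if (is.null(colnames(C)) && ncol(C) > 0)
    colnames(C) <- paste0("cov", seq_len(ncol(C)))
  C
}
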