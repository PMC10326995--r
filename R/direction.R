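#' Direction of effect for continuous interaction variables
#'
#' Three-category rule on estimates from the interaction model with centered
#' E (so the genotype main effect is the QTL effect at the mean of the
#' interaction variable): a nominally non-significant genotype main effect
#' (p_g > alpha) gives "uncertain"; otherwise the sign of the product
#' b_g * b_gxe gives "positive" (QTL effect grows with the interaction
#' variable) or "negative" (shrinks). A product of exactly zero, or missing
#' estimates, gives "uncertain".
#'
#' @param p_g,b_g,b_gxe vectors of genotype main-effect p-values and the two
#'   estimates (recycled to common length).
#' @param alpha nominal significance level (default 0.05).
#' @return character vector in {"positive", "negative", "uncertain"}.
#' @export
classify_direction_continuous <- function(p_g, b_g, b_gxe, alpha = 0.05) {
  n <- max(length(p_g), length(b_g), length(b_gxe))
  p_g <- rep_len(p_g, n); b_g <- rep_len(b_g, n); b_gxe <- rep_len(b_gxe, n)
  out <- rep("uncertain", n)
  prod <- b_g * b_gxe
  sig <- !is.na(p_g) & p_g <= alpha & !is.na(prod)
  out[sig & prod > 0] <- "positive"
  out[sig & prod < 0] <- "negative"
  out
}

#' Direction of effect for binary interaction variables
#'
#' Four-category rule from per-group genotype fits ([fit_group_model()] in
#' each level of the binary variable): both groups non-significant ->
#' "uncertain"; exactly one significant -> "no_effect_in_one"; both
#' significant with the same estimate sign -> "magnitude_difference"; both
#' significant with opposite signs -> "opposite_effect".
#'
#' @param fit_group0,fit_group1 one-row data.frames from [fit_group_model()]
#'   (need `p_g` and `b_g`).
#' @param alpha nominal significance level (default 0.05).
#' @return one of "no_effect_in_one", "magnitude_difference",
#'   "opposite_effect", "uncertain".
#' @export
classify_direction_binary <- function(fit_group0, fit_group1, alpha = 0.05) {
  p0 <- fit_group0$p_g; b0 <- fit_group0$b_g
  p1 <- fit_group1$p_g; b1 <- fit_group1$b_g
  if (any(is.na(c(p0, p1, b0, b1)))) return("uncertain")
  s0 <- p0 < alpha
  s1 <- p1 < alpha
  if (!s0 && !s1) return("uncertain")
  if (xor(s0, s1)) return("no_effect_in_one")
  if (sign(b0) == sign(b1)) return("magnitude_difference")
  "opposite_effect"
}

#' Annotate iQTL records with a direction column
#'
#' Continuous interaction variables use the three-category product rule on
#' the record's own estimates. Binary variables refit the genotype effect
#' separately in both groups (covariates retained) and apply the
#' four-category rule.
#'
#' @param records data.frame of iQTL records (needs `p_g`, `b_g`, `b_gxe`,
#'   and for binary mode `phenotype_id`, `variant_id`).
#' @param bundle the [dataset_bundle()] (required for binary mode).
#' @param e_name interaction variable name (required for binary mode).
#' @param e_type "continuous" or "binary".
#' @param alpha nominal level (default 0.05).
#' @return `records` with a `direction` column added.
#' @export
annotate_direction <- function(records, bundle = NULL, e_name = NULL,
                               e_type = c("continuous", "binary"),
                               alpha = 0.05) {
  e_type <- match.arg(e_type)
  records <- as.data.frame(records)
  if (e_type == "continuous") {
    records$direction <- classify_direction_continuous(
      records$p_g, records$b_g, records$b_gxe, alpha = alpha)
    return(records)
  }
  stopifnot(inherits(bundle, "dataset_bundle"), !is.null(e_name))
  e <- as.numeric(bundle$interactions[[e_name]])
  lv <- sort(unique(e))
  if (length(lv) != 2)
    stop("interaction variable '", e_name, "' is not binary")
  g1 <- e == max(lv)
  dirs <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    y <- bundle$phenotypes$values[, records$phenotype_id[i]]
    g <- bundle$genotypes$dosages[, records$variant_id[i]]
    f0 <- try(fit_group_model(y, g, bundle$covariates, !g1), silent = TRUE)
    f1 <- try(fit_group_model(y, g, bundle$covariates, g1), silent = TRUE)
    dirs[i] <- if (inherits(f0, "try-error") || inherits(f1, "try-error"))
      "uncertain" else classify_direction_binary(f0, f1, alpha = alpha)
  }
  records$direction <- dirs
  records
}
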