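# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes -- biallelic genotypes in HWE with optional AR(1) LD,
# correlated cell-type proportions on the simplex with a configurable
# age-neutrophil correlation, and molecular phenotypes drawn from the
# interaction model Y ~ G + E + GxE + C -- so every pipeline stage is
# testable without access-restricted cohort data.

#' Default blood cell-type panel for the proportion simulator
#'
#' Mean proportions sum to 1; the latent correlation matrix anti-correlates
#' the neutrophil score with the lymphoid types, mimicking the
#' granulocyte-lymphocyte trade-off of whole-blood deconvolution estimates.
#'
#' @param latent_sd SD of the latent Gaussian scores (controls proportion
#'   dispersion; 0.3 gives coefficients of variation near 0.2-0.3).
#' @return list with `names`, `means`, `latent_cor`, `latent_sd`.
#' @export
default_cell_types <- function(latent_sd = 0.3) {
  nm <- c("neutrophil", "t_cd4", "t_cd8", "b_cell", "nk", "monocyte")
  means <- c(0.55, 0.15, 0.08, 0.05, 0.07, 0.10)
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  R["neutrophil", c("t_cd4", "t_cd8", "b_cell", "nk")] <- -0.3
  R[c("t_cd4", "t_cd8", "b_cell", "nk"), "neutrophil"] <- -0.3
  list(names = nm, means = means, latent_cor = R, latent_sd = latent_sd)
}

#' Simulation configuration
#'
#' Effect sizes `b_g`, `b_e`, `b_gxe` apply to the standardized (mean 0,
#' SD 1) interaction variable, so they are directly comparable across
#' scenarios and to the coefficients a scan run on the stored interaction
#' variable recovers.
#'
#' @param n_samples cohort size (default 800, desk-scale).
#' @param n_phenotypes phenotypes (default 200).
#' @param variants_per_phenotype cis variants per phenotype block (default 50).
#' @param maf_range uniform range for target allele frequencies.
#' @param ld_rho AR(1) latent haplotype correlation between adjacent variants
#'   (0 = linkage equilibrium).
#' @param variant_spacing_bp,block_spacing_bp genomic layout; blocks are far
#'   enough apart that cis windows never overlap.
#' @param cell_types panel from [default_cell_types()].
#' @param age_range uniform age range in years (default 45-85, the enrollment
#'   window of a mid-to-late-life cohort).
#' @param age_cell_corr target latent correlation of age with the chosen cell
#'   type (default 0.14, the reported age-neutrophil correlation).
#' @param age_cell_type cell type carrying the age correlation.
#' @param med_age_corr mediator-age correlation used by the
#'   `gxtrait_mediated` scenario only (default 0.5: strong enough that the
#'   induced genotype-by-age signal is detectable at desk scale; see the
#'   methods vignette).
#' @param b_g,b_e,b_gxe effect sizes for causal phenotypes.
#' @param prop_causal fraction of phenotypes carrying the scenario's effect
#'   (the rest are interaction-null; default 1 except where noted).
#' @param scenario one of "null", "gxcell", "gxtrait_direct",
#'   "gxtrait_mediated", "binary_e".
#' @param noise_sd residual SD of the phenotype model.
#' @param n_covariates number of standard-normal nuisance covariates.
#' @param covariate_effect SD of per-phenotype covariate effects.
#' @param binary_prob Bernoulli rate of the smoking-like binary variable.
#' @param kind phenotype kind ("gene" or "cpg").
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 800, n_phenotypes = 200,
                       variants_per_phenotype = 50,
                       maf_range = c(0.05, 0.5), ld_rho = 0,
                       variant_spacing_bp = 10000, block_spacing_bp = 3e6,
                       cell_types = default_cell_types(),
                       age_range = c(45, 85), age_cell_corr = 0.14,
                       age_cell_type = "neutrophil", med_age_corr = 0.5,
                       b_g = 1, b_e = 0.5, b_gxe = 0.5, prop_causal = 1,
                       scenario = c("null", "gxcell", "gxtrait_direct",
                                    "gxtrait_mediated", "binary_e"),
                       noise_sd = 1, n_covariates = 2, covariate_effect = 0.2,
                       binary_prob = 0.3, kind = "gene", seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_samples >= 10, n_phenotypes >= 1, variants_per_phenotype >= 1,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            abs(age_cell_corr) < 1, abs(med_age_corr) < 1,
            all(cell_types$means > 0),
            abs(sum(cell_types$means) - 1) < 1e-8,
            prop_causal >= 0, prop_causal <= 1, noise_sd >= 0)
  ev <- eigen(cell_types$latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("cell-type latent correlation matrix is not positive definite")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate biallelic genotypes in HWE with optional AR(1) LD
#'
#' Each of the two haplotypes per sample is a latent Gaussian AR(1) chain
#' across variants, thresholded at the normal quantile of the variant's
#' target allele frequency; the dosage is the haplotype sum, so single-site
#' genotypes are in Hardy-Weinberg proportions and adjacent-variant allele
#' correlation decays like `ld_rho^distance`.
#'
#' @param n_samples samples; @param n_variants variants.
#' @param maf_range uniform range for target allele frequencies.
#' @param ld_rho AR(1) parameter in \[0, 1).
#' @param chrom chromosome label; @param positions 1-based positions (default
#'   evenly spaced by `spacing_bp`).
#' @param spacing_bp spacing when `positions` is NULL.
#' @param sample_ids,variant_ids optional identifiers.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf_range = c(0.05, 0.5),
                               ld_rho = 0, chrom = "chr1", positions = NULL,
                               spacing_bp = 10000, sample_ids = NULL,
                               variant_ids = NULL) {
  stopifnot(ld_rho >= 0, ld_rho < 1)
  if (is.null(positions)) positions <- seq_len(n_variants) * spacing_bp
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  if (is.null(variant_ids)) variant_ids <- sprintf("v%05d", seq_len(n_variants))
  af <- stats::runif(n_variants, maf_range[1], maf_range[2])
  thr <- stats::qnorm(af)
  hap <- function() {
    Z <- matrix(NA_real_, n_samples, n_variants)
    Z[, 1] <- stats::rnorm(n_samples)
    if (n_variants > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (j in 2:n_variants)
        Z[, j] <- ld_rho * Z[, j - 1] + s * stats::rnorm(n_samples)
    }
    sweep(Z, 2, thr, "<") * 1
  }
  dos <- hap() + hap()
  rownames(dos) <- sample_ids
  meta <- data.frame(variant_id = variant_ids, chrom = chrom,
                     pos = as.integer(positions), ref = "A", alt = "G",
                     af = colMeans(dos) / 2, stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

#' Simulate correlated cell-type proportions on the simplex
#'
#' Latent multivariate-Gaussian scores (with the configured correlation, and
#' age entering the chosen cell type's score linearly at the target
#' correlation) are mapped through a softmax transform, so rows sum to one
#' and negative cross-type correlations are attainable.
#'
#' @param n samples; @param cell_types panel from [default_cell_types()].
#' @param age age vector (length n); may be NULL when `age_cell_corr` = 0.
#' @param age_cell_corr target latent correlation of age with
#'   `age_cell_type`'s score.
#' @param age_cell_type which cell type carries it.
#' @return n-by-K proportion matrix with cell-type column names.
#' @export
simulate_cell_proportions <- function(n, cell_types = default_cell_types(),
                                      age = NULL, age_cell_corr = 0.14,
                                      age_cell_type = "neutrophil") {
  R <- cell_types$latent_cor
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent correlation matrix is not positive definite")
  K <- length(cell_types$names)
  X <- matrix(stats::rnorm(n * K), n, K) %*% chol(R)
  colnames(X) <- cell_types$names
  if (age_cell_corr != 0) {
    if (is.null(age)) stop("age vector required when age_cell_corr != 0")
    z_age <- as.numeric(scale(age))
    k <- match(age_cell_type, cell_types$names)
    if (is.na(k)) stop("unknown cell type '", age_cell_type, "'")
    # The softmax attenuates latent correlations on the proportion scale by
    # kappa = a_k / sqrt(a' R a) with a = p_k (delta_k - p) (delta method on
    # the softmax Jacobian), so inflate the latent loading to hit the target.
    a <- cell_types$means[k] * (as.numeric(seq_len(K) == k) - cell_types$means)
    kappa <- a[k] / sqrt(drop(t(a) %*% R %*% a))
    r_lat <- age_cell_corr / kappa
    if (abs(r_lat) >= 1)
      stop("age_cell_corr = ", age_cell_corr,
           " unattainable for this panel (latent loading would be ",
           round(r_lat, 3), ")")
    X[, k] <- r_lat * z_age + sqrt(1 - r_lat^2) * X[, k]
  }
  eta <- sweep(cell_types$latent_sd * X, 2, log(cell_types$means), "+")
  p <- exp(eta)
  p / rowSums(p)
}

# per-phenotype linear model on top of the shared pieces
build_phenotype <- function(g, e, Cfx, b_g, b_e, b_gxe, noise_sd) {
  b_g * g + b_e * e + b_gxe * g * e + Cfx + stats::rnorm(length(g), 0, noise_sd)
}

#' Simulate a full aligned cohort dataset plus ground truth
#'
#' Lays phenotypes out in disjoint genomic blocks of
#' `variants_per_phenotype` cis variants, draws genotypes, age, sex, a
#' smoking-like binary variable, cell-type proportions and nuisance
#' covariates, then generates each phenotype from the interaction model of
#' the configured scenario:
#' * `null`: genotype and E main effects only, no interaction.
#' * `gxcell`: interaction with the standardized target cell proportion.
#' * `gxtrait_direct`: interaction directly with standardized age.
#' * `gxtrait_mediated`: interaction with the cell proportion ONLY, the
#'   proportion being correlated with age (`med_age_corr`), so any apparent
#'   genotype-by-age signal is transmitted through the cell type.
#' * `binary_e`: interaction with the binary smoking-like variable.
#'
#' The interaction variable each scenario uses is stored standardized in
#' `interactions` (names: `cell`, `age_std`, `smoking`), alongside raw age
#' and the raw proportion columns.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (a [dataset_bundle()]) and `truth` (data.frame:
#'   per phenotype the causal variant, true effects, scenario, `e_name`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples
  P <- cf$n_phenotypes
  V <- cf$variants_per_phenotype
  sample_ids <- sprintf("S%04d", seq_len(n))

  # genomic layout: disjoint blocks, anchor at the block middle
  pos <- unlist(lapply(seq_len(P), function(j)
    (j - 1) * cf$block_spacing_bp + seq_len(V) * cf$variant_spacing_bp))
  geno <- simulate_genotypes(n, P * V, maf_range = cf$maf_range,
                             ld_rho = cf$ld_rho, chrom = "chr1",
                             positions = pos, sample_ids = sample_ids)

  age <- stats::runif(n, cf$age_range[1], cf$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  smoking <- stats::rbinom(n, 1, cf$binary_prob)
  acorr <- if (cf$scenario == "gxtrait_mediated") cf$med_age_corr else cf$age_cell_corr
  props <- simulate_cell_proportions(n, cf$cell_types, age = age,
                                     age_cell_corr = acorr,
                                     age_cell_type = cf$age_cell_type)
  covariates <- if (cf$n_covariates > 0) {
    m <- matrix(stats::rnorm(n * cf$n_covariates), n, cf$n_covariates,
                dimnames = list(sample_ids, paste0("PC", seq_len(cf$n_covariates))))
    m
  } else NULL

  cell_std <- as.numeric(scale(props[, cf$age_cell_type]))
  age_std <- as.numeric(scale(age))
  e_name <- switch(cf$scenario,
                   null = "cell", gxcell = "cell",
                   gxtrait_direct = "age_std",
                   gxtrait_mediated = "cell",
                   binary_e = "smoking")
  e <- switch(e_name, cell = cell_std, age_std = age_std, smoking = smoking)

  causal <- stats::rbinom(P, 1, cf$prop_causal) == 1
  if (cf$scenario == "null") causal[] <- FALSE
  Y <- matrix(NA_real_, n, P, dimnames = list(sample_ids, sprintf("pheno%04d", seq_len(P))))
  truth <- data.frame(phenotype_id = colnames(Y),
                      causal_variant = NA_character_,
                      b_g = cf$b_g, b_e = cf$b_e, b_gxe = 0,
                      scenario = cf$scenario, e_name = e_name,
                      stringsAsFactors = FALSE)
  for (j in seq_len(P)) {
    block <- ((j - 1) * V + 1):(j * V)
    cv <- sample(block, 1)
    truth$causal_variant[j] <- geno$meta$variant_id[cv]
    b_gxe_j <- if (causal[j]) cf$b_gxe else 0
    truth$b_gxe[j] <- b_gxe_j
    Cfx <- if (is.null(covariates)) 0 else
      as.numeric(covariates %*% stats::rnorm(ncol(covariates), 0, cf$covariate_effect))
    Y[, j] <- build_phenotype(geno$dosages[, cv], e, Cfx,
                              cf$b_g, cf$b_e, b_gxe_j, cf$noise_sd)
  }

  anchors <- as.integer((seq_len(P) - 1) * cf$block_spacing_bp +
                          (floor(V / 2) + 1L) * cf$variant_spacing_bp)
  phen <- phenotype_set(Y, data.frame(phenotype_id = colnames(Y), chrom = "chr1",
                                      anchor = anchors, kind = cf$kind,
                                      stringsAsFactors = FALSE))
  inter <- c(list(age = stats::setNames(age, sample_ids),
                  age_std = stats::setNames(age_std, sample_ids),
                  sex = stats::setNames(sex, sample_ids),
                  smoking = stats::setNames(as.numeric(smoking), sample_ids),
                  cell = stats::setNames(cell_std, sample_ids)),
             lapply(stats::setNames(seq_len(ncol(props)), colnames(props)),
                    function(k) stats::setNames(props[, k], sample_ids)))
  bundle <- dataset_bundle(geno, phen, interactions = inter,
                           covariates = covariates, sample_ids = sample_ids)
  list(bundle = bundle, truth = truth)
}

#' Simulate two exams ten years apart with shared genetic effects
#'
#' Exam 2 keeps the genotypes, causal variants and effect sizes of exam 1,
#' ages every sample by `age_shift` years, re-draws the cell proportions and
#' residual noise, so between-exam reproducibility statistics (pi1, nominal
#' replication) can be exercised against a known truth.
#'
#' @param config a [sim_config()].
#' @param age_shift years between exams (default 10).
#' @return list with `exam1`, `exam2` (each a list `bundle`) and shared
#'   `truth`.
#' @export
simulate_two_exams <- function(config, age_shift = 10) {
  stopifnot(inherits(config, "sim_config"))
  ex1 <- simulate_dataset(config)
  b1 <- ex1$bundle
  cf <- config
  n <- cf$n_samples
  sample_ids <- b1$sample_ids
  age2 <- b1$interactions$age + age_shift
  acorr <- if (cf$scenario == "gxtrait_mediated") cf$med_age_corr else cf$age_cell_corr
  props2 <- simulate_cell_proportions(n, cf$cell_types, age = age2,
                                      age_cell_corr = acorr,
                                      age_cell_type = cf$age_cell_type)
  cell_std2 <- as.numeric(scale(props2[, cf$age_cell_type]))
  age_std2 <- as.numeric(scale(age2))
  e2 <- switch(ex1$truth$e_name[1], cell = cell_std2, age_std = age_std2,
               smoking = as.numeric(b1$interactions$smoking))
  Y2 <- b1$phenotypes$values
  geno <- b1$genotypes
  for (j in seq_len(ncol(Y2))) {
    cv <- ex1$truth$causal_variant[j]
    Cfx <- if (is.null(b1$covariates)) 0 else
      as.numeric(b1$covariates %*% stats::rnorm(ncol(b1$covariates), 0, cf$covariate_effect))
    Y2[, j] <- build_phenotype(geno$dosages[, cv], e2, Cfx,
                               ex1$truth$b_g[j], ex1$truth$b_e[j],
                               ex1$truth$b_gxe[j], cf$noise_sd)
  }
  phen2 <- phenotype_set(Y2, b1$phenotypes$meta)
  inter2 <- b1$interactions
  inter2$age <- stats::setNames(age2, sample_ids)
  inter2$age_std <- stats::setNames(age_std2, sample_ids)
  inter2$cell <- stats::setNames(cell_std2, sample_ids)
  for (k in colnames(props2)) inter2[[k]] <- stats::setNames(props2[, k], sample_ids)
  bundle2 <- dataset_bundle(geno, phen2, interactions = inter2,
                            covariates = b1$covariates, sample_ids = sample_ids)
  list(exam1 = ex1["bundle"], exam2 = list(bundle = bundle2), truth = ex1$truth)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `phenotypes.bed`, `genotypes.tsv` (or `genotypes.vcf`),
#' `covariates.tsv`, `interactions.tsv` and `truth.tsv` under `out_dir`;
#' [read_dataset()] reconstructs the bundle.
#'
#' @param bundle a [dataset_bundle()]; @param truth truth table (or NULL).
#' @param out_dir output directory (created if needed).
#' @param genotype_format "dosage_tsv" or "vcf".
#' @export
write_dataset <- function(bundle, truth = NULL, out_dir,
                          genotype_format = c("dosage_tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotype_bed(bundle$phenotypes, file.path(out_dir, "phenotypes.bed"))
  if (genotype_format == "vcf")
    write_vcf(bundle$genotypes, file.path(out_dir, "genotypes.vcf"))
  else
    write_dosage_tsv(bundle$genotypes, file.path(out_dir, "genotypes.tsv"))
  if (!is.null(bundle$covariates)) {
    cv <- data.frame(sample_id = rownames(bundle$covariates),
                     as.data.frame(bundle$covariates), check.names = FALSE)
    data.table::fwrite(cv, file.path(out_dir, "covariates.tsv"), sep = "\t")
  }
  iv <- data.frame(sample_id = bundle$sample_ids,
                   as.data.frame(lapply(bundle$interactions, unname)),
                   check.names = FALSE)
  data.table::fwrite(iv, file.path(out_dir, "interactions.tsv"), sep = "\t")
  if (!is.null(truth))
    data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir directory holding the files.
#' @param kind phenotype kind for the BED reader.
#' @return a [dataset_bundle()].
#' @export
read_dataset <- function(dir, kind = "gene") {
  phen <- read_phenotype_bed(file.path(dir, "phenotypes.bed"), kind = kind)
  gpath <- if (file.exists(file.path(dir, "genotypes.vcf")))
    file.path(dir, "genotypes.vcf") else file.path(dir, "genotypes.tsv")
  geno <- read_genotypes(gpath)
  ids <- rownames(phen$values)
  cov <- if (file.exists(file.path(dir, "covariates.tsv")))
    read_covariates(file.path(dir, "covariates.tsv"), ids) else NULL
  inter <- read_covariates(file.path(dir, "interactions.tsv"), ids)
  dataset_bundle(geno, phen, interactions = as.data.frame(inter),
                 covariates = cov, sample_ids = ids)
}
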