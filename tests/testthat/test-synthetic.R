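test_that("genotype simulator hits target frequencies, HWE and LD regimes", {
  set.seed(131)
  g5 <- simulate_genotypes(4000, 20, maf_range = c(0.5, 0.5))
  expect_equal(mean(g5$meta$af), 0.5, tolerance = 0.02)
  # HWE at f = 0.5: genotype frequencies ~ (0.25, 0.5, 0.25)
  tab <- table(factor(g5$dosages[, 1], levels = 0:2)) / 4000
  expect_equal(unname(as.vector(tab)), c(0.25, 0.5, 0.25), tolerance = 0.04)

  adj_r2 <- function(gm) {
    d <- gm$dosages
    mean(vapply(seq_len(ncol(d) - 1),
                function(j) cor(d[, j], d[, j + 1])^2, numeric(1)))
  }
  set.seed(137)
  # matched allele frequencies: MAF mismatch otherwise caps attainable r2
  g_ld <- simulate_genotypes(600, 40, maf_range = c(0.3, 0.3), ld_rho = 0.99)
  expect_gt(adj_r2(g_ld), 0.8)
  g_le <- simulate_genotypes(600, 40, maf_range = c(0.2, 0.5), ld_rho = 0)
  expect_lt(adj_r2(g_le), 0.02)     # ~ 1/(n-1) scale for independent variants
  expect_true(all(g_le$dosages %in% 0:2))
})

test_that("cell proportions live on the simplex and hit correlation targets", {
  set.seed(139)
  age <- runif(1000, 45, 85)
  p <- simulate_cell_proportions(1000, age = age, age_cell_corr = 0.14)
  expect_equal(unname(rowSums(p)), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(p > 0))
  r <- cor(p[, "neutrophil"], age)
  expect_gt(r, 0.09); expect_lt(r, 0.19)

  p0 <- simulate_cell_proportions(1000, age = age, age_cell_corr = 0)
  expect_lt(abs(cor(p0[, "neutrophil"], age)), 0.07)

  # strong negative latent correlation -> strongly negative proportions
  ct <- list(names = c("a", "b", "c"), means = c(0.4, 0.4, 0.2),
             latent_cor = matrix(c(1, -0.9, 0, -0.9, 1, 0, 0, 0, 1), 3,
                                 dimnames = rep(list(c("a", "b", "c")), 2)),
             latent_sd = 0.3)
  pn <- simulate_cell_proportions(1000, ct, age = age, age_cell_corr = 0)
  expect_lt(cor(pn[, "a"], pn[, "b"]), -0.5)

  ct$latent_cor["a", "b"] <- ct$latent_cor["b", "a"] <- -1.5
  expect_error(simulate_cell_proportions(100, ct, age = age, age_cell_corr = 0),
               "positive definite")
})

test_that("datasets are deterministic under a seed and written losslessly", {
  cfg <- sim_config(n_samples = 50, n_phenotypes = 4, variants_per_phenotype = 6,
                    scenario = "gxcell", seed = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$bundle$phenotypes$values, s2$bundle$phenotypes$values)
  expect_identical(s1$truth, s2$truth)
  cfg3 <- sim_config(n_samples = 50, n_phenotypes = 4, variants_per_phenotype = 6,
                     scenario = "gxcell", seed = 6)
  expect_false(identical(simulate_dataset(cfg3)$bundle$phenotypes$values,
                         s1$bundle$phenotypes$values))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(s1$bundle, s1$truth, d1)
  write_dataset(s2$bundle, s2$truth, d2)
  for (f in list.files(d1))            # byte-identical under a fixed seed
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  back <- read_dataset(d1)
  expect_equal(back$phenotypes$values, s1$bundle$phenotypes$values,
               tolerance = 1e-12)
  expect_equal(back$genotypes$dosages, s1$bundle$genotypes$dosages)
  expect_equal(back$covariates, s1$bundle$covariates, tolerance = 1e-12)
  expect_equal(unname(back$interactions$cell),
               unname(s1$bundle$interactions$cell), tolerance = 1e-12)

  # VCF route round-trips too (integral dosages)
  d3 <- withr::local_tempdir()
  write_dataset(s1$bundle, s1$truth, d3, genotype_format = "vcf")
  backv <- read_dataset(d3)
  expect_equal(unname(backv$genotypes$dosages),
               unname(s1$bundle$genotypes$dosages))
})

test_that("mediated scenario: age signal flows only through the cell type", {
  cfg <- sim_config(n_samples = 4000, n_phenotypes = 1,
                    variants_per_phenotype = 5, scenario = "gxtrait_mediated",
                    b_gxe = 1, noise_sd = 0.5, n_covariates = 0, seed = 23)
  sim <- simulate_dataset(cfg)
  b <- sim$bundle
  g <- b$genotypes$dosages[, sim$truth$causal_variant[1]]
  y <- b$phenotypes$values[, 1]
  m <- b$interactions$cell
  w <- b$interactions$age_std
  # given g*m (and mains), y is conditionally independent of g*age
  f <- lm(y ~ g + m + w + I(g * m) + I(g * w))
  expect_equal(unname(coef(f)["I(g * w)"]), 0, tolerance = 0.05)
  expect_equal(unname(coef(f)["I(g * m)"]), 1, tolerance = 0.05)
  # but marginally the g*age interaction is visible at ~ b_gxe * cor(m, age)
  fm <- lm(y ~ g + w + I(g * w))
  expect_equal(unname(coef(fm)["I(g * w)"]), cfg$med_age_corr * cfg$b_gxe,
               tolerance = 0.1)
})

test_that("two-exam resimulation shares genetics but redraws the rest", {
  cfg <- sim_config(n_samples = 120, n_phenotypes = 5, variants_per_phenotype = 6,
                    scenario = "gxcell", seed = 29)
  tw <- simulate_two_exams(cfg)
  b1 <- tw$exam1$bundle; b2 <- tw$exam2$bundle
  expect_identical(b1$genotypes$dosages, b2$genotypes$dosages)
  expect_identical(b1$sample_ids, b2$sample_ids)
  expect_equal(unname(b2$interactions$age - b1$interactions$age), rep(10, 120))
  expect_false(identical(b1$phenotypes$values, b2$phenotypes$values))
  expect_false(identical(b1$interactions$cell, b2$interactions$cell))
})
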