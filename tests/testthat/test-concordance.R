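test_that("fixed-lambda pi0 estimator: exact and simulated cases", {
  expect_equal(storey_pi0(runif(50, 0, 0.5), 0.5)$pi1, 1)   # empty numerator
  set.seed(61)
  expect_equal(storey_pi0(runif(1000), 0.5)$pi0, 1, tolerance = 0.08)
  p <- c(runif(300, 0, 1e-3), runif(700))   # 30% true signals near 0
  expect_lt(abs(storey_pi0(p, 0.5)$pi1 - 0.3), 0.05)
  expect_error(storey_pi0(numeric(0)), "empty")
})

test_that("pi1 lambda-selection rule reads its boundaries strictly", {
  expect_false(pi1_reproducibility(runif(15))$defined)
  expect_false(pi1_reproducibility(runif(20))$defined)
  expect_equal(pi1_reproducibility(runif(21))$lambda_used, 0.5)
  expect_equal(pi1_reproducibility(runif(50))$lambda_used, 0.5)
  expect_equal(pi1_reproducibility(runif(100))$lambda_used, 0.5)
  expect_equal(pi1_reproducibility(runif(101))$lambda_used, 0.85)
  expect_equal(pi1_reproducibility(runif(500))$lambda_used, 0.85)
})

test_that("pi1 is consistent on mixtures with known pi0", {
  set.seed(67)
  # at lambda = 0.85 the point estimator's Monte Carlo SD on one draw is
  # sqrt(n0 * lam * (1 - lam)) / (n * (1 - lam)) ~ 0.028 at n = 5000;
  # assert within 3 SD here, and tighter (lambda = 0.5) in the fixed-lambda
  # estimator's own test above
  p <- c(runif(1500, 0, 1e-4), runif(3500))  # pi0_true = 0.7
  r <- pi1_reproducibility(p)
  expect_equal(r$lambda_used, 0.85)
  expect_lt(abs(r$pi1 - 0.3), 3 * 0.028)
  # the lambda = 0.5 regime at 20 < n <= 100
  set.seed(68)
  p2 <- c(runif(24, 0, 1e-4), runif(56))     # pi0_true = 0.7, n = 80
  expect_equal(pi1_reproducibility(p2)$lambda_used, 0.5)
})

test_that("nominal replication rate is a simple exceedance fraction", {
  expect_equal(nominal_replication_rate(rep(0.01, 5)), 1)
  expect_equal(nominal_replication_rate(rep(0.5, 5)), 0)
  expect_equal(nominal_replication_rate(c(0.01, 0.2)), 0.5)
  expect_error(nominal_replication_rate(numeric(0)), "empty")
})

test_that("inflation lambda: exact median cases and uniform null", {
  expect_equal(inflation_lambda(rep(0.5, 7)), 1)
  expect_equal(inflation_lambda(rep(0.05, 3)),
               qchisq(0.95, 1) / qchisq(0.5, 1), tolerance = 1e-12)
  set.seed(71)
  expect_equal(inflation_lambda(runif(10000)), 1, tolerance = 0.05)
  expect_error(inflation_lambda(c(0.5, 0)), "p > 0")
})

test_that("LD r2 is squared dosage correlation with flagged degenerates", {
  set.seed(73)
  g <- rbinom(200, 2, 0.4)
  G <- cbind(a = g, b = 2 - g, c = rbinom(200, 2, 0.4), d = rep(1, 200))
  expect_equal(ld_r2(G, rbind(c(1, 1), c(1, 2))), c(1, 1))
  expect_lt(ld_r2(G, rbind(c(1, 3))), 0.05)
  expect_warning(r <- ld_r2(G, rbind(c(1, 4))), "constant")
  expect_true(is.na(r))
})

test_that("normalized overlap counts tagged query variants over the min set", {
  set.seed(79)
  n <- 150
  base <- matrix(rbinom(n * 15, 2, 0.35), n, 15)
  # variants 11..14 duplicate variants 1..4 (perfect LD); 15 is independent
  base[, 11:14] <- base[, 1:4]
  pos <- c(1:10 * 1000L, 1:4 * 1000L + 100L, 5e7L)
  gm <- genotype_matrix(
    `rownames<-`(base, sprintf("S%03d", 1:n)),
    data.frame(variant_id = sprintf("v%02d", 1:15), chrom = "chr1", pos = pos))
  query <- sprintf("v%02d", 1:10)
  validation <- sprintf("v%02d", 11:15)
  r <- normalized_overlap(query, validation, gm)
  expect_equal(r$n_tagged, 4L)
  expect_equal(r$normalized_overlap, 4 / 5)    # min(|q|, |v|) = 5
  # identity and disjoint-unlinked extremes
  expect_equal(normalized_overlap(query, query, gm)$normalized_overlap, 1)
  expect_equal(normalized_overlap("v05", "v15", gm)$normalized_overlap, 0)
  expect_error(normalized_overlap(character(0), query, gm), "empty")
  # reverse direction uses the same denominator but its own tagging relation
  rv <- normalized_overlap(validation, query, gm)
  expect_equal(rv$n_tagged, 4L)
})

test_that("odds ratio applies the all-cells +0.5 correction only on zeros", {
  expect_equal(haldane_anscombe_or(c(1, 1, 1, 1))$odds_ratio, 1)
  r <- haldane_anscombe_or(c(5, 0, 2, 3))
  expect_true(r$corrected)
  expect_equal(r$odds_ratio, 15.4)
  r2 <- haldane_anscombe_or(c(10, 5, 5, 10))
  expect_false(r2$corrected)
  expect_equal(r2$odds_ratio, 4)
  expect_equal(r2$p_value,
               fisher.test(matrix(c(10, 5, 5, 10), 2, byrow = TRUE))$p.value)
})

test_that("odds ratio is equivariant under table symmetries", {
  set.seed(83)
  for (rep in 1:10) {
    tb <- matrix(rpois(4, 6), 2)
    base <- haldane_anscombe_or(tb)$odds_ratio
    expect_equal(haldane_anscombe_or(tb[2:1, 2:1])$odds_ratio, base)
    expect_equal(haldane_anscombe_or(tb[2:1, ])$odds_ratio, 1 / base)
    expect_equal(haldane_anscombe_or(tb[, 2:1])$odds_ratio, 1 / base)
  }
})

test_that("allelic concordance and median absolute effect behave", {
  b <- c(0.5, -1, 2, -0.1)
  expect_equal(allelic_concordance(b, b), 1)
  expect_equal(allelic_concordance(b, -b), 0)
  expect_equal(allelic_concordance(c(1, -1, 0), c(1, 1, 5)), 0.5)  # zero dropped
  set.seed(89)
  expect_equal(allelic_concordance(rnorm(4000), rnorm(4000)), 0.5,
               tolerance = 0.03)
  expect_equal(median_abs_effect(c(1, 2, 3)), 2)
  expect_equal(median_abs_effect(c(-1, -2, -3)), 2)
  expect_equal(median_abs_effect(rnorm(4001)), 0, tolerance = 0.05)
})
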