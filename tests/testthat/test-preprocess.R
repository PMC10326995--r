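test_that("inverse normal transform hits closed-form quantiles and keeps ranks", {
  # n = 3, offset 0.5, no noise: Hazen positions (r - 0.5)/n = (1/6, 1/2, 5/6)
  out <- inverse_normal_transform(c(1, 2, 3), tie_noise_sd = 0)
  expect_equal(out, qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(out[2], 0)
  expect_equal(out[1], -out[3])
  # offset 0 gives Weibull positions r/(n + 1) = (0.25, 0.5, 0.75)
  out0 <- inverse_normal_transform(c(1, 2, 3), tie_noise_sd = 0, rank_offset = 0)
  expect_equal(out0, qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-12)

  # monotone on sorted distinct input, missing preserved
  x <- c(0.1, NA, 5, 20, 21, NA, 100)
  out <- inverse_normal_transform(x, tie_noise_sd = 0)
  expect_true(all(diff(na.omit(out)) > 0))
  expect_identical(is.na(out), is.na(x))

  # ties + noise: same multiset under different seeds, permuted within ties
  x <- c(1, 1, 1, 2, 2, 3)
  a <- inverse_normal_transform(x, seed = 1)
  b <- inverse_normal_transform(x, seed = 2)
  expect_equal(sort(a), sort(b), tolerance = 1e-12)
  expect_true(all(a[x == 3] > a[x == 2]), all(a[x == 2] > a[x == 1]))

  expect_error(inverse_normal_transform(rep(5, 10), tie_noise_sd = 0),
               "identical")
  expect_error(inverse_normal_transform(c(1, 2)), ">= 3")
})

test_that("inverse normal transform output looks standard normal as n grows", {
  set.seed(11)
  x <- rexp(5000)                      # heavily skewed input
  z <- inverse_normal_transform(x, tie_noise_sd = 0)
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(unname(quantile(z, probs)), qnorm(probs), tolerance = 0.02)
  expect_equal(mean(z), 0, tolerance = 1e-3)
  expect_equal(sd(z), 1, tolerance = 0.01)
})

test_that("outlier mask follows the |x - mean| > k * SD rule", {
  # feasible derived case: 99 zeros and one 50; mean 0.5, sd ~ 5.0;
  # |50 - 0.5| = 49.5 > 3 * 5.0 -> excluded, zeros kept
  x <- c(rep(0, 99), 50)
  keep <- exclude_outliers(x, k = 3)
  expect_false(keep[100])
  expect_true(all(keep[1:99]))
  # arithmetic agreement with a direct computation
  expect_identical(keep, abs(x - mean(x)) <= 3 * sd(x))

  expect_true(all(exclude_outliers(rep(2, 10))))        # constant: SD 0
  expect_true(all(exclude_outliers(c(x, NA), k = Inf), na.rm = TRUE))
  expect_true(is.na(exclude_outliers(c(0, 1, NA, 100))[3]))
})

test_that("centering is exact and idempotent", {
  expect_equal(center_vector(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center_vector(rep(7, 5)), rep(0, 5))
  x <- rnorm(20) + 5
  cx <- center_vector(x)
  expect_equal(mean(cx), 0, tolerance = 1e-12)
  expect_equal(center_vector(cx), cx)
  x[3] <- NA
  expect_true(is.na(center_vector(x)[3]))
})

test_that("interaction MAF filter works per half of the E distribution", {
  n <- 20
  e <- seq_len(n)
  # dosage 1 everywhere: f = 0.5 in both halves -> kept at 0.05
  d1 <- matrix(1, n, 1)
  expect_true(interaction_maf_filter(d1, e, 0.05)$keep)
  # minor alleles all in the upper half: lower-half MAF 0 -> excluded
  d2 <- matrix(0, n, 1)
  d2[e > 10, 1] <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_false(interaction_maf_filter(d2, e, 0.05)$keep)
  # constructed lower-half f = 0.04: sum(dosage)/2n_half = 0.8/20... use
  # dosage summing to 0.8 allele count: 10 samples, f = 0.8/20 = 0.04
  d3 <- matrix(1, n, 1)              # upper half fine (f = 0.5)
  d3[e <= 10, 1] <- c(rep(0, 9), 0.8)
  f <- interaction_maf_filter(d3, e, 0.05)
  expect_equal(unname(f$maf_lower), 0.04)
  expect_false(f$keep)
  expect_true(interaction_maf_filter(d3, e, 0.01)$keep)

  expect_error(interaction_maf_filter(matrix(1, 3, 1), 1:3), "fewer than 2")
})

test_that("interaction MAF filter depends on E only through ranks", {
  set.seed(3)
  for (rep in 1:5) {
    d <- matrix(rbinom(40 * 6, 2, runif(6, 0.05, 0.5)), 40, 6, byrow = TRUE)
    e <- rnorm(40)
    base <- interaction_maf_filter(d, e, 0.05)$keep
    expect_identical(interaction_maf_filter(d, exp(3 * e), 0.05)$keep, base)
    expect_identical(interaction_maf_filter(d, rank(e), 0.05)$keep, base)
  }
})

test_that("half split is deterministic with odd n and tied values", {
  lower <- half_split(c(3, 1, 2, 1, 5))
  # order: S2(1), S4(1), S3(2) in lower (median sample to lower half)
  expect_identical(lower, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(half_split(c(1, NA, 2)), "missing")
})

test_that("sentinel collapsing follows the greedy +/- window rule", {
  recs <- data.frame(phenotype_id = c("c1", "c2", "c3"), chrom = "chr1",
                     pos = c(100, 600, 3000), p_gxe = c(1e-8, 1e-5, 1e-6),
                     variant_id = c("v1", "v2", "v3"))
  out <- collapse_sentinels(recs, window_bp = 1000)
  expect_setequal(out$pos, c(100, 3000))

  # all > 1kb apart: everyone is a sentinel
  recs$pos <- c(100, 2000, 4000)
  expect_equal(nrow(collapse_sentinels(recs, 1000)), 3L)

  # equal p 500 bp apart: exactly one sentinel, tie broken by position
  ties <- data.frame(chrom = "chr1", pos = c(1500, 1000), p_gxe = 1e-4,
                     variant_id = c("vB", "vA"))
  out <- collapse_sentinels(ties, 1000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 1000)
})

test_that("sentinel set is order-independent, sparse and p-dominant", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    recs <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                       pos = sample(1:8000, n),
                       p_gxe = 10^-runif(n, 0, 8),
                       variant_id = sprintf("v%02d", 1:n))
    out <- collapse_sentinels(recs, 1000)
    perm <- collapse_sentinels(recs[sample(n), ], 1000)
    expect_equal(out[order(out$variant_id), ], perm[order(perm$variant_id), ],
                 ignore_attr = TRUE)
    # pairwise > 1kb apart within chromosome
    for (chr in unique(out$chrom)) {
      p <- sort(out$pos[out$chrom == chr])
      if (length(p) > 1) expect_true(all(diff(p) > 1000))
    }
    # every collapsed record is dominated by a sentinel within its window
    dropped <- recs[!recs$variant_id %in% out$variant_id, ]
    for (i in seq_len(nrow(dropped))) {
      near <- out[out$chrom == dropped$chrom[i] &
                    abs(out$pos - dropped$pos[i]) <= 1000, ]
      expect_true(any(near$p_gxe <= dropped$p_gxe[i]))
    }
  }
})
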