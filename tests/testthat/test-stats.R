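test_that("consistency ICC matches the ANOVA oracle on random tables", {
  for (s in 1:100) {
    m <- withr::with_seed(s, matrix(sample(1:5, 12, replace = TRUE), 6, 2))
    if (var(rowMeans(m)) < 1e-12) next
    expect_equal(icc_consistency(m)$icc, icc31_aov_oracle(m), tolerance = 1e-10)
  }
  # and for more raters
  m4 <- withr::with_seed(7, matrix(rnorm(40), 10, 4))
  expect_equal(icc_consistency(m4)$icc, icc31_aov_oracle(m4), tolerance = 1e-10)
})

test_that("consistency ICC ignores per-rater offsets and bands correctly", {
  base <- cbind(1:4, 2:5) # rater 2 = rater 1 + 1
  res <- icc_consistency(base)
  expect_equal(res$icc, 1)
  expect_identical(res$band, "excellent")

  ident <- cbind(c(1, 3, 2, 5), c(1, 3, 2, 5))
  expect_equal(icc_consistency(ident)$icc, 1)

  m <- withr::with_seed(3, matrix(rnorm(30), 15, 2))
  shifted <- sweep(m, 2, c(10, -4), "+")
  expect_equal(icc_consistency(shifted)$icc, icc_consistency(m)$icc,
               tolerance = 1e-12)

  # band edges: good means 0.755 <= ICC <= 0.9
  expect_identical(icc_band_probe(0.49), "poor")
  expect_identical(icc_band_probe(0.5), "moderate")
  expect_identical(icc_band_probe(0.754), "moderate")
  expect_identical(icc_band_probe(0.755), "good")
  expect_identical(icc_band_probe(0.9), "good")
  expect_identical(icc_band_probe(0.901), "excellent")
})

test_that("zero between-item variance flags the ICC as undefined", {
  flat <- matrix(3, 8, 2)
  res <- icc_consistency(flat)
  expect_true(res$undefined)
  expect_true(is.na(res$icc))
  tab <- generate_rater_table(10, 2, latent = 3, disagreement_sd = 0, seed = 1)
  expect_true(icc_consistency(tab)$undefined)
})

test_that("Cohen's kappa matches hand-computed and degenerate cases", {
  # confusion counts (20, 5; 5, 20): p_o = 0.8, p_e = 0.5, kappa = 0.6
  r1 <- c(rep(1, 25), rep(2, 25))
  r2 <- c(rep(1, 20), rep(2, 5), rep(1, 5), rep(2, 20))
  k <- cohens_kappa(r1, r2)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$p_observed, 0.8)
  expect_equal(k$p_expected, 0.5)

  expect_equal(cohens_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))$kappa, 1)
  expect_true(cohens_kappa(rep(2, 6), rep(2, 6))$undefined)

  # invariant under relabeling both raters by the same permutation
  perm <- c(3, 1, 2, 5, 4)
  a <- withr::with_seed(11, sample(1:5, 200, replace = TRUE))
  b <- withr::with_seed(12, sample(1:5, 200, replace = TRUE))
  expect_equal(cohens_kappa(a, b)$kappa,
               cohens_kappa(perm[a], perm[b])$kappa, tolerance = 1e-12)

  # independent ratings: kappa near 0 within 3 SE of the MC null
  n <- 1e4
  x <- withr::with_seed(13, sample(1:5, n, replace = TRUE))
  y <- withr::with_seed(14, sample(1:5, n, replace = TRUE))
  k0 <- cohens_kappa(x, y)$kappa
  expect_lt(abs(k0), 3 * sqrt(1 / (n * (1 - 0.2)))) # rough SE at p_e = 0.2
})

test_that("kappa agrees with the e1071 cross-check", {
  skip_if_not_installed("e1071")
  a <- withr::with_seed(15, sample(1:4, 60, replace = TRUE))
  b <- withr::with_seed(16, pmin(pmax(a + sample(-1:1, 60, TRUE), 1), 4))
  tab <- base::table(factor(a, 1:4), factor(b, 1:4))
  expect_equal(cohens_kappa(a, b)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("Mann-Whitney handles identity, separation and exact enumeration", {
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8) # n*m/2
  expect_equal(same$p_value, 1)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  hi <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(hi$U, 9) # n*m

  # exact branch equals brute-force enumeration over all C(10,5) splits
  a <- c(1, 3, 3, 7, 9)
  b <- c(2, 3, 5, 8, 8)
  got <- mann_whitney(a, b)
  pooled <- c(a, b)
  r <- rank(pooled)
  splits <- combn(10, 5)
  us <- colSums(matrix(r[splits], nrow = 5)) - 15
  mu <- 12.5
  u_obs <- sum(r[1:5]) - 15
  p_brute <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  expect_identical(got$method, "exact enumeration")
  expect_equal(got$U, u_obs)
  expect_equal(got$p_value, p_brute)
})

test_that("Mann-Whitney type-I error stays near nominal on a tied Likert null", {
  rejections <- withr::with_seed(99, {
    vapply(1:2000, function(i) {
      a <- sample(1:5, 20, replace = TRUE)
      b <- sample(1:5, 20, replace = TRUE)
      mann_whitney(a, b)$p_value < 0.05
    }, logical(1))
  })
  expect_lte(mean(rejections), 0.065)
})

test_that("Welch t and KS normality behave on knowns", {
  x <- c(1.2, 1.9, 3.1, 4.2, 5.0)
  expect_equal(welch_t(x, x)$t, 0)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")

  # standard-normal quantiles look normal to the KS screen
  q <- qnorm(seq(0.05, 0.95, length.out = 30))
  expect_gt(ks_normality(q)$p_value, 0.5)
  expect_error(ks_normality(rep(2, 5)), "constant")

  # KS D on a 4-point sample vs its fitted normal, hand-computed sup-distance
  y <- c(0, 1, 2, 9)
  mu <- mean(y); s <- sd(y)
  Fhat <- pnorm(sort(y), mu, s)
  d_hand <- max(pmax(abs(Fhat - (0:3) / 4), abs(Fhat - (1:4) / 4)))
  expect_equal(ks_normality(y)$D, d_hand, tolerance = 1e-12)
})

test_that("Welch t power matches the noncentral-t closed form", {
  n <- 40
  delta <- 1
  reps <- 1000
  hits <- withr::with_seed(123, {
    vapply(seq_len(reps), function(i) {
      welch_t(rnorm(n), rnorm(n, delta))$p_value < 0.05
    }, logical(1))
  })
  ncp <- delta / sqrt(2 / n)
  tc <- qt(0.975, 2 * n - 2)
  power <- 1 - pt(tc, 2 * n - 2, ncp) + pt(-tc, 2 * n - 2, ncp)
  se <- sqrt(power * (1 - power) / reps)
  expect_lt(abs(mean(hits) - power), 3 * se + 0.01)
})

test_that("descriptive summaries pick the right reporting convention", {
  d <- describe_sample(1:5)
  expect_equal(d$median, 3)
  expect_equal(c(d$q1, d$q3), c(2, 4))

  flat <- describe_sample(rep(7, 10))
  expect_equal(flat$sd, 0)
  expect_equal(flat$q3 - flat$q1, 0)
  expect_identical(flat$report_as, "median_iqr")

  norm <- describe_sample(withr::with_seed(4, rnorm(200)))
  expect_identical(norm$report_as, "mean_sd")
  skewed <- describe_sample(withr::with_seed(4, rexp(200))^3)
  expect_identical(skewed$report_as, "median_iqr")

  # quantiles agree with a direct sorting oracle for odd and even n
  for (n in c(9, 10)) {
    x <- withr::with_seed(n, rnorm(n))
    d2 <- describe_sample(x)
    expect_equal(d2$median, median(sort(x)))
    expect_equal(d2$q1, unname(quantile(x, 0.25)))
  }
})
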