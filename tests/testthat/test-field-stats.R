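test_that("variance components are exact on noiseless genotype effects", {
  d <- simulate_balanced_trait(16, 4, sigma2_gen = 2, sigma2_eps = 1e-18,
                               seed = 4)
  vc <- estimate_components(d, trait = "y", campaign = "c1")
  expect_equal(vc$h2, 1)
  expect_equal(vc$n_genotypes, 16)
  expect_equal(vc$n_blocks, 4)
})

test_that("the estimator agrees with aov mean squares", {
  d <- simulate_balanced_trait(10, 3, sigma2_gen = 1.3, sigma2_eps = 0.7,
                               seed = 8)
  vc <- estimate_components(d)
  fit <- stats::aov(value ~ block + genotype, data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  expect_equal(vc$sigma2_eps, ms[3], tolerance = 1e-10)
  expect_equal(vc$sigma2_gen, max(0, (ms[2] - ms[3]) / 3), tolerance = 1e-10)
})

test_that("pure-noise trials yield near-zero repeatability", {
  h2 <- vapply(1:200, function(i) {
    d <- simulate_balanced_trait(16, 4, sigma2_gen = 0, sigma2_eps = 1,
                                 seed = 1000 + i)
    estimate_components(d)$h2
  }, 0)
  expect_lt(stats::median(h2), 0.15)
})

test_that("h2 recovery matches the plug-in value for known components", {
  h2 <- vapply(1:500, function(i) {
    d <- simulate_balanced_trait(16, 4, sigma2_gen = 3, sigma2_eps = 1,
                                 seed = 3000 + i)
    estimate_components(d)$h2
  }, 0)
  expect_lt(abs(mean(h2) - 3 / (3 + 1 / 4)), 0.02)
})

test_that("parameter recovery holds across variance ratios", {
  # expected means of the clamped ANOVA h2 estimator, frozen from direct
  # chi-square sampling of the balanced mean squares (2e5 draws per ratio);
  # at low ratios the estimator mean sits below the plug-in value
  # sigma2_gen/(sigma2_gen + sigma2_eps/4) because of the clamp at zero
  # and the nonlinearity of the ratio
  oracle <- c("0.25" = 0.4430, "1" = 0.7693, "4" = 0.9322)
  for (ratio in c(0.25, 1, 4)) {
    h2 <- vapply(1:500, function(i) {
      d <- simulate_balanced_trait(16, 4, sigma2_gen = ratio, sigma2_eps = 1,
                                   seed = round(10000 * ratio) + i)
      estimate_components(d)$h2
    }, 0)
    expect_lt(abs(mean(h2) - oracle[[as.character(ratio)]]), 0.03)
  }
})

test_that("h2 stays in [0, 1] and is location-scale invariant", {
  set.seed(77)
  for (i in 1:50) {
    d <- simulate_balanced_trait(sample(3:16, 1), sample(2:6, 1),
                                 sigma2_gen = stats::runif(1, 0, 5),
                                 sigma2_eps = stats::runif(1, 0.01, 5),
                                 seed = 500 + i)
    vc <- estimate_components(d)
    expect_gte(vc$h2, 0)
    expect_lte(vc$h2, 1)
    shifted <- d; shifted$value <- 3.7 * d$value + 11
    expect_equal(estimate_components(shifted)$h2, vc$h2, tolerance = 1e-9)
  }
})

test_that("unbalanced layouts are rejected with guidance", {
  d <- simulate_balanced_trait(8, 3, 1, 1, seed = 2)
  expect_error(estimate_components(d[-1, ]), "unbalanced")
  expect_error(estimate_components(rbind(d, d[1, ])), "unbalanced")
})

test_that("repeatability rises with plot size when residuals shrink", {
  # residual variance inversely proportional to row count, by construction
  tabs <- lapply(1:4, function(rows) {
    d <- simulate_balanced_trait(16, 4, sigma2_gen = 1, sigma2_eps = 2 / rows,
                                 rows_per_plot = rows, seed = 60 + rows)
    d
  })
  tab <- do.call(rbind, tabs)
  tab$tt <- 371
  prof <- repeatability_profile(tab, "y")
  expect_equal(nrow(prof), 4)
  expect_true(all(diff(prof$h2[order(prof$rows)]) > -0.05))
  expect_warning(empty <- repeatability_profile(tab, "nope"), "absent")
  expect_equal(nrow(empty), 0)
})

test_that("correlation reproduces exact cases and significance codes", {
  x <- c(1, 2, 3, 4, 5, 6)
  perfect <- correlate(x, 2 * x + 1)
  expect_equal(perfect$r, 1.0)
  expect_equal(perfect$code, "***")
  zero <- correlate(c(0, 1, 2), c(0, 1, 0))
  expect_equal(zero$r, 0)
  expect_equal(zero$code, "ns")
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate(c(1, 2), c(1, 2)), "3 complete pairs")
  # brute-force check of r on random samples
  set.seed(14)
  for (i in 1:20) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    r_brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlate(a, b)$r, r_brute, tolerance = 1e-12)
  }
})

test_that("null correlations are flagged ns at about the nominal rate", {
  codes <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    correlate(stats::rnorm(50), stats::rnorm(50))$code
  }, "")
  expect_gte(mean(codes == "ns"), 0.90)
})

test_that("correlation matrices carry codes in formatted cells", {
  set.seed(5)
  df <- data.frame(a = stats::rnorm(30))
  df$b <- 2 * df$a + stats::rnorm(30, 0, 0.1)
  df$c <- stats::rnorm(30)
  cm <- correlation_matrix(df)
  expect_equal(cm$r["a", "b"], stats::cor(df$a, df$b), tolerance = 1e-12)
  expect_match(cm$formatted["a", "b"], "\\*\\*\\*$")
  expect_match(cm$formatted["a", "c"], "ns$")
})

test_that("HSD declares no differences under the null at ~5% familywise", {
  any_diff <- vapply(1:200, function(i) {
    d <- simulate_balanced_trait(16, 4, sigma2_gen = 0, sigma2_eps = 1,
                                 seed = 4000 + i)
    res <- hsd_compare(d)
    max(res$means$mean) - min(res$means$mean) > res$hsd
  }, TRUE)
  expect_lte(mean(any_diff), 0.09)  # ~alpha plus binomial noise
})

test_that("HSD separates well-spaced genotype means", {
  d <- simulate_balanced_trait(2, 4, sigma2_gen = 0, sigma2_eps = 1, seed = 6)
  d$value <- d$value + ifelse(d$genotype == "g00", 0, 10)  # 10 sigma apart
  res <- hsd_compare(d)
  expect_gt(abs(diff(res$means$mean)), res$hsd)
  expect_false(any(grepl(res$means$group[1], res$means$group[2], fixed = TRUE)))
})

test_that("zero residual variance separates all distinct means", {
  d <- simulate_balanced_trait(5, 3, sigma2_gen = 1, sigma2_eps = 1e-30,
                               seed = 9)
  res <- hsd_compare(d)
  expect_equal(res$hsd, 0, tolerance = 1e-10)
  expect_equal(anyDuplicated(res$means$group), 0)
  expect_error(hsd_compare(d[d$block == "b1", ]), "insufficient")
})
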