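test_that("year permutations preserve each taxon's values and variance bit-exactly", {
  set.seed(31)
  m <- random_matrix(5, 12)
  denom <- sum(apply(m, 2, stats::sd))^2
  for (r in 1:200) {
    perm <- reefsync:::permute_years_within_taxa(m)
    for (j in seq_len(ncol(m))) {
      expect_identical(sort(perm[, j]), sort(m[, j]))
      expect_identical(stats::var(perm[, j]), stats::var(m[, j]))
    }
    expect_identical(sum(apply(perm, 2, stats::sd))^2, denom)
  }
})

test_that("a single-population null is degenerate at 1", {
  m <- matrix(c(3, 1, 4, 1, 5), ncol = 1)
  expect_identical(si_null_distribution(m, n_reps = 20, seed = 1),
                   rep(1, 20))
})

test_that("sampled null values lie in the exhaustively enumerated support", {
  m <- cbind(a = c(1, 4, 2), b = c(5, 3, 6))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  support <- c()
  for (p1 in perms) {
    for (p2 in perms) {  # all 36 joint rearrangements
      support <- c(support, synchrony_index(cbind(m[p1, 1], m[p2, 2])))
    }
  }
  nulls <- si_null_distribution(m, n_reps = 300, seed = 2)
  expect_true(all(vapply(nulls, function(x) {
    any(abs(support - x) < 1e-12)
  }, logical(1))))
})

test_that("null distributions are reproducible and order-independent", {
  set.seed(41)
  m <- random_matrix(5, 4)
  expect_identical(si_null_distribution(m, 100, seed = 7),
                   si_null_distribution(m, 100, seed = 7))
})

test_that("quantile-range classification follows the strict two-sided rule", {
  nulls <- (1:100) / 100
  qs <- c(classify_si(0.5, nulls)$null_quantile_low,
          classify_si(0.5, nulls)$null_quantile_high)
  expect_equal(qs, stats::quantile(nulls, c(0.025, 0.975), type = 7,
                                   names = FALSE),
               tolerance = 1e-12)
  lo <- classify_si(qs[1] - 1e-9, nulls)
  hi <- classify_si(qs[2] + 1e-9, nulls)
  mid <- classify_si(0.5, nulls)
  tie_lo <- classify_si(qs[1], nulls)  # equality with a bound: NS
  tie_hi <- classify_si(qs[2], nulls)
  expect_identical(lo$classification, "negative_covariation")
  expect_identical(hi$classification, "positive_covariation")
  expect_identical(mid$classification, "not_significant")
  expect_identical(tie_lo$classification, "not_significant")
  expect_identical(tie_hi$classification, "not_significant")
  expect_equal(lo$null_quantile_low, qs[1])
  expect_equal(hi$null_quantile_high, qs[2])
})

test_that("repeated-measures F matches the aov cross-check on a balanced design", {
  set.seed(51)
  x <- matrix(rnorm(15 * 5, mean = 30, sd = 5), nrow = 15,
              dimnames = list(sprintf("s%02d", 1:15), 2013:2017))
  res <- bootstrap_rm_anova(x, n_reps = 50, seed = 1)
  expect_identical(res$df_between, 4L)
  expect_identical(res$df_error, 56L)

  df <- data.frame(y = as.vector(x),
                   site = factor(rep(rownames(x), times = 5)),
                   year = factor(rep(colnames(x), each = 15)))
  fit <- summary(stats::aov(y ~ year + Error(site), data = df))
  f_aov <- fit[["Error: Within"]][[1]]["year", "F value"]
  expect_equal(res$f_observed, f_aov, tolerance = 1e-10)
})

test_that("all-constant data yield an undefined F and p = 1", {
  x <- matrix(5, nrow = 4, ncol = 3)
  res <- bootstrap_rm_anova(x, n_reps = 50, seed = 1)
  expect_true(is.na(res$f_observed))
  expect_identical(res$p_boot, 1)
})

test_that("permutation p-values detect a strong injected year effect", {
  set.seed(61)
  x <- matrix(rnorm(10 * 4, 20, 1), nrow = 10)
  x[, 4] <- x[, 4] + 15
  res <- bootstrap_rm_anova(x, n_reps = 200, seed = 2)
  expect_identical(res$p_boot, 1 / 201)
  # global shuffling variant also runs and rejects
  resg <- bootstrap_rm_anova(x, n_reps = 200, seed = 2, shuffle = "global")
  expect_lt(resg$p_boot, 0.05)
})

test_that("post hoc contrasts cover all year pairs with sane p-values", {
  set.seed(71)
  x <- matrix(rnorm(8 * 5, 20, 1), nrow = 8,
              dimnames = list(NULL, 2013:2017))
  ph <- posthoc_year_differences(x, n_reps = 200, seed = 3)
  expect_identical(nrow(ph), 10L)  # C(5,2)

  # identical columns: zero difference, p near 1
  x2 <- cbind(a = x[, 1], b = x[, 1], c = x[, 2])
  ph2 <- posthoc_year_differences(x2, n_reps = 200, seed = 4)
  row <- ph2[ph2$year_a == "a" & ph2$year_b == "b", ]
  expect_equal(row$difference, 0)
  expect_gt(row$p_boot, 0.9)

  # a 5-pooled-SD shift is detected at the resampling floor
  x3 <- cbind(a = rnorm(10, 0, 1), b = rnorm(10, 12, 1))
  ph3 <- posthoc_year_differences(x3, n_reps = 200, seed = 5)
  expect_identical(ph3$p_boot, 1 / 201)
})

test_that("two-tailed binomial probabilities match closed forms and binom.test", {
  expect_identical(two_tailed_binomial_p(0, 1), 1)
  expect_equal(two_tailed_binomial_p(15, 15), 2^-14, tolerance = 1e-12)
  expect_equal(two_tailed_binomial_p(12, 15), 1152 / 32768,
               tolerance = 1e-12)
  expect_equal(two_tailed_binomial_p(8, 15), 1)
  for (n in c(5, 9, 14, 20)) {
    for (k in 0:n) {
      expect_equal(two_tailed_binomial_p(k, n),
                   stats::binom.test(k, n, 0.5)$p.value,
                   tolerance = 1e-12,
                   info = sprintf("k=%d n=%d", k, n))
      expect_equal(two_tailed_binomial_p(k, n),
                   two_tailed_binomial_p(n - k, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("covariance-sign consistency counts sites and applies the binomial test", {
  mk <- function(signs) {
    data.frame(site = sprintf("s%02d", seq_along(signs)),
               taxon_i = "a", taxon_j = "b", sign = signs,
               stringsAsFactors = FALSE)
  }
  res <- covariance_sign_consistency(mk(rep("+", 15)))
  expect_identical(res$n_sites_present, 15L)
  expect_identical(res$n_positive, 15L)
  expect_equal(res$p_binomial, 2^-14, tolerance = 1e-12)
  expect_true(res$significant)

  res12 <- covariance_sign_consistency(mk(c(rep("+", 12), rep("-", 3))))
  expect_equal(res12$p_binomial, 1152 / 32768, tolerance = 1e-12)
  expect_true(res12$significant)

  res8 <- covariance_sign_consistency(mk(c(rep("+", 8), rep("-", 7))))
  expect_equal(res8$p_binomial, 1)
  expect_false(res8$significant)

  # zero-covariance sites count toward occurrence but to neither sign;
  # undefined sites are excluded from occurrence entirely
  mixed <- mk(c(rep("+", 7), "0", rep("-", 5), "undefined", "undefined"))
  resm <- covariance_sign_consistency(mixed)
  expect_identical(resm$n_sites_present, 13L)
  expect_identical(resm$n_positive, 7L)
  expect_identical(resm$n_negative, 5L)
  expect_equal(resm$p_binomial, two_tailed_binomial_p(7, 13))

  expect_warning(
    empty <- covariance_sign_consistency(mk(rep("undefined", 3))),
    "omitted"
  )
  expect_null(empty)

  # optional Holm adjustment only toughens significance
  two <- rbind(mk(rep("+", 15)),
               within(mk(c(rep("+", 11), rep("-", 4))), taxon_j <- "c"))
  raw <- covariance_sign_consistency(two)
  holm <- covariance_sign_consistency(two, adjust = "holm")
  expect_true(all(holm$significant <= raw$significant))
})
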