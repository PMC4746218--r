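test_that("WMW p-values match exact enumeration and closed forms", {
  expect_equal(wmw_pvalue(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wmw_pvalue(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wmw_pvalue(numeric(0), c(1, 2)), "non-empty")

  # exact path (n <= 12, no ties) against the brute-force assignment oracle
  withr::with_seed(7, {
    for (rep in 1:10) {
      xs <- rnorm(4); xl <- rnorm(4) + rep / 5
      expect_equal(wmw_pvalue(xs, xl), wmw_enum_pvalue(xs, xl))
    }
  })
})

test_that("WMW approximation matches wilcox.test with tie/continuity corrections", {
  withr::with_seed(11, {
    for (rep in 1:8) {
      xs <- rpois(9, 5) + rnorm(9, sd = 0.01 * (rep %% 2)) # some reps tied
      xl <- rpois(12, 6) + rnorm(12, sd = 0.01 * (rep %% 2))
      ref <- suppressWarnings(
        stats::wilcox.test(xs, xl, exact = FALSE, correct = TRUE))$p.value
      expect_equal(wmw_pvalue(xs, xl), ref, tolerance = 1e-12)
    }
  })
})

test_that("WMW p-values are invariant under monotone transforms and uniform under the null", {
  withr::with_seed(3, {
    xs <- rnorm(15); xl <- rnorm(20)
  })
  p <- wmw_pvalue(xs, xl)
  expect_equal(wmw_pvalue(exp(xs), exp(xl)), p)
  expect_equal(wmw_pvalue(atan(xs), atan(xl)), p)

  # null uniformity over many genes (KS distance < 0.02)
  withr::with_seed(5, {
    X <- matrix(rnorm(10000 * 100), 10000, 100)
  })
  ri <- tcut:::.wmw_rank_info(X)
  p <- tcut:::.wmw_p_rows(ri, rep(c(TRUE, FALSE), each = 50))
  expect_true(all(p >= 0 & p <= 1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.02)
})

test_that("ordinary t, fold change and SAM match hand values and limits", {
  expect_equal(ordinary_t(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3))
  expect_equal(round(ordinary_t(c(1, 2, 3), c(4, 5, 6)), 3), -3.674)
  expect_equal(ordinary_t(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ordinary_t(c(2, 2), c(2, 2)), 0) # 0/0 by convention

  expect_equal(fold_change(c(1, 2, 3), c(4, 5, 6)), -3)
  expect_equal(fold_change(c(1, 2), c(1, 2)), 0)

  expect_equal(sam_stat(c(1, 2, 3), c(4, 5, 6), s0 = 0),
               ordinary_t(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(sam_stat(c(1, 2, 3), c(4, 5, 6), s0 = 1), -3 / (sqrt(2 / 3) + 1))
  expect_equal(round(sam_stat(c(1, 2, 3), c(4, 5, 6), s0 = 1), 3), -1.652)
  expect_lt(abs(sam_stat(c(1, 2, 3), c(4, 5, 6), s0 = 1e9)), 1e-8)

  # antisymmetry under group swap
  withr::with_seed(21, {
    for (rep in 1:5) {
      a <- rnorm(6); b <- rnorm(7) + 1
      expect_equal(ordinary_t(a, b), -ordinary_t(b, a))
      expect_equal(fold_change(a, b), -fold_change(b, a))
      expect_equal(sam_stat(a, b, 0.5), -sam_stat(b, a, 0.5))
    }
  })
})

test_that("SAM fudge factor selection agrees with a brute-force grid loop", {
  withr::with_seed(13, {
    d <- rnorm(500, sd = 2)
    se <- rgamma(500, shape = 2, scale = 0.5)
  })
  s0 <- estimate_sam_s0(d, se)
  # independent re-implementation of the percentile/CV recipe
  cand <- quantile(se, seq(0, 1, 0.05), names = FALSE)
  bins <- cut(se, breaks = quantile(se, seq(0, 1, 0.1)), include.lowest = TRUE)
  cv <- sapply(cand, function(s) {
    m <- tapply(d / (se + s), bins, function(v) median(abs(v - median(v))))
    sd(m) / mean(m)
  })
  expect_equal(s0, max(cand[which.min(cv)], 1e-12))

  # guards: zero ses never divide by zero; identical ses stay finite
  expect_gt(estimate_sam_s0(rnorm(50), rep(0, 50)), 0)
  s0z <- estimate_sam_s0(c(d, 0), c(se * 0, 0.5))
  expect_gt(s0z, 0)
  expect_true(is.finite(estimate_sam_s0(rnorm(50), rep(1, 50))))
})

test_that("EB prior estimation recovers simulated hyperparameters", {
  # no-spread degenerate case: complete shrinkage to the common variance
  pri <- estimate_eb_priors(rep(2.5, 100), residual_df = 30)
  expect_false(is.finite(pri$prior_df))
  expect_equal(pri$prior_var, 2.5, tolerance = 0.05)

  # parameter recovery: gene variances ~ scaled inverse chi-square(df0=4, s0=2)
  withr::with_seed(17, {
    sigma2 <- 4 * 2 / rchisq(10000, df = 4)
    s2 <- sigma2 * rchisq(10000, df = 10) / 10
  })
  pri <- estimate_eb_priors(s2, residual_df = 10)
  expect_equal(pri$prior_df, 4, tolerance = 0.2)
  expect_equal(pri$prior_var, 2, tolerance = 0.1)

  expect_warning(p1 <- estimate_eb_priors(3, residual_df = 4), "no moderation")
  expect_equal(p1$prior_df, 0)
})

test_that("moderated t has the right limits and matches limma", {
  a <- c(1.2, 0.8, 1.7, 0.4)
  b <- c(2.2, 2.9, 1.8, 2.6)
  none <- moderation_priors(0, 1)
  expect_equal(moderated_t(a, b, none)$modT, ordinary_t(a, b))
  full <- moderation_priors(Inf, 4)
  n1 <- 4; n2 <- 4
  expect_equal(moderated_t(a, b, full)$modT,
               (mean(a) - mean(b)) / sqrt(4 * (1 / n1 + 1 / n2)))
  mid <- moderation_priors(3, 4)
  m <- moderated_t(a, b, mid)
  expect_equal(m$modF, m$modT^2)
  # shrinkage keeps |modT| between the two limits
  lims <- sort(abs(c(moderated_t(a, b, none)$modT, moderated_t(a, b, full)$modT)))
  expect_gte(abs(m$modT), lims[1])
  expect_lte(abs(m$modT), lims[2])

  # cross-check the whole moderation path against limma::eBayes
  withr::with_seed(29, {
    X <- matrix(rnorm(200 * 10), 200, 10)
    X[1:40, 6:10] <- X[1:40, 6:10] + 2
  })
  design <- cbind(1, small = rep(c(1, 0), each = 5))
  fit <- limma::eBayes(limma::lmFit(X, design))
  s2 <- fit$sigma^2
  pri <- estimate_eb_priors(s2, residual_df = 8)
  mine <- vapply(seq_len(200), function(i)
    moderated_t(X[i, 1:5], X[i, 6:10], pri)$modT, numeric(1))
  expect_equal(mine, unname(fit$t[, "small"]), tolerance = 1e-10)
})

test_that("B statistic is symmetric, monotone in |modT|, and clamped", {
  pri <- moderation_priors(4, 1, de_proportion = 0.01, effect_var_scale = 3)
  ts <- seq(0, 30, by = 0.25)
  b_pos <- b_stat(ts, total_df = 12, pri)
  b_neg <- b_stat(-ts, total_df = 12, pri)
  expect_equal(b_pos, b_neg)
  expect_true(all(diff(b_pos) > 0))

  tiny <- moderation_priors(4, 1, de_proportion = 1e-320, effect_var_scale = 3)
  expect_equal(b_stat(0, 12, tiny, floor = -500), -500)
  expect_error(b_stat(1, 12, moderation_priors(4, 1)), "effect_var_scale")
})

test_that("compute_stat_matrix columns agree with the scalar operations", {
  st <- make_toy_study("cons", I = 40)
  sp <- split_by_threshold(st, 2.5)
  sm <- compute_stat_matrix(st, sp, fold = FALSE)
  expect_identical(colnames(sm$values), deds_stats())
  expect_false(anyNA(sm$values))

  xs_of <- function(i) st$expression[i, sp$small_mask]
  xl_of <- function(i) st$expression[i, !sp$small_mask]
  pri <- sm$calib$priors
  for (i in c(1, 7, 23, 40)) {
    expect_equal(sm$values[i, "t"], ordinary_t(xs_of(i), xl_of(i)))
    expect_equal(sm$values[i, "FC"], fold_change(xs_of(i), xl_of(i)))
    expect_equal(sm$values[i, "SAM"],
                 sam_stat(xs_of(i), xl_of(i), sm$calib$sam_s0))
    mt <- moderated_t(xs_of(i), xl_of(i), pri)
    expect_equal(sm$values[i, "modT"], mt$modT)
    expect_equal(sm$values[i, "modF"], mt$modF)
    expect_equal(sm$values[i, "B"],
                 b_stat(mt$modT, ncol(st$expression) - 2 + pri$prior_df, pri))
  }

  smf <- compute_stat_matrix(st, sp, fold = TRUE)
  expect_true(all(smf$values[, c("t", "SAM", "FC", "modT")] >= 0))
  expect_equal(smf$values[, "t"], abs(sm$values[, "t"]))

  expect_error(compute_stat_matrix(st, split_by_threshold(st, 0.5)), "invalid")
})

test_that("DE rows separate from background in simulated data", {
  sp <- simdat_spec("simdat1", de_fraction = 0.5, n_features = 400, seed = 9)
  st <- simulate_dataset(sp)
  gs <- split_by_threshold(st, 3.0)
  sm <- compute_stat_matrix(st, gs, stat_names = "t", fold = TRUE)
  de <- seq_len(200)
  expect_gt(median(sm$values[de, "t"]), 2 * median(sm$values[-de, "t"]))
})
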