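test_that("observed and overall extreme points follow their definitions", {
  v <- cbind(a = c(1, 5, 2), b = c(2, 0, 1))
  e <- observed_extreme(make_stat_matrix(v))
  expect_equal(unname(e$coords), c(5, 2))
  expect_identical(e$provenance, "observed")

  single <- observed_extreme(make_stat_matrix(v[2, , drop = FALSE]))
  expect_equal(unname(single$coords), c(5, 0))

  e1 <- extreme_point(c(1, 5), c("a", "b"), "observed")
  e2 <- extreme_point(c(3, 2), c("a", "b"), "permuted")
  ov <- overall_extreme(e1, e2)
  expect_equal(unname(ov$coords), c(3, 5))
  expect_equal(overall_extreme(e2, e1)$coords, ov$coords) # commutative
  dom <- extreme_point(c(9, 9), c("a", "b"), "observed")
  expect_equal(overall_extreme(dom, e2)$coords, dom$coords)
  e3 <- extreme_point(c(1, 2), c("a", "zz"), "permuted")
  expect_error(overall_extreme(e1, e3), "mismatched")
})

test_that("permuted extremes are reproducible, dominate the observed point, and match a nested-loop oracle", {
  st <- make_toy_study("perm", I = 20)
  sp <- split_by_threshold(st, 2.5)
  pc <- perm_config(5, seed = 99)

  ep1 <- permuted_extreme(st, sp, perm = pc)
  ep2 <- permuted_extreme(st, sp, perm = pc)
  expect_identical(ep1, ep2)
  expect_error(permuted_extreme(st, sp, perm = perm_config(0, 1)), "B = 0")

  # forcing the identity relabeling reproduces the observed extreme
  idm <- matrix(sp$small_mask, ncol = 1)
  e_id <- permuted_extreme(st, sp, perm = pc, masks = idm)
  e_obs <- observed_extreme(compute_stat_matrix(st, sp))
  expect_equal(e_id$coords, e_obs$coords, ignore_attr = TRUE)

  # nested-loop oracle: per mask, per gene, scalar statistics
  masks <- tcut:::.perm_masks(ncol(st$expression), sp$n_small, 5,
                              tcut:::.derive_seed(99, st$study_id, 2.5))
  sm <- compute_stat_matrix(st, sp) # supplies the observed calibration
  pri <- sm$calib$priors
  df_tot <- ncol(st$expression) - 2 + pri$prior_df
  oracle <- rep(-Inf, 6)
  for (b in seq_len(ncol(masks))) {
    for (i in seq_len(nrow(st$expression))) {
      xs <- st$expression[i, masks[, b]]
      xl <- st$expression[i, !masks[, b]]
      mt <- moderated_t(xs, xl, pri)
      row <- c(abs(ordinary_t(xs, xl)),
               abs(sam_stat(xs, xl, sm$calib$sam_s0)),
               abs(fold_change(xs, xl)),
               b_stat(mt$modT, df_tot, pri),
               abs(mt$modT), mt$modF)
      oracle <- pmax(oracle, row)
    }
  }
  ep <- permuted_extreme(st, sp, perm = pc)
  expect_equal(unname(ep$coords), oracle, tolerance = 1e-12)

  # E and E_p coordinate-wise dominate E_0
  ov <- overall_extreme(e_obs, ep)
  expect_true(all(ov$coords >= e_obs$coords))
  expect_true(all(ov$coords >= ep$coords))
})

test_that("the full relabeling space is enumerated when small", {
  m <- tcut:::.perm_masks(6, 3, B = 999, seed = 1)
  expect_equal(ncol(m), choose(6, 3))
  expect_equal(ncol(unique(m, MARGIN = 2)), choose(6, 3))
  expect_true(all(colSums(m) == 3))
})

test_that("DEDS distances match hand arithmetic and honor the zero-MAD guard", {
  # MAD of 1..5 is 1 (median |x - 3|)
  expect_equal(tcut:::.mad0(1:5), 1)

  # 2-gene, 2-statistic toy, distances by hand:
  # col1 = (1, 3): median 2, MAD 1; col2 = (4, 2): median 3, MAD 1
  # E = (3, 4); d1 = (1-3)^2/1 + 0 = 4; d2 = 0 + (2-4)^2/1 = 4
  v <- cbind(s1 = c(1, 3), s2 = c(4, 2))
  sm <- make_stat_matrix(v)
  e <- observed_extreme(sm)
  dd <- deds_distances(sm, e)
  expect_equal(dd$d, c(4, 4))
  expect_equal(unname(dd$mad_scales), c(1, 1))

  # a gene sitting exactly at the extreme point has distance 0
  v2 <- cbind(s1 = c(5, 1, 2), s2 = c(7, 3, 1))
  dd2 <- deds_distances(make_stat_matrix(v2), observed_extreme(make_stat_matrix(v2)))
  expect_equal(dd2$d[1], 0)
  expect_true(all(dd2$d >= 0))
  expect_true(all(dd2$d[-1] > 0))

  # zero MAD falls back to sd; fully constant column contributes 0
  v3 <- cbind(s1 = c(1, 1, 1, 9), s2 = c(2, 2, 2, 2))
  dd3 <- deds_distances(make_stat_matrix(v3), observed_extreme(make_stat_matrix(v3)))
  expect_equal(unname(dd3$mad_scales), c(sd(c(1, 1, 1, 9)), Inf))
  expect_equal(dd3$d, ((v3[, 1] - 9) / sd(v3[, 1]))^2)

  e_bad <- extreme_point(c(1, 2), c("x", "y"), "overall")
  expect_error(deds_distances(sm, e_bad), "mismatched")
})

test_that("column rescaling leaves MAD-normalized contributions unchanged", {
  withr::with_seed(43, v <- matrix(rexp(60), 20, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  base <- deds_distances(make_stat_matrix(v), observed_extreme(make_stat_matrix(v)))
  for (cc in c(0.1, 2, 50)) {
    v2 <- v; v2[, 2] <- v[, 2] * cc
    sc <- deds_distances(make_stat_matrix(v2), observed_extreme(make_stat_matrix(v2)))
    expect_equal(sc$d, base$d, tolerance = 1e-12)
    expect_equal(unname(sc$mad_scales[2]), unname(base$mad_scales[2]) * cc)
  }
})

test_that("mdeds_objective reduces to the single-study distance sum and ignores gene order", {
  col <- toy_collection()
  pc <- perm_config(10, seed = 5)

  one <- study_collection(col$studies["a"])
  st <- one$studies$a
  sp <- split_by_threshold(st, 2.5)
  sm <- compute_stat_matrix(st, sp)
  e <- overall_extreme(observed_extreme(sm), permuted_extreme(st, sp, perm = pc))
  expect_equal(mdeds_objective(one, 2.5, perm = pc),
               sum(deds_distances(sm, e)$d))

  # gene order: rows shuffled before matching give the same objective
  shuf <- lapply(col$studies, function(s) {
    idx <- sample(seq_along(s$feature_ids))
    expression_study(s$expression[idx, ], unname(s$sizes), s$study_id)
  })
  expect_equal(mdeds_objective(match_features(shuf), 2.5, perm = pc),
               mdeds_objective(col, 2.5, perm = pc))

  expect_error(mdeds_objective(col, 0.5, perm = pc), class = "tcut_invalid_split")
})
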