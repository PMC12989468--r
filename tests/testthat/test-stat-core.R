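test_that("friedman test matches the exact enumeration oracle on small blocked designs", {
  # moderate-evidence 4x3 design (includes a within-block tie)
  m <- matrix(c(5, 6, 7, 3, 4, 6, 2, 2.5, 4, 1, 3, 2), 4, 3, byrow = TRUE)
  res <- friedman_conover(m)
  expect_lt(abs(res$p - exact_friedman_p(m)), 0.02)

  # monotone increase in every block: the oracle p is the design minimum
  mono <- matrix(c(1, 2, 3, 4, 5, 6, 2, 3, 4, 0, 1, 2), 4, 3, byrow = TRUE)
  p_exact <- exact_friedman_p(mono)
  expect_equal(p_exact, 6 / 6^4) # fully concordant orderings only
  expect_lt(abs(friedman_conover(mono)$p - p_exact), 0.02)

  # all conditions identical within every block
  flat <- matrix(rep(c(2, 2, 2), 4), 4, 3, byrow = TRUE)
  res_flat <- friedman_conover(flat)
  expect_equal(res_flat$statistic, 0)
  expect_equal(res_flat$p, 1)

  # tie-free statistic agrees with the classical base-R implementation
  set.seed(11)
  m2 <- matrix(rnorm(30), 10, 3)
  expect_equal(friedman_conover(m2)$statistic,
               unname(stats::friedman.test(m2)$statistic), tolerance = 1e-12)

  expect_error(friedman_conover(rbind(c(1, NA, 2), c(2, 3, 1))),
               "incomplete")
})

test_that("conover post hoc separates conditions and emits compact letters", {
  set.seed(21)
  base <- matrix(rnorm(60, sd = 0.3), 20, 3)
  base[, 3] <- base[, 3] + 3 # one clearly shifted condition
  colnames(base) <- c("W0", "W4", "W8")
  res <- friedman_conover(base)
  expect_lte(res$p, 0.05)
  pw <- res$pairwise
  expect_true(all(pw$adjusted_p >= pw$p - 1e-12))
  w8_pairs <- pw$a == "W8" | pw$b == "W8"
  expect_true(all(pw$adjusted_p[w8_pairs] <= 0.05))
  expect_false(res$letters[["W8"]] %in%
                 c(res$letters[["W0"]], res$letters[["W4"]]))
  expect_true(grepl(res$letters[["W0"]], res$letters[["W4"]]) ||
                grepl(res$letters[["W4"]], res$letters[["W0"]]))
})

test_that("kruskal-wallis + dunn match a permutation oracle and rank logic", {
  v <- c(2.1, 3.3, 1.8, 4.0, 2.9, 3.5, 5.1, 4.2, 6.0, 3.9,
         2.5, 3.0, 4.5, 3.2, 2.2)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- kruskal_dunn(v, g)
  expect_lt(abs(res$p - mc_kruskal_p(v, g)), 0.02)

  # two identical groups: H = 0 region
  res0 <- kruskal_dunn(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(res0$statistic, 1e-9)
  expect_gt(res0$p, 0.99)

  # pairwise p ordering follows the group shifts
  set.seed(5)
  vals <- c(rnorm(8), rnorm(8) + 1.5, rnorm(8) + 5)
  grp <- rep(c("lo", "mid", "hi"), each = 8)
  pw <- kruskal_dunn(vals, grp)$pairwise
  p_of <- function(a, b) pw$p[(pw$a == a & pw$b == b) | (pw$a == b & pw$b == a)]
  expect_lt(p_of("lo", "hi"), p_of("lo", "mid"))
  expect_lt(p_of("lo", "hi"), p_of("mid", "hi"))

  expect_error(kruskal_dunn(1:5, rep("a", 5)), "2 groups")
})

test_that("wilcoxon with continuity correction tracks the exact rank-sum null", {
  x <- c(1.1, 2.3, 3.1, 4.2, 5.5)
  y <- c(2.0, 3.3, 4.1, 6.0, 7.2)
  expect_lt(abs(wilcoxon_cc(x, y)$p -
                  stats::wilcox.test(x, y, exact = TRUE)$p.value), 0.02)
  x2 <- c(1, 2, 3, 4, 10)
  y2 <- c(5, 6, 7, 8, 9)
  expect_lt(abs(wilcoxon_cc(x2, y2)$p -
                  stats::wilcox.test(x2, y2, exact = TRUE)$p.value), 0.02)

  # identical multisets
  expect_gt(wilcoxon_cc(c(1, 2, 3), c(3, 1, 2))$p, 0.95)

  # p decreases with location shift
  set.seed(8)
  a <- rnorm(12)
  ps <- vapply(c(0.5, 1.5, 3), function(d) wilcoxon_cc(a, a + d)$p, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(wilcoxon_cc(numeric(0), 1:3), "empty")
})

test_that("pearson, adjustment, KS and chi-square worked examples", {
  a <- c(0.3, 1.7, 2.2, 5.0)
  expect_equal(pearson_r(a, 2 * a + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(a, -a)$r, -1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  expect_error(pearson_r(1:5, rep(2, 5)), "variance")
  expect_error(pearson_r(1:4, 1:5), "length")

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  # monotonicity and order preservation
  set.seed(2)
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(holm_adjust(p) >= p))
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-12))
  expect_true(all(diff(holm_adjust(p)[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  expect_equal(ks_test2(1:10, 1:10)$statistic, 0)
  expect_equal(ks_test2(1:5, 101:105)$statistic, 1)
  expect_equal(chi2_test(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_true(chi2_test(matrix(c(3, 1, 2, 4), 2))$expected_warning)
})

test_that("rank-trajectory interaction permutation test is calibrated and powered", {
  # null: no group effect -> empirical p approximately uniform
  ps <- vapply(seq_len(120), function(i) {
    d <- make_longitudinal(10, slope_g2 = 0, seed = 100 + i)
    group_time_interaction_perm(d$value, d$group, d$time, d$participant,
                                n_perm = 99, seed = i)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # identical trajectories in both groups
  d0 <- make_longitudinal(8, slope_g2 = 0, sd = 0, seed = 3)
  d0$value <- rep(c(1, 2, 3), each = 16) # same time profile everywhere
  r0 <- group_time_interaction_perm(d0$value, d0$group, d0$time,
                                    d0$participant, n_perm = 99, seed = 1)
  expect_gt(r0$p, 0.9)

  # strongly divergent time slopes
  d1 <- make_longitudinal(30, slope_g2 = 2, sd = 1, seed = 4)
  r1 <- group_time_interaction_perm(d1$value, d1$group, d1$time,
                                    d1$participant, n_perm = 199, seed = 1)
  expect_lte(r1$p, 0.01)

  expect_error(group_time_interaction_perm(1:9, rep(c("a", "b", "c"), 3),
                                           rep(c("W0", "W4", "W8"), each = 3),
                                           rep(1:3, 3)),
               "2 groups")
})

test_that("type-I error of each test sits at the nominal level under its null", {
  n_rep <- 2000
  alpha <- 0.05
  set.seed(77)
  fri <- mean(vapply(seq_len(n_rep), function(i) {
    friedman_conover(matrix(rnorm(36), 12, 3))$p
  }, 0) <= alpha)
  kw <- mean(vapply(seq_len(n_rep), function(i) {
    kruskal_dunn(rnorm(30), rep(1:3, each = 10))$p
  }, 0) <= alpha)
  wx <- mean(vapply(seq_len(n_rep), function(i) {
    wilcoxon_cc(rnorm(10), rnorm(10))$p
  }, 0) <= alpha)
  pe <- mean(vapply(seq_len(n_rep), function(i) {
    pearson_r(rnorm(20), rnorm(20))$p
  }, 0) <= alpha)
  for (rate in c(fri, kw, wx, pe)) {
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  }
})
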