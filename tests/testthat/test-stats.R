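test_that("pseudo-F reduces to the classical one-way ANOVA F", {
  set.seed(19)
  d <- data.frame(y = rnorm(36), g = factor(rep(letters[1:3], 12)))
  pm <- perm_mancova(d, y ~ g, n_permutations = 49, seed = 1)
  f_classical <- anova(stats::lm(y ~ g, d))["g", "F value"]
  expect_equal(tidy(pm)$pseudo_F, f_classical, tolerance = 1e-9)
  expect_equal(tidy(pm)$df, 2L)
  expect_equal(pm$residual$df, 33L)
})

test_that("pseudo-F matches an independent distance-based implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  d <- data.frame(y1 = rnorm(30), y2 = rnorm(30),
                  g = factor(rep(1:3, each = 10)))
  pm <- perm_mancova(d, cbind(y1, y2) ~ g, n_permutations = 49, seed = 2)
  ad <- vegan::adonis2(cbind(d$y1, d$y2) ~ g, data = d,
                       method = "euclidean", permutations = 49)
  expect_equal(tidy(pm)$pseudo_F, ad$F[1], tolerance = 1e-8)
  expect_equal(tidy(pm)$sum_sq, ad$SumOfSqs[1], tolerance = 1e-8)
})

test_that("permutation p-values hit the attainable floor and reproduce", {
  d <- data.frame(y = c(rnorm(12, 0), rnorm(12, 50)),
                  g = factor(rep(1:2, each = 12)))
  pm <- perm_mancova(d, y ~ g, n_permutations = 999, seed = 3)
  expect_identical(tidy(pm)$p_perm, 1 / (999 + 1))
  pm2 <- perm_mancova(d, y ~ g, n_permutations = 999, seed = 3)
  expect_identical(tidy(pm2)$p_perm, tidy(pm)$p_perm)
  expect_true(all(tidy(pm)$p_perm >= 1 / 1000 & tidy(pm)$p_perm <= 1))
})

test_that("degenerate and aliased designs are handled explicitly", {
  d <- data.frame(y = rep(2.5, 16), g = factor(rep(1:2, each = 8)))
  expect_message(pm <- perm_mancova(d, y ~ g, n_permutations = 19),
                 "no variation")
  expect_true(is.na(tidy(pm)$pseudo_F))
  expect_identical(tidy(pm)$p_perm, 1)

  d2 <- data.frame(y = rnorm(10), g = factor(rep(1:2, each = 5)))
  d2$g2 <- d2$g  # perfectly aliased copy
  expect_error(perm_mancova(d2, y ~ g + g2, n_permutations = 9), "aliased")
})

test_that("covariate-plus-factors designs report every term", {
  set.seed(40)
  n <- 48
  d <- data.frame(y = rnorm(n), patient = rep(seq_len(8), each = 6),
                  machine = factor(rep(c("A", "B"), each = n / 2)),
                  thr = factor(rep(rep(1:3, each = 2), 8)))
  pm <- perm_mancova(d, y ~ patient + machine * thr, n_permutations = 99,
                     seed = 5)
  expect_equal(tidy(pm)$term, c("patient", "machine", "thr", "machine:thr"))
  expect_true(all(tidy(pm)$df == c(1, 1, 2, 2)))
  expect_true(all(tidy(pm)$p_perm > 0 & tidy(pm)$p_perm <= 1))
  expect_equal(glance(pm)$n_obs, n)
})

test_that("Friedman test matches base R and handles the degenerate case", {
  set.seed(6)
  d <- data.frame(y = rnorm(24), trt = factor(rep(1:4, 6)),
                  blk = factor(rep(1:6, each = 4)))
  got <- friedman_test(d, y, trt, blk)
  ref <- stats::friedman.test(d$y, d$trt, d$blk)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)

  dc <- data.frame(y = rep(1:3, each = 3), trt = factor(rep(1:3, 3)),
                   blk = factor(rep(1:3, each = 3)))
  dc$y <- 7  # no within-block variation
  flat <- friedman_test(dc, y, trt, blk)
  expect_identical(flat$statistic, 0)
  expect_identical(flat$p_value, 1)

  expect_error(friedman_test(d[-1, ], y, trt, blk), "incomplete")
})

test_that("fully concordant blocks reach the enumerated maximal statistic", {
  # oracle: exhaustive enumeration of all per-block rank assignments for
  # k = 3, n = 3
  fried_stat <- function(ranks) {
    n <- nrow(ranks); k <- ncol(ranks)
    12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
  }
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  all_orders <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                      c(3, 1, 2), c(3, 2, 1))
  max_stat <- max(apply(perms, 1, function(p)
    fried_stat(rbind(all_orders[p[1], ], all_orders[p[2], ],
                     all_orders[p[3], ]))))
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                  trt = factor(rep(1:3, 3)),
                  blk = factor(rep(1:3, each = 3)))
  got <- friedman_test(d, y, trt, blk)
  expect_equal(got$statistic, max_stat)
})

test_that("signed-rank p-values follow exhaustive sign enumeration", {
  # n = 5, all differences positive: oracle enumerates all 2^5 sign
  # patterns of the rank sum
  d <- c(0.3, 1.1, 0.7, 2.0, 0.5)
  got <- wilcoxon_signed_rank(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  vdist <- signs %*% rank(abs(d))
  p_oracle <- 2 * mean(vdist >= got$statistic)
  expect_identical(p_oracle, 2 / 32)
  expect_equal(got$p_value, 0.0625)
  expect_identical(got$method, "exact")
})

test_that("zero differences are dropped and symmetric data give p near 1", {
  expect_warning(res <- wilcoxon_signed_rank(rep(0, 4)), "zero")
  expect_identical(res$p_value, 1)
  expect_identical(res$n_zero_dropped, 4L)

  mixed <- wilcoxon_signed_rank(c(0, 0, 1.2, -0.8), c(0, 0, 0, 0))
  expect_identical(mixed$n_used, 2L)
  expect_identical(mixed$n_zero_dropped, 2L)

  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_gt(sym$p_value, 0.9)
})

test_that("exact and approximate signed-rank p agree at the switch point", {
  set.seed(77)
  d <- rnorm(26, mean = 0.3)
  p_exact <- wilcoxon_signed_rank(d, exact_max = 26)$p_value
  p_approx <- wilcoxon_signed_rank(d, exact_max = 25)$p_value
  expect_lt(abs(p_exact - p_approx), 0.01)
})

test_that("Bonferroni adjustment caps m-fold scaling at one", {
  expect_equal(bonferroni_adjust(0.01, m = 6), 0.06)
  expect_equal(bonferroni_adjust(0.5, m = 6), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04)), c(0.4, 0.08))
  expect_identical(bonferroni_adjust(0.3, m = 1), 0.3)
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})
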