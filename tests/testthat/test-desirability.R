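test_that("FDR desirability is a hard significance gate", {
  expect_equal(d_fdr(0.2), 0)
  expect_equal(d_fdr(0.05), 1)
  expect_equal(d_fdr(0.1), 1)  # boundary inclusive: ties favour significance
  expect_equal(d_fdr(c(0, 0.099, 0.101, 1)), c(1, 1, 0, 0))
  expect_error(d_fdr(-0.1), "\\[0, 1\\]")
  expect_error(d_fdr(1.2), "\\[0, 1\\]")
})

test_that("p-value desirability follows the power curve on the -log10 axis", {
  expect_equal(d_pvalue(0.5), 0.01)
  expect_equal(d_pvalue(0.2), 0.01)
  expect_equal(d_pvalue(1e-4), 1)
  expect_equal(d_pvalue(1e-6), 1)
  # midpoint of the log scale: t = 1.5/3, d = 0.01 + 0.99 * 0.25
  expect_equal(d_pvalue(10^-2.5, shape = 2), 0.2575)
  # shape 1 is linear interpolation on the log axis
  expect_equal(d_pvalue(10^-2.5, shape = 1), 0.01 + 0.99 * 0.5)
  expect_error(d_pvalue(0), "floor")
  expect_error(d_pvalue(-1), "floor")
  expect_error(d_pvalue(0.5, shape = 0.5), ">= 1")

  # monotone non-increasing in p, bounded in [0.01, 1]
  set.seed(11)
  for (shape in c(1, 2, 4)) {
    p <- sort(10^runif(200, -6, 0))
    d <- d_pvalue(p, shape = shape)
    expect_true(all(diff(d) <= 1e-12))
    expect_true(all(d >= 0.01 & d <= 1))
  }
})

test_that("the LFC boundary is mean +/- 3 sample standard deviations", {
  expect_equal(lfc_boundary(c(-1, 0, 1)), 3)
  expect_equal(lfc_boundary(c(-1, 0, 1), "sensitivity"), -3)
  expect_equal(lfc_boundary(c(5, 5, 5)), 5)  # degenerate sd = 0
  set.seed(3)
  x <- rnorm(50, 2, 3)
  expect_equal(lfc_boundary(x), mean(x) + 3 * sd(x))
  expect_error(lfc_boundary(5), "at least 2")
  expect_error(lfc_boundary(c(1, NA)), "at least 2")
})

test_that("LFC desirability steps at the boundary, favourable side inclusive", {
  expect_equal(d_lfc(4.2, 3), 1)
  expect_equal(d_lfc(2.9, 3), 0.01)
  expect_equal(d_lfc(3, 3), 1)
  expect_equal(d_lfc(-3.5, -3, mode = "sensitivity"), 1)
  expect_equal(d_lfc(-2.9, -3, mode = "sensitivity"), 0.01)
  expect_error(d_lfc(Inf, 3), "finite")
  # smoothed variant stays in range, is monotone, and matches the step far
  # from the boundary
  x <- seq(-5, 5, length.out = 101)
  s <- d_lfc(x, 0, smooth = TRUE)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0.01 & s <= 1))
  expect_equal(d_lfc(5, 0, smooth = TRUE), 1, tolerance = 1e-6)
})

test_that("essentiality desirability filters double-essential and depleted genes", {
  expect_equal(d_essentiality(TRUE, TRUE, 2), 0)
  expect_equal(d_essentiality(FALSE, FALSE, -0.5), 0)
  expect_equal(d_essentiality(FALSE, FALSE, 1), 1)
  expect_equal(d_essentiality(TRUE, FALSE, 1), 1)   # essential in one arm only
  expect_equal(d_essentiality(FALSE, TRUE, 1), 1)
  expect_equal(d_essentiality(c(TRUE, FALSE), c(TRUE, FALSE), c(2, 2)),
               c(0, 1))
})

test_that("aggregation is the weighted geometric mean with zero annihilation", {
  expect_equal(aggregate_desirability(c(1, 1, 1)), 1)
  expect_equal(aggregate_desirability(c(0.25, 1)), 0.5)
  expect_equal(aggregate_desirability(c(0.9, 0, 0.8)), 0)
  expect_equal(aggregate_desirability(c(0.5, 0.5), weights = c(2, 2)), 0.5)
  # weighting shifts towards the heavier component
  expect_equal(aggregate_desirability(c(0.25, 1), weights = c(3, 1)),
               0.25^(3 / 4))
  expect_error(aggregate_desirability(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(aggregate_desirability(c(0.5, 0.5), weights = 1:3),
               "same length")
  expect_error(aggregate_desirability(c(0.5, 0.5), weights = c(1, -1)),
               "positive")

  # property: aggregate of valid components always lands in [0, 1]
  set.seed(21)
  for (i in 1:50) {
    comp <- runif(sample(2:6, 1))
    d <- aggregate_desirability(comp)
    expect_true(d >= 0 && d <= 1)
    expect_equal(aggregate_desirability(c(comp, 0)), 0)
  }
})

make_pair <- function(genes, lfc, p, fdr, ess_cvt = FALSE, ess_cvp = FALSE) {
  list(cvt = toy_comparison(genes, lfc, p, fdr, ess_cvt),
       cvp = toy_comparison(genes, rnorm(length(genes)),
                            runif(length(genes)), runif(length(genes)),
                            ess_cvp, comparison = "CvP"))
}

test_that("overall desirability composes the four resistance rules", {
  set.seed(5)
  n <- 60
  genes <- sprintf("g%02d", 1:n)
  lfc <- rnorm(n)
  lfc[1] <- 8                      # planted well above mean + 3 sd
  p <- runif(n, 0.2, 1)
  p[1] <- 1e-5
  fdr <- rep(0.01, n)
  fdr[2] <- 0.5
  pair <- make_pair(genes, lfc, p, fdr)
  res <- overall_desirability(pair$cvt, pair$cvp)

  expect_equal(res$overall[1], 1)          # every component favourable
  expect_equal(res$overall[2], 0)          # FDR gate annihilates
  expect_true(all(res$overall >= 0 & res$overall <= 1))
  # a significant-FDR null with high p and sub-boundary LFC:
  # (1 * 0.01 * 0.01 * 1)^(1/4) = 0.1
  null_idx <- which(res$d_pvalue == 0.01 & res$d_lfc == 0.01 &
                      res$d_fdr == 1 & res$d_essentiality == 1)
  expect_true(length(null_idx) > 0)
  expect_equal(res$overall[null_idx], rep(0.1, length(null_idx)))
  # zero-annihilation holds row-wise
  expect_true(all(res$overall[res$d_fdr == 0] == 0))
})

test_that("overall desirability is invariant under row permutation and joins universes", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:30)
  pair <- make_pair(genes, rnorm(30), runif(30), runif(30))
  base <- overall_desirability(pair$cvt, pair$cvp)

  perm <- sample(30)
  cvt_p <- toy_comparison(genes[perm], pair$cvt$lfc[perm],
                          pair$cvt$pvalue[perm], pair$cvt$fdr[perm],
                          pair$cvt$essential_flag[perm])
  res_p <- overall_desirability(cvt_p, pair$cvp)
  expect_equal(res_p$overall[match(base$gene, res_p$gene)], base$overall)

  # partial overlap warns and inner-joins; disjoint errors
  cvp_sub <- toy_comparison(genes[1:20], rnorm(20), runif(20), runif(20),
                            FALSE, comparison = "CvP")
  expect_warning(joined <- overall_desirability(pair$cvt, cvp_sub),
                 "universes differ")
  expect_equal(nrow(joined), 20)
  cvp_other <- toy_comparison(paste0("x", 1:5), rnorm(5), runif(5), runif(5),
                              FALSE, comparison = "CvP")
  expect_error(overall_desirability(pair$cvt, cvp_other), "no genes")
})

test_that("sensitivity mode drops the essentiality rule and flips the boundary", {
  set.seed(7)
  n <- 50
  genes <- sprintf("g%02d", 1:n)
  lfc <- rnorm(n)
  lfc[1] <- -8                     # strong depletion
  p <- runif(n); p[1] <- 1e-5
  fdr <- rep(0.01, n)
  pair <- make_pair(genes, lfc, p, fdr, ess_cvt = TRUE, ess_cvp = TRUE)
  res <- overall_desirability(pair$cvt, pair$cvp, mode = "sensitivity")
  expect_true(all(is.na(res$d_essentiality)))
  expect_equal(res$overall[1], 1)  # essential flags are irrelevant here
  expect_equal(res$d_lfc[1], 1)
  expect_true(all(res$d_lfc[lfc > lfc_boundary(lfc, "sensitivity")] == 0.01))
})

test_that("hit calling uses strict thresholds on both axes", {
  expect_true(call_hit(0.8, 0.05))
  expect_false(call_hit(0.7, 0.05))   # strict >
  expect_false(call_hit(0.9, 0.1))    # strict <
  expect_equal(call_hit(c(0.71, 0.7), c(0.09, 0.09)), c(TRUE, FALSE))
  expect_error(call_hit(1.2, 0.05), "\\[0, 1\\]")
})
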