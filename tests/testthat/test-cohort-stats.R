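# Exact two-sided rank-sum p by enumeration of all label assignments.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("Mann-Whitney matches exact enumeration on small samples", {
  got <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(got$U, 0)
  expect_equal(got$p, 1 / 3, tolerance = 1e-12)
  expect_equal(got$p, mw_exact_oracle(c(1, 2), c(3, 4)), tolerance = 1e-12)

  set.seed(31)
  a <- rnorm(4); b <- rnorm(5)
  got2 <- mann_whitney(a, b)
  expect_equal(got2$p, mw_exact_oracle(a, b), tolerance = 1e-12)

  # identical multisets: two-sided p is maximal
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  expect_error(mann_whitney(numeric(0), 1:3), class = "csfflow_config_error")
})

test_that("printed group separations are overwhelmingly significant in simulation", {
  # downward peak flow, patient vs volunteer parameters
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    a <- rnorm(31, 1.76, 0.77)
    b <- rnorm(26, 2.96, 0.92)
    mann_whitney(a, b)$p
  }, numeric(1))
  expect_lt(median(ps), 0.001)
})

test_that("Fisher's exact test reproduces the in-table p-values", {
  # thoracic/lumbar patch-level counts: 10/2 vs 9/4
  expect_equal(round(fisher_exact(matrix(c(10, 9, 2, 4), 2)), 2), 0.64)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  # hypergeometric enumeration oracle for the diagonal table
  p_tbl <- function(a) dhyper(a, 3, 3, 3)
  probs <- vapply(0:3, p_tbl, numeric(1))
  oracle <- sum(probs[probs <= p_tbl(3) + 1e-12])
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), oracle)
  expect_equal(oracle, 0.1)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2)),
               class = "csfflow_degenerate_error")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)),
               class = "csfflow_config_error")
})

test_that("chi-square wrapper validates and reports", {
  out <- chi_square(matrix(c(22, 15, 9, 11), 2))
  expect_true(out$statistic >= 0)
  expect_true(out$p > 0 && out$p <= 1)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)),
               class = "csfflow_degenerate_error")
})

test_that("ROC handles perfect and partial separation correctly", {
  r <- roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_gt(r$cutoff, 2); expect_lte(r$cutoff, 3)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$positive_direction, "higher-is-positive")

  # 3 of 4 pairs concordant by enumeration
  r2 <- roc(c(1, 3, 2, 4), c(0, 0, 1, 1))
  conc <- mean(outer(c(2, 4), c(1, 3), ">"))
  expect_equal(r2$auc, conc)
  expect_equal(r2$auc, 0.75)

  expect_error(roc(1:4, c(1, 1, 1, 1)), class = "csfflow_config_error")
})

test_that("ROC AUC equals the Mann-Whitney probability and the pROC value", {
  set.seed(17)
  for (i in 1:10) {
    pos <- rnorm(15, 1); neg <- rnorm(12)
    vals <- c(pos, neg); labs <- rep(c(1, 0), c(15, 12))
    r <- roc(vals, labs)
    # U-statistic route (folded: roc() auto-orients to AUC >= 0.5)
    u_auc <- mann_whitney(pos, neg)$U / (15 * 12)
    expect_equal(r$auc, max(u_auc, 1 - u_auc), tolerance = 1e-12)
    # independent library route
    pr_auc <- as.numeric(pROC::auc(pROC::roc(labs, vals, quiet = TRUE,
                                             direction = "<")))
    expect_equal(r$auc, max(pr_auc, 1 - pr_auc), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(18)
  vals <- rnorm(40); labs <- rbinom(40, 1, 0.5)
  labs[1] <- 1; labs[2] <- 0
  a1 <- roc(vals, labs)$auc
  expect_equal(roc(exp(vals), labs)$auc, a1)
  expect_equal(roc(qnorm(pnorm(vals)) * 3 + 2, labs)$auc, a1,
               tolerance = 1e-12)
})

test_that("the orientation flips automatically for lower-is-positive metrics", {
  r <- roc(c(4, 3, 2, 1), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$positive_direction, "lower-is-positive")
  expect_equal(r$sensitivity, 100)
})

test_that("binormal AUC matches Monte-Carlo pair probability", {
  expect_equal(binormal_auc(1, 1, 1, 1), 0.5)
  expect_equal(binormal_auc(2, 0, 1, 0), 1.0)
  expect_equal(binormal_auc(1, 0.5, 2, 0.5), 1 - binormal_auc(2, 0.5, 1, 0.5))
  set.seed(19)
  x <- rnorm(4e5, 1.87, 0.52); y <- rnorm(4e5, 1.28, 0.50)
  expect_equal(binormal_auc(1.87, 0.52, 1.28, 0.50), mean(x > y),
               tolerance = 0.005)
  expect_error(binormal_auc(1, -1, 0, 1), class = "csfflow_config_error")
})

test_that("normality check separates normal from exponential samples", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s); normality_check(rnorm(500))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)

  p_exp <- vapply(1:100, function(s) {
    set.seed(s); normality_check(rexp(200))$p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.95)

  expect_warning(out <- normality_check(rep(3, 10)), "Constant")
  expect_lte(out$p, .Machine$double.xmin)
  expect_error(normality_check(c(1, 2)), class = "csfflow_config_error")
})
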