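test_that("Shapiro-Wilk flags non-normality and holds its size", {
  set.seed(71)
  expect_lt(shapiro_wilk(runif(500))$p_value, 0.05)
  expect_error(shapiro_wilk(rnorm(2)), "3, 5000")
  rate <- mean(replicate(2000, shapiro_wilk(rnorm(50))$p_value < 0.05))
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("Levene test detects variance heterogeneity at nominal size", {
  set.seed(72)
  big <- levene(list(rnorm(50, sd = 1), rnorm(50, sd = 5)))
  expect_lt(big$p_value, 0.01)
  expect_error(levene(list(rnorm(10))), "2 groups")
  rate <- mean(replicate(2000, {
    levene(list(rnorm(20), rnorm(20), rnorm(20)))$p_value < 0.05
  }))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Wilcoxon signed rank matches exact sign-assignment enumeration", {
  a <- c(1.2, 2.3, 3.1, 0.5, 2.8)
  b <- c(0.8, 2.9, 1.4, 0.2, 1.9)
  res <- wilcoxon_signed_rank(a, b)
  # frozen from the 2^5 enumeration of sign assignments
  expect_equal(res$p_value, 0.3125)
  expect_equal(unname(res$statistic), 12)
  # runtime enumeration oracle
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  all_t <- vapply(0:31, function(m) sum(r[as.logical(intToBits(m)[1:5])]),
                  numeric(1))
  p_exact <- min(1, 2 * min(mean(all_t <= v_obs), mean(all_t >= v_obs)))
  expect_equal(res$p_value, p_exact)
  expect_error(wilcoxon_signed_rank(a, a), "all differences")
  # power under a 1 SD shift at n = 21
  set.seed(73)
  hits <- sum(replicate(20, {
    x <- rnorm(21)
    wilcoxon_signed_rank(x + 1, x + rnorm(21))$p_value < 0.05
  }))
  expect_gte(hits, 14)
})

test_that("paired t and one-way ANOVA behave on degenerate input", {
  x <- rnorm(10)
  res <- paired_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  g <- rnorm(15)
  aov3 <- one_way_anova(list(g, g, g))
  expect_lt(aov3$statistic, 1e-20)
  expect_equal(aov3$eta_sq, 0, tolerance = 1e-20)
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(74)
  x <- rnorm(12, 1)
  y <- rnorm(15)
  f <- one_way_anova(list(x, y))$statistic
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("Scheirer-Ray-Hare matches the hand-computed rank ANOVA", {
  vals <- c(3.1, 4.2, 3.8, 7.9, 8.4, 9.1, 2.5, 3.3, 2.9, 6.1, 5.8, 7.2)
  A <- rep(c("a1", "a2"), each = 6)
  B <- rep(rep(c("b1", "b2"), each = 3), 2)
  res <- scheirer_ray_hare(vals, A, B)
  # frozen from the independent group-mean computation on joint ranks
  expect_equal(res$statistic, c(1.641026, 8.307692, 0.02564103),
               tolerance = 1e-6)
  expect_equal(res$df, c(1, 1, 1))
  expect_equal(res$p_value[2], 0.003947752, tolerance = 1e-6)
  # runtime brute-force oracle: sums of squares from cell means of ranks
  r <- rank(vals)
  ms_tot <- sum((r - mean(r))^2) / (length(r) - 1)
  mA <- tapply(r, A, mean); mB <- tapply(r, B, mean)
  mAB <- tapply(r, paste(A, B), mean)
  ssA <- 6 * sum((mA - mean(r))^2)
  ssB <- 6 * sum((mB - mean(r))^2)
  ssAB <- 3 * sum((mAB - mean(r))^2) - ssA - ssB
  expect_equal(res$statistic, unname(c(ssA, ssB, ssAB) / ms_tot),
               tolerance = 1e-10)
  expect_error(scheirer_ray_hare(vals[1:9], A[1:9], B[1:9]), "crossed")
})

test_that("Scheirer-Ray-Hare is rank invariant and detects main effects", {
  set.seed(75)
  v <- rexp(24)
  A <- rep(c("x", "y"), 12)
  B <- rep(c("u", "v", "w"), each = 8)
  r1 <- scheirer_ray_hare(v, A, B)
  r2 <- scheirer_ray_hare(exp(v), A, B)  # monotone transform
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  # strong main effect on A only
  hits <- replicate(30, {
    va <- rnorm(24) + 3 * (A == "x")
    p <- scheirer_ray_hare(va, A, B)$p_value
    c(p[1] < 0.01, p[2] > 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.8)
  expect_gte(mean(hits[2, ]), 0.6)
  # type-I calibration of all three effects under the null
  reps <- replicate(2000, scheirer_ray_hare(rnorm(12),
                                            rep(c("a", "b"), 6),
                                            rep(c("u", "v"), each = 6))$p_value)
  rates <- rowMeans(reps < 0.05)
  expect_true(all(rates < 0.08))
})

test_that("BH adjustment follows the step-up closed form and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(76)
  for (i in 1:5) {
    p <- runif(20)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    # adjusted values keep the input ranking (ties allowed by cummin step)
    expect_true(all(diff(adj[order(p)]) >= 0))
    perm <- sample(20)
    expect_equal(bh_fdr(p[perm]), adj[perm])          # order equivariant
  }
})

test_that("the normality gate routes comparisons to the right test", {
  set.seed(77)
  n <- 30
  ref <- rnorm(n)
  gauss <- ref + rnorm(n, 0.2)
  heavy <- ref + rcauchy(n)
  m <- cbind(tscs_off = ref, gauss = gauss, heavy = heavy)
  out <- gated_pairwise(m, reference = "tscs_off")
  expect_equal(out$test_name[out$comparison == "gauss vs tscs_off"], "paired_t")
  expect_equal(out$test_name[out$comparison == "heavy vs tscs_off"],
               "wilcoxon_signed_rank")
  expect_false("tscs_off vs tscs_off" %in% out$comparison)
  expect_equal(out$p_adjusted, bh_fdr(out$p_value))
})
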