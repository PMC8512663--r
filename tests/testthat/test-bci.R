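test_that("classification window crops trials and validates its span", {
  tr <- array(rnorm(2 * 3 * 9600), c(2, 3, 9600),
              dimnames = list(NULL, c("C3", "Cz", "C4"), NULL))
  ep <- epoch_set(tr, fs = 1200, t0_offset = -2,
                  labels = c("right_hand", "bimanual"))
  win <- classification_window(ep)
  expect_equal(dim(win$trials)[3], 2400)
  expect_equal(win$t0_offset, 0.5)
  expect_equal(win$trials[1, 1, 1], ep$trials[1, 1, 2.5 * 1200 + 1])
  expect_error(classification_window(ep, t1 = 7), "outside")
  expect_error(classification_window(ep, t0 = 1, t1 = 1), "t0 < t1")
})

test_that("CSP solves the two-channel diagonal problem analytically", {
  set.seed(61)
  n <- 60
  trials <- array(0, c(2 * n, 2, 400),
                  dimnames = list(NULL, c("C3", "C4"), NULL))
  labels <- rep(c("right_hand", "bimanual"), each = n)
  for (i in seq_len(2 * n)) {
    s <- if (labels[i] == "right_hand") c(sqrt(2), 1) else c(1, sqrt(2))
    trials[i, , ] <- s * matrix(rnorm(800), 2)
  }
  ep <- epoch_set(trials, 100, 0, labels)
  model <- csp_fit(ep, n_pairs = 1)
  # filters align with the coordinate axes (covariances are diagonal)
  w <- abs(model$filters / sqrt(rowSums(model$filters^2)))
  expect_true(all(apply(w, 1, max) > 0.95))
  # extremal variance ratios approach 2 and 1/2
  f <- logvar_features(ep, model)
  ratios <- vapply(1:2, function(j) {
    exp(mean(f[labels == "right_hand", j]) - mean(f[labels == "bimanual", j]))
  }, numeric(1))
  expect_equal(sort(ratios), c(0.5, 2), tolerance = 0.3)
  expect_error(csp_fit(ep, n_pairs = 10), "exceeds channel count")
})

test_that("training variance ratios follow the CSP eigenvalue order", {
  ep <- fix_epochs(n_per_class = 25, n_ch = 6, disc_ch = 2)
  model <- csp_fit(ep, n_pairs = 2)
  f <- logvar_features(ep, model)
  ratios <- vapply(seq_len(ncol(f)), function(j) {
    mean(f[ep$labels == model$classes[1], j]) -
      mean(f[ep$labels == model$classes[2], j])
  }, numeric(1))
  expect_false(is.unsorted(rev(ratios)))  # decreasing with eigenvalue order
})

test_that("log-variance features obey the log scaling rule", {
  ep <- fix_epochs()
  model <- csp_fit(ep, n_pairs = 1)
  f1 <- logvar_features(ep, model)
  ep10 <- ep
  ep10$trials <- ep$trials * 10
  f2 <- logvar_features(ep10, model)
  expect_equal(f2 - f1, matrix(log(100), nrow(f1), ncol(f1)),
               tolerance = 1e-10)
  bad <- ep
  bad$trials[1, , ] <- 0
  expect_error(logvar_features(bad, model), "zero-variance")
})

test_that("cross-validation is leakage-free, seeded and calibrated", {
  ep <- fix_epochs(n_per_class = 20, n_ch = 4, var_ratio = 6)
  r1 <- crossval_accuracy(ep, seed = 3, n_pairs = 2)
  r2 <- crossval_accuracy(ep, seed = 3, n_pairs = 2)
  expect_identical(r1$fold_acc, r2$fold_acc)
  expect_equal(r1$mean_acc, mean(r1$fold_acc))
  expect_gte(r1$mean_acc, 90)  # well-separated classes
  # label permutation: accuracy inside the binomial 95% band around 50%
  set.seed(62)
  epp <- ep
  epp$labels <- sample(ep$labels)
  rp <- crossval_accuracy(epp, seed = 3, n_pairs = 2)
  band <- 100 * qbinom(c(0.025, 0.975), 40, 0.5) / 40
  expect_gte(rp$mean_acc, band[1] - 10)
  expect_lte(rp$mean_acc, band[2] + 10)
  expect_error(crossval_accuracy(fix_epochs(n_per_class = 5)), "n_folds")
})

test_that("chance level matches the exact binomial tail", {
  expect_equal(round(binomial_chance_level(30)), 67)
  expect_equal(binomial_chance_level(30), 100 * 20 / 30, tolerance = 1e-12)
  # brute-force enumeration oracle at n = 60
  n <- 60
  tail_p <- rev(cumsum(rev(dbinom(0:n, n, 0.5))))
  k_star <- (0:n)[which(tail_p < 0.05)[1]]
  expect_equal(binomial_chance_level(60), 100 * k_star / 60)
  expect_equal(binomial_chance_level(1e6), 50, tolerance = 0.2)
  # monotone in n and in alpha
  lv <- vapply(c(10, 20, 40, 80, 160), binomial_chance_level, numeric(1))
  expect_false(is.unsorted(rev(lv)))
  expect_gte(binomial_chance_level(30, 0.01), binomial_chance_level(30, 0.05))
  expect_error(binomial_chance_level(30, 1.5), "alpha")
})

test_that("compare_conditions pairs fold accuracies against the reference", {
  ep <- fix_epochs(n_per_class = 20, n_ch = 4, var_ratio = 6)
  out <- compare_conditions(list(tscs_off = ep, tscs_on = ep), seed = 9,
                            n_pairs = 2)
  expect_equal(out$table$mean_acc[1], out$table$mean_acc[2])
  expect_equal(out$tests$p_value, 1)
  small <- fix_epochs(n_per_class = 15, n_ch = 4)
  expect_error(compare_conditions(list(tscs_off = ep, tscs_on = small)),
               "mismatched")
})
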