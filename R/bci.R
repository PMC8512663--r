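# Movement classification from sensorimotor rhythms: common spatial
# patterns, log-variance features, LDA, stratified cross-validation and the
# binomial chance level.

#' Crop epochs to the classification window
#'
#' @param ep An [epoch_set()].
#' @param t0,t1 Window relative to movement onset, seconds (default
#'   0.5-2.5 s).
#' @return An [epoch_set()] with trials cropped to the window.
#' @export
classification_window <- function(ep, t0 = 0.5, t1 = 2.5) {
  stopifnot(inherits(ep, "epoch_set"))
  if (t1 <= t0) stop("classification_window: need t0 < t1")
  n_samp <- dim(ep$trials)[3]
  i0 <- round((t0 - ep$t0_offset) * ep$fs) + 1L
  i1 <- round((t1 - ep$t0_offset) * ep$fs)
  if (i0 < 1 || i1 > n_samp) stop("classification_window: window outside the epoch span")
  epoch_set(ep$trials[, , i0:i1, drop = FALSE], fs = ep$fs, t0_offset = t0,
            labels = ep$labels)
}

trial_cov <- function(x) {
  c <- tcrossprod(x)
  c / sum(diag(c))
}

#' Fit common spatial patterns
#'
#' Solves the generalised eigenproblem extremising the ratio of the
#' class-average (trace-normalised) trial covariances, and retains
#' `n_pairs` spatial filters from each end of the eigenvalue spectrum --
#' the components whose variance is maximally discriminative between the
#' two classes. Diagonal loading (1e-9 x mean diagonal) is applied when the
#' pooled covariance is numerically rank deficient.
#'
#' @param ep An [epoch_set()] with two classes.
#' @param n_pairs Filter pairs to retain (default 6, i.e. 12 components).
#' @return A list of class `"csp_model"`: `filters` (components x
#'   channels), `eigenvalues`, `n_pairs`, `channels`.
#' @export
csp_fit <- function(ep, n_pairs = 6) {
  stopifnot(inherits(ep, "epoch_set"))
  classes <- sort(unique(ep$labels))
  if (length(classes) != 2) stop("csp_fit: exactly two classes required")
  if (any(table(ep$labels) < 2)) stop("csp_fit: need >= 2 trials per class")
  nch <- dim(ep$trials)[2]
  if (2 * n_pairs > nch) {
    stop("csp_fit: 2 * n_pairs (", 2 * n_pairs, ") exceeds channel count (", nch, ")")
  }
  covs <- lapply(seq_len(n_trials(ep)), function(i) trial_cov(ep$trials[i, , ]))
  csp_from_covs(covs, ep$labels, n_pairs, ep_channels(ep))
}

# CSP from precomputed trace-normalised trial covariances
csp_from_covs <- function(covs, labels, n_pairs, channels) {
  classes <- sort(unique(labels))
  nch <- nrow(covs[[1]])
  avg_cov <- function(class) {
    idx <- which(labels == class)
    Reduce(`+`, covs[idx]) / length(idx)
  }
  c1 <- avg_cov(classes[1])
  c2 <- avg_cov(classes[2])
  cc <- c1 + c2
  ev <- eigen(cc, symmetric = TRUE)
  tol <- 1e-10 * max(ev$values)
  if (any(ev$values <= tol)) {
    message("csp_fit: rank-deficient pooled covariance; applying diagonal loading")
    ridge <- 1e-9 * mean(diag(cc))
    c1 <- c1 + diag(ridge, nch)
    c2 <- c2 + diag(ridge, nch)
    ev <- eigen(c1 + c2, symmetric = TRUE)
    if (any(ev$values <= 0)) stop("csp_fit: covariance irreparably rank deficient")
  }
  wh <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  s1 <- wh %*% c1 %*% t(wh)
  es <- eigen((s1 + t(s1)) / 2, symmetric = TRUE)
  filters <- t(es$vectors) %*% wh   # rows ordered by decreasing eigenvalue
  keep <- c(seq_len(n_pairs), (nch - n_pairs + 1):nch)
  structure(list(filters = filters[keep, , drop = FALSE],
                 eigenvalues = es$values[keep], n_pairs = n_pairs,
                 channels = channels, classes = classes),
            class = "csp_model")
}

#' Log-variance CSP features
#'
#' @param ep An [epoch_set()] whose channels match the model.
#' @param model A [csp_fit()] result.
#' @return Numeric matrix, trials x (2 * n_pairs), of log component
#'   variances.
#' @export
logvar_features <- function(ep, model) {
  stopifnot(inherits(ep, "epoch_set"), inherits(model, "csp_model"))
  if (!identical(ep_channels(ep), model$channels)) {
    stop("logvar_features: channel set does not match the CSP model")
  }
  feats <- t(vapply(seq_len(n_trials(ep)), function(i) {
    y <- model$filters %*% ep$trials[i, , ]
    v <- apply(y, 1, stats::var)
    if (any(v <= 0)) stop("logvar_features: zero-variance component")
    log(v)
  }, numeric(nrow(model$filters))))
  feats
}

#' Stratified k-fold cross-validated CSP-LDA accuracy
#'
#' CSP and LDA are fitted on the training folds only, so no information
#' leaks from the test trials into the spatial filters. Fold assignment is
#' stratified by class and fully determined by `seed`.
#'
#' @param ep An [epoch_set()] (already cropped to the classification
#'   window).
#' @param n_folds Folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param n_pairs CSP filter pairs.
#' @return A list of class `"cv_result"`: `fold_acc` (%), `mean_acc` (%),
#'   `n_per_class`.
#' @export
crossval_accuracy <- function(ep, n_folds = 10, seed = 1, n_pairs = 6) {
  stopifnot(inherits(ep, "epoch_set"))
  tab <- table(ep$labels)
  if (length(tab) != 2 || any(tab < n_folds)) {
    stop("crossval_accuracy: need at least n_folds trials per class")
  }
  fold <- integer(n_trials(ep))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(ep$labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  # trial covariances are fold-independent; compute them once
  covs <- lapply(seq_len(n_trials(ep)), function(i) trial_cov(ep$trials[i, , ]))
  feats_for <- function(model, idx) {
    t(vapply(idx, function(i) {
      y <- model$filters %*% ep$trials[i, , ]
      ns <- ncol(y)
      v <- (rowSums(y^2) - rowSums(y)^2 / ns) / (ns - 1)
      if (any(v <= 0)) stop("crossval_accuracy: zero-variance component")
      log(v)
    }, numeric(nrow(model$filters))))
  }
  fold_acc <- vapply(seq_len(n_folds), function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- csp_from_covs(covs[tr], ep$labels[tr], n_pairs, ep_channels(ep))
    lda <- MASS::lda(feats_for(model, tr), grouping = ep$labels[tr])
    pred <- stats::predict(lda, feats_for(model, te))$class
    100 * mean(as.character(pred) == ep$labels[te])
  }, numeric(1))
  structure(list(fold_acc = fold_acc, mean_acc = mean(fold_acc),
                 n_per_class = as.integer(min(tab))),
            class = "cv_result")
}

#' Binomial chance level for a two-class classifier
#'
#' The smallest accuracy `k / n` (in %) whose upper-tail probability under
#' Binomial(n, 0.5) falls below `alpha` -- the accuracy a classifier must
#' exceed to beat random guessing at the given significance.
#'
#' @param n_trials Number of test trials.
#' @param alpha Significance level.
#' @return Chance-level threshold in percent (unrounded).
#' @export
binomial_chance_level <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1)
  if (alpha <= 0 || alpha >= 1) stop("binomial_chance_level: alpha must be in (0, 1)")
  k <- 0:n_trials
  tail_p <- stats::pbinom(k - 1, n_trials, 0.5, lower.tail = FALSE)
  100 * k[which(tail_p < alpha)[1]] / n_trials
}

#' Cross-validated accuracies across conditions with paired tests
#'
#' Runs [crossval_accuracy()] with the same seed (hence identical fold
#' structure) on every entry and compares each entry's fold accuracies
#' against the reference condition with a normality-gated paired test;
#' p-values are BH-adjusted.
#'
#' @param sessions Named list of [epoch_set()]s with identical trial
#'   structure; must include `reference`.
#' @param seed Fold seed.
#' @param reference Name of the reference entry.
#' @param n_folds,n_pairs Passed to [crossval_accuracy()].
#' @return List with `cv` (named list of `cv_result`), `table` (accuracy
#'   summary data frame) and `tests` ([gated_pairwise()] output over fold
#'   accuracies).
#' @export
compare_conditions <- function(sessions, seed = 1, reference = "tscs_off",
                               n_folds = 10, n_pairs = 6) {
  stopifnot(is.list(sessions), reference %in% names(sessions))
  n0 <- n_trials(sessions[[reference]])
  if (any(vapply(sessions, n_trials, integer(1)) != n0)) {
    stop("compare_conditions: mismatched trial counts across entries")
  }
  cv <- lapply(sessions, crossval_accuracy, n_folds = n_folds, seed = seed,
               n_pairs = n_pairs)
  acc <- vapply(cv, function(r) r$fold_acc, numeric(n_folds))
  tests <- gated_pairwise(acc, reference)
  tbl <- data.frame(condition = names(cv),
                    mean_acc = vapply(cv, function(r) r$mean_acc, numeric(1)),
                    sd_acc = vapply(cv, function(r) stats::sd(r$fold_acc), numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(cv = cv, table = tbl, tests = tests)
}
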