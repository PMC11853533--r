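#' Wolpaw information transfer rate
#'
#' B = log2(N) + P log2(P) + (1 - P) log2((1 - P)/(N - 1)) bits per trial
#' (0 log 0 taken as 0), Q = 60 / T trials per minute, ITR = B * Q.
#' B is convex in P with its minimum 0 at chance (P = 1/N); no clamping
#' or correction is applied off chance.
#'
#' @param accuracy classification accuracy P in [0, 1] (vectorized).
#' @param n_targets number of targets N.
#' @param trial_time per-trial classification time T, s (4.5 here; 5 for
#'   the flash-response pipeline which uses the whole trial).
#' @return ITR in bit/min.
#' @export
itr <- function(accuracy, n_targets = 4, trial_time = 4.5) {
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must be in [0, 1]")
  if (n_targets < 2) stop("need at least 2 targets")
  if (trial_time <= 0) stop("trial_time must be positive")
  p <- accuracy
  b <- log2(n_targets) +
    ifelse(p > 0, p * log2(p), 0) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_targets - 1)), 0)
  b * 60 / trial_time
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: train on the remaining subjects' items, test on
#' the held-out subject.
#'
#' @param items list of per-subject lists of items.
#' @param labels list of per-subject integer label vectors.
#' @param train_fn `function(train_items, train_labels) -> model`.
#' @param classify_fn `function(model, item) -> predicted label`.
#' @param trial_time for the per-fold ITR.
#' @return list of class `cv_report`: `scheme`, `per_fold` accuracies,
#'   `mean_accuracy`, `mean_itr`.
#' @export
losocv <- function(items, labels, train_fn, classify_fn, trial_time = 4.5) {
  ns <- length(items)
  if (ns < 2) stop("LOSOCV needs at least 2 subjects")
  acc <- numeric(ns)
  for (s in seq_len(ns)) {
    tr_items <- do.call(c, items[-s])
    tr_labels <- unlist(labels[-s])
    model <- train_fn(tr_items, tr_labels)
    pred <- vapply(items[[s]], function(it) classify_fn(model, it), numeric(1))
    acc[s] <- mean(pred == labels[[s]])
  }
  structure(list(scheme = "losocv", per_fold = acc,
                 mean_accuracy = mean(acc),
                 mean_itr = mean(itr(acc, trial_time = trial_time))),
            class = "cv_report")
}

#' Repeated stratified hold-out validation
#'
#' Subject-dependent scheme: `repeats` random stratified splits holding
#' out `ratio` of the trials; reports the per-repeat accuracies.
#'
#' @param items list of items (one subject's trials).
#' @param labels integer labels.
#' @param train_fn,classify_fn as in [losocv()].
#' @param ratio held-out fraction (0.3 = the three-to-seven split).
#' @param repeats number of repeats.
#' @param seed RNG seed.
#' @param trial_time for the ITR.
#' @return A `cv_report` with `per_fold`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_itr`.
#' @export
repeated_holdout <- function(items, labels, train_fn, classify_fn,
                             ratio = 0.3, repeats = 30, seed = 1L,
                             trial_time = 4.5) {
  labels <- as.integer(labels)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 700 + r))
    test_idx <- integer(0)
    for (cls in unique(labels)) {
      sel <- which(labels == cls)
      test_idx <- c(test_idx, sample(sel, max(1, round(ratio * length(sel)))))
    }
    tr <- setdiff(seq_along(labels), test_idx)
    model <- train_fn(items[tr], labels[tr])
    pred <- vapply(items[test_idx], function(it) classify_fn(model, it),
                   numeric(1))
    acc[r] <- mean(pred == labels[test_idx])
  }
  structure(list(scheme = "repeated_holdout", per_fold = acc,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 n_repeats = repeats, split_ratio = ratio,
                 mean_itr = mean(itr(acc, trial_time = trial_time))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean accuracy %.3f over %d folds, mean ITR %.2f bit/min\n",
              x$scheme, x$mean_accuracy, length(x$per_fold), x$mean_itr))
  invisible(x)
}

#' PERMANOVA on trial feature vectors
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' between flattened feature vectors (via `vegan::adonis2`), testing
#' whether the four LED stimuli imprint different feature distributions.
#'
#' @param features numeric matrix, trials x features.
#' @param groups factor/vector of group labels.
#' @param n_perm permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `pseudo_F`, `p_value`, `df`.
#' @export
permanova <- function(features, groups, n_perm = 1000, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (min(table(groups)) < 3) stop("need at least 3 trials per group")
  d <- stats::dist(features)
  set.seed(seed)
  df <- data.frame(g = groups)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1], df = fit$Df[1])
}

#' Paired Wilcoxon signed-rank test
#'
#' Used on the mean dynamic Riemannian distance in the 0.5 s before vs
#' after stimulus onset, where normality cannot be assumed. Zero
#' differences are dropped by the standard convention; an all-zero
#' difference vector is rejected as degenerate.
#'
#' @param pre,post paired numeric vectors (length >= 5).
#' @return list with `statistic` (V) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("paired vectors differ in length")
  if (length(pre) < 5) stop("need at least 5 pairs")
  if (all(post - pre == 0)) stop("all differences are zero: degenerate test")
  d <- post - pre
  exact <- length(pre) < 50 && !any(duplicated(abs(d[d != 0]))) && !any(d == 0)
  ht <- stats::wilcox.test(post, pre, paired = TRUE, exact = exact)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
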