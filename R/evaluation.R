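#' F1-measure of a binary prediction
#'
#' Precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)` on the positive (diseased) class — used instead of raw
#' accuracy because held-out test sets are typically class-imbalanced.  If
#' no positives are predicted, none exist, or `P + R = 0`, F1 is 0 by
#' convention.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive The positive class value (default `1L`).
#' @return F1 in \[0, 1\].
#' @examples
#' f1_measure(c(1, 1, 1, -1), c(1, 1, -1, 1))  # TP=2 FP=1 FN=1 -> 2/3
#' @export
f1_measure <- function(predicted, truth, positive = 1L) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  if (tp + fp == 0 || tp + fn == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Paired-sample t-test between two metric series
#'
#' Classical paired t on the differences, two-sided p-value from Student's
#' t with n - 1 degrees of freedom; the sample (n - 1) standard-deviation
#' convention throughout.  When all differences are identical the statistic
#' is undefined (zero variance) and is reported as `NA` rather than
#' inferred.
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 2),
#'   e.g. per-repeat LOOCV accuracies of two method variants.
#' @return List with `t`, `p` (two-sided), `n`, and `degenerate` flag.
#' @export
paired_t_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, n = length(d),
                degenerate = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, n = length(d),
       degenerate = FALSE)
}

# stratified draw without replacement: size[1] positives, size[2] negatives
draw_stratified <- function(labels, size, exclude = integer(0)) {
  pool_pos <- setdiff(which(labels == 1L), exclude)
  pool_neg <- setdiff(which(labels == -1L), exclude)
  if (size[1] > length(pool_pos) || size[2] > length(pool_neg)) {
    stop("requested subset size exceeds available samples per class ",
         "(need ", size[1], "+/", size[2], "-, have ", length(pool_pos),
         "+/", length(pool_neg), "-)", call. = FALSE)
  }
  sort(c(sample(pool_pos, size[1]), sample(pool_neg, size[2])))
}

subset_rows <- function(fm, idx) {
  new_feature_matrix(fm$sample_ids[idx], fm$feature_names,
                     fm$values[idx, , drop = FALSE],
                     if (!is.null(fm$labels)) fm$labels[idx],
                     fm$label_map)
}

as_per_class <- function(size) {
  size <- as.integer(size)
  if (length(size) == 1) size <- c(size, size)
  stopifnot(length(size) == 2, all(size >= 1))
  size
}

# resolve the manifest-or-matrix argument shared by both tests
resolve_features <- function(x, k, feature, normalize, pseudocount) {
  if (inherits(x, "feature_matrix")) return(x)
  if (inherits(x, "sample_manifest")) {
    return(build_feature_matrix(x, k = k, feature = feature,
                                normalize = normalize,
                                pseudocount = pseudocount))
  }
  stop("x must be a sample_manifest or a labeled feature_matrix",
       call. = FALSE)
}

#' Stability test: repeated training-set resampling
#'
#' Draws `repeats` stratified training subsets without replacement, runs
#' the full selection pipeline on each, and records the optimal round's
#' LOOCV accuracy.  A small spread (standard deviation) across repeats
#' means classifiers trained by different research groups on different
#' samples of the same cohort would behave alike — the operational
#' definition of a stable classification algorithm.
#'
#' @param x A labeled `sample_manifest` or `feature_matrix`.  (Features are
#'   extracted once; resampling subsets rows.)
#' @param train_size Training samples per class: one integer for both
#'   classes or `c(positive, negative)`.
#' @param repeats Number of resampling repeats (default 20).
#' @param mode `"dynamic"` or `"static"` selection.
#' @param ladder,cls,kspec,A Passed to [dectico_select()] /
#'   [static_select()]; `ladder = NULL` uses the default ladder.
#' @param seed Master seed; per-repeat sub-seeds are derived from it by
#'   counter, so reports are exactly reproducible.
#' @param k,feature,normalize,pseudocount Feature-extraction settings, used
#'   only when `x` is a manifest.
#' @return An `evaluation_report` with per-repeat accuracies, their mean
#'   and sample standard deviation.
#' @export
stability_test <- function(x, train_size, repeats = 20,
                           mode = c("dynamic", "static"), ladder = NULL,
                           cls = classifier_spec(), kspec = kernel_spec(),
                           A = NULL, seed = 1, k = 4,
                           feature = c("ico", "composition"),
                           normalize = TRUE, pseudocount = 0) {
  mode <- match.arg(mode)
  feature <- match.arg(feature)
  fm <- resolve_features(x, k, feature, normalize, pseudocount)
  stopifnot(!is.null(fm$labels))
  train_size <- as_per_class(train_size)
  values <- vapply(seq_len(repeats), function(i) {
    set.seed(derive_seed(seed, i))
    idx <- draw_stratified(fm$labels, train_size)
    sub <- subset_rows(fm, idx)
    res <- if (mode == "dynamic") {
      dectico_select(sub, ladder, cls, kspec, A)
    } else {
      static_select(sub, ladder, cls, kspec, A)
    }
    res$rounds[[res$optimal]]$accuracy
  }, numeric(1))
  new_evaluation_report("stability", values,
                        config = list(train_size = train_size,
                                      repeats = repeats, mode = mode,
                                      seed = seed))
}

#' Generality test: one classifier, repeated test-set resampling
#'
#' One stratified training subset is drawn and a single optimal classifier
#' trained on it; then `repeats` test subsets are drawn from the remaining
#' samples and the F1-measure recorded for each.  A small spread means the
#' classifier generalizes consistently to whichever unlabeled samples it
#' meets.
#'
#' @inheritParams stability_test
#' @param test_size Test samples per class (may be unbalanced — the reason
#'   F1 is used rather than accuracy).
#' @return An `evaluation_report` with per-repeat F1 values, mean and
#'   sample standard deviation.
#' @export
generality_test <- function(x, train_size, test_size, repeats = 20,
                            mode = c("dynamic", "static"), ladder = NULL,
                            cls = classifier_spec(), kspec = kernel_spec(),
                            A = NULL, seed = 1, k = 4,
                            feature = c("ico", "composition"),
                            normalize = TRUE, pseudocount = 0) {
  mode <- match.arg(mode)
  feature <- match.arg(feature)
  fm <- resolve_features(x, k, feature, normalize, pseudocount)
  stopifnot(!is.null(fm$labels))
  train_size <- as_per_class(train_size)
  test_size <- as_per_class(test_size)
  set.seed(derive_seed(seed, 0))
  train_idx <- draw_stratified(fm$labels, train_size)
  train_fm <- subset_rows(fm, train_idx)
  res <- if (mode == "dynamic") {
    dectico_select(train_fm, ladder, cls, kspec, A)
  } else {
    static_select(train_fm, ladder, cls, kspec, A)
  }
  opt <- res$rounds[[res$optimal]]
  model <- train_final(restrict_features(train_fm, opt$selected), cls)
  values <- vapply(seq_len(repeats), function(i) {
    set.seed(derive_seed(seed, i))
    idx <- draw_stratified(fm$labels, test_size, exclude = train_idx)
    test_fm <- subset_rows(fm, idx)
    pred <- predict(model, test_fm)
    f1_measure(pred$class, test_fm$labels)
  }, numeric(1))
  new_evaluation_report("generality", values,
                        config = list(train_size = train_size,
                                      test_size = test_size,
                                      repeats = repeats, mode = mode,
                                      seed = seed,
                                      optimal_n = opt$n))
}

derive_seed <- function(seed, counter) {
  (as.integer(seed) * 1009L + counter) %% 2147483647L
}

new_evaluation_report <- function(mode, values, config) {
  structure(list(mode = mode, values = values, mean = mean(values),
                 sd = stats::sd(values), config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  metric <- if (x$mode == "stability") "LOOCV accuracy" else "F1-measure"
  cat(x$mode, "test:", length(x$values), "repeats\n")
  cat(sprintf("  %s: mean = %.4f, sd = %.4f\n", metric, x$mean, x$sd))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per repeat plus `mean` and `sd` summary rows.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_evaluation_report <- function(report, path) {
  df <- data.frame(repeat_id = c(seq_along(report$values), "mean", "sd"),
                   value = c(report$values, report$mean, report$sd))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
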