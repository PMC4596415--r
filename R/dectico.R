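#' Fit an alignment-free metagenomic sample classifier
#'
#' The main entry point: extracts per-sample oligonucleotide features
#' (intrinsic correlation of oligonucleotides by default, or plain
#' composition), dynamically selects features with kernel partial least
#' squares over a descending ladder, trains a support vector machine and
#' records leave-one-out cross-validation accuracy at every rung, and
#' retains the classifier with maximal accuracy and fewest feature
#' components.
#'
#' @param x A `sample_manifest` (see [read_manifest()]), a path to a
#'   manifest TSV, or a labeled `feature_matrix` built separately with
#'   [build_feature_matrix()].
#' @param k Oligonucleotide length (default 4).  Ignored when `x` is a
#'   prebuilt feature matrix.
#' @param feature `"ico"` (default) or `"composition"`.
#' @param ladder Strictly descending feature-set sizes starting at the
#'   full dimension; `NULL` (default) uses [default_ladder()].
#' @param mode `"dynamic"` (default; weights re-estimated on the selected
#'   subset every round) or `"static"` (one ranking on the full set).
#' @param normalize Per-sample min-max normalization (default `TRUE`).
#' @param positive_label Label mapped to +1 (the diseased class); defaults
#'   to the lexicographically later label.
#' @param cls SVM hyperparameters, a [classifier_spec()].
#' @param kspec Kernel PLS kernel, a [kernel_spec()].
#' @param A Number of kernel PLS components (default `min(5, N - 1)`).
#' @param pseudocount Passed to [ico_vector()].
#' @return An object of class `"dectico"`: the per-round selection trace
#'   (`$selection`), the final classifier (`$classifier`) and the
#'   extraction settings.  Methods: [print.dectico()],
#'   [summary.dectico()], [predict.dectico()], [coef.dectico()],
#'   [plot.dectico()].
#' @examples
#' \donttest{
#' com <- make_community(4, divergence = 1, seed = 3)
#' dir <- tempfile()
#' ds <- simulate_dataset(com, samples_per_class = 6, n_reads = 300,
#'                        read_length = 80, outdir = dir, seed = 3)
#' fit <- dectico(ds$manifest, k = 3, ladder = c(148, 40, 10))
#' fit
#' }
#' @export
dectico <- function(x, k = 4, feature = c("ico", "composition"),
                    ladder = NULL, mode = c("dynamic", "static"),
                    normalize = TRUE, positive_label = NULL,
                    cls = classifier_spec(), kspec = kernel_spec(),
                    A = NULL, pseudocount = 0) {
  feature <- match.arg(feature)
  mode <- match.arg(mode)
  if (is.character(x)) x <- read_manifest(x)
  if (inherits(x, "sample_manifest")) {
    fm <- build_feature_matrix(x, k = k, feature = feature,
                               normalize = normalize,
                               pseudocount = pseudocount,
                               positive_label = positive_label)
  } else if (inherits(x, "feature_matrix")) {
    fm <- x
  } else {
    stop("x must be a manifest (or its path) or a feature_matrix",
         call. = FALSE)
  }
  if (is.null(fm$labels)) {
    stop("fitting requires labeled samples", call. = FALSE)
  }
  sel <- if (mode == "dynamic") {
    dectico_select(fm, ladder, cls, kspec, A)
  } else {
    static_select(fm, ladder, cls, kspec, A)
  }
  opt <- sel$rounds[[sel$optimal]]
  classifier <- train_final(restrict_features(fm, opt$selected), cls)
  classifier$settings <- list(k = k, feature = feature,
                              normalize = normalize,
                              pseudocount = pseudocount)
  structure(list(selection = sel, classifier = classifier,
                 feature_matrix = fm,
                 settings = classifier$settings, mode = mode),
            class = "dectico")
}

#' @export
print.dectico <- function(x, ...) {
  opt <- x$selection$rounds[[x$selection$optimal]]
  cat("dectico fit (", x$settings$feature, " features, k = ",
      x$settings$k, ", ", x$mode, " selection)\n", sep = "")
  cat(sprintf("  optimal: %d feature components, LOOCV accuracy %.4f\n",
              opt$n, opt$accuracy))
  invisible(x)
}

#' Summary of a fitted dectico classifier
#'
#' @param object A `dectico` fit.
#' @param ... Unused.
#' @return The per-round trace as a `data.frame` (round, size, accuracy,
#'   optimal flag), invisibly, after printing it with the fit settings.
#' @export
summary.dectico <- function(object, ...) {
  sel <- object$selection
  df <- data.frame(
    round = vapply(sel$rounds, `[[`, integer(1), "k"),
    n_features = vapply(sel$rounds, `[[`, numeric(1), "n"),
    loocv_accuracy = vapply(sel$rounds, `[[`, numeric(1), "accuracy"))
  df$optimal <- seq_len(nrow(df)) == sel$optimal
  print(object)
  cat("\n")
  print(df, row.names = FALSE)
  lm <- object$feature_matrix$label_map
  if (!is.null(lm)) {
    cat("\nclass encoding: +1 = '", lm[["positive"]], "', -1 = '",
        lm[["negative"]], "'\n", sep = "")
  }
  invisible(df)
}

#' Predict classes for new samples
#'
#' @param object A `dectico` fit.
#' @param newdata A `sample_manifest` (features are re-extracted with the
#'   stored settings) or a `feature_matrix`.
#' @param ... Unused.
#' @return A `data.frame` with `sample_id`, `class` (+1/-1), `label` and
#'   `decision` columns (see [predict.dectico_classifier()]).
#' @export
predict.dectico <- function(object, newdata, ...) {
  if (missing(newdata)) {
    return(predict(object$classifier, object$feature_matrix))
  }
  predict(object$classifier, newdata, ...)
}

#' Feature weights of the optimal round
#'
#' @param object A `dectico` fit.
#' @param ... Unused.
#' @return Named numeric vector: kernel PLS importance weights of the
#'   optimal round's selected features, re-estimated on the restricted
#'   matrix, in decreasing order.
#' @export
coef.dectico <- function(object, ...) {
  opt <- object$selection$rounds[[object$selection$optimal]]
  fm <- restrict_features(object$feature_matrix, opt$selected)
  m <- fit_kpls(fm)
  sort(feature_weights(m, fm), decreasing = TRUE)
}

#' Plot the selection trace
#'
#' LOOCV accuracy against the number of retained feature components
#' (log-scaled x axis), optimal round highlighted.
#'
#' @param x A `dectico` fit.
#' @param ... Passed to [plot.default()].
#' @export
plot.dectico <- function(x, ...) {
  sel <- x$selection
  n <- vapply(sel$rounds, `[[`, numeric(1), "n")
  a <- vapply(sel$rounds, `[[`, numeric(1), "accuracy")
  plot(n, a, type = "b", log = "x", xlab = "feature components retained",
       ylab = "LOOCV accuracy", ylim = c(0, 1),
       main = paste0("feature selection trace (", sel$mode, ")"), ...)
  points(n[sel$optimal], a[sel$optimal], pch = 19, col = "red")
  invisible(x)
}
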