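#' SVM classifier specification
#'
#' Hyperparameters for the support vector machines trained at every rung of
#' the selection ladder.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C Cost parameter (default 1).
#' @param gamma RBF bandwidth: a positive number or `"scale"` (default),
#'   which resolves to `1 / (n_features * var(x))` on the training data.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kernel = c("rbf", "linear"), C = 1,
                            gamma = "scale") {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(C), C > 0)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  else stopifnot(identical(gamma, "scale"))
  structure(list(kernel = kernel, C = C, gamma = gamma),
            class = "classifier_spec")
}

# resolve "scale" gamma on a concrete training matrix
resolve_gamma <- function(spec, X) {
  if (is.numeric(spec$gamma)) return(spec$gamma)
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

# fit an SVM on matrix X / labels y (+1/-1); handles the degenerate
# single-class fold by returning a majority-class stub
svm_fit <- function(X, y, spec) {
  if (length(unique(y)) < 2) {
    structure(list(majority = y[1]), class = "svm_majority_stub")
  } else {
    e1071::svm(X, factor(y, levels = c(-1L, 1L)),
               kernel = if (spec$kernel == "rbf") "radial" else "linear",
               cost = spec$C, gamma = resolve_gamma(spec, X),
               scale = FALSE)
  }
}

svm_predict <- function(fit, X) {
  if (inherits(fit, "svm_majority_stub")) {
    rep(fit$majority, nrow(X))
  } else {
    as.integer(as.character(stats::predict(fit, X)))
  }
}

#' Leave-one-out cross-validation accuracy of an SVM
#'
#' Each sample is predicted by a classifier trained on the remaining N - 1;
#' the accuracy is the fraction predicted correctly.  Deterministic for
#' fixed inputs.  A training fold that contains a single class (possible
#' only for tiny inputs) predicts that majority class, with a message.
#'
#' @param F A labeled `feature_matrix`.
#' @param spec A [classifier_spec()].
#' @return Accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(F, spec = classifier_spec()) {
  stopifnot(inherits(F, "feature_matrix"), !is.null(F$labels))
  X <- F$values
  y <- F$labels
  N <- nrow(X)
  stopifnot(N >= 2, length(unique(y)) == 2)
  correct <- 0L
  warned <- FALSE
  for (i in seq_len(N)) {
    fit <- svm_fit(X[-i, , drop = FALSE], y[-i], spec)
    if (inherits(fit, "svm_majority_stub") && !warned) {
      message("LOOCV fold with a single class: predicting majority class")
      warned <- TRUE
    }
    pred <- svm_predict(fit, X[i, , drop = FALSE])
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / N
}

# validate a descending ladder against the full feature dimension
check_ladder <- function(ladder, d) {
  ladder <- as.integer(ladder)
  if (ladder[1] != d) {
    stop("ladder must start at the full feature dimension (", d,
         "), got ", ladder[1], call. = FALSE)
  }
  if (length(ladder) > 1 && any(diff(ladder) >= 0)) {
    stop("ladder sizes must be strictly descending", call. = FALSE)
  }
  if (ladder[length(ladder)] < 1) stop("ladder sizes must be >= 1",
                                       call. = FALSE)
  ladder
}

#' Default descending feature-selection ladder
#'
#' Geometric halving from the full dimension `d` down to
#' `max(10, d / 2^10)`, used when no ladder is supplied.
#'
#' @param d Full feature dimension.
#' @return Integer vector `n_0 > n_1 > ... > n_N`.
#' @export
default_ladder <- function(d) {
  floor_n <- max(10, d %/% 2^10)
  sizes <- d
  while (sizes[length(sizes)] %/% 2 >= floor_n) {
    sizes <- c(sizes, sizes[length(sizes)] %/% 2)
  }
  as.integer(sizes)
}

run_selection <- function(F0, ladder, cls, kspec, A, dynamic) {
  stopifnot(inherits(F0, "feature_matrix"), !is.null(F0$labels))
  if (length(unique(F0$labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  ladder <- check_ladder(ladder, ncol(F0$values))
  rounds <- list()
  S_prev <- F0$feature_names
  static_weights <- NULL
  if (!dynamic) {
    m0 <- fit_kpls(F0, A = A, spec = kspec)
    static_weights <- feature_weights(m0, F0)
  }
  for (idx in seq_along(ladder)) {
    n_k <- ladder[idx]
    if (idx == 1) {
      S_k <- S_prev                      # rung 0: the entire feature set
    } else if (dynamic) {
      F_prev <- restrict_features(F0, S_prev)
      model <- fit_kpls(F_prev, A = A, spec = kspec)
      w <- feature_weights(model, F_prev)
      S_k <- select_top(w, n_k)
    } else {
      S_k <- select_top(static_weights, n_k)
    }
    F_k <- restrict_features(F0, S_k)
    fit <- svm_fit(F_k$values, F_k$labels, cls)
    a_k <- loocv_accuracy(F_k, cls)
    rounds[[idx]] <- list(k = idx - 1L, n = n_k, selected = S_k,
                          accuracy = a_k, classifier = fit)
    S_prev <- S_k
  }
  opt <- pick_optimal(rounds)
  structure(list(rounds = rounds, optimal = opt,
                 mode = if (dynamic) "dynamic" else "static",
                 ladder = ladder),
            class = "selection_result")
}

#' Dynamic feature selection over a descending ladder
#'
#' The core recursion: starting from the entire feature set `S_0`
#' (`ladder[1]` must equal the feature dimension), each round k refits
#' kernel PLS on the matrix restricted to the currently selected set
#' `S_{k-1}`, re-estimates feature weights, keeps the top `n_k` as `S_k`,
#' trains an SVM on the restriction of the original matrix to `S_k`, and
#' records its LOOCV accuracy `a_k`.  Re-estimating weights on the shrinking
#' subset — rather than ranking once on the full set — is what
#' distinguishes dynamic from static selection: the weight ranking of the
#' entire feature set is not necessarily suitable at every size.
#'
#' Feature selection uses the full training set; LOOCV cross-validates only
#' the classifier training, so the recorded accuracies carry the usual
#' optimistic selection bias when read as generalization estimates.
#'
#' @param F0 Labeled `feature_matrix` (the full feature set).
#' @param ladder Strictly descending integer sizes, starting at the full
#'   dimension.  `NULL` for [default_ladder()].
#' @param cls A [classifier_spec()].
#' @param kspec A [kernel_spec()].
#' @param A Number of kernel PLS components (default `min(5, N - 1)`).
#' @return A `selection_result`: per-round selected sets, LOOCV accuracies
#'   and classifiers, plus the index of the optimal round (maximal
#'   accuracy; ties resolved toward fewer features).
#' @seealso [static_select()], [pick_optimal()]
#' @export
dectico_select <- function(F0, ladder = NULL, cls = classifier_spec(),
                           kspec = kernel_spec(), A = NULL) {
  if (is.null(ladder)) ladder <- default_ladder(ncol(F0$values))
  run_selection(F0, ladder, cls, kspec, A, dynamic = TRUE)
}

#' Static (non-dynamic) feature selection baseline
#'
#' Feature weights are computed once on the full matrix; every rung keeps
#' the top `n_k` of that single ranking.  SVM training and LOOCV per rung
#' are identical to the dynamic mode.
#'
#' @inheritParams dectico_select
#' @return A `selection_result` with `mode = "static"`.
#' @export
static_select <- function(F0, ladder = NULL, cls = classifier_spec(),
                          kspec = kernel_spec(), A = NULL) {
  if (is.null(ladder)) ladder <- default_ladder(ncol(F0$values))
  run_selection(F0, ladder, cls, kspec, A, dynamic = FALSE)
}

#' Pick the optimal selection round
#'
#' The retained classifier has the maximal LOOCV accuracy; among rounds of
#' equal accuracy, the one with the minimal number of feature components
#' wins — the only reading of "minimal size at maximal accuracy" that
#' always yields a unique answer.
#'
#' @param rounds List of selection rounds (each with `accuracy` and `n`).
#' @return Index (into `rounds`) of the optimal round.
#' @export
pick_optimal <- function(rounds) {
  stopifnot(length(rounds) >= 1)
  acc <- vapply(rounds, `[[`, numeric(1), "accuracy")
  n <- vapply(rounds, `[[`, numeric(1), "n")
  best <- which(acc == max(acc))
  best[which.min(n[best])]
}

#' @export
print.selection_result <- function(x, ...) {
  cat("feature selection (", x$mode, " mode), ladder: ",
      paste(x$ladder, collapse = " > "), "\n", sep = "")
  for (r in x$rounds) {
    cat(sprintf("  round %d: n = %6d  LOOCV accuracy = %.4f%s\n",
                r$k, r$n, r$accuracy,
                if (r$k == x$rounds[[x$optimal]]$k) "  <- optimal" else ""))
  }
  invisible(x)
}

#' Train the final classifier on a restricted feature matrix
#'
#' Materializes the optimal classifier: an SVM fitted on the matrix
#' restricted to the chosen feature set, packaged with the feature-name
#' list and (when attached later by [dectico()]) the extraction settings
#' needed to featurize new samples identically.
#'
#' @param F Labeled `feature_matrix` restricted to the chosen features.
#' @param cls A [classifier_spec()].
#' @return A `dectico_classifier`.
#' @export
train_final <- function(F, cls = classifier_spec()) {
  stopifnot(inherits(F, "feature_matrix"), !is.null(F$labels))
  if (length(unique(F$labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  fit <- svm_fit(F$values, F$labels, cls)
  structure(list(fit = fit, features = F$feature_names, spec = cls,
                 train = F, settings = NULL,
                 positive_label = unname(F$label_map["positive"])),
            class = "dectico_classifier")
}

#' @export
print.dectico_classifier <- function(x, ...) {
  cat("dectico classifier:", length(x$features), "feature(s), SVM kernel:",
      x$spec$kernel, "\n")
  if (!is.null(x$settings)) {
    cat("extraction: k =", x$settings$k, "feature =", x$settings$feature,
        if (isTRUE(x$settings$normalize)) "(min-max normalized)", "\n")
  }
  invisible(x)
}

#' Classify unlabeled samples
#'
#' For a manifest, features are extracted with the settings stored in the
#' model (same k, feature type, pseudocount and per-sample normalization),
#' restricted to the stored selected set in stored order, and classified.
#' A prebuilt `feature_matrix` may be passed instead, in which case it must
#' contain every stored feature column.
#'
#' @param object A `dectico_classifier`.
#' @param newdata A `sample_manifest` or a `feature_matrix`.
#' @param ... Unused.
#' @return A `data.frame` with columns `sample_id`, `class` (+1/-1),
#'   `label` (original label string, when the model records the encoding)
#'   and `decision` (signed distance to the separating surface).
#' @export
predict.dectico_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "sample_manifest")) {
    if (nrow(newdata) == 0) {
      return(data.frame(sample_id = character(), class = integer(),
                        label = character(), decision = numeric()))
    }
    st <- object$settings
    if (is.null(st)) {
      stop("classifier carries no extraction settings; ",
           "pass a feature_matrix instead", call. = FALSE)
    }
    fm <- build_feature_matrix(newdata, k = st$k, feature = st$feature,
                               normalize = st$normalize,
                               pseudocount = st$pseudocount,
                               canonical = isTRUE(st$canonical))
  } else if (inherits(newdata, "feature_matrix")) {
    fm <- newdata
  } else {
    stop("newdata must be a sample_manifest or feature_matrix",
         call. = FALSE)
  }
  fm <- restrict_features(fm, object$features)
  cls <- svm_predict(object$fit, fm$values)
  dec <- if (inherits(object$fit, "svm_majority_stub")) {
    rep(NA_real_, nrow(fm$values))
  } else {
    drop(attr(stats::predict(object$fit, fm$values,
                             decision.values = TRUE), "decision.values"))
  }
  out <- data.frame(sample_id = fm$sample_ids, class = cls,
                    stringsAsFactors = FALSE)
  lm <- object$train$label_map
  if (!is.null(lm)) {
    out$label <- ifelse(cls == 1L, lm[["positive"]], lm[["negative"]])
  }
  out$decision <- dec
  out
}
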