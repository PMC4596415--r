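#' Kernel specification
#'
#' @param kind `"gaussian"` (default) or `"linear"`.
#' @param gamma Gaussian bandwidth: a positive number, or
#'   `"median-heuristic"` (default) to set gamma to the reciprocal of the
#'   median nonzero pairwise squared distance between samples.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("gaussian", "linear"),
                        gamma = "median-heuristic") {
  kind <- match.arg(kind)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  else stopifnot(identical(gamma, "median-heuristic"))
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' Compute the sample-by-sample kernel matrix
#'
#' Linear: inner products of feature rows.  Gaussian:
#' `exp(-gamma * ||x_a - x_b||^2)` with the median heuristic resolving
#' gamma from the data when requested.  The result is symmetric positive
#' semidefinite.
#'
#' @param F A `feature_matrix` (or plain numeric matrix) with N >= 2 rows.
#' @param spec A [kernel_spec()].
#' @return N x N numeric kernel matrix; for gaussian kernels the resolved
#'   gamma is attached as attribute `"gamma"`.
#' @export
compute_kernel <- function(F, spec = kernel_spec()) {
  X <- if (inherits(F, "feature_matrix")) F$values else as.matrix(F)
  stopifnot(nrow(X) >= 2, inherits(spec, "kernel_spec"))
  if (spec$kind == "linear") return(tcrossprod(X))
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  gamma <- spec$gamma
  if (identical(gamma, "median-heuristic")) {
    nz <- d2[upper.tri(d2)]
    nz <- nz[nz > 0]
    if (length(nz) == 0) {
      warning("all sample rows identical; median-heuristic gamma ",
              "undefined, falling back to gamma = 1", call. = FALSE)
      gamma <- 1
    } else {
      gamma <- 1 / stats::median(nz)
    }
  }
  structure(exp(-gamma * d2), gamma = gamma)
}

#' Fit kernel partial least squares to a binary response
#'
#' Kernel PLS extracts, in a kernel-induced feature space, a sequence of
#' orthonormal score vectors maximally covarying with the class response —
#' the kernel NIPALS construction: the kernel matrix is double-centered,
#' and per component the score is `t = K y` (normalized), the response
#' loading `q = t'y`, followed by deflation
#' `K <- (I - t t') K (I - t t')` and `y <- y - t q`.  With a linear kernel
#' this reproduces classical PLS1 on centered data component for
#' component.
#'
#' @param F A `feature_matrix` whose `labels` are +1/-1.
#' @param A Number of components, `1 <= A <= N - 1`.
#' @param spec A [kernel_spec()].
#' @return A `kpls_model`: list with `scores` (N x A orthonormal), `q`
#'   (response loadings), `residual` (response residual after A
#'   deflations), `A`, and the resolved kernel spec.
#' @export
fit_kpls <- function(F, A = NULL, spec = kernel_spec()) {
  stopifnot(inherits(F, "feature_matrix"))
  y <- F$labels
  if (is.null(y)) stop("feature matrix carries no labels", call. = FALSE)
  N <- length(y)
  if (length(unique(y)) < 2) {
    stop("response has zero variance (all samples in one class)",
         call. = FALSE)
  }
  if (is.null(A)) A <- min(5L, N - 1L)
  stopifnot(A >= 1, A <= N - 1)
  K <- compute_kernel(F, spec)
  gamma <- attr(K, "gamma")
  # double-centering: work with centered response and centered kernel
  J <- diag(N) - matrix(1 / N, N, N)
  Kc <- J %*% K %*% J
  yr <- y - mean(y)
  scores <- matrix(0, N, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    t_a <- drop(Kc %*% yr)
    nrm <- sqrt(sum(t_a^2))
    if (nrm < 1e-12) {
      # response orthogonal to the remaining kernel space
      scores <- scores[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      A <- a - 1L
      if (A == 0L) {
        scores <- matrix(0, N, 1)
        q <- 0
        A <- 1L
      }
      break
    }
    t_a <- t_a / nrm
    q[a] <- sum(t_a * yr)
    scores[, a] <- t_a
    P <- diag(N) - tcrossprod(t_a)
    Kc <- P %*% Kc %*% P
    yr <- yr - t_a * q[a]
  }
  structure(list(scores = scores, q = q, residual = yr, A = A,
                 kind = spec$kind, gamma = gamma, n = N),
            class = "kpls_model")
}

#' @export
print.kpls_model <- function(x, ...) {
  cat("kernel PLS model:", x$A, "component(s),", x$n, "samples, kernel:",
      x$kind,
      if (x$kind == "gaussian") paste0("(gamma = ", signif(x$gamma, 4), ")"),
      "\n")
  cat("residual response norm:", signif(sqrt(sum(x$residual^2)), 4), "\n")
  invisible(x)
}

#' Per-feature importance weights from a fitted kernel PLS model
#'
#' The weight of feature j aggregates, over components, the squared
#' covariance of the (centered, unit-norm) feature column with each score,
#' weighted by the squared response loading:
#' `w_j = sum_a q_a^2 (x~_j' t_a)^2`.  Zero-variance columns get weight 0.
#' This VIP-style projection scores how much each original feature drives
#' the response-predictive components; it is the quantity the dynamic
#' selection recursion re-estimates at every rung.
#'
#' @param model A `kpls_model` fitted on the rows of `F`.
#' @param F The `feature_matrix` the model was fitted on.
#' @return Named non-negative numeric vector, one weight per feature.
#' @export
feature_weights <- function(model, F) {
  stopifnot(inherits(model, "kpls_model"), inherits(F, "feature_matrix"))
  X <- F$values
  stopifnot(nrow(X) == model$n)
  Xc <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(Xc^2))
  keep <- nrm > 0
  Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2, nrm[keep], "/")
  # (features x A) covariances of scaled columns with scores
  cv <- crossprod(Xc, model$scores)
  w <- drop(cv^2 %*% model$q^2)
  w[!keep] <- 0
  stats::setNames(w, F$feature_names)
}

#' Select the n highest-weighted features
#'
#' Ties are broken by canonical feature-name order, making selection
#' deterministic.
#'
#' @param weights Named weight vector (from [feature_weights()]).
#' @param n Number of features to keep, `1 <= n <= length(weights)`.
#' @return Character vector of the selected feature names, ordered by
#'   decreasing weight.
#' @export
select_top <- function(weights, n) {
  stopifnot(!is.null(names(weights)))
  n <- as.integer(n)
  if (n < 1 || n > length(weights)) {
    stop("n must be between 1 and ", length(weights), call. = FALSE)
  }
  ord <- order(-weights, names(weights), method = "radix")
  names(weights)[ord][seq_len(n)]
}
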