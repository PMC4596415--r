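test_that("kernel matrices match direct evaluation and are symmetric PSD", {
  # orthogonal unit rows, linear kernel
  K <- compute_kernel(rbind(c(1, 0), c(0, 1)), kernel_spec("linear"))
  expect_equal(unclass(K), diag(2))
  # gaussian: diagonal 1, matches brute-force elementwise evaluation
  set.seed(21)
  X <- matrix(rnorm(5 * 8), 5, 8)
  K <- compute_kernel(X, kernel_spec("gaussian", gamma = 0.5))
  expect_equal(diag(K), rep(1, 5), ignore_attr = TRUE)
  brute <- outer(1:5, 1:5, Vectorize(function(a, b) {
    exp(-0.5 * sum((X[a, ] - X[b, ])^2))
  }))
  expect_equal(unclass(K), brute, ignore_attr = TRUE)
  # symmetry + PSD for both kernels on random inputs
  for (spec in list(kernel_spec("linear"), kernel_spec("gaussian"))) {
    K <- compute_kernel(matrix(rnorm(10 * 6), 10, 6), spec)
    expect_equal(unclass(K), t(unclass(K)))
    expect_true(all(eigen(K, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))
  }
})

test_that("median-heuristic gamma resolves, with fallback on identical rows", {
  X <- matrix(rnorm(12), 4, 3)
  K <- compute_kernel(X, kernel_spec("gaussian"))
  d2 <- as.matrix(dist(X))^2
  expect_equal(attr(K, "gamma"), 1 / median(d2[upper.tri(d2)]))
  same <- matrix(1, 3, 2)
  expect_warning(K2 <- compute_kernel(same, kernel_spec("gaussian")),
                 "identical")
  expect_equal(attr(K2, "gamma"), 1)
})

test_that("linear-kernel KPLS reproduces textbook PLS1 scores up to sign", {
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 50), 20, 50)
    y <- sample(rep(c(-1L, 1L), 10))
    fm <- dectico:::new_feature_matrix(paste0("s", 1:20),
                                       paste0("f", 1:50), X, y)
    m <- fit_kpls(fm, A = 3, spec = kernel_spec("linear"))
    oracle <- pls1_scores(X, y, 3)
    for (a in 1:3) {
      err <- min(max(abs(m$scores[, a] - oracle[, a])),
                 max(abs(m$scores[, a] + oracle[, a])))
      expect_lt(err, 1e-8)
    }
  }
})

test_that("KPLS scores are orthonormal and deflation drives the residual down", {
  fm <- random_fm(41, n = 15, d = 30)
  prev <- Inf
  for (A in c(1, 3, 7, 14)) {
    m <- fit_kpls(fm, A = A, spec = kernel_spec("linear"))
    expect_equal(crossprod(m$scores), diag(m$A), tolerance = 1e-8,
                 ignore_attr = TRUE)
    rn <- sqrt(sum(m$residual^2))
    expect_lte(rn, prev + 1e-12)
    prev <- rn
  }
  # full-rank kernel, A = N-1: response fully explained
  expect_lt(sqrt(sum(fit_kpls(fm, A = 14,
                              spec = kernel_spec("linear"))$residual^2)),
            1e-6)
})

test_that("KPLS rejects degenerate responses", {
  fm <- random_fm(5, n = 10, d = 5)
  fm$labels <- rep(1L, 10)
  expect_error(fit_kpls(fm, A = 2), "one class")
  fm$labels <- NULL
  expect_error(fit_kpls(fm, A = 2), "no labels")
})

test_that("feature weights surface the label-aligned column", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 24
    y <- sample(rep(c(-1L, 1L), n / 2))
    X <- cbind(as.numeric(y), matrix(rnorm(n * 30), n, 30))
    fm <- dectico:::new_feature_matrix(
      paste0("s", 1:n), c("signal", paste0("noise", 1:30)), X, y)
    m <- fit_kpls(fm, A = 3, spec = kernel_spec("linear"))
    w <- feature_weights(m, fm)
    if (names(which.max(w)) == "signal") hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("weights are non-negative, zero for constants, equivariant", {
  fm <- random_fm(7, n = 12, d = 8)
  fm$values[, 3] <- 5  # constant column
  m <- fit_kpls(fm, A = 2)
  w <- feature_weights(m, fm)
  expect_true(all(w >= 0))
  expect_equal(unname(w[3]), 0)
  # permuting columns permutes weights identically
  perm <- c(4, 1, 8, 2, 7, 3, 5, 6)
  fm2 <- dectico:::new_feature_matrix(fm$sample_ids,
                                      fm$feature_names[perm],
                                      fm$values[, perm], fm$labels)
  w2 <- feature_weights(fit_kpls(fm2, A = 2), fm2)
  expect_equal(w2, w[perm])
})

test_that("planted-feature weight rank improves as noise shrinks", {
  med_rank <- function(sigma) {
    ranks <- vapply(1:10, function(seed) {
      set.seed(seed)
      n <- 30
      y <- sample(rep(c(-1L, 1L), n / 2))
      X <- cbind(y + rnorm(n, sd = sigma), matrix(rnorm(n * 40), n, 40))
      fm <- dectico:::new_feature_matrix(
        paste0("s", 1:n), c("planted", paste0("x", 1:40)), X, y)
      w <- feature_weights(fit_kpls(fm, A = 3), fm)
      which(names(sort(w, decreasing = TRUE)) == "planted")
    }, numeric(1))
    median(ranks)
  }
  expect_lte(med_rank(0.3), med_rank(3))
})

test_that("top-n selection orders by weight with canonical tie-break", {
  expect_equal(select_top(c(a = 3, b = 1, c = 2), 2), c("a", "c"))
  expect_equal(select_top(c(b = 1, c = 1, a = 1), 2), c("a", "b"))
  w <- c(x = 2, y = 1, z = 3)
  expect_setequal(select_top(w, 3), names(w))
  expect_error(select_top(w, 0), "between")
  expect_error(select_top(w, 4), "between")
})
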