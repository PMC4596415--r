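test_that("LOOCV is perfect on separable clusters and fails the N=2 case", {
  y <- rep(c(-1L, 1L), each = 5)
  X <- matrix(c(rnorm(5, -3, 0.1), rnorm(5, 3, 0.1)), ncol = 1)
  fm <- dectico:::new_feature_matrix(paste0("s", 1:10), "x", X, y)
  expect_equal(loocv_accuracy(fm), 1.0)

  # N = 2, one per class: every fold trains on one class, the majority
  # rule predicts that class, and is always wrong
  fm2 <- dectico:::new_feature_matrix(c("a", "b"), "x",
                                      matrix(c(-1, 1), 2, 1),
                                      c(-1L, 1L))
  expect_message(acc <- loocv_accuracy(fm2, classifier_spec("linear")),
                 "single class")
  expect_equal(acc, 0)
})

test_that("LOOCV on indistinguishable rows cannot beat the class prior", {
  set.seed(77)
  y <- sample(rep(c(-1L, 1L), 10))
  fm <- dectico:::new_feature_matrix(paste0("s", 1:20), c("a", "b"),
                                     matrix(1, 20, 2), y)
  # with identical rows every fold predicts its training majority, which
  # for balanced labels is always the held-out sample's opposite class:
  # the leave-one-out anti-learning floor, far below the 0.5 prior
  expect_lte(loocv_accuracy(fm), 0.5)
  # with noise features (still no signal) accuracy stays near the prior
  fm$values <- matrix(rnorm(40), 20, 2)
  acc <- loocv_accuracy(fm)
  expect_gte(acc, 0.1)
  expect_lte(acc, 0.9)
})

test_that("dynamic selection nests, recovers planted features, is deterministic", {
  pl <- make_planted(7)
  res <- dectico_select(pl$fm, ladder = c(1000, 100, 10))
  expect_s3_class(res, "selection_result")
  expect_length(res$rounds, 3)
  # nestedness by construction, asserted
  for (k in 2:3) {
    expect_true(all(res$rounds[[k]]$selected %in%
                    res$rounds[[k - 1]]$selected))
  }
  expect_true(all(vapply(res$rounds, `[[`, numeric(1), "accuracy") >= 0))
  expect_true(all(vapply(res$rounds, `[[`, numeric(1), "accuracy") <= 1))
  # planted signal at delta = 2 is linearly separable at some rung
  expect_equal(max(vapply(res$rounds, `[[`, numeric(1), "accuracy")), 1)
  # final rung recovers >= 8 of 10 planted features
  expect_gte(length(intersect(res$rounds[[3]]$selected, pl$planted)), 8)
  # identical inputs, identical result
  res2 <- dectico_select(pl$fm, ladder = c(1000, 100, 10))
  expect_identical(res$rounds, res2$rounds)
})

test_that("identity ladder yields the full-feature classifier only", {
  pl <- make_planted(3, n = 20, d = 50, n_inf = 5)
  res <- dectico_select(pl$fm, ladder = 50)
  expect_length(res$rounds, 1)
  expect_equal(res$rounds[[1]]$n, 50)
  expect_equal(res$optimal, 1L)
  # single-rung static and dynamic coincide
  sta <- static_select(pl$fm, ladder = 50)
  expect_equal(sta$rounds[[1]]$selected, res$rounds[[1]]$selected)
  expect_equal(sta$rounds[[1]]$accuracy, res$rounds[[1]]$accuracy)
})

test_that("static mode ranks once and its rungs are nested by construction", {
  pl <- make_planted(13, n = 24, d = 200, n_inf = 6)
  res <- static_select(pl$fm, ladder = c(200, 50, 10))
  expect_equal(res$mode, "static")
  for (k in 2:3) {
    expect_true(all(res$rounds[[k]]$selected %in%
                    res$rounds[[k - 1]]$selected))
  }
  # rung sets are prefixes of one global ranking
  expect_equal(res$rounds[[3]]$selected, res$rounds[[2]]$selected[1:10])
})

test_that("ladder validation catches mismatches and non-descent", {
  pl <- make_planted(1, n = 10, d = 20, n_inf = 2)
  expect_error(dectico_select(pl$fm, ladder = c(19, 5)), "full feature")
  expect_error(dectico_select(pl$fm, ladder = c(20, 10, 10)), "descending")
  fm <- pl$fm; fm$labels <- rep(1L, 10)
  expect_error(dectico_select(fm, ladder = c(20, 5)), "single class")
})

test_that("default ladder halves geometrically down to its floor", {
  l <- default_ladder(852)
  expect_equal(l[1], 852)
  expect_true(all(diff(l) < 0))
  expect_gte(l[length(l)], 10)
  expect_equal(default_ladder(16), c(16L))
})

test_that("optimal round maximizes accuracy, ties prefer fewer features", {
  mk <- function(a, n) Map(function(x, y) list(accuracy = x, n = y), a, n)
  expect_equal(pick_optimal(mk(c(0.8, 0.9, 0.9), c(100, 50, 10))), 3L)
  expect_equal(pick_optimal(mk(c(0.95, 0.90), c(100, 50))), 1L)
  expect_equal(pick_optimal(mk(0.5, 10)), 1L)
})

test_that("final classifier trains, predicts, and enforces feature contract", {
  pl <- make_planted(17, n = 20, d = 40, n_inf = 5)
  model <- train_final(pl$fm)
  pred <- predict(model, pl$fm)
  expect_equal(pred$class, pl$fm$labels)  # separable: perfect training fit
  # missing feature column is named in the error
  fm_missing <- dectico:::new_feature_matrix(
    pl$fm$sample_ids, pl$fm$feature_names[-5],
    pl$fm$values[, -5], pl$fm$labels)
  expect_error(predict(model, fm_missing), "f0005")
  # empty manifest -> empty prediction table
  model$settings <- list(k = 2, feature = "ico", normalize = TRUE,
                         pseudocount = 0)
  empty <- dectico:::as_manifest(character(0), list())
  expect_equal(nrow(predict(model, empty)), 0)
})

test_that("dynamic beats or ties static on planted data across seeds", {
  wins <- 0L
  for (seed in 1:20) {
    pl <- make_planted(seed, n = 24, d = 300, n_inf = 6, delta = 1)
    lad <- c(300, 30, 10)
    dyn <- dectico_select(pl$fm, ladder = lad)
    sta <- static_select(pl$fm, ladder = lad)
    best <- function(r) max(vapply(r$rounds, `[[`, numeric(1), "accuracy"))
    if (best(dyn) >= best(sta)) wins <- wins + 1L
  }
  expect_gte(wins, 14L)
})
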