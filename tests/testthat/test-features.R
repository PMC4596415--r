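test_that("k-mer counting matches direct enumeration on worked examples", {
  expect_equal(count_kmers("ACGT", 2)$counts[c("AC", "CG", "GT")],
               c(AC = 1, CG = 1, GT = 1))
  expect_equal(unname(count_kmers("AAAA", 2)$counts["AA"]), 3)
  # ambiguous-base windows are skipped
  cnt <- count_kmers("ACGNACG", 2)$counts
  expect_equal(cnt[c("AC", "CG")], c(AC = 2, CG = 2))
  expect_equal(sum(cnt), 4)
})

test_that("k-mer counting agrees with the naive substring oracle", {
  set.seed(101)
  for (rep in 1:100) {
    len <- sample(1:60, 1)
    k <- sample(1:5, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.08)), collapse = "")
    got <- suppressWarnings(count_kmers(s, k)$counts)
    want <- naive_kmer_counts(s, k)
    nz <- got[got > 0]
    expect_equal(length(nz), length(want),
                 label = paste0("seq=", s, " k=", k))
    if (length(want)) {
      expect_setequal(names(want), names(nz))
      expect_equal(as.numeric(nz), as.numeric(want[names(nz)]),
                   label = paste0("seq=", s, " k=", k))
    }
  }
})

test_that("counts pool across reads and k beyond read length warns", {
  expect_equal(count_kmers(c("ACG", "ACG"), 2)$counts[c("AC", "CG")],
               c(AC = 2, CG = 2))
  expect_warning(tb <- count_kmers(c("ACG"), 5), "no countable")
  expect_equal(tb$total, 0)
})

test_that("composition vector is the normalized count table", {
  v <- composition_vector(count_kmers("ACGT", 2))
  expect_length(v, 16)
  expect_equal(sum(v), 1)
  expect_equal(unname(v[c("C:AC", "C:CG", "C:GT")]), rep(1 / 3, 3))
  expect_error(suppressWarnings(
    composition_vector(count_kmers("A", 2))), "no countable")
})

test_that("composition of a long uniform sequence is near-uniform", {
  s <- random_dna(1e6, seed = 11)
  v <- composition_vector(count_kmers(s, 4))
  expect_true(all(abs(v - 1 / 256) < 5e-4))
})

test_that("ICO vector length obeys the dimension law for k = 2..8", {
  dim_law <- function(k) (k - 1) * 4^k + sum(4^(1:(k - 1)))
  for (k in 2:8) {
    expect_length(ico_feature_names(k), dim_law(k))
  }
  # and the computed vectors themselves for small k
  s <- random_dna(2000, seed = 2)
  for (k in 2:5) expect_length(ico_vector(s, k), dim_law(k))
  expect_equal(dim_law(3), 148)
  expect_equal(dim_law(4), 852)
  expect_equal(dim_law(8), 480596)
})

test_that("periodic AC string reproduces the hand-computed ICO", {
  v <- ico_vector(strrep("AC", 10000), k = 2)
  expect_equal(unname(v["F:1:A:C"]), 2, tolerance = 1e-3)
  expect_equal(unname(v["F:1:C:A"]), 2, tolerance = 1e-3)
  others <- v[startsWith(names(v), "F:") &
              !names(v) %in% c("F:1:A:C", "F:1:C:A")]
  expect_true(all(others == 0))
  expect_equal(unname(v[c("I:1:A", "I:1:C", "I:1:G", "I:1:T")]),
               c(1, 1, 0, 0), tolerance = 1e-3)
})

test_that("ICO approaches the independence limit on iid sequence", {
  s <- random_dna(1e6, seed = 42)
  v <- ico_vector(s, k = 3)
  f <- v[startsWith(names(v), "F:")]
  i <- v[startsWith(names(v), "I:")]
  expect_true(all(abs(f - 1) < 0.05))
  expect_true(all(abs(i) < 0.01))
})

test_that("ICO rejects k < 2 and empty count tables", {
  expect_error(ico_vector("ACGT", 1), "k >= 2")
  expect_error(suppressWarnings(ico_vector("ACG", 8)), "no countable")
})

test_that("ICO is invariant to read order within a sample", {
  set.seed(9)
  reads <- replicate(30, random_dna(60))
  expect_identical(ico_vector(reads, 3), ico_vector(rev(reads), 3))
  expect_identical(count_kmers(reads, 4)$counts,
                   count_kmers(sample(reads), 4)$counts)
})

test_that("min-max normalization contracts", {
  expect_equal(minmax_normalize(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(2, 2, 2)), c(0, 0, 0))
  v <- c(0, 0.25, 0.3, 1)
  expect_equal(minmax_normalize(v), v)  # idempotent on [0,1]-spanning input
  set.seed(4)
  for (i in 1:20) {
    out <- minmax_normalize(rnorm(10))
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(range(out), c(0, 1))
  }
})

test_that("feature matrices build with labels, names, normalization", {
  set.seed(12)
  files <- vapply(1:4, function(i) {
    write_fasta(replicate(20, random_dna(50)))
  }, character(1))
  mpath <- write_manifest(paste0("s", 1:4), files,
                          c("case", "ctrl", "case", "ctrl"))
  m <- read_manifest(mpath)
  expect_message(fm <- build_feature_matrix(m, k = 2, feature = "ico"),
                 "positive class")
  expect_equal(dim(fm), c(4L, 20L))
  expect_equal(fm$feature_names, ico_feature_names(2))
  # "ctrl" is lexicographically later -> +1 by default
  expect_equal(fm$labels, c(-1L, 1L, -1L, 1L))
  fm2 <- build_feature_matrix(m, k = 2, positive_label = "case")
  expect_equal(fm2$labels, c(1L, -1L, 1L, -1L))
  # normalized rows span [0, 1]
  expect_true(all(apply(fm$values, 1, min) == 0))
  expect_true(all(apply(fm$values, 1, max) == 1))
  # identical read sets give identical rows
  mpath2 <- write_manifest(c("a", "b"), c(files[1], files[1]))
  fm3 <- build_feature_matrix(read_manifest(mpath2), k = 2)
  expect_identical(fm3$values[1, ], fm3$values[2, ])
  # a sample with zero countable k-mers is reported by name
  nn <- write_fasta("NNNNNNNN")
  bad <- read_manifest(write_manifest(c("ok", "allN"), c(files[1], nn)))
  expect_error(suppressWarnings(build_feature_matrix(bad, k = 3)), "allN")
})
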