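# Shared fixtures and independent oracles for the test suite.

# naive substring k-mer counter: the brute-force oracle count_kmers is
# checked against (windows with any non-ACGT letter are skipped)
naive_kmer_counts <- function(seqs, k) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    if (nchar(s) < k) next
    for (start in 1:(nchar(s) - k + 1)) {
      w <- substr(s, start, start + k - 1)
      if (grepl("[^ACGT]", w)) next
      counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer(0) else out[order(names(out))]
}

# textbook NIPALS PLS1: scores of X (column-centered) against y,
# independent of the kernel implementation under test
pls1_scores <- function(X, y, A) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  T <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    t <- drop(Xc %*% crossprod(Xc, yc))
    t <- t / sqrt(sum(t^2))
    T[, a] <- t
    Xc <- Xc - t %*% crossprod(t, Xc)
    yc <- yc - t * sum(t * yc)
  }
  T
}

# closed-form paired t-test (independent of stats::t.test)
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# a labeled feature matrix with a planted signal: n_inf informative
# columns whose class means differ by delta, the rest standard noise
make_planted <- function(seed, n = 40, d = 1000, n_inf = 10, delta = 2) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1L, seq_len(n_inf)] <- X[y == 1L, seq_len(n_inf)] + delta
  nm <- sprintf("f%04d", seq_len(d))
  fm <- dectico:::new_feature_matrix(sprintf("s%02d", seq_len(n)), nm, X, y)
  list(fm = fm, planted = nm[seq_len(n_inf)])
}

# random feature matrix without structure
random_fm <- function(seed, n = 20, d = 50, labels = TRUE) {
  set.seed(seed)
  y <- if (labels) rep(c(-1L, 1L), length.out = n) else NULL
  dectico:::new_feature_matrix(sprintf("s%02d", seq_len(n)),
                               sprintf("f%03d", seq_len(d)),
                               matrix(rnorm(n * d), n, d), y)
}

# write a small FASTA file, returning its path
write_fasta <- function(seqs, path = tempfile(fileext = ".fa"),
                        ids = paste0("r", seq_along(seqs))) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# write a manifest TSV next to its sequence files
write_manifest <- function(sample_id, paths, label = NULL,
                           path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample_id = sample_id, paths = paths)
  if (!is.null(label)) df$label <- label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
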