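#' Count overlapping k-mers across all reads of a sample
#'
#' Counts every overlapping window of length `k` (stride 1) within each read
#' and sums the counts over the whole read set: a metagenomic sample is
#' treated as one integrated sequence collection, never as per-read vectors
#' averaged afterwards.  Windows containing any non-A/C/G/T letter (N or
#' other IUPAC ambiguity codes) are skipped; windows never span read
#' boundaries.  No reverse-complement canonicalization is applied unless
#' requested.
#'
#' @param reads A `read_set` (see [read_sequences()]) or a character vector
#'   of DNA strings.
#' @param k Oligonucleotide length, an integer >= 1.
#' @param canonical If `TRUE`, each window and its reverse complement are
#'   pooled (strand-insensitive counting).  Off by default: k-mers are
#'   counted as read.
#' @return An object of class `kmer_counts`: list with `k`, `counts` (named
#'   integer vector over all 4^k oligonucleotides in lexicographic
#'   A < C < G < T order) and `total`.
#' @examples
#' count_kmers(c("ACGT"), 2)$counts[c("AC", "CG", "GT")]
#' @export
count_kmers <- function(reads, k, canonical = FALSE) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  stopifnot(is.character(seqs), length(seqs) >= 1)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(x, width = k, step = 1,
                                                 simplify.as = "collapsed")
  if (canonical) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(counts))))
    counts <- counts + counts[rc]
  }
  total <- sum(counts)
  if (total == 0) {
    warning("no countable ", k, "-mers in sample (k exceeds every ",
            "read length or all windows contain ambiguous bases)",
            call. = FALSE)
  }
  structure(list(k = k, counts = counts, total = total),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer count table: k =", x$k, "|", length(x$counts),
      "oligonucleotides |", format(x$total, big.mark = ","),
      "countable windows\n")
  invisible(x)
}

#' Oligonucleotide composition vector
#'
#' The 4^k vector of k-mer occurrence frequencies (count / total) in
#' lexicographic order — the sequence-composition baseline feature against
#' which the intrinsic-correlation feature is compared.
#'
#' @param table A `kmer_counts` object with `total > 0`.
#' @return Named numeric vector of length 4^k summing to 1, names
#'   `C:<kmer>`.
#' @export
composition_vector <- function(table) {
  stopifnot(inherits(table, "kmer_counts"))
  if (table$total == 0) stop("no countable k-mers", call. = FALSE)
  v <- table$counts / table$total
  names(v) <- paste0("C:", names(table$counts))
  v
}

#' Canonical component names of the ICO vector
#'
#' @param k Oligonucleotide length (>= 2).
#' @return Character vector: for each split `m = 1..k-1`, the f-block names
#'   `F:<m>:<i>:<j>` (lexicographic in i then j) followed by the I-block
#'   names `I:<m>:<i>`.
#' @export
ico_feature_names <- function(k) {
  k <- as.integer(k)
  if (k < 2) stop("ICO requires k >= 2 (no split exists for k < 2)",
                  call. = FALSE)
  mers <- lapply(1:(k - 1), all_mers)
  unlist(lapply(1:(k - 1), function(m) {
    n <- k - m
    f <- paste0("F:", m, ":",
                rep(mers[[m]], each = 4^n), ":",
                rep(mers[[n]], times = 4^m))
    c(f, paste0("I:", m, ":", mers[[m]]))
  }), use.names = FALSE)
}

# all length-m oligonucleotides in lexicographic order
all_mers <- function(m) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), m)
}

#' Intrinsic correlation of oligonucleotides (ICO) feature vector
#'
#' For a k-mer split into two consecutive parts i (length m) and j (length
#' n = k - m), the ICO(m, n) descriptor holds, for every pair (i, j), the
#' junction ratio
#' \deqn{f_{ij} = p_{ij} / (p_i p_j)}
#' where \eqn{p_{ij}} is the occurrence probability of the junction i·j
#' among k-mers and \eqn{p_i}, \eqn{p_j} the occurrence probabilities of i
#' and j among m-mers and n-mers respectively (each from its own
#' independent sliding-window count), followed by the average mutual
#' information of each prefix i acquired from its continuations,
#' \deqn{I(i) = \sum_{j \in B} p_{j|i} \log_2\!\big(p_{ij}/(p_i p_j)\big)}
#' with \eqn{p_{j|i}} the conditional continuation probability (k-mer
#' counts with prefix i, row-normalized).  The full ICO for length k
#' concatenates ICO(1, k-1), ICO(2, k-2), ..., ICO(k-1, 1), giving
#' \eqn{(k-1)\,4^k + \sum_{m=1}^{k-1} 4^m} components.
#'
#' Zero conventions: a junction never observed contributes
#' \eqn{f_{ij} = 0} and a zero term to I(i) (0·log ≡ 0); prefixes or
#' suffixes with zero marginal probability contribute zeros throughout.
#'
#' @inheritParams count_kmers
#' @param pseudocount Non-negative count added to every cell of every count
#'   table before probabilities are formed (default 0; for sensitivity
#'   analysis only).
#' @return Named numeric vector (names per [ico_feature_names()]).
#' @examples
#' v <- ico_vector(strrep("AC", 50), k = 2)
#' v[c("F:1:A:C", "F:1:C:A", "I:1:A")]
#' @export
ico_vector <- function(reads, k, pseudocount = 0, canonical = FALSE) {
  k <- as.integer(k)
  if (k < 2) stop("ICO requires k >= 2 (no split exists for k < 2)",
                  call. = FALSE)
  stopifnot(pseudocount >= 0)
  tables <- lapply(1:k, function(w) count_kmers(reads, w, canonical))
  if (tables[[k]]$total == 0) {
    stop("no countable ", k, "-mers in sample", call. = FALSE)
  }
  prob <- lapply(tables, function(tb) {
    cnt <- tb$counts + pseudocount
    cnt / sum(cnt)
  })
  ck <- tables[[k]]$counts + pseudocount

  out <- lapply(1:(k - 1), function(m) {
    n <- k - m
    p_i <- prob[[m]]
    p_j <- prob[[n]]
    # lexicographic k-mer order is row-major in (i, j)
    cij <- matrix(ck, nrow = 4^m, byrow = TRUE)
    pij <- cij / sum(ck)
    denom <- outer(p_i, p_j)
    f <- matrix(0, 4^m, 4^n)
    ok <- cij > 0 & denom > 0
    f[ok] <- pij[ok] / denom[ok]
    rowtot <- rowSums(cij)
    term <- matrix(0, 4^m, 4^n)
    term[ok] <- (cij[ok] / rowtot[row(cij)[ok]]) * log2(f[ok])
    i_block <- rowSums(term)
    i_block[rowtot == 0 | p_i == 0] <- 0
    c(as.vector(t(f)), i_block)
  })
  stats::setNames(unlist(out, use.names = FALSE), ico_feature_names(k))
}

#' Per-sample min-max normalization
#'
#' Rescales a feature vector to \[0, 1\] within the sample:
#' \eqn{v'_i = (v_i - v_{min}) / (v_{max} - v_{min})}, where the extrema are
#' taken among the components of this single vector.  Used because the ICO
#' junction-ratio and mutual-information components (and composition
#' frequencies) live on different magnitudes.  A constant vector maps to all
#' zeros by convention.  Per-feature column scaling across samples is
#' deliberately not used.
#'
#' @param v Non-empty numeric vector.
#' @return Numeric vector in \[0, 1\], same names as `v`.
#' @examples
#' minmax_normalize(c(1, 3, 5))
#' @export
minmax_normalize <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1)
  rng <- range(v)
  if (rng[1] == rng[2]) return(stats::setNames(rep(0, length(v)), names(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

# internal constructor shared by features/seq_io
new_feature_matrix <- function(sample_ids, feature_names, values,
                               labels = NULL, label_map = NULL) {
  stopifnot(nrow(values) == length(sample_ids),
            ncol(values) == length(feature_names))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(sample_ids),
              all(labels %in% c(-1L, 1L)))
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(sample_ids = sample_ids, feature_names = feature_names,
                 values = values, labels = labels, label_map = label_map),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature matrix:", length(x$sample_ids), "samples x",
      length(x$feature_names), "features")
  if (!is.null(x$labels)) {
    cat(" | classes:", sum(x$labels == 1L), "positive /",
        sum(x$labels == -1L), "negative")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# restrict a feature matrix to a named, ordered feature subset
restrict_features <- function(fm, features) {
  missing <- setdiff(features, fm$feature_names)
  if (length(missing)) {
    stop("feature matrix lacks column(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  new_feature_matrix(fm$sample_ids, features,
                     fm$values[, features, drop = FALSE],
                     fm$labels, fm$label_map)
}

#' Extract the feature matrix for all samples of a manifest
#'
#' Runs feature extraction (ICO or composition) sample by sample, in
#' manifest order, and stacks the per-sample vectors into a samples x
#' features matrix.  When `normalize` is set (the default), min-max
#' normalization is applied to each row independently.  Labels, when
#' present, are encoded +1 for the positive (diseased) class and -1
#' otherwise.
#'
#' @param manifest A `sample_manifest` (see [read_manifest()]).
#' @param k Oligonucleotide length.
#' @param feature `"ico"` (default) or `"composition"`.
#' @param normalize Apply per-sample min-max normalization (default `TRUE`).
#' @param positive_label Which label maps to +1.  Defaults to the
#'   lexicographically later of the two labels, with a notice.
#' @inheritParams ico_vector
#' @return A `feature_matrix` with one row per sample; `label_map` records
#'   the label-to-sign encoding.
#' @export
build_feature_matrix <- function(manifest, k,
                                 feature = c("ico", "composition"),
                                 normalize = TRUE, pseudocount = 0,
                                 positive_label = NULL, canonical = FALSE) {
  feature <- match.arg(feature)
  stopifnot(inherits(manifest, "sample_manifest"), nrow(manifest) >= 1)
  rows <- lapply(seq_len(nrow(manifest)), function(r) {
    rs <- read_sequences(unlist(manifest$paths[r]),
                         sample_id = manifest$sample_id[r])
    v <- tryCatch(
      if (feature == "ico") {
        ico_vector(rs, k, pseudocount = pseudocount, canonical = canonical)
      } else {
        composition_vector(count_kmers(rs, k, canonical))
      },
      error = function(e) {
        stop("sample '", manifest$sample_id[r], "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (normalize) minmax_normalize(v) else v
  })
  values <- do.call(rbind, rows)
  labels <- NULL
  label_map <- NULL
  if (any(!is.na(manifest$label))) {
    lab <- sort(unique(manifest$label[!is.na(manifest$label)]))
    if (length(lab) != 2) {
      stop("training manifest must carry exactly two label values",
           call. = FALSE)
    }
    if (is.null(positive_label)) {
      positive_label <- lab[2]
      message("positive class (+1) defaulting to lexicographically later ",
              "label: '", positive_label, "'")
    }
    if (!positive_label %in% lab) {
      stop("positive_label '", positive_label, "' not among manifest labels",
           call. = FALSE)
    }
    labels <- ifelse(manifest$label == positive_label, 1L, -1L)
    label_map <- c(positive = positive_label,
                   negative = setdiff(lab, positive_label))
  }
  new_feature_matrix(manifest$sample_id, colnames(values), values,
                     labels, label_map)
}
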