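DNA <- c("A", "C", "G", "T")

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# decode 0-based context codes to r-mer strings (oldest base most
# significant, so code order == lexicographic order)
decode_context <- function(code, r) {
  m <- matrix("", length(code), r)
  for (t in r:1) {
    m[, t] <- DNA[code %% 4 + 1]
    code <- code %/% 4
  }
  do.call(paste0, asplit(m, 2))
}

#' Build a two-class synthetic community model
#'
#' Each "taxon" is an order-`r` Markov chain over A/C/G/T with
#' Dirichlet-distributed transition rows — a stand-in genome rich enough
#' that intrinsic-correlation features at k > r carry signal beyond
#' mono-nucleotide composition.  The two classes share the taxa but mix
#' them differently: class signal enters through the mixing proportions
#' (a beta-diversity-like contrast), not through mutated genomes.  With
#' divergence `delta`, each class mixing is
#' `(1 - delta) * pi_common + delta * pi_class`, where the two `pi_class`
#' are Dirichlet draws supported on disjoint halves of the taxa — so
#' `delta = 0` makes the classes identical and `delta = 1` gives them
#' disjoint taxon support (with two taxa: mixings (1,0) and (0,1)).
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param order Markov order r (default 2).
#' @param divergence Between-class divergence delta in \[0, 1\].
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @param alpha_transition Dirichlet concentration for transition rows
#'   (default 1: moderately heterogeneous chains).
#' @param alpha_mixing Dirichlet concentration for mixing vectors
#'   (default 2).
#' @return A `community_model`: taxa (each with `initial` over 4^r contexts
#'   and a 4^r x 4 `transitions` matrix), the two class mixing vectors, and
#'   a config echo.
#' @export
make_community <- function(n_taxa, order = 2, divergence = 0.5, seed = 1,
                           alpha_transition = 1, alpha_mixing = 2) {
  stopifnot(n_taxa >= 2, order >= 1)
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1) {
    stop("divergence must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_ctx <- 4L^order
  ctx_names <- decode_context(0:(n_ctx - 1), order)
  taxa <- lapply(seq_len(n_taxa), function(id) {
    trans <- t(vapply(seq_len(n_ctx),
                      function(i) rdirichlet1(rep(alpha_transition, 4)),
                      numeric(4)))
    dimnames(trans) <- list(ctx_names, DNA)
    list(id = paste0("taxon", id), order = order,
         initial = stats::setNames(rdirichlet1(rep(1, n_ctx)), ctx_names),
         transitions = trans)
  })
  pi_common <- rdirichlet1(rep(alpha_mixing, n_taxa))
  half1 <- seq_len(ceiling(n_taxa / 2))
  half2 <- setdiff(seq_len(n_taxa), half1)
  pi_a <- numeric(n_taxa); pi_a[half1] <- rdirichlet1(rep(alpha_mixing, length(half1)))
  pi_b <- numeric(n_taxa); pi_b[half2] <- rdirichlet1(rep(alpha_mixing, length(half2)))
  mixing <- rbind(class1 = (1 - divergence) * pi_common + divergence * pi_a,
                  class2 = (1 - divergence) * pi_common + divergence * pi_b)
  structure(list(taxa = taxa, mixing = mixing,
                 config = list(n_taxa = n_taxa, order = order,
                               divergence = divergence, seed = seed,
                               alpha_transition = alpha_transition,
                               alpha_mixing = alpha_mixing)),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cfg <- x$config
  cat("community model:", cfg$n_taxa, "taxa, Markov order", cfg$order,
      ", divergence =", cfg$divergence, "\n")
  cat("  class mixings (TV distance =",
      signif(sum(abs(x$mixing[1, ] - x$mixing[2, ])) / 2, 3), ")\n")
  invisible(x)
}

# simulate n reads from one taxon's Markov chain, vectorized across reads
simulate_taxon_reads <- function(taxon, n, read_length) {
  r <- taxon$order
  n_ctx <- length(taxon$initial)
  cum <- t(apply(taxon$transitions, 1, cumsum))
  chars <- matrix("", n, read_length)
  ctx0 <- sample.int(n_ctx, n, replace = TRUE, prob = taxon$initial) - 1L
  # the initial context supplies the first r bases
  code <- ctx0
  for (t in r:1) {
    chars[, t] <- DNA[code %% 4 + 1]
    code <- code %/% 4
  }
  for (pos in seq(r + 1, read_length)) {
    u <- stats::runif(n)
    base0 <- rowSums(u > cum[ctx0 + 1L, , drop = FALSE])
    chars[, pos] <- DNA[base0 + 1]
    ctx0 <- (ctx0 %% 4L^(r - 1)) * 4L + base0
  }
  do.call(paste0, asplit(chars, 2))
}

#' Simulate one metagenomic sample
#'
#' Each read independently draws a taxon from the class's mixing vector,
#' an initial context from that taxon's initial distribution, and is
#' extended base by base by the taxon's Markov chain.  Fully deterministic
#' given `seed`.  No sequencing-error model or quality strings are
#' emulated.
#'
#' @param model A [make_community()] model.
#' @param class `1` or `2`: which class's mixing vector to use.
#' @param n_reads Number of reads (>= 1).
#' @param read_length Read length in bp (must exceed the Markov order).
#' @param seed Integer seed.
#' @param sample_id Identifier for the resulting read set.
#' @param path If non-`NULL`, the reads are also written to this path as
#'   FASTA (byte-identical across runs with the same inputs).
#' @return A `read_set`.
#' @export
simulate_sample <- function(model, class, n_reads, read_length, seed = 1,
                            sample_id = paste0("class", class, "_s1"),
                            path = NULL) {
  stopifnot(inherits(model, "community_model"), class %in% c(1, 2),
            n_reads >= 1)
  r <- model$config$order
  if (read_length <= r) {
    stop("read_length must exceed the Markov order (", r, ")",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  mix <- model$mixing[class, ]
  taxon_of <- sample.int(length(model$taxa), n_reads, replace = TRUE,
                         prob = mix)
  seqs <- character(n_reads)
  for (tx in sort(unique(taxon_of))) {
    idx <- which(taxon_of == tx)
    seqs[idx] <- simulate_taxon_reads(model$taxa[[tx]], length(idx),
                                      read_length)
  }
  if (!is.null(path)) {
    fa <- character(2 * n_reads)
    fa[c(TRUE, FALSE)] <- paste0(">", sample_id, "_r", seq_len(n_reads))
    fa[c(FALSE, TRUE)] <- seqs
    writeLines(fa, path)
  }
  structure(list(sample_id = sample_id, sequences = seqs),
            class = "read_set")
}

#' Simulate a labeled two-class dataset on disk
#'
#' Writes `2 * samples_per_class` FASTA files, a labeled manifest TSV and a
#' JSON config echo sufficient for byte-identical regeneration.  Per-sample
#' seeds are derived from the master seed by counter.
#'
#' @inheritParams simulate_sample
#' @param samples_per_class Samples per class.
#' @param outdir Output directory (created if missing).
#' @param labels Length-2 character vector naming classes 1 and 2
#'   (default `c("control", "disease")`).
#' @return Invisibly, a list with `manifest` (a `sample_manifest`),
#'   `manifest_path`, `outdir` and the config echo.
#' @export
simulate_dataset <- function(model, samples_per_class, n_reads,
                             read_length, outdir, seed = 1,
                             labels = c("control", "disease")) {
  stopifnot(inherits(model, "community_model"), samples_per_class >= 1,
            length(labels) == 2)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, mode = 2) != 0) {
    stop("output directory not writable: ", outdir, call. = FALSE)
  }
  ids <- character(0); labs <- character(0); files <- character(0)
  counter <- 0L
  for (cl in 1:2) {
    for (s in seq_len(samples_per_class)) {
      counter <- counter + 1L
      id <- sprintf("%s_s%02d", labels[cl], s)
      fn <- paste0(id, ".fasta")
      simulate_sample(model, cl, n_reads, read_length,
                      seed = derive_seed(seed, counter),
                      sample_id = id, path = file.path(outdir, fn))
      ids <- c(ids, id); labs <- c(labs, labels[cl]); files <- c(files, fn)
    }
  }
  manifest_path <- file.path(outdir, "manifest.tsv")
  utils::write.table(
    data.frame(sample_id = ids, paths = files, label = labs),
    manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  config <- c(model$config,
              list(samples_per_class = samples_per_class,
                   n_reads = n_reads, read_length = read_length,
                   master_seed = seed, labels = labels))
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = as_manifest(ids, as.list(files), labs,
                                        base_dir = outdir),
                 manifest_path = manifest_path, outdir = outdir,
                 config = config))
}
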