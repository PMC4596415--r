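#' Read sequencing reads from FASTA or FASTQ files
#'
#' Reads one or more sequence files (plain or gzip-compressed) and pools all
#' records into a single read set, mirroring the treatment of a metagenomic
#' sample as one integrated sequence collection.  FASTQ quality lines are
#' discarded; sequences are uppercased.  No quality filtering or trimming is
#' performed: any pre-processing is the caller's job.
#'
#' @param paths Character vector of file paths (FASTA or FASTQ, optionally
#'   gzipped).  All records from all files are pooled.
#' @param format `"auto"` (default; detected from the first record character,
#'   `>` for FASTA and `@` for FASTQ), `"fasta"`, or `"fastq"`.
#' @param sample_id Optional sample identifier attached to the result.
#' @return An object of class `read_set`: a list with elements `sample_id`
#'   and `sequences` (character vector of uppercase DNA strings).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT", ">r2", "GGC"), fa)
#' rs <- read_sequences(fa)
#' rs$sequences
#' @export
read_sequences <- function(paths, format = c("auto", "fasta", "fastq"),
                           sample_id = NA_character_) {
  format <- match.arg(format)
  stopifnot(is.character(paths), length(paths) >= 1)
  seqs <- unlist(lapply(paths, function(p) {
    if (!file.exists(p)) stop("sequence file not found: ", p, call. = FALSE)
    fmt <- if (format == "auto") detect_format(p) else format
    s <- tryCatch(
      if (fmt == "fasta") {
        as.character(Biostrings::readDNAStringSet(p, format = "fasta"))
      } else {
        as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
      },
      error = function(e) {
        stop("malformed ", fmt, " file '", p, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (length(s) == 0) stop("empty sequence file: ", p, call. = FALSE)
    if (any(!nzchar(s))) {
      stop("empty sequence record in '", p, "' (record ",
           which(!nzchar(s))[1], ")", call. = FALSE)
    }
    toupper(unname(s))
  }), use.names = FALSE)
  structure(list(sample_id = sample_id, sequences = seqs),
            class = "read_set")
}

# Peek at the first non-empty character, transparently through gzip.
detect_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("empty sequence file: ", path, call. = FALSE)
    if (nzchar(trimws(line))) break
  }
  first <- substr(trimws(line), 1, 1)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop("cannot detect format of '", path,
       "': first record starts with '", first, "'", call. = FALSE)
}

#' Read a sample manifest
#'
#' A manifest is a tab-separated file with a header and columns `sample_id`,
#' `paths` (one or more file paths, comma-joined for samples split across
#' files or lanes; all are pooled into one read set) and an optional `label`
#' column.  A labeled training manifest must carry exactly two distinct
#' labels (binary classification); a manifest without labels is a
#' prediction-mode manifest.
#'
#' @param path Path to the manifest TSV.
#' @return A `data.frame` with columns `sample_id` (character), `paths`
#'   (list of character vectors) and `label` (character, `NA` if absent),
#'   of class `c("sample_manifest", "data.frame")`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "paths") %in% names(df))) {
    stop("manifest must have columns 'sample_id' and 'paths' ",
         "(tab-separated, with header)", call. = FALSE)
  }
  label <- if ("label" %in% names(df)) df$label else rep(NA_character_, nrow(df))
  as_manifest(df$sample_id, strsplit(df$paths, ",", fixed = TRUE), label,
              base_dir = dirname(path))
}

# Build/validate a manifest from its parts; relative paths resolve against
# base_dir (the directory the manifest file lives in).
as_manifest <- function(sample_id, paths, label = NA_character_,
                        base_dir = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(paths)) paths <- as.list(paths)
  if (!is.null(base_dir)) {
    paths <- lapply(paths, function(p) {
      ifelse(file.exists(p), p, file.path(base_dir, p))
    })
  }
  label <- rep_len(as.character(label), length(sample_id))
  lab <- unique(label[!is.na(label)])
  if (length(lab) > 2) {
    stop("a labeled manifest must have exactly two label values, got: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  out$paths <- paths
  out$label <- label
  class(out) <- c("sample_manifest", "data.frame")
  out
}

#' Write and read a feature matrix as TSV
#'
#' The tabular interchange format: first column `sample_id`, then one named
#' column per feature component; an optional `label` column carries class
#' labels.  Values round-trip at full double precision.
#'
#' @param x A `feature_matrix` (see [build_feature_matrix()]).
#' @param path Output/input file path.
#' @return `read_feature_matrix` returns a `feature_matrix`;
#'   `write_feature_matrix` returns `path` invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  df <- data.frame(sample_id = x$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values, check.names = FALSE)
  names(vals) <- x$feature_names
  df <- cbind(df, vals)
  if (!is.null(x$labels)) df$label <- x$labels
  # format() at 17 significant digits preserves doubles exactly
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "label"
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("feature matrix TSV must start with a sample_id column",
         call. = FALSE)
  }
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  feat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(feat) <- "double"
  new_feature_matrix(as.character(df$sample_id), colnames(feat), feat, labels)
}

#' Save and load a trained classifier
#'
#' Serializes a fitted `dectico` model (or the bare classifier returned by
#' [train_final()]) to a self-describing JSON container holding the
#' oligonucleotide length, feature type, normalization convention, selected
#' feature identifiers, SVM hyperparameters and the restricted training data.
#' Loading refits the SVM on the stored data; as libsvm training is
#' deterministic for fixed inputs, the reloaded model reproduces the original
#' predictions exactly.
#'
#' @param model A `dectico` or `dectico_classifier` object.
#' @param path File path for the JSON model container.
#' @return `read_dectico_model` returns the reconstructed object;
#'   `write_dectico_model` returns `path` invisibly.
#' @export
write_dectico_model <- function(model, path) {
  cls <- if (inherits(model, "dectico")) model$classifier else model
  stopifnot(inherits(cls, "dectico_classifier"))
  payload <- list(
    container = "dectico-model",
    schema_version = 1L,
    settings = cls$settings,
    features = cls$features,
    svm = unclass(cls$spec),
    positive_label = cls$positive_label,
    training = list(
      sample_ids = cls$train$sample_ids,
      values = cls$train$values,
      labels = cls$train$labels
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dectico_model
#' @export
read_dectico_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "dectico-model")) {
    stop("'", path, "' is not a dectico model container", call. = FALSE)
  }
  vals <- matrix(as.numeric(p$training$values),
                 nrow = length(p$training$sample_ids),
                 dimnames = list(NULL, p$features))
  fm <- new_feature_matrix(p$training$sample_ids, p$features, vals,
                           as.integer(p$training$labels))
  spec <- classifier_spec(kernel = p$svm$kernel, C = p$svm$C,
                          gamma = if (is.character(p$svm$gamma)) p$svm$gamma
                                  else as.numeric(p$svm$gamma))
  cls <- train_final(fm, spec)
  cls$settings <- p$settings
  cls$positive_label <- p$positive_label
  cls
}
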