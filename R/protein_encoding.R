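#' Construct a set of protein sequences
#'
#' Validates identifiers and residues and returns the container used by the
#' encoding functions: a named character vector of uppercase residue
#' strings.
#'
#' @param sequences Character vector of residue strings.
#' @param ids Character vector of unique, non-empty identifiers; defaults to
#'   the names of `sequences` or `seq1`, `seq2`, ...
#' @param alphabet A [peptide_alphabet()].
#' @param on_invalid What to do with residues outside the alphabet:
#'   `"reject"` (default) raises an error naming the symbol, `"remap"`
#'   replaces them with `"X"`.
#' @return A named character vector of class `protein_set`.
#' @export
protein_set <- function(sequences, ids = NULL,
                        alphabet = peptide_alphabet(),
                        on_invalid = c("reject", "remap")) {
  on_invalid <- match.arg(on_invalid)
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences) || any(!nzchar(ids)) ||
      anyDuplicated(ids)) {
    stop("sequence ids must be unique and non-empty")
  }
  if (any(!nzchar(sequences))) stop("empty sequence for id: ",
                                    paste(ids[!nzchar(sequences)], collapse = ", "))
  letters <- unclass(alphabet)
  pat <- paste0("[^", paste(letters, collapse = ""), "]")
  bad <- grepl(pat, sequences)
  if (any(bad)) {
    if (on_invalid == "reject") {
      offending <- unique(unlist(regmatches(sequences[bad],
                                            gregexpr(pat, sequences[bad]))))
      stop("residue(s) outside the 25-letter alphabet: ",
           paste(offending, collapse = ", "),
           " (in ", paste(ids[bad], collapse = ", "), ")")
    }
    sequences[bad] <- gsub(pat, "X", sequences[bad])
  }
  names(sequences) <- ids
  structure(sequences, class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat("<protein_set> ", length(x), " sequence(s), lengths ",
      min(nchar(x)), "-", max(nchar(x)), "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from FASTA or CSV
#'
#' The CSV reader expects columns `protein_id` and `sequence`.
#'
#' @param path Path to a FASTA file or a CSV file.
#' @param format `"fasta"` or `"csv"`; guessed from the extension by
#'   default.
#' @inheritParams protein_set
#' @return A [protein_set()].
#' @export
read_proteins <- function(path, format = NULL,
                          alphabet = peptide_alphabet(),
                          on_invalid = c("reject", "remap")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "sequence")
    if (!all(need %in% names(tab))) {
      stop("protein CSV must have columns: ", paste(need, collapse = ", "))
    }
    protein_set(tab$sequence, tab$protein_id, alphabet, on_invalid)
  } else {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    protein_set(as.character(aa), ids, alphabet, on_invalid)
  }
}

n_windows <- function(L, n, denominator = c("windows", "L-1")) {
  denominator <- match.arg(denominator)
  if (denominator == "windows") L - n + 1L else L - 1L
}

count_peptides <- function(seq, n, alphabet) {
  L <- nchar(seq)
  if (L < n) stop("sequence shorter than peptide order n = ", n)
  starts <- seq_len(L - n + 1L)
  windows <- substring(seq, starts, starts + n - 1L)
  idx <- peptide_index(windows, alphabet)
  counts <- integer(25L^n)
  tab <- table(idx)
  counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
  counts
}

#' Polypeptide (n-mer) frequency vector of one sequence
#'
#' Counts every overlapping n-residue window of the sequence and divides by
#' the window count `L - n + 1`, so the vector is a probability
#' distribution over the `25^n` possible peptides.  A strict variant
#' divides by `L - 1` regardless of n (identical at n = 2, the dipeptide
#' case); with that denominator the vector no longer sums to one for
#' n other than 2.
#'
#' @param seq A single residue string (or an element of a [protein_set()]).
#' @param n Peptide order.
#' @param alphabet A [peptide_alphabet()].
#' @param denominator `"windows"` (default, `L - n + 1`) or `"L-1"`.
#' @return Numeric vector of length `25^n` named by peptide labels.
#' @examples
#' v <- peptide_frequency("ACAC", 2)
#' v[c("AC", "CA")]  # 2/3, 1/3
#' @export
peptide_frequency <- function(seq, n = 2, alphabet = peptide_alphabet(),
                              denominator = c("windows", "L-1")) {
  n <- as.integer(n)
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("peptide_frequency encodes one sequence at a time")
  counts <- count_peptides(seq, n, alphabet)
  v <- counts / n_windows(nchar(seq), n, denominator)
  names(v) <- peptide_labels(n, alphabet)
  v
}

#' Document counts of peptides over a corpus
#'
#' For every possible n-peptide, counts how many sequences of the corpus
#' contain it at least once (presence, not multiplicity).  These counts are
#' the "word frequency" weights: `w / N` is the fraction of corpus
#' sequences containing each peptide.  Weights are meant to be fitted on
#' the training corpus and reused unchanged for held-out sequences.
#'
#' @param corpus A [protein_set()] or character vector of sequences.
#' @param n Peptide order.
#' @param alphabet A [peptide_alphabet()].
#' @return An object of class `corpus_weights`: list with `n`, `N` (corpus
#'   size) and `w` (integer vector of length `25^n`).
#' @examples
#' cw <- document_counts(c("AC", "CA"), 2)
#' cw$w[peptide_index(c("AC", "CA")) + 1]  # 1, 1
#' @export
document_counts <- function(corpus, n = 2, alphabet = peptide_alphabet()) {
  n <- as.integer(n)
  corpus <- as.character(corpus)
  if (length(corpus) == 0L) stop("document_counts needs a non-empty corpus")
  w <- integer(25L^n)
  for (seq in corpus) {
    present <- count_peptides(seq, n, alphabet) > 0L
    w <- w + as.integer(present)
  }
  structure(list(n = n, N = length(corpus), w = w,
                 labels = peptide_labels(n, alphabet)),
            class = "corpus_weights")
}

#' @export
print.corpus_weights <- function(x, ...) {
  cat("<corpus_weights> order n = ", x$n, ", corpus size N = ", x$N,
      ", ", sum(x$w > 0L), " peptides present\n", sep = "")
  invisible(x)
}

#' Inverse document frequency of peptides
#'
#' `IDF_i = log10(N / w_i)` for peptides present in at least one corpus
#' sequence; peptides with `w_i = 0` are undefined and returned as `NA`.
#' IDF down-weights ubiquitous peptides, which is the opposite of what
#' sequence encoding needs, so the package uses the direct word-frequency
#' weight `w / N` for encoding; IDF is provided for comparison only.
#'
#' @param weights A [document_counts()] result.
#' @return Numeric vector of length `25^n` with `NA` where undefined.
#' @export
idf <- function(weights) {
  stopifnot(inherits(weights, "corpus_weights"))
  out <- ifelse(weights$w > 0L, log10(weights$N / weights$w), NA_real_)
  names(out) <- weights$labels
  out
}

#' Word-frequency-weighted peptide encoding of one sequence
#'
#' The encoding multiplies the within-sequence peptide frequency by the
#' corpus word-frequency weight:
#' `wf_i = (w_i / N) * p_i / (L - n + 1)`,
#' where `p_i` counts occurrences of peptide i in the sequence, `w_i`
#' counts corpus sequences containing peptide i and `N` is the corpus
#' size.  Elementwise `0 <= wf_i <= v_i <= 1`, with `wf_i = v_i` exactly
#' where `w_i = N` or `v_i = 0`.
#'
#' @inheritParams peptide_frequency
#' @param weights A [document_counts()] result fitted on the training
#'   corpus (its order `n` is used).
#' @return Numeric vector of length `25^n` named by peptide labels.
#' @examples
#' cw <- document_counts(c("AC", "CA"), 2)
#' wf_encode("AC", cw)["AC"]  # (1/2) * (1/1) = 0.5
#' @export
wf_encode <- function(seq, weights, alphabet = peptide_alphabet(),
                      denominator = c("windows", "L-1")) {
  stopifnot(inherits(weights, "corpus_weights"))
  v <- peptide_frequency(seq, weights$n, alphabet, denominator)
  (weights$w / weights$N) * v
}

#' Encode a corpus of proteins as a word-frequency feature matrix
#'
#' One row per sequence, `25^n` columns in peptide-index order.  When
#' `weights` is omitted they are fitted on `corpus` itself; to avoid
#' train/test leakage, fit weights on the training corpus with
#' [document_counts()] and pass them here for held-out sequences.
#'
#' @param corpus A [protein_set()] or named character vector of sequences.
#' @param n Peptide order (ignored when `weights` is given).
#' @param weights Optional [document_counts()] result.
#' @param weighting `"word_frequency"` (default) or `"none"` for the plain
#'   peptide-frequency matrix.
#' @inheritParams peptide_frequency
#' @return Numeric matrix, rownames = sequence ids, colnames = peptide
#'   labels.
#' @export
encode_corpus <- function(corpus, n = 2, weights = NULL,
                          weighting = c("word_frequency", "none"),
                          alphabet = peptide_alphabet(),
                          denominator = c("windows", "L-1")) {
  weighting <- match.arg(weighting)
  denominator <- match.arg(denominator)
  seqs <- as.character(corpus)
  ids <- names(corpus)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 0L) stop("encode_corpus needs a non-empty corpus")
  if (is.null(weights) && weighting == "word_frequency") {
    weights <- document_counts(seqs, n, alphabet)
  }
  if (!is.null(weights)) n <- weights$n
  n <- as.integer(n)
  mat <- matrix(0, nrow = length(seqs), ncol = 25L^n,
                dimnames = list(ids, peptide_labels(n, alphabet)))
  for (i in seq_along(seqs)) {
    row <- tryCatch(
      if (weighting == "word_frequency") {
        wf_encode(seqs[i], weights, alphabet, denominator)
      } else {
        peptide_frequency(seqs[i], n, alphabet, denominator)
      },
      error = function(e) stop("sequence '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE))
    mat[i, ] <- row
  }
  mat
}

#' Write an encoded matrix as CSV with peptide-string headers
#'
#' @param mat Matrix from [encode_corpus()].
#' @param path Output file.
#' @export
write_encoded_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}
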