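#' The 25-letter amino-acid alphabet
#'
#' Protein sequences are encoded over a 25-symbol residue alphabet: the 20
#' standard amino acids plus the extended one-letter codes B (Asx), O
#' (pyrrolysine), U (selenocysteine), X (unknown) and Z (Glx).  That is the
#' 26 uppercase letters A-Z without J, in lexicographic order.  The ordering
#' fixes the layout of every peptide-frequency vector produced by the
#' package: peptides are laid out by base-25 positional index with the first
#' residue most significant, so for dipeptides "AA" is column 1 and "ZZ" is
#' column 625.
#'
#' @param letters Character vector of 25 distinct single uppercase symbols.
#'   The default is the standard alphabet described above.
#' @return An object of class `peptide_alphabet`: a character vector of the
#'   25 symbols with a symbol-to-offset lookup attached.
#' @examples
#' peptide_alphabet()
#' @export
peptide_alphabet <- function(letters = setdiff(LETTERS, "J")) {
  letters <- as.character(letters)
  if (length(letters) != 25L || anyDuplicated(letters) ||
      any(nchar(letters) != 1L) || any(letters != toupper(letters))) {
    stop("a peptide alphabet must be 25 distinct single uppercase symbols")
  }
  idx <- seq_along(letters) - 1L
  names(idx) <- letters
  structure(letters, offsets = idx, class = "peptide_alphabet")
}

#' @export
print.peptide_alphabet <- function(x, ...) {
  cat("<peptide_alphabet> ", paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Base-25 positional index of an n-peptide
#'
#' Maps an n-peptide string to its 0-based column offset in a
#' `25^n`-dimensional feature vector.  The first residue is the most
#' significant digit, so the map is a bijection from n-peptides onto
#' `[0, 25^n)`.
#'
#' @param peptide Character vector of peptide strings, all of the same
#'   length n.
#' @param alphabet A [peptide_alphabet()].
#' @return Integer vector of 0-based indices.
#' @examples
#' peptide_index("A")   # 0
#' peptide_index("AA")  # 0
#' peptide_index("ZZ")  # 624
#' @export
peptide_index <- function(peptide, alphabet = peptide_alphabet()) {
  n <- unique(nchar(peptide))
  if (length(n) != 1L || n < 1L) {
    stop("all peptides must be non-empty strings of one common length")
  }
  off <- attr(alphabet, "offsets")
  chars <- matrix(unlist(strsplit(peptide, "", fixed = TRUE)),
                  nrow = n, ncol = length(peptide))
  bad <- !(chars %in% names(off))
  if (any(bad)) {
    stop("residue(s) outside the 25-letter alphabet: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  digits <- matrix(off[chars], nrow = n)
  as.integer(colSums(digits * 25^((n:1) - 1)))
}

#' All n-peptide labels in index order
#'
#' @param n Peptide order (1, 2 or 3 in routine use).
#' @param alphabet A [peptide_alphabet()].
#' @return Character vector of length `25^n`; element `i` is the peptide
#'   whose [peptide_index()] is `i - 1`.
#' @examples
#' head(peptide_labels(2))  # "AA" "AB" "AC" ...
#' @export
peptide_labels <- function(n, alphabet = peptide_alphabet()) {
  n <- as.integer(n)
  if (n < 1L) stop("peptide order n must be >= 1")
  letters <- unclass(alphabet)
  out <- letters
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      out <- as.vector(t(outer(out, letters, paste0)))
    }
  }
  out
}
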