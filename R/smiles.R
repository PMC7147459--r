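# Minimal SMILES reader for drug-like molecules.
#
# Covers the constructs that occur in typical drug SMILES: organic-subset
# atoms (B C N O P S F Cl Br I) and their aromatic lowercase forms,
# bracket atoms with explicit hydrogen counts and charges, branches,
# single/double/triple/aromatic bonds, directional bonds (/ and \, read as
# single), and ring-bond closures including the %nn form.  Stereo marks
# and isotopes inside brackets are accepted and ignored.  Aromatic rings
# must be written in aromatic (lowercase) notation; Kekule-written rings
# are kept as alternating single/double bonds and their atoms are not
# flagged aromatic.  Multi-fragment strings ('.') are rejected.
#
# Implicit hydrogen model (matches the usual cheminformatics-toolkit
# conventions for valid SMILES):
#   * bracket atoms carry exactly the hydrogens written in the bracket and
#     have implicit-H count 0;
#   * organic-subset atoms receive enough hydrogens to reach the smallest
#     standard valence >= their bond-order sum (B 3; C 4; N 3/5; O 2;
#     P 3/5; S 2/4/6; halogens 1);
#   * aromatic carbon counts ring bonds as single and reserves one valence
#     unit for the delocalized system (so unsubstituted benzene carbon has
#     one H); aromatic N/O/S/P written without brackets carry no H.

.ORGANIC_DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

smiles_tokens <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      tokens[[length(tokens) + 1L]] <- paste(chars[i:j], collapse = "")
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens[[length(tokens) + 1L]] <- paste0(ch, chars[i + 1L])
      i <- i + 2L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop("malformed %nn ring closure")
      }
      tokens[[length(tokens) + 1L]] <- paste0("%", chars[i + 1L], chars[i + 2L])
      i <- i + 3L
    } else {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    }
  }
  unlist(tokens)
}

parse_bracket_atom <- function(token) {
  body <- sub("^\\[", "", sub("\\]$", "", token))
  # isotope
  body <- sub("^[0-9]+", "", body)
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|[bcnops]|se|as)", body))
  if (length(m) == 0L) stop("cannot read bracket atom: ", token)
  symbol_raw <- m
  rest <- substring(body, nchar(symbol_raw) + 1L)
  aromatic <- symbol_raw %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  symbol <- if (aromatic) {
    paste0(toupper(substring(symbol_raw, 1, 1)), substring(symbol_raw, 2))
  } else symbol_raw
  rest <- gsub("@", "", rest, fixed = TRUE)  # stereo ignored
  hcount <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1L) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*([+-]*)", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    sign <- if (substring(cm, 1, 1) == "+") 1L else -1L
    digits <- regmatches(cm, regexpr("[0-9]+", cm))
    mag <- if (length(digits) == 1L) as.integer(digits) else
      nchar(gsub("[^+-]", "", cm))
    charge <- sign * max(mag, 1L)
  }
  list(symbol = symbol, aromatic = aromatic, hcount = hcount,
       charge = charge, bracket = TRUE)
}

#' Parse a SMILES string into atoms and bonds
#'
#' Atom indices follow the order of appearance in the string (the
#' convention chemistry toolkits use), hydrogens are implicit.  See the
#' comments in the source for the supported SMILES subset; strings outside
#' it are rejected with an informative error.
#'
#' @param smiles A single SMILES string.
#' @return List with `atoms` (data.frame: `symbol`, `aromatic`, `charge`,
#'   `degree` = heavy-atom neighbors, `num_h` = total hydrogens,
#'   `implicit_h` = implicit hydrogens only) and `bonds` (data.frame:
#'   `from`, `to`, `order` with aromatic bonds coded 1.5), both using
#'   1-based atom indices.
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("parse_smiles expects one non-empty SMILES string")
  }
  tokens <- smiles_tokens(smiles)
  atoms <- list()
  bonds <- list()
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NA_real_
  rings <- list()  # ring-closure id -> c(atom, bond order)

  add_atom <- function(info) {
    atoms[[length(atoms) + 1L]] <<- info
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (info$aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    prev <<- idx
    pending_bond <<- NA_real_
  }

  for (tok in tokens) {
    if (grepl("^\\[", tok)) {
      add_atom(parse_bracket_atom(tok))
    } else if (tok %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) {
      add_atom(list(symbol = tok, aromatic = FALSE, hcount = NA_integer_,
                    charge = 0L, bracket = FALSE))
    } else if (tok %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(list(symbol = toupper(tok), aromatic = TRUE,
                    hcount = NA_integer_, charge = 0L, bracket = FALSE))
    } else if (tok == "(") {
      if (is.na(prev)) stop("branch opened before any atom")
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok %in% c("-", "/", "\\")) {
      pending_bond <- 1
    } else if (tok == "=") {
      pending_bond <- 2
    } else if (tok == "#") {
      pending_bond <- 3
    } else if (tok == ":") {
      pending_bond <- 1.5
    } else if (grepl("^[0-9]$", tok) || grepl("^%[0-9]{2}$", tok)) {
      id <- sub("^%", "", tok)
      if (is.na(prev)) stop("ring closure before any atom")
      if (is.null(rings[[id]])) {
        rings[[id]] <- c(prev, pending_bond)
        pending_bond <- NA_real_
      } else {
        open <- rings[[id]]
        ord <- pending_bond
        if (is.na(ord)) ord <- open[2]
        if (is.na(ord)) {
          ord <- if (atoms[[open[1]]]$aromatic && atoms[[prev]]$aromatic) 1.5 else 1
        }
        bonds[[length(bonds) + 1L]] <- c(open[1], prev, ord)
        rings[[id]] <- NULL
        pending_bond <- NA_real_
      }
    } else if (tok == ".") {
      stop("multi-fragment SMILES (with '.') are not supported")
    } else {
      stop("unsupported SMILES token: '", tok, "'")
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES")
  if (length(rings) > 0L) stop("unclosed ring bond(s): ",
                               paste(names(rings), collapse = ", "))
  if (length(atoms) == 0L) stop("SMILES contains no atoms")

  n_atoms <- length(atoms)
  bond_mat <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(numeric(0), ncol = 3)
  degree <- integer(n_atoms)
  bondsum <- numeric(n_atoms)
  arom_deg <- integer(n_atoms)
  if (nrow(bond_mat)) {
    for (k in seq_len(nrow(bond_mat))) {
      a <- bond_mat[k, 1]; b <- bond_mat[k, 2]; o <- bond_mat[k, 3]
      degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
      unit <- if (o == 1.5) 1 else o
      bondsum[a] <- bondsum[a] + unit; bondsum[b] <- bondsum[b] + unit
      if (o == 1.5) {
        arom_deg[a] <- arom_deg[a] + 1L
        arom_deg[b] <- arom_deg[b] + 1L
      }
    }
  }

  implicit_h <- integer(n_atoms)
  num_h <- integer(n_atoms)
  for (i in seq_len(n_atoms)) {
    at <- atoms[[i]]
    if (at$bracket) {
      implicit_h[i] <- 0L
      num_h[i] <- at$hcount
    } else {
      vals <- .ORGANIC_DEFAULT_VALENCE[[at$symbol]]
      if (is.null(vals)) stop("no default valence for organic-subset atom ",
                              at$symbol)
      used <- bondsum[i]
      if (at$aromatic) {
        # one valence unit reserved for the delocalized ring system on
        # aromatic carbon; aromatic N/O/S/P without brackets carry no H
        if (at$symbol == "C") used <- used + 1 else used <- vals[1]
      }
      fit <- vals[vals >= used]
      implicit_h[i] <- if (length(fit)) as.integer(fit[1] - used) else 0L
      num_h[i] <- implicit_h[i]
    }
  }

  atoms_df <- data.frame(
    symbol = vapply(atoms, function(a) a$symbol, character(1)),
    aromatic = vapply(atoms, function(a) a$aromatic, logical(1)),
    charge = vapply(atoms, function(a) as.integer(a$charge), integer(1)),
    degree = degree,
    num_h = num_h,
    implicit_h = implicit_h,
    stringsAsFactors = FALSE
  )
  bonds_df <- if (nrow(bond_mat)) {
    data.frame(from = as.integer(bond_mat[, 1]),
               to = as.integer(bond_mat[, 2]),
               order = bond_mat[, 3])
  } else {
    data.frame(from = integer(0), to = integer(0), order = numeric(0))
  }
  list(atoms = atoms_df, bonds = bonds_df)
}
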