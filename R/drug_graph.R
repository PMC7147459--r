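#' Atom feature layout for molecular graphs
#'
#' Each atom of a drug molecule is described by five characteristics,
#' concatenated into a 78-dimensional vector:
#' \itemize{
#'   \item element symbol, one-hot over a 44-entry vocabulary (43 common
#'     elements plus a trailing catch-all bucket);
#'   \item atomic rank, one-hot over 0-10.  By default the rank is the
#'     number of bonds to neighboring atoms plus the number of hydrogens
#'     (`rank_mode = "bonds_plus_h"`); `rank_mode = "degree"` uses the
#'     heavy-neighbor count alone;
#'   \item total hydrogen count, one-hot over 0-10;
#'   \item implicit valence (implicit hydrogen count), one-hot over 0-10;
#'   \item a single aromaticity bit.
#' }
#' Counts above 10 are clamped into the top bucket with a warning.
#'
#' @param rank_mode `"bonds_plus_h"` (default) or `"degree"`.
#' @return An object of class `atom_feature_spec`.
#' @export
atom_feature_spec <- function(rank_mode = c("bonds_plus_h", "degree")) {
  rank_mode <- match.arg(rank_mode)
  symbols <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na",
               "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb",
               "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H", "Li",
               "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr", "Pt",
               "Hg", "Pb", "*")
  structure(list(symbols = symbols, count_max = 10L, rank_mode = rank_mode,
                 width = length(symbols) + 3L * 11L + 1L),
            class = "atom_feature_spec")
}

#' @export
print.atom_feature_spec <- function(x, ...) {
  cat("<atom_feature_spec> width ", x$width, " (", length(x$symbols),
      " symbols + 3 x 11 counts + aromatic), rank = ", x$rank_mode,
      "\n", sep = "")
  invisible(x)
}

one_hot <- function(value, n_slots) {
  v <- numeric(n_slots)
  v[value + 1L] <- 1
  v
}

clamp_count <- function(value, max, what) {
  if (value > max) {
    warning(what, " = ", value, " clamped to ", max, call. = FALSE)
    value <- max
  }
  if (value < 0L) stop(what, " must be >= 0")
  value
}

#' 78-dimensional feature vector of one atom
#'
#' @param symbol Element symbol; unknown symbols fall into the catch-all
#'   bucket.
#' @param degree Number of bonds to heavy neighboring atoms.
#' @param num_h Total hydrogen count.
#' @param implicit_valence Implicit valence (implicit hydrogen count).
#' @param aromatic Logical aromaticity flag.
#' @param spec An [atom_feature_spec()].
#' @return Numeric vector of length 78.
#' @export
atom_features <- function(symbol, degree, num_h, implicit_valence,
                          aromatic, spec = atom_feature_spec()) {
  stopifnot(inherits(spec, "atom_feature_spec"))
  slot <- match(symbol, spec$symbols)
  if (is.na(slot)) slot <- length(spec$symbols)  # catch-all bucket
  rank <- if (spec$rank_mode == "bonds_plus_h") degree + num_h else degree
  rank <- clamp_count(rank, spec$count_max, "atomic rank")
  num_h <- clamp_count(num_h, spec$count_max, "hydrogen count")
  implicit_valence <- clamp_count(implicit_valence, spec$count_max,
                                  "implicit valence")
  c(one_hot(slot - 1L, length(spec$symbols)),
    one_hot(rank, spec$count_max + 1L),
    one_hot(num_h, spec$count_max + 1L),
    one_hot(implicit_valence, spec$count_max + 1L),
    as.numeric(isTRUE(aromatic)))
}

#' Convert a SMILES compound into a molecular graph
#'
#' Nodes are heavy atoms carrying 78-dimensional feature vectors (see
#' [atom_feature_spec()]); edges are chemical bonds, stored as directed
#' pairs in both directions.  Bond orders are not retained as edge
#' features: the graph encodes connectivity only.  Self-loops are not
#' stored (graph layers add them internally where their propagation rule
#' requires).
#'
#' @param smiles A SMILES string.
#' @param id Compound identifier attached to the graph (and to error
#'   messages).
#' @param spec An [atom_feature_spec()].
#' @return An object of class `molecular_graph`: list with `compound_id`,
#'   `smiles`, `node_features` (num_atoms x 78 matrix) and `edges`
#'   (two-column integer matrix of 1-based directed pairs, zero rows for a
#'   single-atom molecule).
#' @examples
#' g <- smiles_to_graph("CC", "ethane")
#' nrow(g$node_features)  # 2
#' @export
smiles_to_graph <- function(smiles, id = smiles, spec = atom_feature_spec()) {
  mol <- tryCatch(parse_smiles(smiles),
                  error = function(e) stop("compound '", id, "': ",
                                           conditionMessage(e), call. = FALSE))
  n <- nrow(mol$atoms)
  feats <- matrix(0, nrow = n, ncol = spec$width)
  for (i in seq_len(n)) {
    a <- mol$atoms[i, ]
    feats[i, ] <- atom_features(a$symbol, a$degree, a$num_h, a$implicit_h,
                                a$aromatic, spec)
  }
  edges <- if (nrow(mol$bonds)) {
    und <- cbind(mol$bonds$from, mol$bonds$to)
    rbind(und, und[, 2:1, drop = FALSE])
  } else {
    matrix(integer(0), ncol = 2)
  }
  colnames(edges) <- c("from", "to")
  structure(list(compound_id = id, smiles = smiles,
                 node_features = feats, edges = edges),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> '", x$compound_id, "': ",
      nrow(x$node_features), " atoms, ", nrow(x$edges),
      " directed edges\n", sep = "")
  invisible(x)
}

#' Batch conversion of a compound table into molecular graphs
#'
#' Row order is preserved; duplicated SMILES are parsed once and reuse the
#' cached graph structure.  Failures are collected per row instead of
#' aborting the batch.
#'
#' @param table Data frame with columns `drug_id` and `smiles`.
#' @param spec An [atom_feature_spec()].
#' @return List with `graphs` (named list of [smiles_to_graph()] results
#'   for the successful rows) and `failures` (data.frame `drug_id`,
#'   `smiles`, `message`).
#' @export
graphs_from_table <- function(table, spec = atom_feature_spec()) {
  stopifnot(all(c("drug_id", "smiles") %in% names(table)))
  cache <- new.env(parent = emptyenv())
  graphs <- list()
  failures <- list()
  for (i in seq_len(nrow(table))) {
    id <- as.character(table$drug_id[i])
    smi <- as.character(table$smiles[i])
    key <- paste0("s:", smi)
    g <- if (!is.null(cache[[key]])) {
      cached <- cache[[key]]
      cached$compound_id <- id
      cached
    } else {
      tryCatch(smiles_to_graph(smi, id, spec), error = function(e) e)
    }
    if (inherits(g, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(drug_id = id, smiles = smi,
                   message = conditionMessage(g), stringsAsFactors = FALSE)
    } else {
      cache[[key]] <- g
      graphs[[id]] <- g
    }
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(drug_id = character(0), smiles = character(0),
               message = character(0), stringsAsFactors = FALSE)
  list(graphs = graphs, failures = failures)
}

#' Serialize molecular graphs to JSON for inspection
#'
#' @param graphs A single `molecular_graph` or a list of them.
#' @param path Output path.
#' @export
graphs_to_json <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  payload <- lapply(graphs, function(g) {
    list(compound_id = g$compound_id, smiles = g$smiles,
         node_features = unname(as.matrix(g$node_features)),
         edges = if (nrow(g$edges)) unname(g$edges) else matrix(0L, 0, 2))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
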