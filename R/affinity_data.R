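#' Construct a drug-target affinity dataset
#'
#' A long-format table of (drug, protein, affinity) records, one row per
#' measured pair, with a units tag recording the affinity scale.
#'
#' @param records Data frame with columns `drug_id`, `smiles`,
#'   `protein_id`, `sequence`, `affinity`.
#' @param units `"pKd"` (Davis-style, from [kd_to_pkd()]) or `"KIBA"`
#'   (composite scores used untransformed).
#' @return Object of class `affinity_dataset` (a data.frame with a `units`
#'   attribute).
#' @export
affinity_dataset <- function(records, units = c("pKd", "KIBA")) {
  units <- match.arg(units)
  need <- c("drug_id", "smiles", "protein_id", "sequence", "affinity")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  records$drug_id <- as.character(records$drug_id)
  records$protein_id <- as.character(records$protein_id)
  records$smiles <- as.character(records$smiles)
  records$sequence <- as.character(records$sequence)
  records$affinity <- as.numeric(records$affinity)
  if (any(!nzchar(records$drug_id)) || any(!nzchar(records$protein_id))) {
    stop("drug_id and protein_id must be non-empty")
  }
  if (any(!is.finite(records$affinity))) {
    stop(sum(!is.finite(records$affinity)), " record(s) with non-finite affinity")
  }
  key <- paste(records$drug_id, records$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("drug_id", "protein_id")]
    stop("duplicate (drug, protein) pair(s), e.g. ",
         dup$drug_id[1], " / ", dup$protein_id[1])
  }
  rownames(records) <- NULL
  structure(records, units = units,
            class = c("affinity_dataset", "data.frame"))
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat("<affinity_dataset> ", nrow(x), " records (",
      length(unique(x$drug_id)), " drugs x ",
      length(unique(x$protein_id)), " proteins), units = ",
      attr(x, "units"), "\n", sep = "")
  invisible(x)
}

#' Convert dissociation constants (nM) to pKd
#'
#' `pKd = -log10(Kd / 1e9)`: a Kd given in nanomolar is rescaled to molar
#' and negated on the log10 scale, so stronger binders get larger values
#' (Kd = 1 nM gives pKd = 9).
#'
#' @param kd Numeric vector of dissociation constants in nM; must be
#'   positive.
#' @return Numeric vector of pKd values.
#' @examples
#' kd_to_pkd(c(1e9, 1e4, 1))  # 0, 5, 9
#' @export
kd_to_pkd <- function(kd) {
  kd <- as.numeric(kd)
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("Kd values must be finite and > 0 (in nM)")
  }
  -log10(kd / 1e9)
}

#' Filter a dataset to drugs and proteins with enough interactions
#'
#' Keeps only records whose drug and protein each appear in at least `k`
#' records.  Because dropping records can push other entities below the
#' threshold, the filter iterates to a fixpoint by default; re-applying
#' the filter to its own output is then the identity.  `iterate = FALSE`
#' performs a single pass.
#'
#' @param ds An [affinity_dataset()].
#' @param k Minimum interaction count per drug and per protein
#'   (default 10).
#' @param iterate Iterate to fixpoint (default `TRUE`).
#' @return The filtered [affinity_dataset()] (possibly empty).
#' @export
filter_min_interactions <- function(ds, k = 10, iterate = TRUE) {
  stopifnot(inherits(ds, "affinity_dataset"), k >= 1)
  units <- attr(ds, "units")
  repeat {
    if (nrow(ds) == 0L) break
    drug_n <- table(ds$drug_id)
    prot_n <- table(ds$protein_id)
    keep <- drug_n[ds$drug_id] >= k & prot_n[ds$protein_id] >= k
    if (all(keep)) break
    ds <- ds[keep, , drop = FALSE]
    if (!iterate) break
  }
  rownames(ds) <- NULL
  structure(as.data.frame(ds), units = units,
            class = c("affinity_dataset", "data.frame"))
}

#' Random train/test split of affinity records
#'
#' A uniform random partition at the record (drug, protein pair) level,
#' i.e. a warm-start split: the same drug or protein may appear on both
#' sides.  The split is reproducible under `seed`.
#'
#' @param ds An [affinity_dataset()].
#' @param train_fraction Fraction of records in the training part
#'   (default 0.8); the training size is `round(fraction * n)`.
#' @param seed Integer seed.
#' @return List with `train` and `test` affinity datasets.
#' @export
train_test_split <- function(ds, train_fraction = 0.8, seed = 1) {
  stopifnot(inherits(ds, "affinity_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n <- nrow(ds)
  if (n < 2L) stop("need at least 2 records to split")
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  units <- attr(ds, "units")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  take <- sample.int(n, n_train)
  mk <- function(rows) {
    out <- as.data.frame(ds)[rows, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, units = units,
              class = c("affinity_dataset", "data.frame"))
  }
  list(train = mk(sort(take)), test = mk(sort(setdiff(seq_len(n), take))))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Load a long-format affinity CSV
#'
#' Expects columns `drug_id`, `smiles`, `protein_id`, `sequence`,
#' `affinity`.  Row-level problems (missing sequence or SMILES,
#' non-numeric affinity, duplicated pairs) are itemized in the error.
#'
#' @param path CSV path.
#' @param units Affinity units tag.
#' @return An [affinity_dataset()].
#' @export
load_long_csv <- function(path, units = c("pKd", "KIBA")) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "smiles", "protein_id", "sequence", "affinity")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("affinity CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  aff <- suppressWarnings(as.numeric(tab$affinity))
  bad_aff <- which(!is.finite(aff))
  if (length(bad_aff)) {
    problems <- c(problems, paste0("row ", bad_aff, ": non-numeric affinity"))
  }
  for (col in c("smiles", "sequence")) {
    bad <- which(is.na(tab[[col]]) | !nzchar(tab[[col]]))
    if (length(bad)) {
      problems <- c(problems, paste0("row ", bad, ": missing ", col))
    }
  }
  if (length(problems)) {
    stop("invalid affinity CSV:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "))
  }
  tab$affinity <- aff
  affinity_dataset(tab, units)
}

#' Build an affinity dataset from a dense proteins-by-drugs matrix
#'
#' One record is emitted per non-missing cell; `NA` cells are skipped, not
#' imputed.  A full 442 x 68 Davis-style matrix therefore yields 30,056
#' records.
#'
#' @param affinity_matrix Numeric matrix, rows = proteins, columns =
#'   drugs; or a path to a TSV file with protein ids in the first column
#'   and drug ids as header.
#' @param drug_table Data frame (or CSV path) with columns `drug_id`,
#'   `smiles`, one row per matrix column.
#' @param protein_table Data frame (or CSV path) with columns
#'   `protein_id`, `sequence` — or a FASTA path — covering every matrix
#'   row.
#' @param units Affinity units tag.
#' @return An [affinity_dataset()].
#' @export
load_matrix <- function(affinity_matrix, drug_table, protein_table,
                        units = c("pKd", "KIBA")) {
  if (is.character(affinity_matrix) && length(affinity_matrix) == 1L) {
    tab <- utils::read.delim(affinity_matrix, check.names = FALSE,
                             stringsAsFactors = FALSE)
    affinity_matrix <- as.matrix(tab[, -1, drop = FALSE])
    rownames(affinity_matrix) <- as.character(tab[[1]])
  }
  if (is.character(drug_table) && length(drug_table) == 1L) {
    drug_table <- utils::read.csv(drug_table, stringsAsFactors = FALSE)
  }
  if (is.character(protein_table) && length(protein_table) == 1L) {
    if (grepl("\\.(fa|fasta|faa)$", protein_table, ignore.case = TRUE)) {
      ps <- read_proteins(protein_table)
      protein_table <- data.frame(protein_id = names(ps),
                                  sequence = as.character(ps),
                                  stringsAsFactors = FALSE)
    } else {
      protein_table <- utils::read.csv(protein_table, stringsAsFactors = FALSE)
    }
  }
  stopifnot(all(c("drug_id", "smiles") %in% names(drug_table)),
            all(c("protein_id", "sequence") %in% names(protein_table)))
  if (is.null(rownames(affinity_matrix))) {
    rownames(affinity_matrix) <- protein_table$protein_id[seq_len(nrow(affinity_matrix))]
  }
  if (is.null(colnames(affinity_matrix))) {
    colnames(affinity_matrix) <- drug_table$drug_id[seq_len(ncol(affinity_matrix))]
  }
  prot_ids <- rownames(affinity_matrix)
  drug_ids <- colnames(affinity_matrix)
  miss_p <- setdiff(prot_ids, protein_table$protein_id)
  miss_d <- setdiff(drug_ids, drug_table$drug_id)
  if (length(miss_p) || length(miss_d)) {
    stop("unresolvable ids: ",
         paste(utils::head(c(miss_p, miss_d), 10), collapse = ", "))
  }
  seq_of <- stats::setNames(protein_table$sequence, protein_table$protein_id)
  smi_of <- stats::setNames(drug_table$smiles, drug_table$drug_id)
  keep <- which(is.finite(affinity_matrix), arr.ind = TRUE)
  records <- data.frame(
    drug_id = drug_ids[keep[, "col"]],
    smiles = unname(smi_of[drug_ids[keep[, "col"]]]),
    protein_id = prot_ids[keep[, "row"]],
    sequence = unname(seq_of[prot_ids[keep[, "row"]]]),
    affinity = affinity_matrix[keep],
    stringsAsFactors = FALSE
  )
  records <- records[order(records$protein_id, records$drug_id), ]
  affinity_dataset(records, units)
}

#' Write an affinity dataset as long-format CSV
#'
#' @param ds An [affinity_dataset()].
#' @param path Output file.
#' @export
write_long_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}
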