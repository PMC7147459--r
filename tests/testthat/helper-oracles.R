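# Independent oracles and shared fixtures for the test suite.

# Brute-force concordance index: explicit enumeration of every ordered
# pair, kept deliberately naive and separate from the package's blocked
# implementation.
ci_bruteforce <- function(truth, pred) {
  n <- length(truth)
  num <- 0
  z <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (truth[i] > truth[j]) {
        z <- z + 1
        d <- pred[i] - pred[j]
        num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
      }
    }
  }
  num / z
}

# Frozen chemistry-toolkit reference: per-atom symbol, heavy-neighbor
# degree, total H count, implicit valence and aromatic flag, plus the
# undirected bond list, for a panel of drug-like SMILES (atom indices in
# SMILES appearance order).  Values computed once with RDKit 2024.09.2.
atom_oracle <- data.frame(
  smiles = c("C", "CC", "c1ccccc1", "CCO", "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CC(=O)Nc1ccc(O)cc1", "c1ccncc1", "c1cc[nH]c1", "N#Cc1ccccc1", "CCOC(=O)c1ccccc1N", "CN1CCCC1c1cccnc1", "CCN(CC)C(=O)c1ccccc1", "COc1ccc(CCN)cc1", "CC(N)Cc1ccccc1", "CSc1ccc(CC(=O)O)cc1", "CC(O)c1ccc(F)cc1", "CCOc1ccc(cc1)C(=O)NC", "CN(C)CCc1ccc(Cl)cc1", "FC(F)(F)c1ccccc1", "O=S(=O)(N)c1ccccc1"),
  symbols = c("C", "C,C", "C,C,C,C,C,C", "C,C,O", "C,C,O,O,C,C,C,C,C,C,C,O,O", "C,N,C,N,C,C,C,O,N,C,C,O,N,C", "C,C,C,C,C,C,C,C,C,C,C,C,C,O,O", "C,C,O,N,C,C,C,C,O,C,C", "C,C,C,N,C,C", "C,C,C,N,C", "N,C,C,C,C,C,C,C", "C,C,O,C,O,C,C,C,C,C,C,N", "C,N,C,C,C,C,C,C,C,C,N,C", "C,C,N,C,C,C,O,C,C,C,C,C,C", "C,O,C,C,C,C,C,C,N,C,C", "C,C,N,C,C,C,C,C,C,C", "C,S,C,C,C,C,C,C,O,O,C,C", "C,C,O,C,C,C,C,F,C,C", "C,C,O,C,C,C,C,C,C,C,O,N,C", "C,N,C,C,C,C,C,C,C,Cl,C,C", "F,C,F,F,C,C,C,C,C,C", "O,S,O,N,C,C,C,C,C,C"),
  degree = c("0", "1,1", "2,2,2,2,2,2", "1,2,1", "1,3,1,2,3,2,2,2,2,3,3,1,1", "1,3,2,2,3,3,3,1,3,1,3,1,3,1", "1,3,1,2,3,2,2,3,2,2,3,1,3,1,1", "1,3,1,2,3,2,2,3,1,2,2", "2,2,2,2,2,2", "2,2,2,2,2", "1,2,3,2,2,2,2,2", "1,2,2,3,1,3,2,2,2,2,3,1", "1,3,2,2,2,3,3,2,2,2,2,2", "1,2,3,2,1,3,1,3,2,2,2,2,2", "1,2,3,2,2,3,2,2,1,2,2", "1,3,1,2,3,2,2,2,2,2", "1,2,3,2,2,3,2,3,1,1,2,2", "1,3,1,3,2,2,3,1,2,2", "1,2,2,3,2,2,3,2,2,3,1,2,1", "1,3,1,2,2,3,2,2,3,1,2,2", "1,4,1,1,3,2,2,2,2,2", "1,4,1,1,3,2,2,2,2,2"),
  num_h = c("4", "3,3", "1,1,1,1,1,1", "3,2,1", "3,0,0,0,0,1,1,1,1,0,0,0,1", "3,0,1,0,0,0,0,0,0,3,0,0,0,3", "3,1,3,2,0,1,1,0,1,1,1,3,0,0,1", "3,0,0,1,0,1,1,0,1,1,1", "1,1,1,0,1,1", "1,1,1,1,1", "0,0,0,1,1,1,1,1", "3,2,0,0,0,0,1,1,1,1,0,2", "3,0,2,2,2,1,0,1,1,1,0,1", "3,2,0,2,3,0,0,0,1,1,1,1,1", "3,0,0,1,1,0,2,2,2,1,1", "3,1,2,2,0,1,1,1,1,1", "3,0,0,1,1,0,2,0,0,1,1,1", "3,1,1,0,1,1,0,0,1,1", "3,2,0,0,1,1,0,1,1,0,0,1,3", "3,0,3,2,2,0,1,1,0,0,1,1", "0,0,0,0,0,1,1,1,1,1", "0,0,0,2,0,1,1,1,1,1"),
  implicit = c("4", "3,3", "1,1,1,1,1,1", "3,2,1", "3,0,0,0,0,1,1,1,1,0,0,0,1", "3,0,1,0,0,0,0,0,0,3,0,0,0,3", "3,1,3,2,0,1,1,0,1,1,1,3,0,0,1", "3,0,0,1,0,1,1,0,1,1,1", "1,1,1,0,1,1", "1,1,1,0,1", "0,0,0,1,1,1,1,1", "3,2,0,0,0,0,1,1,1,1,0,2", "3,0,2,2,2,1,0,1,1,1,0,1", "3,2,0,2,3,0,0,0,1,1,1,1,1", "3,0,0,1,1,0,2,2,2,1,1", "3,1,2,2,0,1,1,1,1,1", "3,0,0,1,1,0,2,0,0,1,1,1", "3,1,1,0,1,1,0,0,1,1", "3,2,0,0,1,1,0,1,1,0,0,1,3", "3,0,3,2,2,0,1,1,0,0,1,1", "0,0,0,0,0,1,1,1,1,1", "0,0,0,2,0,1,1,1,1,1"),
  aromatic = c("0", "00", "111111", "000", "0000111111000", "01111110101010", "000011111100000", "00001111011", "111111", "11111", "00111111", "000001111110", "000000111111", "0000000111111", "00111100011", "0000111111", "001111000011", "0001111011", "0001111110000", "000001111011", "0000111111", "0000111111"),
  bonds = c("", "1-2", "1-2;2-3;3-4;4-5;5-6;6-1", "1-2;2-3", "1-2;2-3;2-4;4-5;5-6;6-7;7-8;8-9;9-10;10-11;11-12;11-13;10-5", "1-2;2-3;3-4;4-5;5-6;6-7;7-8;7-9;9-10;9-11;11-12;11-13;13-14;6-2;13-5", "1-2;2-3;2-4;4-5;5-6;6-7;7-8;8-9;9-10;8-11;11-12;11-13;13-14;13-15;10-5", "1-2;2-3;2-4;4-5;5-6;6-7;7-8;8-9;8-10;10-11;11-5", "1-2;2-3;3-4;4-5;5-6;6-1", "1-2;2-3;3-4;4-5;5-1", "1-2;2-3;3-4;4-5;5-6;6-7;7-8;8-3", "1-2;2-3;3-4;4-5;4-6;6-7;7-8;8-9;9-10;10-11;11-12;11-6", "1-2;2-3;3-4;4-5;5-6;6-7;7-8;8-9;9-10;10-11;11-12;6-2;12-7", "1-2;2-3;3-4;4-5;3-6;6-7;6-8;8-9;9-10;10-11;11-12;12-13;13-8", "1-2;2-3;3-4;4-5;5-6;6-7;7-8;8-9;6-10;10-11;11-3", "1-2;2-3;2-4;4-5;5-6;6-7;7-8;8-9;9-10;10-5", "1-2;2-3;3-4;4-5;5-6;6-7;7-8;8-9;8-10;6-11;11-12;12-3", "1-2;2-3;2-4;4-5;5-6;6-7;7-8;7-9;9-10;10-4", "1-2;2-3;3-4;4-5;5-6;6-7;7-8;8-9;7-10;10-11;10-12;12-13;9-4", "1-2;2-3;2-4;4-5;5-6;6-7;7-8;8-9;9-10;9-11;11-12;12-6", "1-2;2-3;2-4;2-5;5-6;6-7;7-8;8-9;9-10;10-5", "1-2;2-3;2-4;2-5;5-6;6-7;7-8;8-9;9-10;10-5"),
  stringsAsFactors = FALSE)

oracle_row <- function(smiles) {
  row <- atom_oracle[atom_oracle$smiles == smiles, ]
  stopifnot(nrow(row) == 1)
  list(
    symbols = strsplit(row$symbols, ",", fixed = TRUE)[[1]],
    degree = as.integer(strsplit(row$degree, ",", fixed = TRUE)[[1]]),
    num_h = as.integer(strsplit(row$num_h, ",", fixed = TRUE)[[1]]),
    implicit = as.integer(strsplit(row$implicit, ",", fixed = TRUE)[[1]]),
    aromatic = strsplit(row$aromatic, "", fixed = TRUE)[[1]] == "1",
    bonds = if (nzchar(row$bonds)) {
      do.call(rbind, lapply(strsplit(row$bonds, ";", fixed = TRUE)[[1]],
                            function(b) as.integer(strsplit(b, "-")[[1]])))
    } else matrix(integer(0), ncol = 2)
  )
}

# canonical undirected edge-set string for comparison
edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
             sep = "-"))
}

# small planted-signal dataset shared across model tests
make_tiny_features <- function(seed = 5, n_proteins = 8, n_drugs = 5,
                               n = 1) {
  spec <- synthetic_spec(seed = seed, n_proteins = n_proteins,
                         n_drugs = n_drugs, length_range = c(60, 120))
  ds <- simulate_dataset(spec)
  list(ds = ds, feats = featurize_pairs(ds, n = n))
}
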