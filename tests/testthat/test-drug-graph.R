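test_that("parsed atoms and bonds match the chemistry-toolkit reference panel", {
  for (smi in atom_oracle$smiles) {
    ref <- oracle_row(smi)
    mol <- parse_smiles(smi)
    expect_identical(mol$atoms$symbol, ref$symbols, label = smi)
    expect_identical(mol$atoms$degree, ref$degree, label = smi)
    expect_identical(mol$atoms$num_h, ref$num_h, label = smi)
    expect_identical(mol$atoms$implicit_h, ref$implicit, label = smi)
    expect_identical(mol$atoms$aromatic, ref$aromatic, label = smi)
    expect_identical(edge_key(as.matrix(mol$bonds[, 1:2])),
                     edge_key(ref$bonds), label = smi)
  }
})

test_that("atom feature vectors are five one-hot blocks of total width 78", {
  spec <- atom_feature_spec()
  expect_identical(spec$width, 78L)

  # methane carbon: paper-literal rank = 0 heavy neighbors + 4 H
  v <- atom_features("C", degree = 0, num_h = 4, implicit_valence = 4,
                     aromatic = FALSE)
  expect_length(v, 78L)
  expect_identical(which(v[1:44] == 1), 1L)           # C is first symbol
  expect_identical(which(v[45:55] == 1), 5L)          # rank 4
  expect_identical(which(v[56:66] == 1), 5L)          # 4 hydrogens
  expect_identical(which(v[67:77] == 1), 5L)          # implicit valence 4
  expect_identical(v[78], 0)

  # heavy-neighbor-only rank mode
  v2 <- atom_features("C", 0, 4, 4, FALSE,
                      spec = atom_feature_spec("degree"))
  expect_identical(which(v2[45:55] == 1), 1L)         # rank 0

  # unknown element lands in the catch-all bucket
  v3 <- atom_features("Xx", 2, 0, 0, FALSE)
  expect_identical(which(v3[1:44] == 1), 44L)

  # counts above 10 clamp into the top bucket with a warning
  expect_warning(v4 <- atom_features("C", 11, 0, 0, FALSE), "clamped")
  expect_identical(which(v4[45:55] == 1), 11L)
})

test_that("molecular graphs carry symmetric edges and exact one-hot block sums", {
  g <- smiles_to_graph("C", "methane")
  expect_identical(nrow(g$node_features), 1L)
  expect_identical(nrow(g$edges), 0L)

  g <- smiles_to_graph("CC", "ethane")
  expect_identical(nrow(g$node_features), 2L)
  expect_identical(edge_key(g$edges), c("1-2", "1-2"))

  g <- smiles_to_graph("c1ccccc1", "benzene")
  expect_identical(nrow(g$node_features), 6L)
  expect_identical(nrow(g$edges), 12L)
  expect_true(all(g$node_features[, 78] == 1))

  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")) {
    g <- smiles_to_graph(smi)
    # reversal leaves the directed edge set unchanged
    expect_identical(edge_key(g$edges), edge_key(g$edges[, 2:1]))
    rev_key <- paste(g$edges[, 2], g$edges[, 1])
    expect_setequal(paste(g$edges[, 1], g$edges[, 2]), rev_key)
    # each one-hot block sums to exactly 1 in every row
    blocks <- list(1:44, 45:55, 56:66, 67:77)
    for (b in blocks) {
      expect_identical(unname(rowSums(g$node_features[, b])),
                       rep(1, nrow(g$node_features)))
    }
    expect_true(all(g$node_features[, 78] %in% c(0, 1)))
  }
})

test_that("graph construction is deterministic and rejections carry the compound id", {
  g1 <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1", "apap")
  g2 <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1", "apap")
  expect_identical(g1, g2)
  expect_error(smiles_to_graph("C1CC", "broken"), "broken")
  expect_error(smiles_to_graph("CC(C", "unbal"), "unbal")
})

test_that("batch conversion preserves order, caches duplicates and collects failures", {
  tab <- data.frame(drug_id = c("d1", "d2", "d3", "d4"),
                    smiles = c("CCO", "not_a_smiles", "CCO", "c1ccncc1"),
                    stringsAsFactors = FALSE)
  res <- graphs_from_table(tab)
  expect_identical(names(res$graphs), c("d1", "d3", "d4"))
  expect_identical(res$failures$drug_id, "d2")
  # cached duplicate is structurally identical apart from the id
  ga <- res$graphs$d1; gb <- res$graphs$d3
  ga$compound_id <- gb$compound_id <- ""
  expect_identical(ga, gb)

  clean <- graphs_from_table(tab[c(1, 3, 4), ])
  expect_identical(nrow(clean$failures), 0L)
})

test_that("graphs serialize to JSON with node matrix and edge list", {
  g <- smiles_to_graph("CCO", "ethanol")
  path <- tempfile(fileext = ".json")
  graphs_to_json(g, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)[[1]]
  expect_identical(back$compound_id, "ethanol")
  expect_identical(dim(back$node_features), c(3L, 78L))
  expect_identical(nrow(back$edges), 4L)
})
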