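make_ds <- function(pairs, affinity = seq_len(nrow(pairs))) {
  affinity_dataset(data.frame(
    drug_id = pairs$d, smiles = "CCO",
    protein_id = pairs$p, sequence = "ACDEFG",
    affinity = affinity, stringsAsFactors = FALSE))
}

test_that("Kd in nM converts to pKd on the molar -log10 scale", {
  expect_equal(kd_to_pkd(1e9), 0)
  expect_equal(kd_to_pkd(1e4), 5)
  expect_equal(kd_to_pkd(1), 9)
  # strictly decreasing; a 10-fold weaker Kd costs exactly one pKd unit
  kd <- 10^runif(20, -1, 9)
  expect_true(all(diff(kd_to_pkd(sort(kd))) < 0))
  expect_equal(kd_to_pkd(10 * kd), kd_to_pkd(kd) - 1)
  expect_error(kd_to_pkd(0), "> 0")
  expect_error(kd_to_pkd(-5), "> 0")
})

test_that("affinity datasets validate ids, finiteness and pair uniqueness", {
  ds <- make_ds(data.frame(d = c("d1", "d1"), p = c("p1", "p2")))
  expect_s3_class(ds, "affinity_dataset")
  expect_identical(attr(ds, "units"), "pKd")
  expect_error(make_ds(data.frame(d = c("d1", "d1"), p = c("p1", "p1"))),
               "duplicate")
  expect_error(make_ds(data.frame(d = "d1", p = "p1"), affinity = NaN),
               "non-finite")
  expect_error(affinity_dataset(data.frame(drug_id = "d")), "lack")
})

test_that("minimum-interaction filter iterates to a fixpoint", {
  # cascading example: d2 drops, then p2, then d1/p1 fall below 2
  ds <- make_ds(data.frame(d = c("d1", "d1", "d2"),
                           p = c("p1", "p2", "p1")))
  expect_identical(nrow(filter_min_interactions(ds, k = 2)), 0L)
  # a single pass keeps the not-yet-recheckable survivors
  expect_identical(nrow(filter_min_interactions(ds, k = 2, iterate = FALSE)), 1L)
  # k = 1 never removes anything
  expect_identical(nrow(filter_min_interactions(ds, k = 1)), 3L)

  # a dense block already satisfying k is untouched, and the output is a
  # fixpoint under re-application
  dense <- make_ds(expand.grid(d = paste0("d", 1:3), p = paste0("p", 1:3)))
  f <- filter_min_interactions(dense, k = 3)
  expect_identical(nrow(f), 9L)
  set.seed(2)
  ragged <- make_ds(data.frame(d = sample(paste0("d", 1:8), 40, TRUE),
                               p = paste0("p", 1:40)))
  out <- filter_min_interactions(ragged, k = 3)
  expect_identical(as.data.frame(filter_min_interactions(out, k = 3)),
                   as.data.frame(out))
})

test_that("train/test split is disjoint, exhaustive and seed-reproducible", {
  ds <- make_ds(expand.grid(d = paste0("d", 1:5), p = paste0("p", 1:2)))
  sp <- train_test_split(ds, 0.8, seed = 42)
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$test), 2L)
  key <- function(x) paste(x$drug_id, x$protein_id)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(ds))
  sp2 <- train_test_split(ds, 0.8, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- train_test_split(ds, 0.8, seed = 43)
  expect_false(identical(key(sp$train), key(sp3$train)))
  expect_error(train_test_split(ds, 1.2), "train_fraction")
  expect_error(train_test_split(make_ds(data.frame(d = "d", p = "p"))),
               "at least 2")
})

test_that("long CSV loader validates rows and reports problems item by item", {
  path <- tempfile(fileext = ".csv")
  good <- data.frame(drug_id = c("d1", "d2"), smiles = "CCO",
                     protein_id = "p1", sequence = "ACDEF",
                     affinity = c(5.1, 6.2))
  utils::write.csv(good, path, row.names = FALSE)
  ds <- load_long_csv(path, units = "KIBA")
  expect_identical(nrow(ds), 2L)
  expect_identical(attr(ds, "units"), "KIBA")

  bad <- good
  bad$affinity <- c("5.1", "not-a-number")
  bad$smiles[1] <- ""
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_long_csv(path), "row 2: non-numeric affinity")
  expect_error(load_long_csv(path), "row 1: missing smiles")
})

test_that("dense matrix loader emits one record per non-missing cell", {
  mk <- function(np, nd, n_missing = 0) {
    m <- matrix(runif(np * nd, 4, 9), np, nd,
                dimnames = list(paste0("p", 1:np), paste0("d", 1:nd)))
    if (n_missing > 0) m[sample(length(m), n_missing)] <- NA
    m
  }
  drugs <- function(nd) data.frame(drug_id = paste0("d", 1:nd), smiles = "CCO")
  prots <- function(np) data.frame(protein_id = paste0("p", 1:np),
                                   sequence = "ACDEFG")
  set.seed(1)
  ds <- load_matrix(mk(2, 3), drugs(3), prots(2))
  expect_identical(nrow(ds), 6L)
  ds2 <- load_matrix(mk(4, 5, n_missing = 1), drugs(5), prots(4))
  expect_identical(nrow(ds2), 19L)
  expect_error(load_matrix(mk(2, 3), drugs(2), prots(2)), "unresolvable")

  # TSV/CSV path-based loading round-trips
  m <- mk(3, 2)
  mpath <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(protein_id = rownames(m), m),
                     mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  ds3 <- load_matrix(mpath, drugs(2), prots(3))
  expect_identical(nrow(ds3), 6L)
  expect_equal(ds3$affinity[ds3$drug_id == "d1" & ds3$protein_id == "p2"],
               unname(m["p2", "d1"]))
})
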