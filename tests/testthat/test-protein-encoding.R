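test_that("peptide index is the base-25 bijection fixed by the alphabet order", {
  ab <- peptide_alphabet()
  expect_identical(peptide_index("A"), 0L)
  expect_identical(peptide_index("AA"), 0L)
  expect_identical(peptide_index("ZZ"), 624L)
  expect_identical(peptide_index("AB"), 1L)
  expect_identical(peptide_index("BA"), 25L)
  # bijectivity at n = 2: labels invert the index
  labels <- peptide_labels(2)
  expect_length(labels, 625L)
  expect_identical(peptide_index(labels), 0:624)
  expect_error(peptide_index("AJ"), "J")
  expect_error(peptide_alphabet(LETTERS), "25")
})

test_that("peptide frequencies match hand-enumerated windows and sum to one", {
  v <- peptide_frequency("AA", 2)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  v <- peptide_frequency("ACAC", 2)
  expect_equal(unname(v["AC"]), 2 / 3)
  expect_equal(unname(v["CA"]), 1 / 3)
  expect_equal(sum(v != 0), 2L)

  v <- peptide_frequency("ACDEFG", 1)
  expect_equal(unname(v[c("A", "C", "D", "E", "F", "G")]), rep(1 / 6, 6))

  expect_error(peptide_frequency("A", 2), "shorter")
  # strict dipeptide-denominator mode agrees at n = 2, differs at n = 3
  expect_equal(peptide_frequency("ACAC", 2, denominator = "L-1"),
               peptide_frequency("ACAC", 2))
  v3 <- peptide_frequency("ACDEF", 3, denominator = "L-1")
  expect_equal(sum(v3), 3 / 4)  # 3 windows / (L-1)
})

test_that("frequency vectors agree with an independent k-mer counting oracle", {
  set.seed(31)
  ab <- peptide_alphabet()
  for (rep in 1:5) {
    s <- paste(sample(unclass(ab), 40, replace = TRUE), collapse = "")
    for (n in 1:2) {
      mine <- peptide_frequency(s, n)
      oracle <- seqinr::count(strsplit(tolower(s), "")[[1]], n,
                              alphabet = tolower(unclass(ab)), freq = TRUE)
      expect_equal(unname(mine), as.vector(oracle), tolerance = 1e-12)
    }
  }
})

test_that("document counts record presence per sequence, invariant to corpus order", {
  cw <- document_counts(c("AC", "CA"), 2)
  expect_identical(cw$N, 2L)
  expect_identical(cw$w[peptide_index("AC") + 1L], 1L)
  expect_identical(cw$w[peptide_index("CA") + 1L], 1L)
  expect_identical(sum(cw$w), 2L)

  cw2 <- document_counts(c("AA", "AA"), 2)
  expect_identical(cw2$w[peptide_index("AA") + 1L], 2L)

  cw3 <- document_counts("AC", 2)
  expect_identical(cw3$w[peptide_index("CA") + 1L], 0L)

  # multiplicity within a sequence does not inflate the document count
  cw4 <- document_counts(c("ACACAC", "CD"), 2)
  expect_identical(cw4$w[peptide_index("AC") + 1L], 1L)

  set.seed(7)
  corpus <- replicate(6, paste(sample(unclass(peptide_alphabet()), 30,
                                      replace = TRUE), collapse = ""))
  expect_identical(document_counts(corpus, 2)$w,
                   document_counts(rev(corpus), 2)$w)
  expect_error(document_counts(character(0), 2), "non-empty")
})

test_that("inverse document frequency is log10(N/w) with undefined zeros", {
  cw <- structure(list(n = 2L, N = 10L,
                       w = c(10L, 1L, 0L, rep(0L, 622L)),
                       labels = peptide_labels(2)),
                  class = "corpus_weights")
  out <- idf(cw)
  expect_equal(unname(out[1]), 0)
  expect_equal(unname(out[2]), 1)
  expect_true(is.na(out[3]))
  cw$N <- 100L
  expect_equal(unname(idf(cw)[2]), 2)
})

test_that("word-frequency encoding multiplies corpus weight into peptide frequency", {
  cw <- document_counts(c("AC", "CA"), 2)
  wf <- wf_encode("AC", cw)
  expect_equal(unname(wf["AC"]), 0.5)
  expect_equal(sum(wf != 0), 1L)

  cw2 <- document_counts(c("AC", "ACA"), 2)
  wf2 <- wf_encode("AC", cw2)
  expect_equal(unname(wf2["AC"]), 1.0)  # w = N makes it the plain frequency

  # wf <= v elementwise, equality exactly where w = N or v = 0
  set.seed(11)
  corpus <- replicate(5, paste(sample(unclass(peptide_alphabet()), 50,
                                      replace = TRUE), collapse = ""))
  cw3 <- document_counts(corpus, 2)
  for (s in corpus[1:2]) {
    v <- peptide_frequency(s, 2)
    wf3 <- wf_encode(s, cw3)
    expect_true(all(wf3 <= v + 1e-15))
    eq <- abs(wf3 - v) < 1e-15
    expect_identical(unname(eq), unname(cw3$w == cw3$N | v == 0))
  }
})

test_that("corpus encoding has the 25^n layout and is deterministic", {
  corpus <- c(p1 = "ACDEFGHIK", p2 = "KIHGFEDCA")
  for (n in 1:3) {
    mat <- encode_corpus(corpus, n = n)
    expect_identical(dim(mat), c(2L, as.integer(25L^n)))
    expect_identical(rownames(mat), c("p1", "p2"))
  }
  expect_identical(colnames(encode_corpus(corpus, n = 2)),
                   peptide_labels(2))
  expect_identical(encode_corpus(corpus, n = 2),
                   encode_corpus(corpus, n = 2))
  expect_error(encode_corpus(character(0), 2), "non-empty")
  # per-sequence failures carry the sequence id
  expect_error(encode_corpus(c(ok = "ACDEF", short = "A"), n = 2), "short")
})

test_that("protein readers accept FASTA and CSV and validate residues", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ACDEFG", ">p2", "KLMNPQ"), fa)
  ps <- read_proteins(fa)
  expect_identical(names(ps), c("p1", "p2"))
  expect_identical(unname(as.character(ps)), c("ACDEFG", "KLMNPQ"))

  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(protein_id = "x", sequence = "ACDEF"),
                   csv, row.names = FALSE)
  expect_identical(unname(as.character(read_proteins(csv))), "ACDEF")

  expect_error(protein_set("ACJX", "bad"), "J")
  remapped <- protein_set("ACJX", "ok", on_invalid = "remap")
  expect_identical(unname(as.character(remapped)), "ACXX")
  expect_error(protein_set(c("AC", "CA"), c("a", "a")), "unique")
})

test_that("encoded matrices round-trip through CSV with peptide headers", {
  mat <- encode_corpus(c(a = "ACAC", b = "CACA"), n = 2)
  path <- tempfile(fileext = ".csv")
  write_encoded_csv(mat, path)
  back <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  expect_identical(colnames(back), peptide_labels(2))
  expect_equal(as.matrix(back), mat, ignore_attr = TRUE)
})
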