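test_that("protein_record enforces alignment and derives the validity mask", {
  rec <- protein_record("P1", "ACD", c(5.0, 900.0, 7.2))
  expect_equal(rec$valid_mask, c(TRUE, FALSE, TRUE))
  expect_equal(length(rec), 3L)
  expect_error(protein_record("P2", "ACD", c(1, 2)), "length")
  expect_error(protein_record("P3", "A1C", c(1, 2, 3)), "invalid character")
  # sentinel is any value >= 900, not just 900 exactly
  rec2 <- protein_record("P4", "AC", c(950.2, 8))
  expect_equal(rec2$valid_mask, c(FALSE, TRUE))
  expect_warning(rec3 <- protein_record("P5", "AB", c(1, 2)), "mapped to 'X'")
  expect_equal(rec3$sequence, "AX")
})

test_that("filter_invalid drops sentinel residues consistently and is idempotent", {
  rec <- protein_record("P1", "ACD", c(5.0, 900.0, 7.2))
  f <- filter_invalid(rec)
  expect_equal(f$sequence, "AD")
  expect_equal(f$scores, c(5.0, 7.2))
  expect_identical(filter_invalid(f), f)
  clean <- protein_record("P2", "AC", c(1, 2))
  expect_identical(filter_invalid(clean), clean)
  allbad <- protein_record("P3", "AC", c(900, 901))
  expect_warning(e <- filter_invalid(allbad), "all residues invalid")
  expect_equal(length(e), 0L)
})

test_that("binarize uses the inclusive-on-disorder threshold of 8", {
  expect_equal(binarize(c(8.0, 16.2, -5.6, 8.0001)),
               c("disorder", "order", "disorder", "order"))
  expect_error(binarize(c(1, 900)), "sentinel")
})

test_that("classify_regions flips SHORT to LONG exactly at a 30-residue run", {
  run30 <- c(rep(10, 10), rep(5, 30), rep(10, 10))
  expect_equal(classify_regions(run30)[11:40], rep("LONG_DISORDER", 30))
  run29 <- c(rep(10, 10), rep(5, 29), rep(10, 10))
  expect_equal(classify_regions(run29)[11:39], rep("SHORT_DISORDER", 29))
  expect_equal(classify_regions(rep(10, 5)), rep("ORDERED", 5))
  expect_error(classify_regions(1:5, lmin = 0), "lmin")
})

test_that("region labels are consistent with binarization", {
  set.seed(11)
  for (i in 1:50) {
    s <- runif(sample(1:100, 1), -5.6, 16.2)
    lab <- classify_regions(s)
    expect_equal(lab != "ORDERED", binarize(s) == "disorder")
  }
})

test_that("one_hot_encode follows the alphabetical column order, X all-zero", {
  m <- one_hot_encode("AXY")
  expect_equal(dim(m), c(3L, 20L))
  expect_equal(as.numeric(m[1, ]), as.numeric(AA_ALPHABET == "A"))
  expect_equal(sum(m[2, ]), 0)
  expect_equal(as.numeric(m[3, ]), as.numeric(AA_ALPHABET == "Y"))
  expect_equal(dim(one_hot_encode("")), c(0L, 20L))
  expect_error(one_hot_encode("A*C"), "position 2")
})

test_that("canonical CheZOD files round-trip bit-identically", {
  recs <- list(
    protein_record("alpha", "ACDEF", c(5, 900, 7.2, -5.6, 16.2)),
    protein_record("beta", "GG", c(1 / 3, sqrt(2)))
  )
  f <- withr::local_tempfile(fileext = ".chezod")
  write_chezod_file(recs, f)
  back <- read_chezod_file(f)
  expect_identical(back, recs)
})

test_that("the reader reports malformed input precisely", {
  f <- withr::local_tempfile(fileext = ".chezod")
  writeLines(c(">p1", "ACD", "1 5.0", "2 900"), f)
  expect_error(read_chezod_file(f), "sequence length 3 != 2 scores")
  writeLines(c(">p1", "AC", "1 1", "2 2", ">p1", "G", "1 1"), f)
  expect_error(read_chezod_file(f), "duplicate id")
  writeLines(c("AC", "1 1"), f)
  expect_error(read_chezod_file(f), "expected '>' header")
  writeLines(c(">p1", "AC", "1 1", "3 2"), f)
  expect_error(read_chezod_file(f), "contiguous")
  writeLines(character(0), f)
  expect_equal(read_chezod_file(f), list())
})

test_that("tolerant three-column residue lines and two-file form parse", {
  f <- withr::local_tempfile(fileext = ".chezod")
  writeLines(c(">p1", "AC", "1 A 5.0", "2 C 900"), f)
  rec <- read_chezod_file(f)[[1]]
  expect_equal(rec$scores, c(5, 900))

  dir <- withr::local_tempdir()
  fa <- file.path(dir, "seqs.fasta")
  write_fasta(c(p9 = "ACD"), fa)
  writeLines(c("1 4.0", "2 900", "3 -1.5"), file.path(dir, "p9.txt"))
  recs <- read_chezod_two_file(fa, dir)
  expect_equal(recs[[1]]$id, "p9")
  expect_equal(recs[[1]]$scores, c(4, 900, -1.5))
})

test_that("the HDF5 embedding container round-trips and enforces contracts", {
  f <- withr::local_tempfile(fileext = ".h5")
  emb <- list(p1 = matrix(rnorm(5 * 8), 5, 8),
              p2 = matrix(rnorm(3 * 8), 3, 8))
  write_embeddings(emb, f)
  back <- read_embeddings(f)
  expect_setequal(names(back), c("p1", "p2"))
  expect_equal(unclass(back$p1), emb$p1, ignore_attr = TRUE)
  expect_error(read_embeddings(f, ids = "nope"), "not in container")
  expect_error(write_embeddings(list(a = matrix(0, 2, 8), b = matrix(0, 2, 4)), f),
               "share one dimension")
})
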