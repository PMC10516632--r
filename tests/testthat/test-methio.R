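write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("coverage files parse with header skipping and field mapping", {
  path <- write_lines_tmp(c("#chrom\tpos\tmeth\ttotal",
                            "chr1\t33746587\t3\t4",
                            "chr1\t100\t0\t5"))
  rec <- read_coverage_file(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$chrom[1], "chr1")
  expect_equal(rec$pos[1], 33746587)
  expect_equal(rec$meth_count[1], 3L)
  expect_equal(rec$total_count[1], 4L)
})

test_that("empty and gzipped coverage files are handled", {
  empty <- write_lines_tmp(character(0))
  expect_equal(nrow(read_coverage_file(empty)), 0L)

  gz <- withr::local_tempfile(fileext = ".cov.gz")
  con <- gzfile(gz, "wt")
  writeLines("chr2\t500\t2\t2", con)
  close(con)
  rec <- read_coverage_file(gz)
  expect_equal(rec$pos, 500)
  expect_equal(rec$total_count, 2L)
})

test_that("malformed and invalid coverage lines fail with a line number", {
  bad <- write_lines_tmp(c("chr1\t10\t1\t2", "chr1\t20\t1"))
  expect_error(read_coverage_file(bad), "line 2")
  overflow <- write_lines_tmp("chr1\t100\t5\t4")
  expect_error(read_coverage_file(overflow), "line 1")
  nonnum <- write_lines_tmp("chr1\txyz\t1\t2")
  expect_error(read_coverage_file(nonnum), "pos")
})

test_that("binarize rounds half up and is monotone in meth_count", {
  expect_identical(binarize(3, 4), 1L)
  expect_identical(binarize(0, 5), 0L)
  expect_identical(binarize(1, 2), 1L)  # tie -> methylated
  expect_error(binarize(1, 0), "total_count")
  expect_error(binarize(5, 4), "meth_count")
  for (total in c(1, 3, 8)) {
    states <- binarize(0:total, rep(total, total + 1))
    expect_true(all(diff(states) >= 0))
  }
})

test_that("build_matrices takes the union of covered positions", {
  recs <- list(
    data.frame(chrom = "chr1", pos = c(10, 20),
               meth_count = c(2, 0), total_count = c(2, 3)),
    data.frame(chrom = "chr1", pos = c(20, 30),
               meth_count = c(3, 1), total_count = c(4, 1)))
  mats <- build_matrices(recs, c("A", "B"))
  m <- mats$chr1
  expect_equal(m$positions, c(10, 20, 30))
  expect_equal(n_observed(m), 4L)
  expect_equal(sparsity(m), 1 - 4 / 6)
  expect_identical(entry_state(m, 1, 1), 1L)   # A @10: 2/2
  expect_identical(entry_state(m, 1, 2), 0L)   # A @20: 0/3
  expect_identical(entry_state(m, 2, 2), 1L)   # B @20: 3/4
  expect_true(is.na(entry_state(m, 2, 1)))
})

test_that("duplicate records for one cell/position merge by summed counts", {
  recs <- list(data.frame(chrom = "chr1", pos = c(50, 50),
                          meth_count = c(1, 0), total_count = c(2, 2)))
  m <- build_matrices(recs, "A")$chr1
  # (1,2) + (0,2) -> (1,4) -> ratio 0.25 -> state 0
  expect_identical(entry_state(m, 1, 1), 0L)
  expect_equal(n_observed(m), 1L)
})

test_that("single record gives a fully observed 1x1 matrix", {
  m <- build_matrices(list(data.frame(chrom = "chrX", pos = 7,
                                      meth_count = 1, total_count = 1)),
                      "A")$chrX
  expect_equal(dim(m$M), c(1L, 1L))
  expect_equal(sparsity(m), 0)
})

test_that("default chromosome split partitions by the naming-robust rule", {
  mats <- list(chr1 = random_matrix(1, chrom = "chr1"),
               chr2 = random_matrix(2, chrom = "chr2"),
               chr13 = random_matrix(3, chrom = "chr13"),
               chrX = random_matrix(4, chrom = "chrX"),
               `14` = random_matrix(5, chrom = "14"))
  sp <- split_matrices(mats)
  expect_setequal(names(sp$train), c("chr1", "chrX"))
  expect_setequal(names(sp$val), c("chr13", "14"))
  expect_setequal(names(sp$test), "chr2")
  empty <- split_matrices(structure(list(), names = character()))
  expect_equal(lengths(empty), c(train = 0L, val = 0L, test = 0L))
})

test_that("overlapping custom splits are rejected", {
  expect_error(chromosome_split(train = "chr1", test = c("1", "4")),
               "more than one split")
})

test_that("matrix triplet serialization round-trips exactly", {
  m <- random_matrix(11, N = 4, P = 30, density = 0.4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_triplets(m, path)
  m2 <- read_matrix_triplets(path)
  expect_identical(observed_entries(m2), observed_entries(m))
  expect_identical(m2$cells, m$cells)
  expect_equal(m2$positions, m$positions)
})

test_that("write_imputed echoes observations and guards against leakage", {
  m <- meth_matrix("chr1", c("A", "B"), c(10, 20, 30),
                   data.frame(u = c(1, 2), v = c(1, 2), state = c(1, 0)))
  dir <- withr::local_tempdir()
  preds <- data.frame(u = 1L, v = 2L, prob = 0.73)
  paths <- write_imputed(m, preds, dir)
  a <- utils::read.table(file.path(dir, "A.tsv"), header = TRUE, sep = "\t")
  expect_equal(a$source, c("observed", "imputed"))
  expect_equal(a$value, c(1, 0.73))
  expect_equal(a$pos, c(10, 20))
  # second write is byte-identical (deterministic output)
  before <- readLines(file.path(dir, "A.tsv"))
  write_imputed(m, preds, dir)
  expect_identical(readLines(file.path(dir, "A.tsv")), before)
  # prediction at an observed key is a leakage error
  expect_error(write_imputed(m, data.frame(u = 1L, v = 1L, prob = 0.5), dir),
               "observed entry")
  # no predictions: observations only
  dir2 <- withr::local_tempdir()
  write_imputed(m, NULL, dir2)
  b <- utils::read.table(file.path(dir2, "B.tsv"), header = TRUE, sep = "\t")
  expect_equal(b$source, "observed")
})

test_that("meth_matrix validates entries", {
  expect_error(meth_matrix("c", "A", c(10, 5), data.frame()), "increasing")
  expect_error(meth_matrix("c", "A", 10,
                           data.frame(u = 1, v = 2, state = 1)),
               "out of range")
  expect_error(meth_matrix("c", "A", c(10, 20),
                           data.frame(u = c(1, 1), v = c(1, 1),
                                      state = c(1, 0))),
               "duplicate")
  expect_error(meth_matrix("c", "A", 10,
                           data.frame(u = 1, v = 1, state = 2)),
               "0 or 1")
})
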