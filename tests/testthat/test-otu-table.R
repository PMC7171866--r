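test_that("reading a table returns validated samples x taxa counts", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\tS1\tS2", "t1\t3\t1", "t2\t0\t2"), tf)
  x <- read_otu_table(tf)
  expect_identical(dim(x), c(2L, 2L))
  expect_identical(rownames(x), c("S1", "S2"))
  expect_identical(unname(rowSums(x)), c(3, 3))
  # samples-as-rows orientation gives the transpose
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tt1\tt2", "S1\t3\t0", "S2\t1\t2"), tf2)
  expect_identical(read_otu_table(tf2, orientation = "samples_as_rows"), x)
})

test_that("write/read round trip preserves counts bit-exactly", {
  x <- rand_table(5, 12, seed = 7)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(x, tf, header = c("fixture"))
  expect_identical(read_otu_table(tf), x)
})

test_that("malformed tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\tS1\tS2", "t1\t3\t-1", "t2\t0\t2"), tf)
  expect_error(read_otu_table(tf), "t1.*S2|S2.*t1")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\tS1\tS2", "t1\t3\t1", "t1\t0\t2"), tf2)
  expect_error(read_otu_table(tf2), "duplicate")
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\tS1\tS2", "t1\t3\t1.5", "t2\t0\t2"), tf3)
  expect_error(read_otu_table(tf3), "non-integer")
})

test_that("rarefaction conserves depth, drops shallow samples, never inflates", {
  x <- ct(c(10L, 10L), c(5L, 30L))
  r <- rarefy(x, depth = 10, seed = 3)
  expect_identical(unname(rowSums(r)), rep(10, nrow(r)))
  expect_true(all(r <= x[rownames(r), colnames(r)]))
  # a sample holding exactly `depth` reads passes through unchanged
  x2 <- ct(c(4L, 6L), c(20L, 30L))
  r2 <- rarefy(x2, depth = 10, seed = 1)
  expect_identical(r2["S1", ], x2["S1", ])
  # the 4060-read preset drops a 4059-read sample with a warning
  x3 <- ct(c(4059L, 0L), c(4000L, 100L))
  expect_warning(r3 <- rarefy(x3, depth = 4060, seed = 1), "S1")
  expect_identical(rownames(r3), "S2")
  expect_identical(unname(sum(r3)), 4060L)
  # depth no sample reaches -> error
  expect_error(rarefy(x, depth = 1e6), "no sample")
  # deterministic given seed
  big <- rand_table(4, 30, seed = 2, depth = 500)
  expect_identical(rarefy(big, 200, seed = 9), rarefy(big, 200, seed = 9))
})

test_that("low-abundance filter uses a strict > threshold per taxon", {
  x <- ct(c(51L, 50L, 49L), c(50L, 50L, 50L))
  expect_identical(colnames(filter_low_abundance(x, 100)), "t1") # totals 101/100/99
  # threshold 0 removes only all-zero taxa
  x2 <- cbind(x, t4 = c(0L, 0L))
  expect_identical(colnames(filter_low_abundance(x2, 0)), c("t1", "t2", "t3"))
  # per-taxon independence: totals unaffected by other columns
  expect_identical(filter_low_abundance(x, 100),
                   filter_low_abundance(x2, 100)[, "t1", drop = FALSE])
  expect_error(filter_low_abundance(x, 1e6), "every taxon")
})

test_that("taxon classes use strict thresholds and partition the taxa", {
  # taxon at 0.2% mean abundance -> abundant; exactly 0.1% -> intermediate
  n <- 1000L
  x <- ct(c(2L, 1L, 500L, n - 503L),
          c(2L, 1L, 500L, n - 503L),
          taxa = c("at02", "at01", "big", "rest"))
  # mean rel abund: 0.2%, 0.1%, 50%, ...
  cls <- classify_taxa(x)
  expect_equal(cls$mean_rel_abund[cls$taxon == "at02"], 0.002)
  expect_identical(as.character(cls$abundance_class[cls$taxon == "at02"]), "abundant")
  expect_identical(as.character(cls$abundance_class[cls$taxon == "at01"]), "intermediate")
  # full occupancy -> cosmopolitan
  expect_identical(as.character(cls$range_class[cls$taxon == "big"]), "cosmopolitan")
  # classes partition taxa
  big <- rand_table(10, 50, seed = 5)
  cl2 <- classify_taxa(big)
  expect_identical(sum(table(cl2$abundance_class)), 50L)
  expect_identical(sum(table(cl2$range_class)), 50L)
  expect_false(anyNA(cl2$abundance_class))
})
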