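test_that("beta-MNTD matches hand evaluation and the double-loop oracle", {
  # Delta(A,C) = 2, Delta(B,C) = 4: k = {A: .5, B: .5}, m = {C: 1} -> 2.5
  tr <- ape::read.tree(text = "((A:1,C:1):2,B:1);")
  x <- ct(c(1L, 1L, 0L), c(0L, 0L, 3L), taxa = c("A", "B", "C"),
          samples = c("k", "m"))
  expect_equal(as.matrix(bmntd(x, tr))["k", "m"], 2.5)
  # identical communities -> 0 (nearest neighbour is the shared taxon itself)
  ident <- ct(c(2L, 3L, 1L), c(2L, 3L, 1L), taxa = c("A", "B", "C"))
  expect_equal(as.matrix(bmntd(ident, tr))["S1", "S2"], 0)
  # empty community -> error
  empty <- ct(c(1L, 0L, 0L), c(0L, 0L, 0L), taxa = c("A", "B", "C"))
  expect_error(bmntd(empty, tr), "empty|zero")
  # oracle equivalence on random instances, both weightings
  for (seed in 1:10) {
    trr <- rand_tree(9, seed = seed)
    xx <- rand_table(5, 9, seed = 200 + seed, depth = 40)
    expect_equal(as.matrix(bmntd(xx, trr)), bmntd_brute(xx, trr),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(as.matrix(bmntd(xx, trr, weighted = FALSE)),
                 bmntd_brute(xx, trr, weighted = FALSE),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("beta-MNTD agrees with picante's comdistnt", {
  skip_if_not_installed("picante")
  tr <- rand_tree(15, seed = 4)
  x <- rand_table(6, 15, seed = 44, depth = 80)
  got <- as.matrix(bmntd(x, tr))
  ref <- as.matrix(picante::comdistnt(x, stats::cophenetic(tr),
                                      abundance.weighted = TRUE))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("beta-NTI centers on its null and matches exhaustive tip relabeling", {
  # exhaustive oracle: 4 taxa, all 4! relabelings computed independently
  tr <- rand_tree(4, seed = 9)
  x <- ct(c(5L, 1L, 0L, 2L), c(0L, 3L, 4L, 1L), c(2L, 0L, 1L, 5L))
  res <- bnti(x, tr, null = "exhaustive")
  # enumerate permutations independently of the package helper
  pm <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  pm <- pm[apply(pm, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
  expect_identical(nrow(pm), 24L)
  vals <- vapply(seq_len(nrow(pm)), function(i) {
    xs <- x
    colnames(xs) <- colnames(x)[pm[i, ]] # relabel taxa across tips
    bmntd_brute(xs[, colnames(x)], tr)["S1", "S2"]
  }, numeric(1))
  want <- (bmntd_brute(x, tr)["S1", "S2"] - mean(vals)) / sd(vals)
  expect_equal(res$bnti["S1", "S2"], want, tolerance = 1e-10)
  # observed equal to null mean -> bNTI 0 (identity of the standardization)
  expect_equal((res$null_mean - res$null_mean)[1, 2] / res$null_sd[1, 2], 0)
})

test_that("degenerate geometry (equidistant tips) yields NA bNTI with warning", {
  star <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0);")
  x <- ct(c(5L, 1L, 0L, 0L), c(0L, 0L, 4L, 1L))
  colnames(x) <- c("A", "B", "C", "D")
  expect_warning(res <- bnti(x, star, n_null = 19, seed = 1), "NA")
  expect_true(is.na(res$bnti["S1", "S2"]))
})

test_that("bNTI is deterministic given the seed", {
  tr <- rand_tree(12, seed = 2)
  x <- rand_table(4, 12, seed = 3, depth = 60)
  a <- bnti(x, tr, n_null = 99, seed = 7)
  b <- bnti(x, tr, n_null = 99, seed = 7)
  expect_identical(a$bnti, b$bnti)
})

test_that("process classification applies the two-step threshold rule", {
  labs <- c("A", "B", "C", "D")
  z <- matrix(0, 4, 4, dimnames = list(labs, labs))
  rc <- matrix(0, 4, 4, dimnames = list(labs, labs))
  z[2, 1] <- z[1, 2] <- 3      # -> heterogeneous selection
  z[3, 1] <- z[1, 3] <- -2.5   # -> homogeneous selection
  z[4, 1] <- z[1, 4] <- 1;  rc[4, 1] <- rc[1, 4] <- 0.99  # -> dispersal limitation
  z[3, 2] <- z[2, 3] <- -1; rc[3, 2] <- rc[2, 3] <- 0     # -> drift
  z[4, 2] <- z[2, 4] <- 0;  rc[4, 2] <- rc[2, 4] <- -0.99 # -> homogenizing dispersal
  z[4, 3] <- z[3, 4] <- 2;  rc[4, 3] <- rc[3, 4] <- 0.95  # boundaries are strict -> drift
  calls <- classify_processes(z, rc)
  got <- setNames(as.character(calls$process), paste(calls$sample_1, calls$sample_2))
  expect_identical(got[["A B"]], "heterogeneous_selection")
  expect_identical(got[["A C"]], "homogeneous_selection")
  expect_identical(got[["A D"]], "dispersal_limitation")
  expect_identical(got[["B C"]], "drift")
  expect_identical(got[["B D"]], "homogenizing_dispersal")
  expect_identical(got[["C D"]], "drift")
  s <- process_summary(calls)
  expect_equal(sum(s$fraction), 1)
  expect_identical(sum(s$n_pairs), nrow(calls))
  # every pair gets exactly one label
  expect_false(anyNA(calls$process))
})

test_that("NA bNTI pairs are excluded from the summary but counted", {
  labs <- c("A", "B", "C")
  z <- matrix(c(0, NA, 3, NA, 0, 0, 3, 0, 0), 3, 3, dimnames = list(labs, labs))
  rc <- matrix(0, 3, 3, dimnames = list(labs, labs))
  calls <- classify_processes(z, rc)
  s <- process_summary(calls)
  expect_identical(sum(s$n_pairs), 2L)
  expect_identical(attr(s, "n_unclassified"), 1L)
  expect_equal(sum(s$fraction), 1)
})
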