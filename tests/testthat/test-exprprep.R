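# Count I/O, size factors, the log-normalization, gene filtering, RIN
# binning and batch centering.

test_that("TSV counts round-trip through write/read unchanged", {
  m <- matrix(c(0L, 5L, 10L, 3L, 7L, 2L), 3, 2,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, path)
  back <- read_counts(path)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_identical(attr(back, "layer"), "counts")
})

test_that("MatrixMarket triplets restore implicit zeros densely", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 3", "1 1 4", "3 1 2", "2 2 9"),
             file.path(dir, "counts.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes.tsv"))
  writeLines(c("sA", "sB"), file.path(dir, "samples.tsv"))
  m <- read_counts(file.path(dir, "counts.mtx"))
  expected <- matrix(c(4L, 0L, 2L, 0L, 9L, 0L), 3, 2,
                     dimnames = list(c("g1", "g2", "g3"), c("sA", "sB")))
  expect_equal(unclass(m), unclass(expected), ignore_attr = TRUE)
})

test_that("malformed count files fail with the offending record named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "GDUP\t1\t2", "GDUP\t3\t4"), path)
  expect_error(read_counts(path), "GDUP")
  writeLines(c("gene_id\ts1", "GA\t1.5"), path)
  expect_error(read_counts(path), "non-integer")
  expect_error(read_counts(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("size factors follow the median-of-ratios law", {
  m <- matrix(rep(c(10L, 20L, 40L), 3), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  attr(m, "layer") <- "counts"
  expect_equal(size_factors(m), c(s1 = 1, s2 = 1, s3 = 1))

  a <- c(10L, 20L, 40L, 5L)
  m2 <- cbind(A = a, B = 2L * a)
  rownames(m2) <- paste0("g", 1:4)
  attr(m2, "layer") <- "counts"
  f <- size_factors(m2)
  expect_equal(unname(f["B"] / f["A"]), 2)
  expect_equal(exp(mean(log(f))), 1)

  single <- m2[, "A", drop = FALSE]
  attr(single, "layer") <- "counts"
  expect_equal(unname(size_factors(single)), 1)
})

test_that("size factors are scale-equivariant per sample", {
  set.seed(1)
  m <- matrix(rpois(60, 50) + 1L, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  attr(m, "layer") <- "counts"
  f0 <- size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  f1 <- size_factors(m2)
  ratio0 <- f0 / f0[1]
  ratio1 <- f1 / f1[1]
  expect_equal(unname(ratio1[3] / ratio0[3]), 4, tolerance = 1e-12)
  expect_equal(unname(ratio1[-3]), unname(ratio0[-3]), tolerance = 1e-12)
})

test_that("size factors demand a gene expressed in all samples", {
  m <- matrix(c(0L, 3L, 2L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  attr(m, "layer") <- "counts"
  expect_error(size_factors(m), "pre-filter")
})

test_that("the log-normalization is anchored, monotone and invertible", {
  m <- matrix(c(0L, 2L, 5L, 9L), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  v <- vst_like(m, factors = 2)
  expect_equal(v["g1", 1], 0)           # count 0 -> 0
  expect_equal(unname(vst_like(matrix(3L, 1, 1, dimnames = list("g", "s")), 3)[1, 1]), 1)
  expect_true(all(diff(v[, 1]) > 0))    # strictly increasing
  back <- (2^v - 1) * 2
  expect_equal(unname(back[, 1]), as.numeric(m[, 1]), tolerance = 1e-12)
  expect_error(vst_like(m, factors = c(-1)), "positive")
})

test_that("gene filtering applies keep-list, zero and low-expression rules in order", {
  # 6 genes / 4 samples: 2 non-coding, 1 all-zero, 1 low-expressed -> 2 kept
  # (faint is >= 1 in only 1/4 samples: 3/4 = 0.75 of samples below threshold,
  # above the 0.7 fraction used here)
  m <- rbind(coding1 = c(50L, 60L, 40L, 55L),
             coding2 = c(30L, 20L, 35L, 25L),
             dead    = c(0L, 0L, 0L, 0L),
             faint   = c(1L, 0L, 0L, 0L),
             junk1   = c(10L, 10L, 10L, 10L),
             junk2   = c(5L, 5L, 5L, 5L))
  colnames(m) <- paste0("s", 1:4)
  attr(m, "layer") <- "counts"
  res <- filter_genes(m, keep_list = c("coding1", "coding2", "dead", "faint"),
                      low_expr_fraction = 0.7, factors = rep(1, 4))
  expect_identical(rownames(res$counts), c("coding1", "coding2"))
  expect_equal(unname(res$report$n_removed),
               c(2L, 1L, 1L))
  expect_equal(res$report$n_input - sum(res$report$n_removed),
               res$report$n_retained)
})

test_that("the low-expression fraction bound is strict", {
  # 20 samples, expression >= 1 in exactly one sample: below-threshold
  # fraction is 19/20 = 0.95, not > 0.95, so the gene stays
  m <- rbind(edge = c(5L, rep(0L, 19L)),
             anchor = rep(10L, 20L))
  colnames(m) <- paste0("s", 1:20)
  attr(m, "layer") <- "counts"
  res <- filter_genes(m, factors = rep(1, 20))
  expect_true("edge" %in% rownames(res$counts))
})

test_that("filtering a filtered matrix removes nothing", {
  set.seed(8)
  m <- matrix(rnbinom(400, mu = 30, size = 5), 20, 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:20)))
  m[3, ] <- 0L
  storage.mode(m) <- "integer"
  attr(m, "layer") <- "counts"
  once <- filter_genes(m)
  twice <- filter_genes(once$counts)
  expect_identical(rownames(twice$counts), rownames(once$counts))
  expect_equal(sum(twice$report$n_removed), 0L)
})

test_that("RIN values bin into the 7 half-width classes", {
  expect_identical(bin_rin(7.2), 2L)
  expect_identical(bin_rin(10), 7L)
  expect_identical(bin_rin(7.0), 2L)   # boundary assigned rightward
  expect_identical(bin_rin(c(6.5, 9.49, 9.5)), c(1L, 6L, 7L))
  expect_error(bin_rin(6.4), "out of range")
  expect_error(bin_rin(10.2), "out of range")
})

test_that("batch centering removes offsets and preserves per-gene grand means", {
  set.seed(3)
  base <- matrix(rnorm(40, 5), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  attr(base, "layer") <- "normalized"
  expect_equal(batch_center(base, rep("b1", 10)), base)

  batch <- rep(c("b1", "b2"), each = 5)
  shifted <- base
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + c(1, -2, 0.5, 3)
  attr(shifted, "layer") <- "normalized"
  out <- batch_center(shifted, batch)
  m1 <- rowMeans(out[, batch == "b1"])
  m2 <- rowMeans(out[, batch == "b2"])
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(rowMeans(out), rowMeans(shifted), tolerance = 1e-10)
  expect_error(batch_center(shifted, c(batch[-1], NA)), "batch label")
})
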