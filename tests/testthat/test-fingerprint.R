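# Interactant assembly, stability selection, direction assignment and the
# up/down deviation scores.

test_that("interactant lists merge into an ordered de-duplicated union", {
  r <- assemble_interactants(c("A", "B"), c("B", "C", "D"), c("A", "C"))
  expect_identical(r$union, c("A", "B", "C", "D"))
  expect_identical(r$present, c("A", "C"))
  expect_identical(r$absent, c("B", "D"))

  # two lists of sizes 210 and 276 with overlap 179 -> union 307
  a <- sprintf("GENE%03d", 1:210)
  b <- sprintf("GENE%03d", 32:307)    # 179 shared with a
  r2 <- assemble_interactants(a, b, dataset_genes = sprintf("GENE%03d", 1:248))
  expect_length(r2$union, 307)
  expect_length(r2$present, 248)
  expect_length(r2$absent, 59)

  expect_warning(assemble_interactants("X", "Y", c("A", "B")), "no interactant")
  expect_error(assemble_interactants(character(0), "A", "A"), "empty")
})

test_that("a strongly separating gene reaches frequency 1 among noise", {
  set.seed(21)
  n <- 60
  lab <- rep(c("C1", "C2"), each = n / 2)
  p <- 80
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%03d", 1:p), sprintf("s%02d", 1:n)))
  x["g001", lab == "C2"] <- x["g001", lab == "C2"] + 3   # 3-unit separation
  attr(x, "layer") <- "normalized"
  panel <- stability_select(x, lab, rownames(x), B = 25, threshold = 1.0,
                            seed = 4, ntree = 100)
  g <- panel$genes
  expect_equal(g$frequency[g$gene_id == "g001"], 1.0)
  expect_true(g$selected[g$gene_id == "g001"])
  # pure-noise candidates almost never survive a 100% threshold
  expect_lte(sum(g$selected), 2)
})

test_that("stability selection rejects degenerate inputs", {
  x <- toy_norm(rnorm(40), 4, 10)
  lab <- rep(c("a", "b"), each = 5)
  expect_error(stability_select(x, lab, rownames(x), B = 0), "B must")
  expect_error(stability_select(x, lab, c("nope1", "nope2"), B = 5), "candidate")
  expect_error(stability_select(x, rep("a", 10), rownames(x), B = 5), ">= 2 clusters")
})

test_that("selection frequencies are invariant to candidate ordering", {
  set.seed(22)
  x <- toy_norm(rnorm(20 * 30), 20, 30)
  x[1:3, 16:30] <- x[1:3, 16:30] + 2.5
  lab <- rep(c("C1", "C2"), each = 15)
  f1 <- stability_select(x, lab, rownames(x), B = 8, seed = 11, ntree = 60)
  f2 <- stability_select(x, lab, rev(rownames(x)), B = 8, seed = 11, ntree = 60)
  expect_identical(f1$genes, f2$genes)
})

test_that("directions reflect the reference-cluster contrast", {
  x <- toy_norm(0, 3, 6)
  lab <- c("C3", "C3", "C1", "C1", "C2", "C2")
  x["g1", lab == "C3"] <- 5    # higher in reference -> +1
  x["g2", lab == "C3"] <- -5   # lower -> -1
  # g3 exactly tied -> falls back to +1
  panel <- suppressWarnings(
    stability_select(x + matrix(rnorm(18, sd = 1e-3), 3), lab,
                     rownames(x), B = 2, threshold = 0.0001, seed = 1,
                     ntree = 30))
  panel$genes$selected <- TRUE
  panel <- split_directions(x, lab, panel, ref_cluster = "C3")
  d <- setNames(panel$genes$direction, panel$genes$gene_id)
  expect_equal(unname(d[c("g1", "g2", "g3")]), c(1L, -1L, 1L))
  expect_error(split_directions(x, lab, panel, ref_cluster = "C9"), "empty")
})

test_that("the deviation score obeys its median law", {
  hv <- toy_norm(c(1, 2, 3, 4, 5), 5, 3)   # per-gene HV medians 1..5
  genes <- rownames(hv)
  y <- setNames(c(2, 4, 6, 8, 10), genes)
  expect_equal(score(y, hv, genes), 3)      # deviations 1..5, median 3

  med <- apply(hv, 1, median)
  expect_equal(score(setNames(med, genes), hv, genes), 0)         # identity
  expect_equal(score(setNames(med + 1.7, genes), hv, genes), 1.7) # shift equivariance

  # invariant to genes outside the set and to gene order
  y2 <- c(y, junk = 99)
  expect_equal(score(y2, hv, genes), 3)
  expect_equal(score(y, hv, rev(genes)), 3)

  expect_error(score(y, hv, character(0)), "empty")
  expect_error(score(y, hv, c(genes, "ghost")), "ghost")
})

test_that("even-sized gene sets use the midpoint median", {
  hv <- toy_norm(0, 4, 3)
  y <- setNames(c(1, 2, 5, 10), rownames(hv))
  expect_equal(score(y, hv, rownames(hv)), (2 + 5) / 2)
})

test_that("z-normalization matches its closed form", {
  expect_equal(z_normalize_scores(3, c(0, 2)), (3 - 1) / sqrt(2))
  hv <- c(0.3, -0.2, 1.1, 0.7)
  z <- z_normalize_scores(hv, hv)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(z_normalize_scores(mean(hv), hv), 0)
  expect_error(z_normalize_scores(1, c(2, 2)), "zero variance")
  expect_error(z_normalize_scores(1, 2), ">= 2")
})

test_that("healthy-volunteer leave-one-out scores center near zero", {
  set.seed(23)
  n_hv <- 100
  genes <- sprintf("g%02d", 1:48)
  hv <- matrix(rnorm(48 * n_hv, mean = 5, sd = 0.5), 48, n_hv,
               dimnames = list(genes, sprintf("h%03d", 1:n_hv)))
  attr(hv, "layer") <- "normalized"
  loo <- vapply(seq_len(n_hv), function(i) {
    score(setNames(hv[, i], genes), hv[, -i, drop = FALSE], genes)
  }, numeric(1))
  expect_lt(abs(median(loo)), 0.05)
})

test_that("score_samples produces ordered severity on a planted cohort", {
  f <- cohort_fixture(seed = 31, n_hv = 40,
                      n_per_cluster = c(C1 = 25, C2 = 30, C3 = 20),
                      n_genes = 300)
  fp <- f$sim$truth$fingerprint
  fp <- fp[fp$gene_id %in% rownames(f$norm), ]
  panel <- structure(list(genes = data.frame(gene_id = fp$gene_id,
                                             frequency = 1, selected = TRUE,
                                             direction = fp$direction,
                                             stringsAsFactors = FALSE),
                          B = 1L, threshold = 1, rule = "shadow"),
                     class = "fingerprint_panel")
  sc <- score_samples(f$norm, panel, f$hv)
  cl <- f$sim$truth$cluster[sc$sample_id]
  med <- function(v, g) median(v[!is.na(cl) & cl == g])
  expect_gt(med(sc$z_up, "C3"), med(sc$z_up, "C1"))
  expect_gt(med(sc$z_up, "C1"), med(sc$z_up, "C2"))
  expect_lt(med(sc$z_down, "C3"), med(sc$z_down, "C1"))
  expect_lt(med(sc$z_down, "C1"), med(sc$z_down, "C2"))
  # recovered directions agree with planted ones for >= 95% of genes
  sel <- stability_select(f$norm[, f$pat], f$truth_cluster, fp$gene_id,
                          B = 2, threshold = 0.0001, seed = 1, ntree = 50)
  sel$genes$selected <- TRUE
  sel <- split_directions(f$norm[, f$pat], f$truth_cluster, sel,
                          ref_cluster = "C3")
  m <- merge(sel$genes, fp, by = "gene_id")
  expect_gte(mean(m$direction.x == m$direction.y), 0.95)
})
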