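# Synthetic cohort and preclinical generators: determinism, planted
# structure, NB moment consistency, and truth-file integrity.

test_that("generators are reproducible from their seed", {
  a <- gen_cohort(cohort_config(seed = 11, n_hv = 10,
                                n_per_cluster = c(C1 = 8, C2 = 9, C3 = 7),
                                n_genes = 100))
  b <- gen_cohort(cohort_config(seed = 11, n_hv = 10,
                                n_per_cluster = c(C1 = 8, C2 = 9, C3 = 7),
                                n_genes = 100))
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)

  p1 <- gen_preclinical(preclinical_config(seed = 3, arms = c(control = 4, disease = 4, T1 = 4),
                                           reversal_fraction = c(T1 = 0.5),
                                           n_genes = 100, n_degs_up = 18, n_degs_down = 2))
  p2 <- gen_preclinical(preclinical_config(seed = 3, arms = c(control = 4, disease = 4, T1 = 4),
                                           reversal_fraction = c(T1 = 0.5),
                                           n_genes = 100, n_degs_up = 18, n_degs_down = 2))
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$truth, p2$truth)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(cohort_config(dispersion = 0), "dispersion")
  expect_error(cohort_config(n_hv = 0), ">= 1")
  expect_error(cohort_config(n_genes = 30), "fingerprint")
  expect_error(preclinical_config(reversal_fraction = c(D11 = 1.2, E07 = 0.8, TD139 = 0.5)),
               "\\[0, 1\\]")
  expect_error(preclinical_config(arms = c(control = 5, T1 = 5),
                                  reversal_fraction = c(T1 = 0.5)),
               "control and one disease")
})

test_that("NB means follow libsize * base * 2^(signed effect)", {
  # large HV arm: per-gene mean of counts/libsize should sit within 3 MC
  # standard errors of the generating mean
  cc <- cohort_config(seed = 5, n_hv = 200, n_per_cluster = c(C1 = 2, C2 = 2, C3 = 200),
                      n_genes = 120, dispersion = 0.1)
  sim <- gen_cohort(cc)
  lib <- sim$truth$libsize
  base <- sim$truth$base_expression
  hv <- sim$meta$sample_id[sim$meta$role == "HV"]
  c3 <- sim$meta$sample_id[!is.na(sim$meta$cluster) & sim$meta$cluster == "C3"]
  fp <- sim$truth$fingerprint

  check_group <- function(ids, expected_mu) {
    scaled <- sweep(sim$counts[, ids], 2, lib[ids], "/")
    m <- rowMeans(scaled)
    # var(count/lib) = mu/lib + alpha*mu^2; MC se of the mean over n samples
    v <- rowMeans(sweep(outer(expected_mu, lib[ids]), 2, lib[ids]^2, "/") +
                    0.1 * outer(expected_mu^2, rep(1, length(ids))))
    se <- sqrt(v / length(ids))
    max(abs(m - expected_mu) / se)
  }
  expect_lt(check_group(hv, base), 3)
  mu_c3 <- base
  mu_c3[fp$gene_id] <- base[fp$gene_id] * 2^(1.0 * fp$direction)
  expect_lt(check_group(c3, mu_c3), 3.5)  # 120 genes, max-abs z
})

test_that("zero effect sizes leave no recoverable cluster structure", {
  aris <- vapply(1:20, function(s) {
    f <- cohort_fixture(seed = s, n_hv = 10,
                        n_per_cluster = c(C1 = 20, C2 = 25, C3 = 15),
                        n_genes = 150,
                        effect_sizes = c(C1 = 0, C2 = 0, C3 = 0))
    cl <- consensus_cluster(f$norm[, f$pat], k = 3, seed = s, n_features = 150)
    idx <- !is.na(cl$consensus)
    if (sum(idx) < 10) return(0)
    adjusted_rand(cl$consensus[idx], f$truth_cluster[idx])
  }, numeric(1))
  expect_lt(abs(median(aris)), 0.1)
})

test_that("truth satisfies referential integrity", {
  sim <- gen_cohort(cohort_config(seed = 2, n_hv = 10,
                                  n_per_cluster = c(C1 = 5, C2 = 5, C3 = 5),
                                  n_genes = 100))
  expect_true(all(sim$truth$fingerprint$gene_id %in% rownames(sim$counts)))
  expect_identical(names(sim$truth$cluster), colnames(sim$counts))

  pre <- gen_preclinical(preclinical_config(seed = 2, arms = c(control = 4, disease = 4, T1 = 4),
                                            reversal_fraction = c(T1 = 0.6),
                                            n_genes = 200, n_degs_up = 45, n_degs_down = 5))
  expect_true(all(pre$truth$degs$gene_id %in% rownames(pre$counts)))
  expect_true(all(unlist(pre$truth$reversed) %in% pre$truth$degs$gene_id))
})

test_that("reversal fraction 1 restores control means, 0 keeps disease means", {
  mk <- function(f) gen_preclinical(
    preclinical_config(seed = 9, arms = c(control = 40, disease = 40, T1 = 40),
                       reversal_fraction = c(T1 = f), n_genes = 150,
                       n_degs_up = 28, n_degs_down = 2,
                       base_meanlog = 6, base_sdlog = 0.5,
                       dispersion = 1e-4, libsize_range = c(1, 1)))
  full <- mk(1.0)
  expect_setequal(full$truth$reversed$T1, full$truth$degs$gene_id)
  deg <- full$truth$degs$gene_id
  ctrl <- full$meta$sample_id[full$meta$arm == "control"]
  trt <- full$meta$sample_id[full$meta$arm == "T1"]
  rel <- abs(rowMeans(full$counts[deg, trt]) / rowMeans(full$counts[deg, ctrl]) - 1)
  expect_lt(max(rel), 0.1)

  none <- mk(0.0)
  expect_length(none$truth$reversed$T1, 0)
  deg <- none$truth$degs$gene_id
  dis <- none$meta$sample_id[none$meta$arm == "disease"]
  trt <- none$meta$sample_id[none$meta$arm == "T1"]
  rel <- abs(rowMeans(none$counts[deg, trt]) / rowMeans(none$counts[deg, dis]) - 1)
  expect_lt(max(rel), 0.1)
})

test_that("clinical covariates follow the severity gradient", {
  sim <- gen_cohort(cohort_config(seed = 13))
  m <- sim$meta
  mean_by <- function(v, cl) mean(v[!is.na(m$cluster) & m$cluster == cl])
  expect_gt(mean_by(m$neutrophils, "C3"), mean_by(m$neutrophils, "C1"))
  expect_gt(mean_by(m$neutrophils, "C1"), mean_by(m$neutrophils, "C2"))
  expect_lt(mean_by(m$b_cells, "C3"), mean_by(m$b_cells, "C2"))
  expect_lt(mean_by(m$t_cells, "C3"), mean_by(m$t_cells, "C2"))
})

test_that("written datasets round-trip through the plain-text formats", {
  sim <- gen_cohort(cohort_config(seed = 4, n_hv = 6,
                                  n_per_cluster = c(C1 = 4, C2 = 4, C3 = 4),
                                  n_genes = 80))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(unclass(counts), unclass(sim$counts), ignore_attr = TRUE)
  meta <- read.delim(file.path(dir, "meta.tsv"))
  expect_equal(meta$sample_id, sim$meta$sample_id)
})
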