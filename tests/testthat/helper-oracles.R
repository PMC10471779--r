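# Independent oracles and small fixtures shared across test files.
# Oracles deliberately avoid the package's own code paths.

# Brute-force Benjamini-Hochberg step-up: q_i = min over j >= rank(i) of
# min(1, m * p_(j) / j). Written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# All permutations of 1..k as a list (independent recursion from the
# package's internal generator).
perm_oracle <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in perm_oracle(k - 1L)) {
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- c(p[seq_len(i - 1L)], k, p[seq.int(i, length.out = k - i)])
    }
  }
  out
}

# Best achievable agreement between two label vectors over all bijections.
best_agreement_oracle <- function(ref, lab) {
  k <- max(ref, lab)
  best <- -1L
  for (m in perm_oracle(k)) {
    best <- max(best, sum(ref == unlist(m)[lab]))
  }
  best
}

# Small normalized matrix with gene/sample names attached.
toy_norm <- function(values, n_genes, n_samples, genes = sprintf("g%d", seq_len(n_genes)),
                     samples = sprintf("s%d", seq_len(n_samples))) {
  m <- matrix(values, n_genes, n_samples, dimnames = list(genes, samples))
  attr(m, "layer") <- "normalized"
  m
}

# Three well-separated Gaussian blobs (distinct random center profiles so
# both Euclidean and correlation geometries see them), samples x features.
blob_data <- function(n_per = 15L, p = 5L, sep = 10, seed = 42) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(3 * p), 3, p) * sep
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(stats::rnorm(n_per * p), n_per, p), 2, centers[i, ], "+")
  }))
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  list(x = x, truth = rep(1:3, each = n_per))
}

# Deterministic decoy sampler (fixed seed, local RNG).
sample_decoys <- function(seed, pool, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(pool, n)
}

# Default-sized synthetic cohort, normalized, restricted to patients.
cohort_fixture <- function(seed, ...) {
  cc <- cohort_config(seed = seed, ...)
  sim <- gen_cohort(cc)
  filt <- filter_genes(sim$counts)
  norm <- vst_like(filt$counts, size_factors(filt$counts))
  pat <- sim$meta$sample_id[sim$meta$role == "patient"]
  hv <- sim$meta$sample_id[sim$meta$role == "HV"]
  list(sim = sim, norm = norm, pat = pat, hv = hv,
       truth_cluster = sim$truth$cluster[pat])
}
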