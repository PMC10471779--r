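## Consensus clustering: three clusterers, optimal label alignment,
## unanimity consensus, k selection, and random-forest extension of
## consensus labels to held-out samples.

#' Select top-variance features
#'
#' @param normalized genes x samples normalized matrix.
#' @param n number of genes to keep (default 5000; capped at the number of
#'   genes present).
#' @return Character vector of gene ids, ordered by decreasing variance.
#' @export
top_variance_features <- function(normalized, n = 5000L) {
  check_expr(normalized)
  v <- apply(normalized, 1, stats::var)
  rownames(normalized)[order(v, decreasing = TRUE)[seq_len(min(n, nrow(normalized)))]]
}

#' Cluster samples three ways
#'
#' Runs the three clusterers whose unanimity defines the consensus:
#' (i) agglomerative hierarchical clustering on the dissimilarity
#' `1 - Pearson(sample, sample)` with Ward linkage (`ward.D2`),
#' (ii) k-means with multiple restarts, and (iii) a Gaussian mixture with
#' full covariance fitted on the top principal components of the feature
#' matrix, EM-initialized from a k-means partition (see the methods
#' vignette for why the mixture is fitted in PC space).
#'
#' @param x samples x features numeric matrix (normalized expression,
#'   samples in rows). Constant features are dropped with a warning.
#' @param k number of clusters, `2 <= k < nrow(x)`.
#' @param seed integer seed controlling the stochastic steps.
#' @param scale_features standardize each feature to unit variance first
#'   (default TRUE).
#' @param n_pcs number of principal components for the Gaussian mixture
#'   (default 10, capped by the data).
#' @param nstart k-means restarts.
#' @return A list with integer label vectors `hierarchical`, `kmeans`,
#'   `gmm`, each in 1..k.
#' @export
cluster_three_ways <- function(x, k, seed = NULL, scale_features = TRUE,
                               n_pcs = 10L, nstart = 25L) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric samples x features matrix", call. = FALSE)
  n <- nrow(x)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant feature(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 non-constant features", call. = FALSE)
  if (scale_features) x <- scale(x)

  with_seed(derive_seed(seed, "cluster3"), {
    d <- stats::as.dist(1 - stats::cor(t(x)))
    hc <- stats::cutree(stats::hclust(d, method = "ward.D2"), k)
    km <- stats::kmeans(x, k, nstart = nstart)$cluster
    q <- min(n_pcs, n - 1L, ncol(x))
    pc <- stats::prcomp(x)$x[, seq_len(q), drop = FALSE]
    km0 <- stats::kmeans(pc, k, nstart = nstart)$cluster
    fit <- tryCatch(mclust::me(modelName = "VVV", data = pc, z = mclust::unmap(km0)),
                    error = function(e) NULL)
    gm <- if (is.null(fit) || is.null(fit$z) || anyNA(fit$z)) km0 else mclust::map(fit$z)
    list(hierarchical = unname(hc), kmeans = unname(km), gmm = unname(gm))
  })
}

# All permutations of 1..k (k <= 8 guarded by callers).
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- vector("list", factorial(k))
  i <- 0L
  for (p in all_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Optimally align cluster labels to a reference
#'
#' Finds the one-to-one relabeling of `labels` that maximizes agreement
#' with `reference` (exhaustive search over bijections of the label sets;
#' label sets of unequal size are handled by implicit zero-padding).
#'
#' @param reference,labels integer label vectors over the same samples.
#' @return `labels` relabeled into the reference labeling.
#' @export
align_labels <- function(reference, labels) {
  if (length(reference) != length(labels)) stop("length mismatch", call. = FALSE)
  k <- max(reference, labels)
  if (k > 8L) stop("exhaustive label alignment supports at most 8 labels", call. = FALSE)
  best <- NULL
  best_ag <- -1L
  for (p in all_perms(k)) {
    m <- unlist(p)
    ag <- sum(reference == m[labels])
    if (ag > best_ag) {
      best_ag <- ag
      best <- m
    }
  }
  best[labels]
}

#' Unanimity consensus of three clusterings
#'
#' Aligns the second and third partitions to the first, then assigns each
#' sample its common label when all three agree and `NA` (ambiguous)
#' otherwise.
#'
#' @param partitions list of three integer label vectors over the same
#'   samples (as returned by [cluster_three_ways()]).
#' @param sample_ids optional sample ids carried onto the result.
#' @param k number of clusters (inferred from the labels by default).
#' @param seed seed recorded for provenance.
#' @return An object of class `consensus_clust` with elements `consensus`
#'   (labels with `NA` for ambiguous samples), `labels_by_method` (aligned),
#'   `n_consensus`, `agreement_score` (mean pairwise adjusted Rand index
#'   among the three methods), `k` and `seed`.
#' @export
consensus_labels <- function(partitions, sample_ids = NULL, k = NULL, seed = NULL) {
  if (length(partitions) != 3L) stop("need exactly three partitions", call. = FALSE)
  n <- unique(lengths(partitions))
  if (length(n) != 1L) stop("partitions have different lengths", call. = FALSE)
  ref <- partitions[[1]]
  aligned <- list(ref,
                  align_labels(ref, partitions[[2]]),
                  align_labels(ref, partitions[[3]]))
  names(aligned) <- names(partitions)
  cons <- ifelse(aligned[[1]] == aligned[[2]] & aligned[[2]] == aligned[[3]],
                 aligned[[1]], NA_integer_)
  if (!is.null(sample_ids)) names(cons) <- sample_ids
  agr <- mean(c(adjusted_rand(aligned[[1]], aligned[[2]]),
                adjusted_rand(aligned[[1]], aligned[[3]]),
                adjusted_rand(aligned[[2]], aligned[[3]])))
  structure(list(consensus = cons,
                 labels_by_method = aligned,
                 n_consensus = sum(!is.na(cons)),
                 agreement_score = agr,
                 k = if (is.null(k)) max(ref) else k,
                 seed = seed),
            class = "consensus_clust")
}

#' @export
print.consensus_clust <- function(x, ...) {
  n <- length(x$consensus)
  cat(sprintf("Consensus clustering (k = %d)\n", x$k))
  cat(sprintf("  consensus samples: %d / %d (%.1f%%)\n",
              x$n_consensus, n, 100 * x$n_consensus / n))
  cat(sprintf("  method agreement (mean pairwise ARI): %.3f\n", x$agreement_score))
  tab <- table(x$consensus, useNA = "ifany")
  cat("  cluster sizes: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Consensus-cluster a normalized expression matrix
#'
#' Convenience wrapper: selects top-variance features, runs
#' [cluster_three_ways()] and [consensus_labels()].
#'
#' @param normalized genes x samples normalized matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_features number of top-variance genes used as features.
#' @param ... passed to [cluster_three_ways()].
#' @return A `consensus_clust` object (see [consensus_labels()]).
#' @export
consensus_cluster <- function(normalized, k, seed = NULL, n_features = 5000L, ...) {
  feats <- top_variance_features(normalized, n_features)
  x <- t(normalized[feats, , drop = FALSE])
  parts <- cluster_three_ways(x, k, seed = seed, ...)
  consensus_labels(parts, sample_ids = colnames(normalized), k = k, seed = seed)
}

#' Choose the number of clusters by method agreement
#'
#' For each k in `k_range`, clusters three ways and records the mean
#' pairwise adjusted Rand index among the three partitions. A coarse
#' partition nested inside a finer stable one reaches the same agreement
#' (all methods merge the same clusters), so a plain argmax collapses
#' graded structure onto k = 2; agreements within `tie_tol` of the
#' maximum are therefore treated as ties, resolved toward the *largest*
#' tied k (the finest partition the three methods still agree on). See
#' the methods vignette for the analysis behind this rule.
#'
#' @param x samples x features matrix (as in [cluster_three_ways()]).
#' @param k_range integer vector of candidate k (default 2:6).
#' @param seed integer seed.
#' @param tie_tol agreement differences below this value are ties
#'   (default 0.05, about the seed-to-seed noise of the statistic).
#' @param low_agreement flag threshold: if at the selected k the weakest
#'   pairwise agreement between methods falls below this value, the
#'   selection is marked weakly supported (default 0.5; the minimum is
#'   used because the mixture fit is initialized from k-means, which makes
#'   the mean pairwise agreement optimistic).
#' @param ... passed to [cluster_three_ways()].
#' @return A list with `k`, `agreement` (named per-k mean pairwise ARI),
#'   `min_agreement` and `low_agreement` flag.
#' @export
select_k <- function(x, k_range = 2:6, seed = NULL, tie_tol = 0.05,
                     low_agreement = 0.5, ...) {
  if (length(k_range) == 0L) stop("empty k_range", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range >= nrow(x))) {
    stop("k_range must lie in [2, n_samples)", call. = FALSE)
  }
  stats_k <- vapply(k_range, function(k) {
    p <- cluster_three_ways(x, k, seed = derive_seed(seed, paste0("selectk", k)), ...)
    pair <- c(adjusted_rand(p[[1]], p[[2]]),
              adjusted_rand(p[[1]], p[[3]]),
              adjusted_rand(p[[2]], p[[3]]))
    c(mean(pair), min(pair))
  }, numeric(2))
  agr <- stats_k[1, ]
  names(agr) <- k_range
  tied <- agr >= max(agr) - tie_tol
  i_best <- max(which(tied))          # finest partition among the ties
  list(k = k_range[i_best], agreement = agr,
       min_agreement = stats_k[2, i_best],
       low_agreement = stats_k[2, i_best] < low_agreement)
}

#' Extend consensus labels to held-out samples
#'
#' Fits a random forest on the consensus-labeled training samples and
#' predicts each test sample; the confidence is the fraction of trees
#' voting for the winning class, and a sample is retained when its
#' confidence reaches `tau`.
#'
#' @param train_x,test_x samples x features matrices over the same features.
#' @param train_labels per-training-sample labels; `NA` (ambiguous) samples
#'   are dropped before fitting.
#' @param tau confidence threshold in \[0, 1\] (default 0.6).
#' @param seed integer seed.
#' @param ntree number of trees.
#' @return An object of class `extension_result`: data.frame with
#'   `sample_id`, `predicted`, `confidence`, `retained`, plus `tau`.
#' @export
extend_to_test <- function(train_x, train_labels, test_x, tau = 0.6,
                           seed = NULL, ntree = 500L) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    stop("tau must lie in [0, 1]", call. = FALSE)
  }
  keep <- !is.na(train_labels)
  y <- factor(train_labels[keep])
  if (nlevels(y) < 2L) stop("need at least 2 labeled classes in training", call. = FALSE)
  if (any(table(y) == 0L)) stop("a class has 0 training samples", call. = FALSE)
  xtr <- train_x[keep, , drop = FALSE]
  if (ncol(test_x) != ncol(xtr)) stop("train and test feature sets differ", call. = FALSE)
  fit <- with_seed(derive_seed(seed, "extend"),
                   randomForest::randomForest(xtr, y, ntree = ntree))
  votes <- stats::predict(fit, test_x, type = "vote", norm.votes = TRUE)
  pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  conf <- votes[cbind(seq_len(nrow(votes)), max.col(votes, ties.method = "first"))]
  ids <- rownames(test_x)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(test_x)))
  res <- data.frame(sample_id = ids, predicted = pred,
                    confidence = as.numeric(conf),
                    retained = conf >= tau,
                    stringsAsFactors = FALSE)
  structure(list(assignments = res, tau = tau, n_retained = sum(res$retained)),
            class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  cat(sprintf("Test-set extension: %d / %d retained at tau = %.2f\n",
              x$n_retained, nrow(x$assignments), x$tau))
  invisible(x)
}
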