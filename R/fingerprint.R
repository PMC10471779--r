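## Interactant panel assembly, bootstrap random-forest stability selection,
## direction assignment, and the up/down deviation scores with HV
## z-normalization.

#' Merge two interactant gene lists against a dataset
#'
#' Case-normalized, de-duplicated union of two gene-symbol lists in order
#' of first occurrence, split into the genes present in the dataset and
#' those absent from it.
#'
#' @param list_a,list_b character vectors of gene symbols.
#' @param dataset_genes gene ids available in the expression data.
#' @return A list with `union` (merged symbols), `present` (union members
#'   found in `dataset_genes`, the candidate set) and `absent`.
#' @export
assemble_interactants <- function(list_a, list_b, dataset_genes) {
  if (!length(list_a) || !length(list_b)) stop("empty input list", call. = FALSE)
  norm <- function(x) toupper(trimws(as.character(x)))
  u <- unique(c(norm(list_a), norm(list_b)))
  ds <- norm(dataset_genes)
  present <- u[u %in% ds]
  if (!length(present)) warning("no interactant found in the dataset")
  list(union = u, present = present, absent = u[!u %in% ds])
}

#' Bootstrap random-forest stability selection
#'
#' Per bootstrap replicate: draw a stratified (per-cluster) bootstrap of
#' the labeled samples, fit a random forest predicting the cluster from
#' the candidate genes, and mark a gene as "chosen" according to `rule`.
#' The selection frequency of a gene is the fraction of replicates in
#' which it was chosen; the panel is the set of genes with frequency at
#' least `threshold`.
#'
#' Rules for "chosen" in a replicate:
#' \describe{
#'   \item{`"shadow"`}{(default) raw permutation importance above the
#'     `shadow_quantile` quantile of the importances of permuted decoy
#'     copies of the candidates fitted alongside them (Boruta-style
#'     threshold; robust to the positive importance bias that bootstrap
#'     row duplication induces).}
#'   \item{`"positive"`}{raw permutation importance > 0.}
#'   \item{`"topq"`}{among the `top_q` largest importances.}
#' }
#'
#' @param normalized genes x samples normalized matrix.
#' @param labels per-sample cluster labels; `NA` samples are ignored.
#' @param candidate_genes character vector of candidate gene ids (must
#'   intersect the matrix rows).
#' @param B number of bootstrap replicates (default 200).
#' @param threshold selection-frequency threshold in (0, 1\] (default 1.0,
#'   i.e. chosen in every replicate).
#' @param seed integer seed.
#' @param rule selection rule, see Details.
#' @param shadow_quantile quantile of the decoy importances used by the
#'   shadow rule.
#' @param top_q number of genes kept per replicate by the `"topq"` rule.
#' @param ntree trees per forest (default 300).
#' @return An object of class `fingerprint_panel`: data.frame `genes` with
#'   `gene_id`, `frequency`, `selected`, `direction` (NA until
#'   [split_directions()]), plus `B`, `threshold`, `rule`.
#' @export
stability_select <- function(normalized, labels, candidate_genes, B = 200L,
                             threshold = 1.0, seed = NULL,
                             rule = c("shadow", "positive", "topq"),
                             shadow_quantile = 0.95, top_q = NULL,
                             ntree = 300L) {
  rule <- match.arg(rule)
  check_expr(normalized)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]", call. = FALSE)
  cand <- sort(unique(intersect(candidate_genes, rownames(normalized))))
  if (!length(cand)) stop("no candidate gene present in the matrix", call. = FALSE)
  keep <- !is.na(labels)
  y <- factor(labels[keep])
  if (nlevels(y) < 2L) stop("need >= 2 clusters", call. = FALSE)
  if (any(table(y) < 5L)) warning("a cluster has fewer than 5 labeled samples")
  if (rule == "topq" && is.null(top_q)) stop("rule 'topq' needs `top_q`", call. = FALSE)

  x <- t(normalized[cand, keep, drop = FALSE])    # samples x candidates
  colnames(x) <- cand
  p <- length(cand)
  n <- nrow(x)
  strata <- split(seq_len(n), y)

  chosen <- matrix(0L, p, B)
  for (b in seq_len(B)) {
    with_seed(derive_seed(seed, paste0("boot", b)), {
      idx <- unlist(lapply(strata, function(i) sample(i, length(i), replace = TRUE)),
                    use.names = FALSE)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      if (rule == "shadow") {
        pi_b <- sample.int(nrow(xb))              # one row permutation for all decoys
        sh <- xb[pi_b, , drop = FALSE]
        colnames(sh) <- paste0(".shadow", seq_len(p))
        rf <- randomForest::randomForest(cbind(xb, sh), yb, ntree = ntree,
                                         importance = TRUE)
        imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
        thr <- stats::quantile(imp[p + seq_len(p)], shadow_quantile, names = FALSE)
        chosen[, b] <- as.integer(imp[seq_len(p)] > thr)
      } else {
        rf <- randomForest::randomForest(xb, yb, ntree = ntree, importance = TRUE)
        imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
        if (rule == "positive") {
          chosen[, b] <- as.integer(imp > 0)
        } else {
          cut <- sort(imp, decreasing = TRUE)[min(top_q, p)]
          chosen[, b] <- as.integer(imp >= cut)
        }
      }
    })
  }
  freq <- rowMeans(chosen)
  genes <- data.frame(gene_id = cand, frequency = freq,
                      selected = freq >= threshold,
                      direction = NA_integer_,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, B = as.integer(B), threshold = threshold,
                 rule = rule, seed = seed),
            class = "fingerprint_panel")
}

#' @export
print.fingerprint_panel <- function(x, ...) {
  sel <- x$genes[x$genes$selected, ]
  cat(sprintf("Fingerprint panel: %d / %d genes at frequency >= %.2f (B = %d, rule = %s)\n",
              nrow(sel), nrow(x$genes), x$threshold, x$B, x$rule))
  if (!all(is.na(sel$direction))) {
    cat(sprintf("  up: %d, down: %d\n",
                sum(sel$direction == 1, na.rm = TRUE),
                sum(sel$direction == -1, na.rm = TRUE)))
  }
  invisible(x)
}

#' Assign up/down directions to a selected panel
#'
#' Direction of a selected gene is the sign of (mean over reference-cluster
#' patients − mean over all other patients) on the normalized layer. Exact
#' ties are broken by comparison against the HV mean, then set to +1.
#'
#' @param normalized genes x samples normalized matrix.
#' @param labels per-sample cluster labels (`NA` allowed).
#' @param panel a `fingerprint_panel` from [stability_select()].
#' @param ref_cluster reference cluster name (default `"C3"`).
#' @param hv_matrix optional genes x HV-samples normalized matrix used for
#'   tie-breaking.
#' @return The panel with `direction` filled in for selected genes, and
#'   `g_up` / `g_down` counts attached.
#' @export
split_directions <- function(normalized, labels, panel, ref_cluster = "C3",
                             hv_matrix = NULL) {
  stopifnot(inherits(panel, "fingerprint_panel"))
  check_expr(normalized)
  in_ref <- !is.na(labels) & labels == ref_cluster
  in_oth <- !is.na(labels) & labels != ref_cluster
  if (!any(in_ref)) stop("reference cluster '", ref_cluster, "' is empty", call. = FALSE)
  sel <- panel$genes$selected
  ids <- panel$genes$gene_id[sel]
  d <- rowMeans(normalized[ids, in_ref, drop = FALSE]) -
       rowMeans(normalized[ids, in_oth, drop = FALSE])
  dir <- sign(d)
  if (any(dir == 0)) {
    tie <- dir == 0
    if (!is.null(hv_matrix)) {
      d2 <- rowMeans(normalized[ids[tie], in_ref, drop = FALSE]) -
            rowMeans(hv_matrix[ids[tie], , drop = FALSE])
      dir[tie] <- sign(d2)
    }
    dir[dir == 0] <- 1
  }
  panel$genes$direction[sel] <- as.integer(dir)
  panel$g_up <- sum(dir == 1)
  panel$g_down <- sum(dir == -1)
  panel$ref_cluster <- ref_cluster
  panel
}

#' Deviation score of one sample over a gene set
#'
#' The median, over the genes in `gene_set`, of the sample's normalized
#' expression minus the per-gene median over the healthy-volunteer (HV)
#' reference. Even-sized medians use the midpoint convention.
#'
#' @param sample_expr named numeric vector of normalized expression for one
#'   sample.
#' @param hv_matrix genes x HV-samples normalized matrix.
#' @param gene_set character vector of gene ids (must be present in both
#'   inputs).
#' @return A single number in normalized-expression units.
#' @export
score <- function(sample_expr, hv_matrix, gene_set) {
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  miss <- setdiff(gene_set, names(sample_expr))
  if (length(miss)) stop("gene(s) missing from sample: ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(gene_set, rownames(hv_matrix))
  if (length(miss)) stop("gene(s) missing from HV matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  hv_med <- apply(hv_matrix[gene_set, , drop = FALSE], 1, stats::median)
  stats::median(sample_expr[gene_set] - hv_med)
}

# Vectorized scores for many samples against fixed HV medians.
score_matrix <- function(normalized, hv_matrix, gene_set) {
  hv_med <- apply(hv_matrix[gene_set, , drop = FALSE], 1, stats::median)
  apply(normalized[gene_set, , drop = FALSE] - hv_med, 2, stats::median)
}

#' Z-normalize scores against the HV population
#'
#' `z = (s - mean(hv_scores)) / sd(hv_scores)` with the n-1 denominator.
#'
#' @param scores numeric vector of raw scores.
#' @param hv_scores raw scores of the HV reference (length >= 2, nonzero
#'   variance).
#' @return Numeric vector of z values.
#' @export
z_normalize_scores <- function(scores, hv_scores) {
  if (length(hv_scores) < 2L) stop("need >= 2 HV scores", call. = FALSE)
  s <- stats::sd(hv_scores)
  if (s == 0) stop("zero variance in HV scores", call. = FALSE)
  (scores - mean(hv_scores)) / s
}

#' Up/down fingerprint scores for every sample
#'
#' Computes the up-gene and down-gene deviation scores of each sample
#' against the HV reference, and their z-normalized versions (each HV is
#' scored against the full HV reference to form the normalizing
#' distribution).
#'
#' @param normalized genes x samples normalized matrix (patients and HV).
#' @param panel a directed `fingerprint_panel` (after [split_directions()]).
#' @param hv_ids sample ids of the healthy volunteers.
#' @return A data.frame with `sample_id`, `score_up`, `score_down`, `z_up`,
#'   `z_down`.
#' @export
score_samples <- function(normalized, panel, hv_ids) {
  stopifnot(inherits(panel, "fingerprint_panel"))
  check_expr(normalized)
  if (!length(hv_ids) || !all(hv_ids %in% colnames(normalized))) {
    stop("`hv_ids` must all be columns of the matrix", call. = FALSE)
  }
  g <- panel$genes[panel$genes$selected, ]
  if (all(is.na(g$direction))) stop("panel has no directions; run split_directions()", call. = FALSE)
  up <- g$gene_id[g$direction == 1]
  dn <- g$gene_id[g$direction == -1]
  if (!length(up) || !length(dn)) stop("panel must contain both up and down genes", call. = FALSE)
  hv <- normalized[, hv_ids, drop = FALSE]
  s_up <- score_matrix(normalized, hv, up)
  s_dn <- score_matrix(normalized, hv, dn)
  hv_up <- s_up[hv_ids]
  hv_dn <- s_dn[hv_ids]
  data.frame(sample_id = colnames(normalized),
             score_up = unname(s_up), score_down = unname(s_dn),
             z_up = unname(z_normalize_scores(s_up, hv_up)),
             z_down = unname(z_normalize_scores(s_dn, hv_dn)),
             stringsAsFactors = FALSE)
}
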