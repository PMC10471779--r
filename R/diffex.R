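## Per-gene linear-model differential expression, fold-change and FDR
## calling, overlap partitions, and treatment-reversal analysis.

#' Per-gene linear model
#'
#' Ordinary least squares of normalized expression on a two-level group
#' indicator plus optional covariates, fitted to all genes at once. The
#' effect is the group coefficient (second level minus first); the p-value
#' comes from a two-sided t test on that coefficient with residual degrees
#' of freedom. With no covariates this reduces exactly to the
#' pooled-variance two-sample t test.
#'
#' @param normalized genes x samples normalized matrix.
#' @param group two-level factor over the samples; the first level is the
#'   reference.
#' @param covariates optional data.frame of per-sample covariates.
#' @param p_floor lower clamp for p-values from zero-residual fits.
#' @return A data.frame with `gene_id`, `effect`, `p`.
#' @export
fit_gene_models <- function(normalized, group, covariates = NULL,
                            p_floor = 1e-300) {
  check_expr(normalized)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("`group` must have exactly 2 levels", call. = FALSE)
  if (any(table(group) < 2L)) stop("need >= 2 samples per group", call. = FALSE)
  if (length(group) != ncol(normalized)) stop("group length != sample count", call. = FALSE)

  if (is.null(covariates)) {
    design <- stats::model.matrix(~group)
  } else {
    covariates <- as.data.frame(covariates)
    design <- stats::model.matrix(~., data = cbind(group = group, covariates))
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    drop_cols <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  y <- t(normalized)                               # samples x genes
  fit <- stats::lm.fit(design, y)
  coef_i <- grep("^group", colnames(design))[1]
  eff <- fit$coefficients[coef_i, ]
  df <- nrow(design) - ncol(design)
  rss <- colSums(fit$residuals^2)
  tss <- colSums(scale(y, scale = FALSE)^2)
  zero_res <- rss <= tss * 1e-20 + 1e-300       # numerically exact fit
  xtx_inv_ii <- chol2inv(qr.R(qr_d))[coef_i, coef_i]
  se <- sqrt(rss / df * xtx_inv_ii)
  tstat <- ifelse(se > 0 & !zero_res, eff / se, ifelse(eff == 0, 0, Inf))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p <- pmax(p, p_floor)
  p[zero_res & eff == 0] <- 1
  data.frame(gene_id = rownames(normalized), effect = unname(eff),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Signed linear fold-change from a log2 effect
#'
#' `fc = 2^effect` when that ratio is at least 1, and `-2^(-effect)`
#' otherwise, so that `|fc| >= 1` always and the sign gives the direction.
#'
#' @param effect numeric log2-scale effect(s).
#' @return Signed fold-change(s).
#' @export
fold_change <- function(effect) {
  if (any(!is.finite(effect))) stop("effect must be finite", call. = FALSE)
  r <- 2^effect
  ifelse(r >= 1, r, -1 / r)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric p-values in \[0, 1\].
#' @return Adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression
#'
#' UP iff `q <= fdr_max` and `fc >= fc_min`; DOWN iff `q <= fdr_max` and
#' `fc <= -fc_min`; otherwise NS. Thresholds are inclusive.
#'
#' @param results data.frame with columns `fc` and `q` (see [de_table()]).
#' @param fc_min minimum absolute linear fold-change (default 1.3).
#' @param fdr_max maximum BH-adjusted p (default 0.05).
#' @return `results` with a `call` column; counts `n_up` / `n_down`
#'   attached as attributes.
#' @export
call_de <- function(results, fc_min = 1.3, fdr_max = 0.05) {
  stopifnot(all(c("fc", "q") %in% names(results)))
  call <- rep("NS", nrow(results))
  sig <- results$q <= fdr_max
  call[sig & results$fc >= fc_min] <- "UP"
  call[sig & results$fc <= -fc_min] <- "DOWN"
  results$call <- call
  attr(results, "n_up") <- sum(call == "UP")
  attr(results, "n_down") <- sum(call == "DOWN")
  results
}

#' Full differential-expression table for one contrast
#'
#' Fits the per-gene linear model, computes fold-changes and BH-adjusted
#' p-values and calls each gene.
#'
#' @inheritParams fit_gene_models
#' @inheritParams call_de
#' @return A data.frame `gene_id`, `effect`, `fc`, `p`, `q`, `call`.
#' @export
de_table <- function(normalized, group, covariates = NULL, fc_min = 1.3,
                     fdr_max = 0.05) {
  res <- fit_gene_models(normalized, group, covariates)
  res$fc <- fold_change(res$effect)
  res$q <- bh_adjust(res$p)
  call_de(res[, c("gene_id", "effect", "fc", "p", "q")],
          fc_min = fc_min, fdr_max = fdr_max)
}

#' Exclusive/shared partition of DE gene sets
#'
#' Inclusion-exclusion partition of the union of several gene sets: one
#' cell per nonempty combination of groups, holding the genes belonging to
#' exactly those groups. Cell sizes sum to the union size.
#'
#' @param sets named list of character vectors (e.g. DE genes per cluster).
#' @return A list with `cells` (named list of gene vectors, names like
#'   `"C1+C3"`) and `sizes`.
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "+"))
  cells <- split(all_genes, key)
  list(cells = cells, sizes = lengths(cells))
}

#' Treatment-reversal analysis
#'
#' Step 1 defines the pathology gene set: genes called differentially
#' expressed between the disease and control arms. Step 2 classifies each
#' pathology gene per treatment arm as reversed or not, by `rule`:
#' \describe{
#'   \item{`"restored"`}{(default) the treated arm is *not* called
#'     differentially expressed versus the control arm, i.e. the gene's
#'     expression pattern has returned to the control level (matching the
#'     reading of reversal as similarity of the treated and control
#'     patterns).}
#'   \item{`"opposite_change"`}{the treated-vs-disease contrast is called
#'     significant with sign opposite to the gene's pathology sign.}
#' }
#'
#' @param normalized genes x samples normalized matrix.
#' @param arms per-sample arm labels.
#' @param control,disease arm names (>= 2 samples each).
#' @param rule reversal rule, see Details.
#' @param fc_min,fdr_max DE-calling thresholds.
#' @return An object of class `reversal_report`: `pathology` (data.frame of
#'   pathology genes with direction), `reversed` (named list of gene ids
#'   per treatment arm), `fraction` (named numeric), `rule`, `de_disease`
#'   (the step-1 table).
#' @export
reversal_analysis <- function(normalized, arms, control = "control",
                              disease = "disease",
                              rule = c("restored", "opposite_change"),
                              fc_min = 1.3, fdr_max = 0.05) {
  rule <- match.arg(rule)
  check_expr(normalized)
  arms <- as.character(arms)
  for (a in c(control, disease)) {
    if (sum(arms == a, na.rm = TRUE) < 2L) stop("arm '", a, "' missing or has < 2 samples", call. = FALSE)
  }
  contrast <- function(test, ref) {
    j <- arms %in% c(test, ref)
    de_table(normalized[, j, drop = FALSE],
             factor(arms[j], levels = c(ref, test)),
             fc_min = fc_min, fdr_max = fdr_max)
  }
  d1 <- contrast(disease, control)
  path <- d1[d1$call != "NS", c("gene_id", "call", "effect")]
  path$direction <- ifelse(path$call == "UP", 1L, -1L)

  treat <- setdiff(unique(arms), c(control, disease))
  reversed <- list()
  fraction <- numeric(0)
  for (a in treat) {
    if (rule == "restored") {
      d2 <- contrast(a, control)
      rev_ids <- path$gene_id[d2$call[match(path$gene_id, d2$gene_id)] == "NS"]
    } else {
      d2 <- contrast(a, disease)
      m <- match(path$gene_id, d2$gene_id)
      opp <- d2$call[m] != "NS" & sign(d2$effect[m]) == -path$direction
      rev_ids <- path$gene_id[opp]
    }
    reversed[[a]] <- rev_ids
    fraction[a] <- if (nrow(path)) length(rev_ids) / nrow(path) else NA_real_
  }
  structure(list(pathology = path, reversed = reversed, fraction = fraction,
                 rule = rule, de_disease = d1),
            class = "reversal_report")
}

#' @export
print.reversal_report <- function(x, ...) {
  cat(sprintf("Reversal analysis (rule = %s)\n", x$rule))
  cat(sprintf("  pathology genes: %d (%d up, %d down)\n", nrow(x$pathology),
              sum(x$pathology$direction == 1), sum(x$pathology$direction == -1)))
  for (a in names(x$fraction)) {
    cat(sprintf("  %s: %d reversed (%.1f%%)\n", a, length(x$reversed[[a]]),
                100 * x$fraction[[a]]))
  }
  invisible(x)
}
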