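## Two-component PLS-DA (NIPALS) for group-discrimination plots.

#' Fit a PLS-DA model
#'
#' NIPALS partial least squares on the column-centered (optionally
#' unit-scaled) expression matrix against a column-centered one-hot
#' encoding of the class labels, with deflation of X after each component.
#' The first weight vector equals (up to sign) the dominant eigenvector of
#' `X'Y Y'X`; the sign convention makes the largest-magnitude weight entry
#' positive, so the fit is fully deterministic.
#'
#' @param x samples x genes numeric matrix.
#' @param labels per-sample class labels (>= 2 classes).
#' @param n_components number of latent components (default 2).
#' @param scale unit-scale the gene columns (default TRUE); constant genes
#'   are dropped with a warning.
#' @param tol NIPALS convergence tolerance on the weight vector.
#' @param max_iter maximum NIPALS iterations per component.
#' @return An object of class `plsda`: `weights` and `loadings`
#'   (genes x components), `scores` (samples x components), `y_loadings`,
#'   `rotation` (projection matrix accounting for deflation), `center`,
#'   `scale`, `labels`, `genes`.
#' @export
fit_plsda <- function(x, labels, n_components = 2L, scale = TRUE,
                      tol = 1e-10, max_iter = 500L) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (length(labels) != nrow(x)) stop("labels length != sample count", call. = FALSE)
  if (n_components >= min(nrow(x), ncol(x))) {
    stop("n_components must be < min(n_samples, n_genes)", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))

  sds <- apply(x, 2, stats::sd)
  if (scale && any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before scaling")
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  scl <- if (scale) sds else rep(1, ncol(x))
  X <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  Y <- stats::model.matrix(~labels - 1)
  Y <- sweep(Y, 2, colMeans(Y))

  p <- ncol(X)
  W <- P <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, nrow(X), n_components)
  C <- matrix(0, ncol(Y), n_components)
  Xd <- X
  for (a in seq_len(n_components)) {
    u <- Y[, 1]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      cc <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% cc / sum(cc^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    if (w[which.max(abs(w))] < 0) {            # fixed sign convention
      w <- -w; tt <- -tt; cc <- -cc
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; C[, a] <- cc
    Xd <- Xd - tcrossprod(tt, pp)
  }
  rotation <- W %*% solve(crossprod(P, W))     # X_c %*% rotation = scores
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = C,
                 rotation = rotation, center = ctr, scale = scl,
                 labels = labels, genes = colnames(X),
                 n_components = n_components),
            class = "plsda")
}

#' Project new samples into a PLS-DA score space
#'
#' Centers and scales `newdata` with the training vectors, aligns genes by
#' id, and projects through the deflation-aware rotation so that
#' projecting the training data reproduces the stored scores.
#'
#' @param object a `plsda` model.
#' @param newdata samples x genes matrix containing all training genes
#'   (matched by column name; extra genes are ignored).
#' @param ... unused.
#' @return A samples x components score matrix.
#' @export
predict.plsda <- function(object, newdata, ...) {
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$genes)) stop("gene set mismatch", call. = FALSE)
    colnames(newdata) <- object$genes
  }
  miss <- setdiff(object$genes, colnames(newdata))
  if (length(miss)) {
    stop("missing gene(s): ", paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  Xn <- newdata[, object$genes, drop = FALSE]
  Xn <- sweep(sweep(Xn, 2, object$center), 2, object$scale, "/")
  Xn %*% object$rotation
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d components, %d samples x %d genes, %d classes\n",
              x$n_components, nrow(x$scores), length(x$genes),
              nlevels(x$labels)))
  ev <- colSums(x$scores^2)
  cat("  score sums of squares:", signif(ev, 4), "\n")
  invisible(x)
}

#' Plot PLS-DA sample scores
#'
#' Scatter of the first two components, colored by class.
#'
#' @param x a `plsda` model.
#' @param comps which two components to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, comps = c(1, 2), ...) {
  s <- x$scores[, comps, drop = FALSE]
  cls <- as.integer(x$labels)
  graphics::plot(s[, 1], s[, 2], col = cls, pch = 19,
                 xlab = paste("Component", comps[1]),
                 ylab = paste("Component", comps[2]), ...)
  graphics::legend("topright", legend = levels(x$labels),
                   col = seq_len(nlevels(x$labels)), pch = 19, bty = "n")
  invisible(x)
}
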