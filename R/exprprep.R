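## Count-matrix I/O, normalization, gene filtering, RIN binning and
## simplified batch adjustment.

#' Read a count matrix
#'
#' Reads a genes x samples count matrix from a tab-separated file (gene ids
#' in the first column, header row of sample ids) or a MatrixMarket triplet
#' file with companion `genes.tsv` / `samples.tsv` id files (one id per
#' line) in the same directory.
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return An integer matrix with gene rownames, sample colnames and layer
#'   `"counts"`. Ids are kept in file order.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv")
    sf <- file.path(dir, "samples.tsv")
    if (!file.exists(gf) || !file.exists(sf)) {
      stop("mtx input needs companion genes.tsv and samples.tsv in ", dir,
           call. = FALSE)
    }
    mm <- Matrix::readMM(path)
    genes <- readLines(gf)
    samples <- readLines(sf)
    if (nrow(mm) != length(genes) || ncol(mm) != length(samples)) {
      stop(sprintf("dimension mismatch: matrix %d x %d vs %d gene ids, %d sample ids",
                   nrow(mm), ncol(mm), length(genes), length(samples)),
           call. = FALSE)
    }
    m <- as.matrix(mm)
    dimnames(m) <- list(genes, samples)
  }
  check_expr(m)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene %s, sample %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  expr_layer(m) <- "counts"
  m
}

#' Write a count matrix as TSV
#'
#' @param counts genes x samples matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  check_expr(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors computed as the median, over reference genes
#' (genes with nonzero counts in every sample), of the ratio of the
#' sample's count to the gene's geometric mean across samples. Factors are
#' rescaled to geometric mean 1, so ratios between samples are preserved.
#'
#' @param counts genes x samples count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_expr(counts, layer = "counts")
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no gene has nonzero counts in every sample; pre-filter the matrix",
         call. = FALSE)
  }
  logs <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logs)
  f <- apply(logs, 2, function(lc) exp(stats::median(lc - loggeo)))
  f / exp(mean(log(f)))
}

#' Variance-stabilizing-style log transform
#'
#' Normalized value `log2(count / factor + 1)`: monotone in the count and
#' exactly 0 at count 0.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample positive size factors ([size_factors()] by
#'   default).
#' @return A normalized matrix (layer `"normalized"`).
#' @export
vst_like <- function(counts, factors = size_factors(counts)) {
  check_expr(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (length(factors) != ncol(counts) || any(factors <= 0)) {
    stop("`factors` must be positive, one per sample", call. = FALSE)
  }
  x <- log2(sweep(counts, 2, factors, "/") + 1)
  expr_layer(x) <- "normalized"
  x
}

#' Filter genes by keep-list, zero counts and low expression
#'
#' Rules applied sequentially, each counted on its input: (1) restrict to
#' `keep_list` if given (e.g. protein-coding genes); (2) drop genes with
#' zero counts in all samples; (3) drop genes whose normalized expression
#' is below `low_expr_threshold` in strictly more than `low_expr_fraction`
#' of samples.
#'
#' @param counts genes x samples count matrix.
#' @param keep_list optional character vector of gene ids to keep.
#' @param low_expr_threshold normalized-expression threshold (default 1).
#' @param low_expr_fraction sample fraction above which a low-expressed
#'   gene is dropped (default 0.95, strict inequality).
#' @param factors optional size factors for the internal normalization used
#'   by rule 3.
#' @return A list with `counts` (filtered matrix) and `report`
#'   (`filter_report`: n_input, per-rule removals, n_retained).
#' @export
filter_genes <- function(counts, keep_list = NULL, low_expr_threshold = 1,
                         low_expr_fraction = 0.95, factors = NULL) {
  check_expr(counts, layer = "counts")
  if (nrow(counts) == 0L) stop("empty matrix", call. = FALSE)
  n_input <- nrow(counts)

  removed <- c(not_in_keep_list = 0L, all_zero = 0L, low_expression = 0L)
  m <- counts
  if (!is.null(keep_list)) {
    keep <- rownames(m) %in% keep_list
    removed["not_in_keep_list"] <- sum(!keep)
    m <- m[keep, , drop = FALSE]
  }
  nz <- rowSums(m) > 0
  removed["all_zero"] <- sum(!nz)
  m <- m[nz, , drop = FALSE]

  if (nrow(m)) {
    if (is.null(factors)) {
      factors <- tryCatch(size_factors(m), error = function(e) rep(1, ncol(m)))
    }
    norm <- vst_like(m, factors)
    low <- rowMeans(norm < low_expr_threshold) > low_expr_fraction
    removed["low_expression"] <- sum(low)
    m <- m[!low, , drop = FALSE]
  }

  report <- structure(list(n_input = n_input, n_removed = removed,
                           n_retained = nrow(m)),
                      class = "filter_report")
  if (nrow(m) == 0L) {
    stop(paste0("no genes retained after filtering (removed ",
                paste(names(removed), removed, sep = "=", collapse = ", "), ")"),
         call. = FALSE)
  }
  expr_layer(m) <- "counts"
  list(counts = m, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Gene filter report\n")
  cat("  input genes:   ", x$n_input, "\n")
  for (r in names(x$n_removed)) {
    cat(sprintf("  removed (%s): %d\n", gsub("_", " ", r), x$n_removed[[r]]))
  }
  cat("  retained:      ", x$n_retained, "\n")
  invisible(x)
}

#' Bin RNA integrity numbers into 7 classes
#'
#' Left-closed, right-open bins of width 0.5 starting at 6.5
#' (\[6.5, 7.0), \[7.0, 7.5), ..., \[9.5, 10\]); the last bin is closed at 10,
#' and boundary values are assigned rightward.
#'
#' @param rin numeric vector of RIN values in \[6.5, 10\].
#' @return Integer class vector in 1..7.
#' @export
bin_rin <- function(rin) {
  if (any(is.na(rin)) || any(rin < 6.5 | rin > 10)) {
    stop("RIN out of range [6.5, 10]", call. = FALSE)
  }
  as.integer(pmin(floor((rin - 6.5) / 0.5) + 1, 7))
}

#' Center out per-batch location shifts
#'
#' Per gene, subtracts the batch mean and adds back the grand mean, so the
#' per-gene grand mean is preserved exactly. A simplified location-only
#' batch adjustment; RIN classes are a typical batch label.
#'
#' @param normalized genes x samples normalized matrix.
#' @param batch per-sample batch labels (no missing values).
#' @return Adjusted normalized matrix.
#' @export
batch_center <- function(normalized, batch) {
  check_expr(normalized, layer = "normalized")
  if (length(batch) != ncol(normalized) || any(is.na(batch) | batch == "")) {
    stop("every sample needs a batch label", call. = FALSE)
  }
  batch <- as.character(batch)
  grand <- rowMeans(normalized)
  out <- normalized
  for (b in unique(batch)) {
    j <- batch == b
    out[, j] <- normalized[, j, drop = FALSE] -
      rowMeans(normalized[, j, drop = FALSE]) + grand
  }
  expr_layer(out) <- "normalized"
  out
}
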