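## Score-clinical association statistics: Kruskal-Wallis across >= 3
## groups, Wilcoxon rank-sum for 2 groups, Pearson correlation on
## log-transformed cell counts, and the neutrophil-to-lymphocyte ratio.

#' Kruskal-Wallis test across three or more groups
#'
#' Rank-based H statistic with tie correction; p from a chi-square with
#' g − 1 degrees of freedom. When all values are tied, H is defined as 0.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 3 nonempty groups).
#' @return A list with `statistic` (H), `p` and `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(as.factor(groups[ok]))
  if (nlevels(groups) < 3L) {
    stop("fewer than 3 groups; use wilcoxon_rank_sum()", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p = 1, n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value, n = length(values))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value for small tie-free samples (both group sizes <= 20),
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples from the two groups (both nonempty).
#' @return A list with `statistic` (W), `p` and `n`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("a group is empty", call. = FALSE)
  exact <- max(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = length(x) + length(y))
}

#' Pearson correlation of a score with a log-transformed count
#'
#' Correlates the score (untransformed; scores may be negative) with
#' `log10` of a positive count variable; p-value from the t transform of
#' r, plus the simple linear fit with a pointwise 95% confidence band.
#'
#' @param score numeric vector.
#' @param count positive numeric vector (cell counts or ratios).
#' @param conf_level confidence level of the band (default 0.95).
#' @return A list with `r`, `p`, `n` and `fit` (data.frame `score`,
#'   `log_count`, `fitted`, `lwr`, `upr`, sorted by score).
#' @export
pearson_log <- function(score, count, conf_level = 0.95) {
  ok <- !is.na(score) & !is.na(count)
  score <- score[ok]; count <- count[ok]
  if (length(score) < 3L) stop("need n >= 3", call. = FALSE)
  if (any(count <= 0)) stop("counts must be positive for the log transform", call. = FALSE)
  y <- log10(count)
  if (stats::sd(score) == 0 || stats::sd(y) == 0) stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(score, y, method = "pearson")
  fit <- stats::lm(y ~ score)
  ord <- order(score)
  pr <- stats::predict(fit, interval = "confidence", level = conf_level)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(score),
       fit = data.frame(score = score[ord], log_count = y[ord],
                        fitted = pr[ord, "fit"], lwr = pr[ord, "lwr"],
                        upr = pr[ord, "upr"]))
}

#' Neutrophil-to-lymphocyte ratio
#'
#' `neutrophils / (b_cells + t_cells)`; undefined (NA, with a warning)
#' when the lymphocyte sum is zero.
#'
#' @param neutrophils,b_cells,t_cells non-negative counts (vectorized).
#' @return Numeric ratio(s).
#' @export
nlr <- function(neutrophils, b_cells, t_cells) {
  if (any(neutrophils < 0 | b_cells < 0 | t_cells < 0, na.rm = TRUE)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  lym <- b_cells + t_cells
  if (any(lym == 0, na.rm = TRUE)) {
    warning("lymphocyte sum of 0: ratio recorded as missing")
  }
  ifelse(lym > 0, neutrophils / lym, NA_real_)
}

#' Score-feature association table
#'
#' For each score column crossed with each clinical feature, runs the test
#' matching the feature's arity: Kruskal-Wallis for >= 3 groups, Wilcoxon
#' for 2 groups, Pearson-on-log for continuous features.
#'
#' @param scores data.frame with `sample_id` and score columns.
#' @param meta data.frame with `sample_id` and feature columns.
#' @param score_cols score column names (default `z_up`, `z_down`).
#' @param features feature column names in `meta`.
#' @return A data.frame with `score`, `feature`, `test`, `statistic`, `p`,
#'   `n`.
#' @export
association_table <- function(scores, meta,
                              score_cols = c("z_up", "z_down"),
                              features) {
  m <- merge(scores, meta, by = "sample_id")
  rows <- list()
  for (sc in score_cols) {
    for (f in features) {
      v <- m[[f]]
      s <- m[[sc]]
      ok <- !is.na(v) & !is.na(s)
      if (is.numeric(v) && length(unique(v[ok])) > 7L) {
        res <- pearson_log(s[ok], v[ok])
        test <- "pearson-log"
      } else {
        g <- droplevels(as.factor(v[ok]))
        if (nlevels(g) >= 3L) {
          res <- kruskal_wallis(s[ok], g)
          test <- "kruskal-wallis"
        } else {
          lv <- levels(g)
          res <- wilcoxon_rank_sum(s[ok][g == lv[1]], s[ok][g == lv[2]])
          test <- "wilcoxon"
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(score = sc, feature = f, test = test,
                   statistic = if (test == "pearson-log") res$r else res$statistic,
                   p = res$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
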