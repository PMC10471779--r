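## Synthetic cohort and preclinical-design generators.
##
## Counts are negative binomial, parameterized by mean mu and dispersion
## alpha so that var = mu + alpha * mu^2 (size = 1/alpha). Planted structure:
## an HV reference population plus three patient clusters with a severity
## gradient on a fingerprint gene set, and a multi-arm preclinical design
## with planted disease genes partially reverted per treatment arm.

#' Configuration for a synthetic patient cohort
#'
#' Defines a cohort of healthy volunteers (HV) plus three patient clusters
#' with a severity gradient planted on a fingerprint gene set: up-genes rise
#' and down-genes fall with cluster severity (default C3 > C1 > C2 = baseline).
#' Clinical covariates follow the gradient: neutrophils increase with
#' severity, B and T lymphocytes decrease.
#'
#' @param n_hv number of healthy volunteers (reference population).
#' @param n_per_cluster named integer vector of patient cluster sizes.
#' @param n_genes total number of genes.
#' @param n_fingerprint_up,n_fingerprint_down number of planted up-/down-
#'   regulated fingerprint genes.
#' @param effect_sizes named numeric vector of per-cluster log2 effects
#'   applied to fingerprint genes (sign flipped for down-genes).
#' @param dispersion NB dispersion alpha (scalar or per-gene vector),
#'   var = mu + alpha * mu^2.
#' @param libsize_range multiplicative library-size interval (length 2).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline gene
#'   expression.
#' @param batch_effects optional named numeric vector of per-batch log2
#'   offsets; samples are assigned to batches round-robin.
#' @param clinical_coef named numeric vector of per-severity-unit slopes on
#'   log10 cell counts for neutrophils, B cells and T cells.
#' @param clinical_sd residual SD of log10 cell counts.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hv = 100L,
                          n_per_cluster = c(C1 = 86L, C2 = 120L, C3 = 43L),
                          n_genes = 500L,
                          n_fingerprint_up = 48L,
                          n_fingerprint_down = 21L,
                          effect_sizes = c(C1 = 0.5, C2 = 0.0, C3 = 1.0),
                          dispersion = 0.1,
                          libsize_range = c(0.7, 1.3),
                          base_meanlog = 4,
                          base_sdlog = 1.5,
                          batch_effects = NULL,
                          clinical_coef = c(neutrophils = 0.25,
                                            b_cells = -0.15,
                                            t_cells = -0.15),
                          clinical_sd = 0.1,
                          seed = 1L) {
  cfg <- list(n_hv = as.integer(n_hv), n_per_cluster = n_per_cluster,
              n_genes = as.integer(n_genes),
              n_fingerprint_up = as.integer(n_fingerprint_up),
              n_fingerprint_down = as.integer(n_fingerprint_down),
              effect_sizes = effect_sizes, dispersion = dispersion,
              libsize_range = libsize_range, base_meanlog = base_meanlog,
              base_sdlog = base_sdlog, batch_effects = batch_effects,
              clinical_coef = clinical_coef, clinical_sd = clinical_sd,
              seed = as.integer(seed))
  if (cfg$n_hv < 1L || any(cfg$n_per_cluster < 1L) || cfg$n_genes < 1L ||
      cfg$n_fingerprint_up < 1L || cfg$n_fingerprint_down < 1L) {
    stop("all cohort sizes must be >= 1", call. = FALSE)
  }
  if (length(cfg$n_per_cluster) != 3L || is.null(names(cfg$n_per_cluster))) {
    stop("`n_per_cluster` must be a named vector of 3 cluster sizes", call. = FALSE)
  }
  if (!all(names(cfg$n_per_cluster) %in% names(cfg$effect_sizes))) {
    stop("`effect_sizes` must name every cluster", call. = FALSE)
  }
  if (any(cfg$dispersion <= 0)) stop("`dispersion` must be > 0", call. = FALSE)
  if (cfg$n_fingerprint_up + cfg$n_fingerprint_down > cfg$n_genes) {
    stop("fingerprint larger than gene universe", call. = FALSE)
  }
  if (length(cfg$libsize_range) != 2L || any(cfg$libsize_range <= 0) ||
      diff(cfg$libsize_range) < 0) {
    stop("`libsize_range` must be a positive increasing interval", call. = FALSE)
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws NB counts with mean
#' `mu_gs = libsize_s * base_g * 2^(effect * direction)` for fingerprint
#' genes in patient clusters (baseline otherwise), plus optional per-batch
#' log2 offsets. Clinical covariates (neutrophil, B and T cell counts) are
#' log-normal with planted slopes along the severity gradient.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `counts` (genes x samples integer matrix,
#'   layer `"counts"`), `meta` (per-sample annotation data.frame) and
#'   `truth` (planted cluster labels, fingerprint genes with direction, and
#'   clinical coefficients).
#' @export
gen_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    n_pat <- sum(cfg$n_per_cluster)
    n <- cfg$n_hv + n_pat
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    samples <- c(sprintf("HV%03d", seq_len(cfg$n_hv)),
                 sprintf("P%03d", seq_len(n_pat)))
    role <- c(rep("HV", cfg$n_hv), rep("patient", n_pat))
    cluster <- c(rep(NA_character_, cfg$n_hv),
                 rep(names(cfg$n_per_cluster), cfg$n_per_cluster))

    base <- stats::rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog)
    n_fp <- cfg$n_fingerprint_up + cfg$n_fingerprint_down
    fp_idx <- sample.int(cfg$n_genes, n_fp)
    fp_dir <- c(rep(1L, cfg$n_fingerprint_up), rep(-1L, cfg$n_fingerprint_down))

    sev <- ifelse(is.na(cluster), 0, cfg$effect_sizes[cluster])
    mu <- matrix(base, cfg$n_genes, n)
    shift <- outer(fp_dir, sev)                  # fingerprint x sample log2 shifts
    mu[fp_idx, ] <- mu[fp_idx, ] * 2^shift

    batch <- rep("B1", n)
    if (!is.null(cfg$batch_effects)) {
      batch <- rep(names(cfg$batch_effects), length.out = n)
      mu <- mu * rep(2^cfg$batch_effects[batch], each = cfg$n_genes)
    }

    libsize <- stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2])
    mu <- sweep(mu, 2, libsize, "*")
    size <- 1 / cfg$dispersion                   # recycled per gene if vector
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     cfg$n_genes, n, dimnames = list(genes, samples))

    cc <- cfg$clinical_coef
    base10 <- c(neutrophils = 3.5, b_cells = 2.4, t_cells = 3.0)
    cells <- sapply(names(cc), function(v) {
      10^(base10[[v]] + cc[[v]] * sev + stats::rnorm(n, 0, cfg$clinical_sd))
    })
    rin <- round(stats::runif(n, 6.5, 10), 1)

    meta <- data.frame(sample_id = samples, role = role, cluster = cluster,
                       rin = rin, batch = batch,
                       neutrophils = cells[, "neutrophils"],
                       b_cells = cells[, "b_cells"],
                       t_cells = cells[, "t_cells"],
                       stringsAsFactors = FALSE)
    truth <- list(cluster = stats::setNames(cluster, samples),
                  fingerprint = data.frame(gene_id = genes[fp_idx],
                                           direction = fp_dir,
                                           stringsAsFactors = FALSE),
                  effect_sizes = cfg$effect_sizes,
                  clinical_coef = cfg$clinical_coef,
                  base_expression = stats::setNames(base, genes),
                  libsize = stats::setNames(libsize, samples))
    expr_layer(counts) <- "counts"
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Configuration for a synthetic preclinical design
#'
#' One control arm, one disease arm, and any number of treatment arms.
#' Disease genes shift the disease (and treatment) arms by planted log2
#' effects; each treatment arm restores the control mean for a random
#' subset (its reversal fraction) of the disease genes and keeps the
#' disease mean for the rest.
#'
#' @param arms named integer vector of arm sizes; must contain `control`
#'   and `disease` names (given by `control` / `disease`).
#' @param control,disease names of the control and disease arms.
#' @param reversal_fraction named numeric vector, one entry in \[0, 1\] per
#'   treatment arm.
#' @param n_genes total number of genes.
#' @param n_degs_up,n_degs_down planted up-/down-regulated disease genes.
#' @param effect_range range of |log2 effect| for planted disease genes.
#' @param dispersion,libsize_range,base_meanlog,base_sdlog as in
#'   [cohort_config()].
#' @param seed integer seed.
#' @return A list of class `preclinical_config`.
#' @export
preclinical_config <- function(arms = c(control = 11L, disease = 12L,
                                        D11 = 12L, E07 = 12L, TD139 = 12L),
                               control = "control", disease = "disease",
                               reversal_fraction = c(D11 = 0.5, E07 = 0.87,
                                                     TD139 = 0.4),
                               n_genes = 6000L,
                               n_degs_up = 484L, n_degs_down = 26L,
                               effect_range = c(1.5, 2.5),
                               dispersion = 0.1,
                               libsize_range = c(0.7, 1.3),
                               base_meanlog = 4, base_sdlog = 1.5,
                               seed = 1L) {
  cfg <- list(arms = arms, control = control, disease = disease,
              reversal_fraction = reversal_fraction,
              n_genes = as.integer(n_genes),
              n_degs_up = as.integer(n_degs_up),
              n_degs_down = as.integer(n_degs_down),
              effect_range = effect_range, dispersion = dispersion,
              libsize_range = libsize_range, base_meanlog = base_meanlog,
              base_sdlog = base_sdlog, seed = as.integer(seed))
  if (is.null(names(cfg$arms)) || any(cfg$arms < 1L)) {
    stop("`arms` must be a named vector of sizes >= 1", call. = FALSE)
  }
  if (sum(names(cfg$arms) == control) != 1L || sum(names(cfg$arms) == disease) != 1L) {
    stop("exactly one control and one disease arm are required", call. = FALSE)
  }
  treat <- setdiff(names(cfg$arms), c(control, disease))
  if (!setequal(names(cfg$reversal_fraction), treat)) {
    stop("`reversal_fraction` must name every treatment arm", call. = FALSE)
  }
  if (any(cfg$reversal_fraction < 0 | cfg$reversal_fraction > 1)) {
    stop("`reversal_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$dispersion <= 0)) stop("`dispersion` must be > 0", call. = FALSE)
  if (cfg$n_degs_up + cfg$n_degs_down > cfg$n_genes) {
    stop("more planted disease genes than genes", call. = FALSE)
  }
  class(cfg) <- "preclinical_config"
  cfg
}

#' Generate a synthetic preclinical design with ground truth
#'
#' @param config a [preclinical_config()].
#' @return A list with `counts`, `meta` (columns `sample_id`, `arm`) and
#'   `truth` (planted disease genes with direction and effect, and the
#'   reversed-gene subset per treatment arm; every reversed gene is a
#'   planted disease gene).
#' @export
gen_preclinical <- function(config) {
  if (!inherits(config, "preclinical_config")) config <- do.call(preclinical_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- sum(cfg$arms)
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    arm <- rep(names(cfg$arms), cfg$arms)
    samples <- sprintf("M%03d", seq_len(n))

    base <- stats::rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog)
    n_deg <- cfg$n_degs_up + cfg$n_degs_down
    deg_idx <- sample.int(cfg$n_genes, n_deg)
    deg_dir <- c(rep(1L, cfg$n_degs_up), rep(-1L, cfg$n_degs_down))
    deg_eff <- stats::runif(n_deg, cfg$effect_range[1], cfg$effect_range[2]) * deg_dir

    treat <- setdiff(names(cfg$arms), c(cfg$control, cfg$disease))
    reversed <- lapply(treat, function(a) {
      k <- round(cfg$reversal_fraction[[a]] * n_deg)
      sort(sample.int(n_deg, k))
    })
    names(reversed) <- treat

    mu <- matrix(base, cfg$n_genes, n)
    for (s in seq_len(n)) {
      a <- arm[s]
      if (a == cfg$control) next
      e <- deg_eff
      if (a %in% treat) e[reversed[[a]]] <- 0   # restored to control mean
      mu[deg_idx, s] <- mu[deg_idx, s] * 2^e
    }

    libsize <- stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2])
    mu <- sweep(mu, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     cfg$n_genes, n, dimnames = list(genes, samples))
    expr_layer(counts) <- "counts"

    meta <- data.frame(sample_id = samples, arm = arm, stringsAsFactors = FALSE)
    truth <- list(degs = data.frame(gene_id = genes[deg_idx],
                                    direction = deg_dir,
                                    log2_effect = deg_eff,
                                    stringsAsFactors = FALSE),
                  reversed = lapply(reversed, function(i) genes[deg_idx][i]),
                  reversal_fraction = cfg$reversal_fraction,
                  base_expression = stats::setNames(base, genes),
                  libsize = stats::setNames(libsize, samples))
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Write a generated dataset to plain-text files
#'
#' Writes `counts.tsv` (genes x samples, `gene_id` first column),
#' `meta.tsv` and `truth.json` under `dir`.
#'
#' @param data result of [gen_cohort()] or [gen_preclinical()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(data$counts, file.path(dir, "counts.tsv"))
  utils::write.table(data$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(data$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
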