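## Pipeline orchestration: validated configuration, staged execution on a
## (typically synthetic) cohort plus preclinical design, TSV/JSON outputs
## and a reproducibility manifest.

pipeline_defaults <- function() {
  list(fc_min = 1.3, fdr_max = 0.05, B = 200L, frequency_threshold = 1.0,
       tau = 0.6, k = "auto", k_range = 2:6, n_features = 5000L,
       train_frac = 0.8, ref_cluster = "auto", seed = 1L,
       cohort = list(), preclinical = list())
}

#' Build and validate a pipeline configuration
#'
#' Named overrides of the stage parameters: `fc_min`, `fdr_max`, `B`,
#' `frequency_threshold`, `tau`, `k` (`"auto"` or an integer), `k_range`,
#' `n_features`, `train_frac`, `ref_cluster`, `seed`, plus `cohort` /
#' `preclinical` lists forwarded to [cohort_config()] /
#' [preclinical_config()]. Unknown keys are rejected; validation happens
#' before any stage runs.
#'
#' @param ... parameter overrides.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$fdr_max <= 0 || cfg$fdr_max > 1) stop("fdr_max must lie in (0, 1]", call. = FALSE)
  if (cfg$fc_min < 1) stop("fc_min must be >= 1", call. = FALSE)
  if (cfg$B < 1) stop("B must be >= 1", call. = FALSE)
  if (cfg$frequency_threshold <= 0 || cfg$frequency_threshold > 1) {
    stop("frequency_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$tau < 0 || cfg$tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  if (!identical(cfg$k, "auto") && (!is.numeric(cfg$k) || cfg$k < 2)) {
    stop("k must be \"auto\" or an integer >= 2", call. = FALSE)
  }
  if (cfg$train_frac <= 0 || cfg$train_frac > 1) stop("train_frac must lie in (0, 1]", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

param_hash <- function(cfg) {
  flat <- utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE))
  sprintf("%08x", poly_hash(flat))
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gal3fp params=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on synthetic or user data
#'
#' Executes, in order: preprocessing (size factors, normalization, gene
#' filtering), consensus clustering of the patient samples (with automatic
#' k selection when `k = "auto"`), train/test split with random-forest
#' extension of the consensus labels, bootstrap stability selection of the
#' fingerprint panel, direction assignment, up/down scoring against the HV
#' reference, per-cluster differential expression versus HV, score-clinical
#' association statistics, PLS-DA, and (when a preclinical design is
#' available) the treatment-reversal analysis. All tabular outputs are TSV
#' with a parameter-hash header comment; a JSON manifest records the seed,
#' parameters and output inventory. Rerunning with the same configuration
#' reproduces all outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param counts,meta optional genes x samples count matrix and annotation
#'   data.frame (`sample_id`, `role`, ...); when omitted, `simulate` must
#'   be TRUE.
#' @param simulate generate a synthetic cohort and preclinical design from
#'   the configuration.
#' @param candidate_genes optional candidate gene ids for the fingerprint
#'   stage; defaults to the planted fingerprint plus decoys (simulated
#'   runs) or all filtered genes.
#' @return Invisibly, a list with the stage results (`clustering`, `panel`,
#'   `scores`, `de`, `assoc`, `plsda`, `reversal`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         counts = NULL, meta = NULL, simulate = is.null(counts),
                         candidate_genes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- param_hash(config)
  manifest <- list(package = "gal3fp",
                   version = as.character(utils::packageVersion("gal3fp")),
                   seed = config$seed, param_hash = hash,
                   parameters = unclass(config)[c("fc_min", "fdr_max", "B",
                                                  "frequency_threshold", "tau",
                                                  "k", "n_features", "train_frac")],
                   outputs = character(0))
  truth <- NULL
  pre <- NULL
  if (simulate) {
    cc <- do.call(cohort_config,
                  utils::modifyList(list(seed = derive_seed(config$seed, "cohort")),
                                    config$cohort))
    sim <- gen_cohort(cc)
    counts <- sim$counts; meta <- sim$meta; truth <- sim$truth
    pc <- do.call(preclinical_config,
                  utils::modifyList(list(seed = derive_seed(config$seed, "preclinical")),
                                    config$preclinical))
    pre <- gen_preclinical(pc)
  }
  if (is.null(counts) || is.null(meta)) {
    stop("counts/meta missing and simulate = FALSE", call. = FALSE)
  }

  ## -- preprocess ----------------------------------------------------------
  filt <- filter_genes(counts)
  sf <- size_factors(filt$counts)
  norm <- vst_like(filt$counts, sf)

  hv_ids <- meta$sample_id[meta$role == "HV"]
  pat_ids <- meta$sample_id[meta$role == "patient"]
  if (!length(hv_ids) || !length(pat_ids)) {
    stop("metadata must label both HV and patient samples", call. = FALSE)
  }

  ## -- cluster (train) + extend (test) -------------------------------------
  split_seed <- derive_seed(config$seed, "split")
  train_ids <- with_seed(split_seed,
                         sort(sample(pat_ids, round(config$train_frac * length(pat_ids)))))
  test_ids <- setdiff(pat_ids, train_ids)

  feats <- top_variance_features(norm[, pat_ids, drop = FALSE], config$n_features)
  xtr <- t(norm[feats, train_ids, drop = FALSE])
  k <- config$k
  ksel <- NULL
  if (identical(k, "auto")) {
    ksel <- select_k(xtr, k_range = config$k_range,
                     seed = derive_seed(config$seed, "selectk"))
    k <- ksel$k
  }
  parts <- cluster_three_ways(xtr, k, seed = derive_seed(config$seed, "cluster"))
  clus <- consensus_labels(parts, sample_ids = train_ids, k = k,
                           seed = config$seed)
  cluster_names <- paste0("C", clus$consensus)
  cluster_names[is.na(clus$consensus)] <- NA

  ext <- NULL
  if (length(test_ids)) {
    ext <- extend_to_test(xtr, cluster_names,
                          t(norm[feats, test_ids, drop = FALSE]),
                          tau = config$tau,
                          seed = derive_seed(config$seed, "extend"))
  }
  labels_all <- stats::setNames(rep(NA_character_, ncol(norm)), colnames(norm))
  labels_all[train_ids] <- cluster_names
  if (!is.null(ext)) {
    ok <- ext$assignments$retained
    labels_all[ext$assignments$sample_id[ok]] <- ext$assignments$predicted[ok]
  }

  ## -- fingerprint + scores -------------------------------------------------
  if (is.null(candidate_genes)) {
    candidate_genes <- if (!is.null(truth)) {
      with_seed(derive_seed(config$seed, "cands"), {
        fp <- truth$fingerprint$gene_id
        fp <- fp[fp %in% rownames(norm)]
        decoys <- setdiff(rownames(norm), fp)
        c(fp, sample(decoys, min(length(decoys), max(0, 248 - length(fp)))))
      })
    } else rownames(norm)
  }
  lab_pat <- labels_all[pat_ids]
  panel <- stability_select(norm[, pat_ids, drop = FALSE], lab_pat,
                            candidate_genes, B = config$B,
                            threshold = config$frequency_threshold,
                            seed = derive_seed(config$seed, "stability"))
  ref_cluster <- config$ref_cluster
  if (identical(ref_cluster, "auto")) {
    # cluster labels are arbitrary: take as severity reference the cluster
    # whose members deviate most from the HV centroid on the candidate genes
    cg <- intersect(candidate_genes, rownames(norm))
    hv_centroid <- rowMeans(norm[cg, hv_ids, drop = FALSE])
    dev <- sqrt(colSums((norm[cg, pat_ids, drop = FALSE] - hv_centroid)^2))
    mean_dev <- tapply(dev[!is.na(lab_pat)], lab_pat[!is.na(lab_pat)], mean)
    ref_cluster <- names(which.max(mean_dev))
  }
  panel <- split_directions(norm[, pat_ids, drop = FALSE], lab_pat, panel,
                            ref_cluster = ref_cluster,
                            hv_matrix = norm[, hv_ids, drop = FALSE])
  scores <- score_samples(norm, panel, hv_ids)

  ## -- differential expression: each cluster vs HV -------------------------
  de <- list()
  for (cl in sort(unique(stats::na.omit(lab_pat)))) {
    ids <- c(hv_ids, names(lab_pat)[!is.na(lab_pat) & lab_pat == cl])
    grp <- factor(ifelse(ids %in% hv_ids, "HV", cl), levels = c("HV", cl))
    de[[cl]] <- de_table(norm[, ids, drop = FALSE], grp,
                         fc_min = config$fc_min, fdr_max = config$fdr_max)
  }

  ## -- associations ---------------------------------------------------------
  assoc <- NULL
  if (all(c("neutrophils", "b_cells", "t_cells") %in% names(meta))) {
    meta$nlr <- nlr(meta$neutrophils, meta$b_cells, meta$t_cells)
    assoc <- association_table(scores[scores$sample_id %in% pat_ids, ], meta,
                               features = c("neutrophils", "b_cells",
                                            "t_cells", "nlr"))
  }

  ## -- PLS-DA ---------------------------------------------------------------
  pl_ids <- c(hv_ids, names(lab_pat)[!is.na(lab_pat)])
  pl_lab <- c(rep("HV", length(hv_ids)), stats::na.omit(lab_pat))
  pls <- fit_plsda(t(norm[feats, pl_ids, drop = FALSE]), pl_lab)

  ## -- reversal (preclinical) ----------------------------------------------
  reversal <- NULL
  if (!is.null(pre)) {
    pfilt <- filter_genes(pre$counts)
    pnorm <- vst_like(pfilt$counts, size_factors(pfilt$counts))
    reversal <- reversal_analysis(pnorm, pre$meta$arm,
                                  fc_min = config$fc_min,
                                  fdr_max = config$fdr_max)
  }

  ## -- outputs --------------------------------------------------------------
  out <- function(df, name) {
    write_stage_tsv(df, file.path(out_dir, name), hash)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  clu_df <- data.frame(sample_id = train_ids,
                       hierarchical = clus$labels_by_method[[1]],
                       kmeans = clus$labels_by_method[[2]],
                       gmm = clus$labels_by_method[[3]],
                       consensus = cluster_names,
                       stringsAsFactors = FALSE)
  out(clu_df, "clusters.tsv")
  if (!is.null(ext)) out(ext$assignments, "extension.tsv")
  out(panel$genes[panel$genes$selected, ], "panel.tsv")
  out(scores, "scores.tsv")
  for (cl in names(de)) out(de[[cl]], sprintf("de_%s_vs_HV.tsv", cl))
  if (!is.null(assoc)) out(assoc, "associations.tsv")
  out(data.frame(sample_id = pl_ids, label = pl_lab,
                 comp1 = pls$scores[, 1], comp2 = pls$scores[, 2]),
      "plsda_scores.tsv")
  if (!is.null(reversal)) {
    rev_df <- data.frame(arm = names(reversal$fraction),
                         n_pathology = nrow(reversal$pathology),
                         n_reversed = lengths(reversal$reversed[names(reversal$fraction)]),
                         fraction = unname(reversal$fraction))
    out(rev_df, "reversal.tsv")
  }
  manifest$counts <- list(n_genes = nrow(norm), n_samples = ncol(norm),
                          k = k, n_consensus = clus$n_consensus,
                          panel_size = sum(panel$genes$selected))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(clustering = clus, extension = ext, select_k = ksel,
                 panel = panel, scores = scores, de = de, assoc = assoc,
                 plsda = pls, reversal = reversal, truth = truth,
                 manifest = manifest))
}
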