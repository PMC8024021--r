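#' Pipeline configuration
#'
#' Collects every analysis parameter of the integrated pipeline; all have
#' working defaults. Integration (hypernetwork anchoring) uses the raw-p
#' DEOE sets while all other stages use the FDR sets, each at its own
#' alpha.
#'
#' @param anchor_layer Layer whose DE features anchor the hypernetworks.
#' @param partner_layer Second tissue layer used for the robustness
#'   pairing and the direction-consistency filter.
#' @param circulating_layers Layers pooled into the combined circulating
#'   hypernetwork.
#' @param alpha_integration Raw-p level for DEOE selection feeding the
#'   hypernetworks (default 0.05).
#' @param alpha_fdr FDR level for all other selections (default 0.05).
#' @param k Dichotomization sd multiplier (default 1.5); when `sweep_k` is
#'   a grid, the chi-squared signal window picks k from it instead.
#' @param sweep_k Optional numeric grid for [threshold_sweep()].
#' @param me_mode Chi-squared expectation mode (see [chi2_signal()]).
#' @param linkage,n_cluster_range,min_size Passed to [central_cluster()].
#' @param raw_intensity_layers Layers arriving as raw positive intensities:
#'   they get sample-median normalization then log2 (default none -- the
#'   simulator emits log2 data).
#' @param iqr_keep Named numeric vector of per-layer IQR-filter keep
#'   fractions (default keeps the top 80\% of metabolome features).
#' @param scale_layers Layers standardized per feature before analysis
#'   (default the miRNA layer).
#' @param min_anchor_fdr Signal gate: the study counts as having signal if
#'   the anchor layer has at least this many FDR DEOEs (default 10) or a
#'   raw-p DEOE fraction of at least twice `alpha_integration` (clearly
#'   above the null expectation); otherwise the pipeline exits cleanly with
#'   a "no signal" report.
#' @param circulating_criterion DEOE criterion for the circulating pooling,
#'   `"raw_p"` (integration convention, the default) or `"fdr"`.
#' @param select_iterations,select_trees Shadow-selection iterations and
#'   trees per iteration (defaults 100 and 500).
#' @param n_trees Trees for the final classification forest (default 5000).
#' @param seed Integer seed covering every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(anchor_layer = "pbmc",
                            partner_layer = "adipose",
                            circulating_layers = c("pbmc", "mirna",
                                                   "metabolome"),
                            alpha_integration = 0.05,
                            alpha_fdr = 0.05,
                            k = 1.5,
                            sweep_k = NULL,
                            me_mode = "mean_element",
                            linkage = "complete",
                            n_cluster_range = 2:10,
                            min_size = NULL,
                            raw_intensity_layers = character(),
                            iqr_keep = c(metabolome = 0.8),
                            scale_layers = "mirna",
                            min_anchor_fdr = 10,
                            circulating_criterion = c("raw_p", "fdr"),
                            select_iterations = 100,
                            select_trees = 500,
                            n_trees = 5000,
                            seed = 1L) {
  circulating_criterion <- match.arg(circulating_criterion)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the integrated multi-omic pipeline
#'
#' Executes preprocessing, paired differential expression, anchor-layer
#' hypernetworks against every other layer, cross-layer overlap accounting,
#' the dissimilarity robustness filter, shadow-permutation feature
#' selection, direction-consistency filtering against the partner tissue,
#' forest classification with out-of-bag AUC, and the combined circulating
#' hypernetwork with central-core extraction and centrality ranking.
#' Deterministic given `config$seed`.
#'
#' @param study Named list of [omic_layer()]s.
#' @param design A [paired_design()].
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory: when given, intermediates (paired
#'   differences, DE tables, selections) and the report JSON are persisted
#'   there, exactly as named in the report's `files` field.
#' @return A list of class `pipeline_report`; see [write_report()].
#' @export
run_pipeline <- function(study, design, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s (%.1fs)", stage, sprintf(...),
                    proc.time()[["elapsed"]] - t0))
  }
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  persist <- function(fun, name) {
    if (is.null(output_dir)) return(NULL)
    path <- file.path(output_dir, name)
    fun(path)
    name
  }
  if (!all(c(config$anchor_layer, config$partner_layer) %in% names(study)))
    stop("pipeline: anchor/partner layer missing from the study")
  files <- character()

  ## -- preprocess -------------------------------------------------------
  prep <- study
  for (layer in names(prep)) {
    if (layer %in% config$raw_intensity_layers)
      prep[[layer]] <- log_transform(median_normalize(prep[[layer]]))
    if (layer %in% names(config$iqr_keep))
      prep[[layer]] <- iqr_filter(prep[[layer]], config$iqr_keep[[layer]])
    if (layer %in% config$scale_layers)
      prep[[layer]] <- suppressWarnings(scale_mean_center(prep[[layer]]))
    log_stage("preprocess", "%s: %d features retained", layer,
              nrow(prep[[layer]]$values))
  }
  D <- lapply(prep, paired_difference, design = design)

  ## -- differential expression -----------------------------------------
  diffs <- lapply(prep, paired_t_test, design = design)
  deoe_raw <- deoe_select(diffs, config$alpha_integration, "raw_p")
  deoe_fdr <- deoe_select(diffs, config$alpha_fdr, "fdr")
  log_stage("diffexpr", "raw-p DEOEs: %s",
            paste(sprintf("%s=%d", names(deoe_raw$sets),
                          lengths(deoe_raw$sets)), collapse = ", "))
  files <- c(files,
             persist(function(p) write_diff_results(diffs, p), "diffexpr.tsv"),
             persist(function(p) utils::write.csv(deoe_raw$summary, p,
                                                  row.names = FALSE),
                     "deoe_summary.csv"))

  report <- list(params = unclass(config),
                 deoe_summary = deoe_raw$summary,
                 deoe_raw = deoe_raw$sets, deoe_fdr = deoe_fdr$sets)

  ## -- signal gate ------------------------------------------------------
  n_anchor_fdr <- length(deoe_fdr$sets[[config$anchor_layer]])
  raw_frac <- length(deoe_raw$sets[[config$anchor_layer]]) /
    nrow(diffs[[config$anchor_layer]])
  if (n_anchor_fdr < config$min_anchor_fdr &&
      raw_frac < 2 * config$alpha_integration) {
    log_stage("gate", "%d FDR DEOEs, raw-p fraction %.3f in anchor layer: no signal",
              n_anchor_fdr, raw_frac)
    report$status <- "no_signal"
    report <- structure(report, class = "pipeline_report")
    report$files <- c(files, persist(function(p) write_report(report, p),
                                     "report.json"))
    return(report)
  }

  ## -- anchor hypernetworks against each other layer -------------------
  anchor_ids <- deoe_raw$sets[[config$anchor_layer]]
  d_anchor <- D[[config$anchor_layer]][anchor_ids, , drop = FALSE]
  pairings <- setdiff(names(study), config$anchor_layer)
  hns <- list(); clusters <- list()
  for (layer in pairings) {
    kk <- config$k
    hn <- hypernetwork(d_anchor, D[[layer]], k = kk)
    if (!is.null(config$sweep_k)) {
      kk <- threshold_sweep(hn$R, config$sweep_k, config$me_mode)$best_k
      hn <- hypernetwork(d_anchor, D[[layer]], k = kk)
    }
    cl <- central_cluster(hn, config$n_cluster_range, config$linkage,
                          config$min_size)
    nm <- paste0(config$anchor_layer, "~", layer)
    hns[[nm]] <- hn; clusters[[nm]] <- cl
    log_stage("hypernetwork", "%s: k=%.2f, central cluster %d of %d",
              nm, kk, length(cl$members), hn$N)
  }
  report$clusters <- lapply(clusters, `[[`, "members")
  report$overlap <- layer_overlap(report$clusters)

  ## -- robustness filter on the anchor~partner pairing ------------------
  key <- paste0(config$anchor_layer, "~", config$partner_layer)
  rob <- dissimilarity_robust(hns[[key]], clusters[[key]],
                              n_cluster_range = config$n_cluster_range,
                              linkage = config$linkage,
                              min_size = config$min_size)
  log_stage("robustness", "%d of %d retained", length(rob$robust),
            length(clusters[[key]]$members))
  report$robust <- rob$robust
  report$eliminated <- rob$eliminated
  if (length(rob$robust) < 2) {
    report$status <- "no_signal"
    report <- structure(report, class = "pipeline_report")
    report$files <- c(files, persist(function(p) write_report(report, p),
                                     "report.json"))
    return(report)
  }

  ## -- classification cascade ------------------------------------------
  anchor_vals <- prep[[config$anchor_layer]]$values
  samp <- intersect(colnames(anchor_vals), design$samples$sample_id)
  X <- t(anchor_vals[rob$robust, samp, drop = FALSE])
  y <- factor(design$condition_of[samp],
              levels = c("withdrawal", "exposure"))
  pls <- plsda_separation(X, y, n_components = 2)
  log_stage("plsda", "perfectly separated: %s", pls$perfectly_separated)

  sel <- shadow_select(X, y, n_iterations = config$select_iterations,
                       n_trees = config$select_trees,
                       seed = config$seed)
  log_stage("selection", "%d of %d confirmed or tentative",
            length(sel$selected), ncol(X))
  dc <- direction_consistent(diffs[[config$anchor_layer]],
                             diffs[[config$partner_layer]], sel$selected)
  dc_sig <- direction_consistent(diffs[[config$anchor_layer]],
                                 diffs[[config$partner_layer]], sel$selected,
                                 require_significant = TRUE,
                                 alpha = config$alpha_fdr)
  clf <- if (length(sel$selected) >= 2)
    rf_oob_auc(X[, sel$selected, drop = FALSE], y,
               n_trees = config$n_trees, seed = config$seed + 1L)
  else NULL
  if (!is.null(clf))
    log_stage("classify", "OOB AUC %.3f on %d features", clf$oob_auc,
              length(sel$selected))
  report$plsda <- list(perfectly_separated = pls$perfectly_separated,
                       explained_variance = as.numeric(
                         pls$explained_variance))
  report$selection <- list(status = as.character(sel$status),
                           feature = names(sel$status),
                           hits = as.integer(sel$hits))
  report$selected <- sel$selected
  report$direction_consistent <- dc
  report$direction_consistent_significant <- dc_sig
  report$classifier <- if (is.null(clf)) NULL else
    list(oob_auc = clf$oob_auc, oob_error_rate = clf$oob_error_rate,
         n_trees = clf$n_trees)
  files <- c(files, persist(function(p) {
    utils::write.table(
      data.frame(feature_id = names(sel$status),
                 status = as.character(sel$status), hits = sel$hits),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, "selection.tsv"))

  ## -- combined circulating hypernetwork --------------------------------
  circ <- tryCatch(
    combined_circulating_hypernetwork(
      D, if (config$circulating_criterion == "fdr") deoe_fdr$sets
         else deoe_raw$sets,
      config$circulating_layers, k = config$k,
      n_cluster_range = config$n_cluster_range, linkage = config$linkage,
      min_size = config$min_size),
    error = function(e) {
      log_stage("circulating", "skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(circ)) {
    log_stage("circulating", "pooled %d elements, core %d, %d clusters",
              circ$n_pooled, length(circ$core$members), circ$n_clusters)
    report$circulating <- list(
      n_pooled = circ$n_pooled,
      n_clusters = circ$n_clusters,
      core = circ$core$members,
      centrality = circ$centrality[seq_len(min(25, nrow(circ$centrality))), ])
  }

  report$status <- "ok"
  report <- structure(report, class = "pipeline_report")
  report$files <- c(files, persist(function(p) write_report(report, p),
                                   "report.json"))
  report
}

#' Combined circulating-layer hypernetwork
#'
#' Pools the paired-difference vectors of all circulating DEOEs (transcripts,
#' miRNAs, metabolites), partitions them by hierarchical correlation
#' clustering (1 - r distance; the cut count is chosen by maximum average
#' silhouette width over the scan range and reported, not fixed), then
#' builds a hypernetwork with the pooled set as both anchor and background,
#' extracts its central core and ranks all pooled elements by eigenvector
#' centrality.
#'
#' @param D Named list of paired-difference matrices (features x subjects).
#' @param deoe_sets Named list of per-layer DEOE feature-ID vectors.
#' @param circulating_layers Layers to pool.
#' @param k Dichotomization multiplier.
#' @param n_cluster_range,linkage,min_size Passed to [central_cluster()]
#'   (and the cut-count scan reuses `n_cluster_range`).
#' @return List: `core` (a `cluster_result`), `centrality` (data.frame),
#'   `n_clusters`, `cluster_assignment` (named vector), `n_pooled`,
#'   `hypernetwork`.
#' @export
combined_circulating_hypernetwork <- function(D, deoe_sets,
                                              circulating_layers,
                                              k = 1.5,
                                              n_cluster_range = 2:10,
                                              linkage = "complete",
                                              min_size = NULL) {
  layers <- intersect(circulating_layers, names(D))
  if (length(layers) < 2)
    stop("need DEOEs from at least 2 circulating layers")
  pooled <- do.call(rbind, lapply(layers, function(l)
    D[[l]][intersect(deoe_sets[[l]], rownames(D[[l]])), , drop = FALSE]))
  if (is.null(pooled) || nrow(pooled) < 10)
    stop("pooled circulating DEOE set has fewer than 10 elements")

  rr <- stats::cor(t(pooled))
  dd <- stats::as.dist(1 - rr)
  hc <- stats::hclust(dd, method = linkage)
  ks <- n_cluster_range[n_cluster_range < nrow(pooled)]
  sil <- vapply(ks, function(kk) {
    cut <- stats::cutree(hc, k = kk)
    mean(cluster::silhouette(cut, dd)[, "sil_width"])
  }, numeric(1))
  n_clusters <- ks[which.max(sil)]
  assignment <- stats::cutree(hc, k = n_clusters)

  hn <- hypernetwork(pooled, pooled, k = k)
  core <- central_cluster(hn, n_cluster_range, linkage, min_size)
  cent <- centrality_rank(hn)
  list(core = core, centrality = cent, n_clusters = n_clusters,
       cluster_assignment = assignment, n_pooled = nrow(pooled),
       hypernetwork = hn)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Integrated multi-omic pipeline report\n")
  cat(sprintf("  status: %s\n", x$status))
  print(x$deoe_summary)
  if (x$status == "ok") {
    for (nm in names(x$clusters))
      cat(sprintf("  central cluster %s: %d members\n", nm,
                  length(x$clusters[[nm]])))
    cat(sprintf("  robust set: %d (eliminated %d)\n", length(x$robust),
                length(x$eliminated)))
    cat(sprintf("  shadow-selected: %d; direction-consistent: %d (+significant: %d)\n",
                length(x$selected), length(x$direction_consistent),
                length(x$direction_consistent_significant)))
    cat(sprintf("  PLS-DA perfectly separated: %s\n",
                x$plsda$perfectly_separated))
    if (!is.null(x$classifier))
      cat(sprintf("  OOB AUC: %.3f (error %.3f, %d trees)\n",
                  x$classifier$oob_auc, x$classifier$oob_error_rate,
                  x$classifier$n_trees))
    if (!is.null(x$circulating))
      cat(sprintf("  circulating: %d pooled, %d correlation clusters, core %d\n",
                  x$circulating$n_pooled, x$circulating$n_clusters,
                  length(x$circulating$core)))
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' The serialization is deterministic: identical config + seed yields a
#' byte-identical file.
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$files <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$iqr_keep)) vals$iqr_keep <- unlist(vals$iqr_keep)
  do.call(pipeline_config, vals)
}
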