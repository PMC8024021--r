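#' Paired t-test per feature
#'
#' One-sample t statistic on each feature's per-subject paired differences
#' (df = n_pairs - 1, two-sided p), with the mean difference reported as the
#' log2 fold change. Features with zero difference variance cannot be
#' tested and conservatively receive t = 0, p = 1 (flagged in the output).
#'
#' @param layer An [omic_layer()] on the log2 scale.
#' @param design A [paired_design()].
#' @return A data.frame of class `diff_result` with columns
#'   `feature_id, layer, log2fc, t_stat, p, q, direction, zero_var`,
#'   where `q` is the Benjamini-Hochberg FDR over the layer's features and
#'   `direction` is `sign(log2fc)`.
#' @export
paired_t_test <- function(layer, design) {
  d <- paired_difference(layer, design)
  n <- ncol(d)
  if (n < 2) stop("paired t-test needs at least 2 complete subject pairs")
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  zero_var <- s == 0
  t_stat <- ifelse(zero_var, 0, m / (s / sqrt(n)))
  p <- ifelse(zero_var, 1, 2 * stats::pt(abs(t_stat), df = n - 1,
                                         lower.tail = FALSE))
  res <- data.frame(feature_id = rownames(d), layer = layer$layer_name,
                    log2fc = m, t_stat = t_stat, p = p,
                    q = bh_fdr(p), direction = sign(m),
                    zero_var = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (capped at 1, monotone in p-rank), via
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues)) stop("NA/NaN p-value")
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed 'omic elements (DEOEs)
#'
#' Per-layer feature sets passing either the raw-p or the FDR criterion at
#' `alpha`, plus a summary table of total features and counts significant
#' at raw p < 0.05 and FDR < 0.05 per layer.
#'
#' @param results Named list of `diff_result` data.frames, one per layer.
#' @param alpha Significance level in `(0, 1)` (default 0.05).
#' @param criterion `"raw_p"` or `"fdr"`.
#' @return List with `sets` (named list of feature-ID vectors) and
#'   `summary` (data.frame: layer, n_features, n_p05, n_fdr05).
#' @export
deoe_select <- function(results, alpha = 0.05, criterion = c("raw_p", "fdr")) {
  criterion <- match.arg(criterion)
  stopifnot(alpha > 0, alpha <= 1)
  sets <- lapply(results, function(r) {
    crit <- if (criterion == "raw_p") r$p else r$q
    r$feature_id[crit < alpha | (alpha == 1)]
  })
  summary <- do.call(rbind, lapply(names(results), function(l) {
    r <- results[[l]]
    data.frame(layer = l, n_features = nrow(r),
               n_p05 = sum(r$p < 0.05), n_fdr05 = sum(r$q < 0.05),
               stringsAsFactors = FALSE)
  }))
  list(sets = sets, summary = summary)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired samples (exact for small n
#' without ties, normal approximation with tie correction otherwise), via
#' [stats::wilcox.test()].
#'
#' @param x,y Paired numeric vectors of equal length.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == y)) stop("all paired differences are zero")
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided")$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum p-value for two independent groups (exact for small n
#' without ties), via [stats::wilcox.test()].
#'
#' @param groupA,groupB Numeric vectors.
#' @export
mann_whitney <- function(groupA, groupB) {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  suppressWarnings(
    stats::wilcox.test(groupA, groupB, alternative = "two.sided")$p.value)
}

#' Write per-layer differential expression results
#'
#' @param results Named list of `diff_result` data.frames.
#' @param path Output TSV path.
#' @export
write_diff_results <- function(results, path) {
  df <- do.call(rbind, results)
  utils::write.table(
    df[, c("layer", "feature_id", "log2fc", "t_stat", "p", "q", "direction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
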