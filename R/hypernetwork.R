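#' Anchor-vs-background correlation matrix
#'
#' Pearson correlations between every anchor feature (the differentially
#' expressed elements, forming the m rows) and every background feature (all
#' elements called present, forming the n columns), computed on per-subject
#' paired-difference vectors. The moments of the pooled r distribution are
#' recorded; the dichotomization threshold is expressed in units of its sd.
#'
#' @param anchor Numeric matrix, anchor features x subjects (paired
#'   differences, see [paired_difference()]).
#' @param background Numeric matrix, background features x the same
#'   subjects.
#' @return An object of class `correlation_matrix`: fields `r` (m x n),
#'   `r_mean`, `r_sd`, `n_subjects`, `zero_var` (IDs of zero-variance
#'   vectors whose correlations were set to 0).
#' @export
correlation_matrix <- function(anchor, background) {
  stopifnot(is.matrix(anchor), is.matrix(background),
            ncol(anchor) == ncol(background))
  if (ncol(anchor) < 3) stop("need at least 3 subjects")
  sd_a <- apply(anchor, 1, stats::sd)
  sd_b <- apply(background, 1, stats::sd)
  zero_var <- c(rownames(anchor)[sd_a == 0], rownames(background)[sd_b == 0])
  if (length(zero_var))
    warning("zero-variance vector(s), correlations set to 0: ",
            paste(utils::head(zero_var, 5), collapse = ", "))
  r <- suppressWarnings(stats::cor(t(anchor), t(background)))
  r[is.na(r)] <- 0
  structure(list(r = r, r_mean = mean(r), r_sd = stats::sd(r),
                 n_subjects = ncol(anchor), zero_var = zero_var),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix: %d anchors x %d background, r ~ %.3f +/- %.3f>\n",
              nrow(x$r), ncol(x$r), x$r_mean, x$r_sd))
  invisible(x)
}

#' Dichotomize correlations into a hypernetwork incidence matrix
#'
#' An anchor-background pair is incident (m_ij = 1) when its correlation
#' deviates from the mean of the pooled r distribution by at least `k`
#' standard deviations: `|r_ij - mean(r)| >= k * sd(r)`. The r-values are
#' close to normally distributed in this setting, so `k` is a z-score style
#' threshold; the conventional default is 1.5.
#'
#' @param R A [correlation_matrix()].
#' @param k Positive sd multiplier (default 1.5).
#' @return An object of class `incidence_matrix`: fields `M` (binary m x n),
#'   `threshold_k`, `r_mean`, `r_sd`.
#' @export
dichotomize <- function(R, k = 1.5) {
  stopifnot(inherits(R, "correlation_matrix"), k >= 0)
  if (!is.finite(R$r_sd) || R$r_sd <= 0)
    stop("degenerate correlation distribution (sd = 0)")
  M <- (abs(R$r - R$r_mean) >= k * R$r_sd) * 1L
  structure(list(M = M, threshold_k = k, r_mean = R$r_mean, r_sd = R$r_sd),
            class = "incidence_matrix")
}

#' Shared-edge adjacency: build the hypernetwork from an incidence matrix
#'
#' Multiplies the incidence matrix by its transpose: `sM = M %*% t(M)`.
#' Entry (i, j) counts the background features whose correlations with both
#' anchor i and anchor j pass the threshold -- the number of edges shared by
#' the pair. The diagonal holds node degrees (incidence row sums).
#'
#' @param Minc An [dichotomize()] result (or a plain binary matrix).
#' @return An object of class `hypernetwork`: fields `sM` (symmetric m x m
#'   integer matrix), `node_ids`, `N` (order of sM), `threshold_k`.
#' @export
adjacency <- function(Minc) {
  M <- if (inherits(Minc, "incidence_matrix")) Minc$M else Minc
  stopifnot(is.matrix(M), all(M %in% c(0, 1)))
  sM <- M %*% t(M)
  storage.mode(sM) <- "integer"
  structure(list(sM = sM, node_ids = rownames(M), N = nrow(sM),
                 threshold_k = if (inherits(Minc, "incidence_matrix"))
                   Minc$threshold_k else NA_real_),
            class = "hypernetwork")
}

#' Fit a hypernetwork in one call
#'
#' Convenience fitting function chaining [correlation_matrix()],
#' [dichotomize()] and [adjacency()]; the returned object additionally
#' carries the correlation and incidence matrices so the chi-squared window
#' and the dissimilarity robustness filter can be computed from it.
#'
#' @inheritParams correlation_matrix
#' @inheritParams dichotomize
#' @return A `hypernetwork` object with extra fields `R`
#'   (the `correlation_matrix`) and `M` (the `incidence_matrix`).
#' @examples
#' d_anchor <- matrix(rnorm(80), 10, 8,
#'                    dimnames = list(paste0("a", 1:10), paste0("S", 1:8)))
#' d_bg <- matrix(rnorm(160), 20, 8,
#'                dimnames = list(paste0("b", 1:20), paste0("S", 1:8)))
#' hn <- hypernetwork(d_anchor, d_bg, k = 1.5)
#' hn
#' @export
hypernetwork <- function(anchor, background, k = 1.5) {
  R <- correlation_matrix(anchor, background)
  Minc <- dichotomize(R, k)
  H <- adjacency(Minc)
  H$R <- R
  H$M <- Minc
  H
}

#' @export
print.hypernetwork <- function(x, ...) {
  cat(sprintf("<hypernetwork: %d nodes, threshold k = %s>\n",
              x$N, format(x$threshold_k)))
  off <- x$sM[upper.tri(x$sM)]
  if (length(off))
    cat(sprintf("  shared edges per pair: mean %.2f, max %d; mean degree %.2f\n",
                mean(off), max(off), mean(diag(x$sM))))
  invisible(x)
}

#' @export
summary.hypernetwork <- function(object, ...) {
  off <- object$sM[upper.tri(object$sM)]
  out <- list(N = object$N, threshold_k = object$threshold_k,
              degree = summary(diag(object$sM)),
              shared_edges = summary(off),
              chi2_mean_element = chi2_signal(object, "mean_element")$chi2)
  class(out) <- "summary.hypernetwork"
  out
}

#' @export
print.summary.hypernetwork <- function(x, ...) {
  cat(sprintf("Hypernetwork on %d nodes (k = %s)\n", x$N,
              format(x$threshold_k)))
  cat("Node degree:\n"); print(x$degree)
  cat("Shared edges (off-diagonal):\n"); print(x$shared_edges)
  cat(sprintf("Chi-squared signal (mean-element mode): %.1f\n",
              x$chi2_mean_element))
  invisible(x)
}

#' Heat-map of the shared-edge matrix
#'
#' @param x A `hypernetwork`.
#' @param cluster Reorder nodes by hierarchical clustering (default TRUE).
#' @param ... Passed to [pheatmap::pheatmap()] when available, else to
#'   [graphics::image()].
#' @export
plot.hypernetwork <- function(x, cluster = TRUE, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(x$sM, cluster_rows = cluster, cluster_cols = cluster,
                       show_rownames = x$N <= 60, show_colnames = FALSE, ...)
  } else {
    ord <- if (cluster) stats::hclust(stats::dist(x$sM))$order else seq_len(x$N)
    graphics::image(x$sM[ord, rev(ord)], axes = FALSE, ...)
  }
  invisible(x)
}

#' Chi-squared signal of a hypernetwork
#'
#' Measures how far the shared-edge matrix departs from a flat expectation:
#' `chi2 = sum over elements of (m_i - m_e)^2 / m_e`, summed over all N^2
#' elements of sM. Two conventions for the expected element value m_e are
#' available: `"mean_element"` divides the total number of shared
#' correlations by N^2 (a per-element expectation, the default) and
#' `"literal"` divides by N (the matrix order).
#'
#' @param H A `hypernetwork` (or plain square matrix).
#' @param mode `"mean_element"` or `"literal"`.
#' @return List of class `chi2_window`: `chi2`, `m_e`, `mode`, `threshold_k`.
#' @export
chi2_signal <- function(H, mode = c("mean_element", "literal")) {
  mode <- match.arg(mode)
  sM <- if (inherits(H, "hypernetwork")) H$sM else H
  stopifnot(is.matrix(sM), nrow(sM) == ncol(sM))
  total <- sum(sM)
  if (total == 0) stop("all-zero sM: no signal")
  N <- nrow(sM)
  m_e <- if (mode == "mean_element") total / N^2 else total / N
  structure(list(chi2 = sum((sM - m_e)^2 / m_e), m_e = m_e, mode = mode,
                 threshold_k = if (inherits(H, "hypernetwork"))
                   H$threshold_k else NA_real_),
            class = "chi2_window")
}

#' Select the dichotomization threshold by chi-squared signal window
#'
#' Evaluates the chi-squared signal over a grid of sd multipliers and
#' returns the grid value maximizing it (ties broken toward the smallest
#' k). Grid points where the incidence or shared-edge matrix degenerates
#' (all zero) are skipped.
#'
#' @param R A [correlation_matrix()].
#' @param k_grid Numeric vector of candidate sd multipliers.
#' @param mode Passed to [chi2_signal()].
#' @return List with `sweep` (data.frame k, chi2, m_e) and `best_k`.
#' @export
threshold_sweep <- function(R, k_grid = seq(0.5, 3, by = 0.25),
                            mode = "mean_element") {
  stopifnot(length(k_grid) > 0)
  k_grid <- sort(k_grid)
  chi2 <- vapply(k_grid, function(k) {
    tryCatch(chi2_signal(adjacency(dichotomize(R, k)), mode)$chi2,
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(chi2))) stop("all grid points degenerate")
  best_k <- k_grid[which.max(chi2)]   # which.max: first max, grid sorted
  list(sweep = data.frame(k = k_grid, chi2 = chi2), best_k = best_k)
}

#' Extract the central (most connected) cluster of a hypernetwork
#'
#' Hierarchically clusters the rows of sM (Euclidean distance; complete
#' linkage by default), scans cut heights k in `n_cluster_range`, and among
#' candidate clusters of at least `min_size` members returns the one with
#' the largest excess connectivity: the sum over intra-cluster pairs of the
#' shared-edge count above the overall off-diagonal mean of sM. This
#' modularity-style score favors the full coherent block -- the "red
#' square" of a clustered hypernetwork heat map -- over a small
#' extra-tight core within it, while still guaranteeing that the winning
#' cluster's mean connectivity exceeds the overall mean. If no candidate
#' exceeds the overall mean there is no central cluster and an error is
#' raised.
#'
#' @param H A `hypernetwork`.
#' @param n_cluster_range Integer cut counts to scan (default 2:10).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param min_size Minimum cluster size (default `max(5, ceiling(0.02 * N))`).
#' @return List of class `cluster_result`: `members` (feature IDs),
#'   `connectivity` (mean intra-cluster off-diagonal sM), `excess`
#'   (the selection score), `overall_connectivity`, `cut_k`, `linkage`,
#'   `min_size`.
#' @export
central_cluster <- function(H, n_cluster_range = 2:10, linkage = "complete",
                            min_size = NULL) {
  stopifnot(inherits(H, "hypernetwork"))
  sM <- H$sM
  N <- H$N
  if (N < 4) stop("need at least 4 nodes to cluster")
  if (is.null(min_size)) min_size <- max(5, ceiling(0.02 * N))
  overall <- mean(sM[upper.tri(sM)])
  hc <- stats::hclust(stats::dist(sM), method = linkage)
  best <- NULL
  for (k in n_cluster_range) {
    if (k > N) next
    cut <- stats::cutree(hc, k = k)
    for (cl in sort(unique(cut))) {
      idx <- which(cut == cl)
      if (length(idx) < min_size) next
      sub <- sM[idx, idx]
      conn <- mean(sub[upper.tri(sub)])
      if (conn <= overall) next
      excess <- sum(sub[upper.tri(sub)] - overall)
      if (is.null(best) || excess > best$excess + 1e-9 ||
          (abs(excess - best$excess) <= 1e-9 &&
           length(idx) > length(best$idx))) {
        best <- list(idx = idx, connectivity = conn, excess = excess,
                     cut_k = k)
      }
    }
  }
  if (is.null(best))
    stop("no cluster of size >= ", min_size,
         " exceeds the overall mean connectivity")
  structure(list(members = sort(H$node_ids[best$idx]),
                 connectivity = best$connectivity, excess = best$excess,
                 overall_connectivity = overall,
                 cut_k = best$cut_k, linkage = linkage, min_size = min_size),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<central cluster: %d members (cut k = %d, %s linkage); mean shared edges %.2f vs overall %.2f>\n",
              length(x$members), x$cut_k, x$linkage, x$connectivity,
              x$overall_connectivity))
  invisible(x)
}

#' Dissimilarity robustness filter
#'
#' Rebuilds the hypernetwork from the complement of the incidence matrix
#' (M' = 1 - M), extracts the central cluster of the resulting
#' dissimilarity shared-edge matrix by the same procedure, and eliminates
#' from `cluster` any member that is also central in the dissimilarity
#' network -- purging elements whose similarity is not stable. When the
#' complement network is degenerate (no off-diagonal variation in sM')
#' there is nothing to eliminate.
#'
#' @param Minc The `incidence_matrix` the hypernetwork was built from (or a
#'   `hypernetwork` carrying one).
#' @param cluster A [central_cluster()] result (or plain ID vector).
#' @param ... Passed to [central_cluster()] (cut range, linkage, min_size).
#' @return List of class `robust_result`: `robust` (retained IDs),
#'   `eliminated`, `dissimilarity_cluster`.
#' @export
dissimilarity_robust <- function(Minc, cluster, ...) {
  if (inherits(Minc, "hypernetwork")) Minc <- Minc$M
  M <- if (inherits(Minc, "incidence_matrix")) Minc$M else Minc
  members <- if (inherits(cluster, "cluster_result")) cluster$members
             else as.character(cluster)
  stopifnot(length(members) > 0)
  Mc <- 1L - M
  Hd <- adjacency(Mc)
  off <- Hd$sM[upper.tri(Hd$sM)]
  dis_members <- character()
  if (length(off) && max(off) > min(off)) {
    dis <- tryCatch(central_cluster(Hd, ...), error = function(e) NULL)
    if (!is.null(dis)) dis_members <- dis$members
  }
  structure(list(robust = setdiff(members, dis_members),
                 eliminated = intersect(members, dis_members),
                 dissimilarity_cluster = dis_members),
            class = "robust_result")
}

#' @export
print.robust_result <- function(x, ...) {
  cat(sprintf("<robustness filter: %d retained, %d eliminated>\n",
              length(x$robust), length(x$eliminated)))
  invisible(x)
}

#' Overlap accounting between feature sets
#'
#' All intersection cardinalities (Venn counts) of the given sets, plus
#' per-set sizes: used to compare the anchor-layer clusters obtained
#' against each background layer.
#'
#' @param clusters Named list of character vectors.
#' @return List with `sizes` (named integer vector) and `overlaps`
#'   (data.frame: sets, n) covering every combination of 2+ sets.
#' @export
layer_overlap <- function(clusters) {
  stopifnot(is.list(clusters), length(clusters) >= 1,
            !is.null(names(clusters)))
  sizes <- vapply(clusters, function(s) length(unique(s)), integer(1))
  nm <- names(clusters)
  combos <- list()
  for (k in 2:max(2, length(nm))) {
    if (k > length(nm)) break
    cc <- utils::combn(nm, k, simplify = FALSE)
    combos <- c(combos, cc)
  }
  overlaps <- do.call(rbind, lapply(combos, function(cc) {
    data.frame(sets = paste(cc, collapse = "&"),
               n = length(Reduce(intersect, clusters[cc])),
               stringsAsFactors = FALSE)
  }))
  list(sizes = sizes, overlaps = overlaps)
}

#' Eigenvector centrality ranking of hypernetwork nodes
#'
#' Principal-eigenvector centrality of the shared-edge matrix with
#' self-loops (the diagonal) removed; scores are scaled to a maximum of 1
#' and nodes ranked in descending order, with ties broken by node ID.
#'
#' @param H A `hypernetwork`.
#' @return data.frame (node_id, score, rank) in rank order.
#' @export
centrality_rank <- function(H) {
  stopifnot(inherits(H, "hypernetwork"))
  A <- H$sM
  diag(A) <- 0L
  if (all(A == 0)) stop("no off-diagonal shared edges: centrality undefined")
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- abs(v)                      # Perron vector of a nonnegative matrix
  score <- v / max(v)
  ids <- H$node_ids
  ord <- order(-round(score, 9), ids)
  data.frame(node_id = ids[ord], score = score[ord],
             rank = seq_along(ids), row.names = NULL,
             stringsAsFactors = FALSE)
}
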