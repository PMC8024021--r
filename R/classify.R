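#' PLS-DA latent-projection separation
#'
#' Fits a partial least squares discriminant analysis (via
#' [mixOmics::plsda()], features standardized) and reports the sample
#' scores on the latent components, the per-component explained variance,
#' and whether the two classes are linearly separable in score space
#' (checked exactly by disjointness of the class convex hulls on the first
#' two components).
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Factor (or coercible) with exactly two levels.
#' @param n_components Number of latent components (default 2).
#' @return List of class `plsda_result`: `scores` (samples x components),
#'   `explained_variance`, `perfectly_separated`.
#' @export
plsda_separation <- function(features, labels, n_components = 2) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  stopifnot(nrow(features) == length(labels),
            n_components <= min(dim(features)))
  fit <- mixOmics::plsda(X = features, Y = labels, ncomp = n_components,
                         scale = TRUE)
  scores <- fit$variates$X
  sc2 <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
  sep <- linearly_separable(sc2[labels == levels(labels)[1], , drop = FALSE],
                            sc2[labels == levels(labels)[2], , drop = FALSE])
  structure(list(scores = scores,
                 explained_variance = fit$prop_expl_var$X,
                 perfectly_separated = sep),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("<plsda: %d components, expl. var %s; %s>\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = " / "),
              if (x$perfectly_separated) "classes perfectly separated"
              else "classes overlap"))
  invisible(x)
}

# Exact 1-2D linear separability via the separating-axis test: two convex
# hulls are disjoint iff the point projections separate along some axis;
# for point sets in the plane it suffices to test hull-edge normals plus
# all pairwise difference directions (covers degenerate collinear hulls).
linearly_separable <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  if (ncol(A) == 1) return(max(A) < min(B) || max(B) < min(A))
  axes <- rbind(edge_normals(A), edge_normals(B),
                pair_axes(A, B))
  for (i in seq_len(nrow(axes))) {
    ax <- axes[i, ]
    if (all(ax == 0)) next
    pa <- A %*% ax; pb <- B %*% ax
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
  }
  FALSE
}

edge_normals <- function(P) {
  h <- grDevices::chull(P)
  if (length(h) < 2) return(matrix(0, 0, 2))
  e <- P[c(h, h[1]), , drop = FALSE]
  d <- diff(e)
  cbind(-d[, 2], d[, 1])
}

pair_axes <- function(A, B) {
  ax <- matrix(0, nrow(A) * nrow(B), 2)
  k <- 1
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    v <- B[j, ] - A[i, ]
    ax[k, ] <- v; k <- k + 1
  }
  ax
}

# Rank-based AUC of scores against a binary truth (equivalent to the
# trapezoid rule over unique thresholds, ties handled by midranks).
auc_from_scores <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Random forest with out-of-bag AUC
#'
#' Fits a bootstrap-per-tree random forest and reports the area under the
#' ROC curve computed from the out-of-bag class-vote fractions (each tree
#' is built on roughly 63% of the samples; the rest are its out-of-bag
#' internal validation set), together with the out-of-bag majority-vote
#' error rate.
#'
#' @param features Numeric matrix or data.frame, samples x features.
#' @param labels Two-level factor (or coercible).
#' @param n_trees Number of trees (default 5000, the convention for stable
#'   out-of-bag estimates at small n; reducible for speed).
#' @param seed Integer seed for the forest's bootstrap draws.
#' @return List of class `classifier_report`: `oob_auc`, `oob_error_rate`,
#'   `n_trees`, `seed`, `votes` (per-sample OOB vote fraction for the
#'   second class level).
#' @export
rf_oob_auc <- function(features, labels, n_trees = 5000, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = labels, ntree = n_trees)
  pos <- levels(labels)[2]
  votes <- rf$votes[, pos]
  structure(list(oob_auc = auc_from_scores(votes, labels == pos),
                 oob_error_rate = unname(rf$err.rate[n_trees, "OOB"]),
                 n_trees = n_trees, seed = seed, votes = votes),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<random forest (%d trees): OOB AUC %.3f, OOB error %.3f%s>\n",
              x$n_trees, x$oob_auc, x$oob_error_rate,
              if (!is.null(x$coverage))
                sprintf(", gene-set coverage %.0f%%", 100 * x$coverage)
              else ""))
  invisible(x)
}

#' Shadow-permutation feature selection
#'
#' Selects features whose forest importance repeatedly beats modeled
#' background noise. Each iteration pairs every real feature with a shadow
#' copy (its values permuted across samples), trains a random forest on
#' real + shadow features, and scores a "hit" for every real feature whose
#' permutation importance exceeds the best shadow importance. After
#' `n_iterations`, a two-sided binomial test against hit probability 0.5 at
#' level `alpha` classifies each feature as confirmed (significantly more
#' hits), rejected (significantly fewer), or tentative. Confirmed and
#' tentative features are the ones carried into classification.
#'
#' @param features Numeric matrix, samples x features (named columns).
#' @param labels Two-level factor.
#' @param n_iterations Number of forest iterations (default 100).
#' @param n_trees Trees per forest (default 500).
#' @param alpha Two-sided binomial decision level (default 0.01).
#' @param seed Integer seed.
#' @return List of class `feature_selection`: `status` (named factor in
#'   confirmed/tentative/rejected), `hits`, `n_iterations`,
#'   `importance_history` (iterations x features),
#'   `shadow_max` (per-iteration max shadow importance), `selected`
#'   (confirmed + tentative feature names).
#' @export
shadow_select <- function(features, labels, n_iterations = 100,
                          n_trees = 500, alpha = 0.01, seed = NULL) {
  labels <- as.factor(labels)
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(features)
  n <- nrow(features)
  hits <- integer(p)
  imp_hist <- matrix(NA_real_, n_iterations, p,
                     dimnames = list(NULL, colnames(features)))
  shadow_max <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    shadow <- apply(features, 2, sample)
    colnames(shadow) <- paste0(".shadow.", colnames(features))
    rf <- randomForest::randomForest(x = cbind(features, shadow), y = labels,
                                     ntree = n_trees, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    real_imp <- imp[colnames(features)]
    smax <- max(imp[colnames(shadow)])
    hits <- hits + (real_imp > smax)
    imp_hist[it, ] <- real_imp
    shadow_max[it] <- smax
  }
  p_hi <- stats::pbinom(hits - 1, n_iterations, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, n_iterations, 0.5)
  status <- factor(ifelse(p_hi < alpha / 2, "confirmed",
                   ifelse(p_lo < alpha / 2, "rejected", "tentative")),
                   levels = c("confirmed", "tentative", "rejected"))
  names(status) <- colnames(features)
  structure(list(status = status,
                 hits = stats::setNames(hits, colnames(features)),
                 n_iterations = n_iterations,
                 importance_history = imp_hist, shadow_max = shadow_max,
                 selected = colnames(features)[status != "rejected"]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  tb <- table(x$status)
  cat(sprintf("<shadow selection (%d iterations): %d confirmed, %d tentative, %d rejected>\n",
              x$n_iterations, tb[["confirmed"]], tb[["tentative"]],
              tb[["rejected"]]))
  invisible(x)
}

#' Cross-tissue direction-consistency filter
#'
#' Retains candidate features whose log2 fold change has the same nonzero
#' sign in two differential expression result sets; optionally additionally
#' requires FDR significance in both (the stricter criterion used to nail
#' down a final gene panel).
#'
#' @param diffA,diffB `diff_result` data.frames (see [paired_t_test()]).
#'   Feature IDs are matched after stripping the layer prefix up to the
#'   first underscore when the literal IDs do not overlap, so that the same
#'   gene measured in two tissues can be compared.
#' @param candidates Character vector of feature IDs (in `diffA`'s naming).
#' @param require_significant Also require `q < alpha` in both sets.
#' @param alpha FDR level for the significance requirement (default 0.05).
#' @return Character vector: the retained subset of `candidates`.
#' @export
direction_consistent <- function(diffA, diffB, candidates,
                                 require_significant = FALSE, alpha = 0.05) {
  keyA <- diffA$feature_id
  keyB <- diffB$feature_id
  candA <- candidates
  if (!any(candidates %in% keyB)) {
    strip <- function(x) sub("^[^_]*_", "", x)
    keyA <- strip(keyA); keyB <- strip(keyB); candA <- strip(candidates)
  }
  ia <- match(candA, keyA)
  ib <- match(candA, keyB)
  missing <- candidates[is.na(ia) | is.na(ib)]
  if (length(missing))
    stop("candidate(s) missing from a result set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  keep <- diffA$direction[ia] == diffB$direction[ib] &
    diffA$direction[ia] != 0
  if (require_significant)
    keep <- keep & diffA$q[ia] < alpha & diffB$q[ib] < alpha
  candidates[keep]
}

#' Validate a gene set on an external labeled expression matrix
#'
#' Restricts the matrix to the gene-set columns present and reports the
#' out-of-bag forest performance of the set, with the coverage fraction.
#'
#' @param geneset Character vector of feature names.
#' @param features Numeric matrix, samples x features (named columns).
#' @param labels Two-level factor.
#' @param n_trees,seed Passed to [rf_oob_auc()].
#' @return A `classifier_report` with an extra `coverage` field.
#' @export
external_validate <- function(geneset, features, labels, n_trees = 5000,
                              seed = NULL) {
  present <- intersect(geneset, colnames(features))
  if (length(present) == 0) stop("no gene-set feature present in the matrix")
  coverage <- length(present) / length(unique(geneset))
  if (coverage < 0.5)
    stop(sprintf("only %.0f%% of the gene set present (need >= 50%%)",
                 100 * coverage))
  rep <- rf_oob_auc(features[, present, drop = FALSE], labels,
                    n_trees = n_trees, seed = seed)
  rep$coverage <- coverage
  rep
}
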