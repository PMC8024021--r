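#' Interquartile-range filter
#'
#' Retains the `ceiling(keep_fraction * n)` features with the largest
#' interquartile range, preserving the original feature order -- the usual
#' variance filter applied to metabolomic layers before integration.
#'
#' @param layer An [omic_layer()].
#' @param keep_fraction Proportion of features to keep, in `(0, 1]`.
#' @return The filtered `omic_layer`.
#' @export
iqr_filter <- function(layer, keep_fraction) {
  stopifnot(inherits(layer, "omic_layer"),
            keep_fraction > 0, keep_fraction <= 1)
  n <- nrow(layer$values)
  if (n == 0L) stop("empty layer")
  keep_n <- ceiling(keep_fraction * n)
  iqr <- apply(layer$values, 1, stats::IQR)
  keep <- sort(order(iqr, decreasing = TRUE)[seq_len(keep_n)])
  omic_layer(layer$values[keep, , drop = FALSE], layer$layer_name)
}

#' Sample-median normalization
#'
#' Divides each sample column by its median so that every column median
#' equals 1; intended for raw (positive) metabolite intensities.
#'
#' @inheritParams iqr_filter
#' @export
median_normalize <- function(layer) {
  stopifnot(inherits(layer, "omic_layer"))
  med <- apply(layer$values, 2, stats::median)
  if (any(med == 0))
    stop("zero sample median in: ",
         paste(colnames(layer$values)[med == 0], collapse = ", "))
  omic_layer(sweep(layer$values, 2, med, "/"), layer$layer_name)
}

#' Element-wise log2 transform
#'
#' @inheritParams iqr_filter
#' @export
log_transform <- function(layer) {
  stopifnot(inherits(layer, "omic_layer"))
  bad <- which(layer$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at feature '%s', sample '%s'",
                 rownames(layer$values)[bad[1, 1]],
                 colnames(layer$values)[bad[1, 2]]))
  omic_layer(log2(layer$values), layer$layer_name)
}

#' Per-feature standardization (mean 0, sd 1)
#'
#' Centers each feature row to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator). Constant rows cannot be scaled and are
#' dropped with a warning.
#'
#' @inheritParams iqr_filter
#' @export
scale_mean_center <- function(layer) {
  stopifnot(inherits(layer, "omic_layer"))
  s <- apply(layer$values, 1, stats::sd)
  if (any(s == 0)) {
    warning("dropping ", sum(s == 0), " constant feature(s): ",
            paste(utils::head(rownames(layer$values)[s == 0], 5),
                  collapse = ", "))
    layer <- omic_layer(layer$values[s > 0, , drop = FALSE], layer$layer_name)
    s <- s[s > 0]
  }
  v <- sweep(layer$values, 1, rowMeans(layer$values), "-")
  omic_layer(sweep(v, 1, s, "/"), layer$layer_name)
}

#' Per-subject paired differences
#'
#' Collapses a layer to one column per subject holding the within-subject
#' difference exposure minus withdrawal (the +1/-1 sign convention). This
#' difference matrix is the space in which all downstream correlations and
#' paired tests are computed: it removes subject-level intercepts, which is
#' the point of the crossover design. Subjects missing either condition are
#' dropped with a message.
#'
#' @param layer An [omic_layer()].
#' @param design A [paired_design()] resolving the layer's samples.
#' @return Numeric matrix, features x complete subjects.
#' @export
paired_difference <- function(layer, design) {
  stopifnot(inherits(layer, "omic_layer"), inherits(design, "paired_design"))
  samp <- intersect(colnames(layer$values), design$samples$sample_id)
  sub <- design$subject_of[samp]
  cond <- design$condition_of[samp]
  complete <- intersect(
    unique(sub[cond == "exposure"]), unique(sub[cond == "withdrawal"]))
  complete <- design$subjects[design$subjects %in% complete]
  dropped <- setdiff(unique(sub), complete)
  if (length(dropped))
    message("paired_difference: dropping subject(s) without both conditions: ",
            paste(dropped, collapse = ", "))
  if (length(complete) == 0L)
    stop("no subject has a complete exposure/withdrawal pair")
  exp_col <- samp[match(complete, ifelse(cond == "exposure", sub, NA))]
  wd_col  <- samp[match(complete, ifelse(cond == "withdrawal", sub, NA))]
  d <- layer$values[, exp_col, drop = FALSE] -
       layer$values[, wd_col, drop = FALSE]
  colnames(d) <- complete
  d
}
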