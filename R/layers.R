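#' Construct a single 'omic layer
#'
#' An `omic_layer` holds one feature-by-sample numeric matrix together with
#' its layer name. Feature and sample identifiers live in the matrix
#' dimnames and must be unique.
#'
#' @param values Numeric matrix, features as rows, samples as columns, with
#'   both dimnames set.
#' @param layer_name Character scalar naming the layer (e.g. `"pbmc"`,
#'   `"mirna"`, `"metabolome"`).
#' @return An object of class `omic_layer`.
#' @export
omic_layer <- function(values, layer_name) {
  stopifnot(is.matrix(values), is.numeric(values))
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("layer matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs in layer '", layer_name, "'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in layer '", layer_name, "'")
  structure(list(layer_name = as.character(layer_name), values = values),
            class = "omic_layer")
}

#' @export
print.omic_layer <- function(x, ...) {
  cat(sprintf("<omic_layer '%s': %d features x %d samples>\n",
              x$layer_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omic_layer <- function(x) dim(x$values)

feature_ids <- function(layer) rownames(layer$values)
sample_ids  <- function(layer) colnames(layer$values)

#' Construct a paired crossover design
#'
#' Maps each sample to a subject and one of two conditions so that
#' per-subject paired differences (exposure minus withdrawal, the +1/-1
#' sign convention) can be formed.
#'
#' @param sample_id,subject_id Character vectors of equal length.
#' @param condition Character vector in `c("exposure", "withdrawal")`.
#' @return An object of class `paired_design` with fields `samples`
#'   (a data.frame), `subjects`, `condition_of`, `subject_of`.
#' @export
paired_design <- function(sample_id, subject_id, condition) {
  condition <- match.arg(condition, c("exposure", "withdrawal"),
                         several.ok = TRUE)
  stopifnot(length(sample_id) == length(subject_id),
            length(sample_id) == length(condition))
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in design")
  samples <- data.frame(sample_id = as.character(sample_id),
                        subject_id = as.character(subject_id),
                        condition = condition,
                        stringsAsFactors = FALSE)
  structure(list(
    samples = samples,
    subjects = unique(samples$subject_id),
    condition_of = stats::setNames(samples$condition, samples$sample_id),
    subject_of = stats::setNames(samples$subject_id, samples$sample_id)
  ), class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design: %d subjects, %d samples (%s)>\n",
              length(x$subjects), nrow(x$samples),
              paste(names(table(x$samples$condition)), collapse = "/")))
  invisible(x)
}

#' Read / write layer matrices and sample sheets
#'
#' Layers are stored as TSV with features as rows and a header row of
#' sample IDs; sample sheets as CSV with columns
#' `sample_id, subject_id, condition, layer`.
#'
#' @param path File path.
#' @param layer_name Layer name to attach on read.
#' @name layer_io
NULL

#' @rdname layer_io
#' @param layer An `omic_layer`.
#' @export
write_layer_tsv <- function(layer, path) {
  df <- data.frame(feature_id = feature_ids(layer), layer$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname layer_io
#' @export
read_layer_tsv <- function(path, layer_name) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omic_layer(m, layer_name)
}

#' @rdname layer_io
#' @param design A `paired_design`.
#' @param layers Character vector of layer names the samples belong to
#'   (recycled), written to the sheet's `layer` column.
#' @export
write_sample_sheet <- function(design, path, layers = "all") {
  sheets <- lapply(layers, function(l)
    cbind(design$samples, layer = l, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, sheets), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname layer_io
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- unique(df[, c("sample_id", "subject_id", "condition")])
  paired_design(df$sample_id, df$subject_id, df$condition)
}
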