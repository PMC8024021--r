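#' Configuration for a synthetic paired crossover multi-omic study
#'
#' The generator emulates a two-period crossover in which every subject is
#' measured under both conditions (exposure and withdrawal) across several
#' 'omic layers. A configurable subset of features per layer carries a
#' planted paired condition effect, and a subset of those additionally loads
#' on one or more cross-layer latent factors that induce correlated
#' per-subject responses -- the structure the hypernetwork stage is designed
#' to recover.
#'
#' All data are generated directly on the log2 scale. `noise_sd` is the
#' standard deviation of a feature's per-subject paired difference, so a
#' responsive feature's standardized paired effect equals `effect_size`
#' exactly. Latent-factor members split that noise into
#' `latent_loading * z_s + sqrt(1 - latent_loading^2) * eps`, where `z_s` is
#' the subject's factor score: the correlation between two members of the
#' same factor is therefore `latent_loading^2`, and between a member and
#' the factor `latent_loading`.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param layer_dims Named integer vector: features per layer. The defaults
#'   are a desk-scale stand-in for the study-sized layers (two transcriptomes
#'   of 28,869 probes, 252 miRNAs, 164 metabolites).
#' @param n_responsive Named integer vector: condition-responsive features
#'   per layer. Defaults to study-like fractions of `layer_dims`
#'   (about 15\%, 12\%, 5\% and 23\% for the transcriptome, second
#'   transcriptome, miRNA and metabolite layers).
#' @param effect_size Standardized mean paired difference of responsive
#'   features, in units of `noise_sd` (default 1.0).
#' @param n_latent Number of cross-layer latent factors (default 1).
#' @param latent_loading Loading in `[0, 1]` of factor members on their
#'   factor (default 0.8).
#' @param latent_members Named integer vector: factor members per layer per
#'   factor; members are drawn from the responsive features. Defaults to
#'   half of `n_responsive` split across factors.
#' @param noise_sd Standard deviation (log2 scale) of the per-subject paired
#'   difference (default 1.0).
#' @param subject_sd Standard deviation of per-feature subject random
#'   intercepts shared by a subject's two samples (default 0.5); this is the
#'   between-subject variation the paired design removes.
#' @param baseline_mean,baseline_sd Per-feature baseline abundance
#'   distribution on the log2 scale (defaults 7 and 1).
#' @param dropout_subject Optional subject index whose withdrawal sample is
#'   omitted, leaving an incomplete pair (emulates a study in which only
#'   nine of ten subjects have matching samples).
#' @param seed Integer seed; identical config + seed reproduces bit-identical
#'   matrices.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       layer_dims = c(pbmc = 2000, adipose = 2000,
                                      mirna = 252, metabolome = 164),
                       n_responsive = NULL,
                       effect_size = 1.0,
                       n_latent = 1,
                       latent_loading = 0.8,
                       latent_members = NULL,
                       noise_sd = 1.0,
                       subject_sd = 0.5,
                       baseline_mean = 7,
                       baseline_sd = 1,
                       dropout_subject = NULL,
                       seed = NULL) {
  if (is.null(names(layer_dims)) || anyDuplicated(names(layer_dims)))
    stop("layer_dims must have unique layer names")
  layers <- names(layer_dims)
  if (is.null(n_responsive)) {
    frac <- c(0.153, 0.122, 0.048, 0.232)   # study-like DE fractions
    frac <- rep_len(frac, length(layers))
    n_responsive <- stats::setNames(round(frac * layer_dims), layers)
  }
  if (!all(layers %in% names(n_responsive)))
    stop("n_responsive must name every layer in layer_dims")
  n_responsive <- n_responsive[layers]
  if (any(n_responsive > layer_dims))
    stop("n_responsive exceeds layer_dims for layer(s): ",
         paste(layers[n_responsive > layer_dims], collapse = ", "))
  if (latent_loading < 0 || latent_loading > 1)
    stop("latent_loading must be in [0, 1]")
  if (is.null(latent_members))
    latent_members <- stats::setNames(
      pmax(0L, floor(n_responsive / (2 * max(1, n_latent)))), layers)
  latent_members <- latent_members[layers]
  if (any(n_latent * latent_members > n_responsive))
    stop("latent members (over all factors) must fit inside the responsive set")
  if (!is.null(dropout_subject) &&
      (dropout_subject < 1 || dropout_subject > n_subjects))
    stop("dropout_subject out of range")
  structure(list(n_subjects = as.integer(n_subjects),
                 layer_dims = layer_dims, n_responsive = n_responsive,
                 effect_size = effect_size, n_latent = as.integer(n_latent),
                 latent_loading = latent_loading,
                 latent_members = latent_members,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 dropout_subject = dropout_subject, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic paired crossover multi-omic study
#'
#' @param config A [sim_config()].
#' @return A list with components `study` (named list of [omic_layer()]s),
#'   `design` (a [paired_design()]) and `truth` (ground-truth labels:
#'   `responsive`, a per-layer list of feature IDs; `factor_members`, one
#'   data.frame of (layer, feature_id) per factor; `effect_signs`, a named
#'   vector of +1/-1 over all responsive features).
#' @seealso [generate_null_study()], [write_study()]
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  samp_exp <- paste0(subjects, "_exposure")
  samp_wd  <- paste0(subjects, "_withdrawal")

  # per-subject factor scores shared by every layer
  z <- matrix(stats::rnorm(config$n_latent * n), config$n_latent, n)

  study <- list()
  responsive <- list()
  factor_members <- lapply(seq_len(max(config$n_latent, 0)),
                           function(i) data.frame(layer = character(),
                                                  feature_id = character()))
  effect_signs <- numeric()

  for (layer in names(config$layer_dims)) {
    p <- config$layer_dims[[layer]]
    fid <- sprintf("%s_f%05d", layer, seq_len(p))
    mu <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)

    n_resp <- config$n_responsive[[layer]]
    resp_idx <- sort(sample.int(p, n_resp))
    signs <- sample(c(-1, 1), n_resp, replace = TRUE)
    delta <- numeric(p)
    delta[resp_idx] <- signs * config$effect_size * config$noise_sd

    # disjoint latent-member sets drawn from the responsive features
    n_mem <- config$latent_members[[layer]]
    mem_pool <- resp_idx
    mem_of_factor <- vector("list", config$n_latent)
    for (f in seq_len(config$n_latent)) {
      take <- if (length(mem_pool) && n_mem > 0)
        sort(sample(mem_pool, min(n_mem, length(mem_pool)))) else integer()
      mem_of_factor[[f]] <- take
      mem_pool <- setdiff(mem_pool, take)
    }

    b <- matrix(stats::rnorm(p * n, 0, config$subject_sd), p, n)
    E <- matrix(stats::rnorm(p * n), p, n)
    lam <- config$latent_loading
    for (f in seq_len(config$n_latent)) {
      rows <- mem_of_factor[[f]]
      if (length(rows))
        E[rows, ] <- lam * matrix(z[f, ], length(rows), n, byrow = TRUE) +
          sqrt(1 - lam^2) * E[rows, , drop = FALSE]
    }
    d <- delta + config$noise_sd * E        # paired differences, p x n

    vals <- cbind(mu + b + d / 2, mu + b - d / 2)
    dimnames(vals) <- list(fid, c(samp_exp, samp_wd))
    study[[layer]] <- omic_layer(vals, layer)

    responsive[[layer]] <- fid[resp_idx]
    effect_signs <- c(effect_signs, stats::setNames(signs, fid[resp_idx]))
    for (f in seq_len(config$n_latent))
      if (length(mem_of_factor[[f]]))
        factor_members[[f]] <- rbind(
          factor_members[[f]],
          data.frame(layer = layer, feature_id = fid[mem_of_factor[[f]]],
                     stringsAsFactors = FALSE))
  }

  design <- paired_design(c(samp_exp, samp_wd),
                          c(subjects, subjects),
                          rep(c("exposure", "withdrawal"), each = n))
  if (!is.null(config$dropout_subject)) {
    drop_samp <- samp_wd[config$dropout_subject]
    study <- lapply(study, function(l)
      omic_layer(l$values[, setdiff(colnames(l$values), drop_samp),
                          drop = FALSE], l$layer_name))
    keep <- design$samples$sample_id != drop_samp
    design <- paired_design(design$samples$sample_id[keep],
                            design$samples$subject_id[keep],
                            design$samples$condition[keep])
  }

  truth <- structure(list(responsive = responsive,
                          factor_members = factor_members,
                          effect_signs = effect_signs),
                     class = "synthetic_truth")
  list(study = study, design = design, truth = truth)
}

#' Generate a global-null study (no effects, no latent structure)
#'
#' Same sampling scheme as [generate_study()] with all condition effects and
#' latent loadings forced to zero; the returned truth sets are empty.
#'
#' @inheritParams generate_study
#' @export
generate_null_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_responsive[] <- 0L
  config$latent_members[] <- 0L
  config$effect_size <- 0
  config$latent_loading <- 0
  generate_study(config)
}

#' Persist a synthetic study to disk
#'
#' Layers as TSV (features x samples), sample sheet as CSV
#' (`sample_id, subject_id, condition, layer`), ground truth as JSON.
#'
#' @param sim Result of [generate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(sim$study))
    write_layer_tsv(sim$study[[layer]],
                    file.path(dir, paste0(layer, ".tsv")))
  write_sample_sheet(sim$design, file.path(dir, "samples.csv"),
                     layers = names(sim$study))
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
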