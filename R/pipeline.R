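#' Configuration of an end-to-end run
#'
#' Defaults follow the method's standard operating point: `k = 30`
#' effective neighbours, embedding dimension 80, 2000 gradient-descent
#' iterations at base learning rate 200 with momentum 0.5 switching to 0.9,
#' and the annealing schedule of [anneal_schedule()].
#'
#' @param view_files Character vector of view file paths (or `NULL` when
#'   `synth` is given).
#' @param synth A [synth_spec()] generating the input instead of files.
#' @param labels_file Optional labels file path (id, label).
#' @param delimiter Delimiter of the view files.
#' @param k_features Per-view feature counts for variance ranking (`NULL`
#'   keeps all features; `NA` entries use `fraction`).
#' @param fraction Fraction for `NA` entries of `k_features`.
#' @param normalize Normalization mode (`"zscore"`, `"minmax"`, `"none"`).
#' @param k Effective number of nearest neighbours.
#' @param d_emb Embedding dimension.
#' @param iterations Gradient-descent iterations.
#' @param eta Base learning rate.
#' @param momentum_initial,momentum_final,momentum_switch Momentum schedule.
#' @param combiner `"conflation"` (default), `"avgprob"` or `"avgdata"`.
#' @param renormalize Row renormalization inside the conflation.
#' @param initializer `"sae"` (stacked denoising autoencoder) or `"pca"`.
#' @param sae An [sae_config()]; its `d_emb` and `seed` are overridden by
#'   this configuration.
#' @param schedule An [anneal_schedule()]; its `seed` is overridden.
#' @param selection Archive selection strategy, `"best_pbm"` or
#'   `"supervised_nmi"`.
#' @param seed Master seed; stage seeds are derived at fixed offsets so
#'   stages can be re-run in isolation.
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(view_files = NULL, synth = NULL, labels_file = NULL,
                       delimiter = "\t", k_features = NULL, fraction = 0.23,
                       normalize = "zscore", k = 30, d_emb = 80,
                       iterations = 2000, eta = 200,
                       momentum_initial = 0.5, momentum_final = 0.9,
                       momentum_switch = 250,
                       combiner = c("conflation", "avgprob", "avgdata"),
                       renormalize = TRUE,
                       initializer = c("sae", "pca"),
                       sae = sae_config(), schedule = anneal_schedule(),
                       selection = c("best_pbm", "supervised_nmi"),
                       seed = 1L, output_dir = NULL, verbose = FALSE) {
  combiner <- match.arg(combiner)
  initializer <- match.arg(initializer)
  selection <- match.arg(selection)
  if (is.null(view_files) && is.null(synth)) {
    stop("provide view_files or a synth spec")
  }
  sae$d_emb <- d_emb
  sae$seed <- as.integer(seed) + 1L
  schedule$seed <- as.integer(seed) + 2L
  structure(list(view_files = view_files, synth = synth,
                 labels_file = labels_file, delimiter = delimiter,
                 k_features = k_features, fraction = fraction,
                 normalize = normalize, k = k, d_emb = d_emb,
                 iterations = iterations, eta = eta,
                 momentum_initial = momentum_initial,
                 momentum_final = momentum_final,
                 momentum_switch = momentum_switch,
                 combiner = combiner, renormalize = renormalize,
                 initializer = initializer, sae = sae,
                 schedule = schedule, selection = selection,
                 seed = as.integer(seed), output_dir = output_dir,
                 verbose = verbose),
            class = "run_config")
}

.log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[mvembed] ", ...)
}

#' Build the unified probability distribution of a dataset
#'
#' Runs the per-view affinity stage (entropy-calibrated Gaussian rows over
#' present samples) and the configured combiner; the incomplete conflation
#' path is taken automatically when any sample is absent from any view.
#'
#' @param ds An `mv_dataset`.
#' @param k Effective neighbour count.
#' @param combiner `"conflation"`, `"avgprob"` or `"avgdata"`.
#' @param renormalize Conflation row renormalization.
#' @return A list: `P` (the `unified_prob`), `view_probs`.
#' @export
unified_distribution <- function(ds, k = 30,
                                 combiner = c("conflation", "avgprob",
                                              "avgdata"),
                                 renormalize = TRUE) {
  combiner <- match.arg(combiner)
  m <- length(ds$views)
  complete <- all(ds$presence)
  if (combiner == "avgdata") {
    P <- average_data(ds$views, k = k,
                      presence = if (complete) NULL else ds$presence)
    return(list(P = P, view_probs = NULL))
  }
  vps <- lapply(seq_len(m), function(v) {
    view_probabilities(ds$views[[v]], k = min(k, sum(ds$presence[, v]) - 1L),
                       present = ds$presence[, v])
  })
  P <- if (combiner == "avgprob") {
    average_probabilities(vps, presence = ds$presence)
  } else if (complete) {
    conflate_views_complete(vps, renormalize = renormalize)
  } else {
    conflate_views_incomplete(vps, ds$presence, renormalize = renormalize)
  }
  list(P = P, view_probs = vps)
}

#' Run the full multi-view embedding and clustering pipeline
#'
#' Stages: load or generate the views, preprocess (variance ranking +
#' normalization), per-view affinities, combiner (conflation by default),
#' initial embedding (autoencoder or PCA), KL-divergence optimization,
#' multi-objective annealing, archive selection, and external metrics when
#' ground-truth labels are available.
#'
#' @param config A [run_config()].
#' @return Object of class `run_result`: `dataset`, `P`, `Y_init`,
#'   `embedding` (an `embedding_state`), `archive`, `solution`, `metrics`
#'   (or `NULL`), `summary` (named numeric vector), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .log_stage(config, "stage: data")
  if (!is.null(config$synth)) {
    gen <- synth_multiview(config$synth)
    ds <- gen$dataset
  } else {
    raw <- lapply(config$view_files, read_view,
                  delimiter = config$delimiter)
    labels <- if (!is.null(config$labels_file)) {
      read_labels(config$labels_file, config$delimiter)
    }
    ds <- align_views(raw, labels = labels)
    ds <- preprocess_views(ds, k_features = config$k_features,
                           fraction = config$fraction,
                           mode = config$normalize)
  }

  .log_stage(config, "stage: affinity + combiner (", config$combiner, ")")
  ud <- unified_distribution(ds, k = config$k, combiner = config$combiner,
                             renormalize = config$renormalize)

  .log_stage(config, "stage: initial embedding (", config$initializer, ")")
  X <- concatenate_views(ds)
  if (config$initializer == "sae") {
    init <- build_and_finetune(X, config$sae)
    Y_init <- init$Y_init
  } else {
    Y_init <- pca_initial_embedding(X, config$d_emb)
  }

  .log_stage(config, "stage: embedding optimization")
  emb <- optimize_embedding(ud$P, Y_init,
                            iterations = config$iterations,
                            eta = config$eta,
                            momentum_initial = config$momentum_initial,
                            momentum_final = config$momentum_final,
                            momentum_switch = config$momentum_switch)

  .log_stage(config, "stage: annealed clustering")
  archive <- amosa_anneal(emb$Y, schedule = config$schedule)
  solution <- select_solution(archive, strategy = config$selection,
                              labels = ds$labels)

  metrics <- NULL
  if (!is.null(ds$labels)) {
    fa <- mapped_f1_accuracy(ds$labels, solution$labels)
    metrics <- c(nmi = nmi(ds$labels, solution$labels),
                 ari = ari(ds$labels, solution$labels),
                 fa)
  }
  summary <- c(n = nrow(emb$Y), K = solution$K,
               xb = solution$objectives[["xb"]],
               pbm = solution$objectives[["pbm"]],
               kl_final = utils::tail(emb$cost_trace, 1),
               metrics)
  res <- structure(list(dataset = ds, P = ud$P, Y_init = Y_init,
                        embedding = emb, archive = archive,
                        solution = solution, metrics = metrics,
                        summary = summary, config = config),
                   class = "run_result")
  if (!is.null(config$output_dir)) .write_artifacts(res, config$output_dir)
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat("run_result (", x$config$combiner, " / ", x$config$selection,
      ")\n", sep = "")
  s <- x$summary
  for (nm in names(s)) {
    cat(sprintf("  %-9s %s\n", nm, format(s[[nm]], digits = 5)))
  }
  invisible(x)
}

.write_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- res$dataset$sample_ids
  write_view(res$embedding$Y, file.path(dir, "embedding.tsv"),
             sample_ids = ids)
  write_view(res$Y_init, file.path(dir, "embedding_init.tsv"),
             sample_ids = ids)
  utils::write.table(
    data.frame(iteration = seq_along(res$embedding$cost_trace),
               kl = res$embedding$cost_trace),
    file.path(dir, "cost_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  arch <- do.call(rbind, lapply(res$archive$solutions, function(s) {
    data.frame(K = s$K, xb = s$objectives[["xb"]],
               pbm = s$objectives[["pbm"]])
  }))
  hit <- which(vapply(res$archive$solutions, function(s) {
    identical(s$centers, res$solution$centers)
  }, logical(1)))[1L]
  arch$chosen <- seq_len(nrow(arch)) == hit
  utils::write.table(arch, file.path(dir, "archive.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = ids, cluster = res$solution$labels),
    file.path(dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(as.list(res$summary),
                         file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
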