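#' Build a peptide bioactivity predictor end to end
#'
#' Runs the whole development life-cycle from a set of known positive
#' peptides: negative sampling from a tagged database (length-matched,
#' overlapping bioactivities excluded), similarity-graph construction,
#' homology-based (or random) train/test partitioning, stratified
#' cross-validation folding, representation, per-algorithm hyperparameter
#' optimization, ensemble fitting and held-out evaluation. Every stage's
#' parameters and seeds are recorded so a build is reproducible.
#'
#' @param positives a peptide tibble of known positives.
#' @param db a tagged peptide database for negative sampling; optional when
#'   `negatives` is supplied directly.
#' @param negatives optional pre-made negative peptide tibble.
#' @param excluded_tags bioactivities excluded from the negative pool.
#' @param identity an [identity_params()] object.
#' @param partition `"ccpart"` (homology-based, default) or `"random"`.
#' @param test_fraction held-out fraction (default 0.2).
#' @param k cross-validation folds (default 10).
#' @param backend embedding backend (default [backend_onehot()]).
#' @param algorithms subset of `c("knn", "gbm", "rfc")`.
#' @param budget HPO trials per algorithm (default 100).
#' @param hpo_method `"smbo"` or `"random"`.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional directory; when given, the model bundle, split,
#'   report (JSON + markdown) and a JSONL build log are written there.
#' @param verbose emit per-stage progress messages (default `TRUE`).
#' @return an object of class `peptide_build`: list with `dataset`,
#'   `graph`, `split`, `hpo`, `ensemble`, `report`, `config`.
#' @export
build_model <- function(positives, db = NULL, negatives = NULL,
                        excluded_tags = character(),
                        identity = identity_params(),
                        partition = c("ccpart", "random"),
                        test_fraction = 0.2, k = 10,
                        backend = backend_onehot(),
                        algorithms = c("knn", "gbm", "rfc"),
                        budget = 100, hpo_method = "smbo", seed = 1L,
                        out_dir = NULL, verbose = TRUE) {
  partition <- match.arg(partition)
  if (is.null(db) && is.null(negatives)) {
    abort(paste0("Provide either a tagged database (`db`) or a ",
                 "`negatives` set before any compute."))
  }
  say <- function(stage, msg) {
    if (verbose) inform(sprintf("[%s] %s", stage, msg))
  }
  log <- list()
  stamp <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage, time = Sys.time()),
                                 list(...))
  }

  positives <- validate_peptides(positives)
  say("negatives", if (is.null(negatives)) {
    "sampling length-matched negatives from the tagged database"
  } else {
    "using the supplied negatives"
  })
  if (is.null(negatives)) {
    negatives <- sample_negatives(db, positives,
                                  excluded_tags = excluded_tags,
                                  seed = derive_seed(seed, "negatives"))
  }
  dataset <- assemble_binary_dataset(positives, negatives)
  stamp("negatives", n_pos = nrow(positives), n_neg = nrow(negatives))

  say("similarity", sprintf("building identity graph over %d peptides",
                            nrow(dataset)))
  graph <- similarity_graph(dataset, identity)
  stamp("similarity", n_edges = nrow(graph$edges))

  say("partition", paste0(partition, " split at test fraction ",
                          test_fraction))
  split <- if (partition == "ccpart") {
    ccpart(graph, dataset, test_fraction = test_fraction, k = k,
           tie_seed = derive_seed(seed, "partition"))
  } else {
    random_partition(dataset, test_fraction = test_fraction, k = k,
                     seed = derive_seed(seed, "partition"))
  }
  stamp("partition", n_train = length(split$train_ids),
        n_test = length(split$test_ids))

  say("represent", paste0("embedding with backend ", backend$name))
  train_data <- dataset[dataset$id %in% split$train_ids, , drop = FALSE]
  emb <- pep_embed(train_data, backend)
  labels <- setNames(dataset$label, dataset$id)
  stamp("represent", backend = backend$name, dim = backend$dim)

  hpo <- list()
  for (algo in algorithms) {
    say("hpo", sprintf("optimizing %s (%d trials)", algo, budget))
    hpo[[algo]] <- optimize_algorithm(
      emb, labels, split$folds, algo, budget = budget,
      seed = derive_seed(seed, paste0("hpo_", algo)), method = hpo_method)
    stamp("hpo", algorithm = algo, best_score = hpo[[algo]]$best_score)
  }

  say("ensemble", sprintf("fitting %d x %d members", length(algorithms), k))
  ensemble <- fit_ensemble(emb, labels, split$folds,
                           lapply(hpo, `[[`, "best_config"),
                           seed = derive_seed(seed, "ensemble"))
  stamp("ensemble", n_members = length(ensemble$members))

  say("evaluate", "scoring the held-out test set")
  test_data <- dataset[dataset$id %in% split$test_ids, , drop = FALSE]
  report <- evaluate_split(ensemble, test_data, backend = backend,
                           graph = graph)
  if (partition == "random") {
    report$guidance <- c(report$guidance,
                         "Partitioning was random: no homology correction was applied; expect optimistic estimates for novel sequences.")
  }
  stamp("evaluate", mcc = report$metrics$mcc)

  config <- list(partition = partition, test_fraction = test_fraction,
                 k = k, backend = backend$name,
                 algorithms = algorithms, budget = budget,
                 hpo_method = hpo_method, seed = seed,
                 threshold = identity$threshold,
                 excluded_tags = excluded_tags)
  build <- structure(
    list(dataset = dataset, graph = graph, split = split, hpo = hpo,
         ensemble = ensemble, report = report, config = config),
    class = "peptide_build")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(ensemble, file.path(out_dir, "bundle"))
    write_split(split, file.path(out_dir, "split.json"))
    render_report(report, file.path(out_dir, "report.json"), "json")
    render_report(report, file.path(out_dir, "report.md"), "markdown")
    writeLines(vapply(log, function(e) {
      jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)
    }, ""), file.path(out_dir, "build_log.jsonl"))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  build
}

#' @export
print.peptide_build <- function(x, ...) {
  cat("<peptide_build>\n")
  print(x$split)
  print(x$ensemble)
  print(x$report)
  invisible(x)
}

#' @rdname tidy_peptideml
#' @export
glance.peptide_build <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$report),
    tibble(n_members = length(x$ensemble$members),
           partition = x$config$partition, backend = x$config$backend)
  )
}

#' Rank peptides by predicted bioactivity
#'
#' Prediction mode: scores peptides with a trained ensemble (or a bundle
#' directory) and returns them sorted by descending score with a
#' member-dispersion uncertainty per peptide.
#'
#' @param peptides a peptide tibble (or FASTA/CSV path readable by
#'   [read_fasta()] / [read_peptide_csv()]).
#' @param model a `peptide_ensemble` or a bundle directory path.
#' @param backend the embedding backend matching the model.
#' @param path optional CSV output path (columns id, sequence, score,
#'   uncertainty, descending score).
#' @return a tibble sorted by descending `score`.
#' @export
predict_peptides <- function(peptides, model, backend = backend_onehot(),
                             path = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(peptides)) {
    peptides <- if (grepl("\\.(fa|fasta|faa)$", peptides, ignore.case = TRUE)) {
      read_fasta(peptides, dedupe = FALSE)
    } else {
      read_peptide_csv(peptides, dedupe = FALSE)
    }
  }
  peptides <- validate_peptides(peptides)
  if (!nrow(peptides)) {
    warn("No input peptides; returning an empty ranking.")
    out <- tibble(id = character(), sequence = character(),
                  score = numeric(), uncertainty = numeric())
  } else {
    emb <- pep_embed(peptides, backend)
    preds <- predict(model, emb)
    out <- dplyr::left_join(preds,
                            peptides[, c("id", "sequence")], by = "id") |>
      select("id", "sequence", "score", "uncertainty") |>
      arrange(dplyr::desc(.data$score))
  }
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Train/test interdependence diagnostics table
#'
#' For a labeled dataset, compares random and homology-based partitioning:
#' per method, the percentage of training peptides with a similar test
#' peptide (interdependence) and the test/train cluster-diversity ratio.
#'
#' @param data a labeled peptide tibble.
#' @param identity an [identity_params()] object.
#' @param test_fraction held-out fraction.
#' @param seed partition seed.
#' @return a tibble with one row per method: `method`,
#'   `interdependence_pct`, `cluster_diversity`, `n_train`, `n_test`.
#' @export
diagnose_dataset <- function(data, identity = identity_params(),
                             test_fraction = 0.2, seed = 1L) {
  data <- validate_peptides(data, require_labels = TRUE)
  graph <- similarity_graph(data, identity)
  clusters <- connected_components(graph)
  splits <- list(
    random = random_partition(data, test_fraction, k = 1, seed = seed),
    ccpart = ccpart(graph, data, test_fraction, k = 1, tie_seed = seed)
  )
  bind_rows(lapply(names(splits), function(m) {
    s <- splits[[m]]
    tibble(method = m,
           interdependence_pct = 100 * interdependence(s, graph),
           cluster_diversity = cluster_diversity(s, clusters),
           n_train = length(s$train_ids), n_test = length(s$test_ids))
  }))
}
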