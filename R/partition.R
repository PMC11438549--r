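#' Connected components of a similarity graph
#'
#' Clusters peptides so that any two peptides in different clusters have no
#' similarity edge between them.
#'
#' @param graph a [similarity_graph()].
#' @return a tibble with columns `id` and `cluster` (integer cluster index,
#'   1-based, ordered by first appearance in the node list).
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(as_igraph(graph))
  tibble(id = names(comp$membership),
         cluster = as.integer(comp$membership))
}

new_split <- function(train_ids, test_ids, folds, method, params,
                      metadata = list()) {
  structure(
    list(train_ids = train_ids, test_ids = test_ids, folds = folds,
         method = method, params = params, metadata = metadata),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split:%s> train %d | test %d | %d folds\n",
              x$method, length(x$train_ids), length(x$test_ids),
              length(unique(x$folds))))
  if (length(x$metadata$warnings)) {
    cat("  warnings:", paste(x$metadata$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname tidy_peptideml
#' @export
tidy.dataset_split <- function(x, ...) {
  bind_rows(
    tibble(id = x$train_ids, set = "train",
           fold = unname(x$folds[x$train_ids])),
    tibble(id = x$test_ids, set = "test", fold = NA_integer_)
  )
}

#' Homology-based train/test partitioning by connected components
#'
#' Whole similarity clusters are transferred to the test set in ascending
#' size order (ties broken by a seeded shuffle, then by lowest member id)
#' until the test set first reaches `test_fraction` of the peptides. Because
#' no cluster straddles the boundary and clusters have no between-cluster
#' edges, no training peptide has a similar peptide in the test set: the
#' split is leakage-free by construction. Transferring the smallest
#' clusters first also packs many distinct clusters into the test set,
#' keeping it diverse and maximally unlike the training distribution.
#'
#' @param graph a [similarity_graph()] over the labeled dataset.
#' @param labels named vector (by id) of binary labels, or a labeled peptide
#'   tibble.
#' @param test_fraction target fraction of peptides in test (default 0.2).
#' @param k number of stratified cross-validation folds over the training
#'   set (default 10); set `k = 1` to skip folding.
#' @param tie_seed seed for the tie-break among equal-size clusters.
#' @return a `dataset_split`; `metadata$overshoot` records how far the test
#'   set exceeded the target.
#' @export
ccpart <- function(graph, labels = NULL, test_fraction = 0.2, k = 10,
                   tie_seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).")
  }
  unsupervised <- is.null(labels)
  if (unsupervised) {
    labels <- setNames(rep(NA_integer_, length(graph$nodes)), graph$nodes)
    k <- 1L
  } else {
    labels <- as_label_vector(labels)
  }
  comp <- connected_components(graph)
  n <- nrow(comp)
  target <- test_fraction * n

  sizes <- comp |> count(.data$cluster, name = "size")
  if (n - max(sizes$size) < target && max(sizes$size) > (1 - test_fraction) * n) {
    abort(paste0(
      "No valid split: one similarity cluster holds ", max(sizes$size),
      " of ", n, " peptides, leaving fewer than the requested ",
      round(target), " test peptides outside it. Lower the identity ",
      "threshold's strictness or the test fraction."))
  }

  first_id <- comp |> group_by(.data$cluster) |>
    summarise(first = min(.data$id), .groups = "drop")
  ord <- sizes |> left_join(first_id, by = "cluster")
  shuffle <- local({
    set.seed(tie_seed %% 2147483647)
    sample(nrow(ord))
  })
  ord <- ord[order(ord$size, shuffle, ord$first), , drop = FALSE]

  test_clusters <- integer()
  test_n <- 0
  for (i in seq_len(nrow(ord))) {
    if (test_n >= target) break
    test_clusters <- c(test_clusters, ord$cluster[i])
    test_n <- test_n + ord$size[i]
  }
  test_ids <- comp$id[comp$cluster %in% test_clusters]
  train_ids <- setdiff(comp$id, test_ids)

  warnings <- character()
  if (!unsupervised) {
    train_labs <- labels[train_ids]
    if (length(unique(train_labs[!is.na(train_labs)])) < 2) {
      abort("Homology partition left a single class in the training set.")
    }
    test_labs <- labels[test_ids]
    if (length(unique(test_labs[!is.na(test_labs)])) < 2) {
      warnings <- c(warnings,
                    "test set contains a single class; evaluation is degenerate")
    }
    folds <- stratified_kfold(train_ids, labels, k = k,
                              seed = derive_seed(tie_seed, "folds"))
  } else {
    folds <- setNames(rep(1L, length(train_ids)), train_ids)
  }
  new_split(
    train_ids, test_ids, folds, "ccpart",
    params = list(test_fraction = test_fraction, k = k, tie_seed = tie_seed,
                  threshold = graph$params$threshold),
    metadata = list(overshoot = length(test_ids) - ceiling(target),
                    n_test_clusters = length(test_clusters),
                    warnings = warnings)
  )
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    labels <- validate_peptides(labels, require_labels = TRUE)
    return(setNames(labels$label, labels$id))
  }
  if (is.null(names(labels))) abort("`labels` must be named by peptide id.")
  labels
}

#' Random train/test partitioning
#'
#' Uniform split at the stated fraction; the test count is
#' `round(test_fraction * n)` (round-half-even). Offers no protection
#' against homologous pairs crossing the boundary.
#'
#' @param data a labeled peptide tibble.
#' @inheritParams ccpart
#' @param seed reproducibility seed.
#' @return a `dataset_split`.
#' @export
random_partition <- function(data, test_fraction = 0.2, k = 10, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).")
  }
  data <- validate_peptides(data, require_labels = TRUE)
  labels <- setNames(data$label, data$id)
  n <- nrow(data)
  n_test <- round(test_fraction * n)
  test_ids <- local({
    set.seed(seed %% 2147483647)
    sample(data$id, n_test)
  })
  train_ids <- setdiff(data$id, test_ids)
  folds <- stratified_kfold(train_ids, labels, k = k,
                            seed = derive_seed(seed, "folds"))
  new_split(train_ids, test_ids, folds, "random",
            params = list(test_fraction = test_fraction, k = k, seed = seed),
            metadata = list(overshoot = n_test - ceiling(test_fraction * n)))
}

#' Stratified k-fold assignment
#'
#' Shuffles each class and deals its members round-robin across folds, so
#' per-fold class counts differ from exact proportionality by at most one
#' peptide.
#'
#' @param ids character vector of (training) peptide ids.
#' @param labels named binary label vector covering `ids`.
#' @param k number of folds; must not exceed the minority-class count.
#' @param seed reproducibility seed.
#' @return named integer vector id -> fold (1..k).
#' @export
stratified_kfold <- function(ids, labels, k = 10, seed = 1L) {
  labels <- as_label_vector(labels)
  labs <- labels[ids]
  if (anyNA(labs)) abort("All training peptides need labels for CV folding.")
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1.")
  if (k == 1) return(setNames(rep(1L, length(ids)), ids))
  minority <- min(table(factor(labs, levels = c(0, 1))))
  if (k > minority) {
    abort(paste0("k = ", k, " exceeds the minority class count (", minority,
                 "); folds would lose a class."))
  }
  fold <- integer(length(ids))
  names(fold) <- ids
  set.seed(seed %% 2147483647)
  for (cls in unique(labs)) {
    members <- sample(ids[labs == cls])
    fold[members] <- rep_len(seq_len(k), length(members))
  }
  fold
}

#' Train/test interdependence of a split
#'
#' The fraction of training peptides with at least one similar peptide
#' (an edge in the similarity graph) in the test set. Homology-based
#' partitioning drives this to exactly zero; random splits of clustered
#' data typically do not.
#'
#' @param split a `dataset_split`.
#' @param graph a [similarity_graph()] covering all split ids.
#' @return fraction in \[0, 1\].
#' @export
interdependence <- function(split, graph) {
  all_ids <- c(split$train_ids, split$test_ids)
  if (!all(all_ids %in% graph$nodes)) {
    abort("Similarity graph does not cover all split ids.")
  }
  if (!length(split$train_ids)) abort("Split has an empty training set.")
  e <- graph$edges
  cross_train <- c(e$id_a[e$id_b %in% split$test_ids],
                   e$id_b[e$id_a %in% split$test_ids])
  sum(split$train_ids %in% cross_train) / length(split$train_ids)
}

#' Cluster diversity of a test set
#'
#' Ratio of the number of similarity clusters represented in the test set
#' to the number represented in the training set; a diagnostic that
#' homology partitioning left the test set diverse (around the test
#' fraction for healthy splits).
#'
#' @param split a `dataset_split`.
#' @param clusters a tibble `id`, `cluster` as returned by
#'   [connected_components()].
#' @return non-negative ratio.
#' @export
cluster_diversity <- function(split, clusters) {
  if (!length(split$train_ids)) abort("Split has an empty training set.")
  n_test <- length(unique(clusters$cluster[clusters$id %in% split$test_ids]))
  n_train <- length(unique(clusters$cluster[clusters$id %in% split$train_ids]))
  if (n_train == 0) abort("No clusters intersect the training set.")
  n_test / n_train
}

#' Serialize / restore a dataset split as JSON
#'
#' @param split a `dataset_split`.
#' @param path output path.
#' @return `path` invisibly; `read_split()` returns the `dataset_split`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(train = split$train_ids, test = split$test_ids,
         folds = as.list(split$folds), method = split$method,
         params = split$params, metadata = split$metadata),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- unlist(x$folds)
  new_split(x$train, x$test, setNames(as.integer(folds), names(folds)),
            x$method, x$params, as.list(x$metadata))
}
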