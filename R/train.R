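#' Default hyperparameter search spaces
#'
#' One space per ensemble algorithm. `knn` is a k-nearest-neighbour
#' classifier whose class probability is the (optionally distance-weighted)
#' positive fraction among neighbours; `gbm` is a leaf-wise gradient-boosted
#' tree classifier (xgboost, `grow_policy = "lossguide"`, so its space
#' mirrors the LightGBM-style parameters: number of boosting rounds,
#' learning rate, leaf count, minimum child weight); `rfc` is a probability
#' random forest (ranger).
#'
#' @return named list of search spaces; each space is a list of parameter
#'   specs (`name`, `type` = int/double/choice, bounds or choices, `log`).
#' @export
default_search_spaces <- function() {
  list(
    knn = list(
      list(name = "n_neighbors", type = "int", lower = 1, upper = 30),
      list(name = "weights", type = "choice",
           choices = c("uniform", "distance"))
    ),
    gbm = list(
      list(name = "n_estimators", type = "int", lower = 50, upper = 500),
      list(name = "learning_rate", type = "double", lower = 1e-3,
           upper = 0.3, log = TRUE),
      list(name = "num_leaves", type = "int", lower = 8, upper = 128),
      list(name = "min_child_samples", type = "int", lower = 2, upper = 50)
    ),
    rfc = list(
      list(name = "n_estimators", type = "int", lower = 50, upper = 500),
      list(name = "max_depth", type = "int", lower = 2, upper = 32),
      list(name = "min_samples_leaf", type = "int", lower = 1, upper = 10)
    )
  )
}

sample_config <- function(space) {
  cfg <- lapply(space, function(p) {
    switch(p$type,
      int = as.integer(round(runif(1, p$lower - 0.499, p$upper + 0.499))),
      double = if (isTRUE(p$log)) {
        exp(runif(1, log(p$lower), log(p$upper)))
      } else {
        runif(1, p$lower, p$upper)
      },
      choice = sample(p$choices, 1),
      abort(paste0("Unknown parameter type: ", p$type))
    )
  })
  setNames(cfg, vapply(space, `[[`, "", "name"))
}

encode_config <- function(space, cfg) {
  vapply(space, function(p) {
    v <- cfg[[p$name]]
    if (p$type == "choice") return(match(v, p$choices))
    if (isTRUE(p$log)) log(as.numeric(v)) else as.numeric(v)
  }, 0)
}

fit_member <- function(algo, config, x, y, seed) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  model <- switch(algo,
    knn = list(x = x, y = y,
               k = min(config$n_neighbors, nrow(x)),
               weights = config$weights),
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = config$learning_rate,
                      max_depth = 0, max_leaves = config$num_leaves,
                      grow_policy = "lossguide", tree_method = "hist",
                      min_child_weight = config$min_child_samples,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = config$n_estimators, verbose = 0)
    },
    rfc = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = config$n_estimators, max.depth = config$max_depth,
      min.node.size = config$min_samples_leaf, seed = seed,
      num.threads = 1),
    abort(paste0("Unknown algorithm: ", algo))
  )
  list(algo = algo, config = config, model = model)
}

predict_member <- function(member, x) {
  switch(member$algo,
    knn = {
      m <- member$model
      nn <- FNN::get.knnx(m$x, x, k = m$k)
      if (identical(m$weights, "distance")) {
        w <- 1 / (nn$nn.dist + 1e-8)
        rowSums(w * matrix(m$y[nn$nn.index], nrow(x), m$k)) / rowSums(w)
      } else {
        rowMeans(matrix(m$y[nn$nn.index], nrow(x), m$k))
      }
    },
    gbm = as.numeric(predict(member$model, xgboost::xgb.DMatrix(x))),
    rfc = as.numeric(predict(member$model, data = x,
                             num.threads = 1)$predictions[, "1"])
  )
}

cv_mean_mcc <- function(embedding, labels, folds, algo, config, seed) {
  x <- embed_matrix(embedding)
  ids <- rownames(x)
  scores <- vapply(sort(unique(folds)), function(f) {
    hold <- names(folds)[folds == f]
    keep <- setdiff(names(folds), hold)
    ytr <- labels[keep]
    if (length(unique(ytr)) < 2) {
      abort(paste0("Fold ", f, " leaves a single class in its training part."))
    }
    member <- fit_member(algo, config, x[keep, , drop = FALSE], ytr,
                         seed = seed)
    p <- predict_member(member, x[hold, , drop = FALSE])
    mcc_score(labels[hold], as.integer(p > 0.5))
  }, 0)
  mean(scores)
}

#' Hyperparameter optimization for one algorithm
#'
#' Sequential model-based optimization of the mean cross-validated Matthews
#' correlation coefficient: a trial's objective is the mean over folds of
#' the MCC on the held-out fold after training on the remaining folds. The
#' default `"smbo"` method warms up with random configurations and then
#' proposes candidates by maximizing a random-forest surrogate fitted to
#' the completed trials (with an epsilon-random exploration step); the
#' `"random"` method is pure seeded random search. Both record every trial.
#'
#' @param embedding an embedding tibble from [pep_embed()] restricted to
#'   the training peptides.
#' @param labels named binary label vector covering the embedding ids.
#' @param folds named fold assignment from [stratified_kfold()].
#' @param algo `"knn"`, `"gbm"` or `"rfc"`.
#' @param space a search space (default from [default_search_spaces()]).
#' @param budget number of trials (default 100).
#' @param seed optimizer seed.
#' @param method `"smbo"` or `"random"`.
#' @return an object of class `hpo_result`: `best_config`, `best_score`,
#'   `trace` (tibble with one row per trial: trial, score, parameters).
#' @export
optimize_algorithm <- function(embedding, labels, folds, algo,
                               space = default_search_spaces()[[algo]],
                               budget = 100, seed = 1L,
                               method = c("smbo", "random")) {
  method <- match.arg(method)
  if (length(unique(folds)) < 2) abort("HPO needs at least 2 CV folds.")
  stopifnot(budget >= 1)
  set.seed(seed %% 2147483647)
  n_warm <- if (method == "random") budget else min(budget, max(5, budget %/% 4))

  trials <- list()
  scores <- numeric()
  enc <- list()
  for (t in seq_len(budget)) {
    cfg <- if (t <= n_warm) {
      sample_config(space)
    } else {
      propose_smbo(space, enc, scores)
    }
    sc <- cv_mean_mcc(embedding, labels, folds, algo, cfg,
                      seed = derive_seed(seed, paste0("trial", t)))
    trials[[t]] <- cfg
    scores[t] <- sc
    enc[[t]] <- encode_config(space, cfg)
  }
  best <- which.max(scores)
  trace <- bind_rows(lapply(seq_along(trials), function(t) {
    dplyr::bind_cols(tibble(trial = t, score = scores[t]),
                     as_tibble(lapply(trials[[t]], identity)))
  }))
  structure(list(algo = algo, best_config = trials[[best]],
                 best_score = scores[best], trace = trace,
                 seed = seed, method = method),
            class = "hpo_result")
}

# Surrogate proposal: score a batch of random candidates with a small
# random-forest regression fitted on completed trials; epsilon-greedy
# exploration keeps the search from collapsing onto the incumbent.
propose_smbo <- function(space, enc, scores, n_candidates = 64,
                         epsilon = 0.15) {
  if (runif(1) < epsilon) return(sample_config(space))
  cands <- lapply(seq_len(n_candidates), function(i) sample_config(space))
  xtr <- do.call(rbind, enc)
  colnames(xtr) <- vapply(space, `[[`, "", "name")
  surrogate <- ranger::ranger(
    x = as.data.frame(xtr), y = scores, num.trees = 100,
    seed = floor(runif(1, 1, 2^30)), num.threads = 1)
  xc <- do.call(rbind, lapply(cands, function(c) encode_config(space, c)))
  colnames(xc) <- colnames(xtr)
  pred <- predict(surrogate, data = as.data.frame(xc),
                  num.threads = 1)$predictions
  cands[[which.max(pred)]]
}

#' @export
print.hpo_result <- function(x, ...) {
  cat(sprintf("<hpo_result:%s> best mean-CV MCC %.3f over %d trials (%s)\n",
              x$algo, x$best_score, nrow(x$trace), x$method))
  invisible(x)
}

#' @rdname tidy_peptideml
#' @export
tidy.hpo_result <- function(x, ...) x$trace

#' Fit the cross-validation ensemble
#'
#' For every enabled algorithm and every fold, fits one member on all
#' training folds except that fold, using the algorithm's optimal
#' configuration; the ensemble therefore holds
#' `n_algorithms x n_folds` members (30 under the defaults: 3 x 10).
#'
#' @inheritParams optimize_algorithm
#' @param best_configs named list algorithm -> hyperparameter configuration
#'   (e.g. `$best_config` of [optimize_algorithm()] results).
#' @param seed base seed for member fits.
#' @return an object of class `peptide_ensemble`.
#' @export
fit_ensemble <- function(embedding, labels, folds, best_configs, seed = 1L) {
  x <- embed_matrix(embedding)
  fold_levels <- sort(unique(folds))
  members <- list()
  for (algo in names(best_configs)) {
    for (f in fold_levels) {
      keep <- names(folds)[folds != f]
      if (!length(keep)) abort("A fold spans the whole training set.")
      member <- tryCatch(
        fit_member(algo, best_configs[[algo]], x[keep, , drop = FALSE],
                   labels[keep],
                   seed = derive_seed(seed, paste0(algo, "_fold", f))),
        error = function(e) abort(paste0(
          "Member fit failed (algorithm ", algo, ", fold ", f, "): ",
          conditionMessage(e)))
      )
      member$fold <- f
      members[[length(members) + 1]] <- member
    }
  }
  backend <- attr(embedding, "backend") %||%
    list(name = "unknown", dim = ncol(x))
  structure(
    list(members = members, backend = backend$name, dim = ncol(x),
         algorithms = names(best_configs), folds = folds,
         train_ids = rownames(x), configs = best_configs, seed = seed,
         version = as.character(utils::packageVersion("peptideml"))),
    class = "peptide_ensemble"
  )
}

#' @export
print.peptide_ensemble <- function(x, ...) {
  cat(sprintf(
    "<peptide_ensemble> %d members (%s x %d folds), backend %s (e=%d)\n",
    length(x$members), paste(x$algorithms, collapse = "+"),
    length(unique(x$folds)), x$backend, x$dim))
  invisible(x)
}

#' Predict bioactivity scores with an ensemble
#'
#' The ensemble score of a peptide is the unweighted mean of all member
#' positive-class probabilities (a convex combination, so always within the
#' member range); the uncertainty is the standard deviation of the member
#' scores.
#'
#' @param object a `peptide_ensemble`.
#' @param embedding an embedding tibble of the peptides to score, produced
#'   with the same backend the ensemble was trained on.
#' @param ... unused.
#' @return a tibble `id`, `score`, `uncertainty`.
#' @export
predict.peptide_ensemble <- function(object, embedding, ...) {
  x <- embed_matrix(embedding)
  if (ncol(x) != object$dim) {
    abort(paste0("Embedding dimension ", ncol(x),
                 " does not match the ensemble's expected e = ", object$dim))
  }
  probs <- vapply(object$members, function(m) predict_member(m, x),
                  numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x))
  tibble(id = embedding$id,
         score = rowMeans(probs),
         uncertainty = apply(probs, 1, sd))
}

#' @rdname tidy_peptideml
#' @export
tidy.peptide_ensemble <- function(x, ...) {
  tibble(
    member = seq_along(x$members),
    algorithm = vapply(x$members, `[[`, "", "algo"),
    fold = vapply(x$members, function(m) as.integer(m$fold), 1L)
  )
}

#' @rdname tidy_peptideml
#' @export
glance.peptide_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members),
         n_algorithms = length(x$algorithms),
         n_folds = length(unique(x$folds)),
         n_train = length(x$train_ids),
         backend = x$backend, dim = x$dim)
}

#' Save / load a model bundle
#'
#' A bundle is a directory holding `manifest.json` (package version,
#' backend, dimension, algorithms, configurations, seeds, fold map and
#' training ids) plus one serialized file per ensemble member; it contains
#' everything needed to reproduce the model's predictions. Loading
#' verifies the version stamp and the member inventory and fails loudly on
#' mismatch.
#'
#' @param ensemble a `peptide_ensemble`.
#' @param path bundle directory (created if needed).
#' @return `path` invisibly; `load_model()` returns the `peptide_ensemble`.
#' @export
save_model <- function(ensemble, path) {
  dir.create(file.path(path, "members"), recursive = TRUE,
             showWarnings = FALSE)
  member_files <- sprintf("members/member_%03d.rds",
                          seq_along(ensemble$members))
  manifest <- list(
    format = "peptideml_bundle_v1",
    package_version = ensemble$version,
    backend = ensemble$backend, dim = ensemble$dim,
    algorithms = ensemble$algorithms,
    configs = ensemble$configs, seed = ensemble$seed,
    folds = as.list(ensemble$folds), train_ids = ensemble$train_ids,
    members = lapply(seq_along(ensemble$members), function(i) {
      m <- ensemble$members[[i]]
      list(file = member_files[i], algorithm = m$algo, fold = m$fold)
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[i]], file.path(path, member_files[i]))
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) abort(paste0("Not a model bundle (no manifest): ", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(manifest$format, "peptideml_bundle_v1")) {
    abort(paste0("Unsupported bundle format: ",
                 manifest$format %||% "<missing>",
                 "; this package reads peptideml_bundle_v1."))
  }
  members <- lapply(manifest$members, function(m) {
    f <- file.path(path, m$file)
    if (!file.exists(f)) {
      abort(paste0("Bundle is incomplete: missing member file ", m$file))
    }
    readRDS(f)
  })
  folds <- unlist(manifest$folds)
  structure(
    list(members = members, backend = manifest$backend,
         dim = manifest$dim,
         algorithms = unlist(manifest$algorithms),
         folds = setNames(as.integer(folds), names(folds)),
         train_ids = unlist(manifest$train_ids),
         configs = lapply(manifest$configs, function(c) lapply(c, identity)),
         seed = manifest$seed,
         version = manifest$package_version),
    class = "peptide_ensemble"
  )
}
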