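# Small labeled embedding fixture with a tunable class margin injected
# into two coordinates of the one-hot composition space.
training_fixture <- function(n_per_class = 30, margin = 0.5, seed = 1L,
                             k = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(runif(n * 6), n, 6)
  y <- rep(c(0L, 1L), each = n_per_class)
  x[y == 1, 1] <- x[y == 1, 1] + margin
  x[y == 1, 2] <- x[y == 1, 2] - margin
  ids <- paste0("p", seq_len(n))
  emb <- dplyr::bind_cols(tibble::tibble(id = ids),
                          tibble::as_tibble(as.data.frame(x)))
  attr(emb, "backend") <- list(name = "fixture", dim = 6L)
  labels <- stats::setNames(y, ids)
  folds <- stratified_kfold(ids, labels, k = k, seed = seed)
  list(emb = emb, labels = labels, folds = folds)
}

test_that("every algorithm recovers a wide-margin signal (mean CV MCC >= 0.9)", {
  fx <- training_fixture(n_per_class = 30, margin = 1.5, seed = 3)
  for (algo in c("knn", "gbm", "rfc")) {
    res <- optimize_algorithm(fx$emb, fx$labels, fx$folds, algo,
                              budget = 5, seed = 11, method = "random")
    expect_gte(res$best_score, 0.9)
    expect_equal(nrow(res$trace), 5)
    expect_true(all(c("trial", "score") %in% names(res$trace)))
  }
})

test_that("pure-noise labels give near-zero best CV MCC", {
  fx <- training_fixture(n_per_class = 100, margin = 0, seed = 5, k = 5)
  res <- optimize_algorithm(fx$emb, fx$labels, fx$folds, "knn",
                            budget = 5, seed = 6, method = "random")
  expect_lt(abs(res$best_score), 0.3)
})

test_that("a budget of one returns that single configuration", {
  fx <- training_fixture(seed = 7)
  res <- optimize_algorithm(fx$emb, fx$labels, fx$folds, "rfc",
                            budget = 1, seed = 8)
  expect_equal(nrow(res$trace), 1)
  expect_identical(res$best_config, as.list(res$trace[1, -(1:2)]))
})

test_that("optimization is reproducible under the optimizer seed", {
  fx <- training_fixture(seed = 9)
  r1 <- optimize_algorithm(fx$emb, fx$labels, fx$folds, "gbm",
                           budget = 6, seed = 21, method = "smbo")
  r2 <- optimize_algorithm(fx$emb, fx$labels, fx$folds, "gbm",
                           budget = 6, seed = 21, method = "smbo")
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_config, r2$best_config)
})

test_that("degenerate folds are rejected by name", {
  fx <- training_fixture(n_per_class = 10, seed = 10, k = 2)
  # force a single-class fold
  bad_folds <- fx$folds
  bad_folds[fx$labels[names(bad_folds)] == 1] <- 1L
  bad_folds[fx$labels[names(bad_folds)] == 0] <- 2L
  expect_error(
    optimize_algorithm(fx$emb, fx$labels, bad_folds, "knn", budget = 1,
                       seed = 1),
    "single class")
})

test_that("ensemble cardinality is algorithms x folds", {
  fx <- training_fixture(n_per_class = 20, margin = 1, seed = 12, k = 5)
  cfgs <- list(
    knn = list(n_neighbors = 5L, weights = "uniform"),
    gbm = list(n_estimators = 60L, learning_rate = 0.1, num_leaves = 15L,
               min_child_samples = 5L),
    rfc = list(n_estimators = 80L, max_depth = 8L, min_samples_leaf = 2L)
  )
  ens <- fit_ensemble(fx$emb, fx$labels, fx$folds, cfgs, seed = 2)
  expect_equal(length(ens$members), 3 * 5)
  expect_equal(glance(ens)$n_members, 15L)
  ens1 <- fit_ensemble(fx$emb, fx$labels, fx$folds, cfgs["rfc"], seed = 2)
  expect_equal(length(ens1$members), 5)
  ens2 <- fit_ensemble(fx$emb, fx$labels, fx$folds, cfgs[c("knn", "gbm")],
                       seed = 2)
  expect_equal(length(ens2$members), 10)
})

test_that("ensemble scores are convex combinations of member scores", {
  fx <- training_fixture(n_per_class = 20, margin = 1, seed = 13, k = 4)
  cfgs <- list(knn = list(n_neighbors = 3L, weights = "distance"),
               rfc = list(n_estimators = 60L, max_depth = 6L,
                          min_samples_leaf = 1L))
  ens <- fit_ensemble(fx$emb, fx$labels, fx$folds, cfgs, seed = 3)
  x <- as.matrix(fx$emb[-1]); rownames(x) <- fx$emb$id
  member_scores <- vapply(ens$members,
                          function(m) peptideml:::predict_member(m, x),
                          numeric(nrow(x)))
  preds <- predict(ens, fx$emb)
  expect_true(all(preds$score >= apply(member_scores, 1, min) - 1e-12))
  expect_true(all(preds$score <= apply(member_scores, 1, max) + 1e-12))
  expect_equal(preds$score, rowMeans(member_scores))
  expect_equal(preds$uncertainty, apply(member_scores, 1, sd))
})

test_that("prediction errors on an embedding dimension mismatch", {
  fx <- training_fixture(seed = 14)
  ens <- fit_ensemble(fx$emb, fx$labels, fx$folds,
                      list(knn = list(n_neighbors = 3L,
                                      weights = "uniform")), seed = 1)
  wrong <- tibble::tibble(id = "q", V1 = 1, V2 = 2)
  expect_error(predict(ens, wrong), "e = 6")
})

test_that("bundles round-trip predictions bit-identically", {
  fx <- training_fixture(n_per_class = 15, margin = 1, seed = 15, k = 3)
  cfgs <- list(knn = list(n_neighbors = 5L, weights = "uniform"),
               gbm = list(n_estimators = 50L, learning_rate = 0.1,
                          num_leaves = 15L, min_child_samples = 5L),
               rfc = list(n_estimators = 60L, max_depth = 8L,
                          min_samples_leaf = 2L))
  ens <- fit_ensemble(fx$emb, fx$labels, fx$folds, cfgs, seed = 4)
  dir <- withr::local_tempdir()
  save_model(ens, dir)
  back <- load_model(dir)
  p1 <- predict(ens, fx$emb)
  p2 <- predict(back, fx$emb)
  expect_identical(p1, p2)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(manifest$members, 9)
  # tampering: drop one member file
  file.remove(file.path(dir, manifest$members[[4]]$file))
  expect_error(load_model(dir), "incomplete")
  expect_error(load_model(withr::local_tempdir()), "manifest")
})

test_that("held-out MCC rises with injected signal strength", {
  # 3 signal levels x 3 seeds, small models: monotone on average
  mean_mcc <- vapply(c(0, 0.75, 2), function(margin) {
    mean(vapply(1:3, function(s) {
      fx <- training_fixture(n_per_class = 25, margin = margin,
                             seed = 100 + s, k = 3)
      hold <- names(fx$folds)[fx$folds == 1]
      keep <- setdiff(names(fx$folds), hold)
      emb_tr <- fx$emb[fx$emb$id %in% keep, ]
      attr(emb_tr, "backend") <- attr(fx$emb, "backend")
      folds_tr <- stratified_kfold(keep, fx$labels, k = 2, seed = s)
      ens <- fit_ensemble(emb_tr, fx$labels, folds_tr,
                          list(rfc = list(n_estimators = 100L,
                                          max_depth = 10L,
                                          min_samples_leaf = 1L)),
                          seed = s)
      emb_te <- fx$emb[fx$emb$id %in% hold, ]
      p <- predict(ens, emb_te)
      peptideml:::mcc_score(fx$labels[p$id], as.integer(p$score > 0.5))
    }, 0))
  }, 0)
  expect_true(all(diff(mean_mcc) >= -0.05))
  expect_lt(abs(mean_mcc[1]), 0.35)
  expect_gt(mean_mcc[3], 0.6)
})
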