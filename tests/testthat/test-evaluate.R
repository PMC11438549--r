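test_that("the decision threshold is strict: 0.5 scores are negative", {
  p <- threshold_predictions(c(a = 0.5, b = 0.51, c = 0.0, d = 1.0))
  expect_identical(unname(p), c(0L, 1L, 0L, 1L))
  expect_error(threshold_predictions(c(1.2)), "0, 1")
})

test_that("mcc matches the closed formula and conventions", {
  expect_equal(mcc(tp = 10, tn = 12, fp = 0, fn = 0), 1.0)
  expect_equal(mcc(tp = 3, tn = 2, fp = 1, fn = 0), 6 / sqrt(72))
  # all-positive predictor on balanced data: a zero marginal gives 0
  expect_equal(mcc(tp = 10, tn = 0, fp = 10, fn = 0), 0)
  expect_equal(mcc(tp = 0, tn = 0, fp = 0, fn = 0), 0)
})

test_that("mcc equals the Pearson correlation of 0/1 vectors", {
  set.seed(29)
  for (i in 1:300) {
    n <- sample(4:60, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    cc <- confusion_counts(truth, pred)
    m <- mcc(cc)
    r <- suppressWarnings(cor(truth, pred))
    if (is.na(r)) {
      expect_equal(m, 0)
    } else {
      expect_equal(m, r, tolerance = 1e-12)
    }
  }
})

test_that("mcc is invariant under swapping the class labels", {
  set.seed(31)
  for (i in 1:50) {
    cc <- as.list(sample(0:30, 4, replace = TRUE))
    names(cc) <- c("tp", "tn", "fp", "fn")
    a <- mcc(cc$tp, cc$tn, cc$fp, cc$fn)
    b <- mcc(cc$tn, cc$tp, cc$fn, cc$fp)
    expect_equal(a, b)
    expect_gte(a, -1); expect_lte(a, 1)
  }
})

test_that("evaluation refuses test peptides seen during training", {
  d <- separable_family_dataset(6, 8, seed = 201)
  g <- similarity_graph(d, identity_params(use_prefilter = FALSE))
  sp <- ccpart(g, d, test_fraction = 0.2, k = 3, tie_seed = 2)
  train <- validate_peptides(d[d$id %in% sp$train_ids, ])
  emb <- pep_embed(train, backend_onehot())
  labels <- stats::setNames(d$label, d$id)
  ens <- fit_ensemble(emb, labels, sp$folds,
                      list(knn = list(n_neighbors = 5L,
                                      weights = "uniform")), seed = 1)
  leaky <- validate_peptides(d[d$id %in% c(sp$test_ids,
                                           sp$train_ids[1]), ])
  expect_error(evaluate_split(ens, leaky), "leakage")
})

test_that("separable families under ccpart reach test MCC >= 0.8", {
  # varied family sizes so the smallest-first transfer mixes both classes
  # into the held-out set
  fam <- generate_families(14, members_per_family = c(3, 12),
                           seed_length = c(25, 40), mutation_rate = 0.1,
                           alphabet = setdiff(strsplit(
                             "ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("W", "K")),
                           seed = 220)
  d <- inject_label_signal(fam, motif = "WWKWW", fraction = 1,
                           scatter = TRUE, seed = 221)
  g <- similarity_graph(d, identity_params(use_prefilter = FALSE))
  sp <- ccpart(g, d, test_fraction = 0.2, k = 5, tie_seed = 3)
  # fixture sanity: both classes present in the held-out set
  test_labels <- d$label[d$id %in% sp$test_ids]
  expect_gt(length(unique(test_labels)), 1)
  train <- validate_peptides(d[d$id %in% sp$train_ids, ])
  emb <- pep_embed(train, backend_onehot())
  labels <- stats::setNames(d$label, d$id)
  hpo <- optimize_algorithm(emb, labels, sp$folds, "rfc", budget = 5,
                            seed = 4, method = "random")
  ens <- fit_ensemble(emb, labels, sp$folds,
                      list(rfc = hpo$best_config), seed = 5)
  rep <- evaluate_split(ens, validate_peptides(d[d$id %in% sp$test_ids, ]),
                        backend_onehot(), graph = g)
  expect_gte(rep$metrics$mcc, 0.8)
  expect_equal(rep$interdependence, 0)
})

test_that("label-permuted evaluation stays near chance", {
  set.seed(203)
  mccs <- vapply(1:5, function(s) {
    d <- separable_family_dataset(10, 10, motif_fraction = 1,
                                  seed = 300 + s)
    # permute labels -> no sequence/label association remains
    d$label <- sample(d$label)
    sp <- random_partition(d, 0.2, k = 3, seed = s)
    train <- validate_peptides(d[d$id %in% sp$train_ids, ])
    emb <- pep_embed(train, backend_onehot())
    labels <- stats::setNames(d$label, d$id)
    ens <- fit_ensemble(emb, labels, sp$folds,
                        list(knn = list(n_neighbors = 7L,
                                        weights = "uniform")), seed = s)
    rep <- evaluate_split(ens,
                          validate_peptides(d[d$id %in% sp$test_ids, ]))
    rep$metrics$mcc
  }, 0)
  expect_lt(abs(mean(mccs)), 0.3)
})

test_that("reports render losslessly to JSON and readably to markdown", {
  d <- separable_family_dataset(6, 8, seed = 205)
  sp <- random_partition(d, 0.25, k = 3, seed = 6)
  train <- validate_peptides(d[d$id %in% sp$train_ids, ])
  emb <- pep_embed(train, backend_onehot())
  labels <- stats::setNames(d$label, d$id)
  ens <- fit_ensemble(emb, labels, sp$folds,
                      list(knn = list(n_neighbors = 5L,
                                      weights = "uniform")), seed = 7)
  rep <- evaluate_split(ens, validate_peptides(d[d$id %in% sp$test_ids, ]))
  fj <- withr::local_tempfile(fileext = ".json")
  render_report(rep, fj, "json")
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$metrics$mcc, rep$metrics$mcc)
  expect_equal(back$threshold, 0.5)
  expect_equal(nrow(back$predictions), rep$n_test)
  fm <- withr::local_tempfile(fileext = ".md")
  render_report(rep, fm, "markdown")
  md <- readLines(fm)
  expect_true(any(grepl("MCC", md)))
  expect_true(any(grepl("0.50", md)))
})
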