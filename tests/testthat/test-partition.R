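mk_graph <- function(ids, edges) {
  structure(list(
    nodes = ids,
    edges = tibble::tibble(
      id_a = vapply(edges, `[[`, "", 1),
      id_b = vapply(edges, `[[`, "", 2),
      identity = rep(0.9, length(edges))),
    params = identity_params()), class = "similarity_graph")
}

test_that("connected components partition the node set", {
  g <- mk_graph(c("a", "b", "c", "d"), list(c("a", "b"), c("b", "c")))
  comp <- connected_components(g)
  expect_equal(length(unique(comp$cluster)), 2)
  expect_equal(sort(comp$id), c("a", "b", "c", "d"))
  expect_equal(length(unique(comp$cluster[comp$id %in% c("a", "b", "c")])), 1)

  iso <- mk_graph(letters[1:5], list())
  expect_equal(length(unique(connected_components(iso)$cluster)), 5)
})

test_that("ccpart transfers smallest clusters first until the target", {
  # clusters sized 1, 1, 8 -> the two singletons make the 20% test set
  g <- mk_graph(c(paste0("big", 1:8), "s1", "s2"),
                lapply(1:7, function(i) c(paste0("big", i),
                                          paste0("big", i + 1))))
  sp <- ccpart(g, test_fraction = 0.2, tie_seed = 1)
  expect_setequal(sp$test_ids, c("s1", "s2"))
  # singleton-only graph: 2 of 10 go to test
  iso <- mk_graph(paste0("n", 1:10), list())
  sp2 <- ccpart(iso, test_fraction = 0.2, tie_seed = 3)
  expect_length(sp2$test_ids, 2)
})

test_that("no edge ever crosses a ccpart boundary (zero leakage)", {
  set.seed(77)
  for (i in 1:25) {
    fam <- generate_families(
      n_families = sample(5:14, 1),
      members_per_family = sample(3:9, 1),
      seed_length = c(12, 30),
      mutation_rate = runif(1, 0, 0.25), seed = 700 + i)
    g <- similarity_graph(fam, identity_params(use_prefilter = FALSE))
    sp <- ccpart(g, fam, test_fraction = 0.2, k = 1, tie_seed = i)
    expect_identical(interdependence(sp, g), 0)
    # whole-cluster assignment
    comp <- connected_components(g)
    straddles <- tapply(comp$id %in% sp$test_ids, comp$cluster,
                        function(x) any(x) && !all(x))
    expect_false(any(straddles))
    # smallest-first: largest test cluster <= smallest train cluster
    sizes <- table(comp$cluster)
    test_cl <- unique(comp$cluster[comp$id %in% sp$test_ids])
    if (length(test_cl) && length(test_cl) < length(sizes)) {
      expect_lte(max(sizes[as.character(test_cl)]),
                 min(sizes[setdiff(names(sizes), as.character(test_cl))]))
    }
  }
})

test_that("a dominating cluster makes the split infeasible", {
  g <- mk_graph(paste0("n", 1:10),
                lapply(1:8, function(i) c(paste0("n", i), paste0("n", i + 1))))
  expect_error(ccpart(g, test_fraction = 0.2), "No valid split")
})

test_that("ccpart errors when training would hold a single class", {
  iso <- mk_graph(paste0("n", 1:10), list())
  labs <- stats::setNames(c(rep(1L, 9), 0L), paste0("n", 1:10))
  # only one negative; ccpart cannot guarantee both classes in train when
  # it lands in test -> with all-singleton clusters it must sometimes error
  g2 <- mk_graph(c("a", "b"), list())
  expect_error(
    ccpart(g2, stats::setNames(c(1L, 1L), c("a", "b")), test_fraction = 0.5),
    "single class")
})

test_that("random partition sizes follow round-half-even and reseed identically", {
  d <- separable_family_dataset(4, 5, seed = 81)
  s1 <- random_partition(d, test_fraction = 0.2, k = 2, seed = 5)
  s2 <- random_partition(d, test_fraction = 0.2, k = 2, seed = 5)
  expect_identical(s1$test_ids, s2$test_ids)
  expect_length(s1$test_ids, round(0.2 * nrow(d)))
  d3 <- validate_peptides(d[1:3, ])
  s3 <- random_partition(d3, test_fraction = 0.5, k = 1, seed = 1)
  expect_equal(length(s3$test_ids), round(0.5 * 3))
})

test_that("stratified folds balance classes within one sample", {
  ids <- paste0("p", 1:100)
  labs <- stats::setNames(rep(c(0L, 1L), each = 50), ids)
  folds <- stratified_kfold(ids, labs, k = 10, seed = 2)
  expect_length(folds, 100)
  expect_equal(sort(unique(folds)), 1:10)
  per_fold <- table(folds, labs[names(folds)])
  expect_true(all(per_fold == 5))   # 50/50 at k=10: exactly 5+5 per fold
  # odd counts: within one of proportional
  labs2 <- stats::setNames(c(rep(0L, 47), rep(1L, 53)), ids)
  f2 <- stratified_kfold(ids, labs2, k = 10, seed = 3)
  t2 <- table(f2, labs2[names(f2)])
  expect_true(all(abs(t2[, "0"] - 4.7) <= 1))
  expect_true(all(abs(t2[, "1"] - 5.3) <= 1))
})

test_that("fold count above the minority class is rejected", {
  ids <- paste0("p", 1:12)
  labs <- stats::setNames(c(rep(1L, 10), 0L, 0L), ids)
  expect_error(stratified_kfold(ids, labs, k = 5), "minority")
  expect_equal(unname(stratified_kfold(ids, labs, k = 1)), rep(1L, 12))
})

test_that("interdependence counts train peptides with test neighbours", {
  g <- mk_graph(c("a", "b", "c"), list(c("a", "b")))
  sp <- structure(
    list(train_ids = c("a", "c"), test_ids = "b",
         folds = stats::setNames(c(1L, 1L), c("a", "c")),
         method = "manual", params = list(), metadata = list()),
    class = "dataset_split")
  expect_equal(interdependence(sp, g), 0.5)
  g0 <- mk_graph(c("a", "b", "c"), list())
  expect_equal(interdependence(sp, g0), 0)
})

test_that("cluster diversity is the test/train cluster ratio", {
  clusters <- tibble::tibble(id = paste0("p", 1:20),
                             cluster = rep(1:20, each = 1))
  sp <- structure(list(train_ids = paste0("p", 1:16),
                       test_ids = paste0("p", 17:20),
                       folds = NULL, method = "manual",
                       params = list(), metadata = list()),
                  class = "dataset_split")
  expect_equal(cluster_diversity(sp, clusters), 4 / 16)
  sp$test_ids <- character(); sp$train_ids <- paste0("p", 1:20)
  expect_equal(cluster_diversity(sp, clusters), 0)
})

test_that("splits serialize losslessly to JSON", {
  d <- separable_family_dataset(4, 6, seed = 91)
  sp <- random_partition(d, 0.25, k = 3, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(sp, f)
  back <- read_split(f)
  expect_identical(back$train_ids, sp$train_ids)
  expect_identical(back$test_ids, sp$test_ids)
  expect_identical(back$folds, sp$folds)
  expect_identical(back$method, sp$method)
})
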