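test_that("length histogram bins on half-open multiples of the bin width", {
  mk <- function(lens) {
    peptide_tbl(paste0("p", seq_along(lens)),
                vapply(lens, function(l) strrep("A", l), ""))
  }
  h <- length_histogram(mk(c(6, 7, 12)))
  expect_equal(h$lower, c(5L, 10L))
  expect_equal(h$count, c(2L, 1L))
  h1 <- length_histogram(mk(5))
  expect_equal(h1$lower, 5L)
  expect_equal(h1$count, 1L)
  h2 <- length_histogram(mk(c(4, 5)))
  expect_equal(h2$lower, c(0L, 5L))
  expect_equal(h2$count, c(1L, 1L))
  expect_equal(sum(length_histogram(mk(c(3, 9, 14, 33)))$count), 4L)
})

test_that("exclusion removes any peptide carrying an excluded tag", {
  db <- peptide_tbl(c("p1", "p2", "p3"), c("ACDE", "KLMW", "PQRS"),
                    tags = list("antibacterial", "antiviral",
                                c("antibacterial", "antioxidant")))
  kept <- apply_exclusions(db, "antibacterial")
  expect_equal(kept$id, "p2")          # any-match rule removes p3 too
  expect_equal(apply_exclusions(db, character())$id, db$id)
  expect_warning(apply_exclusions(db, "no_such_tag"), "not present")
})

test_that("sampled negatives match the positives' length histogram exactly", {
  db <- generate_tagged_db(4000, seed = 31)
  pos <- generate_families(8, 8, seed_length = c(8, 40),
                           mutation_rate = 0.1, seed = 32)
  neg <- sample_negatives(db, pos, excluded_tags = "antiviral", seed = 33)
  expect_equal(nrow(neg), nrow(pos))
  expect_equal(attr(neg, "deficit"), 0L)
  expect_equal(length_histogram(neg), length_histogram(pos))
  # exclusion soundness over the whole output
  expect_false(any(vapply(neg$tags, function(t) "antiviral" %in% t, NA)))
  # no sequence collision with the positives
  expect_length(intersect(neg$sequence, pos$sequence), 0)
})

test_that("sampling is deterministic under a seed and uniform within bins", {
  db <- generate_tagged_db(500, seed = 5)
  pos <- peptide_tbl(paste0("p", 1:4),
                     c("ACDEFG", "MKLWYT", "ACDEFGH", "MKLWYTS"))
  n1 <- sample_negatives(db, pos, seed = 11)
  n2 <- sample_negatives(db, pos, seed = 11)
  expect_identical(n1$id, n2$id)
  n3 <- sample_negatives(db, pos, seed = 12)
  expect_false(identical(n1$id, n3$id))
  expect_true(all(nchar(n1$sequence) >= 5 & nchar(n1$sequence) < 10))
})

test_that("per-bin shortfalls spill to the next ascending bin", {
  # 3 positives in [5,10) but only 1 eligible DB peptide there; the other
  # two must come from [10,15)
  db <- peptide_tbl(
    paste0("d", 1:5),
    c("MKLWYTA",                      # length 7 -> bin [5,10)
      "MKLWYTAPQR", "ACDEFGHIKL", "TTTTTTTTTTT", "WYTAPQRSKLMN"),
    tags = rep(list("antioxidant"), 5)
  )
  pos <- peptide_tbl(paste0("p", 1:3), c("ACDEF", "GHIKL", "MNPQRS"))
  neg <- sample_negatives(db, pos, seed = 1)
  expect_equal(nrow(neg), 3)
  expect_equal(sum(nchar(neg$sequence) < 10), 1)
  expect_equal(sum(nchar(neg$sequence) >= 10), 2)
})

test_that("an exhausted database yields a partial result with a deficit", {
  db <- peptide_tbl(c("d1", "d2"), c("MKLWYTA", "ACDEFGHIKL"),
                    tags = rep(list("toxin"), 2))
  pos <- peptide_tbl(paste0("p", 1:4),
                     c("ACDEF", "GHIKL", "MNPQR", "STVWY"))
  expect_warning(neg <- sample_negatives(db, pos, seed = 1), "exhausted")
  expect_equal(nrow(neg), 2)
  expect_equal(attr(neg, "deficit"), 2L)
})

test_that("binary assembly labels classes and resolves id collisions", {
  pos <- peptide_tbl(c("a", "b", "c"), c("ACDE", "KLMW", "PQRS"))
  neg <- peptide_tbl(c("a", "z"), c("GGGG", "TTTT"))
  d <- assemble_binary_dataset(pos, neg)
  expect_equal(nrow(d), 5)
  expect_equal(sum(d$label == 1), 3)
  expect_true("neg_a" %in% d$id)
  expect_true(attr(d, "supervised_ready"))
  empty <- peptide_tbl(character(), character())
  expect_warning(d0 <- assemble_binary_dataset(pos, empty), "unusable")
  expect_false(attr(d0, "supervised_ready"))
})
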