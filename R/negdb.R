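#' Validate a bioactivity-tagged peptide database
#'
#' A tagged database is a peptide tibble in which every peptide carries at
#' least one bioactivity tag. It stands in for large curated collections of
#' bioactive peptides from which presumed-inactive negatives are drawn.
#'
#' @param db a peptide tibble with a non-empty `tags` entry per row.
#' @return the database invisibly, normalized.
#' @export
validate_peptide_db <- function(db) {
  db <- validate_peptides(db)
  n_tags <- lengths(db$tags)
  if (any(n_tags == 0)) {
    abort(paste0(sum(n_tags == 0),
                 " database peptide(s) carry no bioactivity tag."))
  }
  invisible(db)
}

db_tag_vocabulary <- function(db) sort(unique(unlist(db$tags)))

#' Bin peptide lengths into a fixed-width histogram
#'
#' Bins are half-open `[lower, upper)` intervals aligned to multiples of
#' `bin_width` (default 5 residues), starting at the largest multiple not
#' exceeding the shortest peptide. Only occupied and intermediate bins up to
#' the longest peptide are returned, so counts sum to the number of
#' peptides.
#'
#' @param data a peptide tibble (typically the positives).
#' @param bin_width bin width in residues (default 5).
#' @return a tibble with columns `lower`, `upper`, `count`.
#' @examples
#' pos <- peptide_tbl(c("a", "b", "c"),
#'                    c("ACDEFG", "ACDEFGH", "ACDEFGHIKLMW"))
#' length_histogram(pos)   # [5,10): 2, [10,15): 1
#' @export
length_histogram <- function(data, bin_width = 5) {
  data <- validate_peptides(data)
  if (!nrow(data)) abort("Cannot bin an empty dataset.")
  if (bin_width < 1) abort("`bin_width` must be >= 1.")
  len <- nchar(data$sequence)
  lo0 <- (min(len) %/% bin_width) * bin_width
  hi0 <- (max(len) %/% bin_width) * bin_width
  lowers <- seq(lo0, hi0, by = bin_width)
  counts <- vapply(lowers, function(lo) sum(len >= lo & len < lo + bin_width),
                   integer(1))
  tibble(lower = as.integer(lowers),
         upper = as.integer(lowers + bin_width),
         count = counts)
}

#' Remove peptides carrying excluded bioactivity tags
#'
#' A peptide is removed if ANY of its tags is in `excluded_tags` (the
#' any-match rule): a peptide that is, say, both antibacterial and
#' antioxidant may still be a false negative for an antibacterial target.
#' Unknown tags in the policy produce a warning, not an error.
#'
#' @param db a tagged peptide database (see [validate_peptide_db()]).
#' @param excluded_tags character vector of bioactivity tags that overlap
#'   with the activity of interest.
#' @return the filtered database tibble.
#' @export
apply_exclusions <- function(db, excluded_tags) {
  db <- validate_peptide_db(db)
  excluded_tags <- unique(as.character(excluded_tags))
  unknown <- setdiff(excluded_tags, db_tag_vocabulary(db))
  if (length(unknown)) {
    warn(paste0("Exclusion tag(s) not present in the database: ",
                paste(unknown, collapse = ", ")))
  }
  keep <- !vapply(db$tags, function(t) any(t %in% excluded_tags), logical(1))
  db[keep, , drop = FALSE]
}

#' Draw length-matched negative peptides from a tagged database
#'
#' For each bin of the positives' length histogram, draws (uniformly,
#' without replacement) as many database peptides with lengths inside the
#' bin as the bin's count. Shortfalls carry over to the next bin in
#' ascending-length order; any deficit remaining after the last bin is, by
#' default, drawn from the nearest preceding bins. Peptides whose sequence
#' exactly equals a positive are never returned. Remaining deficit is
#' reported in the `deficit` attribute and via a warning.
#'
#' @param db a tagged peptide database.
#' @param positives the positive peptide tibble whose length distribution
#'   is matched.
#' @param excluded_tags bioactivity tags to exclude (see
#'   [apply_exclusions()]).
#' @param seed integer seed making the draw reproducible.
#' @param bin_width histogram bin width in residues (default 5).
#' @param ratio negatives per positive (default 1).
#' @param backfill when bins are exhausted in ascending order, take the
#'   residual deficit from preceding bins (default `TRUE`).
#' @return a peptide tibble of negatives with attributes `deficit` (number
#'   of requested negatives that could not be drawn) and `histogram` (the
#'   target histogram).
#' @export
sample_negatives <- function(db, positives, excluded_tags = character(),
                             seed = 1L, bin_width = 5, ratio = 1,
                             backfill = TRUE) {
  positives <- validate_peptides(positives)
  db <- apply_exclusions(db, excluded_tags)
  db <- db[!db$sequence %in% positives$sequence, , drop = FALSE]
  if (!nrow(db)) abort("No database peptides remain after exclusions.")

  hist <- length_histogram(positives, bin_width = bin_width)
  db_len <- nchar(db$sequence)

  # Bin grid covering both the positives' histogram and the database's
  # length range, so ascending spillover can continue past the last
  # histogram bin and backfill can reach shorter peptides.
  lo <- min(hist$lower, (min(db_len) %/% bin_width) * bin_width)
  hi <- max(hist$lower, (max(db_len) %/% bin_width) * bin_width)
  lowers <- seq(lo, hi, by = bin_width)
  need <- integer(length(lowers))
  need[match(hist$lower, lowers)] <- as.integer(round(hist$count * ratio))
  pools <- lapply(lowers, function(l) {
    which(db_len >= l & db_len < l + bin_width)
  })
  pools <- local({
    set.seed(seed %% 2147483647)
    lapply(pools, function(idx) idx[sample.int(length(idx))])
  })

  taken <- integer(0)
  carry <- 0L
  for (i in seq_along(lowers)) {
    want <- need[i] + carry
    got <- head(pools[[i]], want)
    pools[[i]] <- setdiff(pools[[i]], got)
    taken <- c(taken, got)
    carry <- want - length(got)
  }
  if (carry > 0L && backfill) {
    # walk back through preceding bins' leftover pools, nearest first
    for (i in rev(seq_along(lowers))) {
      if (carry <= 0L) break
      got <- head(pools[[i]], carry)
      pools[[i]] <- setdiff(pools[[i]], got)
      taken <- c(taken, got)
      carry <- carry - length(got)
    }
  }
  if (carry > 0L) {
    warn(paste0("Database exhausted: ", carry,
                " requested negative(s) could not be drawn."))
  }
  out <- db[taken, , drop = FALSE]
  attr(out, "deficit") <- as.integer(carry)
  attr(out, "histogram") <- hist
  out
}

#' Assemble a labeled binary dataset from positives and negatives
#'
#' Positives get label 1 and negatives label 0; a `provenance` column
#' records the origin of each peptide. Negative ids colliding with positive
#' ids are re-prefixed with `"neg_"`.
#'
#' @param positives,negatives peptide tibbles.
#' @return a labeled peptide tibble. When `negatives` is empty the result
#'   carries attribute `supervised_ready = FALSE`.
#' @export
assemble_binary_dataset <- function(positives, negatives) {
  positives <- validate_peptides(positives)
  negatives <- validate_peptides(negatives)
  if (any(negatives$id %in% positives$id)) {
    negatives$id <- paste0("neg_", negatives$id)
  }
  positives$label <- 1L
  negatives$label <- 0L
  positives$provenance <- "positive"
  negatives$provenance <- if (nrow(negatives)) "sampled_negative" else character()
  out <- bind_rows(positives, negatives)
  attr(out, "supervised_ready") <- nrow(negatives) > 0
  if (!nrow(negatives)) {
    warn("No negatives supplied: dataset is unusable for supervised training.")
  }
  out
}
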