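#' Generate synthetic families of homologous peptides
#'
#' Emulates the cluster structure of real bioactivity datasets: each family
#' starts from a random seed sequence and adds mutated copies (substitutions
#' only by default, so within-family identity is analytically boundable;
#' optional indels for alignment stress tests). The true family map is
#' returned in the `family` column, giving ground truth for
#' similarity-graph and partitioning tests.
#'
#' @param n_families number of families.
#' @param members_per_family single number or `c(min, max)` range.
#' @param seed_length `c(min, max)` residue range of family seed sequences
#'   (within the 3-50 peptide range).
#' @param mutation_rate per-residue substitution probability in family
#'   copies (0 = identical copies).
#' @param indel_rate per-residue insertion/deletion probability (default 0).
#' @param alphabet residue alphabet families draw from (default the full
#'   canonical alphabet); restricting it, e.g. away from a motif's
#'   residues, gives [inject_label_signal()] dedicated composition
#'   coordinates.
#' @param disjoint_alphabets give each family its own residue alphabet so
#'   families are mutually dissimilar by construction (requires
#'   `n_families <= 20`; with one residue per family, cross-family identity
#'   is exactly 0).
#' @param labels `"family"` assigns each family a label (alternating, so
#'   both classes exist) or `"none"`.
#' @param seed reproducibility seed.
#' @return a peptide tibble with extra columns `family` (integer) and,
#'   when requested, `label`.
#' @export
generate_families <- function(n_families = 20, members_per_family = 10,
                              seed_length = c(10, 30), mutation_rate = 0.1,
                              indel_rate = 0, alphabet = AA_ALPHABET,
                              disjoint_alphabets = FALSE,
                              labels = c("family", "none"), seed = 1L) {
  labels <- match.arg(labels)
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("`mutation_rate` must be in [0, 1].")
  }
  if (length(members_per_family) == 1) {
    members_per_family <- rep(members_per_family, 2)
  }
  if (length(seed_length) == 1) seed_length <- rep(seed_length, 2)
  alphabet <- unique(strsplit(paste(alphabet, collapse = ""), "")[[1]])
  stopifnot(all(alphabet %in% AA_ALPHABET))
  if (disjoint_alphabets && n_families > length(alphabet)) {
    abort("More families than alphabet letters; disjoint alphabets impossible.")
  }
  set.seed(seed %% 2147483647)
  alphabets <- if (disjoint_alphabets) {
    split(alphabet, cut(seq_along(alphabet), n_families, labels = FALSE))
  } else {
    rep(list(alphabet), n_families)
  }
  rows <- list()
  for (f in seq_len(n_families)) {
    ab <- alphabets[[f]]
    len <- sample_between(seed_length[1], seed_length[2])
    seed_seq <- paste(sample(ab, len, replace = TRUE), collapse = "")
    n_mem <- sample_between(members_per_family[1], members_per_family[2])
    seqs <- c(seed_seq,
              vapply(seq_len(max(0, n_mem - 1)), function(i) {
                mutate_sequence(seed_seq, mutation_rate, indel_rate, ab)
              }, ""))
    rows[[f]] <- tibble(
      id = sprintf("fam%02d_m%02d", f, seq_len(n_mem)),
      sequence = seqs, family = f
    )
  }
  out <- bind_rows(rows)
  out$label <- if (labels == "family") {
    as.integer(out$family %% 2 == 0)
  } else {
    NA_integer_
  }
  out$tags <- rep(list(character()), nrow(out))
  out$desc <- NA_character_
  validate_peptides(out)
  out
}

mutate_sequence <- function(sequence, mutation_rate, indel_rate, alphabet) {
  # single-letter alphabets admit no substitutions
  if (length(alphabet) == 1 && indel_rate == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- runif(length(chars)) < mutation_rate
  if (any(hit) && length(alphabet) > 1) {
    chars[hit] <- vapply(chars[hit], function(c) {
      pool <- setdiff(alphabet, c)
      pool[sample.int(length(pool), 1)]
    }, "")
  }
  if (indel_rate > 0) {
    out <- character()
    for (c in chars) {
      r <- runif(1)
      if (r < indel_rate / 2 && length(chars) > 4) next          # deletion
      out <- c(out, c)
      if (r > 1 - indel_rate / 2) out <- c(out, sample(alphabet, 1))
    }
    chars <- if (length(out)) out else chars
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic bioactivity-tagged peptide database
#'
#' Random peptides with lengths uniform over `length_range` and 1-3 tags
#' drawn from `tags`; with the default density every 5-residue length bin
#' is well populated, which negative sampling relies on.
#'
#' @param n number of database peptides.
#' @param tags tag vocabulary (character vector).
#' @param length_range `c(min, max)` peptide lengths.
#' @param seed reproducibility seed.
#' @return a tagged peptide database tibble (see [validate_peptide_db()]).
#' @export
generate_tagged_db <- function(n = 1000,
                               tags = c("antibacterial", "antiviral",
                                        "antifungal", "antioxidant",
                                        "antihypertensive", "neuropeptide"),
                               length_range = c(5, 50), seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  set.seed(seed %% 2147483647)
  lens <- length_range[1] + sample.int(length_range[2] - length_range[1] + 1,
                                       n, replace = TRUE) - 1L
  seqs <- vapply(lens, function(l) {
    paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
  }, "")
  tag_sets <- lapply(seq_len(n), function(i) {
    sample(tags, sample(1:min(3, length(tags)), 1))
  })
  db <- peptide_tbl(sprintf("db%05d", seq_len(n)), seqs, tags = tag_sets)
  validate_peptide_db(db)
  db
}

#' Inject a learnable composition signal into positive peptides
#'
#' Inserts a short motif into the stated fraction of positive peptides at a
#' random position. Because the motif shifts amino-acid composition, the
#' signal is visible even to the mean-pooled one-hot representation, so
#' downstream models can achieve above-chance MCC; the injected fraction
#' controls the signal strength.
#'
#' @param data a labeled peptide tibble.
#' @param motif motif sequence to insert (canonical residues).
#' @param fraction fraction of positives receiving the motif.
#' @param scatter insert the motif's residues one by one at independent
#'   random positions instead of as one contiguous substring (default
#'   `FALSE`). A scattered motif shifts amino-acid composition identically
#'   but leaves no local-alignment anchor, so it is visible to mean-pooled
#'   representations yet (by design) almost invisible to the
#'   sequence-identity graph - useful when a learnable signal must not
#'   alter the homology structure.
#' @param seed reproducibility seed.
#' @return the dataset with modified sequences.
#' @export
inject_label_signal <- function(data, motif = "WWKWW", fraction = 1.0,
                                scatter = FALSE, seed = 1L) {
  data <- validate_peptides(data)
  motif <- validate_sequence(motif, policy = "coerce")
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  pos_idx <- which(data$label == 1)
  set.seed(seed %% 2147483647)
  n_hit <- round(fraction * length(pos_idx))
  hit <- pos_idx[sample.int(length(pos_idx))[seq_len(n_hit)]]
  insert_at <- function(s, piece) {
    at <- sample(0:nchar(s), 1)
    paste0(substr(s, 0, at), piece, substr(s, at + 1, nchar(s)))
  }
  data$sequence[hit] <- vapply(data$sequence[hit], function(s) {
    if (scatter) {
      for (r in strsplit(motif, "")[[1]]) s <- insert_at(s, r)
      s
    } else {
      insert_at(s, motif)
    }
  }, "")
  data
}

# sample() treats a length-one vector as 1:x; draw bounds explicitly instead
sample_between <- function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1L
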