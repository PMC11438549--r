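#' Construct a peptide table
#'
#' The package's core data structure is an ordinary tibble with one row per
#' peptide and columns `id` (character, unique), `sequence` (character over
#' the canonical 20-letter amino-acid alphabet), `label` (integer 0/1 or
#' `NA`), `tags` (list-column of character vectors of bioactivity tags) and
#' `desc` (free-text description, `NA` when absent). All user-facing
#' functions accept and return this shape so calls chain with the pipe.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param label optional integer/numeric vector of binary labels (0/1).
#' @param tags optional list of character vectors (bioactivity tags) or a
#'   single character vector recycled per peptide.
#' @param desc optional character vector of descriptions.
#' @param validate validate sequences with [validate_sequence()] policy
#'   `"coerce"` (default `TRUE`).
#' @return a peptide tibble.
#' @examples
#' peptide_tbl(c("p1", "p2"), c("ACDE", "KLMW"), label = c(1, 0))
#' @export
peptide_tbl <- function(id, sequence, label = NULL, tags = NULL, desc = NULL,
                        validate = TRUE) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  n <- length(id)
  if (length(sequence) != n) abort("`id` and `sequence` lengths differ.")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(paste0("Duplicate peptide ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (validate) sequence <- vapply(sequence, validate_sequence, "", policy = "coerce")
  if (is.null(label)) {
    label <- rep(NA_integer_, n)
  } else {
    label <- check_binary_label(label)
    if (length(label) != n) abort("`label` length differs from `id`.")
  }
  if (is.null(tags)) {
    tags <- rep(list(character()), n)
  } else if (is.character(tags)) {
    tags <- rep(list(tags), n)
  }
  if (length(tags) != n) abort("`tags` length differs from `id`.")
  tags <- lapply(tags, function(t) unique(as.character(t)))
  if (is.null(desc)) desc <- rep(NA_character_, n)
  tibble(id = id, sequence = unname(sequence), label = label,
         tags = tags, desc = as.character(desc))
}

check_binary_label <- function(label) {
  lab <- suppressWarnings(as.numeric(label))
  bad <- !is.na(lab) & !(lab %in% c(0, 1))
  bad <- bad | (is.na(lab) & !is.na(label))
  if (any(bad)) {
    abort(paste0("Labels must be binary 0/1; offending values: ",
                 paste(unique(head(label[bad], 5)), collapse = ", ")))
  }
  as.integer(lab)
}

#' Validate an amino-acid sequence
#'
#' Checks a sequence against the canonical 20-letter alphabet. Ambiguity and
#' non-standard codes (B, J, O, U, X, Z) are rejected under both policies:
#' every downstream representation assumes the 20-letter alphabet.
#'
#' @param seq a single sequence string.
#' @param policy `"coerce"` (map lowercase to uppercase, then check) or
#'   `"strict"` (reject any character that is not an uppercase canonical
#'   residue).
#' @return the validated (possibly uppercased) sequence; errors otherwise.
#' @examples
#' validate_sequence("acde")            # "ACDE"
#' try(validate_sequence("ACB1"))       # error: B, 1 not canonical
#' @export
validate_sequence <- function(seq, policy = c("coerce", "strict")) {
  policy <- match.arg(policy)
  if (length(seq) != 1 || is.na(seq)) abort("`seq` must be a single string.")
  if (!nzchar(seq)) abort("Empty sequence is not a valid peptide.")
  checked <- if (policy == "coerce") toupper(seq) else seq
  chars <- strsplit(checked, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    abort(paste0(
      "Non-canonical residue(s) in sequence: ",
      paste(sprintf("'%s' at position %d", chars[bad], bad), collapse = ", ")
    ))
  }
  checked
}

#' Check that a data frame is a valid peptide table
#'
#' @param data a data frame with at least `id` and `sequence` columns.
#' @param require_labels require a complete binary `label` column (for
#'   supervised use).
#' @return the data invisibly, normalized to the full column set.
#' @export
validate_peptides <- function(data, require_labels = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of peptides.")
  missing_cols <- setdiff(c("id", "sequence"), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(data$id)) abort("Peptide ids must be unique.")
  vapply(data$sequence, validate_sequence, "", policy = "strict")
  if (!"label" %in% names(data)) data$label <- NA_integer_
  if (!"tags" %in% names(data)) data$tags <- rep(list(character()), nrow(data))
  if (!"desc" %in% names(data)) data$desc <- NA_character_
  data$label <- check_binary_label(data$label)
  if (require_labels && anyNA(data$label)) {
    abort("Supervised use requires a label for every peptide.")
  }
  invisible(as_tibble(data))
}

#' Read peptides from a FASTA file
#'
#' The header token up to the first whitespace becomes the peptide id; the
#' remainder is retained in `desc`. Sequences are uppercased and validated
#' against the canonical alphabet. Wrapped (multi-line) records are
#' supported.
#'
#' @param path path to a FASTA file.
#' @param dedupe drop peptides whose sequence duplicates an earlier record
#'   (default `TRUE`); duplicates are reported with a warning.
#' @return a peptide tibble (see [peptide_tbl()]).
#' @export
read_fasta <- function(path, dedupe = TRUE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("Empty FASTA file: ", path))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    abort(paste0("Malformed FASTA: line 1 of ", path,
                 " does not start with '>'."))
  }
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), NA_character_)
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) paste(trimws(x), collapse = ""), "")
  # headers with no sequence lines produce no split element
  full <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  full[names(seqs)] <- seqs
  empty <- !nzchar(full)
  if (any(empty)) {
    abort(paste0("FASTA record(s) without sequence: ",
                 paste(ids[empty], collapse = ", ")))
  }
  out <- peptide_tbl(ids, toupper(unname(full)), desc = descs)
  if (dedupe) out <- dedupe_sequences(out)
  out
}

dedupe_sequences <- function(data) {
  dup <- duplicated(data$sequence)
  if (any(dup)) {
    warn(paste0("Dropped ", sum(dup), " duplicate sequence(s): ",
                paste(head(data$id[dup], 5), collapse = ", ")))
    data <- data[!dup, , drop = FALSE]
  }
  data
}

#' Write peptides to a FASTA file
#'
#' @param data a peptide tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  data <- validate_peptides(data)
  hdr <- ifelse(is.na(data$desc), paste0(">", data$id),
                paste0(">", data$id, " ", data$desc))
  writeLines(as.vector(rbind(hdr, data$sequence)), path)
  invisible(path)
}

#' Read a peptide dataset from a delimited file
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param seq_col name of the sequence column.
#' @param id_col optional id column; row numbers (`pep1`, `pep2`, ...) are
#'   used when absent.
#' @param label_col optional binary label column.
#' @param tag_col optional bioactivity-tag column; cells are split on
#'   `tag_delim`.
#' @param tag_delim delimiter between tags within a cell (default `";"`).
#' @param sep field separator (`","`; use `"\t"` for TSV).
#' @param dedupe drop duplicate sequences as in [read_fasta()].
#' @return a peptide tibble.
#' @export
read_peptide_csv <- function(path, seq_col = "sequence", id_col = NULL,
                             label_col = NULL, tag_col = NULL,
                             tag_delim = ";", sep = ",", dedupe = TRUE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(seq_col, id_col, label_col, tag_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Column(s) not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- if (is.null(id_col)) paste0("pep", seq_len(nrow(raw))) else
    as.character(raw[[id_col]])
  label <- if (is.null(label_col)) NULL else raw[[label_col]]
  tags <- if (is.null(tag_col)) NULL else
    lapply(strsplit(as.character(raw[[tag_col]]), tag_delim, fixed = TRUE),
           function(t) trimws(t[nzchar(trimws(t))]))
  out <- peptide_tbl(ids, raw[[seq_col]], label = label, tags = tags)
  if (dedupe) out <- dedupe_sequences(out)
  out
}

#' Write a peptide dataset to CSV
#'
#' Tags are joined with `tag_delim` so the file round-trips through
#' [read_peptide_csv()].
#'
#' @inheritParams read_peptide_csv
#' @param data a peptide tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_csv <- function(data, path, tag_delim = ";") {
  data <- validate_peptides(data)
  flat <- data.frame(
    id = data$id, sequence = data$sequence, label = data$label,
    tags = vapply(data$tags, paste, "", collapse = tag_delim),
    stringsAsFactors = FALSE
  )
  write.csv(flat, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
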