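#' One-hot residue matrix
#'
#' @param sequence a single validated sequence.
#' @return an n x 20 matrix; row i has a single 1 at the column of residue
#'   i (columns ordered by the canonical alphabet).
#' @export
one_hot_matrix <- function(sequence) {
  sequence <- validate_sequence(sequence, policy = "strict")
  chars <- strsplit(sequence, "")[[1]]
  m <- matrix(0, nrow = length(chars), ncol = 20,
              dimnames = list(NULL, AA_ALPHABET))
  m[cbind(seq_along(chars), match(chars, AA_ALPHABET))] <- 1
  m
}

#' Mean-pool a residue matrix into a peptide vector
#'
#' Collapses an n x e per-residue matrix to one e-dimensional vector by
#' averaging across residues. Applied identically to every backend so all
#' representations share one downstream contract; for one-hot input the
#' result is exactly the amino-acid composition vector.
#'
#' @param m an n x e numeric matrix (n >= 1 residues).
#' @return numeric vector of length e.
#' @export
mean_pool <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0) abort("Cannot pool an empty matrix.")
  colMeans(m)
}

#' Embedding backends
#'
#' A backend is a list with fields `name`, `dim` and `encode(sequence)`
#' returning the n x e per-residue matrix (special tokens, if a backend has
#' any, must already be excluded). Three backends ship with the package:
#'
#' * `backend_onehot()` - the naive 20-dimensional baseline.
#' * `backend_mock(dim, seed)` - a deterministic stand-in for a protein
#'   language model: each residue's vector is drawn from a seeded hash of
#'   its 3-residue context window, so embeddings are position-sensitive,
#'   reproducible, and require no downloads. It carries no biological
#'   information and exists for testing the representation contract.
#' * `backend_precomputed(table)` - per-peptide vectors computed elsewhere
#'   (e.g. by a real protein language model) and imported from a TSV with
#'   an `id` column; `encode` is unavailable, only pooled lookup.
#'
#' Real language-model adapters can be registered by constructing a backend
#' list with the same fields; requesting an unavailable backend errors with
#' installation guidance rather than silently falling back.
#'
#' @param dim embedding width of the mock backend (default 32).
#' @param seed seed of the mock backend's hash stream.
#' @name embedding_backends
NULL

#' @rdname embedding_backends
#' @export
backend_onehot <- function() {
  structure(list(
    name = "one_hot", dim = 20L,
    encode = function(sequence) one_hot_matrix(sequence)
  ), class = "embedding_backend")
}

#' @rdname embedding_backends
#' @export
backend_mock <- function(dim = 32L, seed = 7L) {
  dim <- as.integer(dim)
  force(seed)
  structure(list(
    name = paste0("mock", dim, "_s", seed), dim = dim,
    encode = function(sequence) {
      sequence <- validate_sequence(sequence, policy = "strict")
      n <- nchar(sequence)
      padded <- paste0("^", sequence, "$")
      rows <- lapply(seq_len(n), function(i) {
        ctx <- substr(padded, i, i + 2)
        h <- (string_hash31(ctx) + as.double(seed) * 2654435761) %% 2147483647
        splitmix_runif(h, dim) * 2 - 1
      })
      do.call(rbind, rows)
    }
  ), class = "embedding_backend")
}

#' @rdname embedding_backends
#' @param table a data frame with an `id` column and numeric vector columns,
#'   or a path to a TSV file of that shape.
#' @export
backend_precomputed <- function(table) {
  if (is.character(table)) {
    if (!file.exists(table)) {
      abort(paste0("Precomputed embedding file not found: ", table))
    }
    table <- read.csv(table, sep = "\t", check.names = FALSE)
  }
  if (!"id" %in% names(table)) {
    abort("Precomputed embeddings need an `id` column.")
  }
  mat <- as.matrix(table[setdiff(names(table), "id")])
  if (!is.numeric(mat)) abort("Precomputed embedding columns must be numeric.")
  rownames(mat) <- table$id
  structure(list(
    name = "precomputed", dim = ncol(mat), matrix = mat, encode = NULL
  ), class = "embedding_backend")
}

#' @rdname embedding_backends
#' @param name name of a pretrained protein language model (e.g. an ESM2
#'   checkpoint).
#' @export
backend_plm <- function(name) {
  abort(paste0(
    "Protein language model backend '", name, "' is not bundled. Compute ",
    "per-peptide mean-pooled embeddings externally (e.g. with the ",
    "fair-esm or transformers Python packages), write them as a TSV with ",
    "an `id` column, and load them with backend_precomputed()."))
}

#' Embed peptides into fixed-length vectors
#'
#' Runs the backend on every sequence and mean-pools the per-residue
#' matrices. Results are cached by (backend name, sequence) within the
#' returned object's provenance and, optionally, on disk, so embedding is a
#' pure function of backend identity and sequence.
#'
#' @param data a peptide tibble.
#' @param backend an embedding backend (default [backend_onehot()]).
#' @param cache_dir optional directory for a persistent vector cache.
#' @return a tibble with column `id` followed by `e` numeric columns
#'   `V1..Ve`; attribute `backend` records the backend name and dimension.
#' @export
pep_embed <- function(data, backend = backend_onehot(), cache_dir = NULL) {
  data <- validate_peptides(data)
  if (identical(backend$name, "precomputed")) {
    missing_ids <- setdiff(data$id, rownames(backend$matrix))
    if (length(missing_ids)) {
      abort(paste0("No precomputed embedding for id(s): ",
                   paste(head(missing_ids, 5), collapse = ", ")))
    }
    vecs <- backend$matrix[data$id, , drop = FALSE]
  } else {
    vecs <- t(vapply(data$sequence, function(s) {
      cached <- cache_get(cache_dir, backend$name, s)
      if (!is.null(cached)) return(cached)
      v <- mean_pool(backend$encode(s))
      cache_put(cache_dir, backend$name, s, v)
      v
    }, numeric(backend$dim)))
  }
  colnames(vecs) <- paste0("V", seq_len(ncol(vecs)))
  out <- dplyr::bind_cols(tibble(id = data$id), as_tibble(vecs))
  attr(out, "backend") <- list(name = backend$name, dim = ncol(vecs))
  out
}

cache_key <- function(backend_name, sequence) {
  paste0(backend_name, "_", string_hash31(sequence), "_", nchar(sequence))
}

cache_get <- function(cache_dir, backend_name, sequence) {
  if (is.null(cache_dir)) return(NULL)
  f <- file.path(cache_dir, paste0(cache_key(backend_name, sequence), ".txt"))
  if (!file.exists(f)) return(NULL)
  lines <- readLines(f)
  if (!identical(lines[1], sequence)) return(NULL)  # hash collision guard
  as.numeric(strsplit(lines[2], "\t")[[1]])
}

cache_put <- function(cache_dir, backend_name, sequence, v) {
  if (is.null(cache_dir)) return(invisible(NULL))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(cache_key(backend_name, sequence), ".txt"))
  writeLines(c(sequence, paste(format(v, digits = 17), collapse = "\t")), f)
  invisible(NULL)
}

embed_matrix <- function(embedding) {
  m <- as.matrix(embedding[setdiff(names(embedding), "id")])
  rownames(m) <- embedding$id
  m
}
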