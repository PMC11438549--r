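# BLOSUM62 over the canonical alphabet (Henikoff & Henikoff 1992),
# row/column order ACDEFGHIKLMNPQRSTVWY.
BLOSUM62_20 <- matrix(c(
  4,0,-2,-1,-2,0,-2,-1,-1,-1,-1,-2,-1,-1,-1,1,0,0,-3,-2,
  0,9,-3,-4,-2,-3,-3,-1,-3,-1,-1,-3,-3,-3,-3,-1,-1,-1,-2,-2,
  -2,-3,6,2,-3,-1,-1,-3,-1,-4,-3,1,-1,0,-2,0,-1,-3,-4,-3,
  -1,-4,2,5,-3,-2,0,-3,1,-3,-2,0,-1,2,0,0,-1,-2,-3,-2,
  -2,-2,-3,-3,6,-3,-1,0,-3,0,0,-3,-4,-3,-3,-2,-2,-1,1,3,
  0,-3,-1,-2,-3,6,-2,-4,-2,-4,-3,0,-2,-2,-2,0,-2,-3,-2,-3,
  -2,-3,-1,0,-1,-2,8,-3,-1,-3,-2,1,-2,0,0,-1,-2,-3,-2,2,
  -1,-1,-3,-3,0,-4,-3,4,-3,2,1,-3,-3,-3,-3,-2,-1,3,-3,-1,
  -1,-3,-1,1,-3,-2,-1,-3,5,-2,-1,0,-1,1,2,0,-1,-2,-3,-2,
  -1,-1,-4,-3,0,-4,-3,2,-2,4,2,-3,-3,-2,-2,-2,-1,1,-2,-1,
  -1,-1,-3,-2,0,-3,-2,1,-1,2,5,-2,-2,0,-1,-1,-1,1,-1,-1,
  -2,-3,1,0,-3,0,1,-3,0,-3,-2,6,-2,0,0,1,0,-3,-4,-2,
  -1,-3,-1,-1,-4,-2,-2,-3,-1,-3,-2,-2,7,-1,-2,-1,-1,-2,-4,-3,
  -1,-3,0,2,-3,-2,0,-3,1,-2,0,0,-1,5,1,0,-1,-2,-2,-1,
  -1,-3,-2,0,-3,-2,0,-3,2,-2,-1,0,-2,1,5,-1,-1,-3,-3,-2,
  1,-1,0,0,-2,0,-1,-2,0,-2,-1,1,-1,0,-1,4,1,-2,-3,-2,
  0,-1,-1,-1,-2,-2,-2,-1,-1,-1,-1,0,-1,-1,-1,1,5,0,-2,-2,
  0,-1,-3,-2,-1,-3,-3,3,-2,1,1,-3,-2,-2,-3,-2,0,4,-3,-1,
  -3,-2,-4,-3,1,-2,-2,-3,-3,-2,-1,-4,-4,-2,-3,-3,-2,-3,11,2,
  -2,-2,-3,-2,3,-3,2,-1,-2,-1,-1,-2,-3,-1,-2,-2,-2,-1,2,7
), nrow = 20, byrow = TRUE,
dimnames = list(AA_ALPHABET, AA_ALPHABET))

#' Parameters of the pairwise-identity criterion
#'
#' Two peptides are called similar when the fraction of identical aligned
#' residue pairs in their optimal local (Smith-Waterman) alignment, divided
#' by the length of the LONGER sequence, exceeds `threshold` (strict `>`).
#' The exact-k-mer prefilter restricts which pairs are aligned when building
#' a similarity graph; `k = 3` suits short peptides.
#'
#' @param threshold identity fraction in (0, 1]; default 0.30.
#' @param prefilter_kmer k-mer length for the prefilter (default 3).
#' @param prefilter_min_shared minimum number of shared distinct k-mers for
#'   a pair to be aligned (default 1).
#' @param use_prefilter set `FALSE` to align all pairs exhaustively.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 1; a gap
#'   of length L costs `gap_open + L * gap_extend`).
#' @param substitution_matrix a 20x20 scoring matrix with rows/columns named
#'   by the canonical alphabet (default BLOSUM62).
#' @return an object of class `identity_params`.
#' @export
identity_params <- function(threshold = 0.30, prefilter_kmer = 3,
                            prefilter_min_shared = 1, use_prefilter = TRUE,
                            gap_open = 10, gap_extend = 1,
                            substitution_matrix = BLOSUM62_20) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  if (prefilter_kmer < 1) abort("`prefilter_kmer` must be >= 1.")
  stopifnot(identical(dim(substitution_matrix), c(20L, 20L)))
  structure(
    list(threshold = threshold, prefilter_kmer = as.integer(prefilter_kmer),
         prefilter_min_shared = as.integer(prefilter_min_shared),
         use_prefilter = isTRUE(use_prefilter),
         gap_open = gap_open, gap_extend = gap_extend,
         substitution_matrix = substitution_matrix),
    class = "identity_params"
  )
}

#' Pairwise sequence identity under local alignment
#'
#' Vectorized over pairs: `seq_a[i]` is aligned to `seq_b[i]`. Identity is
#' the number of identical aligned residue pairs in the optimal local
#' alignment divided by the longer sequence's length, hence symmetric and in
#' \[0, 1\]. Ties among equal-score optimal alignments are resolved toward
#' the maximum match count.
#'
#' @param seq_a,seq_b character vectors of equal length (validated
#'   sequences).
#' @param params an [identity_params()] object.
#' @return numeric vector of identity fractions.
#' @examples
#' pairwise_identity("AAAA", "AAAATTTT")  # 4 matches / 8 = 0.5
#' @export
pairwise_identity <- function(seq_a, seq_b, params = identity_params()) {
  seq_a <- vapply(seq_a, validate_sequence, "", policy = "coerce")
  seq_b <- vapply(seq_b, validate_sequence, "", policy = "coerce")
  .sw_align_pairs(unname(seq_a), unname(seq_b), params$substitution_matrix,
                  paste(AA_ALPHABET, collapse = ""),
                  params$gap_open, params$gap_extend)$identity
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Candidate pairs sharing exact k-mers
#'
#' Returns all unordered peptide pairs sharing at least
#' `prefilter_min_shared` distinct exact k-mers. Sequences shorter than k
#' contribute no k-mers and are never candidates.
#'
#' The filter is an approximation, not a guarantee: a pair can exceed the
#' identity threshold through scattered single-residue matches while
#' sharing no k consecutive identities, in which case it is (wrongly)
#' dropped. Such misses become likely only when homologs are heavily
#' diverged relative to k; set `use_prefilter = FALSE` in
#' [identity_params()] to align all pairs exhaustively when completeness
#' matters more than speed.
#'
#' @param data a peptide tibble.
#' @param params an [identity_params()] object.
#' @return a tibble with columns `id_a`, `id_b` (id_a < id_b in dataset
#'   order) and `shared` (number of shared distinct k-mers).
#' @export
kmer_prefilter <- function(data, params = identity_params()) {
  data <- validate_peptides(data)
  k <- params$prefilter_kmer
  km <- lapply(data$sequence, seq_kmers, k = k)
  idx <- tibble(
    kmer = unlist(km),
    i = rep(seq_len(nrow(data)), lengths(km))
  )
  if (!nrow(idx)) {
    return(tibble(id_a = character(), id_b = character(), shared = integer()))
  }
  pairs <- idx |>
    dplyr::inner_join(idx, by = "kmer", relationship = "many-to-many") |>
    filter(.data$i.x < .data$i.y) |>
    count(.data$i.x, .data$i.y, name = "shared") |>
    filter(.data$shared >= params$prefilter_min_shared)
  tibble(id_a = data$id[pairs$i.x], id_b = data$id[pairs$i.y],
         shared = as.integer(pairs$shared))
}

#' Build a sequence-identity similarity graph
#'
#' Nodes are peptide ids (isolated nodes kept); an edge connects two
#' peptides whose pairwise identity strictly exceeds the threshold. With
#' the prefilter enabled only k-mer-sharing pairs are aligned; pairs with no
#' shared k-mer are treated as dissimilar.
#'
#' @param data a peptide tibble.
#' @param params an [identity_params()] object.
#' @return an object of class `similarity_graph`: list with `nodes`
#'   (character), `edges` (tibble id_a, id_b, identity) and `params`.
#' @export
similarity_graph <- function(data, params = identity_params()) {
  data <- validate_peptides(data)
  if (!nrow(data)) abort("Cannot build a similarity graph from 0 peptides.")
  if (params$use_prefilter) {
    cand <- kmer_prefilter(data, params)
    ia <- match(cand$id_a, data$id)
    ib <- match(cand$id_b, data$id)
  } else {
    n <- nrow(data)
    if (n > 1) {
      cmb <- utils::combn(n, 2)
      ia <- cmb[1, ]; ib <- cmb[2, ]
    } else {
      ia <- integer(); ib <- integer()
    }
  }
  if (length(ia)) {
    ident <- .sw_align_pairs(data$sequence[ia], data$sequence[ib],
                             params$substitution_matrix,
                             paste(AA_ALPHABET, collapse = ""),
                             params$gap_open, params$gap_extend)$identity
    keep <- ident > params$threshold
    edges <- tibble(id_a = data$id[ia][keep], id_b = data$id[ib][keep],
                    identity = ident[keep])
  } else {
    edges <- tibble(id_a = character(), id_b = character(),
                    identity = numeric())
  }
  structure(list(nodes = data$id, edges = edges, params = params),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "<similarity_graph> %d nodes, %d edges (identity > %.0f%%)\n",
    length(x$nodes), nrow(x$edges), 100 * x$params$threshold))
  invisible(x)
}

#' @rdname tidy_peptideml
#' @export
tidy.similarity_graph <- function(x, ...) x$edges

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = graph$nodes
  )
}

#' Export a similarity graph's edges as TSV
#'
#' @param graph a `similarity_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
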