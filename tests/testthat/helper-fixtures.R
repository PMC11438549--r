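# Shared fixture builders and independent oracle implementations.

toy_peptides <- function() {
  peptide_tbl(
    id = c("p1", "p2", "p3", "p4"),
    sequence = c("ACDEFGHIKL", "ACDEFGHIKM", "WWWWYYYYWW", "KLMNPQRSTV"),
    label = c(1, 1, 0, 0)
  )
}

# A labeled family dataset where half the families are positives and the
# positives carry a scattered composition motif on residues the family
# alphabet excludes: separable by mean-pooled one-hot, while the motif
# leaves the homology structure intact (no local-alignment anchor).
separable_family_dataset <- function(n_families = 10, members = 10,
                                     motif_fraction = 1, seed = 1L) {
  fam <- generate_families(
    n_families, members, seed_length = c(20, 35), mutation_rate = 0.1,
    alphabet = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       c("W", "K")),
    seed = seed)
  inject_label_signal(fam, motif = "WWKWW", fraction = motif_fraction,
                      scatter = TRUE, seed = seed + 1L)
}

edge_key <- function(graph) {
  e <- graph$edges
  sort(paste(pmin(e$id_a, e$id_b), pmax(e$id_a, e$id_b)))
}

# Brute-force property oracles, independent of the package implementations.
oracle_aliphatic <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  100 * (mean(ch == "A") + 2.9 * mean(ch == "V") +
           3.9 * (mean(ch == "I") + mean(ch == "L")))
}

oracle_charge <- function(seq, ph) {
  pka_basic <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
  pka_acid <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  ch <- strsplit(seq, "")[[1]]
  q <- 1 / (1 + 10^(ph - pka_basic["Nterm"])) -
    1 / (1 + 10^(pka_acid["Cterm"] - ph))
  for (r in ch) {
    if (r %in% names(pka_basic)) q <- q + 1 / (1 + 10^(ph - pka_basic[r]))
    if (r %in% names(pka_acid)) q <- q - 1 / (1 + 10^(pka_acid[r] - ph))
  }
  unname(q)
}

oracle_hydrophobic_moment <- function(seq, scale) {
  h <- scale[strsplit(seq, "")[[1]]]
  d <- 100 * pi / 180
  re <- sum(h * cos(seq_along(h) * d))
  im <- sum(h * sin(seq_along(h) * d))
  sqrt(re^2 + im^2) / length(h)
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
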