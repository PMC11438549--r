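# Physico-chemical scales are shipped as CSV data files, not code:
#   eisenberg_hydrophobicity.csv - Eisenberg consensus hydrophobicity scale
#     (Eisenberg et al. 1984), used for the hydrophobic moment.
#   boman_transfer_energy.csv - water->cyclohexane transfer free energies
#     (Radzicka & Wolfenden 1988) as used by the Boman (2003) protein
#     interaction index; proline has no measured value and is set to 0.
#   pka_emboss.csv - the EMBOSS pKa set for ionizable groups and termini.
.scale_env <- new.env(parent = emptyenv())

load_scale <- function(name) {
  if (!is.null(.scale_env[[name]])) return(.scale_env[[name]])
  path <- system.file("extdata", "scales", paste0(name, ".csv"),
                      package = "peptideml", mustWork = TRUE)
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  .scale_env[[name]] <- tbl
  tbl
}

residue_scale <- function(name) {
  tbl <- load_scale(name)
  setNames(tbl$value, tbl$residue)
}

#' Physico-chemical property profile of peptides
#'
#' Computes, per peptide: the aliphatic index
#' (100 (x_Ala + 2.9 x_Val + 3.9 (x_Ile + x_Leu)) over mole fractions x),
#' the Boman interaction index (negated mean per-residue transfer free
#' energy, kcal/mol), the net charge at `ph` (Henderson-Hasselbalch over
#' the EMBOSS pKa set, termini included), the isoelectric point (bisection
#' on net charge to |charge| < 1e-4) and the hydrophobic moment
#' mu_H = (1/n) |sum_j H_j exp(i j delta)| with delta = 100 degrees (the
#' ideal alpha-helix turn) on the Eisenberg scale.
#'
#' @param data a peptide tibble.
#' @param ph pH at which net charge is evaluated (default 7.0).
#' @return a tibble: `id`, `length`, `aliphatic_index`, `boman_index`,
#'   `net_charge`, `isoelectric_point`, `hydrophobic_moment`.
#' @examples
#' property_profile(peptide_tbl("a", "AAAAA"))$aliphatic_index  # 100
#' @export
property_profile <- function(data, ph = 7.0) {
  data <- validate_peptides(data)
  tibble(
    id = data$id,
    length = nchar(data$sequence),
    aliphatic_index = unname(vapply(data$sequence, aliphatic_index, 0)),
    boman_index = unname(vapply(data$sequence, boman_index, 0)),
    net_charge = unname(vapply(data$sequence, net_charge, 0, ph = ph)),
    isoelectric_point = unname(vapply(data$sequence, isoelectric_point, 0)),
    hydrophobic_moment = unname(vapply(data$sequence, hydrophobic_moment, 0))
  )
}

seq_chars <- function(sequence) strsplit(sequence, "")[[1]]

aliphatic_index <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  x <- function(aa) sum(chars == aa) / n
  100 * (x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L")))
}

boman_index <- function(sequence) {
  scale <- residue_scale("boman_transfer_energy")
  -mean(scale[seq_chars(sequence)])
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch: each basic group contributes
#' `1 / (1 + 10^(pH - pKa))`, each acidic group `-1 / (1 + 10^(pKa - pH))`;
#' the N- and C-termini are always included.
#'
#' @param sequence a validated sequence.
#' @param ph pH value.
#' @return net charge (elementary charges).
#' @export
net_charge <- function(sequence, ph = 7.0) {
  sequence <- validate_sequence(sequence, policy = "coerce")
  pka <- load_scale("pka_emboss")
  chars <- seq_chars(sequence)
  counts <- vapply(pka$group, function(g) {
    if (g %in% c("Nterm", "Cterm")) 1 else sum(chars == g)
  }, 0)
  pos <- pka$type == "basic"
  sum(counts[pos] / (1 + 10^(ph - pka$pka[pos]))) -
    sum(counts[!pos] / (1 + 10^(pka$pka[!pos] - ph)))
}

#' Isoelectric point by bisection
#'
#' Net charge is strictly decreasing in pH, so the root is bracketed in
#' \[0, 14\] and bisection converges; iteration stops when
#' `|net_charge(pI)| < 1e-4`.
#'
#' @inheritParams net_charge
#' @return pI in \[0, 14\].
#' @export
isoelectric_point <- function(sequence) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, ph = mid)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

hydrophobic_moment <- function(sequence, delta_deg = 100) {
  h <- residue_scale("eisenberg_hydrophobicity")[seq_chars(sequence)]
  n <- length(h)
  ang <- (seq_len(n)) * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / n
}

#' Compare a property's distribution between two datasets
#'
#' Produces aligned-bin histograms of one physico-chemical property for two
#' datasets plus the Wasserstein-1 distance between the empirical
#' distributions (the integral of the absolute ECDF difference), as data
#' for plotting or reporting.
#'
#' @param a,b peptide tibbles (e.g. positives vs sampled negatives).
#' @param property one of `"length"`, `"aliphatic_index"`, `"boman_index"`,
#'   `"net_charge"`, `"isoelectric_point"`, `"hydrophobic_moment"`.
#' @param bins number of histogram bins spanning the pooled range.
#' @param ph pH for charge-dependent properties.
#' @return a list of class `property_comparison`: `histogram` (tibble
#'   `dataset`, `mid`, `count`, `density`), `distance` (Wasserstein-1),
#'   `property`.
#' @export
compare_distributions <- function(a, b, property = "length", bins = 15,
                                  ph = 7.0) {
  choices <- c("length", "aliphatic_index", "boman_index", "net_charge",
               "isoelectric_point", "hydrophobic_moment")
  if (!property %in% choices) {
    abort(paste0("Unknown property '", property, "'. Choose one of: ",
                 paste(choices, collapse = ", ")))
  }
  va <- property_profile(a, ph = ph)[[property]]
  vb <- property_profile(b, ph = ph)[[property]]
  if (!length(va) || !length(vb)) abort("Both datasets must be non-empty.")
  rng <- range(c(va, vb))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  hist_of <- function(v, label) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    tibble(dataset = label, mid = h$mids, count = h$counts,
           density = h$counts / length(v))
  }
  structure(
    list(histogram = bind_rows(hist_of(va, "a"), hist_of(vb, "b")),
         distance = wasserstein1(va, vb), property = property),
    class = "property_comparison"
  )
}

#' Wasserstein-1 distance between two empirical distributions
#'
#' Exact for finite samples: integrates `|F_a(x) - F_b(x)|` over the pooled
#' support.
#'
#' @param a,b numeric samples.
#' @return non-negative distance in the property's units.
#' @export
wasserstein1 <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  if (length(grid) < 2) return(0)
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  sum(abs(fa[-length(grid)] - fb[-length(grid)]) * diff(grid))
}
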