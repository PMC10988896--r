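# Monoisotopic mass bookkeeping for tryptic peptides with fixed
# carbamidomethyl-C and SILAC-style C-terminal heavy labels (Lys8 / Arg10).

#' @keywords internal
.mass_proton <- 1.007276466
#' @keywords internal
.mass_h2o <- 18.0105646863

# Residue monoisotopic masses; C carries fixed carbamidomethylation (+57.02146).
.residue_mass <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276385,
  V = 99.06841391, T = 101.04767846, C = 103.00918448 + 57.02146372,
  L = 113.08406398, I = 113.08406398, N = 114.04292744, D = 115.02694302,
  Q = 128.05857750, K = 128.09496301, E = 129.04259308, M = 131.04048461,
  H = 137.05891186, F = 147.06841391, R = 156.10111102, Y = 163.06332853,
  W = 186.07931295
)

# Heavy-label mass shifts: 13C6 15N2 lysine and 13C6 15N4 arginine.
.label_shift <- c(light = 0, heavy_K8 = 8.014199, heavy_R10 = 10.008269)

# Mean spacing between successive isotopologue peaks (one extra neutron).
.neutron_spacing <- 1.0033548378

.residue_vec <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.residue_mass))
  if (length(bad) > 0) {
    stop("unknown residue letter(s) in '", sequence, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  unname(.residue_mass[aa])
}

#' Monoisotopic mass of a peptide
#'
#' Neutral monoisotopic mass from residue-mass summation, with fixed
#' carbamidomethyl-C and an optional heavy C-terminal label.
#'
#' @param sequence Amino-acid string (uppercase one-letter codes).
#' @param label One of `"light"`, `"heavy_K8"`, `"heavy_R10"`.
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, label = "light") {
  label <- match.arg(label, names(.label_shift))
  sum(.residue_vec(sequence)) + .mass_h2o + .label_shift[[label]]
}

#' Precursor m/z of a peptide ion
#'
#' @inheritParams peptide_mass
#' @param charge Positive integer charge state.
#' @return m/z in Th.
#' @export
precursor_mz <- function(sequence, charge, label = "light") {
  stopifnot(charge >= 1)
  (peptide_mass(sequence, label) + charge * .mass_proton) / charge
}

#' Theoretical fragment m/z for b and y ions
#'
#' Monoisotopic fragment m/z from residue-mass summation. A heavy C-terminal
#' label (Lys8/Arg10) shifts every y ion by the full label mass (divided by
#' the fragment charge) and leaves b ions untouched, because the labelled
#' residue is C-terminal.
#'
#' @param sequence Amino-acid string.
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment length, `1 <= ordinal < nchar(sequence)`.
#' @param charge Fragment charge (default 1).
#' @param label Label channel of the precursor.
#' @return m/z in Th.
#' @export
#' @examples
#' fragment_mz("ELVISLIVESK", "y", 3)
fragment_mz <- function(sequence, series, ordinal, charge = 1, label = "light") {
  series <- match.arg(series, c("b", "y"))
  label <- match.arg(label, names(.label_shift))
  res <- .residue_vec(sequence)
  n <- length(res)
  if (any(ordinal < 1 | ordinal >= n)) {
    stop("ordinal must satisfy 1 <= ordinal < ", n, call. = FALSE)
  }
  if (series == "b") {
    frag_mass <- vapply(ordinal, function(k) sum(res[seq_len(k)]), numeric(1))
  } else {
    frag_mass <- vapply(ordinal, function(k) sum(res[(n - k + 1):n]), numeric(1)) +
      .mass_h2o + .label_shift[[label]]
  }
  (frag_mass + charge * .mass_proton) / charge
}

# Averagine model unit: average elemental composition per 111.1254 Da of
# peptide. Isotope abundances from standard tables.
.averagine <- list(
  unit_mass = 111.1254,
  atoms = c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417),
  # per-element distribution of extra neutrons (offset 0, 1, 2, ...)
  iso = list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
)

# Distribution of extra-neutron count for n atoms of one element, truncated
# to max_k, by repeated self-convolution of the single-atom distribution.
.element_neutron_dist <- function(n, p, max_k) {
  acc <- c(1, rep(0, max_k))
  one <- c(p, rep(0, max_k))[seq_len(max_k + 1)]
  remaining <- n
  pow <- one
  while (remaining > 0) {
    if (remaining %% 2 == 1) {
      acc <- convolve(acc, rev(pow), type = "open")[seq_len(max_k + 1)]
    }
    remaining <- remaining %/% 2
    if (remaining > 0) {
      pow <- convolve(pow, rev(pow), type = "open")[seq_len(max_k + 1)]
    }
  }
  acc
}

#' Averagine isotope envelope for a peptide species
#'
#' Approximates the isotopologue pattern of a peptide ion by scaling the
#' averagine elemental composition to the species' monoisotopic mass and
#' convolving per-element extra-neutron distributions. Peak spacing is the
#' mean neutron mass divided by charge; abundances are renormalised over the
#' retained peaks.
#'
#' @param species One-row species tibble (or list) with at least
#'   `precursor_mz`, `charge`, and `sequence` or `mass` fields; see
#'   [make_pair()].
#' @param n_peaks Number of isotopologue peaks to keep (>= 1).
#' @return A tibble with columns `mz` (Th) and `relative_abundance`
#'   (summing to 1).
#' @export
isotope_envelope <- function(species, n_peaks = 3) {
  stopifnot(n_peaks >= 1)
  species <- as.list(species)
  mass <- if (!is.null(species$mass)) {
    species$mass
  } else {
    peptide_mass(species$sequence, species$label %||% "light")
  }
  rel <- averagine_envelope(mass, n_peaks)
  tibble::tibble(
    mz = species$precursor_mz + (seq_len(n_peaks) - 1) *
      .neutron_spacing / species$charge,
    relative_abundance = rel
  )
}

#' Averagine isotopologue abundances for a given mass
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param n_peaks Number of peaks retained.
#' @return Numeric vector of relative abundances summing to 1.
#' @export
averagine_envelope <- function(mass, n_peaks = 3) {
  stopifnot(n_peaks >= 1, mass > 0)
  n_units <- mass / .averagine$unit_mass
  max_k <- n_peaks - 1
  dist <- 1
  for (el in names(.averagine$atoms)) {
    n_atoms <- max(0L, round(n_units * .averagine$atoms[[el]]))
    if (n_atoms == 0) next
    p <- .averagine$iso[[el]]
    d <- .element_neutron_dist(n_atoms, p, max_k)
    dist <- convolve(dist, rev(d), type = "open")[seq_len(max_k + 1)]
  }
  dist <- pmax(dist, 0)
  if (length(dist) < n_peaks) dist <- c(dist, rep(0, n_peaks - length(dist)))
  dist / sum(dist)
}
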