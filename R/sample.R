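# Synthetic sample generation: heavy/light peptide pairs, dilution series and
# a statistically emulated complex background matrix, all with known ground
# truth so downstream claims are testable.

#' Build a heavy/light peptide pair
#'
#' Creates the light endogenous species and its stable-isotope-labelled heavy
#' counterpart. Both share sequence, charge, retention time and peak shape and
#' differ only in label channel, amount, and precursor m/z. Tryptic C-termini
#' determine the label: Lys8 (+8.014199 Da) for K, Arg10 (+10.008269 Da) for R.
#'
#' @param sequence Peptide sequence; must end in K or R.
#' @param charge Charge state, one of 2, 3, 4.
#' @param light_amount_fmol,heavy_amount_fmol Amounts on column (fmol, >= 0).
#' @param rt_apex_s Elution apex (seconds).
#' @param peak_sigma_s Gaussian peak sigma (seconds); default 6 s
#'   (full width at base about 30 s).
#' @param protein Optional protein-group label for rollup; defaults to the
#'   sequence itself.
#' @return A two-row species tibble (light first), with a `fragments`
#'   list-column of the peptide's declared fragment ions.
#' @export
#' @examples
#' make_pair("DFDQNQGEVVK", 2, light_amount_fmol = 1, heavy_amount_fmol = 100,
#'           rt_apex_s = 1800)
make_pair <- function(sequence, charge, light_amount_fmol, heavy_amount_fmol,
                      rt_apex_s, peak_sigma_s = 6, protein = NULL) {
  last <- substr(sequence, nchar(sequence), nchar(sequence))
  if (!last %in% c("K", "R")) {
    stop("sequence must end in K or R (tryptic C-terminus determines the ",
         "heavy label); got '", sequence, "'", call. = FALSE)
  }
  if (!charge %in% c(2, 3, 4)) {
    stop("charge must be one of 2, 3, 4", call. = FALSE)
  }
  if (light_amount_fmol < 0 || heavy_amount_fmol < 0) {
    stop("amounts must be >= 0", call. = FALSE)
  }
  heavy_label <- if (last == "K") "heavy_K8" else "heavy_R10"
  species_tbl(
    sequence = sequence, charge = charge,
    label = c("light", heavy_label),
    amount_fmol = c(light_amount_fmol, heavy_amount_fmol),
    rt_apex_s = rt_apex_s, peak_sigma_s = peak_sigma_s,
    protein = protein %||% sequence
  )
}

# Construct a validated species tibble (vectorised over rows) with computed
# mass, precursor m/z, ids and per-peptide fragment sets.
species_tbl <- function(sequence, charge, label, amount_fmol, rt_apex_s,
                        peak_sigma_s, protein = sequence) {
  tbl <- tibble::tibble(
    sequence = sequence, charge = as.integer(charge), label = label,
    amount_fmol = amount_fmol, rt_apex_s = rt_apex_s,
    peak_sigma_s = peak_sigma_s, protein = protein
  )
  tbl <- dplyr::mutate(
    tbl,
    id = paste(.data$sequence, .data$charge, .data$label, sep = "/"),
    mass = purrr::map2_dbl(.data$sequence, .data$label, peptide_mass),
    precursor_mz = (.data$mass + .data$charge * .mass_proton) / .data$charge,
    fragments = purrr::pmap(
      list(.data$sequence, .data$charge, .data$label), .fragment_set
    )
  )
  dplyr::select(
    tbl, "id", "sequence", "charge", "label", "amount_fmol",
    "rt_apex_s", "peak_sigma_s", "precursor_mz", "mass", "protein", "fragments"
  )
}

# Declared fragment set: up to 6 y/b ions, mostly y (the label-bearing
# series), with relative intensities drawn once per peptide from a
# symmetric Dirichlet and fixed thereafter (seeded by a peptide hash, so the
# set is identical across samples and independent of the global RNG state).
.fragment_set <- function(sequence, charge, label, n_frag = 6) {
  n <- nchar(sequence)
  max_ord <- n - 1
  y_ord <- seq(2, max_ord)
  b_ord <- seq(2, max_ord)
  n_y <- min(length(y_ord), ceiling(n_frag * 2 / 3))
  n_b <- min(length(b_ord), n_frag - n_y)
  withr::with_seed(.peptide_hash(sequence, charge), {
    y_pick <- sort(sample(y_ord, n_y))
    b_pick <- sort(sample(b_ord, n_b))
    k <- n_y + n_b
    rel <- rgamma(k, shape = 1)
    rel <- rel / sum(rel)
  })
  tibble::tibble(
    series = c(rep("y", n_y), rep("b", n_b)),
    ordinal = c(y_pick, b_pick),
    mz = c(
      if (n_y) fragment_mz(sequence, "y", y_pick, 1, label) else numeric(0),
      if (n_b) fragment_mz(sequence, "b", b_pick, 1, "light") else numeric(0)
    ),
    rel_int = rel
  )
}

#' Generate a complex background matrix statistically
#'
#' Emulates a whole-proteome digest background (e.g. a HeLa standard) by
#' drawing random tryptic-like peptides with log-normal abundances spanning
#' several orders of magnitude, uniform retention-time apexes, and charges 2
#' or 3 constrained to an m/z range.
#'
#' @param n_peptides Number of background species (>= 0).
#' @param rt_range_s Length-2 numeric, retention-time window (seconds).
#' @param mz_range_th Length-2 numeric, allowed precursor m/z (Th).
#' @param abundance_meanlog,abundance_sdlog Parameters of the log-normal
#'   amount law in fmol; the default sdlog of 1.5 decades spans >= 4 orders
#'   of magnitude across a few thousand peptides.
#' @param abundance_cap_fmol Upper truncation of the amount law; the most
#'   abundant background peptides sit a couple of orders of magnitude above
#'   a typical reference spike, not unboundedly higher.
#' @param peak_sigma_s Chromatographic peak sigma (seconds).
#' @param seed Integer seed; identical seeds give identical species lists.
#' @return Species tibble (possibly empty).
#' @export
generate_background <- function(n_peptides, rt_range_s = c(0, 7200),
                                mz_range_th = c(400, 1210),
                                abundance_meanlog = log(1),
                                abundance_sdlog = 1.5 * log(10),
                                abundance_cap_fmol = 2000,
                                peak_sigma_s = 6, seed = 1) {
  stopifnot(n_peptides >= 0)
  if (n_peptides == 0) {
    return(species_tbl(character(0), integer(0), character(0), numeric(0),
                       numeric(0), numeric(0), character(0)))
  }
  aa_pool <- c("G", "A", "S", "P", "V", "T", "L", "N", "D", "Q", "E", "H",
               "F", "Y", "W", "M", "I")
  withr::with_seed(seed, {
    seqs <- character(0)
    charges <- integer(0)
    while (length(seqs) < n_peptides) {
      need <- n_peptides - length(seqs)
      len <- sample(7:16, need, replace = TRUE)
      cand <- vapply(len, function(l) {
        paste0(paste(sample(aa_pool, l - 1, replace = TRUE), collapse = ""),
               sample(c("K", "R"), 1))
      }, character(1))
      z <- sample(2:3, need, replace = TRUE)
      mz <- vapply(seq_along(cand), function(i) {
        precursor_mz(cand[i], z[i])
      }, numeric(1))
      ok <- mz >= mz_range_th[1] & mz <= mz_range_th[2] & !duplicated(cand) &
        !cand %in% seqs
      seqs <- c(seqs, cand[ok])
      charges <- c(charges, z[ok])
    }
    seqs <- seqs[seq_len(n_peptides)]
    charges <- charges[seq_len(n_peptides)]
    amounts <- pmin(rlnorm(n_peptides, meanlog = abundance_meanlog,
                           sdlog = abundance_sdlog), abundance_cap_fmol)
    rts <- runif(n_peptides, rt_range_s[1], rt_range_s[2])
  })
  species_tbl(seqs, charges, "light", amounts, rts, peak_sigma_s,
              protein = paste0("BG_", seq_len(n_peptides)))
}

#' Build a dilution series of samples
#'
#' One sample per light level: light members of every pair are set to the
#' level, heavy members are held constant (the spiked reference), and the
#' background matrix is identical across samples.
#'
#' @param pairs Species tibble of heavy/light pairs (e.g. rows from
#'   [make_pair()]).
#' @param light_levels_fmol Numeric vector of light amounts, sorted
#'   descending; zero is allowed.
#' @param heavy_level_fmol Constant heavy spike amount (default 100 fmol).
#' @param background Optional species tibble appended unchanged to every
#'   sample.
#' @param seed Integer recorded with each sample for reproducibility.
#' @return A nested tibble with columns `name`, `light_level_fmol`, `seed`
#'   and a `species` list-column of per-sample species tibbles.
#' @export
dilution_series <- function(pairs, light_levels_fmol,
                            heavy_level_fmol = 100, background = NULL,
                            seed = 1) {
  if (any(light_levels_fmol < 0) || heavy_level_fmol < 0) {
    stop("levels must be >= 0", call. = FALSE)
  }
  if (is.unsorted(rev(light_levels_fmol), strictly = FALSE)) {
    stop("light_levels_fmol must be sorted descending", call. = FALSE)
  }
  samples <- purrr::map(light_levels_fmol, function(level) {
    sp <- dplyr::mutate(
      pairs,
      amount_fmol = ifelse(.data$label == "light", level, heavy_level_fmol)
    )
    if (!is.null(background) && nrow(background) > 0) {
      sp <- dplyr::bind_rows(sp, background)
    }
    sp
  })
  tibble::tibble(
    name = sprintf("dilution_%g_fmol", light_levels_fmol),
    light_level_fmol = light_levels_fmol,
    seed = seed,
    species = samples
  )
}

#' Gaussian elution flux of a species
#'
#' Ion flux (charge units per second) at time `t` for a symmetric Gaussian
#' elution profile: `A * exp(-(t - rt_apex)^2 / (2 sigma^2))` with amplitude
#' `A = amount * k / (sigma * sqrt(2 pi))`, so the time integral is
#' proportional to amount with a single global constant `k`.
#'
#' @param species One-row species tibble or list with `amount_fmol`,
#'   `rt_apex_s`, `peak_sigma_s`.
#' @param t Time (seconds), vectorised.
#' @return Flux in charges per second.
#' @export
elution_flux <- function(species, t) {
  species <- as.list(species)
  a <- species$amount_fmol * .flux_per_fmol /
    (species$peak_sigma_s * sqrt(2 * pi))
  a * exp(-(t - species$rt_apex_s)^2 / (2 * species$peak_sigma_s^2))
}

# Vectorised flux over all rows of a species tibble at scalar time t.
.flux_at <- function(species, t) {
  a <- species$amount_fmol * .flux_per_fmol /
    (species$peak_sigma_s * sqrt(2 * pi))
  a * exp(-(t - species$rt_apex_s)^2 / (2 * species$peak_sigma_s^2))
}

#' Write / read a sample definition as TSV
#'
#' Round-trips the defining columns (`id`, `sequence`, `charge`, `label`,
#' `amount_fmol`, `rt_s`, `sigma_s`); derived quantities (precursor m/z,
#' mass, fragment sets) are recomputed on read, so write-then-read is the
#' identity on species tibbles.
#'
#' @param species Species tibble.
#' @param path File path.
#' @return `write_sample_tsv` returns `path` invisibly; `read_sample_tsv`
#'   returns a species tibble.
#' @export
write_sample_tsv <- function(species, path) {
  out <- tibble::tibble(
    id = species$id, sequence = species$sequence, charge = species$charge,
    label = species$label, amount_fmol = species$amount_fmol,
    rt_s = species$rt_apex_s, sigma_s = species$peak_sigma_s,
    protein = species$protein
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sample_tsv
#' @export
read_sample_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  .assert_cols(raw, c("sequence", "charge", "label", "amount_fmol",
                      "rt_s", "sigma_s"), "sample TSV")
  species_tbl(raw$sequence, raw$charge, raw$label, raw$amount_fmol,
              raw$rt_s, raw$sigma_s,
              protein = raw$protein %||% raw$sequence)
}
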