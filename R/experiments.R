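# Experiment presets: the three study designs — a heavy/light dilution
# series compared across acquisition modes, a target-count stress test of
# the duty cycle, and a clinical-style marker panel producing side-by-side
# DIA and hybrid data matrices.

.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647L) + 1L
}

#' Generate a synthetic heavy/light pair panel
#'
#' Random tryptic-like peptide pairs with retention-time apexes spread over
#' a window; a convenience generator for experiment presets.
#'
#' @param n_pairs Number of pairs.
#' @param rt_range_s Apex range (seconds).
#' @param light_amount_fmol,heavy_amount_fmol Initial channel amounts.
#' @param peak_sigma_s Peak sigma (seconds).
#' @param seed Integer seed.
#' @return Species tibble with two rows per pair.
#' @export
make_pair_panel <- function(n_pairs, rt_range_s = c(600, 6600),
                            light_amount_fmol = 100,
                            heavy_amount_fmol = 100, peak_sigma_s = 6,
                            seed = 1) {
  base <- generate_background(
    n_pairs, rt_range_s = rt_range_s,
    mz_range_th = c(420, 1000), seed = .sub_seed(seed, 17)
  )
  pairs <- purrr::map(seq_len(n_pairs), function(i) {
    make_pair(base$sequence[i], base$charge[i], light_amount_fmol,
              heavy_amount_fmol, base$rt_apex_s[i], peak_sigma_s,
              protein = paste0("P", sprintf("%03d", i)))
  })
  dplyr::bind_rows(pairs)
}

# Quantify every target of a run, one row per target, tagging sample/mode.
.quantify_run <- function(run, targets, min_scans = 3) {
  if (run$mode == "dia") {
    res <- dplyr::bind_rows(purrr::map(seq_len(nrow(targets)), function(i) {
      dia_detect_pair(run, targets[i, ], min_scans = min_scans)
    }))
    res$amount_estimate_fmol <- NA_real_
    res$ratio <- NA_real_
    res
  } else {
    dplyr::bind_rows(purrr::map(seq_len(nrow(targets)), function(i) {
      quantify_pair(run, targets[i, ], min_scans = min_scans)
    }))
  }
}

#' Run the dilution-series comparison experiment
#'
#' Measures the same heavy/light panel at several light dilution levels with
#' a constant heavy spike, in up to three acquisition modes run on identical
#' samples and seeds, and summarises per (level, mode): detection rate,
#' median CV of the light signal over replicates, and median relative error
#' of the absolute-amount estimate (targeted modes only).
#'
#' @param pairs Pair panel (default: 20 synthetic pairs).
#' @param light_levels_fmol Descending light levels (default 100 to 0.01
#'   fmol).
#' @param heavy_level_fmol Constant heavy spike (default 100 fmol).
#' @param background Background species tibble (default: 2000-peptide
#'   synthetic matrix over the run).
#' @param n_replicates Technical replicates per level (default 3).
#' @param modes Acquisition modes to run.
#' @param config A [method_config()].
#' @param run_length_s Run length (seconds; default from config).
#' @param seed Master seed.
#' @return List of class `dilution_experiment`: `summary` (per level x
#'   mode), `results` (per target x replicate), `targets`, `samples`.
#' @export
run_dilution_experiment <- function(pairs = NULL,
                                    light_levels_fmol = c(100, 10, 1, 0.1,
                                                          0.01),
                                    heavy_level_fmol = 100,
                                    background = NULL, n_replicates = 3,
                                    modes = c("hybrid", "dia", "prm"),
                                    config = method_config(),
                                    run_length_s = NULL, seed = 1) {
  stopifnot(length(light_levels_fmol) >= 2, n_replicates >= 2)
  run_length_s <- run_length_s %||% config$run_length_s
  pairs <- pairs %||% make_pair_panel(
    20, rt_range_s = c(0.1, 0.9) * run_length_s,
    heavy_amount_fmol = heavy_level_fmol, seed = seed
  )
  background <- background %||% generate_background(
    2000, rt_range_s = c(0, run_length_s), seed = .sub_seed(seed, 1)
  )
  samples <- dilution_series(pairs, light_levels_fmol, heavy_level_fmol,
                             background, seed = seed)
  targets <- targets_from_pairs(
    dplyr::mutate(pairs, amount_fmol = ifelse(.data$label == "light",
                                              .data$amount_fmol,
                                              heavy_level_fmol))
  )
  grid <- tidyr::expand_grid(
    level_idx = seq_len(nrow(samples)),
    replicate = seq_len(n_replicates),
    mode = modes
  )
  results <- purrr::pmap(grid, function(level_idx, replicate, mode) {
    run <- run_acquisition(
      samples$species[[level_idx]], config, mode, targets,
      run_length_s = run_length_s,
      seed = .sub_seed(seed, level_idx * 100 + replicate)
    )
    res <- .quantify_run(run, targets)
    res$nominal_fmol <- samples$light_level_fmol[level_idx]
    res$mode <- mode
    res$replicate <- replicate
    res
  })
  results <- dplyr::bind_rows(results)
  summary <- results |>
    dplyr::group_by(.data$nominal_fmol, .data$mode) |>
    dplyr::summarise(
      detection_rate = mean(.data$status == "quantified"),
      median_recovery_error = median(
        abs(.data$amount_estimate_fmol - .data$nominal_fmol) /
          .data$nominal_fmol, na.rm = TRUE
      ),
      .groups = "drop"
    )
  cvs <- results |>
    dplyr::group_by(.data$nominal_fmol, .data$mode, .data$target_id) |>
    dplyr::summarise(
      cv = if (sum(.data$light_area > 0) >= 2) {
        replicate_cv(.data$light_area[.data$light_area > 0])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$nominal_fmol, .data$mode) |>
    dplyr::summarise(median_cv = median(.data$cv, na.rm = TRUE),
                     .groups = "drop")
  summary <- dplyr::left_join(summary, cvs, by = c("nominal_fmol", "mode"))
  structure(
    list(summary = summary, results = results, targets = targets,
         samples = samples, seed = seed),
    class = "dilution_experiment"
  )
}

#' Run the target-count stress experiment
#'
#' Runs hybrid acquisition with growing panel sizes over a common background
#' and reports, per size: completed DIA cycles, MSxPRM scan count, and the
#' fraction of targets with replicate CVs at or below 20% and 10%. A size of
#' zero reduces to standalone DIA.
#'
#' @param panel_sizes Ascending panel sizes (default 60, 120, 179).
#' @param pairs Pair panel of at least `max(panel_sizes)` pairs (default:
#'   synthetic, light and heavy both at 100 fmol).
#' @param background Background species tibble.
#' @param n_replicates Replicates per size (default 2).
#' @param config A [method_config()].
#' @param run_length_s Run length (seconds).
#' @param seed Master seed.
#' @return List of class `stress_experiment` with `summary` and `results`.
#' @export
run_target_count_stress <- function(panel_sizes = c(60, 120, 179),
                                    pairs = NULL, background = NULL,
                                    n_replicates = 2,
                                    config = method_config(),
                                    run_length_s = NULL, seed = 1) {
  stopifnot(!is.unsorted(panel_sizes))
  run_length_s <- run_length_s %||% config$run_length_s
  n_max <- max(panel_sizes)
  pairs <- pairs %||% make_pair_panel(
    n_max, rt_range_s = c(0.1, 0.9) * run_length_s, seed = seed
  )
  background <- background %||% generate_background(
    2000, rt_range_s = c(0, run_length_s), seed = .sub_seed(seed, 1)
  )
  plan <- plan_dia_cycle(config$scan_range[1], config$scan_range[2],
                         config$dia_window_width, config$ms2_per_ms1)
  per_size <- purrr::map(seq_along(panel_sizes), function(si) {
    size <- panel_sizes[si]
    pair_ids <- unique(pairs$sequence)[seq_len(max(size, 0))]
    sub_pairs <- dplyr::filter(pairs, .data$sequence %in% pair_ids)
    sample <- dplyr::bind_rows(sub_pairs, background)
    targets <- if (size > 0) targets_from_pairs(sub_pairs) else
      empty_targets()
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      run <- run_acquisition(sample, config, "hybrid", targets,
                             run_length_s = run_length_s,
                             seed = .sub_seed(seed, si * 100 + r))
      res <- if (size > 0) .quantify_run(run, targets) else NULL
      list(
        cycles = floor(sum(run$scans$type == "DIA_MS2") /
                         nrow(plan$windows)),
        msxprm = sum(run$scans$type == "MSxPRM"),
        res = res
      )
    })
    cv_tbl <- if (size > 0) {
      dplyr::bind_rows(purrr::imap(reps, function(r, i) {
        dplyr::mutate(r$res, replicate = i)
      })) |>
        dplyr::group_by(.data$target_id) |>
        dplyr::summarise(
          cv = if (sum(.data$light_area > 0) >= 2) {
            replicate_cv(.data$light_area[.data$light_area > 0])
          } else {
            NA_real_
          },
          identified = all(.data$status == "quantified"),
          .groups = "drop"
        )
    } else {
      tibble::tibble(target_id = character(0), cv = numeric(0),
                     identified = logical(0))
    }
    tibble::tibble(
      panel_size = size,
      dia_cycles = mean(purrr::map_dbl(reps, "cycles")),
      msxprm_scans = mean(purrr::map_dbl(reps, "msxprm")),
      n_identified = sum(cv_tbl$identified),
      frac_cv_le_20 = if (size > 0) {
        mean(!is.na(cv_tbl$cv) & cv_tbl$cv <= 20)
      } else {
        NA_real_
      },
      frac_cv_le_10 = if (size > 0) {
        mean(!is.na(cv_tbl$cv) & cv_tbl$cv <= 10)
      } else {
        NA_real_
      }
    )
  })
  structure(
    list(summary = dplyr::bind_rows(per_size), pairs = pairs, seed = seed),
    class = "stress_experiment"
  )
}

#' Run the clinical marker-panel experiment
#'
#' A panel of heavy/light pairs is measured over many synthetic "patient"
#' samples whose light (endogenous) abundances are randomised log-uniformly
#' over four decades with a fraction of structural zeros, while the heavy
#' spike stays constant. DIA and hybrid acquisitions run side by side on
#' identical samples; both quantification matrices and a completeness
#' summary are returned. In the hybrid arm, samples with an absent light
#' peptide appear as `below_LOD` (the heavy reference still triggers),
#' whereas the DIA arm can only call them `missing`.
#'
#' @param n_pairs Panel size (default 30).
#' @param n_samples Number of samples (default 30).
#' @param heavy_level_fmol Constant heavy spike.
#' @param zero_fraction Fraction of structural zeros among light abundances.
#' @param abundance_range_fmol Log-uniform range of nonzero light abundances.
#' @param n_replicates Hybrid technical replicates per sample (default 2).
#' @param background Background species tibble.
#' @param config A [method_config()].
#' @param run_length_s Run length (seconds).
#' @param seed Master seed.
#' @return List of class `marker_panel_experiment`: `matrix_hybrid`,
#'   `matrix_dia`, `completeness` tibble, `results`, `truth`.
#' @export
run_marker_panel <- function(n_pairs = 30, n_samples = 30,
                             heavy_level_fmol = 100, zero_fraction = 0.2,
                             abundance_range_fmol = c(0.01, 100),
                             n_replicates = 2, background = NULL,
                             config = method_config(), run_length_s = NULL,
                             seed = 1) {
  run_length_s <- run_length_s %||% config$run_length_s
  pairs <- make_pair_panel(n_pairs,
                           rt_range_s = c(0.1, 0.9) * run_length_s,
                           heavy_amount_fmol = heavy_level_fmol, seed = seed)
  background <- background %||% generate_background(
    2000, rt_range_s = c(0, run_length_s), seed = .sub_seed(seed, 1)
  )
  targets <- targets_from_pairs(pairs)
  light_idx <- which(pairs$label == "light")
  truth <- withr::with_seed(.sub_seed(seed, 2), {
    purrr::map(seq_len(n_samples), function(s) {
      amt <- 10^runif(n_pairs, log10(abundance_range_fmol[1]),
                      log10(abundance_range_fmol[2]))
      amt[runif(n_pairs) < zero_fraction] <- 0
      amt
    })
  })
  results <- purrr::map(seq_len(n_samples), function(s) {
    sp <- pairs
    sp$amount_fmol[light_idx] <- truth[[s]]
    sample <- dplyr::bind_rows(sp, background)
    per_mode <- purrr::map(c("hybrid", "dia"), function(mode) {
      n_rep <- if (mode == "hybrid") n_replicates else 1
      purrr::map(seq_len(n_rep), function(r) {
        run <- run_acquisition(sample, config, mode, targets,
                               run_length_s = run_length_s,
                               seed = .sub_seed(seed, s * 100 + r +
                                                  (mode == "dia") * 50))
        res <- .quantify_run(run, targets)
        res$sample <- sprintf("S%02d", s)
        res$replicate <- r
        res$mode <- mode
        res
      })
    })
    dplyr::bind_rows(purrr::flatten(per_mode))
  })
  results <- dplyr::bind_rows(results)
  first_rep <- dplyr::filter(results, .data$replicate == 1)
  mat_hybrid <- quant_matrix(dplyr::filter(first_rep,
                                           .data$mode == "hybrid"))
  dia_res <- dplyr::filter(first_rep, .data$mode == "dia")
  mat_dia <- quant_matrix(dia_res)
  comp <- tibble::tibble(
    mode = c("hybrid", "dia"),
    completeness_quantified = c(completeness(mat_hybrid),
                                completeness(mat_dia)),
    completeness_with_below_lod = c(completeness(mat_hybrid, TRUE),
                                    completeness(mat_dia, TRUE))
  )
  structure(
    list(matrix_hybrid = mat_hybrid, matrix_dia = mat_dia,
         completeness = comp, results = results, truth = truth,
         targets = targets, seed = seed),
    class = "marker_panel_experiment"
  )
}
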