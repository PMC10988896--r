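# Downstream analysis of a simulated run: extracted ion chromatograms, peak
# integration, heavy/light ratio and absolute-amount estimation, calibration
# curves with limit of detection, replicate CVs, protein rollup and the
# clinical data matrix distinguishing below-LOD from missing cells.

#' Extract an ion chromatogram
#'
#' One point per scan of the requested source type: the summed intensity of
#' all peaks within `ppm_tol` of `mz`. Scans outside `rt_window` are skipped.
#'
#' @param run An `acq_run` from [run_acquisition()].
#' @param mz Trace m/z (Th).
#' @param ppm_tol Mass tolerance (ppm).
#' @param rt_window Optional length-2 numeric (seconds).
#' @param source One of `"ms1_precursor"`, `"msxprm_fragment"`,
#'   `"dia_ms2_fragment"`.
#' @param target_id Optional: restrict MSxPRM traces to one target's scans.
#' @param precursor_mz For `dia_ms2_fragment` traces: keep only scans whose
#'   isolation window contains this precursor m/z (a fragment trace is only
#'   meaningful in the window that fragments its precursor).
#' @return A tibble of class `chromatogram` with `time_s`, `intensity`, and
#'   attributes `mz`, `ppm_tol`, `source`, `noise_floor`.
#' @export
extract_xic <- function(run, mz, ppm_tol = 10, rt_window = NULL,
                        source = c("msxprm_fragment", "ms1_precursor",
                                   "dia_ms2_fragment"),
                        target_id = NULL, precursor_mz = NULL) {
  source <- match.arg(source)
  scans <- run$scans
  sel <- switch(source,
    ms1_precursor = scans$type == "MS1",
    msxprm_fragment = scans$type == "MSxPRM",
    dia_ms2_fragment = scans$type == "DIA_MS2"
  )
  if (!is.null(target_id)) {
    sel <- sel & !is.na(scans$target_id) & scans$target_id == target_id
  }
  if (!is.null(precursor_mz)) {
    holds <- vapply(scans$windows, function(w) {
      !is.null(w) && any(precursor_mz >= w$center - w$width / 2 &
                           precursor_mz < w$center + w$width / 2)
    }, logical(1))
    sel <- sel & holds
  }
  if (!is.null(rt_window)) {
    sel <- sel & scans$start_s >= rt_window[1] & scans$start_s <= rt_window[2]
  }
  idx <- which(sel)
  inten <- vapply(idx, function(i) {
    m <- scans$mz[[i]]
    hit <- abs(m - mz) <= mz * ppm_tol * 1e-6
    sum(scans$intensity[[i]][hit])
  }, numeric(1))
  out <- tibble::tibble(time_s = scans$start_s[idx], intensity = inten)
  class(out) <- c("chromatogram", class(out))
  attr(out, "mz") <- mz
  attr(out, "ppm_tol") <- ppm_tol
  attr(out, "source") <- source
  attr(out, "noise_floor") <- if (length(idx)) {
    max(scans$noise_floor[idx])
  } else {
    NA_real_
  }
  out
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal area over the detected peak boundaries: the contiguous block
#' of points above `snr * noise_floor` around the trace maximum. Traces with
#' fewer than two points above the threshold have zero area.
#'
#' @param chrom A chromatogram tibble (`time_s`, `intensity`).
#' @param noise_floor Baseline counts; defaults to the trace attribute or 0.
#' @param snr Detection multiple of the noise floor (default 3).
#' @return List with `area`, `n_points` (points inside the boundaries) and
#'   `bounds_s`.
#' @export
integrate_peak <- function(chrom, noise_floor = NULL, snr = 3) {
  noise_floor <- noise_floor %||% attr(chrom, "noise_floor") %||% 0
  if (is.na(noise_floor)) noise_floor <- 0
  y <- chrom$intensity
  t <- chrom$time_s
  if (length(y) < 2 || all(y <= 0)) {
    return(list(area = 0, n_points = 0L, bounds_s = c(NA_real_, NA_real_)))
  }
  thr <- snr * noise_floor
  above <- y > thr
  apex <- which.max(y)
  if (!above[apex]) {
    return(list(area = 0, n_points = 0L, bounds_s = c(NA_real_, NA_real_)))
  }
  lo <- apex
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- apex
  while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  if (hi == lo) {
    return(list(area = 0, n_points = 1L, bounds_s = c(t[lo], t[hi])))
  }
  seg_t <- t[lo:hi]
  seg_y <- y[lo:hi]
  area <- sum(diff(seg_t) * (head(seg_y, -1) + tail(seg_y, -1)) / 2)
  list(area = area, n_points = hi - lo + 1L, bounds_s = c(t[lo], t[hi]))
}

#' Quantify a heavy/light pair from a run
#'
#' Sums the integrated areas of the target's declared fragment traces from
#' its MSxPRM scans, per channel. The light/heavy ratio times the spiked
#' heavy amount estimates the endogenous absolute amount. Status encodes the
#' spike-in logic: `quantified` when both channels are detected from at
#' least `min_scans` scan points; `below_LOD` when the heavy reference is
#' detected but the light endogenous partner is not (the reference proves
#' the instrument looked); `missing` when the heavy reference itself never
#' produced a quantifiable trace.
#'
#' @param run An `acq_run`.
#' @param target One target row (tibble).
#' @param spiked_heavy_fmol Heavy spike amount; defaults to the target's
#'   `spiked_heavy_fmol`.
#' @param min_scans Minimum MSxPRM points across the peak (default 3).
#' @param snr Detection multiple of the noise floor.
#' @return One-row tibble: `target_id`, `protein`, `light_area`,
#'   `heavy_area`, `ratio`, `amount_estimate_fmol`, `status`, `n_scans`.
#' @export
quantify_pair <- function(run, target, spiked_heavy_fmol = NULL,
                          min_scans = 3, snr = 3) {
  spiked_heavy_fmol <- spiked_heavy_fmol %||% target$spiked_heavy_fmol
  fr <- target$fragments[[1]]
  rtw <- c(target$rt_start_s, target$rt_end_s)
  # summed trace of the declared fragments per channel (one point per scan)
  sum_trace <- function(mzs) {
    traces <- purrr::map(mzs, function(m) {
      extract_xic(run, m, run$config$ppm_tol, rtw,
                  "msxprm_fragment", target$target_id)
    })
    base <- traces[[1]]
    if (length(traces) > 1) {
      base$intensity <- Reduce(`+`, purrr::map(traces, "intensity"))
    }
    base
  }
  heavy_tr <- sum_trace(fr$heavy_mz)
  light_tr <- sum_trace(fr$light_mz)
  floor_counts <- attr(heavy_tr, "noise_floor")
  if (is.na(floor_counts)) floor_counts <- run$config$noise_floor
  # peak boundaries come from the heavy reference and are applied to both
  # channels (reference-guided integration keeps the ratio unbiased even
  # when the light signal dips below the detection threshold at the edges)
  hp <- integrate_peak(heavy_tr, noise_floor = floor_counts, snr = snr)
  heavy_ok <- hp$area > 0 && hp$n_points >= min_scans
  light_area <- 0
  light_n <- 0L
  if (heavy_ok) {
    sel <- light_tr$time_s >= hp$bounds_s[1] &
      light_tr$time_s <= hp$bounds_s[2]
    tt <- light_tr$time_s[sel]
    yy <- light_tr$intensity[sel]
    if (sum(sel) >= 2) {
      light_area <- sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
    }
    light_n <- sum(yy > snr * floor_counts)
  }
  light_ok <- heavy_ok && light_area > 0 && light_n >= min_scans
  status <- if (heavy_ok && light_ok) {
    "quantified"
  } else if (heavy_ok) {
    "below_LOD"
  } else {
    "missing"
  }
  ratio <- if (heavy_ok && light_ok) light_area / hp$area else NA_real_
  tibble::tibble(
    target_id = target$target_id,
    protein = target$protein %||% target$target_id,
    light_area = if (light_ok) light_area else 0,
    heavy_area = hp$area,
    ratio = ratio,
    amount_estimate_fmol = ratio * spiked_heavy_fmol,
    status = status,
    n_scans = max(hp$n_points, light_n)
  )
}

#' DIA-side detection of a pair
#'
#' The comparison arm's simple detection rule (a stand-in for spectral
#' library search): a channel counts as DIA-detected when its precursor
#' MS1 trace and at least `min_fragments` of its declared fragment traces in
#' the matching DIA window have an integrable peak above the noise floor.
#'
#' @inheritParams quantify_pair
#' @param min_fragments Minimum detected fragment traces (default 3).
#' @return One-row tibble: `target_id`, `protein`, `light_detected`,
#'   `heavy_detected`, `light_area`, `status` (quantified / missing; DIA has
#'   no spike-in logic to call below-LOD).
#' @export
dia_detect_pair <- function(run, target, min_fragments = 3, min_scans = 3,
                            snr = 3) {
  fr <- target$fragments[[1]]
  rtw <- c(target$rt_start_s, target$rt_end_s)
  detect_channel <- function(prec_mz, frag_mz) {
    prec <- integrate_peak(
      extract_xic(run, prec_mz, run$config$ppm_tol, rtw, "ms1_precursor"),
      snr = snr
    )
    if (prec$area <= 0 || prec$n_points < min_scans) {
      return(list(ok = FALSE, area = 0))
    }
    fa <- purrr::map(frag_mz, function(m) {
      integrate_peak(
        extract_xic(run, m, run$config$ppm_tol, rtw, "dia_ms2_fragment",
                    precursor_mz = prec_mz),
        snr = snr
      )
    })
    n_det <- sum(purrr::map_dbl(fa, "area") > 0 &
                   purrr::map_int(fa, "n_points") >= min_scans)
    list(ok = n_det >= min_fragments, area = sum(purrr::map_dbl(fa, "area")))
  }
  light <- detect_channel(target$light_mz, fr$light_mz)
  heavy <- detect_channel(target$heavy_mz, fr$heavy_mz)
  tibble::tibble(
    target_id = target$target_id,
    protein = target$protein %||% target$target_id,
    light_detected = light$ok, heavy_detected = heavy$ok,
    light_area = light$area,
    status = ifelse(light$ok, "quantified", "missing")
  )
}

#' Fit a calibration curve and estimate the limit of detection
#'
#' Least squares on log10(nominal amount) versus log10(measured light/heavy
#' ratio), fitted on quantified points only. The LOD is detection-based by
#' default: the smallest nominal level quantified in at least half of its
#' replicates. A blank-based mode (`lod_mode = "blank_3sd"`) instead takes
#' the lowest level whose mean ratio exceeds the zero-level mean plus three
#' standard deviations.
#'
#' @param results Tibble of dilution [quantify_pair()] rows with a
#'   `nominal_fmol` column (replicates allowed).
#' @param spiked_heavy_fmol Heavy spike amount (for reporting).
#' @param lod_mode `"detection"` or `"blank_3sd"`.
#' @return Object of class `calibration_curve`: points, `slope`,
#'   `intercept`, `r_squared`, `lod_fmol`, `lod_label`, `fit_ok`.
#' @export
fit_calibration <- function(results, spiked_heavy_fmol = 100,
                            lod_mode = c("detection", "blank_3sd")) {
  lod_mode <- match.arg(lod_mode)
  .assert_cols(results, c("nominal_fmol", "ratio", "status"), "results")
  det <- dplyr::filter(results, .data$status == "quantified",
                       .data$nominal_fmol > 0, .data$ratio > 0)
  fit_ok <- dplyr::n_distinct(det$nominal_fmol) >= 3
  slope <- intercept <- r2 <- NA_real_
  if (fit_ok) {
    m <- lm(log10(ratio) ~ log10(nominal_fmol), data = det)
    slope <- unname(coef(m)[2])
    intercept <- unname(coef(m)[1])
    r2 <- summary(m)$r.squared
  }
  lod <- if (lod_mode == "detection") {
    per_level <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(results, .data$nominal_fmol > 0),
                      .data$nominal_fmol),
      det_frac = mean(.data$status == "quantified"), .groups = "drop"
    )
    ok <- per_level$nominal_fmol[per_level$det_frac >= 0.5]
    if (length(ok)) min(ok) else NA_real_
  } else {
    blank <- dplyr::filter(results, .data$nominal_fmol == 0)
    thr <- if (nrow(blank) >= 2) {
      mean(blank$ratio, na.rm = TRUE) + 3 * sd(blank$ratio, na.rm = TRUE)
    } else {
      0
    }
    if (is.na(thr)) thr <- 0
    per_level <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(results, .data$nominal_fmol > 0),
                      .data$nominal_fmol),
      mean_ratio = mean(.data$ratio, na.rm = TRUE), .groups = "drop"
    )
    ok <- per_level$nominal_fmol[!is.na(per_level$mean_ratio) &
                                   per_level$mean_ratio > thr]
    if (length(ok)) min(ok) else NA_real_
  }
  structure(
    list(points = results, slope = slope, intercept = intercept,
         r_squared = r2, lod_fmol = lod,
         lod_label = if (is.na(lod)) NA_character_ else
           sprintf("< %.4g fmol/μl", lod),
         fit_ok = fit_ok, spiked_heavy_fmol = spiked_heavy_fmol,
         lod_mode = lod_mode),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> log-log slope =", round(x$slope, 4),
      "| r^2 =", round(x$r_squared, 5), "\n")
  cat("  LOD (", x$lod_mode, ") =", x$lod_fmol, "fmol; below-LOD report:",
      x$lod_label, "\n")
  if (!x$fit_ok) cat("  [unfit: fewer than 3 detected levels]\n")
  invisible(x)
}

#' Coefficient of variation across replicates
#'
#' `100 * sd / mean` (sample standard deviation). A zero or undefined mean
#' yields `NA`.
#'
#' @param x Numeric vector of replicate measurements (length >= 2).
#' @return CV in percent.
#' @export
replicate_cv <- function(x) {
  if (length(x) < 2) stop("need >= 2 replicates", call. = FALSE)
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * sd(x) / m
}

#' Roll peptide quantities up to a protein
#'
#' Protein quantity is the mean of its quantified peptides' amounts. A
#' protein whose peptides are all below the LOD inherits `below_LOD`; one
#' with no detected heavy reference at all is `missing`.
#'
#' @param peptides Tibble with `amount_estimate_fmol` and `status` for one
#'   protein.
#' @return One-row tibble `value`, `status`, `n_peptides`.
#' @export
protein_rollup <- function(peptides) {
  stopifnot(nrow(peptides) >= 1)
  q <- dplyr::filter(peptides, .data$status == "quantified")
  if (nrow(q) > 0) {
    tibble::tibble(value = mean(q$amount_estimate_fmol),
                   status = "quantified", n_peptides = nrow(q))
  } else if (any(peptides$status == "below_LOD")) {
    tibble::tibble(value = NA_real_, status = "below_LOD",
                   n_peptides = 0L)
  } else {
    tibble::tibble(value = NA_real_, status = "missing", n_peptides = 0L)
  }
}

#' Build a protein x sample quantification matrix
#'
#' @param results Tibble of per-(sample, target) quantification rows with
#'   columns `sample`, `protein`, `amount_estimate_fmol`, `status`.
#' @return Long tibble of class `quant_matrix`: `protein`, `sample`,
#'   `value`, `status`.
#' @export
quant_matrix <- function(results) {
  .assert_cols(results, c("sample", "protein", "amount_estimate_fmol",
                          "status"), "results")
  out <- results |>
    dplyr::group_by(.data$protein, .data$sample) |>
    dplyr::group_modify(~ protein_rollup(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("protein", "sample", "value", "status")
  class(out) <- c("quant_matrix", class(out))
  out
}

#' Data completeness of a quantification matrix
#'
#' Percent of cells with status `quantified`; with
#' `count_below_lod_as_informative = TRUE`, below-LOD cells also count
#' (the spike-in reference proves they are true negatives, not technical
#' dropouts).
#'
#' @param matrix A [quant_matrix()] (long tibble with `status`).
#' @param count_below_lod_as_informative Logical flag.
#' @return Completeness in percent.
#' @export
completeness <- function(matrix, count_below_lod_as_informative = FALSE) {
  if (nrow(matrix) == 0) stop("matrix is empty", call. = FALSE)
  ok <- matrix$status == "quantified"
  if (count_below_lod_as_informative) {
    ok <- ok | matrix$status == "below_LOD"
  }
  100 * mean(ok)
}

#' Write a quantification matrix as TSV
#'
#' Wide layout with paired `<sample>_value` / `<sample>_status` columns.
#'
#' @param matrix A [quant_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix_tsv <- function(matrix, path) {
  wide <- tidyr::pivot_wider(
    matrix, id_cols = "protein", names_from = "sample",
    values_from = c("value", "status"), names_glue = "{sample}_{.value}"
  )
  readr::write_tsv(wide, path)
  invisible(path)
}
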