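# Run export: scan-log TSV, centroided mzML, and YAML method configuration.

#' Write the scan log of a run as TSV
#'
#' One row per executed scan: start time, scan type, provenance, target,
#' isolation windows (`center:width` pairs, `;`-separated), injection time
#' and duration.
#'
#' @param run An `acq_run`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scan_log <- function(run, path) {
  s <- run$scans
  out <- tibble::tibble(
    scan_id = s$scan_id, start_s = s$start_s, type = s$type,
    provenance = s$provenance, target_id = s$target_id,
    windows = vapply(s$windows, function(w) {
      if (is.null(w)) "" else
        paste(sprintf("%.4f:%.2f", w$center, w$width), collapse = ";")
    }, character(1)),
    injection_ms = s$injection_ms, duration_s = s$duration_s,
    n_peaks = vapply(s$mz, length, integer(1))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export a run as centroided mzML
#'
#' Writes every scan's spectrum with retention time, MS level, injection
#' time and (for MS2-type scans) the first isolation window as precursor
#' metadata. Requires the mzR package.
#'
#' @param run An `acq_run`.
#' @param path Output .mzML path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML export needs the mzR package", call. = FALSE)
  }
  s <- run$scans
  n <- nrow(s)
  if (n == 0) stop("run holds no scans", call. = FALSE)
  peaks <- purrr::map(seq_len(n), function(i) {
    cbind(mz = s$mz[[i]], intensity = s$intensity[[i]])
  })
  ms_level <- ifelse(s$type == "MS1", 1L, 2L)
  iso <- purrr::map(s$windows, function(w) {
    if (is.null(w)) c(NA_real_, NA_real_) else c(w$center[1], w$width[1] / 2)
  })
  iso_mz <- vapply(iso, `[`, numeric(1), 1)
  iso_off <- vapply(iso, `[`, numeric(1), 2)
  npk <- vapply(peaks, nrow, integer(1))
  base_idx <- vapply(seq_len(n), function(i) {
    if (npk[i] == 0) NA_integer_ else which.max(s$intensity[[i]])
  }, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = ms_level,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(s$intensity, sum, numeric(1)),
    retentionTime = s$start_s,
    basePeakMZ = vapply(seq_len(n), function(i) {
      if (is.na(base_idx[i])) 0 else s$mz[[i]][base_idx[i]]
    }, numeric(1)),
    basePeakIntensity = vapply(seq_len(n), function(i) {
      if (is.na(base_idx[i])) 0 else s$intensity[[i]][base_idx[i]]
    }, numeric(1)),
    collisionEnergy = ifelse(ms_level == 2L, 30, NA_real_),
    ionisationEnergy = 0,
    lowMZ = vapply(s$mz, function(m) if (length(m)) min(m) else 0,
                   numeric(1)),
    highMZ = vapply(s$mz, function(m) if (length(m)) max(m) else 0,
                    numeric(1)),
    precursorScanNum = NA_integer_, precursorMZ = iso_mz,
    precursorCharge = NA_integer_, precursorIntensity = NA_real_,
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_,
    mergedResultEndScanNum = NA_integer_,
    injectionTime = s$injection_ms,
    filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = iso_mz,
    isolationWindowLowerOffset = iso_off,
    isolationWindowUpperOffset = iso_off,
    scanWindowLowerLimit = run$config$scan_range[1],
    scanWindowUpperLimit = run$config$scan_range[2]
  )
  # empty spectra are not representable; give them a single zero peak
  for (i in which(npk == 0)) {
    peaks[[i]] <- cbind(mz = run$config$scan_range[1], intensity = 0)
    hdr$peaksCount[i] <- 1L
  }
  mzR::writeMSData(peaks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Write / read a method configuration as YAML
#'
#' Field names mirror the acquisition method parameters (`scan_range`,
#' `dia_window_width`, `ms2_per_ms1`, resolutions, AGC targets, injection
#' times, `ppm_tol`, `intensity_threshold`, `exclusion_s`, ...).
#'
#' @param config A [method_config()].
#' @param path File path.
#' @return `write_method_config` returns `path` invisibly;
#'   `read_method_config` returns a [method_config()].
#' @export
write_method_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_method_config
#' @export
read_method_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(method_config, vals)
}
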