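# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an acquisition run into its scan log
#'
#' @param x An `acq_run`.
#' @param ... Unused.
#' @return Scan-log tibble (one row per scan, spectra dropped).
#' @method tidy acq_run
#' @export
tidy.acq_run <- function(x, ...) {
  dplyr::select(x$scans, "scan_id", "type", "provenance", "target_id",
                "start_s", "injection_ms", "duration_s")
}

#' One-row run summary
#'
#' @param x An `acq_run`.
#' @param ... Unused.
#' @return Tibble: mode, total scans by type, triggers, clock.
#' @method glance acq_run
#' @export
glance.acq_run <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_scans = nrow(x$scans),
    n_ms1 = sum(x$scans$type == "MS1"),
    n_dia_ms2 = sum(x$scans$type == "DIA_MS2"),
    n_validation = sum(x$scans$type == "VALIDATION_MS2"),
    n_msxprm = sum(x$scans$type == "MSxPRM"),
    n_triggers_acquired = sum(x$trigger_log$event == "acquired"),
    run_length_s = x$run_length_s,
    clock_s = x$clock
  )
}

#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::as_tibble(x$points)
}

#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, lod_fmol = x$lod_fmol,
                 lod_label = x$lod_label, fit_ok = x$fit_ok,
                 lod_mode = x$lod_mode)
}

#' @method tidy dilution_experiment
#' @export
tidy.dilution_experiment <- function(x, ...) x$results

#' @method glance dilution_experiment
#' @export
glance.dilution_experiment <- function(x, ...) x$summary

#' @method tidy stress_experiment
#' @export
tidy.stress_experiment <- function(x, ...) x$summary

#' @method tidy marker_panel_experiment
#' @export
tidy.marker_panel_experiment <- function(x, ...) x$results

#' @method glance marker_panel_experiment
#' @export
glance.marker_panel_experiment <- function(x, ...) x$completeness

#' Plot an extracted ion chromatogram
#'
#' @param object A chromatogram from [extract_xic()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chromatogram
#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Retention time (s)", y = "Intensity (counts)",
      title = sprintf("XIC m/z %.4f (%s, %.0f ppm)", attr(object, "mz"),
                      attr(object, "source"), attr(object, "ppm_tol"))
    )
}

#' Plot a calibration curve
#'
#' Quantified points and the log-log fit; below-LOD levels appear as open
#' symbols on the baseline.
#'
#' @param object A [fit_calibration()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  pts <- dplyr::filter(object$points, .data$nominal_fmol > 0)
  p <- ggplot2::ggplot(
    dplyr::filter(pts, .data$status == "quantified"),
    ggplot2::aes(.data$nominal_fmol, .data$ratio)
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Nominal amount (fmol)", y = "Light/heavy ratio",
                  subtitle = object$lod_label)
  if (isTRUE(object$fit_ok)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  linetype = 2)
  }
  p
}

#' Plot a quantification matrix as a status heatmap
#'
#' Quantified cells are coloured by log10 amount; below-LOD cells are white,
#' missing cells grey.
#'
#' @param object A [quant_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quant_matrix
#' @export
autoplot.quant_matrix <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    log_value = ifelse(.data$status == "quantified", log10(.data$value),
                       NA_real_)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$protein)) +
    ggplot2::geom_tile(
      ggplot2::aes(fill = .data$log_value),
      colour = "grey80"
    ) +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$status == "below_LOD"),
      fill = "white", colour = "grey80"
    ) +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$status == "missing"),
      fill = "grey50", colour = "grey80"
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey50",
                                  name = "log10 amount") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a target-panel concurrency profile
#'
#' @param object A [max_concurrency()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concurrency_profile
#' @export
autoplot.concurrency_profile <- function(object, ...) {
  df <- tibble::tibble(time_s = object$breakpoints, active = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$active)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Retention time (s)", y = "Active targets",
                  title = sprintf("Peak concurrency: %d parallel targets",
                                  object$maximum))
}
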