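# Trigger-target lists: construction from heavy/light pairs, the tab-
# separated on-disk layout, retention-time-window concurrency profiling, and
# duty-cycle feasibility for growing panel sizes.

#' Empty target tibble
#' @return Zero-row target tibble with the canonical columns.
#' @export
empty_targets <- function() {
  tibble::tibble(
    target_id = character(0), heavy_mz = numeric(0), charge = integer(0),
    rt_start_s = numeric(0), rt_end_s = numeric(0), light_mz = numeric(0),
    fragments = list(), intensity_threshold = numeric(0),
    protein = character(0), spiked_heavy_fmol = numeric(0)
  )
}

#' Build a trigger-target list from heavy/light pairs
#'
#' One target per pair: the heavy species is watched, the light endogenous
#' partner is co-isolated on trigger. Declared fragments are the pair's y
#' ions (the series carrying the C-terminal label, hence channel-specific).
#' Retention-time windows are centred on the true apex.
#'
#' @param pairs Species tibble containing both channels of each pair.
#' @param rt_window_s Total width of the scheduling window (seconds);
#'   default 120 s.
#' @param intensity_threshold Optional per-target MS1 trigger threshold
#'   (counts); `NA` defers to the method default.
#' @return Target tibble.
#' @export
targets_from_pairs <- function(pairs, rt_window_s = 120,
                               intensity_threshold = NA_real_) {
  heavy <- dplyr::filter(pairs, .data$label != "light")
  light <- dplyr::filter(pairs, .data$label == "light")
  key <- paste(light$sequence, light$charge)
  idx <- match(paste(heavy$sequence, heavy$charge), key)
  if (anyNA(idx)) {
    stop("every heavy species needs a light partner (same sequence, charge)",
         call. = FALSE)
  }
  frags <- purrr::map2(heavy$fragments, light$fragments[idx], function(h, l) {
    keep <- h$series == "y"
    tibble::tibble(
      series = h$series[keep], ordinal = h$ordinal[keep],
      heavy_mz = h$mz[keep], light_mz = l$mz[l$series == "y"]
    )
  })
  tibble::tibble(
    target_id = paste(heavy$sequence, heavy$charge, sep = "/"),
    heavy_mz = heavy$precursor_mz, charge = heavy$charge,
    rt_start_s = heavy$rt_apex_s - rt_window_s / 2,
    rt_end_s = heavy$rt_apex_s + rt_window_s / 2,
    light_mz = light$precursor_mz[idx],
    fragments = frags,
    intensity_threshold = intensity_threshold,
    protein = heavy$protein,
    spiked_heavy_fmol = heavy$amount_fmol
  )
}

.label_shift_from_delta <- function(delta_mass) {
  shifts <- c(heavy_K8 = 8.014199, heavy_R10 = 10.008269)
  d <- abs(shifts - delta_mass)
  if (min(d) > 0.01) return(NA_real_)
  shifts[[which.min(d)]]
}

#' Write / parse a trigger-target list
#'
#' The on-disk layout is the triggering API's input table: tab-separated
#' columns `target_id`, `heavy_mz`, `charge`, `rt_start`, `rt_end`,
#' `light_mz`, `fragment_mz_list` (semicolon-separated heavy fragment m/z),
#' plus an optional `intensity_threshold`. An `rt_unit` column header suffix
#' is honoured: columns named `rt_start_min`/`rt_end_min` are converted from
#' minutes to seconds (scheduling tables are commonly authored in minutes).
#' Light fragment m/z are reconstructed from the label mass shift implied by
#' the precursor pair (declared fragments are y ions, which carry the full
#' shift at fragment charge 1).
#'
#' Parsing enforces the row invariants (finite m/z, `rt_end > rt_start`,
#' `light_mz < heavy_mz`, a heavy/light precursor shift consistent with Lys8
#' or Arg10, at least one fragment) and reports the offending row number.
#'
#' @param targets Target tibble.
#' @param path File path.
#' @return `write_target_list` returns `path` invisibly;
#'   `parse_target_list` returns a target tibble.
#' @export
write_target_list <- function(targets, path) {
  out <- tibble::tibble(
    target_id = targets$target_id,
    heavy_mz = sprintf("%.6f", targets$heavy_mz),
    charge = targets$charge,
    rt_start_s = targets$rt_start_s,
    rt_end_s = targets$rt_end_s,
    light_mz = sprintf("%.6f", targets$light_mz),
    fragment_mz_list = vapply(targets$fragments, function(f) {
      paste(sprintf("%.6f", f$heavy_mz), collapse = ";")
    }, character(1)),
    intensity_threshold = targets$intensity_threshold
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_target_list
#' @export
parse_target_list <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  rt_factor <- 1
  if (all(c("rt_start_min", "rt_end_min") %in% names(raw))) {
    names(raw)[match(c("rt_start_min", "rt_end_min"), names(raw))] <-
      c("rt_start_s", "rt_end_s")
    rt_factor <- 60
  }
  .assert_cols(raw, c("target_id", "heavy_mz", "charge", "rt_start_s",
                      "rt_end_s", "light_mz", "fragment_mz_list"),
               "target list")
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    fail <- function(msg) {
      stop("target list row ", i, " (", r$target_id, "): ", msg,
           call. = FALSE)
    }
    num <- function(x, what) {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) fail(paste("malformed", what))
      v
    }
    heavy_mz <- num(r$heavy_mz, "heavy_mz")
    light_mz <- num(r$light_mz, "light_mz")
    charge <- as.integer(num(r$charge, "charge"))
    rt_start <- num(r$rt_start_s, "rt_start") * rt_factor
    rt_end <- num(r$rt_end_s, "rt_end") * rt_factor
    if (rt_end <= rt_start) fail("inverted RT window (rt_end <= rt_start)")
    if (light_mz >= heavy_mz) fail("light_mz must be below heavy_mz")
    shift <- .label_shift_from_delta((heavy_mz - light_mz) * charge)
    if (is.na(shift)) {
      fail("heavy/light precursor shift matches neither Lys8 nor Arg10")
    }
    fr <- suppressWarnings(
      as.numeric(strsplit(r$fragment_mz_list, ";", fixed = TRUE)[[1]])
    )
    if (length(fr) == 0 || anyNA(fr)) fail("missing or malformed fragments")
    thr <- if ("intensity_threshold" %in% names(r)) {
      suppressWarnings(as.numeric(r$intensity_threshold))
    } else {
      NA_real_
    }
    tibble::tibble(
      target_id = r$target_id, heavy_mz = heavy_mz, charge = charge,
      rt_start_s = rt_start, rt_end_s = rt_end, light_mz = light_mz,
      fragments = list(tibble::tibble(
        series = "y", ordinal = NA_integer_,
        heavy_mz = fr, light_mz = fr - shift
      )),
      intensity_threshold = thr,
      protein = r$target_id, spiked_heavy_fmol = NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Concurrency profile of a target panel
#'
#' Sweep-line count of simultaneously scheduled targets: how many
#' retention-time windows overlap at any instant. The maximum is the
#' panel's peak number of parallel MSxPRM events.
#'
#' @param targets Target tibble.
#' @return A list of class `concurrency_profile` with `breakpoints` (sorted
#'   times), `counts` (active targets on each interval between breakpoints),
#'   and `maximum`.
#' @export
max_concurrency <- function(targets) {
  if (nrow(targets) == 0) {
    return(structure(list(breakpoints = numeric(0), counts = integer(0),
                          maximum = 0L),
                     class = "concurrency_profile"))
  }
  ev <- rbind(
    data.frame(t = targets$rt_start_s, d = 1L),
    data.frame(t = targets$rt_end_s, d = -1L)
  )
  # closed windows: at a shared instant, starts count before ends
  ev <- ev[order(ev$t, -ev$d), ]
  run <- cumsum(ev$d)
  bp <- unique(ev$t)
  counts <- vapply(bp, function(x) sum(targets$rt_start_s <= x &
                                         targets$rt_end_s >= x), integer(1))
  structure(
    list(breakpoints = bp, counts = counts, maximum = max(run)),
    class = "concurrency_profile"
  )
}

#' @export
print.concurrency_profile <- function(x, ...) {
  cat("<concurrency_profile> maximum =", x$maximum, "parallel targets over",
      length(x$breakpoints), "breakpoints\n")
  invisible(x)
}

#' Duty-cycle feasibility report
#'
#' Worst-case time budget per time bin: assuming every target active in a
#' bin fires once per dynamic-exclusion period, the fraction of wall time
#' consumed by triggered scans (one fast validation plus one MSxPRM scan per
#' firing) versus DIA, and the resulting stretched DIA cycle time. Bins
#' whose expected cycle time exceeds `cycle_ceiling_s` are flagged.
#'
#' @param targets Target tibble.
#' @param config A [method_config()].
#' @param bin_s Bin width (seconds).
#' @param run_length_s Horizon; defaults to the config run length.
#' @param cycle_ceiling_s Flag threshold for the stretched cycle time.
#' @return Tibble with `time_bin_s`, `n_active`, `dia_time_fraction`,
#'   `triggered_time_fraction`, `expected_cycle_time_s`, `overloaded`.
#' @export
duty_cycle_report <- function(targets, config = method_config(), bin_s = 60,
                              run_length_s = NULL, cycle_ceiling_s = 10) {
  run_length_s <- run_length_s %||% config$run_length_s
  plan <- plan_dia_cycle(config$scan_range[1], config$scan_range[2],
                         config$dia_window_width, config$ms2_per_ms1)
  ms1_dur <- scan_duration(config$ms1_resolution, config$ms1_max_injection_ms)
  ms2_dur <- scan_duration(config$ms2_resolution,
                           config$dia_ms2_max_injection_ms)
  val_dur <- scan_duration(config$validation_resolution,
                           config$validation_max_injection_ms)
  msx_dur <- scan_duration(config$ms2_resolution,
                           config$msxprm_max_injection_ms)
  base_cycle <- plan$ms1_per_cycle * ms1_dur + nrow(plan$windows) * ms2_dur
  trig_cost <- val_dur + msx_dur
  bins <- seq(0, run_length_s - bin_s, by = bin_s)
  n_active <- vapply(bins, function(b) {
    sum(targets$rt_start_s <= b + bin_s & targets$rt_end_s >= b)
  }, integer(1))
  triggered <- pmin(1, n_active * trig_cost / config$exclusion_s)
  tibble::tibble(
    time_bin_s = bins,
    n_active = n_active,
    triggered_time_fraction = triggered,
    dia_time_fraction = 1 - triggered,
    expected_cycle_time_s = ifelse(triggered < 1,
                                   base_cycle / (1 - triggered), Inf),
    overloaded = !(triggered < 1) |
      base_cycle / pmax(1 - triggered, 1e-12) > cycle_ceiling_s
  )
}
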