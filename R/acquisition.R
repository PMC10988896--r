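# The acquisition engine: a state machine that runs DIA cycles and, in
# hybrid mode, interleaves internal-standard-triggered multiplexed PRM
# (MSxPRM) scans. Standalone DIA and scheduled-PRM modes support three-way
# method comparisons on identical samples.

#' Plan a DIA cycle
#'
#' Tiles the precursor scan range with half-open isolation windows of fixed
#' width (the last window may be truncated) and schedules one MS1 scan ahead
#' of every block of `ms2_per_ms1` MS2 scans. With the default method (range
#' 400-1210 Th, 15 Th windows, one MS1 every 18 MS2) a cycle holds 54 MS2
#' windows and 3 MS1 scans.
#'
#' @param low,high Scan range bounds (Th), `high > low`.
#' @param width Isolation window width (Th, > 0).
#' @param ms2_per_ms1 MS2 scans per MS1 scan (>= 1).
#' @return A list of class `dia_cycle_plan` with the window table, the MS1
#'   count and the interleaved scan sequence of one cycle.
#' @export
#' @examples
#' plan <- plan_dia_cycle(400, 1210, 15, 18)
#' nrow(plan$windows)  # 54
#' plan$ms1_per_cycle  # 3
plan_dia_cycle <- function(low, high, width, ms2_per_ms1 = 18) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (high <= low) stop("high must exceed low", call. = FALSE)
  stopifnot(ms2_per_ms1 >= 1)
  n <- ceiling((high - low) / width)
  starts <- low + (seq_len(n) - 1) * width
  ends <- pmin(starts + width, high)
  windows <- tibble::tibble(
    index = seq_len(n),
    low = starts, high = ends,
    center = (starts + ends) / 2,
    width = ends - starts
  )
  ms1 <- ceiling(n / ms2_per_ms1)
  # interleave: MS1, then up to ms2_per_ms1 windows, repeat
  seq_types <- character(0)
  seq_window <- integer(0)
  for (b in seq_len(ms1)) {
    block <- ((b - 1) * ms2_per_ms1 + 1):min(b * ms2_per_ms1, n)
    seq_types <- c(seq_types, "MS1", rep("DIA_MS2", length(block)))
    seq_window <- c(seq_window, NA_integer_, block)
  }
  structure(
    list(windows = windows, ms1_per_cycle = ms1,
         sequence = tibble::tibble(type = seq_types, window = seq_window),
         low = low, high = high, width = width, ms2_per_ms1 = ms2_per_ms1),
    class = "dia_cycle_plan"
  )
}

#' Screen an MS1 spectrum for trigger candidates
#'
#' A watched target becomes a candidate when (a) the clock is inside its
#' retention-time window (closed interval), (b) it is armed (not dynamically
#' excluded), (c) the spectrum holds a peak within `ppm_tol` of the heavy
#' precursor m/z, and (d) that peak's intensity reaches the MS1 intensity
#' threshold (per-target if set, else the method default).
#'
#' @param ms1_spectrum Spectrum list (`mz`, `intensity`) from an MS1 scan.
#' @param watch Watch-state tibble (targets plus `excluded_until_s`).
#' @param t Clock time of the MS1 scan (seconds).
#' @param config A [method_config()].
#' @return Watch-state rows of the candidates, ordered by ascending heavy
#'   precursor m/z, with a `ms1_intensity` column.
#' @export
check_triggers <- function(ms1_spectrum, watch, t, config) {
  if (nrow(watch) == 0) return(watch[0, ])
  thr <- ifelse(is.na(watch$intensity_threshold),
                config$intensity_threshold, watch$intensity_threshold)
  in_rt <- t >= watch$rt_start_s & t <= watch$rt_end_s
  armed <- t >= watch$excluded_until_s
  inten <- vapply(watch$heavy_mz, function(mz) {
    hit <- abs(ms1_spectrum$mz - mz) <= mz * config$ppm_tol * 1e-6
    if (any(hit)) max(ms1_spectrum$intensity[hit]) else 0
  }, numeric(1))
  keep <- in_rt & armed & inten >= thr
  out <- watch[keep, , drop = FALSE]
  out$ms1_intensity <- inten[keep]
  out[order(out$heavy_mz), , drop = FALSE]
}

#' Validate a trigger candidate from a fast MS2 scan
#'
#' The selectivity filter: the candidate is accepted only if at least
#' `min_validated_fragments` of the target's declared heavy fragment m/z
#' values are matched in the validation spectrum within `ppm_tol` at an
#' intensity above the noise floor. This rejects co-eluting background
#' precursors that merely share the heavy precursor m/z.
#'
#' @param validation_spectrum Spectrum list from the fast MS2 scan isolating
#'   the heavy precursor.
#' @param target One watch/target row (with a `fragments` list-column).
#' @param config A [method_config()].
#' @return `TRUE` if validated.
#' @export
validate_candidate <- function(validation_spectrum, target, config) {
  frag <- target$fragments[[1]]$heavy_mz
  floor_counts <- validation_spectrum$noise_floor %||% config$noise_floor
  n_match <- sum(vapply(frag, function(mz) {
    any(abs(validation_spectrum$mz - mz) <= mz * config$ppm_tol * 1e-6 &
          validation_spectrum$intensity > floor_counts)
  }, logical(1)))
  n_match >= config$min_validated_fragments
}

#' Build the MSxPRM scan request for a validated target
#'
#' Exactly two narrow isolation windows (default 1.4 Th) centred on the
#' heavy and light precursor m/z, co-isolating the pair in one multiplexed
#' quantification scan at MS2 resolution with the triggered-scan injection
#' time and AGC target.
#'
#' @param target One target row.
#' @param config A [method_config()].
#' @return A [scan_request()] of type `"MSxPRM"`.
#' @export
emit_msxprm <- function(target, config) {
  w <- config$msxprm_isolation_width
  scan_request(
    "MSxPRM",
    isolation_windows = tibble::tibble(
      center = c(target$heavy_mz, target$light_mz), width = w
    ),
    resolution = config$ms2_resolution,
    max_injection_ms = config$msxprm_max_injection_ms,
    agc_target = config$msxprm_agc
  )
}

# Mutable scan-log accumulator (amortised append).
.new_log <- function(n0 = 256) {
  env <- new.env(parent = emptyenv())
  env$data <- vector("list", n0)
  env$n <- 0L
  env
}
.log_push <- function(env, x) {
  env$n <- env$n + 1L
  if (env$n > length(env$data)) {
    length(env$data) <- 2L * length(env$data)
  }
  env$data[[env$n]] <- x
}
.log_collect <- function(env) {
  if (env$n == 0L) return(NULL)
  dplyr::bind_rows(env$data[seq_len(env$n)])
}

#' Run a simulated acquisition
#'
#' Executes one LC-MS/MS run over a sample in one of three modes:
#' \describe{
#'   \item{`dia`}{DIA cycles only, repeated until the run length.}
#'   \item{`prm`}{time-scheduled MSxPRM scans: each cycle records one MS1
#'     scan and one MSxPRM scan per target whose retention-time window is
#'     active. Cycles whose mandatory scan load exceeds the configured cycle
#'     budget are reported in `schedule_warnings` (never silently dropped).}
#'   \item{`hybrid`}{DIA cycles with a trigger check on every MS1 scan; a
#'     candidate immediately receives a fast validation scan and, if
#'     validated, an MSxPRM scan, after which the target is dynamically
#'     excluded for `exclusion_s`.}
#' }
#' The clock advances by every scan's duration; the full scan log and
#' trigger decision log are returned.
#'
#' @param sample Species tibble (see [make_pair()], [generate_background()]).
#' @param config A [method_config()].
#' @param mode `"dia"`, `"prm"` or `"hybrid"`.
#' @param targets Target tibble (see [targets_from_pairs()] or
#'   [parse_target_list()]); required for `prm`, optional for `hybrid`.
#' @param run_length_s Run length (seconds); defaults to the config value.
#' @param seed Integer seed driving all stochastic instrument noise.
#' @return An object of class `acq_run`: scan log, trigger log, watch state,
#'   configuration and inputs.
#' @export
run_acquisition <- function(sample, config = method_config(),
                            mode = c("hybrid", "dia", "prm"),
                            targets = NULL, run_length_s = NULL, seed = 1) {
  mode <- match.arg(mode)
  run_length_s <- run_length_s %||% config$run_length_s
  targets <- targets %||% empty_targets()
  if (mode == "prm" && nrow(targets) == 0) {
    stop("prm mode needs a non-empty target list", call. = FALSE)
  }
  too_few <- vapply(targets$fragments, nrow, integer(1)) <
    config$min_validated_fragments
  if (any(too_few)) {
    stop("target(s) ", paste(targets$target_id[too_few], collapse = ", "),
         " declare fewer fragments than min_validated_fragments (",
         config$min_validated_fragments, ")", call. = FALSE)
  }

  plan <- plan_dia_cycle(config$scan_range[1], config$scan_range[2],
                         config$dia_window_width, config$ms2_per_ms1)
  sim <- .sim_index(sample)
  watch <- targets
  watch$excluded_until_s <- 0
  watch$trigger_count <- 0L
  if (!"intensity_threshold" %in% names(watch)) {
    watch$intensity_threshold <- NA_real_
  }

  scans <- .new_log(1024)
  trig <- .new_log(64)
  warn <- .new_log(4)
  clock <- 0
  scan_id <- 0L

  record <- function(request, provenance, target_id = NA_character_) {
    spec <- acquire(sim, request, clock, config)
    dur <- scan_duration(request$resolution, spec$injection_ms)
    scan_id <<- scan_id + 1L
    .log_push(scans, list(
      scan_id = scan_id, type = request$scan_type, provenance = provenance,
      target_id = target_id, start_s = clock,
      injection_ms = spec$injection_ms, duration_s = dur,
      windows = request$isolation_windows,
      mz = spec$mz, intensity = spec$intensity,
      noise_floor = spec$noise_floor
    ))
    clock <<- clock + dur
    spec
  }

  ms1_req <- scan_request("MS1", NULL, config$ms1_resolution,
                          config$ms1_max_injection_ms, config$ms1_agc)
  dia_req <- function(widx) {
    w <- plan$windows[widx, ]
    scan_request("DIA_MS2",
                 tibble::tibble(center = w$center, width = w$width),
                 config$ms2_resolution, config$dia_ms2_max_injection_ms,
                 config$ms2_agc)
  }
  val_req <- function(tg) {
    scan_request("VALIDATION_MS2",
                 tibble::tibble(center = tg$heavy_mz,
                                width = config$msxprm_isolation_width),
                 config$validation_resolution,
                 config$validation_max_injection_ms, config$ms2_agc)
  }

  service_triggers <- function(ms1_spec, t_ms1) {
    cands <- check_triggers(ms1_spec, watch, t_ms1, config)
    for (i in seq_len(nrow(cands))) {
      tg <- cands[i, ]
      .log_push(trig, tibble::tibble(
        time_s = t_ms1, target_id = tg$target_id, event = "candidate",
        detail = sprintf("ms1_intensity=%.3g", tg$ms1_intensity)
      ))
      vspec <- record(val_req(tg), "trigger_validation", tg$target_id)
      ok <- validate_candidate(vspec, tg, config)
      if (ok) {
        .log_push(trig, tibble::tibble(
          time_s = clock, target_id = tg$target_id, event = "validated",
          detail = NA_character_
        ))
        record(emit_msxprm(tg, config), "msxprm", tg$target_id)
        j <- match(tg$target_id, watch$target_id)
        watch$excluded_until_s[j] <<- clock + config$exclusion_s
        watch$trigger_count[j] <<- watch$trigger_count[j] + 1L
        .log_push(trig, tibble::tibble(
          time_s = clock, target_id = tg$target_id, event = "acquired",
          detail = sprintf("excluded_until=%.3f", clock + config$exclusion_s)
        ))
      } else {
        .log_push(trig, tibble::tibble(
          time_s = clock, target_id = tg$target_id, event = "rejected",
          detail = "validation_failed"
        ))
      }
    }
  }

  withr::with_seed(seed, {
    if (mode %in% c("dia", "hybrid")) {
      while (clock < run_length_s) {
        for (k in seq_len(nrow(plan$sequence))) {
          if (clock >= run_length_s) break
          row <- plan$sequence[k, ]
          if (row$type == "MS1") {
            t_ms1 <- clock
            spec <- record(ms1_req, "dia_cycle")
            if (mode == "hybrid" && nrow(watch) > 0) {
              service_triggers(spec, t_ms1)
            }
          } else {
            record(dia_req(row$window), "dia_cycle")
          }
        }
      }
    } else {
      msx_dur <- scan_duration(config$ms2_resolution,
                               config$msxprm_max_injection_ms)
      while (clock < run_length_s) {
        active <- which(clock >= watch$rt_start_s & clock <= watch$rt_end_s)
        if (length(active) * msx_dur > config$prm_cycle_budget_s) {
          .log_push(warn, tibble::tibble(
            time_s = clock, n_active = length(active),
            needed_s = length(active) * msx_dur,
            budget_s = config$prm_cycle_budget_s
          ))
        }
        record(ms1_req, "standalone_prm")
        for (j in active) {
          if (clock >= run_length_s) break
          tg <- watch[j, ]
          record(emit_msxprm(tg, config), "standalone_prm", tg$target_id)
          watch$trigger_count[j] <- watch$trigger_count[j] + 1L
        }
      }
    }
  })

  sc <- if (scans$n > 0) {
    recs <- scans$data[seq_len(scans$n)]
    tibble::tibble(
      scan_id = vapply(recs, `[[`, integer(1), "scan_id"),
      type = vapply(recs, `[[`, character(1), "type"),
      provenance = vapply(recs, `[[`, character(1), "provenance"),
      target_id = vapply(recs, `[[`, character(1), "target_id"),
      start_s = vapply(recs, `[[`, numeric(1), "start_s"),
      injection_ms = vapply(recs, `[[`, numeric(1), "injection_ms"),
      duration_s = vapply(recs, `[[`, numeric(1), "duration_s"),
      windows = purrr::map(recs, "windows"),
      mz = purrr::map(recs, "mz"),
      intensity = purrr::map(recs, "intensity"),
      noise_floor = vapply(recs, `[[`, numeric(1), "noise_floor")
    )
  } else {
    NULL
  }
  structure(
    list(
      scans = sc %||% tibble::tibble(
        scan_id = integer(0), type = character(0), provenance = character(0),
        target_id = character(0), start_s = numeric(0),
        injection_ms = numeric(0), duration_s = numeric(0),
        windows = list(), mz = list(), intensity = list(),
        noise_floor = numeric(0)
      ),
      trigger_log = .log_collect(trig) %||% tibble::tibble(
        time_s = numeric(0), target_id = character(0),
        event = character(0), detail = character(0)
      ),
      schedule_warnings = .log_collect(warn) %||% tibble::tibble(
        time_s = numeric(0), n_active = integer(0),
        needed_s = numeric(0), budget_s = numeric(0)
      ),
      watch = watch, config = config, mode = mode, targets = targets,
      sample = sample, run_length_s = run_length_s, seed = seed,
      clock = clock
    ),
    class = "acq_run"
  )
}

#' @export
print.acq_run <- function(x, ...) {
  n_by <- table(x$scans$type)
  cat("<acq_run> mode =", x$mode, "| run length =", x$run_length_s,
      "s | clock =", round(x$clock, 3), "s\n")
  cat("  scans:", nrow(x$scans),
      paste0("(", paste(names(n_by), n_by, sep = "=", collapse = ", "), ")"),
      "\n")
  cat("  targets:", nrow(x$targets), "| trigger events:",
      sum(x$trigger_log$event == "acquired"), "acquired /",
      sum(x$trigger_log$event == "candidate"), "candidates\n")
  invisible(x)
}
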