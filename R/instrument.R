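# Orbitrap-like instrument model: ion accumulation under automatic gain
# control (AGC), resolution-dependent transient times, and a simple
# linear-response detector with saturation, m/z jitter and intensity noise.

# Transient duration is linear in resolution; anchored at 64 ms for R=30,000.
.transient_s <- c(`7500` = 0.016, `15000` = 0.032, `30000` = 0.064,
                  `60000` = 0.128, `120000` = 0.256)
.scan_overhead_s <- 0.005

#' Ion injection time under AGC control
#'
#' Accumulation stops when the AGC charge target is reached or the maximum
#' injection time elapses, whichever comes first:
#' `min(max_injection_ms, 1000 * agc_target / total_flux)`. Zero flux gives
#' the maximum injection time.
#'
#' @param total_flux Total ion flux entering the trap (charges/s, >= 0).
#' @param agc_target AGC charge target (charges).
#' @param max_injection_ms Maximum injection time (ms).
#' @return Injection time in ms.
#' @export
injection_time <- function(total_flux, agc_target, max_injection_ms) {
  stopifnot(total_flux >= 0)
  if (total_flux == 0) return(max_injection_ms)
  min(max_injection_ms, 1000 * agc_target / total_flux)
}

#' Duration of one scan
#'
#' Injection and the Orbitrap transient overlap, so the scan takes the longer
#' of the two, plus a fixed overhead. Model constants: transient 64 ms at
#' resolution 30,000, linear in resolution; overhead 5 ms.
#'
#' @param resolution One of 7500, 15000, 30000, 60000, 120000 (at m/z 200).
#' @param injection_ms Injection time (ms).
#' @return Scan duration in seconds.
#' @export
scan_duration <- function(resolution, injection_ms) {
  key <- as.character(resolution)
  if (!key %in% names(.transient_s)) {
    stop("unsupported resolution ", resolution, "; must be one of ",
         paste(names(.transient_s), collapse = ", "), call. = FALSE)
  }
  max(injection_ms / 1000, .transient_s[[key]]) + .scan_overhead_s
}

#' Acquisition method configuration
#'
#' Bundles the DIA cycle parameters, trigger parameters and instrument
#' timing/noise constants into one list. Defaults follow a high-resolution
#' MS1-based DIA method with internal-standard-triggered MSxPRM: 400-1210 Th
#' precursor range tiled by 15 Th windows with one MS1 scan every 18 MS2
#' scans (54 MS2 windows, three MS1 scans per cycle), 1.4 Th MSxPRM
#' isolation co-isolating heavy and light, 10 ppm trigger mass tolerance,
#' 1e5 counts MS1 trigger intensity threshold, and 5 s dynamic exclusion.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `method_config`.
#' @export
method_config <- function(...) {
  cfg <- list(
    scan_range = c(400, 1210),
    dia_window_width = 15,
    ms2_per_ms1 = 18,
    ms1_resolution = 60000,
    ms2_resolution = 30000,
    validation_resolution = 7500,
    ms1_agc = 3e6,
    ms2_agc = 1e6,
    msxprm_agc = 1e6,
    ms1_max_injection_ms = 100,
    dia_ms2_max_injection_ms = 54,
    msxprm_max_injection_ms = 116,
    validation_max_injection_ms = 10,
    ppm_tol = 10,
    intensity_threshold = 1e5,
    min_validated_fragments = 4,
    exclusion_s = 5,
    multiplex_count = 2,
    msxprm_isolation_width = 1.4,
    mz_ppm_sigma = 2,
    intensity_cv = 0.05,
    detector_gain = 10,
    noise_floor = 50,
    noise = TRUE,
    run_length_s = 7200,
    prm_cycle_budget_s = 3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown method_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "method_config")
}

#' Build a scan request
#'
#' @param scan_type One of `"MS1"`, `"DIA_MS2"`, `"VALIDATION_MS2"`,
#'   `"MSxPRM"`.
#' @param isolation_windows Tibble with columns `center`, `width` (Th);
#'   `NULL` for MS1. MSxPRM requests must carry exactly two windows.
#' @param resolution,max_injection_ms,agc_target Instrument settings.
#' @return A list of class `scan_request`.
#' @export
scan_request <- function(scan_type, isolation_windows = NULL, resolution,
                         max_injection_ms, agc_target) {
  scan_type <- match.arg(scan_type,
                         c("MS1", "DIA_MS2", "VALIDATION_MS2", "MSxPRM"))
  if (scan_type == "MS1") {
    if (!is.null(isolation_windows)) {
      stop("MS1 requests carry no isolation window", call. = FALSE)
    }
  } else {
    stopifnot(!is.null(isolation_windows), all(isolation_windows$width > 0))
    if (scan_type == "MSxPRM" && nrow(isolation_windows) != 2) {
      stop("MSxPRM requests must carry exactly 2 isolation windows",
           call. = FALSE)
    }
  }
  structure(
    list(scan_type = scan_type, isolation_windows = isolation_windows,
         resolution = resolution, max_injection_ms = max_injection_ms,
         agc_target = agc_target),
    class = "scan_request"
  )
}

# Precompute per-run simulation index: flux amplitudes, isotope envelope
# peaks and a flattened fragment table, so per-scan work is pure vector
# arithmetic.
.sim_index <- function(species, n_iso = 3) {
  n <- nrow(species)
  amp <- species$amount_fmol * .flux_per_fmol /
    (species$peak_sigma_s * sqrt(2 * pi))
  iso_mz <- matrix(0, n, n_iso)
  iso_frac <- matrix(0, n, n_iso)
  for (i in seq_len(n)) {
    frac <- averagine_envelope(species$mass[i], n_iso)
    iso_frac[i, ] <- frac
    iso_mz[i, ] <- species$precursor_mz[i] +
      (seq_len(n_iso) - 1) * .neutron_spacing / species$charge[i]
  }
  frag_n <- vapply(species$fragments, nrow, integer(1))
  frag <- list(
    sp = rep(seq_len(n), frag_n),
    mz = unlist(purrr::map(species$fragments, "mz"), use.names = FALSE),
    rel_int = unlist(purrr::map(species$fragments, "rel_int"),
                     use.names = FALSE)
  )
  frag_rows <- split(seq_along(frag$sp), frag$sp)
  frag_idx <- vector("list", n)
  frag_idx[as.integer(names(frag_rows))] <- frag_rows
  list(
    species = species, amp = amp, rt = species$rt_apex_s,
    sigma = species$peak_sigma_s, iso_mz = iso_mz, iso_frac = iso_frac,
    frag = frag, frag_idx = frag_idx, n_iso = n_iso
  )
}

# Eluting species (within 6 sigma of apex) and their flux at scalar time t.
.sim_flux <- function(sim, t) {
  z <- (t - sim$rt) / sim$sigma
  live <- which(abs(z) < 6)
  list(live = live, flux = sim$amp[live] * exp(-z[live]^2 / 2))
}

# Fraction of selected species' isotope envelopes captured by a set of
# isolation windows.
.capture_fraction <- function(sim, rows, windows) {
  iso_mz <- sim$iso_mz[rows, , drop = FALSE]
  iso_frac <- sim$iso_frac[rows, , drop = FALSE]
  cap <- numeric(length(rows))
  for (w in seq_len(nrow(windows))) {
    lo <- windows$center[w] - windows$width[w] / 2
    hi <- windows$center[w] + windows$width[w] / 2
    inside <- iso_mz >= lo & iso_mz < hi
    cap <- cap + rowSums(iso_frac * inside)
  }
  pmin(cap, 1)
}

#' Simulate one scan
#'
#' Produces a centroided spectrum for the sample state at time `t`. MS1 scans
#' contain every eluting species' isotope envelope; MS2-type scans contain
#' the fragments of every precursor whose envelope overlaps any isolation
#' window (chimeric by construction), scaled by the captured envelope
#' fraction. Peak intensity is `flux(t) x injection_time`; injection time is
#' AGC-controlled by the total flux entering the isolation window(s), which
#' is what lets high-abundance background shorten injection and mask
#' low-abundance fragments. With noise enabled, each m/z is perturbed by a
#' Gaussian ppm error and each intensity by multiplicative log-normal
#' jitter.
#'
#' @param sim Simulation index from a species tibble (built internally by
#'   [run_acquisition()]); a species tibble is also accepted.
#' @param request A [scan_request()].
#' @param t Clock time (seconds).
#' @param config A [method_config()] (noise constants, scan range).
#' @return List with `mz`, `intensity`, `noise_floor`, `injection_ms`.
#' @export
acquire <- function(sim, request, t, config = method_config()) {
  if (is.data.frame(sim)) sim <- .sim_index(sim)
  el <- .sim_flux(sim, t)
  if (request$scan_type == "MS1") {
    iso_mz <- sim$iso_mz[el$live, , drop = FALSE]
    iso_frac <- sim$iso_frac[el$live, , drop = FALSE]
    in_range <- rowSums(iso_frac * (iso_mz >= config$scan_range[1] &
                                      iso_mz < config$scan_range[2]))
    it <- injection_time(sum(el$flux * in_range), request$agc_target,
                         request$max_injection_ms)
    counts <- el$flux * it / 1000
    keep_sp <- counts > 1e-3
    mz <- as.vector(t(iso_mz[keep_sp, , drop = FALSE]))
    inten <- as.vector(t(iso_frac[keep_sp, , drop = FALSE] *
                           counts[keep_sp]))
    keep <- mz >= config$scan_range[1] & mz < config$scan_range[2] &
      inten > 0
    mz <- mz[keep]; inten <- inten[keep]
  } else {
    cap <- .capture_fraction(sim, el$live, request$isolation_windows)
    eff_flux <- el$flux * cap
    it <- injection_time(sum(eff_flux), request$agc_target,
                         request$max_injection_ms)
    counts <- eff_flux * it / 1000
    live <- el$live[counts > 1e-3]
    counts <- counts[counts > 1e-3]
    if (length(live) > 0) {
      rows <- unlist(sim$frag_idx[live], use.names = FALSE)
      per_sp <- counts[match(sim$frag$sp[rows], live)]
      mz <- sim$frag$mz[rows]
      inten <- sim$frag$rel_int[rows] * per_sp
    } else {
      mz <- numeric(0); inten <- numeric(0)
    }
  }
  inten <- inten * config$detector_gain
  if (isTRUE(config$noise) && length(mz) > 0) {
    mz <- mz * (1 + rnorm(length(mz), 0, config$mz_ppm_sigma * 1e-6))
    inten <- inten * rlnorm(length(inten), 0, config$intensity_cv)
  }
  ord <- order(mz)
  list(mz = mz[ord], intensity = inten[ord],
       noise_floor = config$noise_floor, injection_ms = it)
}
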