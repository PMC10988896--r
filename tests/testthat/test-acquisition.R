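# Acquisition engine: DIA cycle planning, trigger chain, run modes.

.watch_of <- function(targets) {
  targets$excluded_until_s <- 0
  targets$trigger_count <- 0L
  targets
}

test_that("DIA cycle planning tiles the range and interleaves MS1 blocks", {
  plan <- plan_dia_cycle(400, 1210, 15, 18)
  expect_equal(nrow(plan$windows), 54)
  expect_equal(plan$ms1_per_cycle, 3)
  expect_equal(plan$windows$low[1], 400)
  expect_equal(plan$windows$high[54], 1210)
  expect_true(all(plan$windows$width == 15))
  # contiguity: each window starts where the previous ended
  expect_equal(plan$windows$low[-1], plan$windows$high[-54])
  expect_equal(sum(plan$sequence$type == "MS1"), 3)
  expect_equal(sum(plan$sequence$type == "DIA_MS2"), 54)

  # truncated last window
  p2 <- plan_dia_cycle(400, 410, 4, 2)
  expect_equal(nrow(p2$windows), 3)
  expect_equal(p2$windows$width, c(4, 4, 2))
  expect_equal(p2$ms1_per_cycle, 2)

  # degenerate single window
  p3 <- plan_dia_cycle(500, 510, 20, 18)
  expect_equal(nrow(p3$windows), 1)
  expect_equal(p3$windows$width, 10)
  expect_error(plan_dia_cycle(500, 400, 15), "high must exceed")
  expect_error(plan_dia_cycle(400, 500, 0), "width")
})

test_that("trigger screening enforces ppm window, threshold, RT and exclusion", {
  cfg <- method_config()
  pairs <- fix_pairs(1)
  watch <- .watch_of(targets_from_pairs(pairs))
  mz0 <- watch$heavy_mz
  t0 <- mean(c(watch$rt_start_s, watch$rt_end_s))
  spec <- function(ppm_off, inten) {
    list(mz = mz0 * (1 + ppm_off * 1e-6), intensity = inten)
  }
  # valid hit
  expect_equal(nrow(check_triggers(spec(9, 2e5), watch, t0, cfg)), 1)
  # +11 ppm off: no candidate
  expect_equal(nrow(check_triggers(spec(11, 2e5), watch, t0, cfg)), 0)
  # just under the intensity threshold
  expect_equal(nrow(check_triggers(spec(0, 9.9e4), watch, t0, cfg)), 0)
  expect_equal(nrow(check_triggers(spec(0, 1e5), watch, t0, cfg)), 1)
  # outside RT window
  expect_equal(nrow(check_triggers(spec(0, 2e5), watch,
                                   watch$rt_end_s + 1, cfg)), 0)
  # dynamically excluded
  w2 <- watch
  w2$excluded_until_s <- t0 + 1
  expect_equal(nrow(check_triggers(spec(0, 2e5), w2, t0, cfg)), 0)
  # candidate carries the matched MS1 intensity
  got <- check_triggers(spec(0, 3e5), watch, t0, cfg)
  expect_equal(got$ms1_intensity, 3e5)
})

test_that("candidates are returned in ascending heavy m/z order", {
  cfg <- method_config()
  pairs <- fix_pairs(5)
  watch <- .watch_of(targets_from_pairs(pairs, rt_window_s = 1e6))
  spec <- list(mz = watch$heavy_mz, intensity = rep(2e5, nrow(watch)))
  got <- check_triggers(spec, watch, 150, cfg)
  expect_equal(got$heavy_mz, sort(got$heavy_mz))
  expect_equal(nrow(got), 5)
})

test_that("validation demands enough matching heavy fragments above the floor", {
  cfg <- method_config()  # min_validated_fragments = 4
  tg <- targets_from_pairs(fix_pairs(1))[1, ]
  fr <- tg$fragments[[1]]$heavy_mz
  mk <- function(mz, int = 1e4) list(mz = mz, intensity = rep(int, length(mz)),
                                     noise_floor = cfg$noise_floor)
  expect_true(validate_candidate(mk(fr), tg, cfg))
  expect_true(validate_candidate(mk(fr[1:4]), tg, cfg))
  expect_false(validate_candidate(mk(fr[1:3]), tg, cfg))
  # matches below the noise floor do not count
  expect_false(validate_candidate(mk(fr, int = cfg$noise_floor / 2), tg, cfg))
  expect_false(validate_candidate(mk(numeric(0)), tg, cfg))
})

test_that("decoy validation spectra are rejected at >= 99%", {
  cfg <- method_config()
  tg <- targets_from_pairs(fix_pairs(1))[1, ]
  rejected <- withr::with_seed(17, {
    vapply(1:200, function(i) {
      decoy <- list(mz = runif(30, 200, 1400), intensity = rep(1e5, 30),
                    noise_floor = cfg$noise_floor)
      !validate_candidate(decoy, tg, cfg)
    }, logical(1))
  })
  expect_gte(mean(rejected), 0.99)
})

test_that("the MSxPRM request co-isolates heavy and light in two 1.4 Th windows", {
  cfg <- method_config()
  tg <- targets_from_pairs(make_pair("ELVISLAVESK", 2, 1, 100, 300))[1, ]
  req <- emit_msxprm(tg, cfg)
  expect_equal(req$scan_type, "MSxPRM")
  expect_equal(nrow(req$isolation_windows), 2)
  expect_equal(req$isolation_windows$width, c(1.4, 1.4))
  expect_equal(abs(diff(req$isolation_windows$center)), 8.014199 / 2,
               tolerance = 1e-6)
  expect_equal(req$max_injection_ms, cfg$msxprm_max_injection_ms)
})

test_that("hybrid with zero targets reduces exactly to plain DIA", {
  pairs <- fix_pairs(2)
  bg <- fix_background(40)
  sample <- dplyr::bind_rows(pairs, bg)
  cfg <- method_config()
  h <- run_acquisition(sample, cfg, "hybrid", empty_targets(),
                       run_length_s = 60, seed = 5)
  d <- run_acquisition(sample, cfg, "dia", run_length_s = 60, seed = 5)
  expect_identical(h$scans$type, d$scans$type)
  expect_identical(h$scans$start_s, d$scans$start_s)
  expect_identical(h$scans$mz, d$scans$mz)
  expect_identical(h$scans$intensity, d$scans$intensity)
  expect_equal(nrow(h$trigger_log), 0)
})

test_that("an unreachable trigger threshold yields zero MSxPRM scans", {
  pairs <- fix_pairs(2)
  targets <- targets_from_pairs(pairs, intensity_threshold = 1e12)
  run <- run_acquisition(pairs, method_config(), "hybrid", targets,
                         run_length_s = 120, seed = 5)
  expect_equal(sum(run$scans$type == "MSxPRM"), 0)
  expect_equal(sum(run$trigger_log$event == "candidate"), 0)
})

test_that("hybrid trigger chain has no orphan scans and respects RT windows", {
  fx <- shared_hybrid_run()
  run <- fx$run
  msx <- dplyr::filter(run$scans, type == "MSxPRM")
  expect_gt(nrow(msx), 0)
  scans <- run$scans
  for (i in seq_len(nrow(msx))) {
    tid <- msx$target_id[i]
    tg <- run$targets[run$targets$target_id == tid, ]
    # MSxPRM only inside the target's scheduling window
    expect_gte(msx$start_s[i], tg$rt_start_s)
    expect_lte(msx$start_s[i], tg$rt_end_s)
    # immediately preceded by a validation scan of the same target
    prev <- scans[scans$scan_id == msx$scan_id[i] - 1L, ]
    expect_equal(prev$type, "VALIDATION_MS2")
    expect_equal(prev$target_id, tid)
    # ... which was itself preceded by an MS1 scan at some earlier id
    pre2 <- scans[scans$scan_id < prev$scan_id & scans$type == "MS1", ]
    expect_gt(nrow(pre2), 0)
  }
  # every validation scan stems from a logged candidate event
  val <- dplyr::filter(scans, type == "VALIDATION_MS2")
  cand <- dplyr::filter(run$trigger_log, event == "candidate")
  expect_equal(nrow(val), nrow(cand))
})

test_that("dynamic exclusion spaces repeated MSxPRM scans of one target", {
  fx <- shared_hybrid_run()
  msx <- dplyr::filter(fx$run$scans, type == "MSxPRM")
  gaps <- msx |>
    dplyr::group_by(target_id) |>
    dplyr::summarise(min_gap = if (dplyr::n() > 1) min(diff(sort(start_s)))
                     else NA_real_) |>
    dplyr::pull(min_gap)
  gaps <- gaps[!is.na(gaps)]
  expect_gt(length(gaps), 0)
  expect_true(all(gaps >= fx$run$config$exclusion_s))
})

test_that("the clock equals the summed scan durations (time conservation)", {
  fx <- shared_hybrid_run()
  expect_equal(fx$run$clock, sum(fx$run$scans$duration_s), tolerance = 1e-9)
  expect_equal(fx$run$scans$start_s,
               cumsum(c(0, fx$run$scans$duration_s[-nrow(fx$run$scans)])),
               tolerance = 1e-9)
})

test_that("scheduled PRM covers active targets and reports overload honestly", {
  pairs <- fix_pairs(3, rt_range = c(60, 120))
  targets <- targets_from_pairs(pairs, rt_window_s = 60)
  run <- run_acquisition(pairs, method_config(), "prm", targets,
                         run_length_s = 200, seed = 2)
  msx <- dplyr::filter(run$scans, type == "MSxPRM")
  expect_setequal(unique(msx$target_id), targets$target_id)
  # every target's scans lie inside its window (+ one cycle of slack at end)
  for (tid in targets$target_id) {
    tg <- targets[targets$target_id == tid, ]
    s <- msx$start_s[msx$target_id == tid]
    expect_true(all(s >= tg$rt_start_s - 1 & s <= tg$rt_end_s + 1))
  }
  expect_error(run_acquisition(pairs, method_config(), "prm", empty_targets()),
               "non-empty")
  # a tiny budget must be flagged, not silently satisfied
  run2 <- run_acquisition(pairs, method_config(prm_cycle_budget_s = 0.1),
                          "prm", targets, run_length_s = 200, seed = 2)
  expect_gt(nrow(run2$schedule_warnings), 0)
})

test_that("targets with too few declared fragments are rejected up front", {
  tg <- targets_from_pairs(fix_pairs(1))
  tg$fragments[[1]] <- tg$fragments[[1]][1:2, ]
  expect_error(
    run_acquisition(fix_pairs(1), method_config(), "hybrid", tg,
                    run_length_s = 30),
    "fewer fragments"
  )
})

test_that("runs are reproducible under the same seed", {
  pairs <- fix_pairs(2)
  targets <- targets_from_pairs(pairs)
  a <- run_acquisition(pairs, method_config(), "hybrid", targets,
                       run_length_s = 60, seed = 21)
  b <- run_acquisition(pairs, method_config(), "hybrid", targets,
                       run_length_s = 60, seed = 21)
  expect_identical(a$scans$mz, b$scans$mz)
  expect_identical(a$scans$intensity, b$scans$intensity)
  expect_identical(a$trigger_log, b$trigger_log)
})
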