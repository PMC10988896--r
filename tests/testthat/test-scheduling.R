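# Target lists on disk, concurrency profiling and duty-cycle feasibility.

# brute-force concurrency oracle: count active windows on a 0.1 s grid
.oracle_max_concurrency <- function(targets, step = 0.1) {
  if (nrow(targets) == 0) return(0L)
  grid <- seq(min(targets$rt_start_s), max(targets$rt_end_s), by = step)
  grid <- unique(c(grid, targets$rt_start_s, targets$rt_end_s))
  max(vapply(grid, function(t) {
    sum(targets$rt_start_s <= t & targets$rt_end_s >= t)
  }, integer(1)))
}

test_that("target lists round-trip through the tab-separated layout", {
  targets <- targets_from_pairs(fix_pairs(4))
  path <- withr::local_tempfile(fileext = ".txt")
  write_target_list(targets, path)
  back <- parse_target_list(path)
  expect_equal(back$target_id, targets$target_id)
  expect_equal(back$heavy_mz, targets$heavy_mz, tolerance = 1e-6)
  expect_equal(back$light_mz, targets$light_mz, tolerance = 1e-6)
  expect_equal(back$rt_start_s, targets$rt_start_s)
  for (i in seq_len(nrow(targets))) {
    expect_equal(back$fragments[[i]]$heavy_mz, targets$fragments[[i]]$heavy_mz,
                 tolerance = 1e-6)
    # light fragments reconstructed from the precursor-implied label shift
    expect_equal(back$fragments[[i]]$light_mz, targets$fragments[[i]]$light_mz,
                 tolerance = 1e-5)
  }
})

test_that("minute-based retention columns are converted to seconds", {
  targets <- targets_from_pairs(fix_pairs(2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_target_list(targets, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab$rt_start_s <- tab$rt_start_s / 60
  tab$rt_end_s <- tab$rt_end_s / 60
  names(tab)[names(tab) == "rt_start_s"] <- "rt_start_min"
  names(tab)[names(tab) == "rt_end_s"] <- "rt_end_min"
  readr::write_tsv(tab, path)
  back <- parse_target_list(path)
  expect_equal(back$rt_start_s, targets$rt_start_s, tolerance = 1e-9)
  expect_equal(back$rt_end_s, targets$rt_end_s, tolerance = 1e-9)
})

test_that("malformed target rows fail with the row number in the message", {
  targets <- targets_from_pairs(fix_pairs(3))
  path <- withr::local_tempfile(fileext = ".txt")

  corrupt <- function(mutate) {
    write_target_list(targets, path)
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    tab <- mutate(tab)
    readr::write_tsv(tab, path)
    path
  }
  expect_error(parse_target_list(corrupt(function(t) {
    t$heavy_mz[2] <- "oops"; t
  })), "row 2.*malformed heavy_mz")
  expect_error(parse_target_list(corrupt(function(t) {
    tmp <- t$rt_start_s[3]; t$rt_start_s[3] <- t$rt_end_s[3]
    t$rt_end_s[3] <- tmp; t
  })), "row 3.*inverted RT")
  expect_error(parse_target_list(corrupt(function(t) {
    t$light_mz[1] <- sprintf("%.6f", as.numeric(t$heavy_mz[1]) + 1); t
  })), "row 1.*below heavy_mz")
  expect_error(parse_target_list(corrupt(function(t) {
    t$light_mz[1] <- sprintf("%.6f", as.numeric(t$heavy_mz[1]) - 2.5); t
  })), "row 1.*neither Lys8 nor Arg10")
  expect_error(parse_target_list(corrupt(function(t) {
    t$fragment_mz_list[2] <- ""; t
  })), "row 2.*fragments")
})

test_that("concurrency profile handles trivial panels exactly", {
  expect_equal(max_concurrency(empty_targets())$maximum, 0L)
  tg <- targets_from_pairs(fix_pairs(1))
  expect_equal(max_concurrency(tg)$maximum, 1L)
  # two disjoint windows -> 1; touching endpoints count as overlapping
  t2 <- dplyr::bind_rows(tg, tg)
  t2$target_id <- c("a", "b")
  t2$rt_start_s <- c(0, 100); t2$rt_end_s <- c(50, 150)
  expect_equal(max_concurrency(t2)$maximum, 1L)
  t2$rt_start_s <- c(0, 50); t2$rt_end_s <- c(50, 150)
  expect_equal(max_concurrency(t2)$maximum, 2L)
})

test_that("sweep-line maximum matches the brute-force grid oracle", {
  base <- targets_from_pairs(fix_pairs(1))[rep(1, 200), ]
  withr::with_seed(123, {
    for (trial in 1:100) {
      n <- sample(2:40, 1)
      tg <- base[seq_len(n), ]
      tg$target_id <- as.character(seq_len(n))
      tg$rt_start_s <- round(runif(n, 0, 500), 1)
      tg$rt_end_s <- tg$rt_start_s + round(runif(n, 0.1, 200), 1)
      prof <- max_concurrency(tg)
      expect_identical(prof$maximum, .oracle_max_concurrency(tg))
      # the reported counts at breakpoints agree with direct evaluation
      direct <- vapply(prof$breakpoints, function(t) {
        sum(tg$rt_start_s <= t & tg$rt_end_s >= t)
      }, integer(1))
      expect_identical(prof$counts, direct)
    }
  })
})

test_that("duty-cycle report is zero without targets and monotone in load", {
  cfg <- method_config()
  rep0 <- duty_cycle_report(empty_targets(), cfg, bin_s = 60,
                            run_length_s = 600)
  expect_true(all(rep0$triggered_time_fraction == 0))
  expect_true(all(rep0$dia_time_fraction == 1))
  expect_false(any(rep0$overloaded))

  # fractions conserve: dia + triggered == 1, triggered <= 1
  tg <- targets_from_pairs(fix_pairs(10, rt_range = c(0, 500)),
                           rt_window_s = 300)
  rep1 <- duty_cycle_report(tg, cfg, bin_s = 60, run_length_s = 600)
  expect_equal(rep1$dia_time_fraction + rep1$triggered_time_fraction,
               rep(1, nrow(rep1)))
  expect_true(all(rep1$triggered_time_fraction <= 1))

  # doubling the panel never lowers any bin's triggered fraction
  tg2 <- dplyr::bind_rows(tg, dplyr::mutate(tg, target_id = paste0(target_id,
                                                                   "_b")))
  rep2 <- duty_cycle_report(tg2, cfg, bin_s = 60, run_length_s = 600)
  expect_true(all(rep2$triggered_time_fraction >=
                    rep1$triggered_time_fraction))
})

test_that("duty-cycle arithmetic matches the worst-case hand computation", {
  cfg <- method_config()
  tg <- targets_from_pairs(fix_pairs(1))
  tg <- tg[rep(1, 36), ]
  tg$target_id <- as.character(1:36)
  tg$rt_start_s <- 0
  tg$rt_end_s <- 600
  rep36 <- duty_cycle_report(tg, cfg, bin_s = 60, run_length_s = 600)
  val_dur <- scan_duration(cfg$validation_resolution,
                           cfg$validation_max_injection_ms)
  msx_dur <- scan_duration(cfg$ms2_resolution, cfg$msxprm_max_injection_ms)
  expect_equal(unique(rep36$n_active), 36L)
  expect_equal(unique(rep36$triggered_time_fraction),
               min(1, 36 * (val_dur + msx_dur) / cfg$exclusion_s))
})
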