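# Quantification: XIC extraction, peak integration, ratio/status logic,
# calibration + LOD, replicate CVs, rollup and the data matrix.

# synthetic chromatogram helper
.chrom <- function(time_s, intensity, noise_floor = 0) {
  out <- tibble::tibble(time_s = time_s, intensity = intensity)
  class(out) <- c("chromatogram", class(out))
  attr(out, "noise_floor") <- noise_floor
  out
}

test_that("XIC traces have one point per matching scan within tolerance", {
  fx <- shared_hybrid_run()
  run <- fx$run
  tg <- fx$targets[1, ]
  tr <- extract_xic(run, tg$heavy_mz, 10, source = "ms1_precursor")
  expect_s3_class(tr, "chromatogram")
  expect_equal(nrow(tr), sum(run$scans$type == "MS1"))
  expect_true(all(tr$intensity >= 0))
  # a trace at an m/z nothing produces is all zero
  empty <- extract_xic(run, 1400, 10, source = "ms1_precursor")
  expect_true(all(empty$intensity == 0))
  # target restriction keeps only that target's MSxPRM scans
  trm <- extract_xic(run, tg$fragments[[1]]$heavy_mz[1], 10,
                     source = "msxprm_fragment", target_id = tg$target_id)
  expect_equal(nrow(trm), sum(run$scans$type == "MSxPRM" &
                                run$scans$target_id == tg$target_id))
})

test_that("peak integration reproduces analytic areas", {
  # rectangle: constant 10 over 0..5 sampled at 10 Hz -> area 50 within 0.5%
  t <- seq(0, 5, by = 0.1)
  rect <- .chrom(t, rep(10, length(t)))
  expect_equal(integrate_peak(rect, noise_floor = 0)$area, 50,
               tolerance = 0.005)
  # Gaussian: amplitude 100, sigma 2, dense sampling -> A*sigma*sqrt(2*pi)
  t2 <- seq(-20, 20, by = 0.05)
  g <- .chrom(t2, 100 * exp(-t2^2 / (2 * 4)))
  expect_equal(integrate_peak(g, noise_floor = 0)$area,
               100 * 2 * sqrt(2 * pi), tolerance = 0.01)
  # flat zero trace integrates to nothing
  z <- integrate_peak(.chrom(t, rep(0, length(t))), noise_floor = 1)
  expect_equal(z$area, 0)
  expect_equal(z$n_points, 0L)
  # boundaries stop at the threshold crossing around the apex
  y <- c(0, 0, 5, 40, 100, 40, 5, 0, 0)
  p <- integrate_peak(.chrom(seq_along(y), y), noise_floor = 3, snr = 3)
  expect_equal(p$bounds_s, c(4, 6))
  expect_equal(p$n_points, 3L)
  expect_equal(p$area, (40 + 100) / 2 + (100 + 40) / 2)
})

test_that("equal-amount pairs quantify at ratio 1 without noise", {
  pairs <- make_pair("ELVISLAVESK", 2, 100, 100, 150)
  targets <- targets_from_pairs(pairs)
  run <- run_acquisition(pairs, method_config(noise = FALSE), "hybrid",
                         targets, run_length_s = 300, seed = 1)
  q <- quantify_pair(run, targets[1, ])
  expect_equal(q$status, "quantified")
  expect_equal(q$ratio, 1, tolerance = 0.01)
  expect_equal(q$amount_estimate_fmol, 100, tolerance = 1)
})

test_that("absent light gives below_LOD; no heavy trigger gives missing", {
  pairs <- make_pair("ELVISLAVESK", 2, 0, 100, 150)
  targets <- targets_from_pairs(pairs)
  run <- run_acquisition(pairs, method_config(noise = FALSE), "hybrid",
                         targets, run_length_s = 300, seed = 1)
  q <- quantify_pair(run, targets[1, ])
  expect_equal(q$status, "below_LOD")
  expect_gt(q$heavy_area, 0)
  expect_equal(q$light_area, 0)
  expect_true(is.na(q$ratio))

  # heavy spike absent: nothing triggers, the target is missing
  pairs2 <- make_pair("ELVISLAVESK", 2, 100, 0, 150)
  targets2 <- targets_from_pairs(pairs2)
  run2 <- run_acquisition(pairs2, method_config(noise = FALSE), "hybrid",
                          targets2, run_length_s = 300, seed = 1)
  q2 <- quantify_pair(run2, targets2[1, ])
  expect_equal(q2$status, "missing")
})

test_that("calibration on perfect ratios recovers slope 1 and the LOD rules", {
  levels <- c(100, 10, 1, 0.1)
  results <- tidyr::expand_grid(nominal_fmol = levels, rep = 1:3) |>
    dplyr::mutate(ratio = nominal_fmol / 100, status = "quantified")
  cal <- suppressWarnings(fit_calibration(results, spiked_heavy_fmol = 100))
  expect_true(cal$fit_ok)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, -2, tolerance = 1e-9)
  expect_gt(cal$r_squared, 0.999)
  expect_equal(cal$lod_fmol, 0.1)
  expect_match(cal$lod_label, "^< 0\\.1 fmol")

  # a level quantified in under half its replicates does not set the LOD
  res2 <- results
  res2$status[res2$nominal_fmol == 0.1 & res2$rep >= 2] <- "below_LOD"
  expect_equal(suppressWarnings(fit_calibration(res2))$lod_fmol, 1)

  # fewer than 3 detected levels: honest unfit
  res3 <- dplyr::filter(results, nominal_fmol >= 10)
  expect_false(fit_calibration(res3)$fit_ok)
  expect_true(is.na(fit_calibration(res3)$slope))
})

test_that("blank-based LOD uses the zero level mean plus three SDs", {
  results <- dplyr::bind_rows(
    tibble::tibble(nominal_fmol = 0, ratio = c(0.001, 0.002, 0.0015),
                   status = "quantified"),
    tidyr::expand_grid(nominal_fmol = c(10, 1, 0.1), rep = 1:2) |>
      dplyr::mutate(ratio = nominal_fmol / 100, status = "quantified")
  )
  cal <- suppressWarnings(fit_calibration(results, lod_mode = "blank_3sd"))
  # blank threshold ~ 0.0015 + 3*5e-4 = 0.003 -> 0.1 fmol (ratio 0.001) fails
  expect_equal(cal$lod_fmol, 1)
})

test_that("replicate CV follows the textbook definition", {
  expect_equal(replicate_cv(c(1, 2)), 100 * sd(c(1, 2)) / 1.5)
  expect_equal(replicate_cv(c(1, 2)), 47.14045, tolerance = 1e-6)
  expect_equal(replicate_cv(rep(3.7, 5)), 0)
  expect_true(is.na(replicate_cv(c(-1, 1))))
  expect_error(replicate_cv(5), ">= 2")
})

test_that("protein rollup averages quantified peptides and propagates status", {
  pep <- tibble::tibble(amount_estimate_fmol = c(2, 4, NA),
                        status = c("quantified", "quantified", "below_LOD"))
  r <- protein_rollup(pep)
  expect_equal(r$value, 3)
  expect_equal(r$status, "quantified")
  expect_equal(r$n_peptides, 2L)
  r2 <- protein_rollup(tibble::tibble(amount_estimate_fmol = NA_real_,
                                      status = c("below_LOD", "missing")))
  expect_equal(r2$status, "below_LOD")
  r3 <- protein_rollup(tibble::tibble(amount_estimate_fmol = NA_real_,
                                      status = "missing"))
  expect_equal(r3$status, "missing")
})

test_that("quant matrix and completeness follow the status logic", {
  results <- tidyr::expand_grid(protein = c("A", "B"),
                                sample = c("s1", "s2")) |>
    dplyr::mutate(amount_estimate_fmol = c(1, 2, NA, NA),
                  status = c("quantified", "quantified", "below_LOD",
                             "missing"))
  m <- quant_matrix(results)
  expect_s3_class(m, "quant_matrix")
  expect_equal(nrow(m), 4)
  expect_equal(completeness(m), 50)
  expect_equal(completeness(m, count_below_lod_as_informative = TRUE), 75)
  # counting below-LOD as informative can only raise completeness
  expect_gte(completeness(m, TRUE), completeness(m))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_matrix_tsv(m, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  expect_true(all(c("s1_value", "s1_status", "s2_value", "s2_status") %in%
                    names(back)))
})
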