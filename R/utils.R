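#' @importFrom rlang %||% .data
#' @importFrom stats convolve rnorm runif rlnorm rgamma sd median lm coef setNames
#' @importFrom utils head tail
NULL

# Deterministic small-integer hash of a peptide (sequence, charge), used to
# seed per-peptide draws (fragment choice, intensities) independently of any
# global seed, so the same peptide always carries the same fragment pattern.
.peptide_hash <- function(sequence, charge) {
  codes <- utf8ToInt(sequence)
  h <- sum(codes * seq_along(codes)) * 131 + charge * 7919
  as.integer(h %% .Machine$integer.max)
}

# Ion flux reaching the trap per fmol on column (integrated charges over the
# whole peak); single global calibration constant combining ionisation and
# transmission efficiency. 1e6 charges/fmol puts a 100 fmol reference just
# below the MS2 AGC target within a maximal 116 ms injection.
.flux_per_fmol <- 1e6

.assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
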