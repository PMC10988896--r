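# Shared fixtures: small synthetic panels and a lazily built, session-cached
# hybrid run reused by the property tests (building it is the expensive part).

.fixture_cache <- new.env(parent = emptyenv())

fix_pairs <- function(n = 5, rt_range = c(60, 240), light = 1, heavy = 100,
                      seed = 3) {
  make_pair_panel(n, rt_range_s = rt_range, light_amount_fmol = light,
                  heavy_amount_fmol = heavy, seed = seed)
}

fix_background <- function(n = 120, run_length = 300, seed = 4) {
  generate_background(n, rt_range_s = c(0, run_length), seed = seed)
}

# one standard hybrid run (5 pairs at 1 fmol light / 100 fmol heavy over a
# 120-peptide background, 300 s), cached per test session
shared_hybrid_run <- function() {
  if (is.null(.fixture_cache$hybrid)) {
    pairs <- fix_pairs()
    bg <- fix_background()
    targets <- targets_from_pairs(pairs)
    run <- run_acquisition(dplyr::bind_rows(pairs, bg), method_config(),
                           "hybrid", targets, run_length_s = 300, seed = 11)
    .fixture_cache$hybrid <- list(run = run, pairs = pairs, bg = bg,
                                  targets = targets)
  }
  .fixture_cache$hybrid
}
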