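---
title: "Simulating internal-standard-triggered hybrid PRM/DIA acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating internal-standard-triggered hybrid PRM/DIA acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriddia)
library(dplyr)
```

## The scientific problem

Clinical proteomics wants two things at once from a single LC-MS/MS run:
an unbiased, proteome-wide survey (which data-independent acquisition, DIA,
provides) and sensitive, absolute quantification of a predefined marker
panel (which targeted parallel reaction monitoring, PRM, provides). The two
compete for the same instrument time. A hybrid scheme resolves the conflict
by spiking stable-isotope-labelled ("heavy") reference peptides into every
sample at a known amount and letting the instrument watch for them in real
time: DIA cycles run continuously, and whenever an MS1 survey scan shows a
heavy reference above an intensity threshold inside its retention-time
window, the instrument inserts a fast low-resolution validation scan and —
if enough declared fragment ions confirm the identity — a single
*multiplexed* PRM scan (MSxPRM) that co-isolates the heavy reference and
its light endogenous partner in two narrow windows. The target is then
dynamically excluded for a few seconds and DIA resumes.

Because the heavy reference is always present, a sample where the light
partner yields no signal is *below the limit of detection*, not missing:
the instrument demonstrably looked. This turns the usual missing-value
problem of clinical data matrices into an informative zero.

`hybriddia` implements this whole loop as a desk-scale in-silico
instrument, so that scheduling, triggering and quantification logic can be
studied, stress-tested and taught without an Orbitrap.

## The model

### Sample

A sample is a tibble of species. Each heavy/light pair shares a sequence,
charge, elution apex and peak width; the heavy channel is shifted by the
C-terminal label mass (Lys8 = 8.014199 Da, Arg10 = 10.008269 Da), which
moves the precursor by `shift / z` and every y ion by the full shift while
leaving b ions untouched. Each peptide carries a deterministic fragment set
(up to six ions, mostly y series, with Dirichlet-distributed relative
intensities) seeded by a hash of sequence and charge, so the same peptide
fragments identically in every sample and run. Elution is Gaussian in time;
the ion flux of a species at time $t$ is

$$ f(t) = A \cdot c \cdot \exp\!\left(-\frac{(t - t_0)^2}{2\sigma^2}\right), $$

with $A$ the amount in fmol and $c$ a single global flux constant.
Background matrices are random tryptic-like peptides with lognormal
abundances (1.5 decades sigma, capped at 2000 fmol so that no single
fat-tail species permanently saturates the automatic gain control).

### Instrument

Scans follow an Orbitrap-like duty-cycle model. Ion injection time is
AGC-limited: `min(max_injection, 1000 * agc_target / total_flux)` ms, so a
busy isolation window fills its ion target quickly and dim species inside
it are crushed to few counts — the physical reason DIA loses low-abundance
peptides in crowded windows, and the reason a triggered narrow-window scan
with a 116 ms injection recovers them. Scan duration is
`max(injection, transient) + overhead`, with resolution-dependent
transients (0.016 s at 7,500; 0.064 s at 30,000; 0.128 s at 60,000).
Measured m/z has Gaussian ppm error; intensities have multiplicative
lognormal noise; a constant noise floor models detector background, and
detection anywhere downstream means exceeding three times that floor.

Isotope envelopes are computed from the averagine model by convolving
per-element extra-neutron distributions, so MS1 spectra show realistic
isotope clusters at `1.0033548 / z` spacing.

### Acquisition

The default method tiles the 400–1210 Th precursor range into 54 windows
of 15 Th with one MS1 scan per 18 MS2 scans (3 per cycle):

```{r}
plan <- plan_dia_cycle(400, 1210, 15, 18)
nrow(plan$windows)
plan$ms1_per_cycle
```

Three modes run on identical samples and seeds: plain `dia`, scheduled
`prm` (one MSxPRM per active target per cycle, with overload warnings when
the mandatory load exceeds the cycle budget rather than silent drops), and
`hybrid`. The hybrid trigger chain is: MS1 peak within 10 ppm of a watched
heavy precursor, above the intensity threshold (default 1e5 counts), inside
the retention-time window, not excluded → fast validation MS2 (7,500
resolution, 10 ms) → at least 4 declared fragments matched above the noise
floor → MSxPRM (two 1.4 Th windows, 116 ms maximum injection) → 5 s
dynamic exclusion. Every decision is written to a trigger log, and every
scan to a scan log whose durations always sum to the run clock.

### Quantification

Fragment chromatograms are extracted per channel from the MSxPRM scans,
summed into one trace per channel, and integrated by trapezoid. Peak
boundaries are determined on the heavy reference trace and *applied* to the
light trace, which is integrated without a threshold inside those bounds
(reference-guided integration): thresholding each faint light point
individually biases ratios low near the limit of detection. The estimate is
`light_area / heavy_area * spiked_heavy_fmol`. Status logic: `quantified`
when both channels integrate over at least 3 scan points; `below_LOD` when
the heavy reference was quantifiable but the light channel was not;
`missing` when the reference itself never produced a usable trace.
Calibration curves are least squares on log-log ratio versus nominal
amount, with a detection-based LOD (smallest level quantified in at least
half its replicates), reported in the conventional `"< x fmol/μl"` form.

## A worked comparison

```{r, eval = FALSE}
pairs <- make_pair_panel(10, rt_range_s = c(60, 420),
                         light_amount_fmol = 0.01,
                         heavy_amount_fmol = 100, seed = 19)
background <- generate_background(300, rt_range_s = c(0, 480), seed = 20)
sample <- bind_rows(pairs, background)
targets <- targets_from_pairs(pairs)

hybrid <- run_acquisition(sample, method_config(), "hybrid", targets,
                          run_length_s = 480, seed = 23)
dia <- run_acquisition(sample, method_config(), "dia", targets,
                       run_length_s = 480, seed = 23)

sum(sapply(seq_len(nrow(targets)), function(i)
  quantify_pair(hybrid, targets[i, ])$status == "quantified"))
sum(sapply(seq_len(nrow(targets)), function(i)
  dia_detect_pair(dia, targets[i, ])$light_detected))
```

At a 10 amol light level over a realistic background, the triggered MSxPRM
scans recover most pairs while the DIA arm recovers none: the narrow
co-isolation window and long injection give the light channel orders of
magnitude more ions per scan than its share of a crowded 15 Th DIA window.

## Numerical and design choices

Several constants are the package's own calibration, chosen at design time
so the simulator's operating points are realistic and internally
consistent; they are design parameters, not fitted values:

* **Flux scale (1e6 charges/s per fmol) and detector gain (10
  counts/charge).** Together these put a 100 fmol heavy spike just under
  the MS2 AGC target within the maximal 116 ms MSxPRM injection, and give
  MS1 apex responses a few-fold above the 1e5-count trigger threshold —
  so triggering happens on the rising edge of the peak and raising the
  threshold visibly clips the integrated peak, as real
  intensity-triggered acquisition does.
* **Noise floor (50 counts, detection at 150).** Calibrated so a ~10 amol
  light partner sits at the edge of MSxPRM detectability while remaining
  invisible to DIA, which is the regime where the hybrid scheme matters.
* **Background abundance cap (2000 fmol).** An uncapped lognormal
  occasionally produces one species so abundant that AGC starves every MS1
  scan for the whole run; the cap keeps the matrix hostile but physical.
* **Worst-case duty-cycle model.** The feasibility report assumes every
  active target fires once per exclusion period, each firing costing one
  validation plus one MSxPRM scan. This upper-bounds the triggered time
  fraction; real loads are lower because peaks are narrower than their
  scheduling windows.
* **y-ion-only target declarations.** y ions carry the C-terminal label,
  so they are channel-specific; b ions are identical in both channels and
  would be chimeric under co-isolation. Declaring only y ions also lets
  the on-disk target list carry heavy fragment m/z alone and reconstruct
  the light values from the label shift implied by the precursor pair.

## What the generator emulates — and what it does not

Emulated: AGC/injection-time coupling and its suppression of dim species
in crowded windows; resolution-dependent scan durations and their duty-cycle
consequences; isotope envelopes; ppm-scale mass error and multiplicative
intensity noise; trigger threshold/validation/exclusion dynamics including
peak clipping; co-isolation chimerism inside any isolation window;
scheduling overload.

Not emulated: chromatographic tailing, drift or run-to-run retention
shifts; ion suppression and matrix effects beyond AGC competition;
fragmentation chemistry (fragment sets are stochastic stand-ins, not
mobile-proton predictions); FDR-controlled spectral library search on the
DIA side — `dia_detect_pair()` is a transparent XIC rule, so DIA counts
here are comparable only *between modes of this simulator*, not to DIA-NN
or Spectronaut output; and real protein inference (proteins are declared
groupings of their peptides).

## Limitations

The simulator is desk-scale by intent: panels of tens of targets, hundreds
of background peptides and minutes-long gradients, where a real experiment
has hundreds of targets, tens of thousands of peptides and 110-minute
gradients. All directional behaviours (triggered sensitivity advantage,
duty-cycle stretch with panel size, completeness gains from below-LOD
calls) are scale-free claims of the model, but absolute counts are not
transferable to any particular instrument or sample.
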