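---
title: "Widefield ratiometric voltage imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Widefield ratiometric voltage imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(widevolt)
```

## The measurement and its model

FRET-based genetically encoded voltage indicators such as VSFP Butterfly 1.2
report membrane potential through *anticorrelated* intensity changes of two
fluorophores: depolarisation dims the donor (mCitrine) and brightens the
acceptor (mKate2). Two synchronised cameras image the two emission bands of
the same cortical window (here: layer 2/3 pyramidal neurons across a
hemisphere of awake, head-fixed mouse cortex) at 100 Hz, 200 frames per
trial, 12-bit counts. The acceptor/donor ratio

$$R(x,t) = \frac{A(x,t)}{D(x,t)}, \qquad
\frac{\Delta R}{R}(x,t) = \frac{R(x,t) - R_0(x)}{R_0(x)} \times 100\,\%$$

is the voltage readout: genuine voltage signals move the channels in
opposite directions and add in the ratio, whereas multiplicative artifacts
that move both channels together — above all the heartbeat-locked
hemodynamic oscillation — cancel.

They only cancel, however, if the artifact has the *same relative amplitude*
in both channels. In practice the modulation depths differ (different
emission bands overlap the hemoglobin absorption spectrum differently), so
the pipeline first **equalises** the channels: the heartbeat frequency is
found as the dominant peak of the amplitude spectrum (FFT over the lit
pre-stimulus segment, search band 5–14 Hz, the head-fixed mouse heart-rate
range), and the donor's fluctuations about unity are rescaled per pixel by
the ratio of acceptor to donor amplitude at that frequency. The acceptor is
the reference channel; the choice is arbitrary because the ratio is
invariant to which channel is rescaled when the gain is exact.

### Processing chain

Per trial, `preprocess_trial()` performs, in order:

1. **Spatial binning** (`bin_spatial()`, factor 4 by block averaging):
   1920 × 1200 sensor frames become 480 × 300 images (14.55 µm pixels).
2. **Vessel masking** (`make_vessel_mask()`): dark, non-fluorescent pixels
   (surface vessels, window imperfections) are excluded from *all* further
   computation, using a fixed count threshold shared across animals (an Otsu
   mode is available).
3. **Dark-offset subtraction** (`subtract_dark_offset()`): the per-pixel
   camera offset is the mean over frames 1–25, acquired before the
   excitation light turns on.
4. **Pre-stimulus normalisation** (`normalize_prestim()`): each pixel trace
   is divided by its mean over the baseline window, giving F/F0 with
   baseline exactly 1.
5. **Heartbeat equalisation** (`estimate_heartbeat_gain()`,
   `apply_equalization()`), as above.
6. **Ratio conversion** (`compute_drr()`): %ΔR/R with R0 averaged over the
   same pre-stimulus window.

Region-averaged traces (`region_trace()`) are unweighted means over the
valid pixels of atlas regions rasterised onto the window
(`rasterize_atlas()`); evoked-response metrics, paired-pulse adaptation and
voltage maps are computed from those traces and from the per-pixel stack.

## Frame-timing conventions

All configuration windows are 1-based inclusive frame ranges. The packaged
defaults encode one consistent trial timeline at 100 Hz:

| window | frames | rationale |
|---|---|---|
| dark (camera offset) | 1–25 | light off for the first 250 ms |
| baseline / R0 | 31–120 | 90 frames = 900 ms; a few frames after light-on are skipped while the LED settles |
| stimulus | 125 | stimulation 1000 ms after light-on |
| metric baseline | stim−10 … stim−1 | 10 frames = 100 ms |
| peak search | stim+2 … stim+10 | 20–100 ms post-stimulus, endpoints inclusive |
| hyperpolarisation | peak … stim+30 | to 300 ms post-stimulus |
| movement analysis | stim−10 … stim+60 | behaviour-camera window |

A note on the baseline window: a window of frames 30–120 and a count of 90
frames conflict by one (30–120 inclusive is 91 frames). The package defaults
to frames 31–120 — exactly 90 frames, 900 ms, ending 40 ms before the
stimulus frame — and every window is configurable.

## Response metrics and their edge rules

* **Peak** (`detect_peak()`): maximum of (trace − baseline mean) over the
  20–100 ms window; ties break to the earliest frame.
* **Inclusion** (`trial_inclusion()`): a trial is kept iff
  peak ≥ 2 × baseline SD. The boundary is *inclusive* — the exclusion rule
  is "less than two times the SD", so exactly 2 SD stays in. The degenerate
  all-flat case (SD = 0, peak ≤ 0) is excluded.
* **Hyperpolarisation** (`measure_hyperpolarisation()`): minimum of the
  baseline-subtracted trace from just after the peak to 300 ms; reported as
  a positive magnitude with the signed excursion kept alongside; a trace
  that never dips below baseline reports 0.
* **Half-decay** (`decay50()`): first crossing of half the peak amplitude
  after the peak, linearly interpolated between frames (a strict
  frame-resolution mode exists); never reached ⇒ `NA`, not an error.
* **Paired-pulse adaptation** (`paired_pulse()`): each stimulus' amplitude
  is measured in its own 20–100 ms window against the signal immediately
  preceding *that* stimulus. "Immediately preceding" is implemented as the
  mean of the 2 frames (20 ms) before the stimulus — one frame is
  noise-dominated at this SNR — and is configurable down to 1 frame. The
  ratio amp2/amp1 is undefined (flagged `NA`) when amp1 ≤ 0.
* **Asymmetry index** (`asymmetry_index()`): the cylinder-test statistic
  AI = (right − both/2) / (right + left + both). With this (default) minus
  variant the theoretical symmetric value 0.5 is attained only when
  `both = 0`; a plus variant — plausibly the intended form, since it gives
  0.5 for any `both` count — is provided as an option. The ambiguity is
  documented rather than silently resolved.

## Movement-based trial selection

Trials are classified from a behaviour camera synchronised with the imaging
cameras. Every frame from 10 before to 60 after the stimulus is compared,
pixel by pixel, against the stimulation frame; a pixel "changes" when its
absolute difference exceeds a per-pixel threshold calibrated from a
recording of a stationary fabric mouse (`calibrate_noise()`). The threshold
statistic is the per-pixel *range* over the stationary recording (the
maximum difference between any two frames): this is the reading of
"difference between the frames" that keeps the calibration independent of
which frame later serves as the reference, and it guarantees the stationary
recording itself classifies quiet. Two numerical points matter:

* with a max-type statistic over *N* frames, a fresh noise sample exceeds
  the calibrated maximum with probability ≈ 1/(N+1) per pixel, so the
  reference recording must be much longer than a trial; the synthetic
  stand-in uses 1000 frames, putting the stationary false-change rate near
  0.1 % — well below the decision boundary;
* the classifier labels a trial "movement" when any analysed frame's
  changed fraction *strictly* exceeds 0.5 % (a separating value, so the
  boundary itself is quiet). The 0.5 % separator is an empirical constant
  from visual classification of behaviour videos against the computed
  fractions; it ships as the package default and is configurable.

A guard flag additionally records whether the exceedance fell within
±100 ms of the stimulus. The default pipeline analyses quiet trials only;
`include_movement = TRUE` overrides the exclusion but keeps the labels.

## Voltage maps

`trial_map()` subtracts the per-pixel mean over the 10 pre-stimulus frames
(ΔR = ΔR/R − baseline); `average_aligned_maps()` rigidly aligns trials
(translate bregma to a common origin, rotate the midline to vertical) and
averages per pixel over contributing trials. Resampling is
nearest-neighbour, deliberately: the upstream analysis applies *no*
additional spatial or temporal filtering, and nearest-neighbour is the
resampling that introduces none. Pixels with no contributing trials are
`NA`, never rendered as 0. Rendering uses the standard diverging convention
(red saturating at +0.5 %ΔR/R, blue at −0.5 %). Trials are weighted
equally (not per animal); per-animal weighting can be obtained by averaging
per-animal maps first.

## Atlas registration

Region polygons (S1FL, S1HL, S1BF, M1, M2) are millimetre coordinates
relative to bregma (x lateral, y rostral), rasterised onto a window through
translation to the annotated bregma pixel, rotation by the midline angle and
the pixel size. The alignment model is rigid only — no scaling between
animals — because bregma and the interhemispheric fissure are the only
references available. Pixel membership uses pixel-centre containment with
boundary pixels counted in (deterministic, order-independent for disjoint
polygons). The packaged layout in
`inst/extdata/atlas_regions_mm.yaml` is an *approximate*, synthetic encoding
of the Paxinos-derived surface map — the source atlas publishes no
machine-readable surface vertices — and is a first-class, user-replaceable
input. The rasteriser is implemented in-package (scanline/even-odd with the
inclusive-boundary rule) because no installed geometry library exposes
control over boundary semantics.

## The synthetic forward model

No raw recordings are publicly deposited, so validation rests on a forward
model with known ground truth (`synthetic_config()`,
`generate_voltage_truth()`, `render_trial()`, `generate_session()`).

**Voltage kernels.** Each region's evoked response is a normalised
difference of exponentials, zero before stimulus onset + 10 ms (the sensory
conduction delay), with the rise time constant solved so the kernel peaks at
the configured latency; this is the minimal smooth kernel matching the three
observables a trace summary provides (onset, peak time, amplitude). The slow
hyperpolarisation is a second, negative kernel of the same family starting
at 100 ms (where the slow component visibly begins) and peaking at
120–180 ms depending on region. Because the two components do not overlap in
the peak-search window, the *measured* peak of a noiseless trace equals the
configured amplitude exactly — the normalisation contract the recovery
experiments rely on. Defaults encode the published means: forepaw → S1FL
0.195 %ΔR/R at 59.83 ms with a smaller M1 response (0.112 % at 61.96 ms);
whisker → S1BF 0.156 % at 50.58 ms; the secondary depolarisations and
cross-modal hyperpolarisation amplitudes are plausible one-time choices
(0.03–0.08 %), as they are not printed as numbers.

**Channel model.** For lit frames,

$$D = \mathrm{offset} + F_D\,(1 - g_D V/100)\,(1 + m_D \sin 2\pi f_{hb} t + \varphi) + \varepsilon,$$

and the acceptor analogously with $+g_A$ and $m_A$; dark frames and vessel
pixels carry offset (+ noise) only; counts are rounded and clipped to 12
bits after noise. The heartbeat is a single 10 Hz sinusoid — the
equalisation step uses only the dominant spectral peak, so a harmonic train
would add realism without testing anything further. Modulation depths
default to 0.02 (donor) and 0.01 (acceptor): *unequal*, so the equalisation
step is load-bearing. The voltage truth is expressed in % units of the
equalised ratiometric readout; the channel gains therefore default to
$g_D = g_A = 1/(1 + m_A/m_D)$, making the equalised ratio's sensitivity to
the configured voltage exactly 1. Region membership for rendering is defined
on the analysis (binned) grid and replicated to raw pixels, so recovery
experiments measure pipeline error rather than partial-volume mixing at
region borders.

**Noise.** The default Gaussian noise (SD 10 counts per raw pixel at the
reduced 240 × 384 scale) is chosen to reproduce the *region-level*
shot-noise budget of the instrument: a region average of a real S1FL-sized
patch carries ≈ 0.01 %ΔR/R per-frame noise, and the default reproduces that
figure at the reduced scale. Two consequences worth knowing:

* the per-pixel, per-frame ratio noise (~0.18 %) dwarfs a 0.2 % response —
  single-pixel traces are meaningless, exactly as with the real instrument;
* the peak statistic (max over a 9-frame window) has a *positive* noise
  bias of roughly +5 % of the amplitude at this SNR. The published means
  were measured with the same max rule on comparably noisy traces, so the
  recovery comparison is like-for-like; the bias is visible in the recovery
  experiments and is not corrected away.

**What the generator does not emulate.** Slow hemodynamic drifts,
breathing, photobleaching, spiking activity (the indicator reports
sub-threshold voltage), biological trial-to-trial amplitude variability,
and any real registration error (bregma is exact in synthetic sessions).
Passing recovery tests therefore demonstrates correctness of the signal
path under the stated noise model, not robustness to every artifact of real
recordings; the optional multiplicative drift terms are stress-test knobs,
off by default.

**Problem sizes.** Validation experiments run 100 trials per condition at
the reduced 240 × 384 raw scale (a single scale parameter of the native
1200 × 1920 geometry; the millimetre atlas geometry is scale-invariant
through the pixel-size metadata). Unit tests use a 48 × 80 scale. The
rendering and binning inner loops are compiled (Rcpp), with a
seed-deterministic portable RNG so identical configurations reproduce
stacks bit for bit.

## Reproducibility and provenance

Every generator and pipeline entry point takes an integer seed; per-trial
seeds derive deterministically from it. `run_pipeline()` records settings,
package version, per-trial failures and movement labels in a provenance
object that `write_outputs()` serialises as JSON beside the tidy CSVs and a
data dictionary with units. Deterministic stages are bit-identical on
rerun.

## Known limitations

* The packaged atlas polygons are approximate; region-trace absolute values
  on real data depend on the user's own layout.
* Per-pixel heartbeat gains are clipped to [0.2, 5] and 3 × 3
  median-filtered by default (FFT amplitude ratios are unstable at low
  SNR); both behaviours can be disabled, and a global-gain mode is offered
  because "per pixel" versus "global" equalisation is ambiguous in the
  source description.
* Whether the original FFT used the whole 2 s trace or the pre-stimulus
  segment is unstated; the pre-stimulus lit segment is used to avoid
  stimulus-evoked power at harmonics of the response.
* Group-level statistics (treatment comparisons) are out of scope by
  design: the pipeline emits tidy per-trial tables for external tools.
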