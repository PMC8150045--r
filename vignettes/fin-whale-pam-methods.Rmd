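---
title: "Methods: passive acoustic indices of fin whale 20-Hz pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive acoustic indices of fin whale 20-Hz pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finpam)
```

## The analysis problem

Fin whales (*Balaenoptera physalus*) advertise their presence with a highly
stereotyped vocalisation, the 20-Hz pulse: a ~1-second downsweep from about
28 Hz to about 15 Hz, often accompanied by a simultaneous higher-frequency
component near 86 Hz. Moored autonomous recorders can log these pulses for
years, and several derived metrics turn the raw audio into ecological time
series:

* **LTS** — a long-term spectrogram built from one Welch power spectral
  density (PSD) per analysed file, each computed on the quietest 10 s of
  that file to suppress mooring (flow/shackle) transients.
* **FIN indices** — band signal-to-noise ratios of a call band against the
  mean of two bracing noise bands, e.g. FIN86 uses 86–88 Hz against 80–82
  and 92–94 Hz: `10 log10( S_sig / (0.5 (S_lo + S_hi)) )` on linear
  densities. Because a calibration error shifts all three bands equally,
  FIN is exactly invariant under constant calibration offsets.
* **CAB** — call abundance: countable 20-Hz pulses per hour of screened
  audio, with counts above 100 per 10-min file censored ("calls merge")
  and files with excessive ambient noise excluded.
* **DAO** — daily acoustic occurrence: a day is "present" as soon as the
  first individually recognisable pulse is found; the chorus formed by many
  distant overlapping callers never establishes presence.
* **Environmental covariates** — ADCP echo intensity converted to mean
  volume backscatter strength (MVBS) with the Deines sonar equation, and
  daily sea-ice concentration averaged over the 30-km acoustic detection
  radius.
* **Diel statistics** — each counted file is classed by solar altitude into
  light / nautical twilight (0 to −12°) / dark, and call abundances are
  compared across regimes with a Kruskal–Wallis test at α = 0.05.

The package implements every step as tested functions, and a seeded
synthetic-data generator emulates the recorders and the acoustic scene so
the whole chain can be exercised, end to end, without any real recordings.

## Calibration

Stored ADC counts convert to sound pressure level as
`SPL = 20 log10(c) − S − G − M` with hydrophone sensitivity `S = −164` dB
re 1 V/µPa, amplifier gain `G = 22` dB and digital gain `M = 84` dB, i.e. a
combined constant of +58 dB. The constant is applied per sample
(`counts_to_pressure()`), not to derived metrics, because a per-sample gain
commutes with linear spectral estimation; band levels computed from the
calibrated series are then already in µPa²/Hz.

## Spectral estimation

`welch_psd()` is a standard averaged modified periodogram: segments of
`nfft` samples (no zero padding), Hann or Hamming window, mean removal
only, one-sided density scaling so that `sum(density * df)` recovers the
variance. The three deployed analysis chains are available as presets:
2¹⁴-point Hamming / 50 % overlap at 32 768 Hz for LTS and FIN (2.0 Hz
resolution), 20 000-point Hann for occurrence screening (1.6 Hz), and
334-point Hann / 90 % overlap on 500-Hz-decimated audio for call counting.
For the last chain the configuration tables in circulation quote a window
duration and resolution that are mutually inconsistent with a 334-point FFT
at 500 Hz; the implementation follows the explicit point count (334,
≈1.5 Hz).

"Quietest" in the LTS sense means minimal broadband mean-square pressure
over a 10-s window at a 1-s hop (both configurable), ties broken by the
earliest offset. The selection is exactly equal to brute-force search (a
property the test-suite checks against an independent re-computation on 50
random files) and is invariant to adding loud energy outside the selected
window.

Band densities average the linear PSD over bins whose *centres* fall in the
closed band interval — with 2-Hz bins, "86–88 Hz" means the 86 and 88 Hz
bins. Published band conventions differ between deployments; all of them
are available via `fin_band_presets()`.

## The automated detector

The original screening of such data is manual. The package substitutes a
documented automated detector (`detect_pulses()`) and characterises it on
synthetic ground truth; it is never asserted to replicate analyst
judgement. The stages:

1. Hann STFT at ~1.5 Hz resolution, 90 % overlap, in dB.
2. Per-frequency median subtraction (stationary noise and any sustained
   chorus) and per-frame median subtraction over 10–35 Hz (broadband
   transients).
3. Cross-correlation with a 28→15 Hz, 1-s downsweep kernel; the score is
   the kernel-weighted mean dB ridge excess. Local maxima above 7 dB with
   ≥0.5 s separation become candidates.
4. A Viterbi ridge tracker (summed excess minus 3 dB per Hz of
   frame-to-frame jump) extracts the spectro-temporal trajectory around
   each candidate. The jump penalty matters: where a pulse sweeps out of a
   chorus-filled band, per-frame floors differ and a greedy argmax tracker
   tears the ridge apart.
5. Rule-based classification (`classify_event()`): *fin20* for a
   monotone-decreasing ridge sweeping ≥8 Hz within 15–30 Hz in ≤2 s
   (assessed from the excess-weighted slope, with allowances for STFT
   smear of about one window length in duration and ~4 Hz at the band
   edges, and up to ~2 resolution bins of upward jitter); *zcall* for a
   tonal segment near 26–28 Hz of at least 1.5 s nominal duration
   (≥1.2 s measured, after edge trimming) preceding a ≥4 Hz downward
   step — the Antarctic blue whale's bi-tonal signature, the main
   confounder in the 20–22 Hz band; *chorus* for ≥60 s of elevated
   15–30 Hz band energy without a resolvable ridge.

On the pulse-in-noise validation scenario (120 one-minute files, per-event
band SNR drawn from 10–20 dB) the operating point at the default threshold
is recall ≈ 0.93 and precision ≈ 0.97, with zero false alarms over 100
noise-only files and recall degrading towards low SNR. Under peak-season
chorus masking recall drops to ≈ 0.84 — automated counting is known to
underestimate during intense calling, and users comparing CAB against
ground truth should expect that bias.

Counting (`count_interval()`) censors files above 100 calls (reported as
the lower bound) and excludes files whose ambient level exceeds the 95th
percentile of the deployment's file levels. The ambient level is measured
over 35–80 Hz — *outside* both call bands — so broadband storm and flow
noise trips the gate while a loud biological chorus does not; a gate on
full-band level would systematically discard the most call-rich files.
`cab()` then pools calls over counted minutes, omitting censored and
excluded files from numerator and denominator alike.

## The synthetic scene

`synthesize_recording_set()` emulates a duty-cycled deployment
(`aural_like`: 5 min every hour; `sonovault_like`: continuous 10-min
files) and writes ordinary 16-bit PCM WAV files plus a ground-truth event
log. Its statistical structure:

* **Seasonality.** Expected calls per 10-min interval follow a Gaussian
  season (default onset 1 March, peak 12 May at 84 calls/10 min, width 28
  days — placing ~99 % of calls between early March and mid-July) over a
  small year-round background. Per-interval counts are Poisson.
* **Song regularity.** Each file's Poisson count is laid out
  quasi-periodically (jittered regular spacing) rather than i.i.d.-uniform:
  20-Hz pulses are sung in regular sequences, and this keeps pulses of a
  bout from overlapping.
* **Chorus.** Distant callers are drawn per file as
  `Poisson(distant_ratio × rate)`; they contribute exact band-limited
  Gaussian noise at 16–29 Hz and (for the HF component) 85.5–88.5 Hz with
  in-band density `chorus_gain × N_distant` times the ambient density.
  Two choices here are deliberate. First, the chorus bands sit ≥3.5 Hz
  clear of the FIN noise bands because the Welch main lobe at 2-Hz
  resolution spans ±4 Hz: a chorus edge closer than that leaks into the
  bracing bands and caps the index. Second, the default gain (2.4 per
  caller) puts the band SNR in the chorus-dominated regime across the
  season, where FIN responds linearly to call abundance and a tenfold rate
  change moves the smoothed index by ≈10 dB, the incoherent-source
  relation `10 log10(N₂/N₁)`. The absolute peak value of the synthetic
  index (~21 dB) is a consequence of that choice, not a target; with an
  ambient-dominated gain the same pipeline yields lower peaks and a
  compressed rise, because a month at a tenth of the peak rate is then no
  longer chorus-dominated.
* **Event levels.** Per-event SNR (default uniform 10–20 dB) references
  the file's current in-band background *including* chorus: a "clearly
  recognisable individual signal" is one that stands out of the chorus,
  which is what manual screening counts.
* **Confounders.** Optional Antarctic blue whale Z-call surrogates (1.5-s
  27 Hz tone, downsweep to 19 Hz, 3 s total — long enough to carry the
  bi-tonal signature the classifier keys on), and storm transients as
  scheduled broadband noise bursts, which exercise the exclusion gate.
* **Determinism.** A configuration (including its seed) fixes the output
  byte-for-byte; every event is logged with its exact sample index, and
  events falling in duty-cycle gaps can be simulated and flagged
  unrecorded.

`synthesize_adcp()` produces ensembles every 3 h 45 min (45 pings at 5-min
intervals) with 16-m bins (first bin 24.52 m), counts in 0–255, and a
Gaussian scattering layer whose centre depth oscillates with a 24-h period,
deepest at local noon. `synthesize_ice_field()` produces daily 6.25-km
gridded concentrations with an austral-winter envelope peaking around 1
September.

What the generator does **not** emulate: multipath or normal-mode
propagation (the detection radius enters only as the 30-km ice-averaging
radius), coloured ambient spectra beyond white noise plus storm bursts,
clock drift, recorder self-noise structure, and analyst-level judgement on
marginal calls. Passing tests therefore demonstrate the correctness and
calibration of the *analysis chain*, not field performance on real
recordings.

## Environmental modules

`mvbs()` evaluates
`MVBS = C + 10 log10((Tx + 273.16) R²) − L_DBM − P_DBW + 2αR + Kc(E − Er)`
per bin. Only the system constant `C = −159.1` dB is an instrument-documented
value; pulse length, power, absorption (0.027 dB/m), `Kc` (0.45 dB/count)
and `Er` are representative defaults that a deployment should override.
The analysis window is 50–200 m depth (the upper 50 m suffer side lobes,
bubbles and ice; one source text mentions 50–300 m once — the window is
configurable). Noon (10:00–14:00) and midnight (22:00–02:00) local windows
give monthly mean backscatter-maximum depths; migration amplitude is noon
minus midnight, positive for normal diel vertical migration. Recovery on
synthetic ensembles is accurate to within one 16-m bin; the small (~6 m)
negative bias comes from the range-dependent terms tilting the within-layer
maximum.

Ice averaging takes the unweighted mean over pixels whose centres lie
within a great-circle radius (sphere 6371.0 km) of the site; 30 km
corresponds to ≈2.8 × 10³ km². Local time is the fixed offset UTC − 3 h
40 min (true local time of meridian 56° W). Solar altitude comes from a
standard low-precision almanac algorithm (declination from the solar
ecliptic longitude, hour angle from sidereal time), geometric (no
refraction), accurate to a few hundredths of a degree — far finer than the
0°/−12° class boundaries, which are assigned to twilight when hit exactly.

## Statistical conventions

* The 14-day running mean is centred (±7 days, half-open window), truncates
  at the series edges, and ignores missing values.
* `kruskal_wallis()` uses mid-ranks with tie correction; a fully tied
  sample reports H = 0, p = 1 (no rank information) rather than NaN. With
  three light regimes, df = 2 and the α = 0.05 critical value is 5.99.
  Each non-excluded, non-censored file contributes one observation;
  intervals spanning a regime boundary take their midpoint's regime. Under
  a 1000-replicate null the empirical size is within 0.05 ± 0.02, and a
  twofold median shift in one regime at n = 50/group is detected with
  power > 0.8 (implementation-chosen sanity threshold).
* Subsampling schemes ("every seventh file of every sixth day", etc.)
  anchor at the first available file and day; the phase is configurable
  because the original analyses do not state it.

## Problem sizes

The bundled analyses and tests run reduced-size scenarios that keep the
statistical structure intact: the year-long index deployment uses 30-s
files four times a day at 1024 Hz (2-Hz PSD bins, identical FIN band
arithmetic), the call-abundance deployment one-minute files every 10
minutes at 500 Hz, 60 synthetic ADCP days and a 365-day ice year. These
sizes were chosen so a complete pipeline run finishes in about a minute on
one core while every estimator still sees hundreds to thousands of events;
all of them scale up through `scenario_config()` without code changes.

## Known limitations

* The detector's chorus-season recall bias (above) propagates into CAB
  during the peak weeks; DAO is robust to it because presence needs only
  one detection per day.
* FIN21 is structurally contaminated by Z-call energy in the 20–22 Hz
  band; the package reports it as-is (a config flag can mask
  Z-call-dominated intervals) and FIN86 is the preferred index.
* The WAV layer handles mono 16-bit PCM only; 24-bit recorder output is
  represented at 16 bits with a documented scale constant, since bit depth
  carries no signal content at the SNRs studied here.
* Absolute-abundance inference from FIN or CAB is out of scope; the
  indices support relative, between-deployment comparison only.
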