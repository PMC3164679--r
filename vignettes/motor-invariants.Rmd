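---
title: "Motor invariants of plosive consonants: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor invariants of plosive consonants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Stop consonants are produced by a stereotyped motor act: an articulator
closes the vocal tract completely, holds, and releases. For /b/ and /p/ the
closure is made by the lips (bilabial); for /d/ and /t/ by the tongue tip
against the upper teeth (dental). The *motor invariant* hypothesis holds
that this kinematic act — not its variable acoustic consequences — is the
stable signature of the phoneme class, and therefore that features derived
from articulator kinematics should discriminate bilabial from dental stops
more robustly than audio features, especially across speakers, across
coarticulation contexts, and under acoustic noise. When no articulograph is
available at recognition time, an *audio-motor map* (AMM) — a regression
from the speech signal to articulator kinematics — can stand in for the
measured trajectories.

This package implements that entire analysis as a reusable, seeded pipeline:
a synthetic corpus generator (the original 6-speaker electromagnetic
articulography corpus is not publicly available), kinematic plosion
segmentation, the audio-motor map, four per-segment feature encodings,
RBF-kernel support-vector classifiers, and six cross-validation schemas with
balanced-error evaluation, including a noise-robustness experiment.

## The plosion and its detection

Let $d(t) = \lVert s_1(t) - s_2(t) \rVert$ be the Euclidean distance between
two articulator sensors — `lio` (lips opening) or `ttu` (tongue-tip to
upper-teeth distance) — with velocity $v$ and acceleration $a$ (denoted
vlio, alio, vttu, attu). A **plosion** is the interval $[t_1, t_2]$ where

* $v(t_1) = 0$ and $a(t_1) > 0$ — the onset of opening, and
* $v(t_2)$ is the first subsequent velocity maximum, $a(t_2) = 0$.

Cutting at the velocity peak rather than at maximal opening keeps the
segment confined to the release and keeps contamination by the following
phone minimal.

`detect_plosions()` operates on a moving-average-smoothed distance signal,
with velocity and acceleration from central differences (one-sided at the
ends). Zero crossings are located by linear interpolation between samples
and snapped to the nearest sample, since sub-sample landmarks are
meaningless at extraction granularity. Candidates outside a duration window
(default 20–200 ms) are dropped.

Two numerical choices matter here:

* **Smoothing window = 3 samples** (15 ms at 200 Hz). The detection support
  of a moving average of width $w$ followed by central differences is
  $\pm(w-1)/2 + 1$ samples; with $w = 5$ the onset estimate can land 3
  samples early, which is incompatible with the 2-sample localization this
  pipeline demands of itself at a 200 Hz motor rate. $w = 3$ bounds the
  support at $\pm 2$ samples while still suppressing sample-level noise.
* **Vetting.** The corpus this method was designed for was segmented
  semi-automatically — every kinematic candidate was auditioned by an
  experimenter. `vet_segments()` replaces that judgment by overlap with
  ground-truth intervals (≥ 50% of both intervals, both directions) in
  synthetic mode, or by a caller-supplied callback on real data. False
  positives on the non-critical channel (e.g. a lip gesture during /d/)
  are expected and are exactly what vetting removes.

## The synthetic corpus

`make_corpus()` generates the full balanced design — speakers × consonants
{b, p, d, t} × coarticulating phones {a, e, i, o, u, r, s} × word position
{initial, medial} — of synchronized audio (16 kHz) and articulator
trajectories (200 Hz), with ground-truth landmarks. Motor sample $k$ is
simultaneous with audio time $k/f_s^{motor}$.

**Kinematics.** The critical channel executes: open posture → closing bell →
an exactly constant hold near zero aperture (0.3 mm) → a release whose
*velocity profile is a raised cosine*: $v(t) \propto 1 - \cos(\pi (t -
t_1)/T)$, so $v(t_1)=0$ with $a(t_1)>0$, the peak falls at $t_2 = t_1 + T$,
and the gesture is $C^2$ everywhere. Gesture phase durations are quantized
to the 5 ms motor frame, so true landmarks lie on motor samples — at this
resolution the quantization is far below articulatory timing variability.
The release duration $T$ is drawn per speaker and utterance from 35–60 ms:
below ~32 ms the central-difference velocity at the true onset exceeds 1% of
the peak ($\pi^2 h^2 / 24 T^2$ at sample spacing $h = 5$ ms), i.e. the
landmark conditions would no longer be numerically verifiable at the motor
rate. The non-critical channel is slow postural drift — a seeded sum of
three sub-0.6 Hz sinusoids (σ = 1.5 mm): smooth, landmark-free, and
unpredictable from the audio. Band-limiting it at speech-gesture rates
(several Hz) instead would manufacture spurious duration-qualifying
"plosions" on nearly every utterance, defeating its role as the
unconstrained control channel.

**Speakers.** A profile (`make_speaker()`) draws articulator scales
(0.8–1.3× on each channel), plosion timing means and jitters, base formants
and pitch from documented ranges, deterministically per seed.

**Audio.** The waveform deterministically encodes the critical articulator's
state, which is what gives the audio-motor map signal to learn:

* closure: near-silence, plus a faint low-frequency voicing bar for the
  voiced members /b/, /d/ (amplitude 0.0015 — voicing is irrelevant to the
  bilabial/dental contrast but keeps the class pairs acoustically distinct);
* release: a noise burst whose envelope follows the critical channel's
  opening velocity and whose band centre is class-dependent — low for
  bilabial (~1.1 kHz), high for dental (~3 kHz) — modulated by a speaker
  factor (inverse articulator scale × inverse base F2, span ≈ 0.64–1.56), an
  anticipatory coarticulation factor ($(F_2^{phone}/1400)^{0.45}$), and
  token-level log-normal jitter (σ = 0.25). These factors overlap the class
  distributions *across* speakers while keeping them mostly separated
  *within* a speaker — the structure that makes speaker-independent audio
  classification genuinely harder than speaker-dependent, as the analysis
  presupposes;
* following phone: onsets at release + voice-onset time (10 ms voiced /
  35 ms voiceless), its amplitude gated by the articulator aperture (an open
  mouth radiates; a closed one does not), with formants gliding from a
  class-dependent locus (bilabial F2 ≈ 800 Hz, dental F2 ≈ 1800 Hz,
  exponential, τ = 25 ms) to the vowel target — the locus-theory transition
  cue for place of articulation; /s/ is a high-band noise, /r/ a low-F3
  tone. Medial-position utterances carry a preceding vowel faded out by the
  closing aperture;
* a 0.0008 recording noise floor throughout.

Amplitudes (vowel 0.85, burst peak 0.05) put the burst 20–25 dB below the
vowel nucleus, in the realistic range for stop bursts. This matters for the
noise experiment, whose noise scale is each utterance's waveform standard
deviation: at twice that scale the burst — the main class cue — is fully
masked, while the vowel-borne transition cue degrades more gracefully.

**What the generator does *not* emulate.** No vocal-tract resonance model,
no lexicon or prosody, no sensor noise or head-movement artifacts, no
electroglottography. Classes are separable *by construction* in the
kinematics (disjoint critical-channel dynamics), so real-motor error rates
near zero say nothing about articulograph noise in real recordings; the
meaningful results are the *orderings and trends* across feature sets,
schemas and noise levels, which is also all this pipeline asserts.

## The audio-motor map

`train_amm()` regresses each motor sample of (vlio, alio, vttu, attu) from a
sliding spectrogram context: 20 ms Hamming slices every 10 ms, a triangular
Mel filterbank (100 Hz – 8 kHz), log-compressed; for each motor sample the
context concatenates the slices centred on the slice nearest that sample's
time ((context−1)/2 on each side, replication-padded at the edges; default
19 slices ≈ 200 ms of speech). The targets are restricted to the vetted
segments, but the spectrogram is computed over the whole utterance waveform:
a ~200 ms context cannot fit inside a 35–100 ms segment, so the sliding
window necessarily reads the surrounding audio (closure silence before,
vowel transition after) — which is also where its noise robustness comes
from.

The network has one hidden layer of logistic sigmoids and sigmoid outputs;
targets are affinely mapped per channel into (0.1, 0.9), inside the
logistic asymptotes, with exact inversion stored in the model. Inputs are
raw log-Mel values — no per-sample normalization, preserving the time
structure of the context. The loss is a regularized mean-square error,
$r \cdot \mathrm{MSE} + (1-r)\,\overline{w^2}$ with $r = 0.95$, implemented
through the **nnet** backend whose weight-decay least-squares objective
equals this loss up to a positive constant (the decay coefficient is derived
from $r$, the sample count and the weight count, so minimizer and
early-stopping order are unchanged). Training proceeds in warm-started
chunks with early stopping on a held-out validation set drawn from
training-side utterances only (10%, class-stratified, per split), repeated
over seeded random restarts; the best-validation checkpoint of the best
restart is kept. Any optimizer honoring this loss-plus-early-stopping
contract would do; BFGS (nnet's optimizer) replaces scaled conjugate
gradients, which no installed R package provides.

Reconstruction quality is summarized by NRMSE — RMSE divided by the *test
set's* target range — against the closed-form mean-predictor baseline
(population SD / range of the test targets), and by the per-segment Pearson
correlation between reconstructed and real trajectories grouped by class.
The **double dissociation** — vlio reconstructed better from bilabials than
from dentals, vttu better from dentals — follows from the generator's
structure: the audio encodes only the *critical* articulator, so the
non-critical channel is unpredictable and its correlations hover near zero.

## Feature sets and classifiers

* **Audio**: 7 slices of 20 ms spread uniformly across the segment
  (overlapping when the segment is short, gapped when long), each yielding
  13 Mel-cepstral coefficients plus first- and second-order across-slice
  differences — 273 values, fixed length regardless of duration.
* **Real motor**: for each of vlio, alio, vttu, attu, the four coefficients
  of an ordinary least-squares cubic fit on time rescaled to [0, 1] — 16
  values abstracting the gesture's shape from its duration. The cubic-fit
  reading (one global least-squares cubic per channel) is the only
  interpretation consistent with "four coefficients per signal".
* **Reconstructed motor**: the same 16 coefficients computed from
  AMM-reconstructed trajectories.
* **Joint**: the average of the audio and reconstructed-motor classifiers'
  posterior probabilities, thresholded at 0.5 (a tie goes to dental — an
  arbitrary but fixed rule).

Classification uses a C-SVM with Gaussian kernel (libsvm via \pkg{e1071}).
Motor feature sets are z-scored dimension-wise with training statistics
(zero-variance dimensions dropped and recorded); audio features are used
raw. $(C, \gamma)$ come from a grid search minimizing 5-fold inner
cross-validated balanced error on the training split (ties toward the
smallest cost, then smallest γ); the default lattice is $C \in 2^{-5..15}$,
$\gamma \in 2^{-15..3}$ in powers of four. Posteriors are approximate by
construction: a Platt sigmoid fitted on cross-validated decision values
(libsvm's internal probability training is not deterministic across runs,
so the calibration is done here, seeded).

The evaluation metric is the **balanced error rate**,
$1 - (\mathrm{recall}_{bil} + \mathrm{recall}_{den})/2$: a constant
predictor scores exactly 0.5 regardless of class imbalance.

## Cross-validation schemas and experiments

`make_splits()` builds six schemas over utterances: `overall` (k = 6 random
equal folds — six matches the speaker count and keeps folds equal),
`spk5vs1` / `spk3vs3` / `spk1vs5` (every m-subset of speakers trains, the
complement tests: 6, 20, 6 splits), `coart4vs1` / `coart3vs2` (every
m-subset of the five vowels trains; the held-out vowels *plus /r/ and /s/,
which never appear on a training side*, test: 5, 10 splits). Every split is
audited programmatically for disjointness and group exclusivity before use,
and each reserves the stratified 10% AMM validation set.

Experiments: (1) feature-set comparison under `overall`; (2) the same under
the grouped schemas; (3) noise robustness — white noise with standard
deviation equal to `level` × the utterance's waveform SD, training side one
realization per utterance, test side `replicates` realizations; audio and
reconstructed features are recomputed from noisy audio (the AMM retrained
per level on noisy audio with clean kinematic targets), real-motor features
untouched and therefore bit-identical across levels. Whether training audio
is also corrupted is configurable (`noise_on_train`); the default is yes —
with clean-only training, every audio-derived feature set collapses to
chance at high noise and the comparison degenerates. Feature sets are
compared within schema by two-tailed pooled-variance (Student) t-tests on
per-split balanced errors; means are reported ± one standard error over
splits. Paired tests would also be defensible — the unpaired reading of
"two-sample t-test" was chosen and is noted here.

## Problem sizes and determinism

All randomness flows from one master seed through named substreams
(`derive_seed()`), so every run — corpus, splits, network initializations,
noise realizations — is a pure function of (config, seed), and result files
carry the config hash and seed in their headers.

The analysis scripts, the test suite and `scripts/acceptance.R` run the
pipeline at documented reduced sizes: 16 Mel filters, 7-slice contexts, 16
hidden units, 2 restarts, ≤ 8 early-stopping checks of 30 epochs, at most
1500 training samples per AMM fit, and a 6-point SVM grid
($C \in \{1, 100\}$, $\gamma \in \{10^{-3}, 10^{-2}, 10^{-1}\}$); the noise
experiment uses levels {0, 1, 2} × utterance SD with 5 replicates. These
sizes were chosen once as the smallest at which every qualitative property
of the analysis (detection fidelity, baseline-beating reconstruction, the
double dissociation, the feature-set ordering, the noise trends) is stable
across seeds; the package defaults (`mi_config()`) remain at the full-size
settings (24 filters, 19 slices, 100 hidden units, 5 restarts, the full
grid, 7 noise levels × 10 replicates).

## Known limitations

* Real-motor error rates are ~0 on synthetic corpora because the kinematic
  classes are disjoint by construction; only orderings and trends transfer
  to real data.
* The AMM resolves the acoustic-to-articulatory inversion only because two
  articulators and a deterministic audio encoding are involved; the
  one-to-many inversion problem of real speech is out of scope.
* The vetting callback path is provided for real corpora but exercised here
  only with ground-truth vetting.
* Velar stops (/k/, /g/) would need a tongue-dorsum channel that neither
  the generator nor the detection configuration currently includes.
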