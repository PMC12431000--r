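---
title: "Topology-enhanced temporal decoding of fNIRS signals: models and methods"
author: "topofnirs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-enhanced temporal decoding of fNIRS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The decoding problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through optical-density changes at two near-infrared
wavelengths. A brain-computer-interface decoder receives short epochs
of oxygenated (HbO) and deoxygenated (HbR) hemoglobin concentration
changes across many optode channels and must assign each epoch to a
task class. The signals are slow (~10 Hz sampling), delayed by
neurovascular coupling, and contaminated by Mayer waves (~0.1 Hz),
respiration (~0.3 Hz), cardiac pulsation (~1 Hz), drift and
instrument noise. `topofnirs` implements a decoder that augments the
raw multichannel time series with explicit functional-connectivity
structure, on the premise that tasks reorganize the coupling between
cortical regions as much as they modulate amplitudes.

# From photons to epochs

The modified Beer-Lambert law inverts optical density at two
wavelengths into chromophore concentrations,
\[
\begin{pmatrix}\Delta HbO\\ \Delta HbR\end{pmatrix}
 = E^{-1}\begin{pmatrix}\Delta OD(\lambda_1)\\ \Delta OD(\lambda_2)
 \end{pmatrix} / (d\,l),
\]
with extinction matrix \(E\), differential pathlength factor \(d\)
and source-detector separation \(l\). All constants live in the
`OpticalRecording` container (`defaultExtinction()` supplies
tabulated literature values); nothing is hard-coded, because
instruments differ.

Filtering is a zero-phase (forward-backward) Butterworth filter of
order 3 per pass. Zero-phase filtering is the standard choice in
fNIRS because hemodynamic latencies are themselves informative and a
causal filter would shift them. The conventional task band (0.01-0.1
Hz bandpass) or a lowpass are both available; note that a 0.01 Hz
corner implies edge transients that decay over minutes, which is why
the package's own tests probe DC rejection only in the interior of
long records. Resampling uses an anti-alias lowpass at 80% of the
new Nyquist frequency followed by interpolation; onsets are rescaled
proportionally.

Task windows are cut into non-overlapping epochs of
`epoch_length_s` (default 1 s; at 10 Hz an epoch is a `C x 10`
matrix, and a non-integer product is rounded). Trailing partial
segments are dropped by default (`"pad"` edge-replicates instead).
An optional symmetric context pad exists for hemodynamic-delay
studies but defaults to 0 so epochs stay disjoint. Baseline
correction subtracts, per channel, the mean of the 1 s immediately
pre-onset interval of the epoch's parent trial; 1 s is the longest
interval guaranteed by the rest periods of all the acquisition
paradigms the package targets, and it is configurable.

# Graph-theoretic connectivity features

Channels pair up: the HbO and HbR series of one optode form a
*channel pair*, the unit of functional coupling (\(C = 2C_p\)).
Per pair \(i\) and epoch, three local features are computed:

* connection strength \(s_i = (\rho_i + 1)/2\), the normalized
  Pearson correlation of the pair;
* connection density
  \(Sd_i = \frac{1}{T-L+1}\sum_k 1[\rho_{ik} > 0.3]\), the fraction
  of length-\(L\) sliding windows (stride 1) whose correlation
  exceeds the significance threshold 0.3. With the default
  \(L = 1\) s equal to the epoch length there is a single window and
  the density degenerates to an indicator; shorter windows give a
  graded stability measure;
* RFSMD \(= 1/(\mathrm{mean}_t\,|x_i(t) - x'_i(t)| + \epsilon)\)
  with \(\epsilon = 10^{-6}\), a reciprocal mean-difference proxy
  for transfer efficiency, bounded by \(1/\epsilon\). The absolute
  difference is used so the reciprocal stays positive.

Thresholds act on *signed* correlations, as defined; because HbO and
HbR are physiologically anti-correlated this can zero out densities,
so a documented `thresholds_signed = FALSE` escape hatch thresholds
\(|\rho|\) instead. Zero-variance windows get \(\rho = 0\) with a
degeneracy flag rather than `NaN`.

Globally, a binary adjacency over all \(C\) rows (HbO and HbR
channels alike, as the full-channel construction specifies) connects
channels with \(\rho > 0.3\); its *global efficiency*
\(e = \frac{1}{C(C-1)}\sum_{c_1 \ne c_2} 1/d(c_1,c_2)\) uses
unweighted shortest paths with disconnected pairs contributing 0
(the standard convention). The implementation delegates shortest
paths to `igraph::distances`; the test suite re-derives every value
with a hand-written Floyd-Warshall over all graphs on up to six
nodes, exhaustively.

The fused vector \(f_3 = [f_1; f_2; e]\) concatenates the
column-stacked raw epoch (\(f_1 \in \mathbb{R}^{CT}\)), the pair
features interleaved as \((s_1, Sd_1, RFSMD_1, \dots)\)
(\(f_2 \in \mathbb{R}^{3C_p}\)) and the efficiency, so
\(D = CT + 3C_p + 1\). Plain concatenation is the default; z-score,
min-max and fixed-weight block scalings are available for the fusion
ablation, fitted on training data only.

# The network

Per epoch the model runs:

1. **Input projection.** Each pair's \((HbO_t, HbR_t)\) 2-vector maps
   through a shared linear layer into \(d\) dimensions (default
   \(d = 64\)); sinusoidal positional encoding is added (the
   published description leaves the encoding unstated; sinusoidal is
   the conventional default).
2. **Transformer encoding.** One standard encoder layer (4-head
   self-attention, feed-forward width 128, residual + layer
   normalization) runs independently along each pair's time axis,
   with weights shared across pairs.
3. **Temporal pooling.** Mean over time gives one \(d\)-vector per
   pair.
4. **Fused projection.** \(f_3\) projects to \(d\) dimensions
   (dropout 0.1 in training), and is concatenated to every pair's
   pooled vector, giving the pair sequence
   \(E_i = [F_i; f_{proj}] \in \mathbb{R}^{2d}\). The printed
   dimensional analysis of the source architecture is inconsistent
   (a pooled matrix equated to a vector); the per-pair sequence is
   the one reading that gives the recurrent stage a sequence to
   traverse and lets the attention weights modulate it per pair, so
   it is the one implemented.
5. **Graph attention (GAM).** \(\alpha = \mathrm{softmax}(W_\alpha
   [s_i, Sd_i, RFSMD_i]^\top)\) over pairs — a learned, simplex-
   normalized salience per channel pair, derived from connectivity
   alone.
6. **Attention-modulated Bi-LSTM.** Forward and backward LSTMs run
   over the *pair* sequence. Each gate input is
   \([h_{prev}, E_i, \alpha_i]\): by default the scalar
   \(\alpha_i\) of the current step (`alpha_mode =
   "scalar_per_step"`), matching the per-pair modulation narrative;
   `"full_vector"` appends all of \(\alpha\) instead, the literal
   reading of the printed gate equations. Both modes are tested. The
   readout concatenates the two final hidden states (default) or
   mean-pools over steps (`hidden_readout = "mean"`).
7. **Classifier.** \([f_3; h]\) through a ReLU MLP (width 128,
   dropout 0.2) and softmax over classes.

All tensors are plain R matrices; the forward pass and a fully
hand-derived backward pass live in `model.R` / `backprop.R`.
Gradients are verified against central finite differences for every
parameter group, in the full model and in every ablation variant.
One structural fact the tests assert: the key-projection bias of
self-attention receives exactly zero gradient, because softmax
attention is invariant to constant key shifts.

# Training and evaluation

Adam (learning rate \(10^{-3}\), weight decay \(10^{-4}\) added to
the gradient), batch size 5, at most 200 epochs, with a
reduce-on-plateau schedule (factor 0.5, patience 10) keyed on
validation accuracy. An inner stratified 80/20 split of the training
indices provides that validation signal. By default the *final*
epoch's parameters are returned: with batch size 5 the inner
validation set is small enough that its accuracy saturates within a
few epochs, so a best-validation checkpoint freezes on a premature
model, while the annealing schedule leaves the final parameters in a
settled minimum (`checkpoint = "best_val"`, with accuracy ties
broken by validation loss, remains available). Training is fully
seeded (initialization, shuffling, dropout) and bit-reproducible.

Evaluation offers subject-specific stratified 5-fold
cross-validation and leave-one-subject-out folds, with accuracy,
Cohen's kappa (marginal-product chance correction; degenerate
single-cell tables return 0 with a flag), and one-vs-rest ROC/AUC
whose threshold sweep is tie-aware and exactly equals the
Mann-Whitney pair-counting statistic. Aggregate accuracy is the mean
of fold accuracies; kappa is computed from the pooled confusion
matrix. Misprints in the source's TPR/FPR definitions were corrected
to the standard \(TP/(TP+FN)\) and \(FP/(FP+TN)\).

Interpretation mirrors the usual violin/box summaries: per pair and
feature, Welch t (2 classes) or one-way ANOVA (3+) with group means,
SDs and quartiles; Benjamini-Hochberg correction is available but
off by default, matching per-pair \(p < 0.05\) reporting. Groups
that tie exactly (zero variance everywhere, identical values) return
\(p = 1\) with a degeneracy flag.

# The synthetic generator

No public fNIRS dataset ships with the package; instead
`simulateDataset()` builds recordings in which every ground truth is
known:

* a boxcar task drive convolved with a double-gamma HRF (response
  peak 6 s, undershoot 16 s, ratio 1/6, peak-normalized; the
  convolution kernel is sum-normalized so a sustained task plateaus
  at `task_amplitude`);
* latent per-pair activation fluctuations drawn i.i.d. over time
  from a class-specific correlation template. Two components share
  the template: a slow one convolved with the HRF
  (kernel-energy-normalized, amplitude `act_sd`) and a fast
  unsmoothed one (`act_fast`). The fast component exists because HRF
  convolution is a lowpass: without it, coupling planted in the
  latents would be invisible inside 1 s epochs, whose correlation
  estimates rest on 10 samples;
* an HbR series per pair, built as `hbr_scale` (default \(-0.3\);
  the recovery preset uses \(-0.4\)) times a mixture whose
  correlation with the pair's HbO fluctuation equals the configured
  per-pair coupling \(\kappa_i \in [-1, 1]\);
* Mayer-wave, respiratory and cardiac sinusoids with random phases,
  linear drift and white noise. The ~1 Hz cardiac component sits
  near the 10 Hz Nyquist frequency and is deliberately
  undersampled, as in real recordings.

Three presets name the study conditions. `recovery`: two classes
coupling disjoint halves of the pairs (template correlation 0.9 in
the block, within-pair coupling 1 in the block, 0 outside) plus a
moderate amplitude contrast (task gains 1 and 1.5), white-noise SD
0.25 — the realistic regime where tasks differ in both amplitude and
connectivity. `coupled_blocks`: the same coupling design with
identical mean responses, so class information lives *only* in the
covariance — the regime that isolates the graph-feature pathway.
`amplitude_only`: identity coupling, amplitude contrast only — the
complementary control. These parameter values were fixed as the
package's definition of a realistic, moderately noisy recording and
are used unchanged by the test suite and the acceptance script.

What the generator does *not* emulate: motion artifacts,
short-separation superficial contamination, inter-subject anatomical
variability, or 1/f physiological backgrounds. Passing tests on
synthetic data therefore demonstrate correct recovery of planted
structure under realistic noise amplitudes, not performance on any
public benchmark.

The default pipeline for synthetic data applies a light 3 Hz lowpass
rather than the 0.01-0.1 Hz task band: with 1 s epochs the
discriminative coupling lives in the fast band, and the narrow task
band — designed for block-averaged analyses — would remove it along
with the noise. For real recordings analyzed at trial scale the
conventional band remains the default of `preprocessConfig()`.

# Problem sizes and numerical choices

The shipped experiments run at sizes chosen for a laptop-class
single core: the recovery and control datasets use 2 subjects x 2
classes x 5 trials x 10 epochs (200 epochs, \(C_p = 10\)), training
runs 40 epochs for cross-validation (validation metrics plateau well
before that at these data sizes; the 200-epoch cap remains the
configuration default), 25 epochs for the five-seed module-ablation
comparison, and the memorization check uses 10 epochs with the full
cap. Random seeds derive from a single integer via a fixed affine
map, kept below \(2^{31}\).

Other numerical choices: layer normalization uses
\(\epsilon = 10^{-5}\); softmax subtracts row maxima;
cross-entropy clips probabilities at \(10^{-12}\); correlation of a
zero-variance series is 0 with a flag; resampling preserves DC
exactly by filtering deviations from the channel mean; the
non-integer sample count of a 13.3 Hz x 1 s epoch rounds to 13.

# Known limitations

* The recurrent stage traverses pairs in index order; the
  architecture is deliberately order-sensitive (the tests assert
  it), so channel numbering is part of the model.
* Pure-R training is BLAS-bound; at the default sizes one
  cross-validation fold trains in tens of seconds, but hundreds of
  epochs on thousands of samples call for a compiled backend.
* The statistics harness tests features marginally per pair;
  dependencies between pairs are not modeled.
* Dataset-specific loaders for public MATLAB containers are out of
  scope; users adapt their data to the CSV + JSON container or build
  `HemodynamicRecording` objects directly.
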