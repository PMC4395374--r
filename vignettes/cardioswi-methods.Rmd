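---
title: "Susceptibility-weighted cardiac MR reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Susceptibility-weighted cardiac MR reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioswi)
```

## The problem and the signal model

Intramyocardial hemorrhage (IMH) after reperfused infarction deposits
paramagnetic blood products in the myocardial wall. Two measurable
consequences drive everything in this package: the effective transverse
relaxation time T2\* shortens (hemorrhagic segments around 16 ms against
roughly 34 ms for normal myocardium), and the local resonance shift imprints
a focal *negative* phase on gradient-echo images. A multi-echo spoiled
gradient-echo acquisition samples both effects: the package's default
protocol is 12 echoes at 1.2 ms spacing ending at 15.5 ms
(`default_echo_times()`; the first echo is 2.3 ms, the value consistent with
a 1.2 ms ladder ending at 15.5 ms).

Every stage is validated against a synthetic short-axis left-ventricle
phantom whose per-pixel complex signal at echo time TE is

$$ S(x, y, TE) = \rho \, e^{-TE/T_2^*} \,
   e^{\,i\,(2\pi \Delta f \, TE + \varphi_f \, w(x,y))} $$

with proton density $\rho$, off-resonance $\Delta f$ (Hz, a smooth
background-phase source), and a focal phase offset $\varphi_f$ applied only
inside the lesion ($w = 1$ there, 0 elsewhere). Multi-coil k-space is the
centered orthonormal 2-D FFT of the image times each coil sensitivity, plus
i.i.d. circular complex Gaussian noise of standard deviation
`noise_sigma` per channel; because the transform is unitary, the same sigma
describes image-domain noise, and signal-free magnitude pixels are
Rayleigh-distributed with that scale (tested).

## Reconstruction chain

**Magnitude.** Per-echo, per-coil centered inverse FFT, then sum-of-squares
over coils. Coil sensitivities in the phantom are smooth Gaussian-falloff
profiles normalized pixelwise to unit sum-of-squares, so the noiseless
combined magnitude equals the ground-truth magnitude exactly and the
simulate-to-reconstruct round trip is machine-precision.

**High-pass filtered phase.** The homodyne construction: low-pass filter the
complex image by multiplying k-space with a radial squared-Hanning window

$$ W(r) = \left[\tfrac{1}{2}\left(1 + \cos\tfrac{2\pi r}{N-1}\right)\right]^2,
 \qquad r \le (N-1)/2, \quad N = 64 $$

and take the phase of full / low-pass. A literal reading of the common
printed form of this window zeroes DC; a low-pass must pass DC, so the
package uses the descending half, $W(0) = 1$ falling smoothly to 0 at
$r \approx N/2$ k-space samples. The division cancels any phase the low-pass
image retains — global offsets and smooth off-resonance exactly
(phase-invariance under global complex scaling is tested) — while compact
phase features survive. Coil combination of phase is not determined by a
sum-of-squares magnitude recipe; the package combines the per-coil
full/low-pass ratios by a magnitude-squared-weighted complex sum, which is
phase-reference-free and standard for phased arrays. Pixels whose low-pass
magnitude falls below $10^{-6}$ of the per-echo maximum (air) are flagged
invalid, carried as a validity plane, excluded from every ROI statistic, and
given mask value 1 downstream so no lesion can be fabricated from masked
regions.

**What homodyne filtering does to a compact lesion.** The low-pass kernel
(image-domain width about grid/(N/2) pixels, roughly 6 px at the default
192-point grid) absorbs part of a compact region's own phase, so the
high-pass phase inside a lesion is *attenuated* by approximately the
fraction of kernel mass the lesion occupies: a 3-px-radius lesion retains
about 65% of a −1 rad focal phase, a 1-px feature more than 90%. This is a
property of the method, not an implementation artifact: tests assert strong
negativity in the lesion interior and near-zero phase away from the rim,
not exact recovery of $\varphi_f$. It also means phantom contrast-gain
figures are illustrative, not reproductions of patient values — the true
lesion phase magnitude in vivo is not printed anywhere and the default
$\varphi_f = -1$ rad is a free parameter.

**SWI.** The negative-phase mask is unity for non-negative phase and the
linear ramp $(\pi + \varphi)/\pi$ on $(-\pi, 0)$; the SWI image is
$|I| \cdot \text{mask}^{N_m}$ pixelwise. $N_m = 6$ is the default (better
contrast and SDNR than 3 in the sweep); $N_m = 0$ is the identity. The mask
is computed once from the combined-coil phase and applied to the
sum-of-squares magnitude — computing per-coil masks would amplify coil
phase noise for no benefit.

**TE-averaging.** The nTE-average is the arithmetic mean of the nTE
longest-echo images (mean rather than sum keeps the intensity scale
comparable across nTE; contrast and SDNR are unaffected either way). SWI
images are masked per echo *first* and then averaged, matching the reading
that magnitude and SWI stacks are averaged as images. The inverted-grayscale
transform (clip to a window, reverse linearly onto [0, 1]) exists for
display only; results are flagged `display_only` and metrics are always
computed on non-inverted images. The default display window is
[0, 99th percentile of myocardial intensity] — windowing is unspecified in
the source protocol, and this choice keeps a few bright blood pixels from
compressing the map.

## T2\* fitting

ROI decay curves (per-echo ROI means, as in the original analysis — not
pixelwise maps) are fitted with $S = S_o e^{-TE/T_2^*} + C$, where the free
offset $C$ absorbs the magnitude noise floor; no Rician likelihood is used.
The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
$T_2^* \in (0.1, 500]$ ms, initialized from $C_0 = \min S$,
$S_{o,0} = \max S - C_0$, and a log-linear fit of the early echoes; because
the SSE surface is multimodal when the echo train is short relative to
T2\*, the fit restarts from a small grid of T2\* values
(5, 15, 40, 120 ms plus the log-linear guess) and keeps the lowest-SSE
solution. Non-convergence — including fits pinned at a T2\* bound and flat,
unidentifiable curves — is reported through a `converged` flag, never an
exception. Fits are invariant to uniform signal rescaling (T2\* unchanged,
$S_o$ and $C$ scaling linearly; tested).

A genuine limitation, quantified during development and worth knowing
before trusting any single fit: with echoes only to 15.5 ms, T2\* near
34 ms sits at roughly twice the train length and the three-parameter model
is ill-conditioned — at a curve SNR of 20, 30–40% of replicate fits pin at
the upper bound and the 200-replicate median error ranges from about 9% to
over 50% across noise realizations even for the global least-squares
solution. Short T2\* (hemorrhage-like, ~16 ms) is well conditioned and its
median recovery stays within a few percent. Tissue-class separation
(hemorrhage below normal) survives in either regime, which is what the
clinical question needs. Longer echo trains or a fixed offset would
recondition the long-T2\* case; both change the model and are left out of
scope.

The AHA-style partition divides the annulus by polar angle about its
centroid into 6 equal sectors at basal and mid levels and 4 apically,
numbered counterclockwise from the supplied reference (anterior RV
insertion) angle; the apex cap is not modeled. Sectors with fewer than 5
pixels are flagged low-confidence but still fitted.

## Metrics

Contrast $(S_1-S_2)/S_1$ and SDNR $(S_1-S_2)/\text{STD}$ are applied
verbatim, with $S_1$ the adjacent-myocardium mean, $S_2$ the lesion mean and
STD the *raw* standard deviation of magnitude values in a signal-free ROI —
deliberately uncorrected for Rayleigh statistics, mirroring the operational
definition used with scanner images. The threshold-volume rule selects LV
pixels at or above half the maximum myocardial signal and then adds enclosed
hypointense cores — 4-connected below-threshold components completely
surrounded by selected pixels — so a no-reflow core inside an enhancing rim
counts toward lesion volume; a visual hypointensity threshold is replaced by
an explicit numeric parameter (`manual_hypo`), since observer judgment is
out of scope. The half-max rule is invariant to positive rescaling but not
to intensity offsets (the 50%-of-max threshold moves by half the offset);
only the scaling invariance is claimed and tested.

## Phantom defaults and what they do and do not emulate

Defaults (all overridable through `phantom_spec()`): 192×192 grid at 1.5 mm;
annulus radii 20/28 px (a 12 mm wall, thick enough for sectors and a guard
ring); lesion radius 3 px mid-wall in the inferior wall with a 2-px guard
ring separating it from the "adjacent myocardium" ROI; proton densities 1.0
(myocardium, lesion), 1.2 (blood), 0 (background); T2\* 34.1 / 16.2 / 150 ms
for myocardium / lesion / blood; uniform 3 Hz off-resonance; 4 coils;
`noise_sigma = 0.03` (first-echo myocardial SNR ≈ 30, mid-range for a
segmented breath-hold acquisition); the noise ROI is a 64×64 background
corner block, kept large because its STD sits in every SDNR denominator.
The deterministic contrast/SDNR structure these values produce has an
interior SDNR maximum near nTE = 10 for the magnitude source — close to,
though not identical with, the nTE = 9 optimum reported for patient data.

The phantom deliberately omits: cardiac motion and flow phase, dipole
susceptibility fields (the lesion is a compact constant phase offset — the
minimal model that survives homodyne filtering; a dipole pattern would add
shape but no new mechanism), dark-blood magnetization preparation,
multi-slice geometry, and TE-dependent phase growth. Passing tests therefore
demonstrate the *reconstruction chain's* correctness and its qualitative
contrast/noise trades, not quantitative agreement with any patient cohort.

## Numerical conventions

One FFT convention everywhere: DC at the array center
(`floor(n/2) + 1`), orthonormal scaling in both directions, so Parseval's
identity holds and phantom and reconstruction are exact inverses. Filter
radius is measured in k-space samples, isotropically, on the native grid.
Phase angles live in $(-\pi, \pi]$; $\varphi = -\pi$ maps to mask 0 (the
continuous limit of the ramp). Test problem sizes follow the defaults
(192-point grids, 12 echoes, up to 12 noise replicates for profile
averaging, 200 replicates for fitter statistics) — small enough to run the
whole suite in a few minutes on one core while leaving every stage's
statistics resolvable.
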