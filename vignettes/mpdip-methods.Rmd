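---
title: "Methods: two-stage atomic decomposition of multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage atomic decomposition of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdip)
```

## The model

An EEG epoch is a matrix $x \in \mathbb{R}^{N \times C}$ ($N$ samples,
$C$ derivations; with the default preprocessing $N = 2560$, i.e. 20 s at
128 Hz). The package represents it as a sparse sum of *Gabor atoms*

$$g_\gamma(t) = K(\gamma)\, e^{-\pi\left(\frac{t-u}{s}\right)^2}
  \cos\!\big(2\pi f (t-u) + \phi\big),
  \qquad \gamma = \{u, f, s, \phi\},$$

with $K(\gamma)$ normalizing $\|g_\gamma\| = 1$ on the sampling grid. The
multivariate matching pursuit (MMP) recursion keeps a per-channel residual
$R^n x_i$ and at every iteration selects the single atom maximizing the
summed squared inner products across channels,

$$g_{\gamma_n} = \arg\max_{g_\gamma} \sum_{i=1}^{C}
  |\langle R^n x_i,\, g_\gamma\rangle|^2 ,$$

then subtracts $\langle R^n x_i, g_{\gamma_n}\rangle\, g_{\gamma_n}$ from
every channel. All channels share one envelope, frequency and phase; the
channels differ only by real signed weights (the inner products). Those
weights are the atom's scalp topography. The expansion is exact by
construction: atoms plus the final residual reproduce the epoch to
round-off, and the residual energy decreases monotonically.

A cross-term-free time--frequency energy density per channel is the
weighted sum of the atoms' Wigner distributions; for a Gabor atom the
Wigner distribution is the 2-D Gaussian
$2\exp(-2\pi((t-u)/s)^2 - 2\pi (s(f-f_0))^2)$, which integrates to one, so
each atom contributes exactly its squared weight to the map.

### Dictionary and optimization

The dictionary covers widths `s_range` (default 0.1--10 s, log-spaced),
frequencies up to `f_max` (default 45 Hz) and all time shifts. Its density
is governed by a single parameter, `energy_error` (default 0.05): the grid
steps are chosen from the Gabor autocorrelation so that atoms adjacent in
$u$, $f$, or $s$ have squared inner products of at least
`1 - energy_error`. Concretely, with
$\beta = \sqrt{-\ln(1-\varepsilon)/\pi}$, time shifts are spaced
$\beta s$, frequencies $\beta/s$, and scales by the ratio $r$ solving
$2r/(1+r^2) = 1-\varepsilon$.

Each iteration scans all candidates with per-scale FFTs (one batched FFT
over channels per time-shift block), with the optimal common phase obtained
in closed form: for fixed $(u, f, s)$ the criterion is a ratio of two
quadratic forms in $(\cos\phi, \sin\phi)$, i.e. a $2\times 2$ generalized
eigenproblem. The scan winner is then refined by a derivative-free
coordinate search on $(u, f, s)$. Two engineering details keep the scan
fast without changing its result: the phase-maximized criterion is
invariant under a common rotation of the channel spectra (so the scan works
on window-referenced FFTs and the phase is recovered only for the winner),
and for expensive wide-envelope blocks the channel spectra are cached and
updated incrementally after each subtraction (the subtracted waveform is
shared across channels up to scale, so an update costs one FFT per block).

Atoms near the epoch boundary are evaluated on the epoch support only and
renormalized there, which keeps the expansion of the finite epoch exact.
Decomposition is fully deterministic; there is no randomness anywhere in
this stage. Stopping: a fixed number of iterations (default 200) or a
residual below $10^{-12}$ of the input energy, whichever comes first.

## Dipole stage

Assuming an oscillation of constant frequency and phase reflects at most
one neural generator, a single equivalent current dipole is fitted to each
atom's (average-referenced) weight vector. The default volume conductor is
an analytic three-shell concentric-spheres model (brain/skull/scalp radii
81/86/92 mm, conductivities 0.3/0.006/0.3 S/m — the customary BEM defaults
of the common EEG forward-modeling toolchains; both overridable). The per-harmonic radial transfer coefficients
are obtained by solving the Laplace boundary-value problem per degree
(continuity of potential and radial current at both interfaces, insulating
scalp boundary); the series is truncated adaptively once its geometric tail
is negligible (the cap is 100 terms). A lead-field-table adapter
(`head_model_table`, `read_leadfield_table`) accepts precomputed BEM-style
gain matrices as a drop-in replacement.

Electrode coordinates are built geometrically from the 10--20 construction
(ring electrodes 72° from the vertex at 36° azimuthal spacing; F3/F4/P3/P4
midway on great circles between their midline and ring neighbours),
RAS-oriented in mm ("MNI-like"), origin at the sphere centre.

`fit_dipole` minimizes the residual over location with the moment solved
linearly at each candidate (the gain at a location is a 3-column matrix),
using Nelder--Mead from 10 fixed lattice start points — no RNG. Goodness of
fit is the explained percentage of topography energy; it is invariant to
scaling, and a sign flip of the topography flips the moment, not the
location. Distance to cortex (DtC) is the minimum Euclidean distance to a
cortical point set. The package ships a deterministic *synthetic* stand-in
cloud (Fibonacci lattices on shells 35--75 mm) that makes the DtC criterion
operational without any atlas; for anatomical work supply a real surface
sampling.

## Spindle selection

Detected structures are filtered by explicit criteria (defaults):
peak-to-peak amplitude, highest across derivations, 12.5--150 µV
(amplitude is $2|w_i|K(\gamma)$); frequency 11--16 Hz; duration 0.5--3.5 s;
at least 3 oscillation periods within the width ($f\,s \ge 3$); dipole
goodness of fit 60--100%; DtC 0--20 mm; optionally a local SNR floor
(off by default; $-7$ dB reproduces the "clearly visible" setting). The
*duration* of an atom is identified with its width $s$, the only reading
consistent with counting periods within the width; the scoring interval of
a detection is $[u-s/2,\, u+s/2]$. Local SNR is
$10\log_{10}\!\big(w_i^2 / \|EEG_{u\pm s} - w_i g_\gamma\|^2\big)$: the
atom's energy in the scoring channel against the surrounding signal with
the atom's own contribution removed. Selection is a pure filter — order
preserving, idempotent, monotone in every range — and each rejection is
labelled with the first failing criterion in the order above.

## Synthetic benchmark

`simulate_dataset` builds the accuracy benchmark entirely in code:

* **Background**: a stable MVAR model. `builtin_mvar` ships a deterministic
  coefficient set — per-channel AR(6) from three resonance factors (a
  strong pole near 1.2 Hz for the $1/f$-like low-frequency dominance, a
  theta-range resonance, and a mild sigma-band resonance near 13 Hz),
  spatially mixed by an inter-electrode-distance kernel for realistic
  cross-channel correlation. `fit_mvar` (least squares, with a
  companion-matrix stability check) lets users substitute a model fitted to
  a real N2 fragment, the default order being 14.
* **Spindles**: Gabor waveforms at fixed 14.5 Hz and 3 s, with uniform
  random phases, scaled per channel by the forward solution of 20 dipolar
  sources placed along a line in the $y$--$z$ plane (default from
  $(y,z) = (-60, 10)$ to $(55, 55)$ mm, covering depths from ~4 to ~50 mm —
  both shallow and deep generators) with $x \sim N(0, 11.5\ \text{mm})$.
  Each source carries 5 random orientations; dipole amplitudes cycle
  through 15 values linearly spaced between 75 and 150 nAm. The
  (source, orientation, amplitude) assignment is cycled so the counts are
  exact, then shuffled so consecutive spindles come from unrelated sources.
* **Placement**: uniform within epochs with a guard margin of $s$ from the
  edges, under a minimum centre separation, sampled exactly (order
  statistics of the residual slack) — no rejection loops. The full-scale
  design (1500 spindles in 225 epochs) uses a 2-s separation; the reduced
  benchmark below uses 3 per epoch at $\ge 6$ s. The wider spacing keeps
  same-frequency bursts resolvable: two equal-energy 14.5 Hz bursts closer
  than a few seconds can be captured by a single wide-envelope atom
  whenever their topographies correlate and phases align, which is an
  artifact of dense same-frequency placement rather than a property of
  real recordings (real spindle sequences differ in frequency and
  generator).
* **Calibration**: the background is scaled to a 5 µV per-channel RMS,
  which, with the 75--150 nAm forward fields, places the manifest SNRs
  (computed by the same windowed definition as above, on each event's
  strongest channel) mostly within $[-23, 5]$ dB — the intended operating
  range of the benchmark. Mixing is linear and exact: background plus the
  manifest events reproduce the epochs to round-off.

What the generator deliberately does **not** emulate: sleep-stage dynamics,
artifacts, K-complexes or other transients, spindle chirp (intra-spindle
frequency change), and frequency/duration variability across spindles.
Passing the benchmark therefore demonstrates parameter recovery and
selection behaviour under colored, spatially correlated noise — not
robustness to every property of clinical recordings.

The benchmark's mismatched ("other") inverse model is a single-shell
homogeneous sphere with a displaced centre. This is a deliberate design
point: concentric multi-shell spheres span nearly the same topography
space, so a merely rescaled or shifted three-shell variant refits the
forward fields with near-perfect goodness of fit and produces no
mismatch effect at all; dropping the skull compartment is the strongest
geometry contrast the analytic family offers, and it biases fitted depths
the way an anatomically wrong conductor would.

## Scoring and evaluation

`match_intervals` pairs detections with references greedily by descending
overlap, one-to-one, with deterministic tie-breaks; the overlap fraction is
normalized by the shorter interval, and `min_overlap = 0` means "at least
one point". The greedy pairing is validated against a brute-force optimal
bipartite oracle in the tests. `f1_score` is $2TP/(2TP+FP+FN)$ (zero when
undefined), `f1_vs_snr` sweeps a minimum-SNR threshold, `param_errors`
reports absolute frequency/time/amplitude errors and Euclidean location
errors for matched pairs with per-SNR-bin aggregates, and `ks_compare`
applies the two-sample Kolmogorov--Smirnov test to TP/FP parameter
distributions (samples below 5 are flagged and excluded). Whether several
atoms inside one reference count as one or several detections is handled
by the default one-to-one pairing (extras become false positives);
`merge_overlapping_detections` provides the merge-first alternative.

## Frequency-gradient analysis

Dipole locations and frequencies of accepted spindles form a sparsely
sampled scalar field; `fit_gradient` estimates its mean gradient by OLS on
$f(x,y,z) = jx + ky + lz + c$, normalizes $(j,k,l)$ to unit length,
projects every location on that direction and reports the Spearman
correlation (and per-axis correlations) with two-sided p-values, ties by
average ranks. Per-subject fits are aggregated by vector-averaging the unit
gradients (`gradient_by_subject`); no pooled meta-test is performed.
Constant fields yield a zero gradient and are flagged rather than
normalized.

## Problem sizes and numerical choices

* The reduced-scale benchmark used by `spindle_benchmark` (and by
  `scripts/acceptance.R` and the acceptance tests) is 150 spindles in 50
  epochs with 40 MMP iterations per epoch; these sizes keep a full run in
  the tens of minutes on one core while retaining >100 matched events for
  the error statistics. The full-scale design (225 epochs, 1500 spindles,
  200 iterations) is a parameter choice away.
* Dictionary defaults: `energy_error = 0.05`, widths 0.1--10 s,
  `f_max = 45` Hz, 200 iterations.
* Dipole fitting restricts locations to 97% of the brain radius (the gain
  is singular at the interface) and, by default, is run only for atoms
  passing the amplitude/frequency/duration/period screen — the catalog is
  identical because those criteria are evaluated first.
* Ties in the dictionary argmax resolve to the lowest block index;
  refinement accepts only strict improvements, so the reported criterion
  is never below the grid optimum.
* Degenerate inputs: atoms narrower than two sample intervals, all-zero
  topographies, empty cortex clouds, collinear gradient geometries and
  unstable MVAR fits all raise typed errors; batch operations
  (`mp_dip`) flag per-item failures instead of aborting.

## Known limitations

* The spherical forward model is a deliberate simplification; absolute
  dipole locations (and hence DtC) inherit its geometry. The lead-field
  table adapter is the escape hatch.
* Because spherical conductors refit each other's dipole fields almost
  perfectly (at a biased depth), a mismatched *spherical* inverse model
  degrades location accuracy strongly but barely lowers the detection
  yield: hardly any atom fails the goodness-of-fit or
  distance-to-cortex screens. Reproducing the yield drop seen when two
  different realistic (BEM) head models are swapped requires genuinely
  non-spherical lead fields, which are outside this package's scope.
* "Current density" is reported as the fitted moment magnitude (nAm).
* Very dense trains of same-frequency structures can still be summarized
  by one wide atom (see above); at the benchmark's spacing this is rare
  but not impossible.
* The EDF layer covers continuous 16-bit recordings with a common sampling
  rate; EDF+ annotations and discontinuous records are out of scope.
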