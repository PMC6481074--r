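---
title: "Multi-spot hologram synthesis with compressive-sensing Gerchberg-Saxton algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-spot hologram synthesis with compressive-sensing Gerchberg-Saxton algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Holographic photostimulation drives light-gated ion channels in many neurons
or sub-cellular compartments at once by focusing a single coherent beam into
a cloud of diffraction-limited spots distributed through the sample volume.
The beam is shaped by a phase-only spatial light modulator (SLM) conjugated
to the objective's back aperture: a programmable phase map $\phi_{cgh}(x',y')$
over the SLM pixels — a computer-generated hologram (CGH) — determines where
the light lands. Because stimulation patterns change "on the fly" during an
experiment, the time needed to *compute* a hologram is often the limiting
resource, and experimenters are forced to trade hologram quality against
computation speed. This package implements the family of multi-spot
synthesis algorithms that spans that trade-off, including compressive-sensing
variants that approach the speed of the cheapest method at nearly the
quality of the best.

## Forward model

A single spot at image-space position $(x, y, z)$ is produced by a pupil
phase combining tip, tilt and defocus,

$$\phi_n(x', y') = \frac{\pi z_n}{\lambda f^2}\left(x'^2 + y'^2\right)
  + \frac{2\pi}{\lambda f}\left(x_n x' + y_n y'\right),$$

where $(x', y')$ are physical pixel coordinates centred on the SLM,
$\lambda$ the wavelength and $f$ the equivalent focal length of the optical
train. For $N$ spots, the hologram is taken as the phase of the weighted
superposition of the single-spot fields,

$$\phi_{cgh} = \arg \sum_{n=1}^{N} \omega_n\, e^{i(\phi_n + \theta_n)},$$

with per-spot amplitude weights $\omega_n$ and constant phase offsets
$\theta_n$ — the only degrees of freedom available to the algorithms. The
field a hologram delivers to spot $n$ is measured by the pupil average

$$c_n = \frac{1}{M} \sum_{m=1}^{M} e^{i(\phi_{cgh,m} - \phi_{n,m})},
  \qquad I_n = |c_n|^2,$$

with $M$ the number of pupil pixels. On this normalization $|c_n| \le 1$, a
perfect single-spot hologram scores $I = 1$, and the total pupil throughput
is 1, so efficiency is the plain sum $e = \sum_n I_n$. Uniformity is
$u = 1 - (I_{max} - I_{min}) / (I_{max} + I_{min})$.

A note on signs: we use the self-consistent pair above — superposition with
$e^{+i(\phi_n + \theta_n)}$ and projection with
$e^{+i(\phi_{cgh} - \phi_n)}$ — under which the single-spot case
($N = 1$) recovers $c_1 = e^{i\theta_1}$ exactly and every reduction
(GS at $K{=}1$ equals RS, compression 1 equals plain GS) holds bit for bit.

## The five algorithms

All variants are driven by one seeded generator per run (offsets first, then
the pixel subset) and are pure functions of their inputs including the seed.
One *iteration* is a projection step ($\theta_n \leftarrow \arg c_n$ over
the iteration's pixel domain) followed by a superposition; iteration 1 is
the random initialization.

* **RS** (random superposition): draw $\theta_n \sim U[0, 2\pi)$, superpose
  once. Cost $N \cdot M$.
* **GS** (Gerchberg–Saxton): $K$ alternating-projection iterations on the
  full pupil. Cost $K \cdot N \cdot M$; a few tens of iterations reach a
  plateau.
* **WGS** (weighted GS): as GS, but each iteration rescales the weights by
  the mean-to-spot ratio of the projection modulus,
  $\omega_n \leftarrow \omega_n \,\langle |c| \rangle / |c_n|$, driving the
  spot intensities together at a small efficiency cost. We use the modulus
  — not its square — in this ratio: because the delivered amplitude responds
  roughly linearly to $\omega_n$, the modulus ratio is the damped,
  convergent correction, whereas the squared (intensity) ratio overshoots
  and oscillates without converging on regular patterns (we measured
  $u \approx 0.006$ after 50 iterations on the 10×10 grid with the squared
  ratio, versus $u \approx 0.98$ with the modulus ratio). The ratio is
  additionally clamped to a 10× boost per iteration, with the modulus
  floored at $10^{-12}$, so a spot whose intensity momentarily collapses
  cannot blow up the weight vector.
* **CS-GS**: the compressive-sensing acceleration. The superposition is an
  underdetermined linear system ($M \gg N$), so the first $K - 1$ iterations
  are run on a fixed random subset of $cM$ pupil pixels
  ($N/M < c < 1$); only the final superposition is evaluated on the full
  pupil, with $\theta$ taken from the last compressed state (no extra
  full-pupil refinement). Cost $(K-1) \cdot N \cdot cM + N \cdot M$.
  Subset averages divide by the subset size, so the compressed projections
  are unbiased estimates of the full-pupil ones.
* **CS-WGS**: weight updates diverge when computed from subsampled
  intensities, so the weighted variant runs $K - 1$ compressed GS iterations
  and finishes with a *single* weighted iteration on the full pupil: the
  full hologram of the compressed state is synthesized, all $c_n$ measured
  on the full pupil, the weights updated once, and the final weighted
  superposition evaluated. Cost $(K-1) \cdot N \cdot cM + 2 N \cdot M$.
  In a convergence trace this final step appears as an abrupt uniformity
  jump at iteration $K$.

The `op_count` reported with every fit tallies spot–pixel visits of
superposition evaluations (one $N \times |\mathrm{domain}|$ per evaluation;
projection passes traverse the same cached phasors and are not tallied).
This single rule reproduces the four cost formulas above exactly, which the
tests assert. Diagnostic evaluations (the final quality report, traces)
are excluded.

### Subset lifetime

The pixel subset is sampled once per run and held fixed for all compressed
iterations — the measurement-matrix reading of compressed sensing, and the
default here. Per-iteration resampling is available (`resample_subset =
TRUE`); it leaves the cost model unchanged but turns the compressed phase
into a stochastic approximation.

## Numerical choices

* Internally all lengths live in micrometres; the boundary I/O keeps the
  conventional units (nm for $\lambda$, mm for $f$, µm for pitch and spot
  coordinates).
* Phases are kept unwrapped through all arithmetic; wrapping happens once,
  at mask export, where grey $g = \mathrm{round}(\mathrm{wrap}(\phi)/2\pi
  \cdot L)$ with $L$ the configured full-wave grey level (default 255; a
  phase just below $2\pi$ rounds to $L$, never to 0).
* A pixel where the superposed field cancels exactly gets phase 0 (the
  `Arg(0)` convention); this is measure-zero for generic inputs.
* The iterative engine materializes the $M \times N$ matrix of per-spot
  phasors $e^{i\phi_{n,m}}$ once per run and drives the iterations with
  complex BLAS matrix–vector products; this is what makes the benchmark
  protocol tractable in R, at a transient memory cost of $16 M N$ bytes
  (about 100 MB for a 256² pupil and 100 spots). The exported
  `superpose()` / `spot_amplitudes()` helpers and the brute-force test
  oracle accumulate spot by spot instead and never form the matrix.
* Per-spot `weight`s, when supplied, set target intensity *ratios*: initial
  amplitudes go as $\sqrt{w_n}$ and the WGS ratio is computed relative to
  $\sqrt{w_n}$, so the update drives $I_n \propto w_n$.
* Fixed iteration counts only — no adaptive stopping — so costs are
  predictable and runs comparable.

## What the generators emulate

The benchmark configurations are square pupils that downsample the short
side of a 1920×1152, 9.2 µm-pitch SLM at *fixed physical aperture*
(10.6 mm): pixel pitch scales up as the pixel count shrinks. This preserves
the diffraction-limited spot size and the depth of focus of the full-size
instrument, so axial structure in a 3D pattern remains optically meaningful
at 256² and 512²; only the accessible lateral field (Nyquist half-width
$\lambda f / 2p \approx 0.68 \cdot n_{px}$ µm) shrinks. The default
equivalent focal length, 18 mm, corresponds to a 20× objective
($f_{obj} = 9$ mm) behind a 2× pupil relay.

The three pattern generators supply the study conditions: a seeded uniform
cloud of 100 spots in a 200×200×100 µm box (a realistic photostimulation
workload, well separated at the benchmark spot size); a 10×10 grid at 20 µm
spacing in the focal plane — the worst case for uniformity, since the
periodic arrangement makes the spot fields interfere coherently; and a
25-point letter pattern ("TUD") spanning 500 µm, used for the
field-of-view protocol. What the simulated metrics do *not* capture:
camera noise, SLM pixel cross-talk and fill factor, zero-order light
(blocked in hardware), or aberrations — so passing benchmarks here
establish the algorithmic properties, not instrument performance. Real
systems estimate uniformity from fitted camera peak values, a different
estimator from the intensity-range formula used here.

## Benchmark scales and what the tests show

The package's own protocol runs GS-family comparisons on a 256² pupil with
the 100-spot cloud and the 10×10 grid at $K = 50$ over 10 replicate seeds
(replicate $r$ uses seed $base + r$), and the letter-pattern protocol on a
512² pupil at $K = 100$, $c = 0.05$ over 5 seeds. At these scales the test
suite verifies, among others: paired-seed orderings (GS beats RS in
efficiency; WGS beats GS in uniformity on the grid), CS-GS staying within
5% of GS quality at $c = 1/32$, the CS-WGS uniformity discontinuity, exact
cost-model counts, and equality of the fast path with a scalar double-loop
oracle to $10^{-12}$ on small pupils.

One caveat worth stating: GS efficiency at iteration 50 on the 256²/100-spot
problem still drifts by about $2 \times 10^{-4}$ per iteration — a plateau,
but not machine-level convergence — so the convergence test asserts a
late-to-early contraction of the per-iteration change rather than a hard
increment bound.

## A worked example

```{r, eval = FALSE}
library(csgs)

cfg <- benchmark_config(256)
cloud <- random_spot_cloud(100, lateral_extent_um = 100,
                           axial_extent_um = 50, seed = 1)

fit <- cgh(cloud, cfg, method = "cs-wgs", iterations = 50,
           compression = 1 / 32, seed = 1)
summary(fit)
plot(fit)                               # the wrapped phase mask
write_phase_mask(fit, "mask.png")       # 8-bit SLM upload format

# quality-versus-compression curve, 10 replicates per level
sw <- compression_sweep(cloud, cfg, method = "cs-gs", iterations = 50)
plot(sw)
```

## Known limitations

* Efficiency can exceed 1 for patterns with (near-)duplicated spots, whose
  pupil fields are not orthogonal; the bound $e \le 1$ holds for spot sets
  separated by more than a diffraction-limited spot.
* The full-size SLM with hundreds of spots implies a multi-GB phasor
  matrix; the engine favours speed over a blocked low-memory path.
* No GPU or multi-threaded path, no FFT-based full-frame synthesis, no
  modelling of SLM fill factor, dispersion or aberration correction.
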