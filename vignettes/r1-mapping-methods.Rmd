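---
title: "R1 mapping from MP2RAGE with 1D and 2D lookup tables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{R1 mapping from MP2RAGE with 1D and 2D lookup tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(r1lut)
library(ggplot2)
```

## The problem

MP2RAGE acquires two rapid gradient-echo (GRE) images, $I_1$ and $I_2$, at
two inversion times within one magnetization-prepared cycle, and combines
them voxel by voxel into the unified contrast

$$ \mathrm{UNI} = \frac{\Re(I_1^* I_2)}{|I_1|^2 + |I_2|^2} \in [-0.5, 0.5], $$

which cancels $M_0$, $T_2^*$ and receive-field effects. Because UNI is
quantitative, a transfer curve simulated from the sequence parameters maps
UNI to the longitudinal relaxation rate $R_1 = 1/T_1$. The classic procedure
inverts that curve with a one-dimensional lookup table (1D-LUT), which
requires the curve to be bijective over the $R_1$ window of interest.

Protocols tuned for tolerance to transmit-field (B1+) inhomogeneity tend to
*lose* that bijectivity: the UNI curve folds back on itself wherever
$I_1 = \pm I_2$, so two tissues (typically CSF and deep gray matter) share a
UNI value. This package implements the resolution of that ambiguity with a
second contrast derived from the same acquisition, the difference-sum ratio

$$ \mathrm{DSR} = \frac{|I_1| - |I_2|}{2\,(|I_1| + |I_2|)} \in [-0.5, 0.5], $$

and a two-dimensional lookup that matches the measured (UNI, DSR) pair to
the nearest simulated reference pair in weighted Euclidean distance. DSR
reaches its extremes exactly where UNI is uninformative ($|I_i| = 0$ versus
$I_1 = \pm I_2$), which is what makes the pair jointly injective.

## The signal model

One MP2RAGE cycle is modelled as a sequence of operations on the
longitudinal magnetization $M_z$, each affine in $M_z$:

1. instantaneous inversion, $M_z \mapsto -\,\epsilon\, M_z$ with inversion
   efficiency $\epsilon \in [0, 1]$ (default 0.96, a standard assumption at
   3 T; note $\epsilon = 0$ is *saturation* under this convention);
2. free relaxation for $T_A = TI_1 - \lfloor n/2 \rfloor\, \tau$;
3. the first FLASH block: $n$ repetitions of (excitation
   $M_z \mapsto M_z \cos\alpha_1$, then relaxation over
   $\tau = TR_\mathrm{FLASH}$), with $\alpha_1 = b_1 \cdot FA_1$;
4. free relaxation for $T_B = TI_2 - TI_1 - n\tau$;
5. the second FLASH block with $\alpha_2 = b_1 \cdot FA_2$;
6. free relaxation for $T_C = TR_\mathrm{MP2RAGE} - TI_2 - (n - \lfloor n/2 \rfloor)\tau$.

Composing the stages gives one affine map $M_z \mapsto a M_z + b$ per cycle
(`affine_cycle()`); $|a| < 1$ always holds for $R_1 > 0$, so the steady
state is the unique fixed point $M_z^\ast = b/(1-a)$ (`steady_state_mz()`).
Signals are read at the k-space-centre excitation of each block, taken as
excitation index $\lfloor n/2 \rfloor$ (0-based) under linear encoding, so
$TI_i$ is referenced to the centre of block $i$:
$s_i = \sin(\alpha_i)\, M_z$ just before that excitation
(`simulate_signals()`). Transverse magnetization is assumed perfectly
spoiled between excitations; $T_2^*$ decay, off-resonance, slice profiles
and finite inversion pulses are out of scope.

The transmit scale $b_1$ multiplies the two excitation flip angles only.
Holding the inversion efficiency fixed as $b_1$ varies is a deliberate
choice: adiabatic inversions are comparatively insensitive to moderate B1+
deviations, and the behaviour at large deviations is not modelled here.

### The readout train length

The per-block excitation count $n$ is rarely reported for published
protocols, yet the fold location depends (weakly) on it. It is therefore an
explicit protocol field. The two shipped protocol files use `n_exc = 138`,
the largest even count compatible with the LessBias timing constraint
$n \le 2\,TI_1 / TR_\mathrm{FLASH} = 139.3$; with it, the LessBias fold sits
at $R_1 = 0.418\ \mathrm{s^{-1}}$ (the package's own `find_folds()` result,
also recomputed by `scripts/acceptance.R`). Sensible alternative choices
(e.g. an asymmetric k-space centre as produced by partial Fourier) move the
fold by well under $0.05\ \mathrm{s^{-1}}$.

## Transfer tables and lookup inversion

`build_table()` samples the forward model on an equidistant $R_1$ grid,
default $0.01$ to $20\ \mathrm{s^{-1}}$ in steps of
$\Delta R_1 = 0.001\ \mathrm{s^{-1}}$ (19,991 rows). Equidistant $R_1$
spacing (rather than equidistant $T_1$) concentrates resolution in the
white/gray-matter range. The wide grid avoids truncation effects; matches at
the grid boundary are *flagged* (`truncated`), never silently clamped.

```{r transfer-curves}
tab <- build_table(protocol_lessbias(), 0.05, 8, 0.005)
autoplot(tab)
find_folds(tab, window = c(0.2, 5))
```

Inversion is exact nearest-reference search:

* `lut_invert_1d()` minimizes $|\mathrm{UNI} - \mathrm{UNI}_\mathrm{ref}|$;
* `lut_invert_2d()` minimizes
  $\sqrt{w^2(\mathrm{UNI}-\mathrm{UNI}_\mathrm{ref})^2 +
  (\mathrm{DSR}-\mathrm{DSR}_\mathrm{ref})^2}$, where the weight $w$
  (default 100) scales the measured and reference UNI equally. The 100:1
  ratio keeps the estimate UNI-driven — mirroring the 1D procedure wherever
  the curve is bijective — while DSR breaks ties between fold branches;
* `lut_invert_1d_b1()` is the measured-B1-map comparator: per voxel it picks
  a 1D table from a family precomputed over $b_1 \in \{0.5, 0.55, \dots,
  1.5\}$ (nearest member; out-of-range values are clamped, warned about and
  flagged).

Numerical choices: equal distances resolve to the lowest grid index (lowest
$R_1$), a deterministic rule the tests rely on; undefined contrasts
($I_1 = I_2 = 0$, e.g. noise-free background) propagate as an
`invalid`-voxel mask rather than errors. The search itself is written in
C++ over UNI-sorted references with pruned outward expansion; its arithmetic
matches a brute-force argmin term for term, and the test suite asserts exact
index equality against that brute force on random voxels — acceleration is
admissible only because it is bit-identical.

`find_folds()` reports local extrema of the UNI reference (sign changes of
its first difference) inside the window of interest, refined by three-point
parabolic interpolation and reported to $10^{-3}\ \mathrm{s^{-1}}$. On the
shipped protocols it finds one fold each inside $(0.2, 5)\ \mathrm{s^{-1}}$:
LessBias at $0.418$ and — worth stressing — a very shallow fold for the
Standard protocol at $0.225\ \mathrm{s^{-1}}$, where its UNI curve touches
$-0.5$ (the curve is often described as "near-bijective" for exactly this
reason). Both locations coincide with the $I_1 = -I_2$ condition to within
the grid step, which the tests verify by root-finding on $s_1 + s_2$.

## B1+ sensitivity analyses

`scale_excitation()` multiplies both flip angles by a factor, emulating a
transmit deviation or a deliberate excitation-amplitude rescaling (the
scanner-side equivalent of non-integer flip angles). `bias_curve()` then
measures, against the *nominal* table, the $R_1$ error incurred when the
data were actually produced at a different transmit scale — bias is defined
against known truth, which phantoms and grids provide; consistency across
scalings (what real-data studies must settle for) is computed separately by
`cross_scaling_stats()`.

```{r bias}
bc <- bias_curve(protocol_lessbias(), b1_scales = c(0.6, 1, 1.4),
                 r1_true = seq(0.5, 1.5, by = 0.1))
glance(bc)
```

`fa_manipulation_study()` reproduces the noise-versus-bias decomposition:
three replicate acquisitions of the same object are mapped with tables built
at nominal, reduced and increased flip angles (steps of 10% up to 90%); at
0% manipulation the three tables coincide and the cross-replicate variance
is the noise floor, so growth with the manipulation isolates the
bias-driven part. The per-tissue percentages observed on real acquisitions
are properties of those acquisitions; on phantoms the package asserts only
the qualitative structure (zero variance without noise at 0%, agreement
with a Monte-Carlo noise floor at 0%, growth with the manipulation).

## The digital phantom

`generate_phantom()` builds a fully labelled synthetic acquisition:

* **geometry** — three nested ellipsoids (CSF shell, GM shell, WM core) over
  empty background; analytic, so truth is exact and generation instant;
* **tissue $R_1$** — defaults CSF 0.25, GM 0.75, WM 1.25 $\mathrm{s^{-1}}$:
  package conventions placed inside the usual $R_1$ window of interest (GM
  inside the common 0.65–0.85 $\mathrm{s^{-1}}$ display window), not
  literature tissue values;
* **B1+ field** — a low-order smooth surface (linear through-slice gradient
  plus a transverse quadratic), normalized to span exactly
  $1 \pm 0.4$ by default and clipped to $[0.6, 1.4]$, the stress range used
  for transmit-field experiments;
* **noise** — each GRE signal passes through a complex Gaussian channel,
  $z_i = s_i + \mathcal{N}(0,\sigma) + i\,\mathcal{N}(0,\sigma)$; magnitudes
  are therefore Rician and the measured UNI is computed from the same noisy
  complex pair, so noise enters numerator and denominator consistently.
  Background voxels carry noise only.

The default $\sigma = 7\times10^{-4}\, m_0$ deserves a note: MP2RAGE GRE
signals are only a few percent of $m_0$ (low flip angles), so $\sigma$
relative to $m_0$ overstates the effective noise. The default was chosen to
land the phantom in the SNR regime of real 3 T acquisitions — about 70
under the max-intensity / background-mean definition of `compute_snr()` —
and the test suite verifies that placement. At a much heavier
$\sigma = 5\times10^{-3}$ (SNR of order 10) the median GM/WM relative error
of the 2D lookup grows to roughly 12%; the suite pins both regimes with
bounds calibrated once against the generator's own Monte-Carlo baseline.

What passing phantom tests do *not* show: the geometry is not anatomical,
there is no partial-volume mixing, no coil-sensitivity or k-space
(GRAPPA/partial-Fourier) structure, no motion. Results on the phantom
demonstrate correctness of the mapping machinery under the stated model,
not in-vivo accuracy.

## Reproducibility and problem sizes

Phantoms are bit-reproducible from (spec, seed); replicates use
`base_seed + replicate index`. Every CLI run writes a manifest (config,
seed, package version, output checksums) sufficient to reproduce it.

The shipped tests use full 19,991-row tables throughout, a $64^3$ phantom
for the headline parameter-recovery comparison, and $16^3$–$32^3$ phantoms
for noise and variance studies; these sizes were chosen as the smallest
that leave the measured quantities' Monte-Carlo scatter far below the
asserted margins.

## Known limitations

* The per-block excitation count and encoding order of published protocols
  are usually unknown; fold locations inherit that (small) uncertainty.
* The 2D lookup returns grid values only; no sub-grid interpolation of the
  estimate is performed (by design — interpolated output is out of scope).
* With only magnitude inputs and no UNI volume, the recomputed UNI is
  unsigned, which biases long-$T_1$ voxels; the CLI warns when it must fall
  back to this. A supplied UNI always wins over recomputation.
* Inversion efficiency is held fixed under transmit scaling; at ultra-high
  field this assumption weakens.
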