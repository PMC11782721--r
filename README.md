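# r1lut

Quantitative longitudinal relaxation rate (R1 = 1/T1) mapping from MP2RAGE
acquisitions, for MRI methods researchers and neuroimagers who want
B1+-tolerant R1 maps without an extra transmit-field scan.

## What it does

An MP2RAGE sequence acquires two gradient-echo images (I1, I2) at two
inversion times in one cycle and combines them into the unified contrast

    UNI = Re(I1* · I2) / (|I1|² + |I2|²)  ∈  [−0.5, 0.5],

which is insensitive to M0, T2* and the receive field. Since UNI is
quantitative, a Bloch-simulated transfer curve maps it to R1 — classically
with a one-dimensional lookup table (1D-LUT), which requires the curve to be
bijective. Protocols optimized for transmit-field (B1+) tolerance break that
bijectivity: the curve folds where I1 = ±I2, and two tissues can share one
UNI value.

`r1lut` resolves the ambiguity with a second contrast from the same data,
the difference-sum ratio

    DSR = (|I1| − |I2|) / (2 (|I1| + |I2|))  ∈  [−0.5, 0.5],

and a two-dimensional lookup that assigns each voxel the grid R1 minimizing
the weighted Euclidean distance

    √( w² (UNI − UNIref)² + (DSR − DSRref)² ),      w = 100 by default,

where the weight scales measured and reference UNI equally, so UNI drives
the estimate and DSR disambiguates fold branches. The package provides:

* a steady-state MP2RAGE signal simulator built from composed affine maps
  (`affine_cycle()`, `steady_state_mz()`, `simulate_signals()`);
* transfer tables on an equidistant R1 grid plus exact nearest-reference
  inversion (`build_table()`, `lut_invert_1d()`, `lut_invert_2d()`,
  `lut_invert_1d_b1()`) and fold detection (`find_folds()`);
* B1+ analyses: excitation scaling, bias curves against truth,
  cross-scaling statistics, and a flip-angle-manipulation variance study
  separating noise from bias (`scale_excitation()`, `bias_curve()`,
  `cross_scaling_stats()`, `fa_manipulation_study()`);
* a fully labelled digital brain phantom with Rician noise and a smooth
  ±40% B1+ field (`phantom_spec()`, `generate_phantom()`,
  `make_replicates()`);
* NIfTI I/O, two shipped reference protocols (`protocol_standard()`,
  `protocol_lessbias()`), broom-style `tidy()`/`glance()` methods,
  `autoplot()` figures, and a CLI (`inst/cli/r1lut`) with `sim-curve`,
  `map`, `phantom`, `b1-study` and `verify` subcommands.

## Worked example

```r
library(r1lut)

# B1-tolerant protocol: its UNI curve folds inside the R1 window of interest
tab <- build_table(protocol_lessbias())     # 19,991-row transfer table
find_folds(tab)
#> <fold_report> 1 fold(s) in (0.2, 5) s^-1 at: 0.418

# synthetic acquisition: 3-compartment head, ±40% B1+ field, Rician noise
ph <- generate_phantom(phantom_spec(), protocol_lessbias())
compute_snr(ph$m1, ph$m2, ph$labels == 0L)
#> [1] 73.5

# invert the measured (UNI, DSR) pair against the nominal table
res <- lut_invert_2d(ph$uni, compute_dsr(ph$m1, ph$m2), tab)
glance(res)
#> # A tibble: 1 × 7
#>   method n_voxels n_invalid n_truncated median_r1 q25_r1 q75_r1
#>   <chr>     <int>     <int>       <int>     <dbl>  <dbl>  <dbl>
#> 1 2d       262144         0         480     0.747  0.248   1.33

# median |R1 error| per tissue (s^-1): CSF, GM, WM
err <- abs(res$r1 - ph$r1_truth)
round(tapply(err, ph$labels, median, na.rm = TRUE), 4)
#>     0     1     2     3
#>    NA 0.016 0.013 0.021

# how much does a ±40% transmit deviation bias the estimates?
glance(bias_curve(protocol_lessbias(), b1_scales = c(0.6, 1, 1.4),
                  r1_true = c(0.75, 1.25)))
#> # A tibble: 3 × 3
#>   b1_scale max_abs_bias rms_bias
#>      <dbl>        <dbl>    <dbl>
#> 1      0.6       0.0320   0.0239
#> 2      1         0        0
#> 3      1.4       0.0580   0.0422
```

Reading the output: the LessBias transfer curve is non-bijective, folding at
R1 ≈ 0.42 s⁻¹, yet the 2D lookup recovers tissue R1 with median errors of
about 0.01–0.02 s⁻¹ across a ±40% B1+ field at realistic SNR — biases that a
1D lookup on a B1-sensitive standard protocol exceeds several-fold (the test
suite makes that comparison explicit). `n_truncated` counts voxels matched
at the grid boundary (noise-only background here); nothing is clamped
silently.

The same pipeline from the shell:

```sh
inst/cli/r1lut sim-curve --protocol inst/extdata/protocols/lessbias.json --out out/
inst/cli/r1lut map --i1 inv1.nii.gz --i2 inv2.nii.gz --uni uni.nii.gz \
    --protocol inst/extdata/protocols/lessbias.json --method 2d --out out/
```

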