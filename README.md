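# slprep

Simulation and quantification of spin-lock T1ρ preparation modules for
quantitative MRI.

T1ρ — the longitudinal relaxation time in the rotating frame — is an
emerging quantitative contrast for detecting myocardial and liver
fibrosis and early osteoarthritis. It is measured by *spin-lock*
preparation: tip the magnetization with a 90° pulse, lock it along a
long low-amplitude RF pulse of duration T<sub>SL</sub> where it decays
as exp(−T<sub>SL</sub>/T1ρ), tip it back, image, and fit

  S(T<sub>SL</sub>) = S₀ · e^(−T<sub>SL</sub>/T1ρ)

pixel by pixel. The catch: static-field (B0) and RF-field (B1)
inhomogeneities tilt and detune the lock axis, turning the clean decay
into an oscillating trajectory — banding artifacts in the images and
bias in the T1ρ map.

`slprep` is a matrix-propagation simulator for studying how different
preparation module designs tolerate those field errors. It implements:

* **Propagation core** — 3×3 rotation and rotating-frame relaxation
  propagators in the tilted rotating frame, with
  SL±(τ) = R<sub>x</sub>(∓θ)·E<sub>ρ</sub>(τ)·R<sub>y</sub>(ωτ)·R<sub>x</sub>(±θ)
  spin-lock segments and B1-scaled hard pulses.
* **Module library** — the composite (C-SL), balanced (B-SL),
  triple-refocused (TR-SL) and quadruple-refocused (QR-SL) preparation
  modules, plus a generic n-refocused builder and JSON (de)serialization
  of custom modules.
* **Analytic oracles** — independent closed forms for the B1-only and
  B0-only limiting cases, used to verify the numeric propagators to
  machine precision.
* **Quantification** — mono-exponential fitting (Levenberg–Marquardt),
  the relative quantization errors Δq = T1ρ,fit/T1ρ,true − 1 and
  repetition-averaged ΔQ, dense-trajectory residuals (banding
  susceptibility), and voxel-wise T1ρ/S₀/residual maps.
* **Sweeps** — ΔQ and residual grids over ±600 Hz × ±50% field
  deviations with paired random sampling across modules, criterion
  proportions, frequency and relaxation-ratio curves, and a
  refocusing-phase combination study.
* **Digital phantom** — a five-tube 120-mm phantom with gradient B0 and
  uniform B1 maps, T1ρ-weighted series synthesis (optionally with Rician
  noise), NIfTI+JSON I/O, and dual-echo B0 / double-angle B1 map
  estimators.
* **RF metrics** — per-module RMS RF amplitude as a SAR proxy.

## Worked example

The headline robustness scenario — spin-lock frequency 500 Hz, 350 Hz
off-resonance, −25 % flip-angle error, T1ρ:T2ρ = 1, eight random
spin-lock times per repetition, 100 repetitions with the same draws
reused across modules:

```r
library(slprep)
rl  <- relaxation_params(0.05, 0.05)          # T1rho = T2rho = 50 ms
tab <- quant_error_table("all", delta_f0 = 350, db1 = -0.25, f_sl = 500,
                         relax = rl, rng_seed = 1, angle_mode = "literal")
transform(tab, dQ_abs_pct = round(100 * dQ_abs, 2),
               dQ_s0_abs_pct = round(100 * dQ_s0_abs, 2))[,
  c("module", "dQ_abs_pct", "dQ_s0_abs_pct", "rss")]
#>   module dQ_abs_pct dQ_s0_abs_pct          rss
#> 1    csl       3.65         10.59 0.0004221887
#> 2    bsl      13.01         19.13 0.0041511464
#> 3   trsl       5.80          8.86 0.0009795666
#> 4   qrsl       4.48          7.55 0.0006543842
```

`dQ_abs_pct` is the mean absolute T1ρ quantization error in percent,
`dQ_s0_abs_pct` the corresponding fitted-amplitude error, and `rss` the
mean squared residual of the dense |Mz| trajectory against its
mono-exponential fit (banding susceptibility). The balanced module is
hit hardest by this combined B0+B1 deviation; the quadruple-refocused
module has the lowest amplitude error and, together with the composite
module, the lowest T1ρ error.

Individual pieces are directly accessible:

```r
f <- field_conditions(350, 0.75, 500, "pulses_only")
f
#> field conditions: df0 = 350 Hz, B1 scale = 0.75 (pulses_only), fSL = 500 Hz
#>   theta = 0.6107 rad, fe = 610.33 Hz

qr <- sl_preset("qrsl")
qr
#> <sl_module> qrsl: 90(+) SL+(0.125) 180(+) SL-(0.25) 180(+) SL+(0.25)
#>   180(-) SL-(0.25) 180(-) SL+(0.125) 90(-)

mz_after_prep(qr, c(0.01, 0.05, 0.1), f, rl, "literal")
#> [1] 0.7597514 0.3347331 0.1158430
```

Grid sweeps and the phantom digital twin follow the same pattern; see
`?inhomogeneity_sweep`, `?proportion_within`, `?make_tube_phantom` and
the vignette (`vignettes/spin-lock-simulation.Rmd`) for the full
methodology.

A command-line driver is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","slprep",package="slprep"))') \
  simulate --module all --fsl 500 --db0 350 --db1 -0.25 --reps 100 \
  --seed 7 --out sim.csv
```

Subcommands: `simulate`, `sweep`, `phantom`, `map`, `rf`, `phase-study`.

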