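# bnyg — a two-regime phase-separation model of Brownian yet non-Gaussian diffusion

Single-particle tracking of colloidal beads on phospholipid-bilayer
tubes shows *Brownian yet non-Gaussian* diffusion: the mean squared
displacement grows linearly in time, ⟨x²(t)⟩ = 2·D_avg·t, yet the
displacement distribution is a Laplace (double-exponential) density
rather than a Gaussian — and only after a critical time t_c does it
relax to a Gaussian. `bnyg` implements a microscopic explanation of this
behaviour and the machinery to test it, for biophysicists and soft-matter
physicists analysing or simulating such experiments.

## The model in brief

Weak Van der Waals attraction between the Brownian particle and the
fluid — the long-range tail of a 6-12 Lennard-Jones pair potential,
U(r) = −4ε(σ/r)⁶ — integrates over the particle's interface into an
inverse-cube potential V(z) ∝ −εσ⁶ρ_s/z³. In a weakly interacting,
compressible fluid this triggers a phase separation into

* a **gas-like phase** (compressibility factor Z_G ≈ 1), in which the
  radial particle-number gradient d(ZN)/dr = −Z/r produces an attractive
  inter-cluster force F = −k_BT/(rZ).  The resulting overdamped Langevin
  equation has a constant-magnitude drift toward the origin
  (dry friction), dX = −μ·sgn(X)dt + √(2D)dW, whose stationary law is
  the Laplace density p(x) = e^{−|x|/λ}/(2λ) with λ(t) = √(D_eff^G·t);
* a **liquid phase** (Z_L ≪ 1), where the drift is negligible and the
  motion is free diffusion with a much larger effective diffusivity
  D_eff^L = D/Z_L².

Each trajectory belongs to one phase with probability ½, giving the
strictly linear mixture MSD 2·D_avg·t with
D_avg = ½(D_eff^G + D_eff^L).  At t_c the gas-like phase ends; the
frozen Laplace density then evolves by free diffusion
(∂p/∂t′ = D_eff^L ∂²p/∂x²) into the **transition density** — the exact
Laplace⊛Gaussian convolution, written with the scaled complementary
error function so it never overflows — whose excess kurtosis
3(2λ₀²)²/(2λ₀² + 2D_eff^L t′)² interpolates from 3 (Laplace) to 0
(Gaussian).  The bare diffusivity uses the extensional-viscosity
Stokes–Einstein relation D = k_BT/(18πηR), appropriate for a
compressible medium (η_e = 3η).

The package provides the closed forms, a seeded Euler–Maruyama
simulator of the two-regime process (the synthetic-data generator and
Monte-Carlo oracle), independent numerical oracles (Crank–Nicolson
diffusion solver, direct-quadrature convolution), and a CLI.

## Worked example

The bead-on-bilayer-tube experiment: T = 22 °C, medium viscosity 100×
bulk water, bead radius R = 50 nm, measured D_avg = 0.40 μm²/s,
t_c = 4 s.

```r
library(bnyg)
rep <- reproduce_application()
print(rep)
#> Two-regime phase-separation model -- derived quantities
#>   bare diffusivity D            : 0.014 um^2/s
#>   cholesterol control D         : 0.012 um^2/s
#>   measured average Davg         : 0.4 um^2/s
#>   liquid-phase DeffL            : 0.79 um^2/s
#>   liquid compressibility Z_L    : 0.14
#>   critical time tc              : 4 s
#>   Gaussianization time after tc : 0.5 s (kurtosis < 0.05)
#>   model curves at               : t=0.06s, t=0.6s, t=3s, t=5.8s
```

Reading: the extensional Stokes–Einstein bare diffusivity is
0.014 μm²/s, ~30× smaller than the measured average — the signature of
the fast liquid phase, whose inferred diffusivity 0.79 μm²/s implies a
liquid-like compressibility factor Z_L ≈ 0.135 (printed at two
significant figures).  With 20 % more viscosity (cholesterol-stiffened
membranes, no phase separation) the same relation gives 0.012 μm²/s.
After t_c the displacement density is operationally Gaussian (excess
kurtosis < 0.05) within 0.5 s — consistent with the observed ~2 s.

Simulate the process and recover the diffusivity from the ensemble:

```r
ens <- simulate_ensemble(sim_config(rep$phase, n_paths = 1e4, dt = 1e-3,
                                    t_max = 8, seed = 1,
                                    record_stride = 500L))
fit <- fit_davg(ens)                     # MSD regression over (0, tc]
#> recovered Davg = 0.394 +/- 0.001 um^2/s
ensemble_stats(ens, times = c(3, 8))$summary
#>   time      msd excess_kurtosis     n
#> 1    3 2.391164       3.0804772 10000
#> 2    8 9.248244       0.5712829 10000
```

The empirical excess kurtosis is ≈ 3 (Laplace) before t_c and decays
toward 0 (Gaussian) after it, while the MSD stays linear throughout.

## Command line

```sh
inst/cli/bnyg infer --json           # D, DeffL, Z_L from a config
inst/cli/bnyg pdf --time 5.8 --out curve.csv
inst/cli/bnyg gauss-time --threshold 0.05
inst/cli/bnyg simulate --n 1000 --tmax 8 --seed 1 --out traj.csv
inst/cli/bnyg stats --in traj.csv --times 3,8
inst/cli/bnyg reproduce --out report.json
inst/cli/bnyg compare --model-time 0.06 --data hist.csv
```

`compare` scores a displacement histogram (CSV columns
`x_over_d,log10_density,time_s`) against the model curve with a
fixed-intercept least-squares fit: the log₁₀-density intercept is pinned
to the model's value and the percentage error of the highest-order
coefficient (the |x| slope on the Laplace branch, the x² coefficient on
the transition branch) is reported.

## Documentation

The methods vignette (`vignettes/bnyg-methods.Rmd`) describes the model,
its assumptions, every tunable parameter with units and defaults, what
the simulator does and does not emulate, and the numerical choices.
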