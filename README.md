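# glidemech

Biophysical simulation of bacterial gliding motility, built to ask one
mechanical question: are the gliding motors of *Myxococcus xanthus*
coupled to the substrate **elastically** (as the focal-adhesion mechanism
predicts) or **viscously** (as the helical-rotor mechanism predicts)?

The package implements a flexible node-and-spring cell — a chain of
circular nodes and rectangular spacers with joint springs, angular
(bending) springs, distributed 12 pN motor forces, and Stokes drag
calibrated to the observed 4 µm/min gliding speed — in which the two
coupling hypotheses differ *only* in the node–substrate force law:

* **VCM** (viscous coupling): drag is the only substrate interaction;
* **ECM** (elastic coupling): each interior node carries a breakable
  substrate bond, a linear spring of stiffness κ acting on displacement
  perpendicular to the cell axis (axial gliding is free), breaking at a
  stretch `d_break` and reforming after an exponential waiting time
  (mean 7.5 s).

On top of the simulator it provides the analyses that discriminate the
two models:

* head-to-side **cell–cell collision experiments** with sweeps over bond
  stiffness, collision position and collision angle, and a robustness
  sweep over all mechanical parameters — the central metric is Δθ_max,
  the largest change in the struck (primary) cell's orientation over all
  interior collision positions;
* **track quantification** for experimental pole-coordinate exports:
  orientation time series, the spontaneous-turning statistic
  Δθ_s = (1/M) Σᵢ (1/nᵢ) Σⱼ |θᵢ(tⱼ + τ_c) − θᵢ(tⱼ)|, and net collision
  orientation changes;
* a synthetic **force-clamp bead assay** with the published trigger and
  validation rules, stall classification (|v| ≤ 2·SE), and the
  exponential force–velocity fit v = v₀·exp(−F/F_c) with broom-style
  `tidy()`/`glance()` methods and `autoplot()` figures.

## A worked example

```r
library(glidemech)

p   <- mech_params()                                  # defaults, real units
vcm <- adhesion_params(mode = "VCM", n_nodes = p$n_nodes)
ecm <- adhesion_params(kappa = 2000, n_nodes = p$n_nodes)

delta_theta_max(params = p, aparams = vcm, seed = 1)
#> [1] 32.35665   (degrees; viscous coupling: the struck cell is strongly turned)

delta_theta_max(params = p, aparams = ecm, seed = 1)
#> [1] 6.493908   (degrees; 50-pN elastic bonds pin the struck cell's course)

sw <- sweep_kappa(params = p, seed = 1)
min_matching_kappa(sw)     # smallest stiffness inside the experimental
#> [1] 500                 # 15 +/- 15 degree band (pN/um)

fit <- fit_force_velocity(simulate_fv_dataset(v0 = 67, f_c = 2.3,
                                              trials = 6, cv = 0.2,
                                              seed = 1))
fit
#> <fv_fit> v = v0 exp(-F / f_c)
#>   v0 = 67.5 +/- 2.67 nm/s
#>   f_c = 2.31 +/- 0.0177 pN  (n = 66)
```

The first two numbers are the collision contrast at a ~90° impact: under
viscous coupling the primary cell is deflected by tens of degrees, under
strong elastic bonds it holds its course — the signature that, compared
with experiments (net turn 15 ± 15°), favors elastic motor–substrate
coupling. The force–velocity fit recovers the characteristic decay force
from synthetic bead data generated at 2.3 pN ground truth, with an
uncertainty that reflects the 20 % velocity noise.

A command-line front end with subcommands (`simulate-collision`,
`sweep-kappa`, `quantify-tracks`, `forceclamp-sim`, ...) is installed at
`inst/cli/glidemech`; every run writes tidy CSV tables plus a JSON
manifest with the config snapshot and seed. The methods vignette
(`vignettes/gliding-mechanics.Rmd`) describes the model, its assumptions,
the tunable parameters and the design decisions in detail.

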