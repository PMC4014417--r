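---
title: "Mechanics of bacterial gliding: the glidemech model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of bacterial gliding: the glidemech model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glidemech)
```

## The scientific question

*Myxococcus xanthus* glides over surfaces without flagella or pili. Two
mechanisms have been proposed for how its distributed motors couple to the
substrate: focal-adhesion-like complexes that bind the substrate
**elastically**, and helical-rotor surface distortions that couple only
through **viscous** drag. The two hypotheses make different mechanical
predictions: an elastically anchored cell resists lateral displacement of
its body, a viscously coupled one does not. `glidemech` implements a
biophysical cell model in which the two couplings differ *only* in the
node–substrate force law, so that their consequences for cell–cell
collisions and loaded-motor velocity can be compared quantitatively.

## The cell model

A cell is a chain of `n_nodes` circular nodes (radius `node_radius`)
alternating with rigid rectangular spacers, connected by stiff
zero-rest-length joint springs at the node centres. All quantities are in
real units: micrometres, piconewtons, minutes.

Forces on the bodies:

* **Joint springs** (`k_joint`): Hooke forces between each node centre and
  the coincident spacer endpoint, holding the chain together. They are
  stiff but finite; the default (2000 pN/µm) keeps joint-length
  fluctuations below 1 % of the spacer length at the model's force scales.
* **Angular springs** (`k_bend`): one per interior node, rest angle π,
  energy ½·`k_bend`·(θ − π)² per triple. Forces are the exact analytic
  gradient of this energy, so each triple exerts zero net force. `k_bend`
  sets the cell's flexural rigidity (EI ≈ `k_bend` × spacer length).
* **Propulsion** (`f_prop`): a constant-magnitude motility force at every
  interior node, directed along the chain toward the leading pole. The
  poles are motor-free. The default, 12 pN per node at 5 interior nodes,
  gives the 60 pN whole-cell motor force estimated for gliding cells.
* **Stokes drag** (`gamma_node`): −γ·v on every body (and a matched
  rotational drag on spacers). γ is not free: `calibrate_drag()` sets it so
  total drag balances total propulsion at the observed gliding speed of
  4 µm/min. The question whether drag should act on the spacers as well as
  on the nodes is not settled by the biology; we apply it uniformly to all
  bodies and verify that collision outcomes are insensitive to body mass
  and step size (the overdamped limit).
* **Substrate adhesion** (ECM only; `kappa`, `d_break`, `reform_rate`):
  see below.
* **Contacts**: all-pairs overlap tests between bodies of different
  cells — circle–circle, circle–rectangle, and spacer–spacer as
  capsule–capsule (segment-to-segment distance against the cell width;
  without this last case, obliquely crossing chains can tunnel between
  the node circles and pass through each other). Overlaps are resolved by
  penalty forces of stiffness `k_contact` along the contact normal plus a
  regularized Coulomb friction force `friction_mu`·|F_n|·tanh(v_slip/0.5)
  on the tangential slip velocity. The default `friction_mu = 0.2` is the
  customary rigid-body-engine value; the tangential coupling is what lets
  a cell sliding along its collision partner rotate into alignment rather
  than rake along it indefinitely, and it markedly stabilizes the
  elastic-coupling outcomes. Overlap at accepted steps is bounded by 5 %
  of the cell width; exceeding it aborts the run, signalling that
  `k_contact` or `dt` needs adjustment.

### Substrate adhesion: the elastic-coupling law

Each adhesion node (interior nodes 2…`n_nodes` − 1; the leading pole never
adheres, which preserves the cell's ability to change direction) carries a
breakable bond to the substrate:

* The bond stores an **anchor point** and a **bond axis**, the cell's local
  axis at the moment the bond formed, frozen thereafter. The anchor slides
  freely along this line, so motors can translocate the cell axially
  against stationary adhesions; only displacement **perpendicular** to the
  line is loaded, with force −`kappa` × lateral displacement.
* A lateral stretch beyond `d_break` breaks the bond. Broken bonds reform
  at the node's current position after an exponentially distributed waiting
  time (mean 1/`reform_rate` = 7.5 s by default, the time for the next
  motor to arrive at an adhesion site).
* **Turnover**: once a node has slid one node spacing along its bond line,
  the load is handed to a fresh adhesion site — the anchor re-forms at the
  node with the current local axis, deterministically. This mirrors the
  observed turnover of adhesion complexes (they assemble at the leading
  pole and disperse at the lagging pole as the cell advances) and it
  bounds the memory of the bond: without it, bond lines frozen during a
  past maneuver act as misaligned "rails" that steer the cell long after
  the encounter.

This formulation was selected after explicitly comparing three
alternatives. Anchors fixed rigidly at their formation point (loading the
perpendicular component of total displacement) become hair-triggers once
the cell has glided a few micrometres — a 0.2° wobble then projects to a
stretch beyond `d_break` — and break en masse at first contact. Anchors
that slide along the *current* (rotating) axis lose all static resistance
to slow rotations: the stored lateral stretch leaks into the free axial
direction as the axis turns, leaving only rate-dependent damping, and
collided cell pairs then spin slowly without limit. The frozen-axis,
turnover-limited bond keeps true spring-like resistance to reorientation
on short timescales while forgetting stale geometry on the timescale of
one node spacing of travel (~16 s).

With `kappa = 0` no force is ever exerted and the trajectories are
identical (to machine precision) to viscous-coupling (VCM) runs — the two
models genuinely differ only in the substrate law.

## Time integration

Positions and velocities follow Newtonian dynamics integrated with
semi-implicit (symplectic) Euler: velocities are updated from the total
force first, positions then move with the *updated* velocities. The Stokes
drag term is treated implicitly in the velocity update,

v ← (v + F_other·dt/m) / (1 + γ·dt/m),

which is what makes the quasi-overdamped regime stable: body mass is
chosen so the inertial relaxation time m/γ (≈ 10⁻⁶ min by default) is far
below `dt`, as appropriate at a Reynolds number this low, and an explicit
drag term would oscillate violently whenever γ·dt/m > 2. The scheme
reduces to the standard update exactly in the limit γ → 0 and converges to
the drag-decay closed form with first-order error. The default step
(2 × 10⁻⁵ min) is set by the stiffest spring in the system (the contact
penalty): k·dt/γ ≈ 0.35, comfortably inside the monotone-stability region,
and halving it changes collision orientation outcomes by well under a
degree. Runs with a fixed seed are bit-reproducible; bond reformation
timing is the only stochastic element.

The inner loop (forces, contacts, bonds, integration) is compiled C++;
the exported R force functions (`joint_forces()`, `bending_forces()`, …)
are the readable reference implementation, and the test suite asserts
that one compiled step equals the R-side computation to 10⁻¹².

## Collision experiments

`setup_collision()` builds the canonical head-to-side geometry: a primary
cell gliding along +x and a secondary cell approaching at the collision
angle, aimed so its leading node and the chosen primary node reach the
impact point simultaneously, starting at least one cell length away with
both cells at terminal speed. `run_collision()` advances the world and
measures each cell's orientation (the CCW angle of the lagging→leading
vector, unwrapped) before first contact and again at the end of the
encounter.

**When is "after"?** The settling criterion (< 0.5°/min orientation rate
over a trailing 0.5 min window, evaluated only after contact) captures the
plateau most runs reach. Encounters that never plateau — hooked pairs can
keep creeping — are measured at first contact + `post_window` (default
2.9 min), the mean duration of experimentally observed collisions, which
makes the simulated and experimental observables commensurate. A 10 min
cap applies to contact-free runs.

`delta_theta_max()` is the headline metric: the largest primary-cell
orientation change over all interior collision nodes at a fixed angle
(~90° by default, where the effect is maximal). The poles are excluded —
with no adhesion at the poles, pole impacts produce large swings in both
models and carry no discriminating power. Because bond-reformation timing
is stochastic, the head-adjacent collision (node 2) is bimodal at strong
adhesion: in most realizations the cell holds to within a few degrees, but
when the node-2 bond's reformation happens to lag, the unanchored head
section swings 20–27°. Each elastic-coupling node is therefore simulated
`n_rep = 5` times and summarized by its median; viscous and `kappa = 0`
runs are deterministic and run once. The replicate SD is reported alongside
so this variability is visible rather than hidden.

Sweeps build on this metric: `sweep_kappa()` (bond stiffness at fixed
breaking distance, so the breaking force κ·`d_break` scales with κ),
`sweep_position()`, `sweep_angle()`, `robustness_sweep()` (each mechanical
parameter varied 0.1×–10×), and `min_adhesion_strength()` (bisecting the
smallest κ whose response enters the experimental comparison band, as a
function of propulsion force). The experimental band — net orientation
change of 15 ± 15° for wild-type collisions after subtracting spontaneous
turning — is a configurable input, not a constant baked into the code.

### What the defaults represent

`n_nodes = 7` makes the interior-node count equal the ~5 adhesion
complexes per cell inferred from imaging, and 5 × 12 pN reproduces the
~60 pN whole-cell force estimate. `d_break = 0.025` µm ties the reference
stiffness κ = 2000 pN/µm to a 50 pN bond-breaking force, the magnitude
reported for integrin-class adhesions. `k_bend = 90` pN·µm/rad
(EI ≈ 97 pN·µm², within the published range for *M. xanthus* flexural
rigidity) is the flexibility at which an unadhered cell's maximal
collision response reproduces the tens-of-degrees orientation change
expected under pure viscous coupling; cell flexibility is explicitly a
tuned quantity in this model class, and all of these are exposed as
configuration.

## Track quantification

The experimental pipeline consumes manually tracked cell-pole coordinates
(MTrackJ-style CSV: cell id, frame, head/tail, pixel coordinates).
`orientation_series()` converts head/tail positions to unwrapped CCW
orientations. `spontaneous_turning()` computes the mean absolute
orientation change of isolated cells over non-overlapping windows of
length `tau_c` (2.9 min by default, the mean collision duration): cells
wander even without collisions, and this statistic is subtracted from
observed collision turns (`collision_delta_theta()`, floored at zero — a
negative net turn is not meaningful). An overlapping-window variant exists
behind a flag for sensitivity analysis; the non-overlapping definition
(n_i = ⌊T_i/τ_c⌋ windows) is the default. Whether the correction is
applied per event or only to the distribution mean is also genuinely open;
per-event is the default here. Simulated trajectories can be converted to
the same track format (`trajectory_to_tracks()`), and the pipeline
recovers the simulator's own orientation change to within 0.5°.

## The synthetic force-clamp assay

`simulate_bead_trace()` emulates the optical-trap experiment: a bead
driven by a gliding motor runs, pauses, and occasionally reverses; when it
moves 63 nm within 3 s the trap applies a constant preset force for 8 s.
Under load F the run velocity is v₀·exp(−F/F_c) for elastic coupling
(never negative — the bead stalls but is never dragged backwards) or
v₀·(1 − F/F_stall) for viscous coupling (negative above stall). The stall
force default of 12 pN makes the two laws agree at zero velocity, so they
differ only in the super-stall regime — the discriminating signature.
Pause rate, pause duration, reversal probability and positional noise are
fixture parameters with no measured counterparts; the defaults
(0.06 s⁻¹, 2 s, 0.3, 5 nm) produce the observed phenomenology of bead
traces and leave roughly half of triggered clamps rejected by segment
validation, as in practice. The unloaded velocity default (67 nm/s) is
the cell-model speed scale (4 µm/min) expressed in nm/s, not a measured
bead velocity, and is configurable.

`detect_runs_and_validate()` applies the published acceptance rule: a
clamp segment counts only if the bead's linear velocity before and after
force application agrees in sign and within twice the combined standard
error. `fit_linear_velocity()` is ordinary least squares on position vs
time; `classify_stall()` calls a segment stalled when |v| ≤ 2·SE.

`fit_force_velocity()` fits v = v₀·exp(−F/F_c) by nonlinear least
squares, iteratively reweighted by the fitted mean because bead-velocity
noise scales with the mean (constant CV). The reweighting matters for
inference, not for the point estimate: with 20 % CV noise the unweighted
fit's standard errors undercover (77 % at nominal ~95 %), while the
reweighted fit's 2-SE intervals cover at 97 % with bias below 0.1 %.
`normalize_collapse()` divides each condition's velocities by its own
fitted v₀ and fits a single shared F_c to the pooled data — the collapse
that demonstrates the decay force is independent of motor speed.

## Numerical and design notes

* Degenerate geometry (zero-length bending arms, coincident poles) and
  non-finite states abort with the offending term named.
* Contact detection is exact all-pairs every step; with ≤ 26 bodies this
  is cheaper than any broadphase structure.
* The collision-angle scan covers 15–165°; angles within 5° of 0 or 180°
  cannot produce a side impact and are rejected at setup.
* `robustness_sweep()` varies {k_bend, k_joint, gamma_node, f_prop,
  body_mass} — the mechanical parameters with no directly measured values;
  unstable runs are excluded and counted.
* Problem sizes used throughout the tests and the acceptance analysis
  (5-minute calibration runs, 5-node collision sweeps, 5 reformation
  replicates, 10⁵ waiting-time samples, ≥ 6 trials per force point) are
  chosen so every check completes at desk scale while keeping Monte-Carlo
  error well inside the stated tolerances.

## Known limitations

* The model is two-dimensional and ignores slime-trail following, cell
  polarity reversals, growth, and torsion.
* Cells in a collision share one parameter set; per-cell length variation
  is not modelled.
* The adhesion law is isotropic and linear up to a brittle break; real
  complexes are likely viscoelastic and anisotropic.
* Intermediate adhesion strengths (κ ≈ 200–1000 pN/µm) sit near a
  mechanical bifurcation: bonds strong enough to pivot the cell but weak
  enough to break under the collision load can *amplify* the primary
  cell's turn beyond the viscous limit in some reformation realizations.
  The stiffness sweep is therefore not strictly monotone run-by-run, and
  the replicate medians still carry visible spread there. Conclusions
  should rest on the well-separated regimes (κ = 0 vs κ ≥ 2000), which are
  robust.
* In the collision-angle scan the viscous-coupling response peaks one
  15° grid step *below* perpendicular (75°, not 90°). At sub-perpendicular
  angles the secondary keeps a forward velocity component, stays engaged
  with the primary's lagging half far longer, and levers it around; the
  effect survives variation of the bending stiffness over 65–110 pN·µm/rad
  and friction on or off. Treat the location of the angular maximum as
  implementation-sensitive; the qualitative shape — small response at both
  range extremes, large in the middle, with the two coupling models
  diverging there — is robust.
* Under strong adhesion, an exactly perpendicular impact can end in a
  head-on stalemate within the measurement window: the secondary's own
  bonds pin it in place and the frictional contact blocks the lateral
  sliding that would rotate it, so both cells hold position with the
  primary's course intact but the secondary not yet aligned. At oblique
  incidence the secondary does rotate into the primary's direction. The
  primary-cell orientation change — the discriminating metric — is
  unaffected.
* Passing tests on synthetic tracks and traces show the pipeline's
  internal consistency; they cannot validate the model against features of
  real data the generators do not emulate (segmentation error, uneven
  frame intervals, drift).

## A worked example

```{r example, eval = FALSE}
p <- mech_params()
ecm <- adhesion_params(kappa = 2000, n_nodes = p$n_nodes)

# one head-to-side collision under strong elastic coupling
out <- run_collision(collision_node = 4, collision_angle = 90,
                     params = p, aparams = ecm, seed = 1)
out$delta_theta_primary    # a fraction of a degree: the primary holds course
out$delta_theta_secondary  # larger: the deflection lands on the secondary

# the two-model contrast
vcm <- adhesion_params(mode = "VCM", n_nodes = p$n_nodes)
delta_theta_max(params = p, aparams = vcm, seed = 1)   # tens of degrees
delta_theta_max(params = p, aparams = ecm, seed = 1)   # < 15 degrees

# force-velocity analysis at the bead
d <- simulate_fv_dataset(v0 = 67, f_c = 2.3, trials = 6, cv = 0.2,
                         seed = 1)
fit_force_velocity(d)
```
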