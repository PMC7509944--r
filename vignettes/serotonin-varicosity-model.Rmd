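---
title: "The serotonin varicosity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The serotonin varicosity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serosim)
```

# The model

`serosim` implements a deterministic kinetic model of a single serotonin
varicosity and the extracellular space around it.  Sixteen coupled ODEs
track:

* the pterin cofactor pair `bh2`/`bh4` (dihydro/tetrahydrobiopterin),
  recycled by dihydropteridine reductase (DRR) against fixed NADPH/NADP;
* cytosolic tryptophan `trp`, imported from blood tryptophan `btrp` by the
  neutral amino acid transporter, drained by catabolism and by exchange
  with a cellular `pool` representing all non-serotonin uses;
* the synthesis pathway `trp -> htp -> cht`: tryptophan hydroxylase (TPH,
  with substrate inhibition in `trp`) followed by aromatic amino acid
  decarboxylase (AADC);
* cytosolic serotonin `cht`, packaged into vesicles (`vht`) by the
  vesicular monoamine transporter (MAT, forward Michaelis-Menten minus a
  linear back-leak), catabolized by monoamine oxidase, and leaking to the
  extracellular space;
* extracellular serotonin `eht`: released from vesicles at rate
  `inhib(G*_ht) * inhib_ha(G*_ha) * fire(t) * vht`, recaptured by the
  SERTs (high affinity, low capacity), taken into glia by the thresholded
  Uptake 2 (low affinity, high capacity), removed by
  diffusion/capillaries, and reversibly bound by the 5HT1B autoreceptor;
* glial serotonin `ght`, catabolized in the glia;
* two G-protein receptor cascades, each with three species: bound
  receptor `B`, activated G-protein `G*`, and activated RGS protein `T*`.
  Bound ligand drives `G` to `G*`; `G*` activates `T`; `T*` deactivates
  `G*`.  The serotonin cascade (5HT1B autoreceptor, ligand `eht`) carries
  speed factors `beta1..beta3`; the histamine cascade (H3 receptor,
  ligand `eha`) is the receptor submodel of a histamine-neuron model,
  imported here unchanged.

`btrp` and `eha` have no differential equations: they are forcings whose
time courses are supplied (constant at 96 and 1.39 uM by default).

The feedback enters through three linear "inhibition multipliers" anchored
at equilibrium operating points:

* release: `inhib(G*_ht) = 1.89 - s_rel (G*_ht - G*_ht,eq)`, slope 12.5;
* synthesis: `inhibsyn(G*_ht) = 1 - s_syn (G*_ht - G*_ht,eq)`, slope 2.5;
* histamine: `inhib_ha(G*_ha) = 1 - s_ha (G*_ha - G*_ha,eq)`, slope 5.

All three are clamped below at zero: a negative release or synthesis rate
is unphysical.  The clamp matters in practice — during a strong
stimulation `G*_ht` overshoots far enough that the release multiplier
saturates at zero for part of the transient.

## Units and conventions

Concentrations are uM and rates uM/h (first-order constants /h); receptor
species are in arbitrary units, as effective surface concentrations of
receptors cannot be estimated.  The integrator runs entirely on the hours
clock; stimulation protocols are specified in seconds and converted only
at the `fire(t)` call site.  `eht` is reported in nM where that is the
conventional scale (response curves, population summaries); the Uptake 2
gate thresholds are defined in nM for the same reason.

Two printed-source ambiguities were resolved by mass balance:

* The extracellular balance lists the cytosolic and glial leak terms
  without an operator between them; both are implemented as inflows to
  `eht`, the only reading consistent with their outflow terms in the
  `cht` and `ght` equations.
* The basal firing rate is never stated; `f_basal = 1/h` is adopted
  because the reported release flux, release multiplier, and vesicular
  concentration (`release = 1.89 * f_basal * vht`) force it to 1 within
  rounding.  It is an ordinary parameter and can be changed.

A further bookkeeping caveat is inherited from the source model: the
`eht` equation uses the unscaled binding terms `k5 eht (B_tot - B) - k6 B`
while the `B_ht` equation is scaled by `beta3`.  When `beta3 != 1` the
serotonin bound to receptors is not exactly conserved between the two
equations.  We implement the equations as printed; the imbalance is tiny
(the binding pool is ~1 receptor unit) and affects no reported quantity.

## Steady state: the anchoring problem

The multipliers reference the equilibrium they help define, so "the
steady state" needs care.  `compute_equilibrium()` has two modes.

**Self-anchored (default).**  Pass 1 freezes the multipliers at their
anchored values (1.89, 1, 1) and solves the metabolic system; pass 2 sets
the anchors from the solved receptor state and verifies that the full
right-hand side vanishes under the live inhibition functions (it does, by
construction, because the multipliers equal their anchored values at the
anchor).  This is the mode for "what is this parameter set's resting
state", and is used to pre-equilibrate stimulation experiments.

**Reference-anchored.**  Given anchors from a *reference* model, the
equilibrium is solved with the feedback live: an individual whose `G*_ht`
rests above the reference anchor has its release and synthesis tonically
inhibited, and vice versa.  This is the mode for virtual populations,
parameter sweeps, and meal forcing, and it is what gives the
autoreceptors their population-level role: they defend the reference
operating point, buffering inter-individual variation and dietary
fluctuation.  With both slopes zero the two modes coincide.

Numerically, the receptor cascade is eliminated analytically: for fixed
ligand, `B_eq` is closed-form and `G*_eq` solves a scalar equation whose
left side decreases and right side increases in `G*`, so a bracketed root
on `[0, G_tot]` is unique (`receptor_equilibrium()`, tolerance 1e-13).
The remaining metabolic unknowns reduce to five (`bh2`, `trp`, `cht`,
`vht`, `eht`) after eliminating `htp`, `pool`, `ght`, and `hiaa`, and are
solved by a damped Newton iteration with finite-difference Jacobian,
seeded from the normal resting state.  If Newton fails (it can, far from
the seed), the stiff integrator runs 200 h from the seed and Newton
restarts from the endpoint; if root and integration limit disagree the
solver reports both and aborts rather than guessing.  The pterin total
`bh2 + bh4` is conserved by the dynamics, so it is a datum (1 uM by
default), not an unknown.

The solved equilibrium residual is required to be below 1e-6 uM/h; in
practice it lands near 1e-12.

## Integration

The receptor binding constants (`k5`, `k6` of order 1e4/h) make the
system stiff.  `sero_simulate()` uses `deSolve::ode` (lsoda) with
`rtol = 1e-8`, `atol = 1e-10` uM.  Discontinuous forcings (meal steps)
advertise their breakpoints, and the integration is chained segment by
segment so no step straddles a jump.

## Stimulation

Vesicles carry a serotonin binding protein (SBP) that releases serotonin
by first-order dissociation (rate `b`, /s).  A stimulation of `duration`
seconds dumps complex at a constant rate, so free serotonin appears at

```
R(t) = 1 - exp(-b t)                          t <= duration
R(t) = exp(-b (t - duration)) - exp(-b t)     t >  duration
```

with `fire(t) = f_basal + r R(t - onset)`.  `R` is continuous, peaks at
`t = duration`, and integrates to `duration` exactly — the kernel
reshapes release in time but conserves the stimulated mass, which is why
the total extra release is exactly linear in `r`.  The dissociation rate
is uncertain within roughly 0.5-2 /s; `b = 1` is the baseline.

Response curves are recorded on a 0-30 s grid with onset at 5 s,
reported as `delta eht` (nM) relative to the preset's own pre-stimulus
baseline.  Presets (`male`, `female` for hippocampus CA2; `fast`,
`hybrid`, `slow` for the SNr) live as JSON under `inst/extdata/presets/`
and mirror the published fitted values cell-for-cell.  Two notes on the
preset tables: the fast preset's synthesis-inhibition slope is kept as
printed (`(.2)(12.5) = 2.5`) even though it plausibly intends
`(.2)(2.5)`; and the run-together strength row is read column-wise as
`r = 10.3, 22, 4.5` — with `r = 4.5` the slow preset peaks just below its
Uptake 2 gate ceiling, which is the published behaviour of that response.
Both cells are plain JSON and trivially editable.

For the SNr presets the true extracellular histamine transient is not
available (it lives in unpublished prior measurements), so `eha` defaults
to its constant baseline and `eha_pulse()` provides a parameterized
stand-in (step + exponential decay, or a tabulated curve).  SNr
assertions in the test suite are therefore qualitative (peak position
relative to the gate), never trace-matching.

## The meal forcing

Blood tryptophan is doubled (2 x 96 uM) for 2 h after breakfast and
lunch and 3 h after dinner (07:00, 12:00, 18:00 by default), and sits at
the between-meal level `960/17 ~ 56.5 uM` chosen so the 24 h mean is
exactly 96 uM.  We also simulated the alternative reading in which the
elevated level is twice the *between-meal* level (74.3/148.6 uM); the
published daily minima discriminate clearly between the two (the
alternative leaves the no-autoreceptor minimum ~5 nM too high), so the
first reading is used.  Meal experiments run 48 h and report day 2: the
vesicular pool drains on a ~10 h timescale, so day 1 is initial-condition
burn-in and the daily minimum is genuinely dynamics-limited, not a
quasi-equilibrium.

## Virtual populations

Enzyme and transporter expression varies by ~25% or more between
individuals, so a single parameterization is an "average animal", not
the model.  `build_population()` draws each individual by multiplying
the parameters listed in a `variation_spec()` by independent
`Uniform(lower, upper)` factors:

* `fig2` (steady-state design): Vmax of TRPin, TPH, AADC, MAT, MAO,
  Uptake 2 and SERT, the basal firing strength, and the
  release-inhibition slope, each 75-125%;
* `fig6ab` (response design): six Vmax values, both autoreceptor slopes,
  `eha`, and the joint receptor speed `beta`, each 60-140%; stimulation
  strength 75-125%; SBP rate (which sets the release-kernel peak time)
  80-120%;
* `ssri_mao` and `aadc_b6`: two-factor designs at 25-175%.

Each individual's steady state is solved in reference-anchored mode
(anchors from the unvaried base model), and failures are excluded —
never resampled, which would bias the distribution — with a logged
count; more than 1% failures aborts the run.  Reproducibility is exact:
a master seed spawns one child seed per individual, so databases are
bit-identical for a given `(seed, spec, n)` and independent of
evaluation order, and a shorter run is a prefix of a longer one.

Response populations equilibrate each individual self-anchored (its own
resting state is the baseline its receptors defend during the transient)
and stimulate with its own scaled protocol.  `attribute_variation()`
regresses a response summary on the standardized multipliers;
`two_factor_scan()` extracts the records of the two-factor designs.  The
operationalization of "uncorrelated with AADC activity" is
`|cor| < 0.1`, a repository choice.

Problem sizes: population statistics in the test suite and acceptance
script use n = 1000 for the steady-state designs (solver cost ~25 ms per
individual) and smaller n for response populations, whose per-individual
cost is dominated by the 30 s stiff transient.

## What the generator does and does not emulate

The synthetic populations emulate *expression-level* variation only:
independent uniform multipliers on maximal rates, slopes and forcings.
Real populations have correlated expression, varying Michaelis
constants, region-dependent geometry, and measurement noise; response
data additionally carry electrode calibration and placement effects.
Passing population tests therefore demonstrates that the model's
feedback buffers parameter variation as described, not that the sampled
distributions match any particular animal cohort.

## Known limitations and open points

* The printed 5HIAA catabolism constant (1.82/h) is inconsistent with
  the reported resting 5HIAA concentration given the reported catabolic
  flux; the constant is used as printed, and the model's resting `hiaa`
  (~0.87 uM) accordingly differs from the reported table value.  No
  downstream quantity depends on `hiaa`.
* With the SERT capacity raised to 433 uM/h the solved equilibrium
  `eht` is 40.6 nM against a published 39.8 nM (2%); the balance at that
  operating point is steep (~4 uM/h per nM), so a sub-2% difference in
  any large flux reproduces the gap, and no printed parameter reading
  closes it exactly.
* The no-autoreceptor population dispersion computed from the printed
  rate laws is smaller than the published one (single-factor
  sensitivities, which sum in quadrature to the computed SD, confirm the
  implementation); the discrepancy is documented in the acceptance suite
  rather than absorbed into the generator.
* Whether the synthesis multiplier keeps its zero clamp under extreme
  stimulation is unstated in the source; the clamp is applied uniformly.
* No spatial structure, vesicle-pool discreteness, autoreceptor
  modulation of reuptake, or electrochemical signal model.
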