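---
title: "Modelling TRAIL-LY303511 apoptosis synergy and ROS-driven cFLIP dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TRAIL-LY303511 apoptosis synergy and ROS-driven cFLIP dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apopsynergy)
```

## The scientific problem

TRAIL (TNF-related apoptosis-inducing ligand) kills cancer cells through the
extrinsic apoptosis pathway, but many lines -- including HeLa -- are largely
resistant at clinically tolerable doses. The kinase-inactive LY294002
analogue LY303511 ("LY30") sensitises several cancer lines to TRAIL: low
doses of either agent alone kill few cells, while the combination kills far
more than the sum of the single treatments. `apopsynergy` implements the
computational side of that story: mass-action ODE models of the TRAIL
pathway and of the LY30 mechanism, Monte Carlo simulation of heterogeneous
cell populations, quantification of combination synergy, and a second,
deliberately small ODE model in which two reactive-oxygen species (ROS)
with opposite effects explain a non-monotonic excursion of the caspase-8
inhibitor cFLIP.

## The mass-action engine

Every biological event is an elementary reaction with mass-action kinetics:
the flux of a reaction is its rate constant times the product of the
amounts of its reactants and catalytic modifiers. Modifiers (e.g. an active
protease catalysing the activation of a zymogen) appear in the flux but
have zero net stoichiometry, which keeps the network compact without
tracking every enzyme-substrate complex. Protein synthesis is zeroth-order
and degradation first-order. Amounts are copy numbers per cell and time is
in hours.

Two numerical choices matter:

* **Tolerances.** `deSolve::lsoda` with relative tolerance `1e-6` and
  absolute tolerance `1e-8` copies. Copy numbers span six orders of
  magnitude (tens of DISC complexes against a million PARP copies), and the
  integrator's undershoot below zero scales with the absolute tolerance; an
  undershoot below `-1e-6` copies is treated as an integration failure,
  so the absolute tolerance must sit well below that threshold. Segments
  that still undershoot are automatically retried at 1000-fold tighter
  tolerance before failing.
* **Events.** Treatments are step changes at known times (LY30 at 0 h,
  TRAIL at 1 h), so integration simply stops and restarts at each event
  time; no root-finding is needed, and all non-event species are continuous
  across events.

On linear networks the integrator reproduces matrix-exponential closed
forms to better than `1e-6` relative error (at tightened tolerances), which
is the package's basic numerical oracle.

## The TRAIL network

`build_trail_network()` returns a condensed HeLa extrinsic-apoptosis
network in the tradition of the well-known snap-action/variable-delay
receptor-to-PARP models: ligand and receptor form the death-inducing
signalling complex (DISC); the DISC activates caspase-8, which cleaves Bid
and activates caspase-3; truncated Bid activates Bax, which dimerises twice
into a mitochondrial pore; the pore releases cytochrome c (activating the
apoptosome and caspase-9) and Smac (neutralising XIAP); free caspase-3
cleaves PARP. Cell death is declared when at least half the PARP pool is
cleaved.

Four structural choices depart from the classic cycloheximide-era model:

1. active caspase-3 feeds back onto caspase-9 activation;
2. caspase-3 feeds back directly onto caspase-8, and caspase-6 is absent
   from the network entirely;
3. cFLIP starts 10-fold higher (1000 copies): the low published value
   reflected blocked protein synthesis, which does not apply here;
4. ARC, not BAR, is the stoichiometric caspase-8 inhibitor.

Because synthesis is not blocked, caspases (and only caspases) carry
turnover: first-order degradation plus zeroth-order synthesis balanced so
that the unstimulated network rests exactly at its initial state
(`set_turnover()`). This is what makes death threshold-like: a slow
pro-apoptotic trickle is degraded away instead of accumulating until every
cell eventually dies. The untreated model drifts less than 1% over 48 h.

### Rate constants are calibration defaults

The supplementary rate tables of the original study are not redistributed
here; rate constants are therefore the package's own calibration defaults.
They keep the published initial amounts and reproduce the study-level
behaviour at the study doses (20 ng/ml TRAIL, 25 uM LY30): each single
agent kills only a modest fraction of a 40%-CV population at 24 h, the
combination kills synergistically (well over the 30% excess actually
observed), and the combination's simulated caspase-8 signal peaks before
5 h. Every constant is exposed and can be overridden or re-fit.

Dose conversions are configurable model constants: 60 ligand copies per
ng/ml TRAIL (so 20 ng/ml is 1200 copies/cell) and LY30 carried on its
micromolar input scale.

## The LY30 extension

`build_ly30_extension()` adds three mechanisms, matching what is known
about LY30 in this system:

* **Receptor priming** -- LY30 catalyses conversion of the TRAIL receptor
  into a "primed" (clustered) form whose DISC-formation rate constant is
  `prime_factor` (default 150) times larger. A single knob multiplying the
  binding step keeps the mechanism identifiable.
* **cFLIP degradation** -- an LY30-catalysed first-order decay of cFLIP, a
  lumped representation of transcriptional repression, ubiquitylation and
  similar routes.
* **ROS** -- LY30 drives production of a generic ROS species that (i)
  catalyses Bax activation, i.e. some mitochondrial permeabilisation in
  every cell, and (ii) in a small flagged subpopulation (default 12% of
  cells) opens a direct, mitochondria-independent route to PARP cleavage.
  The study only states that such a subpopulation exists; a per-cell
  binary flag with configurable probability is the simplest faithful
  encoding.

LY30 itself is non-depleting by default (no clearance is known);
first-order decay is available as a configuration parameter.

## Monte Carlo populations

Apoptosis is all-or-nothing per cell, with cell-to-cell variability in the
delay. Population-level assays (immunoblots, enzyme activities) therefore
look nothing like single-cell trajectories: individual cells switch
sharply, the population average rises smoothly. `run_population()` samples
each cell's nonzero initial protein amounts independently from normal
distributions with mean equal to the network value and standard deviation
0.4 times the mean, resampling negative draws. The study phrase "variance
equal to 40% of the mean" is read as a coefficient of variation of 0.4:
the literal reading (variance = 0.4 x mean) is dimensionally inconsistent
across species that span four orders of magnitude, and CV is the standard
convention in this literature. Both the varied-species set and the CV are
configurable.

The study population is 10 000 cells; package checks run 1000 (population
death fractions have Monte Carlo standard errors below 1.6 percentage
points at that size, well inside every margin asserted) and unit tests use
a dozen. Averaged trajectories include all cells, dying and surviving,
like a lysate. The death time of a cell is the first time cleaved PARP
reaches 50% of the total pool, linearly interpolated between grid points.

Measured caspase activity is not isoform-specific, so simulated activities
are converted to "measured-style" fold-changes: a weighted sum of active
caspases (default caspase-8-like weights: C8 with 0.2 cross-talk from C3)
plus a small positive background, normalised to its untreated baseline.

## Synergy

With per-arm 24 h death fractions in hand, the additive expectation is the
capped sum of the single-agent fractions, and the synergy excess is the
percentage by which combination killing exceeds it. At the death levels
reached here the cap never binds, so the ambiguity between capped and
uncapped addition is inert; Bliss independence is available as an
alternative null. Classification uses a 5-percentage-point dead band,
the scale of replicate noise in viability assays.

## The ROS-cFLIP model

The constant-decay picture of LY30's effect on cFLIP fails at early times:
cFLIP first *rises* (around 30 min) before falling well below baseline
(by 6 h). `build_ros_cflip_network()` implements the two-ROS explanation:

* LY30 drives superoxide production from a finite generating capacity
  (`SoxCap`, 100 units); superoxide dismutates into hydrogen peroxide,
  which is cleared by antioxidant systems.
* Superoxide acts fast and pro-cFLIP: it inhibits cFLIP degradation.
* H2O2 acts slowly and anti-cFLIP: it inhibits cFLIP production at the
  transcript level (cFLIP has an explicit mRNA pool, and degraded protein
  goes to an explicit `cFLIP_Deg` pool so fluxes are accountable).

The two inhibitions are saturating multipliers `1/(1 + [ROS]/K)` on the
affected rates -- the only non-elementary laws in the package, flagged as
such; a strictly elementary encoding would need explicit sequestration
species and would add nothing at this level of abstraction.

The finite superoxide-generating capacity deserves a note. With a
non-depleting LY30 input and unlimited capacity, superoxide would settle
at a constant elevated level, cFLIP degradation would stay inhibited
forever, and neither the catalase prediction (cFLIP back to baseline at
6 h when H2O2 is scavenged) nor the coupling into the apoptosis model
could work. A transient superoxide burst is also what redox biology
expects. Timescale defaults (dismutation 4/h, H2O2 clearance 0.5/h, cFLIP
turnover 1.5/h) put the superoxide peak near 30 min and the H2O2-dominated
trough hours later, reproducing the 30 min rise / 6 h fall phenomenology.
Dismutation is encoded 1:1; the physiological 2:1 stoichiometry would only
rescale the H2O2 axis and its inhibition constant.

Scavengers are first-order removal reactions targeting exactly one ROS
species: Tiron removes superoxide (pre-incubated from -1 h; the simulation
grid extends backwards automatically), catalase removes H2O2 (active from
the start). Large removal rates abolish the 30 min elevation (Tiron) and
restore the 6 h level to baseline (catalase); both effects are monotone in
the removal rate until they saturate at a sub-percent structural residue.

`couple_to_apoptosis()` swaps the constant-rate LY30-driven cFLIP decay of
the combination model for this dynamic submodel, merging `LY30` and
`cFLIP`/`flip` by name. The early cFLIP rise then delays caspase-8
activation relative to the constant-decay model -- the qualitative
behaviour that motivated the refined model. The coupled model is not
expected to capture late (~10 h) caspase-8 behaviour, and no claim is made
there.

## Calibration

`fit_calibration()` is multi-start bounded local optimisation in log
parameter space: a maximin Latin-hypercube sample of the log bounding box
(plus the box centre) refined by Nelder-Mead (Brent in one dimension) --
derivative-free on purpose, because timed-event discontinuities degrade
finite-difference gradients. Fitting happens on the fold-change scale,
matching the relative readouts and removing unidentifiable scale factors.
Residuals are weighted by replicate standard errors. Parameters ending
within 0.1% of a bound are flagged. `profile_loss()` re-optimises the
remaining parameters along a grid in one parameter; a flat profile flags
non-identifiability.

On zero-noise synthetic densitometry the generating cFLIP-turnover and
H2O2-clearance rates are recovered within 20%, and with 10% replicate
noise within a factor of two in at least 80% of 20 seeded runs -- the
package's round-trip guarantee.

## Synthetic data

The generators produce observation tables with the statistical structure
of the real assays, from known ground truth (embedded as metadata):

* caspase activity time courses (default sampling grid 0-240 min) with
  mean-1 lognormal replicate noise -- multiplicative noise matches
  positive-support assay behaviour;
* cFLIP densitometry observed through two noisy band intensities sharing a
  per-lane scale factor that the loading-control division cancels exactly;
* 24 h viability fractions with additive Gaussian noise truncated to
  [0, 1], normalised to the untreated replicate mean.

Default noise (10% CV, three replicates) is a stated assumption -- the
study does not print assay noise magnitudes. What passing recovery tests
show is that the pipeline is consistent and the targeted parameters are
identifiable under the assumed noise; they cannot certify performance on
real blots, whose error structure (saturation, background subtraction,
batch effects) is not modelled.

## Problem sizes used by the checks

Deterministic checks (steady state, ROS-cFLIP, scavengers, coupling
delay) run in seconds. Population-level checks use 1000 cells at CV 0.4 on
a 0.1 h grid; parameter-recovery checks use 20 seeded fits of the
deterministic ROS model. The end-to-end driver `reproduce_all()` accepts
any population size; its default remains the study's 10 000.

## Known limitations

* Rate constants are calibrated, not transcribed from the original
  supplementary tables; quantitative trajectories are therefore
  illustrative, while the study-level claims (synergy magnitude, peak
  timing, cFLIP excursion, scavenger responses) are the calibrated
  targets.
* Initial amounts vary independently across proteins; correlated
  expression and extrinsic noise in rate constants are not modelled.
* The mitochondria-independent death channel is a phenomenological flag,
  not a mechanism.
* Stochastic (SSA) simulation, spatial effects, NF-kB/Akt survival
  signalling and other cell types' phenomena are out of scope.
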