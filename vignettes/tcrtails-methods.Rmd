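---
title: "Entropic control of multisite receptor modification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic control of multisite receptor modification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

The T cell receptor transmits its activation signal through six intrinsically
disordered cytoplasmic tails (two copies each of the zeta and epsilon chains,
one delta, one gamma) that carry 20 tyrosines organised in 10 ITAMs. The
kinase LCK phosphorylates these tyrosines, the phosphatase CD45 removes the
phosphates, and the tandem-SH2 reader ZAP70 binds phosphorylated ITAMs.
`tcrtails` models the physics of this system at residue scale and asks how
purely entropic effects — local stiffening upon phosphorylation, membrane
association, and crowding by already-bound ligands — reshape modification
kinetics into nonlinear, switch-like behaviour.

## The chain model

Each tail is a freely jointed chain in a theta solvent: one bead per residue,
fixed segment (Kuhn) length $\delta = 0.3$ nm, free joint angles, no
excluded volume between beads. The bead counts are those of the human
subunits: 113 (zeta), 55 (epsilon), 47 (delta), 45 (gamma). Bead 0 is the
membrane anchor, fixed on the plane $z = 0$; residues are numbered from the
anchor (the tails' N-terminal, juxtamembrane end). Ligands — LCK kinase
domain (radius 2.1 nm), ZAP70 tandem SH2 (2.7 nm), CD45 phosphatase domains
(3.4 nm) — are hard spheres with radii derived from their molecular mass at
a protein density of 1.41 g/cm³ (`radius_from_mass()`).

The zeta tyrosine positions follow the printed landmarks of the source
model: the membrane-proximal tyrosine 21 residues from the anchor, the
membrane-distal one 12 residues from the C-terminus, the second-to-last at
residue 83, with the remaining positions completing ITAM-like pairs. These
differ slightly from positions derived from the canonical human sequence;
the fixture file documents the choice. Basic-residue (Lys/Arg) positions are
an approximate reconstruction from the canonical sequences; the epsilon tail
carries 14, concentrated in the juxtamembrane basic-rich stretch. The counts
drive the analytic repulsion bound, so they are part of the fixture
definition rather than hidden constants.

## Sampling the canonical ensemble

`run_sampler()` draws chain configurations by Metropolis–Hastings Monte
Carlo. The move set is a single-joint pivot: a uniformly chosen joint
rotates its downstream sub-chain (and any ligands tethered to it) by a
random axis-angle rotation. Pivots preserve bond lengths exactly and rotate
rigid (stiffened) segments as units. Tethered ligand spheres additionally
reorient about their tether site. Hard constraints — chains may not cross
the membrane when it is a hard wall, beads may not enter ligand spheres,
spheres may not overlap each other or the membrane — are enforced by
rejection; soft potentials enter through the usual acceptance probability
$\min(1, e^{-\Delta E})$.

The perturbation size is adaptive: every 100 burn-in proposals the step is
multiplied or divided by 1.05 until the acceptance rate reaches 0.44, and it
is frozen before measurement so detailed balance holds exactly in the
recorded phase. A single pivot saturates at a half-turn, which for weakly
constrained systems leaves the acceptance rate above target; the sampler
therefore spends any surplus step size on composing several pivots per
proposal, which keeps acceptance controllable down to 0.44 for every
constrained system. For a completely unconstrained chain nothing can reject
a move and the acceptance rate stays at 1; the ideal-chain oracle tests
cover that regime directly.

Stationarity is declared by the quarter criterion: the recorded site-height
series is split in quarters and the third and fourth must agree by a
two-sample Kolmogorov–Smirnov test at $\alpha = 0.05$. Because MCMC series
are autocorrelated, each quarter is subsampled to at most 400 evenly spaced
points before the test; a failed check doubles the recording budget (twice
at most) before the run is flagged non-converged. Occlusion and calibration
routines refuse non-converged ensembles unless forced.

Default budgets: 20,000 recorded samples per chain state, recorded every
$M/2$ proposals for $M$ beads, after a burn-in of $\max(20{,}000, 50M)$
proposals. These sizes keep a full 64-state zeta table under three minutes
on one core while placing the binomial error of a per-site occlusion
estimate near $7\times10^{-4}$.

## Occlusion and binding rates

The entropic change in the dissociation constant between two chain states
reduces to the ratio of the probabilities that the ligand's required region
of space is free, so the relative association rate in a state is
$k_{on} = (1 - P_{occ})\,k_{on0}$, with $k_{on0}$ the free-space rate; all
rates are reported in units of $k_{on0}$. (The source text also prints the
rate as proportional to $P_{occ}$ itself; that form contradicts the
derivation it follows — a fully occluded site must have zero rate — so the
$1 - P_{occ}$ form is used throughout.)

$P_{occ}$ is measured by probe insertion: at each recorded sample a sphere
of the ligand's radius is placed with its surface touching the site bead,
its centre in a uniformly random direction redrawn each sample, and the
sample counts as occluded if the probe overlaps the membrane half-space,
any chain bead, or any bound ligand sphere. Two alternatives are exposed as
configuration (`probe_placement`): a fixed-normal placement directly above
the site, and a site-centred region (which requires excluding the contour
the ligand engulfs, `probe_exclude`, to avoid degeneracy). The default
excludes only the site bead itself. These choices shift absolute rates by
tens of percent but move relative, state-to-state comparisons far less.

`build_rate_table()` runs one converged sampler per phosphostate (a
$2^{n}$-state bitmask space; 64 states for zeta) and records $P_{occ}$,
its standard error and the relative rate for every site in every state.
Phosphorylation may rigidify a window of $2w+1$ residues around its site
(default experiments use $w = 5$, 11 residues, about one-twelfth of zeta);
overlapping windows merge into one straight rod. Rates toward
already-modified sites are masked per direction when the table is used for
kinetics.

## Kinetics on rate tables

`simulate_sequences()` runs the Gillespie algorithm on a table: from the
all-unmodified (or all-modified) state, each event picks a site with
probability proportional to its state-dependent rate and draws an
exponential waiting time with the total applicable rate. Sequence
probabilities come from counting completed orders. The path-weighted rate
of the $k$-th event is the reciprocal of the mean waiting time between
events $k-1$ and $k$ pooled over runs, so likelier paths weigh more; the
per-site variant (`per_site = TRUE`) averages the rate of the transition
actually taken, which removes the trivial decline caused by having fewer
available sites and corresponds to the "accessibility of a remaining site"
reading used for the membrane-affinity scenario. The unweighted variant
averages total applicable rates over the distinct states realised at a
step, weighting every realised state equally.

`reversible_steady_state()` simulates the kinase/phosphatase cycle over a
log-spaced grid of free-space activity ratios, with the phosphatase either
constant per site (enzymatic domain too small for steric effects) or driven
by its own occlusion table (both enzymes share the 2.1 nm radius in the
stiffening experiments, so one table serves both directions). Runs default
to $10^6$ events with the first half discarded as transient; the packaged
experiments and acceptance checks use $2\times10^5$ events, where the
response standard error is already below 0.005.

Steepness is quantified two ways (`hill_coefficient()`): the maximal
logarithmic slope of the response odds versus the ratio, smoothed by a
cubic polynomial fitted to finite-difference slopes (its RMS error is the
reported uncertainty), and the log-effective-concentration convention
$\log 81 / \log(EC_{90}/EC_{10})$ computed on the curve's own range, which
is signed (decreasing responses give negative values) and falls below 1
for shallow curves. The exact supplementary definition behind the source's
negative Hill values is not in its main text; this convention reproduces
the qualitative behaviour (shallow < 1 < ultrasensitive) and is exposed as
a method argument rather than hard-wired.

## Membrane interactions

Three per-residue potentials act when a membrane is present: basic residues
feel a piecewise parabolic well of depth $E_{B0}$ that vanishes above the
crossover height $\sqrt{E_{B0}/k_{PC}}$; phosphotyrosines feel a screened
repulsion $E_{P0}\,e^{-z/z_{Debye}}$ with $z_{Debye} = 1$ nm; all other
residues feel a soft wall $k_S z^2$ ($k_S = 0.05\,k_BT/\mathrm{nm}^2$)
below the membrane plane. The stated relation between $E_{B0}$ and $k_{PC}$
is dimensionally a length only as $\sqrt{E_{B0}/k_{PC}}$, so the package
pins the crossover height to 1 nm by default ($k_{PC} = E_{B0}$ per nm²),
making the well vanish one Debye length above the membrane; `k_PC` remains
a free parameter.

`calibrate_EB0()` sweeps the well depth (default grid 0–1 $k_BT$ in 0.1
steps) and reports the smallest value whose first-tyrosine height variance
falls below half the free-chain value — the confinement criterion, with the
50% threshold configurable since the source defines confinement only
through a figure. `calibrate_EP0()` then fixes $E_{B0}$, phosphorylates the
chain fully, and finds the smallest repulsion whose first-tyrosine height
distribution is statistically indistinguishable (KS test) from the free
reference. The analytic energy-balance bound
`phospho_repulsion_bound()` — $E_{P0} \ge (n_B/n_Y) E_{B0}$ — uses the
fixture's basic and tyrosine counts; epsilon's clumped distal tyrosines let
simulation undercut this bound, which is the scenario's headline contrast.

## Multi-ligand binding and packing

For the six-chain receptor, reader binding is modelled at one site per
ITAM (the midpoint of its tyrosine pair), ten sites in all. A bound ligand
is a hard sphere whose surface stays tethered to its site bead and which
reorients freely during sampling. `multi_ligand_rate_curve()` grows
Gillespie paths over bound-site subsets, computing each visited state's
per-site rates from a converged sampler run with the bound spheres present
as obstacles; the $k$-th event's rate is the reciprocal mean waiting time
across paths, so predecessor states are sampled by their path
probabilities. Crowded states leave very few occlusion-free samples, so a
state's recording budget doubles (pooling runs) until at least 30 free
samples are seen or a cap is reached — without this the late-event rates
are dominated by estimator noise and the first:seventh ratio is biased
upward.

`feasible_packing()` asks the complementary volume question: can all ten
spheres be bound at once? Simulated annealing over chain conformations and
ligand orientations minimises a squared-overlap penalty from a tilted
straight-chain start (spheres alternating sides along multi-site chains);
a zero-penalty configuration is re-validated by an independent plain-R
constraint checker before being reported. Feasibility is one-sided: a
witness proves packability, while exhausting the budget only reports "not
found".

## The integrative model

The continuous-state model collapses site identity: of $N = 10$ sites,
$n_P$ are phosphorylated and $n_Z$ ZAP70-bound, ZAP70-bound sites are
protected from dephosphorylation, and every enzymatic rate carries the
factor $\lambda_K^{n_P} \lambda_Z^{n_Z}$ ($\lambda_K = 1.2$ enhancement
per phosphorylation, $\lambda_Z = 0.6$ reduction per bound ZAP70, defaults
from the rate-table scenarios). With $k_{off} = 0.2\,s^{-1}$, the package
defaults $k_{on0}$ to $k_{off}/0.6^{6} \approx 4.29\,s^{-1}$: the source
gives no free-space binding rate but states that ZAP70 loading saturates
where $k_{on0}\lambda_Z^{n} = k_{off}$ at $n \approx 6$, which fixes the
scale. Steady states come from a stiff integrator (`deSolve::lsoda`,
relative tolerance $10^{-10}$) polished by damped Newton iteration to a
relative residual of $10^{-8}$; dose-response sweeps hold $k_{F0}$ fixed
and vary $k_{K0}$ over $10^{-3}$–$10^{3}$ (41 points). "Counteracting" a
reduction $\lambda_Z < 1$ is operationalised as returning the ZAP70
dose-response's log-effective-concentration Hill coefficient to its neutral
($\lambda_K = \lambda_Z = 1$) value, solved by bisection in $\lambda_K$
(`neutralizing_lambda_K()`).

## What the synthetic generators do and do not emulate

The toy fixtures (`generate_fixture()`) — short chains with evenly spaced
sites, state-independent rate tables — exist so kinetics and sampling can
be checked against closed forms (uniform sequence probabilities, competing
exponentials, birth-death stationary distributions, brute-force rejection
sampling). They share the real system's structure but none of its
heterogeneity: passing those tests validates the machinery, not the
biology. Conversely the packaged TCR fixtures carry the real chain lengths
and landmark site positions but approximate the unpublished details
(middle tyrosine positions, basic-residue placement), so quantities that
depend on those details — sequence-preference magnitudes, membrane-release
percentages — carry systematic uncertainty beyond their Monte Carlo error.
The freely jointed chain itself omits sequence-dependent persistence,
excluded volume between residues, and any lipid-composition physics.

## Numerical choices and limitations

Geometric tolerances are $10^{-9}$ nm on hard constraints; packing
witnesses are validated at $10^{-6}$ nm. Seeded runs are bit-reproducible
across platforms (the compiled core uses its own xoshiro256++ generator
with Box–Muller normals). Where a quantity is a ratio of small occlusion
probabilities, budgets are chosen so the binomial errors stay a small
fraction of the contrasts being measured; the per-state budgets used by
each packaged experiment are printed in its metadata.

Two limitations are worth stating plainly. First, with 11-residue
stiffening the measured per-site rate enhancement across the
phosphorylation course is 2–3-fold (a per-event factor near 1.2, matching
the integrative model's default $\lambda_K$), and reversible cycles built
on such tables reach Hill coefficients near 1.1–1.2 (constant
dephosphorylation) and just above 1 (steric); stronger published steepness
values would require per-event enhancements near 1.8 that these ensembles
do not produce under any probe-placement variant. Second, for the epsilon
membrane scenario the direction of the dephosphorylation trend depends on
the balance between membrane re-association (which lowers the remaining
phosphotyrosine) and chain flattening (which clears its surroundings);
with the packaged basic-residue layout the first effect dominates slightly,
so the phosphatase's per-site rate declines mildly across events rather
than rising. Both behaviours are reported as computed.
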