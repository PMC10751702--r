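---
title: "Track-structure simulation of low-energy electron damage to atomistic DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-structure simulation of low-energy electron damage to atomistic DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most of the biological damage done by therapeutic radiation is inflicted not
by the primary beam but by the shower of secondary electrons it liberates,
the majority of which carry between a few eV and a few hundred eV.  At those
energies electrons no longer simply ionize: they attach resonantly to
molecular sites (dissociative electron attachment, DEA), excite vibrational
and electronic levels, and -- above roughly 10 eV -- ionize.  Which of these
channels actually ruptures a DNA backbone, and at which energies, cannot be
separated experimentally: a measured strand-break yield integrates over all
channels and all electron generations.  An event-by-event (track-structure)
Monte Carlo simulation can do the separation, because every single physical
interaction is sampled, scored with its position, channel and energy
deposit, and then mapped onto the DNA molecule that was hit.

`dnatrackmc` implements such a simulator for an atomistic B-DNA target in
vacuum, together with the damage bookkeeping that converts interaction
events into single- and double-strand breaks (SSB/DSB) and into the
standard summary statistics of the field: absorbed dose in Gy, breaks per
incident electron, and break yields per Gray per Dalton.

## Geometry

The target is a B-DNA double helix built atom by atom.  Every heavy atom is
a sphere with its element's van der Waals radius (H 0.120, C 0.170,
N 0.155, O 0.152, P 0.180 nm -- a single editable constant set), and every
sphere belongs to exactly one molecule record: a phosphate group (1 P + 4 O
spheres), a deoxyribose (6 heavy-atom spheres) or one of the four bases.
Each of the `2 * n_bp` nucleotides contributes one molecule of each group,
so strand and base-pair index are known for every sphere.  The builder uses
the canonical B-form parameters, 0.34 nm rise and 36 degrees twist per base
pair.

Two axis modes are provided.  `straight` runs the helix along a line; a
1122-bp molecule would then be about 381 nm long.  `condensed` winds the
helix axis itself along a solenoid (radius 12 nm, pitch 5.6 nm per turn) so
that 1122 bp fold into an overall extent of about 30 nm, emulating a
partially condensed in-vivo-like target.  The exact fold of such targets is
not standardized; the solenoid is this package's documented convention, and
its two parameters are constants in the geometry module.  Per-nucleotide
atom templates carry correct heavy-atom counts and approximate internal
geometry -- for sphere-based transport only sphere positions, radii and
molecule labels matter, not crystallographic detail.  Real structures can
be used instead via `load_pdb()`, which classifies atoms into
phosphate/sugar/base from standard nucleotide atom naming.

Ray-sphere tracing is accelerated by a uniform grid written in C++; a
pure-R brute-force tracer with identical boundary conventions is kept as
the test oracle, and the two are asserted equal on randomized scenes.  A
ray that merely grazes a sphere (zero chord) counts as a miss, so no
zero-length chords reach the transport.

## Cross-sections

Per molecule kind (four bases, deoxyribose, phosphate) the library carries
four competing channels: elastic scattering, excitation (one shared table
for vibrational and electronic excitation), ionization and DEA.  Published
work in this area shows the underlying cross-sections only as figure
curves, so the package ships a *parameterized fixture library* whose
defaults encode the qualitative structure those curves agree on:

* DEA is resonant.  Each DEA table is a sum of Gaussian resonances
  restricted to a hard energy window: the bases attach below 4 eV, the
  deoxyribose between 0 and 3 eV, and the phosphate group has its dominant
  peak between 4 and 10 eV (default centre 8.5 eV, width 1.5 eV) plus a
  small low-energy shoulder.
* Ionization rises slowly from a binding-energy threshold pinned strictly
  above 10 eV for every kind (10.8-11.5 eV), with the documented shape
  `A (1 - B/E) ln(E/B) / sqrt(E/B)` that peaks broadly near 100-200 eV.
  Pinning every threshold above 10 eV makes "zero ionization at 4, 6 and
  10 eV" a structural property of the library, not a statistical outcome.
* Excitation uses one sampling table; when an excitation interaction
  occurs, one level not exceeding the electron energy is chosen uniformly
  among the permitted vibrational (0.1/0.2/0.4 eV) and electronic levels,
  and the event is recorded as vibrational or electronic excitation
  according to the realized level.  Every lowest electronic level sits
  above 4 eV, so a 4 eV beam can only scatter elastically, excite
  vibrations, or attach.
* Elastic scattering is a smooth decreasing shape with a
  screened-Rutherford angular model (screening parameter `eta = 5/E`,
  clipped); it moves electrons without depositing energy.

Absolute magnitudes are calibration constants of the library (order
10^-3 -- 10^-2 nm^2 at the resonances).  They were chosen once so that the
desk-scale study conditions below give resolvable break statistics while
honoring all the window and threshold constraints; every test that depends
on magnitudes is a property or ordering test, never an absolute-value test.
Interpolation is linear on a grid of about 300 points covering
0.1-500 eV (dense, 0.1 eV spacing, through the resonance region); at that
density the difference from log-log interpolation is negligible.  Tables
are exact on grid nodes and clamp to the last value above the grid.

Mean free paths follow `lambda = 1/(n sigma_total)` with the molecule
number density `n` implied by a pinned mass density of 1.35 g/cm^3 for all
six kinds (a standard DNA-class value) and the per-kind molecular masses of
the heavy-atom templates.

## Transport

Electrons are tracked one interaction at a time.  A free flight samples an
exponential optical depth `u ~ Exp(1)` and integrates `chord / lambda`
along the ray, sphere by sphere; vacuum contributes nothing.  If `u` is
exhausted inside a sphere the interaction happens there, with the channel
drawn proportionally to the per-channel cross-sections of that sphere's
molecule kind at the electron's energy; otherwise the electron leaves the
400 nm world box and escapes.  Overlapping spheres are each traversed with
their own chord, which double-counts material in overlap regions -- the
union-solid approximation is documented and shared by both tracers.

Interactions follow the per-channel rules: elastic events deposit nothing;
excitation deposits the realized level; ionization deposits the binding
energy, reduces the primary by `B + eps` and spawns a secondary with
`eps ~ Uniform(0, (E-B)/2]` (the spectrum is a documented, swappable
convention) plus Auger electrons by the simplified multiplicity rule --
ionization of a carbon or oxygen atom emits one Auger electron, of a
nitrogen atom two, at pinned element energies (C 11, O 13, N 9 eV), booked
as injected energy; DEA deposits the electron's entire remaining kinetic
energy at the site and terminates it (the termination is standard; keeping
the energy local is this package's convention so that the ledger closes).
Secondaries start isotropically from the interaction point.  Electrons
below the 1 eV tracking cutoff -- the region where no channel in the
library is meaningfully open -- are killed with a local deposit booked
separately.

Every history closes an energy ledger,
`E_initial + E_auger_injected = E_deposited + E_escaped + E_cutoff_killed`,
and the test suite asserts the balance to relative 1e-9 at all ten beam
energies.  Each history runs on its own RNG substream derived from the
master seed by a counter scheme, so runs are reproducible as a whole and
per history, and repeats are independent.

## Damage rules

* DEA on a backbone molecule (phosphate or deoxyribose): SSB,
  unconditionally.
* Ionization on a backbone molecule: SSB when the local deposit reaches
  the 10 eV ionization threshold (inclusive comparison; deposits equal to
  the threshold count).
* Electronic excitation on a backbone molecule: SSB when the deposit is
  strictly greater than the molecule's excitation threshold (default
  10 eV for every kind).
* Vibrational excitation and elastic scattering never break, though
  vibrational deposits do count toward dose.
* Qualifying hits on a base are recorded as base damage, not strand
  breaks: base-to-backbone charge transfer is deliberately out of scope.

Repeated qualifying hits on one nucleotide collapse to a single break (a
broken bond cannot re-break).  A DSB is two SSBs on opposite strands
strictly fewer than 10 base pairs apart, measured in base-pair index.
Clustering is greedy and deterministic: breaks are processed in ascending
base-pair order and paired with the nearest admissible unpaired partner,
ties toward the lower index.  An exhaustive maximum-matching oracle is kept
in the package, and a 500-case randomized test asserts the greedy count
equals the optimum on the tested distribution (processing in ascending
order makes the nearest available partner the smallest available one, the
classical optimal greedy for such proximity graphs).  Breaks from different
primary histories may pair; the fraction of such cross-history DSBs is
measured and reported rather than forbidden.  The reported SSB tally counts
every accepted break including DSB constituents (switchable via
`damage_rules()`).

## Scoring

Dose is `E_deposited` (interaction deposits plus cutoff kills, which occur
at interaction sites inside the DNA) converted with
1 eV = 1.602176634e-19 J and 1 Da = 1.66053907e-27 kg; both the run total
and the per-incident-electron dose are reported explicitly to avoid
normalization ambiguity.  Yields are `count / n_histories` and
`Y = count / (dose x mass)`.  The broken-nucleotide percentage divides
distinct broken positions by the strand count `2 x n_bp`.  Repeats use
derived seeds and report the sample mean and n-1 standard deviation; with
a single repeat the SD is reported as 0 with a warning.

## Study conditions and problem sizes

The full-scale protocol (`run_config("paper")`) is six condensed 1122-bp
targets in a 400 nm vacuum cube, an isotropic cone source 40 nm from the
bundle covering all targets, 1e7 electrons per energy at 4, 6, 10, 15, 20,
30, 50, 100, 200 and 500 eV, repeated 10 times.  It is opt-in and
long-running.  The default desk preset -- one straight 200-bp target, 1e5
histories, 3 repeats -- keeps every qualitative feature of the physics and
runs the whole pipeline in minutes; the shipped tests use 1e4-2e5 histories
per energy.  How the six full-scale targets are arranged is not specified
anywhere authoritative; the package uses a parallel bundle on a square
grid (40 nm spacing) as its documented default.

At desk scale with the default library the simulator reproduces the
qualitative structure expected of this system, and the test suite asserts
it as ordering relations: the SSB-per-electron curve has a local maximum at
the 10 eV grid point (the phosphate DEA resonance), a local minimum at
15 eV after the resonance dies and before ionization opens, and DEA is the
only break-producing channel below 10 eV.  The SSB:DSB ratio at 50 eV and
above comes out at roughly 2-4, and the dose per electron peaks near
100 eV with a small secondary bump at 10 eV.  Per-electron SSB yields at
desk scale are of order 1e-3; because the fixture amplitudes are
calibrated for resolvable statistics at 1e5 histories, absolute yields are
not comparable across geometry scales.  The cross-history DSB fraction is
large at low energies in these conditions -- below 10 eV a DEA terminates
the electron after its first break, so opposite-strand partners must come
from other histories accumulated over the run; this is reported, not
hidden.

## What the synthetic conditions do and do not show

The fixture library reproduces resonance windows, thresholds and
qualitative shapes, not measured magnitudes; consequently the package's
quantitative outputs (doses, yields) characterize the fixture conditions,
not any specific experiment.  Water radiolysis and radical chemistry, DNA
repair, multi-DSB clustering categories, substrate backscatter and
base-to-backbone charge transfer are all out of scope.  Passing tests
demonstrate internal correctness (conservation, oracles, orderings,
determinism) and the threshold-structural zeros; they do not validate
absolute break yields against experiment.

## Numerical choices

* Tangent rays count as misses; entry distances clamp to 0 for origins
  inside a sphere.
* The spatial grid covers only the geometry bounding box (cell 1 nm by
  default); queries are asserted identical to the brute-force scan.
* Seeds derived by a counter scheme stay below 2^31; the same master seed
  gives byte-identical output files.
* Excitation threshold comparison is strict (`>`), ionization inclusive
  (`>=`), both pinned in `damage_rules()`.
* With zero total cross-section the mean free path is `Inf` (an escape),
  never an error.
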