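---
title: "Constructing and analysing diel plant metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and analysing diel plant metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielgem)
```

## The problem

A genome-scale metabolic model (GEM) predicts flux distributions by linear
programming over the steady-state constraint $S v = 0$ with flux bounds
$lb \le v \le ub$, maximizing an objective such as biomass. For plants this
picture is incomplete: photosynthesis only runs while light is available,
and night metabolism runs on reserves accumulated during the day. A *diel*
model represents both phases of a 24-hour light/dark cycle inside one LP,
so a single optimization chooses how much to fix, store and respire in each
phase.

`dielgem` systematizes the construction of diel models from non-diel plant
GEMs and provides the validation toolkit used to interrogate them. This
vignette explains the model, the tunable parameters, the numerical choices,
and what the package's synthetic test models do and do not demonstrate.

## The transformation steps and their assumptions

**Phase duplication** copies every compartment, metabolite and reaction
into `_Day` and `_Night` versions (both ids and display names are suffixed,
keeping ids unique and names readable). All internal references are
rewritten within the same phase, so the two phases are initially
disconnected, structurally identical copies. Exchange reactions are
duplicated like any other reaction: both phases may exchange all nutrients
with the environment; only photons (step 3) and nitrate proportions
(step 4) are treated specially. Running duplication on an already-suffixed
model raises an error rather than silently quadrupling it.

**The storage pool** is the only connection between phases. For each
user-listed metabolite $X$ the pool holds $X\_sp$ with two reversible
exchanges, written so that positive flux moves material day → pool →
night:

* `SP_X_Day`: $X\_{Day} \rightleftharpoons X\_{sp}$
* `SP_X_Night`: $X\_{sp} \rightleftharpoons X\_{Night}$

At steady state the pool metabolite's balance forces the two fluxes to be
equal, so their common sign is the net direction of cycling. Pool exchange
bounds default to ±1000 (the conventional "unbounded" magnitude of
published GEMs) and are configurable via `storage_bound`. Exactly the
user-listed metabolite ids are pooled; the package does not guess
same-species metabolites in other compartments. For multi-tissue models one
pool per tissue is created; tissues are matched to storage metabolites by
case-insensitive substring of metabolite and compartment ids, and an
explicit per-tissue list (`tissue_storage`) overrides the matching when id
conventions are less regular.

**Night photon blocking** fixes both bounds of every night-phase photon
uptake reaction to zero. Several photon reactions may be listed
(multi-tissue models have one per photosynthetic tissue). The package never
guesses which reactions are photon uptakes — identification is the user's,
by id.

**The nitrate uptake ratio** pins the day:night uptake proportion to $p:q$
(default 3:2, the empirically observed proportion in several plant
species) through the coupling constraint

$$ q \, v_{day} - p \, v_{night} = 0 , $$

one per nitrate uptake reaction. A coupling constraint — rather than fixed
bounds — is the only encoding that pins the *proportion* while leaving the
absolute uptake to the optimizer. Each nitrate reaction must be oriented so
positive flux is uptake; export-oriented reactions are rejected with a
request to re-orient. The step is optional (`ratio = NULL` skips it), and
removing it can only increase the optimum, since it is a pure relaxation.

**Biomass merging** adds, per original biomass reaction, a total reaction
whose stoichiometry is the coefficient-wise weighted sum of the day and
night copies, fixes the phase copies to zero flux and makes the total
reaction(s) the sole objective. The phase weights are a genuinely open
design point: nothing in the diel-modelling literature fixes them, and
unequal splits are used for some tissues. The default is an even 0.5/0.5
split, exposed as `biomass_weights` (two positive values summing to 1).
The merged reaction consumes phase-specific precursors directly; no
intermediate per-phase biomass pseudo-metabolite is introduced.

**Photoperiod duration** is deliberately out of scope: the model is
agnostic to how long each phase lasts, so maintenance (ATP) fluxes are not
scaled by phase length. Scaling maintenance by photoperiod would be a
natural additional pipeline step; the configuration object is the intended
hook for it.

## Solving and validation quantities

`solve_fba()` maximizes the objective subject to mass balance, bounds and
coupling constraints. Because optimal flux distributions of GEMs are
usually degenerate, all reporting defaults to the **parsimonious** variant:
a second LP minimizes $\sum_i |v_i|$ (by positive/negative flux splitting)
while holding the objective at its optimum. Infinite bounds are capped at
`default_bound` (1000) so the LP is always bounded, solutions are projected
onto the bound box (removing solver-tolerance overshoot), and "equals
zero" assertions throughout the package use an absolute tolerance of
$10^{-6}$.

The LP backend is an in-package bounded-variable two-phase primal simplex
with Bland's anti-cycling rule. Diel models are heavily degenerate LPs —
blocking night photons fixes whole pathways to zero — and Bland's rule
trades pivot-selection speed for guaranteed termination there. The basis
system is re-solved densely each pivot, which is the right trade-off at the
hundreds-of-reactions scale this package targets; the backend sits behind a
thin internal interface and can be swapped without touching any module.

**Quantum yield** is the flux of RuBisCO carboxylation divided by the flux
of photon uptake at the optimum (mol CO₂ fixed per mol photons absorbed);
for diel models the day-phase ids are used. A photon flux below $10^{-6}$
leaves QY undefined (error) rather than returning an arbitrary ratio. QY is
a flux ratio, so it is invariant under uniform rescaling of all bounds.

**Storage-pool reports** classify each pooled metabolite as
`day_to_night`, `night_to_day` or `inactive` (both magnitudes ≤ $10^{-6}$)
from the signs of its pool exchange fluxes. Directions are only meaningful
under parsimonious solutions, and even then alternate optima can flip
directions in under-determined models; the package's own test models are
engineered so the reported directions are forced by network structure, not
by solver tie-breaking.

## Differential flux analysis

`sample_fluxes()` draws near-uniform samples from the feasible polytope
with an artificial-centering hit-and-run walk. Two reductions make every
sample exactly feasible: the walk runs in the null space of the equality
system (mass balance, equality couplings, fixed reactions), and —
because diel polytopes are usually not full-dimensional even there (night
blocking pins whole pathways through one-sided bounds) — warmup vertices
obtained by flux-variability and random-objective LPs identify the affine
hull of the feasible set, and the chain moves only inside that hull. The
warmup vertices seed the ACHR direction pool (directions are differences
between stored points and the running centre). Thinning keeps every 100th
step by default; "n samples" always means post-thinning samples. The seed
is a mandatory API argument — there is no implicit global RNG state — and
the full chain is bit-reproducible given it.

`differential_reactions()` compares the sampled flux rows of each
day/night pair. No canonical test exists for this comparison in the
flux-sampling literature; the package adopts the two-sided Mann–Whitney
test (rank-based, distribution-free, standard in sampling-based DFA) with
Benjamini–Hochberg correction at $\alpha = 0.05$, and exposes
Kolmogorov–Smirnov behind `method = "ks"` as the swappable alternative.
The normal approximation with continuity correction is used throughout
(sample sizes are ~100; exact tie handling would add nothing).

`pathway_enrichment()` takes the universe to be reaction *pairs* carrying a
pathway label — a pathway's size counts pairs, matching how pathway totals
are quoted for the original (pre-duplication) model — and computes
upper-tail hypergeometric probabilities $P(X \ge k)$. Reactions without a
label are excluded from the universe rather than pooled into a pseudo
pathway.

`pca_overlap()` arranges the day and night copies of significant pairs as
row points over their sampled fluxes, mean-centres each row, and takes
principal components by SVD. Rows are *not* scaled to unit variance:
flux-magnitude separation is exactly the signal the overlap metric relies
on, and unit scaling would erase it. A pair overlaps when its day and
night points are within Euclidean distance 1 in the (PC1, PC2) plane; the
overlap fraction over significant pairs is the headline statistic. Whether
the points should be reactions-over-samples (adopted) or
samples-over-reactions is ambiguous in the DFA literature; the adopted
orientation is the one in which "two reactions overlap" is well-defined.

## The synthetic models, and what passing tests show

`make_toy_plant_gem()` builds a ~25-reaction photoautotroph with photon,
CO₂, nitrate, water and phosphate exchanges, a light reaction
($\lceil 1/QY_{target}\rceil$ photons → 2 NADPH + 3 ATP + reduced
ferredoxin), RuBisCO carboxylation (CO₂ + 2 NADPH + 3 ATP → sucrose),
sucrose/starch interconversion, ferredoxin-dependent alanine synthesis,
respiration, ATP maintenance, a biomass reaction and pathway-labelled
filler reactions. Three features are engineered, not incidental:

* NADPH is produced only by the light reaction and consumed only by
  fixation, which couples carboxylation 1:1 to the light reaction by mass
  balance, so the quantum yield is *exactly* the analytic target
  (default 0.125) independent of how downstream ATP is spent.
* Reduced ferredoxin exists only in the light, so nitrate assimilation is
  structurally impossible at night; under the 3:2 coupling, night uptake
  exceeds night demand and pooled nitrate is *forced* to flow night → day.
* Night biomass can draw carbon only from the storage pool, forcing sugar
  day → night, with the direct sucrose route strictly cheaper in total flux
  than the starch detour, so parsimonious solutions are direction-unique.

The photon supply cap (100 flux units) makes light limiting, which gives
the model the closed-form optimum $75/13 \approx 5.77$ used as the LP
oracle in the tests. The two-tissue variant (leaf/root with an apoplast,
dark roots, per-tissue pools and two nitrate uptakes) exercises every
multi-tissue branch. Fixture generation is deterministic: identical
specifications produce bit-identical SBML.

These models emulate the *structural* features the pipeline consumes; they
do not attempt elemental balancing, realistic stoichiometric coefficients,
GPR complexity, or the thousands-of-reactions scale of published pGEMs.
Passing tests therefore demonstrate the correctness of the transformation
arithmetic, constraint encoding, solver contracts and statistical
machinery — not the biological accuracy of any particular published model,
and not full-scale results (e.g. differential-reaction counts of specific
published genome-scale models), which depend on externally distributed
model files and their annotation conventions.

Problem sizes used by the test-suite and the acceptance script — 100 ACHR
samples over a ~59-reaction diel model, 200 synthetic null pairs of 100
samples, exhaustive hypergeometric checks to universe size 25 — were chosen
as the smallest sizes at which each property is sharply testable.

## Numerical and serialization choices

* Tolerances: $10^{-6}$ absolute for all feasibility/zero assertions;
  $10^{-9}$ for the simplex's reduced-cost and ratio tests; rank decisions
  in the sampler use an SVD cutoff scaled by machine epsilon.
* SBML: models are written as Level 3 Version 1 with FBC v2 — bounds as
  shared flux-bound parameters, the objective as an FBC objective, GPRs and
  pathway labels in `GENE_ASSOCIATION:` / `SUBSYSTEM:` notes (pathway
  labels are also read from the SBML groups package when present; absent
  labels simply exclude a reaction from enrichment universes). Identifiers
  are opaque and never mangled; invalid SBML SIds are an error.
* Cross-reaction coupling constraints have no native SBML FBC encoding, so
  they are serialized in a model-level annotation block under the
  `urn:dielgem:coupling` namespace (`<dgc:constraint id lower upper>` with
  `<dgc:coefficient reaction value/>` children) and re-hydrated on read —
  a diel model stays one self-describing file, and tools that ignore the
  annotation still read a valid FBC model.
* Numbers are serialized with 17 significant digits, so write/read
  round-trips are exact for doubles.

## Known limitations

* No dynamic FBA, kinetic laws, SBML Level 2, flux variability analysis as
  a user-facing report, gene-deletion analysis, or loopless sampling.
* Reaction identification (photon, nitrate, biomass) is entirely explicit;
  there is deliberately no name-based auto-detection.
* The ACHR walk's mixing is not diagnosed automatically; for models far
  larger than the desk scale, users should increase thinning and compare
  seeds.
* Storage-pool direction classification assumes the pipeline's `SP_`
  naming scheme; pools built by other tools are not recognized.
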