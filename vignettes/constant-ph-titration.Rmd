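---
title: "Constant-pH Monte Carlo titration of a tripodal mannoside receptor"
author: "tripodCpH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-pH Monte Carlo titration of a tripodal mannoside receptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripodCpH)
```

## The system and the question

Synthetic tripodal aminopyrrolic receptors bind mannosides strongly in
acetonitrile but hardly at all in water.  The receptor at the centre of this
package carries a benzene core and three identical arms, each with a
pyrrolic NH and two titratable secondary amines: a buried *first-generation*
amine near the core and an exposed *second-generation* amine at the arm tip
— six titratable sites, hence $2^6 = 64$ protonation microstates.  In water
the amines ionise, the arms repel each other, and the hydrogen-bonding head
group of an octyl mannoside competes with solvent; understanding which
protonation patterns are populated at each pH, how protonation reshapes the
conformational ensemble, and which receptor–ligand contacts survive in each
solvent is the purpose of the analyses implemented here.

`tripodCpH` re-creates that study at desk scale: a multi-site titration
Monte Carlo engine over the 64 microstates, a synthetic conformational
ensemble generator, a stop-and-go coupling loop between the two, and the
structural and interaction descriptors used to read the results.

## The titration model

A microstate $s \in \{0,1\}^6$ has free energy, in pK units,

$$ g(s) = \sum_i s_i\,(\mathrm{pH} - \mathrm{p}K_{\mathrm{int},i})
        + \sum_{i<j} W_{ij}\, s_i s_j , $$

with Boltzmann weight $10^{-g(s)}$.  Working in pK units with base-10
exponentials keeps the pKa scale and the pair-move threshold (2.0 pK units)
free of unit conversions; one pK unit is $kT\ln 10 = 5.705$ kJ/mol at
298 K.

* $\mathrm{p}K_{\mathrm{int}} = 10.64$ for every site — the dimethylamine
  model-compound value for these secondary amines.
* $W_{ij} \ge 0$ is the extra cost of protonating sites $i$ and $j$
  together (two like charges).

The reference workflow obtains $W$ from finite-difference
Poisson–Boltzmann calculations.  Those are out of scope here; the package
substitutes a **screened-Coulomb surrogate** on the amine-nitrogen
positions,

$$ W_{ij} = \frac{C\, e^{-\kappa r_{ij}}}{\varepsilon_r\, r_{ij}\, kT\ln 10}, $$

with $C = 138.935$ kJ mol$^{-1}$ nm (unit charges), solvent dielectric
$\varepsilon_r = 80$, ionic strength 0.1 M ($\kappa = 1.03$ nm$^{-1}$) and
$T = 298$ K — the solvent parameters of the electrostatic stage it stands
in for.  The surrogate preserves what the microstate analysis depends on
(distance-dependent repulsion between protonated sites, symmetric under the
arm permutations) but is much weaker than a low-dielectric PB solution;
consequences are flagged below.

```{r}
conf <- generateConformation(openness = 0.4, seed = 1, noise = 0)
W <- computeInteractionMatrix(conf)
round(W, 3)
```

### Exact enumeration and Monte Carlo

With 64 states the equilibrium is exactly enumerable
(`enumerateEquilibrium()`), which doubles as the internal oracle for the
sampler.  `mcTitration()` follows the published MC protocol: each step is a
cycle of single-site proposals over all sites in fresh random order, then
simultaneous two-site proposals for every pair coupled above 2.0 pK units,
each accepted with $\min(1, 10^{-\Delta g})$; $10^5$ steps per calculation
by default, first 10% discarded.  Proposals draw a *random* state for the
visited site (not a deterministic flip): a flip proposal is non-ergodic in
the degenerate $W = 0$, $\mathrm{pH} = \mathrm{p}K_{\mathrm{int}}$ case,
where every $\Delta g$ is zero and the chain would alternate between the
all-protonated and all-deprotonated states for ever.  Tautomers are
collapsed into a single protonated form (a per-site degeneracy slot exists
for future use); pair moves are listed once per conformation from
$W_{ij} > 2$.

```{r}
m <- titrationModel(10.64, 0)
exact <- enumerateEquilibrium(m, pH = 10.64)
mc <- mcTitration(m, pH = 10.64, nSteps = 2e4, seed = 1)
c(exact = totalProtonation(exact), mc = totalProtonation(mc))
```

### The plateau calibration

The receptor's measured titration curve has a plateau at total protonation
≈ 3 across mid pH, carried mostly by the exposed second generation.  The
PB energies behind that are unpublished, so the package ships a
*calibration model* that encodes the qualitative coupling pattern instead:
strong repulsion (6 pK units) for gen1–gen1 and intra-arm gen1–gen2 pairs,
weak (1 pK unit) for gen2–gen2.

The one genuinely open knob is the **inter-arm gen1–gen2 coupling**.
Strong (the default) suppresses the first generation completely — total 3,
gen2 ≈ 100%.  Weak (1 pK unit) makes "two gen2 + one gen1 on the free arm"
exactly degenerate with the pure-gen2 state, and the plateau splits
75%/25% between the generations — precisely the split the receptor's
titration shows.  Both variants keep the plateau height at 3:

```{r}
d1 <- enumerateEquilibrium(plateauCalibrationModel(), pH = 6)
d2 <- enumerateEquilibrium(plateauCalibrationModel(interArmCross = 1), pH = 6)
rbind(strongCross = c(total = totalProtonation(d1), generationOccupancy(d1)),
      weakCross   = c(total = totalProtonation(d2), generationOccupancy(d2)))
```

`classifyMicrostates()` merges the 64 states into equivalence classes under
the **full** six-element arm-permutation group (preserving generation
labels), giving class counts (1, 2, 4, 6, 4, 2, 1) for $n = 0..6$ protons.
The full group is the only convention consistent with six classes at
$n = 3$; cyclic-only merging would give eight.  Within each $n$, per-state
populations decrease with the class repulsion energy — charges arrange to
minimise repulsion.

## The synthetic receptor geometry

The generator is a coarse bead model carrying only the atoms the analyses
reference: 6 ring carbons (hexagon, bond 0.139 nm), 3 pyrrolic N, 6 amine N
and their polar hydrogens.  A single order parameter, `openness`
$\in [0,1]$, moves the arms from folded (elevation 35° from the ring
normal) to fully radial (90°), with the gen2 distance from the core growing
from 1.05 to 1.40 nm; a fixed +18° azimuthal twist makes the geometry
chiral, so mirror images are distinct conformations.  Independent per-arm
Gaussian jitter (default 0.02 nm) provides within-openness variability.

The absolute distances are calibrated to the two printed anchors: closed
conformations have receptor $R_g \approx 0.50$ nm and open ones exceed
0.65 nm, and the first-generation amines sit much closer to one another
than the second-generation ones (which is what shifts their pKa down).
Nothing else about the real molecule's internal coordinates is represented,
and no force field is implied.

```{r}
c(closed = radiusOfGyration(generateConformation(0, 1, noise = 0)),
  open = radiusOfGyration(generateConformation(1, 1, noise = 0)))
```

## The coupled loop

`coupledCpHLoop()` re-expresses the stop-and-go constant-pH scheme with a
conformational MC stage in place of molecular dynamics.  Each cycle:

1. rebuild $W$ from the current conformation and run a short titration MC
   (default 1000 steps — the reference protocol's $10^5$ scaled down for
   desk-scale runs; the last sampled state is kept);
2. make Metropolis proposals in `openness` (reflected Gaussian random walk,
   step 0.08) on the conformational energy
   $E = b \cdot \mathrm{openness} + \sum_{i<j} W^c_{ij} s_i s_j$.

Two choices here are the package's own, made analytically before any test
was run.  The closed-arm bias $b = 1.2$ pK units stands in for the
hydrophobic preference of the neutral receptor for compact conformations
(the closed shoulder seen at high pH).  The conformational Coulomb term
$W^c$ is evaluated at an effective dielectric of 20 and 0.01 M — between
solvent (80) and solute interior (2) — because arm–arm repulsion acts
partly through the molecule itself; at $\varepsilon_r = 80$ the repulsion
would barely move the arms.  With these values the Boltzmann distribution
of openness has mean 0.29 (IQR 0.33) for the neutral receptor and mean
0.86 (IQR 0.15) for the fully protonated one: at low pH the ensemble is
pushed open and pressed against the extended limit, hence *narrower* — the
qualitative pH trend of the study.  The titration stage itself always uses
the solvent parameters (80, 0.1 M).

```{r}
ens <- coupledCpHLoop(pH = 1, nCycles = 200, seed = 7, mcStepsPerCycle = 200)
mean(ens@metadata$openness[-(1:20)])
```

Because the geometric surrogate's couplings are weak (≤ 0.75 pK units),
the coupled loop's titration curve is close to six independent sites with
midpoint near 10.64: it does **not** develop the plateau at 3, which in the
real system comes from strong PB couplings.  The plateau lives in the
calibration model above.  A green coupled-loop test therefore establishes
the protonation→conformation feedback (low pH opens and narrows the
ensemble), not the printed titration curve.

## Structural descriptors

* `radiusOfGyration()` — unit-mass RMS distance from the centroid, over the
  15 receptor heavy atoms by default.
* `symmetryRMSD()` — least-squares rigid superposition (SVD Kabsch, proper
  rotations only) minimised over arm relabellings.  Default group:
  the **3 cyclic rotations** — the receptor is chiral, so the reflections
  of the full group would compare the molecule against arrangements it
  cannot reach; the full group remains available for comparison with the
  classification convention.
* `armPositions()` — pyrrolic N coordinates in a deterministic ring frame
  (origin at the ring centroid, $z$ along the right-handed ring normal,
  $x$ through ring atom 1), invariant under global rigid motion.  In this
  geometry opening the arms increases their radial reach while *lowering*
  them toward the ring plane — the in-plane spread is what maximises
  charge–charge distances.
* `freeEnergyLandscape()` — product-Gaussian KDE on a regular grid,
  converted to $\Delta G = -kT\ln(P/P_{\max})$ with the minimum exactly 0.
  Bandwidth defaults to Scott's rule per axis ($\sigma_i n^{-1/6}$); the
  grid defaults to 100×100 (the stated "2 pm²" bins read as "very fine",
  impractically so — resolution is a parameter and results should be
  grid-robust).  The grid is padded by max(5% of range, 3 bandwidths) so
  the density integrates to 1 on it; zero-density bins carry +Inf in the
  raw surface and a machine-scale cap in `cappedFreeEnergy()` for
  plotting.
* `autocorrCorrectedError()` — statistical inefficiency
  $g = 1 + 2\sum_t C(t)$ (truncated at the first non-positive estimate),
  corrected SE $\sqrt{\mathrm{var}\,g/N}$, effective samples $N/g$; the
  autocorrelation-function route to "number of independent blocks".

## Receptor–mannoside interactions

The mannoside mimic is a six-atom sugar ring (5 C + ring O), four hydroxyl
O–H groups, a glycosidic O and an eight-carbon tail.  Three pose modes span
the binding modes seen in the two solvents: `head` (hydroxyls directed at
nearby amine nitrogens — hydrogen-bond rich, the acetonitrile mode), `tail`
(terminal tail carbons stacked over the phenyl ring — the hydrophobic
aqueous mode) and `loose`.  `runInteractionStudy()` samples a
state-dependent mixture of the three for each named protonation state
(W^q0, W^q3a, W^q3b, W^q4, aprotic), weighted so that the aprotic regime is
head-dominated, the neutral aqueous state tail-dominated, and
first-generation-protonated states unspecific — the qualitative contrasts
of the study, asserted by the tests.

* Hydrogen bonds are geometric: donor–acceptor ≤ 0.35 nm and D–H–A within
  30° of linear — the criterion is unstated in the source, so the
  community-standard default of the usual trajectory tools is used; both
  cutoffs are parameters.  Donors: amine and pyrrole N–H, hydroxyl O–H;
  acceptors: amine N and the hydroxyl/ring/glycosidic oxygens; only
  intermolecular pairs count.
* `restraintPotential()`/`restraintEnergy()` — the flat/quadratic/linear
  pair restraint (k = 100 kJ mol$^{-1}$ nm$^{-2}$, quadratic 1.0–1.2 nm,
  linear above, value- and slope-continuous).  Whether the reference
  restraint sums over all 36 ring-atom pairs or acts on a single violating
  pair is ambiguous in the text; the sum is the default and a `"min"`
  variant is exposed.

## What the synthetic world does and does not establish

The generator emulates: the two-generation site geometry and its
consequences for the protonation pattern, the closed↔open conformational
axis with the printed $R_g$ anchors, coupling between charge and openness,
and pose-dependent receptor–ligand contacts able to realise both the
six-bond head pose and the tail-stacked pose.  It does not emulate: real
PB energetics (so absolute per-generation percentages are only reproduced
by the calibration model), solvent structure, binding free energies, or
any force-field dynamics — histogram *shapes* are therefore qualitative.
Green tests establish internal consistency (MC ↔ enumeration, estimator ↔
closed forms, symmetry handling ↔ brute force) and the qualitative trends;
they do not validate quantitative agreement with experiment.

## Numerical choices

* Overflow guard: the minimum $g$ is subtracted before exponentiation in
  the enumeration.
* Seeds: every stochastic entry point takes one; streams for replicates
  are derived from the master seed by a fixed affine counter scheme, and
  the RNG state is restored after each seeded call.
* Floors and retries: conformations reject inter-atom distances below
  0.05 nm; site–site distances below 0.1 nm are an error in the
  interaction matrix (unphysical geometry); ligand placement retries up to
  100 times with growing jitter before failing.
* Ties: the orbit representative is the lexicographically smallest
  occupation string; class tables order by $n$, then population.
* Degenerate KDE axes fall back to a small fixed bandwidth; duplicated
  samples and rescaled weights leave the surface unchanged at fixed
  bandwidth (Scott's rule itself depends on $n$).

## Known limitations

Six sites are enumerable, so the MC engine is validated against exactness
but never *needed* for the receptor alone — it matters for the coupled
loop, where the matrix changes every cycle, and it is the piece that would
scale to larger receptors.  The bead model has no excluded volume between
arms, openness is the only collective coordinate, and the aprotic regime
is represented only as "titration off, head pose favoured".  Replicate
errors in the study runners are replicate-level standard errors; the
per-series autocorrelation machinery is available but the default study
grids keep runs short.
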