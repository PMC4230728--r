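---
title: "Structure-based models of multi-domain folding cooperativity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based models of multi-domain folding cooperativity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Many multi-domain proteins fold all-or-nothing even though their domains
have different intrinsic stabilities. One architectural route to this
cooperativity is *domain insertion*: embedding the sequence of a small,
marginally stable domain inside the sequence of a larger, more stable one.
The host becomes discontinuous along the chain, and — once it is folded —
it pins the N- and C-termini of the insert, paying the insert's folding
entropy bill and coupling the two folding equilibria. E. coli adenylate
kinase is the archetype: its NMP and LID domains are inserted into the
CORE domain, its folding is two-state in bulk experiments, and circular
permutation (which converts an inserted domain into a singly-linked one
without changing any native contact) measurably de-cooperativizes folding.

`foldcoop` implements the full computational apparatus needed to ask this
question of coarse-grained models: C-alpha structure-based (Go) potentials
and their perturbations (interface deletion, circular permutation,
dual-basin open/closed models), a Langevin dynamics engine, the
thermodynamic analysis layer (Q reaction coordinates, WHAM, heat capacity,
van't Hoff/calorimetric cooperativity, foldedness, foldon clustering,
domain-insertion metrics), and a synthetic-structure generator so that the
entire pipeline runs, end to end, with no external inputs.

## The model

Each residue is one bead at its C-alpha position. The potential is the
standard C-alpha structure-based form, with every reference value taken
from the native structure so the native state is the exact global minimum
of the bonded + contact terms:

* bonds: $V = k_b (r - r_0)^2$ with $k_b = 100\ \epsilon_0/\text{\AA}^2$
  (note: no factor 1/2; the curvature is $2k_b$);
* angles: $V = k_a (\theta - \theta_0)^2$, $k_a = 20\ \epsilon_0$/rad$^2$;
* dihedrals: $V = k_d[(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)]$,
  $k_d = 1\ \epsilon_0$;
* native contacts: a 10–12 well
  $V = \epsilon[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$ of depth $\epsilon$
  at the native distance $\sigma$;
* non-native pairs (sequence separation $\ge 3$, not a native contact, not
  bonded): a truncated-and-shifted repulsion
  $V = \epsilon_{nn}[(\sigma_{nn}/r)^{12} - 1]$ for $r < \sigma_{nn}$,
  zero beyond, with $\sigma_{nn} = 4.0$ Å, $\epsilon_{nn} = 1$.

Units are reduced throughout: $\epsilon_0 = 1$ sets the energy scale,
$k_B = 1$ (so temperature is in $\epsilon_0$), masses are uniform 1,
lengths are in Angstrom.

Two numerical choices deserve comment. First, the non-native repulsion is
truncated at its own diameter rather than left with an $r^{-12}$ tail;
with the contact criterion (cutoff 8 Å > $\sigma_{nn}$) this makes the
native energy *exactly* $-\sum \epsilon$ and the native state an exact
stationary point, which the test suite asserts to $10^{-6}$. Second,
contact wells are evaluated at all distances with no radial cutoff: at the
system sizes this package targets (tens to a few hundred beads) exactness
is cheaper than neighbour-list bookkeeping, and microcanonical energy
conservation stays clean (drift $< 10^{-4}\ \epsilon_0$ per $10^4$ steps
at $dt = 5\times10^{-4}$).

## Dynamics

`run_langevin()` integrates Langevin dynamics with a BAOAB splitting
(velocity-Verlet when `friction = 0`, exposed for energy-conservation
tests). Defaults: $dt = 5\times10^{-4}$ reduced time units — very
conservative for the stiffest (bond) mode, whose period is $\approx 0.44$
— and friction 1. The production analyses in `analysis/` use
$dt = 5\times10^{-3}$, still an order of magnitude under the stability
limit, chosen for sampling efficiency; the equipartition and
bond-variance tests pass at both values. The thermostat's random stream
is a seeded Mersenne Twister inside the compiled core, so trajectories
are bit-reproducible for a given seed on a given platform.

## Reaction coordinates and thermodynamics

The fraction of native contacts Q scores each contact with the rational
switching function $s(r) = 1/(1 + (r/1.2\sigma)^6)$, clamped to 1 for
$r \le \sigma$, and averages the scores (weighted by $\epsilon$ for the
strength-scaled Q*). Native geometry maps to exactly 1, the all-broken
limit to 0, so no further rescaling constants are needed. The published
form of this coordinate is a rational switching function of the same
family; the exact midpoint (here $1.2\sigma$) and exponent pair (6, 12)
are surfaced as arguments.

Free energies come from self-consistent multi-histogram reweighting
(WHAM) over one or more constant-temperature runs. The per-state free
energies are found by maximizing the convex WHAM likelihood with BFGS;
the degenerate single-run case reduces exactly to $-\ln$(histogram),
which is tested to $10^{-9}$. Heat capacity is
$C_v(T) = (\langle E^2\rangle_T - \langle E\rangle_T^2)/k_BT^2$ under
reweighted expectations, the folding temperature $T_f$ is its argmax, and
profiles are reported in $k_BT$ with delete-one-block jackknife variances
(10 contiguous blocks by default; error bars downstream are
$2\sqrt{\mathrm{var}}$).

Folding cooperativity is quantified as $\Delta H_{vH}/\Delta H_{cal}$
with $\Delta H_{vH} = 2T_f\sqrt{k_B C_v(T_f)}$ and $\Delta H_{cal} =
\int C_v\,dT$ between the $C_v$ minima flanking the peak. Both use the
*excess* heat capacity after subtracting the linear baseline joining the
window endpoints: coarse-grained chains carry a large harmonic background
($\approx$ one half $k_B$ per quadratic degree of freedom) that is not
part of the folding transition, and leaving it under the peak (or under
the square root) makes the ratio meaningless for small systems. On an
exact two-level system the implementation returns a ratio of 1 within 2%,
and the peak sits at $\Delta/(k_B\ln g)$ within 1% (for $\ln g$ large;
the peak of $\beta^2\Delta^2 p(1-p)$ is displaced below the equal-
population temperature by $O(1/\ln^2 g)$, which is why the analytic
check uses $\ln g = 25$).

Foldedness of a variant relative to a reference is
$\exp(-\Delta G_{var}(q_{ref}))/\exp(-\Delta G_{ref}(q_{ref}))$ with both
profiles zeroed at their folded-basin minima and $q_{ref}$ the reference's
folded-basin mode; the worked values $\exp(-1.6) \approx 0.202$ and
$\exp(-0.94) \approx 0.390$ are unit-tested through the same code path.
Basin thresholds are folded $Q > 0.7$ / unfolded $Q < 0.3$, and the
folded-basin search region starts at $Q = 0.5$; all configurable.

## Variant construction

**Interface deletion** removes all contacts with a given interface label
and then restores every affected residue's total contact strength
(sum of $\epsilon$ over its contacts) by iterative proportional fitting:
each surviving contact $(i,j)$ is repeatedly scaled by
$\sqrt{f_i f_j}$, where $f_i$ is the ratio of residue $i$'s wild-type
strength sum to its current sum ($f = 1$ for unaffected residues), until
all sums match within $10^{-9}$. This is a symmetric, deterministic
realization of "scale the other contacts of that residue". Two honest
failure modes are reported as warnings and recorded in the topology
provenance: a residue whose only contacts were interface contacts cannot
be compensated at all, and a residue subset whose surviving contacts
connect only to each other can make the balance equations infeasible (a
single surviving contact cannot equal two different target sums). Both
arise in adversarial random maps; neither occurs in the geometric
interfaces the generator produces.

**Circular permutation** joins the original termini through a bead linker
and cuts elsewhere; all contacts are renumbered with identical
$\sigma, \epsilon$, and linker beads carry only bonded terms. Linker
geometry: straight-line equal spacing between the old termini when that
spacing lands in [3.0, 4.5] Å; when the termini are closer than the
linker's natural length, the beads bow out on a circular arc whose chord
is the termini gap and whose arc length is $(L+1)\times3.8$ Å; a gap
wider than $(L+1)\times4.5$ Å cannot be bridged and is an error. (An arc
cannot be *shorter* than its chord, so an arc fallback in the too-wide
direction would be geometrically impossible; the arc solves the
too-short case.) All junction bonded reference values are taken from the
built geometry, so a permutant's native energy is still $-\sum\epsilon$.

**Dual-basin models** add the contacts present in a closed conformation
and absent from the open map, with $\sigma$ from the closed structure and
a common strength $\epsilon_{closed}$; the dual potential decomposes
exactly as $E_{open} + E_{closed\ contacts}$. `tune_closed_strength()`
scans multiples $\{0.4, 0.6, \ldots, 2.0\}$ of the mean open-contact
strength and returns the smallest that lets a short simulation occupy
both conformational basins (each $\ge 10\%$ of frames, basins defined on
the fraction of closed-specific contacts formed: open $< 0.3$, closed
$> 0.7$).

**Foldons** are clusters of native contacts that form and break together
across folding transition paths: frames are restricted to detected
transition segments, contact formation ($r < 1.2\sigma$) is binarized,
Pearson-correlated, and clustered as the connected components of the
correlation graph at threshold 0.5 with a 10-contact size floor
(average-linkage clustering is available behind the same interface).
Constant columns — contacts formed or broken throughout, like contacts
internal to stable local structure — get zero correlation and drop out.
These parameters are deterministic stand-ins for a force-directed
visual clustering whose parameters were never published; the planted-
block recovery tests show the defaults recover known structure exactly,
and the analysis script prints a sensitivity-friendly cluster table.

## The synthetic generator: what it does and does not emulate

`make_toy_domain()` grows a self-avoiding random walk (bond 3.8 Å,
centripetal bias proportional to compactness) and collapses it by seeded
Langevin dynamics under a soft spherical restraint of radius
$2.7\,n^{1/3}$ Å, followed by a cold quench. At default compactness this
yields 2–3.7 contacts per residue under the 8 Å / minimum-separation-3
criterion — the packing range typical of C-alpha contact maps of real
domains — with no non-bonded pair closer than 3.5 Å, deterministically
for a given seed.

`make_two_domain_protein()` docks a small domain against a surface patch
of a large one (centroid 7 Å from the patch residue; among a seeded set
of rigid rotations, the one that shortens the chain junctions without
steric clash is chosen) and then threads the chain through the assembly
either with the small domain's sequence *inserted* after an interior
residue of the large domain, or *singly linked* after it. The docking
distance default of 7 Å is deliberate: at the 8 Å contact criterion it
produces a sparse emergent interface (roughly 5–15 contacts across
seeds), resembling the small functional interfaces of natural inserted
domains, whereas docking at 10 Å leaves essentially no interface and
nothing for the interface-deletion machinery to act on. A candidate pair
counts as a contact only when its sequence separation is $\ge 3$ under
*both* threadings, so the two modes have literally identical contact
content — same pairs, same $\sigma$, same $\epsilon$ — and differ only in
chain connectivity, which is the variable under study. The stability
contrast is encoded in the strengths: intra-large $\epsilon = 1$,
intra-small $\epsilon =$ `stability_ratio` (default 0.5), interface
$\epsilon = \sqrt{\text{ratio}}$ (geometric mean).

What the toys do **not** emulate: secondary structure and its anisotropic
contact patterns, side-chain packing, energetic heterogeneity beyond the
two-level domain contrast, and real linker chemistry. Passing tests on
these toys therefore demonstrate that the *machinery* — potentials,
sampling, reweighting, metrics — behaves correctly and that the
insertion-versus-linkage contrast emerges from chain connectivity alone;
they do not by themselves predict the magnitude of the effect in any real
protein.

## The headline computational experiment

`insertion_study()` generates the same two-domain assembly in both
threadings (28 + 12 beads, stability ratio 0.5), simulates each across a
five-temperature ladder spanning 1.05–1.70 $\epsilon_0$ (400,000 steps
per temperature at $dt = 0.005$, first 10% discarded), and compares:

* the van't Hoff / calorimetric cooperativity ratio of the whole protein;
* $\langle Q_{small} \mid Q > 0.7\rangle$ at $T_f$ — how folded the small
  domain is *within the folded ensemble* at the whole-protein folding
  temperature (the tail population $P(Q_{small} > 0.7)$ is also reported
  but is noise-limited when the small domain is strongly destabilized);
* the whole-protein foldedness of the linked construct relative to the
  inserted one, the same ratio used to compare circular permutants
  against a wild type.

These problem sizes were chosen as the smallest at which the constructs
show a clear, sampled melting transition; across every seed we have run,
the inserted threading gives the higher cooperativity ratio and the more
folded small domain, and the linked construct's foldedness is below 1.
The acceptance script re-runs this comparison from scratch at three seeds
and reports the per-seed and mean values.

## Known limitations

* The cooperativity ratio from simulation retains sampling noise of
  several percent at these run lengths; its *ordering* between constructs
  is the robust observable, not its absolute value.
* WHAM assumes overlapping energy distributions between ladder
  neighbours; the implementation warns when they do not overlap.
* The interface-deletion balance is infeasible for adversarial contact
  graphs (warned, see above).
* Transition detection and foldon clustering need trajectories that
  actually cross between basins; at temperatures far from $T_f$ they
  correctly report nothing.
* Kinetics (rates, transition-path times) are out of scope; only
  equilibrium thermodynamics is computed.
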