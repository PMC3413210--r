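---
title: "Methods: all-atom building and contact auditing in clashaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: all-atom building and contact auditing in clashaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clashaudit)
```

# The model and its assumptions

`clashaudit` treats a crystal structure as a fixed set of heavy-atom
coordinates plus a set of discrete, chemically ambiguous degrees of
freedom: hydrogen positions that are not determined by the heavy atoms
(hydroxyl, sulfhydryl, phenolic and water hydrogens), protonation and
tautomeric states (Asp, Glu, His), and terminal-group flips (Asn, Gln,
His) whose two orientations are indistinguishable in typical electron
density. Everything the package does rests on three assumptions:

1. **Heavy atoms are trusted.** Building an all-atom model never moves a
   non-hydrogen atom; flips only swap coordinates within the terminal pair,
   which is a relabelling, not a refinement.
2. **Riding hydrogens are deterministic.** An H whose position is implied
   by its parent's frame is placed from ideal geometry (tetrahedral or
   trigonal frames, staggered methyls, in-plane amide and aromatic H).
3. **The remaining freedom is discrete.** Rotatable hydrogens and flip /
   protonation states are chosen from enumerated candidate states by
   maximizing hydrogen bonding while avoiding close nonbonded contacts,
   not by continuous force-field minimization (a deliberate substitution:
   the discrete optimum captures the same decisions a force-field H-only
   minimization would make at far lower complexity, and is exactly
   testable against enumeration).

# Clash definition

A nonbonded pair is a **clash** when its center-to-center distance is at
most 0.8 times the sum of the van der Waals radii, and a **severe clash**
at 0.7 times; both boundaries are inclusive and severe takes precedence.
Radii are the Rowland–Taylor contact radii with H = 1.10 Å; elements
outside that compilation fall back to Bondi values with a warning. Two
hydrogens thus clash at 1.76 Å and two oxygens at 2.53 Å. The
comparison mode implements the Richardson-system rule instead: a clash is
a van der Waals overlap of at least 0.4 Å, with H radii split by
environment (1.00 Å when bonded to N/O/S or an aromatic carbon, 1.17 Å
otherwise), reproducing the 1.60 / 1.94 / 2.40 Å thresholds exactly.

**Exclusions.** Before classification we remove, in order and with a
per-reason tally: (a) pairs within three covalent bonds (1-2, 1-3, 1-4;
the reference procedure is silent on depth, and at these radii a 1-4 H–H
pair cannot reach ratio 0.8 in realistic geometry, so the standard
nonbonded-exclusion convention is safe); (b) heavy donor–acceptor pairs
that *could* hydrogen bond, applied by role alone with no distance or
angle test — the most conservative reading of "removed from
consideration even if an H atom was not found directly between them";
(c) a donor-attached H against any acceptor; (d) pairs within one
residue's flip-ambiguous group. Donors are N/O/S atoms carrying a bonded
H, or canonical donor names in united-atom input; acceptors are
carbonyl / carboxylate / amide / hydroxyl / water oxygens, His ring N
without H, Met SD and Cys SG. Water-involving contacts are tallied
separately and never enter the headline counts; symmetry mates are not
generated.

**Reporting.** Frequencies print per 100 residues to one decimal; cohorts
pool as `100 × Σcounts / Σresidues` (the totals-row convention: 52 counts
over 3543 residues prints 1.5), while geometry columns average
unweighted.

# Hydrogen-bond network optimization

Variable species are enumerated per residue: one per Ser/Thr/Tyr/Cys
rotatable hydrogen (a Cys in a disulfide has none), one per Asp/Glu
(5 states: deprotonated, or H on either oxygen syn/anti in-plane), one
per His (3 protonation states × 2 flips), one per Asn/Gln (flip or not),
one per water. Torsional species get one state aimed at each acceptor
within 3.5 Å, one anti to each nearby donor, plus three staggered
defaults, merged within 15°; waters get orientations pairing their two
O–H vectors with nearby partners plus defaults, deduplicated at 0.3 Å.

Species whose polar atoms lie within the **coupling cutoff** (4.0 Å =
the 3.5 Å donor–acceptor ceiling plus slack) are joined into clusters
(connected components). Each cluster is scored by

```
score = 1.0·n_hbonds − 10·n_clashes − 100·n_severe + priors
```

with a hydrogen bond defined by D–A ≤ 3.5 Å, H···A ≤ 2.5 Å and
D–H···A ≥ 120°, and a −0.5 prior for a neutral Asp/Glu or a charged His.
The weights are a design choice (the reference describes the objective
only in words): they are ordered so that *any* clash outweighs any
plausible hydrogen-bond gain, and all are configurable through
`network_params()`. Because hydrogen bonds and clashes are pair
properties, the score decomposes exactly into per-species and pairwise
terms, which are precomputed; search and enumeration then operate on the
tables.

Clusters with at most 10⁴ state combinations are solved **exhaustively**
— exactness where affordable, and the enumeration doubles as the test
oracle. Larger clusters run 10 random starts of coordinate-wise
best-response to convergence, uniform-crossover recombination (20
offspring), and simulated annealing (Metropolis single-species moves,
geometric cooling 1.0 → 0.01 over 200·|species| steps), returning the
best assignment ever seen after a final best-response polish. All
randomness derives from the user seed; per-cluster seeds are offset from
it, so runs are bit-reproducible.

# Geometry statistics

Bond and angle deviations are measured against a packaged
Engh–Huber-style restraint table (`inst/extdata/eh_bonds.csv`,
`eh_angles.csv`; editable and overridable). `rmsd = sqrt(mean(Δ²))`,
`rms Z = sqrt(mean((Δ/σ)²))`. Side-chain planarity fits the
least-squares plane (smallest singular vector) through each planar group
— Arg guanidinium with CD, Asn/Gln amides with the adjacent carbon,
Asp/Glu carboxylates, His/Phe/Tyr/Trp rings with first substituents,
Tyr OH in the ring plane — skipping groups with fewer than four atoms
present, and averages group r.m.s.d.s. ω = CA(i)–C(i)–N(i+1)–CA(i+1) is
assigned trans (180°) or cis (0°) by proximity and the summary is the RMS
circular deviation **about the ideal**, so a perfectly planar peptide
scores 0; measuring about the circular mean is available as an option
(`omega_stats(..., about = "mean")`) since the reference does not specify
the convention. Hydrogens never enter geometry statistics, matching the
united-atom validators the numbers are compared against.

The angle list is deliberately restricted to the angles the fixture
builder sets explicitly, plus planar complements (such as O–C–N) that are
exactly determined by them. This guarantees the zero-deviation oracle is
exact rather than approximate; the cost is that a handful of
branch angles (e.g. CG1–CB–CG2) are not audited, and the exact inclusion
list of the historical validators cannot be verified anyway.

# The synthetic-data generator

`build_ideal_peptide()` constructs peptides atom-by-atom in internal
coordinates (the NeRF construction) using *the same* target tables the
validators read, so every constructed bond and angle equals its reference
value to machine precision. Backbone torsions default to an extended
β conformation (φ = −120°, ψ = 130°), which is clash-free for all
sidechain defaults; sidechains use common rotamers (Ile mt, proline ring
torsions solved numerically so the closing N–CD bond and CA–N–CD angle
land exactly on target). What the generator does *not* emulate: real
ring-closure strain (the His/Phe/Tyr/Trp ring-closing bond deviates from
its target by under 0.02 Å because the reference values are not perfectly
ring-consistent — zero-deviation tests therefore use acyclic sequences),
thermal disorder, alternate conformations, solvent shells, or crystal
packing. A green test on these fixtures establishes that the *rules* are
implemented exactly; it does not establish agreement with any particular
deposited structure.

Noise fixtures rebuild the peptide with each internal coordinate
displaced by `k·σ·z` (z standard normal under a fixed seed, drawn
identically for every k, making RMS Z exactly linear in k for a fixed
seed), or by a deterministic `k·σ` shift for exact recovery tests.
`inject_contact()` translates a whole residue rigidly so one atom pair
lands at an exact distance ratio, and raises if any unintended contact at
ratio ≤ 0.8 appears. `build_network_toy()` docks acceptor fragments along
computed H directions so that the known optimum (2 hydrogen bonds for the
Asn flip, a full Ser→water→acceptor chain, the HID tautomer for the His
toy) is forced by construction and verified by brute-force enumeration.

# Numerical choices and degenerate inputs

* Classification boundaries are inclusive with a 1e-9 guard against
  floating-point rounding at the printed thresholds.
* Altloc ties (equal occupancy) keep the first-listed conformer;
  selection is idempotent and blank-altloc atoms always survive.
* Only the first MODEL of a multi-model file is read (with a warning).
* Modified amino acids carrying an N/CA/C backbone count as polymer
  residues; waters and other heteroatoms never do. A model with zero
  polymer residues is an audit error; per-100 values are absent rather
  than infinite.
* Unknown residues get distance-fallback bonds at `0.6 × (r1 + r2)`;
  hydrogens bond only to their nearest heavy atom, so H degree is always
  exactly one.
* PDB output uses fixed 8.3 coordinate fields (round trips preserve
  coordinates to 1e-3 Å) and hybrid-36 serials above 99999 (or an error,
  per option).
* X–H bond lengths are nuclear (C–H 1.090, N–H 1.010, O–H 0.960, S–H
  1.340 Å) because the positions being emulated come from
  molecular-mechanics conventions; the table is user-overridable.

# Known limitations

* No crystallographic symmetry expansion: contacts across symmetry mates
  are invisible (matching the audited convention, but a limitation for
  tightly packed lattices).
* The donor–acceptor exclusion is purely role-based; it can suppress a
  genuine clash between polar atoms that cannot actually hydrogen bond
  for geometric reasons.
* Asp/Glu/His protonation enumeration covers the standard state spaces
  only; ligand protonation, metal coordination and pKa effects are out of
  scope, and nucleic acids have no templates.
* Geometry targets ship as a single parameter set; conformation-dependent
  target libraries are not implemented.
* The stochastic search is exact on all clusters small enough to
  enumerate; for very large coupled clusters global optimality is not
  guaranteed (it is for every cluster the test suite builds).
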