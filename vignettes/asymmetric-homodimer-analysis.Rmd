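---
title: "Detecting asymmetric homodimerization from NMR and structural evidence"
author: "asymdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting asymmetric homodimerization from NMR and structural evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymdimer)
```

## The scientific question

A protein that homodimerizes can do so symmetrically — the two protomers
related by an exact two-fold (C2) rotation — or asymmetrically, with the
two protomers in distinct conformational environments. Protein-binding
(Type B) dsRBDs of the Dicer cofactor family dimerize through their
β-sheet face, and the question of whether that dimer is symmetric has
direct mechanistic consequences: backbone hydrogen bonding between
*parallel* β-strands of the two subunits is geometrically impossible in a
C2 dimer, because the two-fold axis misaligns hydrogen-bond donors and
acceptors. A register shift between the strands restores the bonds at the
cost of the symmetry.

`asymdimer` implements the complete chain of solution-NMR and structural
computations by which such asymmetry is established:

1. **Peak doubling.** An asymmetric homodimer in slow exchange shows two
   amide resonances per residue (states A and B) in a 2D (¹H,¹⁵N)
   spectrum; a monomerizing point mutation collapses them to one.
   `pair_states()` pairs doubled peaks and reports singletons.
2. **Compound shift asymmetry.** The per-residue separation of the two
   states, Δδ = √(Δδ_H² + (Δδ_N/6.5)²), localizes the asymmetry;
   `rank_asymmetry()` orders residues by it.
3. **EXSY exchange kinetics.** Exchange spectroscopy cross peaks grow
   with mixing time; `fit_exchange_global()` extracts one global
   two-site rate with `bootstrap_ci()` for uncertainty.
4. **State-labelled intermolecular NOEs.** In a symmetric dimer,
   intermolecular NOEs connect like states (A–A, B–B); in an asymmetric
   dimer they connect unlike states (A–B). `classify_dimer()` turns this
   dichotomy into a verdict; `validate_against_structure()` checks
   contacts and their mirrors against a model.
5. **Interface geometry.** `detect_hbonds()`, `beta_register()`,
   `symmetry_score()`, `buried_fraction()` and `interface_overlap()`
   quantify the hydrogen-bond ladder, the strand register shift, the
   deviation from C2, the buried surface, and whether the two
   overlapping interfaces preclude fibril growth.

Every input can be generated at desk scale by the synthetic-data module,
so the full pipeline is exercised without any external data.

## The two-site exchange model

Slow exchange between states A and B with one-way rates
k_AB and k_BA is modelled on longitudinal magnetization as

$$\frac{d}{dt}\begin{pmatrix} m_A \\ m_B \end{pmatrix}
  = -\begin{pmatrix} R_{1A} + k_{AB} & -k_{BA} \\
                     -k_{AB} & R_{1B} + k_{BA} \end{pmatrix}
    \begin{pmatrix} m_A \\ m_B \end{pmatrix},$$

whose matrix exponential (`two_site_propagator()`, closed 2×2 form)
gives the four EXSY intensities I_AA, I_BB, I_AB, I_BA at each mixing
time. The *global* exchange rate is reported in the standard two-site
convention k_ex = k_AB + k_BA, with k_AB = k_ex·p_B and k_BA = k_ex·p_A
so that detailed balance holds; populations default to p_A = ½, the
equal-populations assumption supported by the near-equal doubled-peak
intensities (`equal_population_check()`).

For equal populations and equal R1, relaxation cancels in the ratio

$$r(t) = \frac{I_{AB} + I_{BA}}{I_{AA} + I_{BB}} = \tanh(k_{ex} t / 2),$$

which is the `ratio_tanh` estimator's model. Two numerical points
matter:

* **Pooling.** The fitted ratio at each mixing time is formed from
  residue-summed intensities, not averaged per-measurement ratios. A
  per-measurement ratio has a noisy denominator (auto peaks decay
  substantially by t = 1 s), and E[x/y] > E[x]/E[y] inflates the
  apparent rate; summing ~60 residues first suppresses that bias to
  negligible levels. This is what lets the percentile bootstrap attain
  near-nominal coverage.
* **`matrix_lsq`.** When the two states relax at different rates the
  ratio model is biased by construction; the full propagator fit (per
  residue amplitude and two R1 values, one shared global rate, separable
  linear amplitude inside a 1-D profile search over k_ex) stays exact
  on noiseless data and is the reference method in that regime.

Uncertainty is a percentile bootstrap resampling *residues* with
replacement (default 1000 replicates): residues are the exchangeable
unit since each contributes a full mixing-time series. The method
produces an asymmetric interval consistent with the published style of
confidence statement for such rates.

## Synthetic data: what it emulates and what it does not

`exsy_sim_config()` defaults are the package's study conditions: 60
residues, 10 mixing times spanning 0.05–1.0 s, k_ex = 0.71 s⁻¹,
p_A = ½, R1 = 1.2 s⁻¹ for both states (a typical amide ¹⁵N R1 at high
field), per-residue amplitudes uniform in [0.5, 2], and additive
Gaussian intensity noise with sd = 2% of the residue amplitude,
truncated at zero. `simulate_doubled_peaklist()` emits two peaks per
residue split by a specified shift-difference table
(`pact_like_truth()` shapes it like a Type B dsRBD construct spanning
residues 239–313 with maxima at the interface strand residues 283 and
285); residues with zero difference collapse to a single merged peak,
mimicking a monomerized mutant.

The generators reproduce the *statistical* structure the analyses
assume — propagator kinetics, peak doubling, state-crossed NOE
labelling, idealized sheet geometry — not spectra. There are no
lineshapes, no peak overlap, no assignment ambiguity, and noise is
independent across peaks. Passing tests therefore demonstrate that the
estimators recover what they model at realistic noise, not that the
pipeline is robust to spectral artefacts.

## Idealized β-sheet dimers

`build_sheet_dimer()` constructs two-chain fixtures from an extended
strand template: 3.4 Å rise per residue, backbone N, H, C, O on the
strand line with amide H and carbonyl O displaced toward alternating
faces (the β pleat), a 0.5 Å CA pleat, and a QB side-chain pseudo-atom
perpendicular to the sheet plane. Chain B is always an exact rigid-body
image of chain A:

* `c2_antiparallel` — two-fold perpendicular to the sheet plane;
  reciprocal inter-chain N–H···O=C pairs form by construction.
* `symmetric_parallel` — two-fold about the strand axis; strands
  parallel and in register. Donor–acceptor x-alignment then requires an
  odd residue offset while face alignment requires an even one, so *no*
  valid bond exists — the symmetry-vs-hydrogen-bonding incompatibility
  as computable geometry.
* `offset_parallel` — the same rotation followed by a strand-axis
  translation of (register_offset − 1) residues. This yields the
  characteristic shifted ladder in which residue i of chain A bonds to
  residues i and i + offset of chain B while its own mirror image does
  not, e.g. (with Loqs-like numbering 430–440 and offset 2) 436_A
  bonded to 436_B and 438_B but 436_B bonded to 434_A and 436_A.

The hydrogen-bond-facing parity is derived from the first residue
number so that landmark residues sit on the bonded face for both the
430-based and 277-based numbering schemes used in examples. The
register offset must be even because the pleat alternates every other
residue; the separation default of 4.1 Å between strand lines puts
N···O near 2.9 Å, the canonical β-ladder distance.

**Register offset convention.** `beta_register()` reports the register
shift as the largest |j − i| over inter-chain bridged residue pairs.
In the idealized shifted ladder each rung links residue i to both i +
offset − 2 and i + offset on the partner strand, so the *modal* offset
is boundary-dependent and ambiguous, while the maximum is well-defined,
chain-swap invariant, and equals the configured shift. The `symmetric`
flag tests whether the bridged pairing is an involution under chain
swap — true for the antiparallel C2 ladder, false for any shifted
parallel ladder.

**Swap-RMSD.** `symmetry_score()` superposes chain A onto chain B
(Kabsch on sequence-equivalent CA atoms), applies the transform to the
whole dimer, swaps chain labels and measures the RMSD to the original.
For an exact C2 dimer the transform is an involution and the score is
0; a one-residue register shift already contributes twice the 3.4 Å
rise along the strand axis, so the 1.0 Å classification threshold
separates the regimes by a wide margin.

## Surface burial and interface overlap

SASA is Shrake–Rupley with a deterministic golden-spiral point set (960
points, probe 1.4 Å, Bondi-style element radii). Burial per residue is
(SASA_isolated − SASA_complex)/SASA_isolated, clamped to [0, 1] and
averaged between the two subunits; interface membership uses a burial
threshold of 0.1 per chain (the continuous burial map carries no
canonical cutoff; 0.1 cleanly separates strand-face from solvent-face
residues in the fixtures). Because the same numeric surface is used on
both sides of the difference, point-sampling error largely cancels.

Interface overlap — |S_A ∩ S_B| / min(|S_A|, |S_B|) on the common
residue numbering — captures the fibril argument: an asymmetric dimer
uses two different surfaces, and only if those surfaces overlap is a
third protomer excluded, capping growth at the dimer. Overlap below
0.25 is reported as fibril-capable (the situation described for
HYL1-like interfaces, where disjoint asymmetric surfaces would permit
unbounded polymerization).

## NOE conventions

Distance cutoff 5.5 Å between protons or pseudo-atoms — the upper range
of observable NOEs — with a 1 Å pseudo-atom correction whenever a Q*
(methyl/methylene centroid) atom is involved. Strict classification is
the default because the state-labelling argument is categorical: a
symmetric dimer *cannot* produce cross-state intermolecular NOEs. The
majority mode exists for curated lists that may contain
exchange-mediated artefacts; contacts are otherwise assumed
pre-curated. Mirror validation implements the structural signature of
asymmetry: if (i_A, j_B) is in contact, its mirror (i_B, j_A) must be
violated in a register-shifted dimer.

## Numerical choices and degenerate inputs

* Rate search on [0, 50] s⁻¹ by golden-section; a fit at the k = 0
  boundary (no resolvable exchange, the monomer-mutant situation) warns.
* Measurements with non-positive auto-peak sums are excluded with a
  warning; residues with zero isolated SASA are reported missing rather
  than given a burial fraction.
* Peak pairing uses canonical labels (state A = lower ¹H shift, ties by
  ¹⁵N) so every downstream statistic is invariant under a global A/B
  relabelling — the state names carry no physical meaning.
* More than two peaks on one residue: the closest pair in
  tolerance-scaled shift space (defaults 0.05 ppm ¹H, 0.3 ppm ¹⁵N) is
  kept, the rest reported unpaired.
* Kabsch superposition rejects collinear point sets (rotation
  underdetermined); the sheet fixtures avoid the degeneracy through the
  CA pleat.
* PDB files with insertion codes or altlocs are rejected outright
  rather than silently resolved; synthetic fixtures never need them.

## Problem sizes

The test suite and the acceptance script run the exchange analysis at
60 residues × 10 mixing times with 1000-replicate bootstraps, the
coverage study at 200 Monte-Carlo replicates, and the structural stages
on 11-residue-per-strand dimers with 960-point SASA — sizes chosen so
the full suite completes in well under a minute on one core while
keeping every statistical check meaningful.

## Known limitations

* The ratio estimator assumes equal populations and equal R1; unequal
  populations are only handled through the propagator fit, and neither
  method models temperature, pressure or denaturant dependence.
* Idealized strands are flat ladders: no strand twist, no side chains
  beyond a centroid pseudo-atom, hydrogen-bond energetics reduced to
  distance/angle cutoffs (N···O ≤ 3.5 Å, N–H···O ≥ 120°).
* SASA uses a fixed element-radius table and is not parameterized to
  reproduce any particular server's absolute values; conclusions rest
  on burial *fractions* on the package's own fixtures.
* `percent_identity()` compares pre-aligned sequences only — it
  performs no alignment, and interface identity statements require an
  explicit position mask for the residue set of interest.
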