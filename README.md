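# asymdimer

Symmetric or asymmetric? `asymdimer` answers that question for protein
homodimers from solution-NMR and structural evidence, the way it is
answered for the protein-binding (Type B) dsRBDs of the Dicer cofactor
family: peak doubling in 2D (¹H,¹⁵N) spectra, compound chemical-shift
asymmetry profiles, global two-site EXSY exchange kinetics, state-labelled
intermolecular NOEs, and the geometry of the inter-subunit β-sheet
(hydrogen-bond ladders, strand register, C2 swap-RMSD, buried surface and
interface overlap). A synthetic-data module generates every input at desk
scale, so the whole pipeline runs and is tested without external data.

## The core computations

* **Two-site exchange.** Longitudinal magnetization evolves under
  `dm/dt = −K m` with
  `K = [[R1A + k_AB, −k_BA], [−k_AB, R1B + k_BA]]`; the EXSY
  auto/cross intensity quadruple is the (closed-form) matrix exponential
  scaled by per-residue amplitudes. With equal populations and equal R1
  the ratio statistic obeys `r(t) = (I_AB + I_BA)/(I_AA + I_BB)
  = tanh(k_ex t / 2)`, with `k_ex = k_AB + k_BA` the global rate.
  `fit_exchange_global()` fits `k_ex` by pooled-ratio least squares (or a
  full propagator fit for unequal R1); `bootstrap_ci()` resamples
  residues for a percentile 95% interval.
* **Compound shift asymmetry.** `Δδ = sqrt(ΔδH² + (ΔδN/6.5)²)` per
  paired residue; `rank_asymmetry()` localizes the dimer asymmetry.
* **NOE state logic.** Intermolecular NOEs in a symmetric homodimer can
  only connect like states (A–A/B–B); cross-state contacts (A–B) prove
  asymmetry. `classify_dimer()` applies the rule;
  `validate_against_structure()` measures each contact and its mirror
  (i_B, j_A) — satisfied contact, violated mirror is the register-shift
  signature.
* **Interface geometry.** Shrake–Rupley SASA burial, geometric
  N–H···O hydrogen-bond detection, β-strand register and orientation,
  Kabsch-based swap-RMSD against exact C2, and interface-overlap
  (fibril-capability) analysis.

## Worked example

```r
library(asymdimer)

dir <- tempfile()
cfg <- make_demo(dir, seed = 1)   # writes peak list, EXSY table, PDB, NOEs
bundle <- run_pipeline(cfg)
bundle
#> asymdimer report bundle
#> List of 8
#>  $ exchange              :List of 2
#>   ..$ k_ex: num 0.715
#>   ..$ ci95: num [1:2] 0.692 0.739
#>  $ top_asymmetry_residues: int [1:5] 283 285 302 305 301
#>  $ dimer_verdict         : chr "asymmetric"
#>  $ register              :List of 3
#>   ..$ orientation      : chr "parallel"
#>   ..$ offset           : int 2
#>   ..$ symmetric_pairing: logi FALSE
#>  $ swap_rmsd             : num 4.81
#>  $ symmetry_class        : chr "asymmetric"
#>  $ interface_overlap     : num 1
#>  $ fibril_capable        : logi FALSE
```

Reading the summary: the EXSY stage recovered a global exchange rate of
0.715 s⁻¹ (95% bootstrap CI 0.692–0.739) from the simulated series whose
true rate is 0.71 s⁻¹; the largest chemical-shift differences between the
two states fall on residues 283 and 285, the interface strand; the NOE
contacts are all cross-state, so the dimer is asymmetric; the structural
stage finds a parallel inter-subunit β-ladder shifted by two residues in
register (hence asymmetric pairing and a 4.8 Å swap-RMSD from exact C2);
and the two binding surfaces overlap completely, so the asymmetric dimer
cannot polymerize into fibrils.

Individual stages are plain functions:

```r
op <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                           resid_start = 430))
detect_hbonds(op)[, c("donor_chain", "donor_seqnum",
                      "acceptor_chain", "acceptor_seqnum")]
#> row 4:  A 436 -> B 436      # the shifted-ladder topology:
#> row 10: B 438 -> A 436      # 436_A bonded to 436_B and 438_B,
#> row 9:  B 436 -> A 434      # 436_B bonded to 434_A and 436_A
```

A thin shell wrapper over the same functions lives at
`inst/scripts/asymdimer-pipeline.R`
(`Rscript asymdimer-pipeline.R demo --out-dir DIR --seed 1`).

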