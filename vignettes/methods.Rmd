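---
title: "Methods: partition-based energy features and ensemble prediction of binding-affinity changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partition-based energy features and ensemble prediction of binding-affinity changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `pnimut`, its assumptions, the
parameters that matter, the synthetic data generator, and the numerical and
design choices a maintainer should know about. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## Problem and model

A missense mutation in a DNA- or RNA-binding protein changes the binding free
energy of the complex by ΔΔG = ΔG~mutant~ − ΔG~wild-type~ (kcal·mol⁻¹,
positive = weakened binding). `pnimut` estimates ΔΔG by regression and flags
mutations with ΔΔG ≥ 1 kcal·mol⁻¹ ("hotspots", i.e. significantly
affinity-decreasing) by classification. Protein–DNA mutations (MPD) and
protein–RNA mutations (MPR) get separately configured models because the two
interaction classes respond differently to mutation.

The inputs are: wild-type and mutant complex structures (PDB), per-residue-pair
five-term energy decompositions (total, electrostatic, van der Waals, polar
solvation, nonpolar solvation) for both states, PSI-BLAST-layout conservation
profiles, and a mutation table. The energy engine itself is out of scope:
decomposition tables are a documented CSV dialect produced externally or by
the built-in generator, tagged with the GB model that produced them
(HCT/OBC1/OBC2/GBn1/GBn2, or `synthetic`).

### Energy feature groups

Working from the per-pair decomposition, each feature group sums pair
energies over a geometric partition; every group is computed per term (5
terms), for the wild type and as mutant-minus-wild-type differences, giving
vector lengths 10 (EWC), 60 (ETOR), 60 (EPP), 20 (EINI), 30 (EPI):

* ETOR partitions the target residue's pair energies with other protein
  residues by minimum heavy-atom distance into shells 0 (the target's own
  self-entry), (0,3], (3,4], (4,5], (5,6], (6,∞) Å. Shell boundaries are
  half-open at the upper end: a residue at exactly 3.0 Å belongs to (0,3].
  The source material lists the shells without a boundary convention; the
  half-open choice is ours and is centralized in one constant.
* EPP uses the same shells but sums *residue energies* (a residue's
  self-entry plus all its pair energies with every residue and nucleotide).
* EINI splits all table entries into interface vs non-interface. The
  interface is defined by the heavy-atom contact rule: a residue and
  nucleotide are in contact when their minimum heavy-atom distance is
  strictly below 5 Å. An entry is interfacial when *both* of its monomers are
  interface members (self entries of members included); everything else,
  including pairs that straddle the boundary, is non-interface, so the two
  partitions always sum to EWC.
* EPI splits the interfacial entries by monomer kinds
  (residue–residue / residue–nucleotide / nucleotide–nucleotide); self
  entries join their same-kind partition.

These definitions give exact conservation identities (ETOR shells sum to the
target's protein-pair energies; EPP shells to the protein residue-energy
total; EINI partitions to EWC; EPI partitions to the EINI interface), which
the acceptance suite checks to 10⁻⁶ kcal·mol⁻¹ on random tables.

Interface membership is computed on the wild-type structure and reused for
the mutant state by default (`interface_per_state = TRUE` recomputes it),
since the source material does not state per-state recomputation and reusing
wild-type membership keeps wild-type/mutant partitions aligned.

### Nonenergy feature groups

Seventeen groups. Solvent accessibility uses an in-package Shrake–Rupley
implementation: deterministic golden-spiral sphere sampling, probe 1.4 Å, 960
points by default (240 in the pipeline default for speed; determinism holds
for any fixed count), Chothia-style van der Waals radii, heavy atoms only.
The unbound state is the protein chains extracted in place (no
re-minimization). Relative accessibility divides by the area of the residue
extracted in isolation, per atom category. This isolated-residue reference
(rather than tabulated Gly-X-Gly/Ala-X-Ala values) is a deliberate package
convention: it is self-consistent, exactly reproducible, and applies equally
to real residues and to the generator's pseudo-atom residues; its RSA values
run slightly lower than NACCESS-style tables because an isolated residue
exposes the peptide-bond faces. Glycine's sidechain categories are zero by
convention.

Residue geometric locations (interior / surface / support / rim / core)
follow the bound/unbound relative-accessibility scheme with a 25% exposure
threshold: interior and surface lose no area on binding (split by exposure);
support is buried in both states but loses area; rim stays exposed; core
goes from exposed to buried. The exact thresholds are centralized and
documented as retunable.

Hydrogen bonds are geometric: donor–acceptor heavy-atom distance ≤ 3.5 Å,
and, when the donor's antecedent (nearest bonded heavy atom < 1.8 Å) is
resolvable, an antecedent–donor–acceptor angle ≥ 90°; hydrogens are not
required. Donor/acceptor typing uses curated atom-name tables for standard
residues and nucleotides with an element fallback (N → donor, O → acceptor);
this is a deliberate approximation of classic hydrogen-bond software
defaults, not a bit-exact reimplementation. Contact features reuse the 5 Å
heavy-atom cutoff (no separate value is stated for them in the source
material): CFAA/CFNA are (number of interacting amino-acid/nucleic-acid
monomers, atomic contacts per interacting monomer), and the IR- variants are
exact sums over interface residues — as are IR-dASA, IR-dRSA, IR-NHB and
IR-ENDES, a property the tests assert.

Conservation is the Jensen–Shannon divergence (mixture weight ½, log base 2,
hence bounded in [0,1]) between a position's weighted-observed-percentage
distribution and BLOSUM62 background frequencies, without a sequence window.
All-zero profile rows fall back to the background.

The seven knowledge-based interface scores are a provider slot: their
original definitions live in external software that this package does not
reimplement. The default provider computes three package-defined scores —
sidechain burial against the nucleic acid, a fixed residue-type
nucleic-acid-interface propensity table, and the JSD conservation score —
and zero-fills the remaining four; any function returning a numeric 7-vector
can be registered with `set_endes_provider()`.

### Selection, ensemble, validation

Random forests (the `randomForest` package) with 500 trees, default `mtry`,
unlimited depth, seed 2021: the learner is named in the source material but
hyperparameters are not, so we fix conventional defaults and a seed for
reproducibility. Group-wise sequential backward selection starts from all
candidate groups and removes, per round, the group whose removal most
improves the LOCOV criterion (PCC for regression; AUC for classification —
the classification criterion is our extension since the source procedure is
described for regression), halting when no removal improves it; removal ties
break to the lexicographically smallest group name.

The ensemble operates on model *predictions* (weighted-output form): for MPD,
Energy = α·ETOR + (1−α)·EPI with α = 0.4 (HCT-tagged tables); for MPR the
EWC prediction passes through. The final score is β·Energy + (1−β)·Nonenergy
with β = 0.6 (MPD) and 0.5 (MPR). `grid_search_weight()` tunes a weight over
the 11-point grid 0, 0.1, …, 1, ties to the smaller weight. α and β are tuned
sequentially (α first on the energy components, then β) — whether the
original tuning was joint or sequential is not stated, and the sequential
order is cheaper and reproduces planted weights exactly in the tests.
Classification reuses the same architecture with positive-class
probabilities and a 0.5 probability threshold for the MCC table (no
threshold is stated in the source material).

Validation is leave-one-complex-out: one fold per complex, metrics on pooled
out-of-fold predictions, so no complex contributes to both training and test
of any fold.

## The synthetic generator

`synthetic_spec()` defaults define the package's benchmark conditions: 40
complexes × 6 mutations, ΔΔG = planted effect + N(0, 0.3²) kcal·mol⁻¹ with
the effect drawn uniformly from [−1, 3] (a realistic spread: mostly
destabilizing, some stabilizing, range of a few kcal·mol⁻¹), 10-residue
chains with every second residue designated interfacial. Toy complexes are
idealized straight strands: a peptide backbone with code-dependent
pseudo-sidechains facing an idealized nucleic strand whose nucleotides sit
above the designated interface residues; interface residues extend a terminal
sidechain atom so that exactly the designated set satisfies the 5 Å rule,
with ≥0.8 Å of margin on both sides of the cutoff under the deterministic
coordinate jitter. Energy tables draw pair energies from a distance-decaying
kernel with per-term noise and exact term closure; the mutant table perturbs
the mutated residue's self entry by the planted effect, so the whole-complex
energy difference equals the effect exactly. Profiles are Dirichlet-like with
sharpened rows at interface positions.

What the benchmark demonstrates: that the pipeline recovers a planted,
feature-expressible signal through the full
structures→tables→features→forest→ensemble path under LOCOV, determinately
and without leakage. What it does not demonstrate: performance on real
complexes — real energetics are not distance-kernel draws, real interfaces
are not straight strands, real ΔΔG is not linear in any single feature
group, and real helices, grooves and minimization artifacts are absent. The
acceptance thresholds (PCC ≥ 0.8 noisy, ≥ 0.95 noiseless) are therefore
pipeline-correctness checks, not accuracy claims.

Problem sizes in the tests are scaled to what the checks need: micro
complexes of 3–11 monomers for exact oracles, 8–12 complexes for pipeline
round trips, and the full 40 × 6 benchmark only where parameter recovery is
the point.

## Numerical choices and degenerate inputs

* Distances: minimum heavy-atom distance between monomers everywhere
  (the source material says "distances between residues" without an atom
  convention; the heavy-atom minimum matches its contact rule). Strict `<`
  at the 5 Å cutoff ("less than").
* Keys are author numbering with insertion codes, `chain:resno[icode]`;
  altloc resolution keeps the highest occupancy, ties to first encountered;
  first model only; HETATM (waters, ions, ligands) excluded from all
  geometry; PDB only (mmCIF is a non-goal).
* Decomposition tables are canonicalized to unordered pairs (directions
  summed); term closure |total − Σ components| ≤ 10⁻³ kcal·mol⁻¹ is enforced
  on read (configurable; the identity is approximate for real engines and
  exact for synthetic tables).
* Empty interface → all-zero interface partition with a warning, not an
  error. A residue with no partner has average atomic contact strength 0.
  A mutation at a position whose structure code mismatches the stated
  wild-type is rejected with a reason (mirroring dataset-curation
  elimination), not an error.
* Forest `call` slots are stripped before serialization so repeated seeded
  runs produce byte-identical model bundles.
* ΔΔG difference direction is mutant − wild-type throughout, so positive
  feature differences align with destabilization and the ΔΔG ≥ 1 hotspot
  rule is boundary-inclusive (1.0 is a hotspot; 0.999 is not).

## Known limitations

* The default interface-score provider implements three of the seven scores
  with package-defined formulas; the other four are zero until an external
  provider is registered.
* The isolated-residue RSA reference shifts absolute RSA values relative to
  tripeptide-based tables; location-class boundaries were chosen for the 25%
  convention and may warrant retuning for NACCESS-compatible inputs.
* Hydrogen-bond detection without hydrogens over-counts relative to
  explicit-H criteria in dense polar clusters.
* MPD ensembles require exactly two energy groups (the α-combination); more
  general energy ensembles would need a different combination rule.
* Real-data performance depends entirely on the external energy engine's
  decomposition quality; nothing in the package validates that engine.
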