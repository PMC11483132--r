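---
title: "Mapping mutations onto protein structures: methods and design"
author: "MutStruct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mutations onto protein structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MutStruct)
```

# The problem

A recurrent somatic substitution such as R248Q in a tumour-suppressor gene
is only interpretable against the protein's three-dimensional structure:
the same notation can describe a buried core residue whose loss unfolds the
domain, a residue hydrogen-bonded to DNA, a zinc ligand, or a surface
position of no structural consequence. MutStruct automates the mapping from
a mutation table (gene symbol, protein-change notation, sample identifiers)
to per-structure, per-chain structural context, over every experimental
structure available for the protein plus a predicted model for the regions
experiments do not cover.

The pipeline has five stages, each usable on its own: structure parsing,
residue renumbering, solvent accessibility, distance-based context
annotation, and mutation aggregation/statistics.

# Structure model and parsing

`parseStructure()` reads PDB and mmCIF through *bio3d* into a single flat
atom table (the `StructureModel` S4 class). Normalisations applied at parse
time, in this order:

* **Multi-model files** keep model 1 only (each deposition is treated as
  one structure; NMR ensembles are not averaged).
* **Alternate locations** resolve to the highest-occupancy conformer, ties
  broken by altloc letter, per (residue, atom name) — so altloc resolution
  can never change the residue count.
* **Hydrogens** are parsed but flagged, and excluded from all SASA and
  distance computations; most X-ray depositions lack them, and including
  them where present would make cutoffs incomparable across entries.
* **Occupancies** outside [0, 1] are clamped with a warning; blank element
  symbols are inferred from atom names with a warning.
* Every residue receives one **category**: `protein` (standard plus a
  bundled modified-residue table, e.g. MSE → M), `nucleic`
  (DA/DC/DG/DT/DU and the RNA codes, configurable), `water`, `metal`
  (monoatomic ion component ids), or `ligand` (everything else, including
  unknown codes, which are logged). Monoatomic ions (NA, MG, CA, K, CL,
  ...) are deliberately *not* ligands: the ligand-site annotation should
  reflect small-molecule binding, and zinc has its own annotation.

Predicted models are distinguished only by a user flag (`source =
"predicted"`); their B-factor column is read as pLDDT. The package never
downloads anything: structures, models and mutation tables are local files.

# Residue renumbering

Author residue numbering in deposited structures rarely matches UniProt
coordinates, and a mutation's stated position is a UniProt position. Each
protein chain's observed one-letter sequence is aligned to the reference
with `Biostrings::pairwiseAlignment` in global–local mode: the chain is
aligned end to end while the reference may overhang freely on both sides.
Scoring is BLOSUM62 with gap opening 10 and gap extension 0.5 (a gap of
length $L$ costs $10 + 0.5L$). These are conventional anchoring parameters;
for the near-identical sequences this task sees, the optimum is insensitive
to them. Letters outside the BLOSUM62 alphabet (U, O) score as X.

From the alignment, every structure residue in a both-non-gap column maps
to that column's 1-based reference position (`buildResidueMap()`), giving
an injective per-chain map. Two deliberate choices:

* **Mismatched aligned pairs are mapped, not dropped** — crystal constructs
  often carry engineered substitutions at exactly the positions mutation
  analysis cares about. They are counted (`nMismatches`) and each mapped
  row records both observed and reference residues.
* **An identity floor of 0.30** (configurable) rejects chains that likely
  belong to a different protein; below that, a map would be noise.

Alignment ambiguity is real: when the residues flanking a deletion repeat
the residues just inside it, several alignments score identically and the
chosen gap placement is the aligner's deterministic tie-break, not
biological truth. The test suite therefore plants deletions with
distinguishable edges when it demands exact recovery.

# Solvent accessibility and burial

`shrakeRupley()` implements the classic test-point algorithm: $n$ points
(default 960) are spread over each atom's probe-expanded sphere by a
deterministic golden-section spiral, and the per-atom area is

$$A_i = \frac{\text{unoccluded points}}{n} \; 4\pi (r_i + r_p)^2$$

with probe radius $r_p = 1.4$ Å (water). Radii come from a bundled
plain-text element table (Bondi/Mantina single-element values: C 1.70,
N 1.55, O 1.52, S 1.80, ...), overridable per call; an element without a
radius is an error unless a default is supplied. Waters and hydrogens are
excluded both as scored atoms and as occluders. SASA is computed on the
assembly as given in the file, so dimer partners, nucleic chains and
ligands occlude — the single per-residue value used for classification
reflects the biological context of that entry.

Quadrature properties the tests pin down: an unoccluded sphere is exact; a
fully caged atom scores exactly 0; per-residue areas are exact sums of atom
areas; adding an occluder never increases any other atom's area; and
per-residue areas agree within 5% with an independent implementation
(biotite's Shrake–Rupley, same radii) at 960 points. 960 points keeps a
~2500-atom complex under half a minute in pure R; `nPoints` can be lowered
to ~100 for quick passes.

Relative accessibility divides the residue area by its type's theoretical
maximum in an extended Gly-X-Gly tripeptide (Tien et al. 2013 values,
bundled as text, keyed by one-letter code; modified residues normalise by
their parent). Unknown residue types get an `NA` marker, never a silent
zero. Burial classes follow the 25/80 convention **on the relative scale**:

* RSA < 25 → `core`
* 25 ≤ RSA ≤ 80 → `noninterface` (both boundaries inclusive)
* RSA > 80 → `exposed`

Two notes. First, absolute thresholds of 25/80 Å² would misclassify large
residues, so the thresholds are interpreted as percentages; 25/80 are
standard relative-accessibility breakpoints. Second, highly accessible
residues are sometimes called "interface residues" in solvent-accessibility
nomenclature; this package labels the class `exposed` because its interface
calls are distance-based and independent of SASA.

# Distance-based context annotation

All four annotations are minimal heavy-atom distances between a protein
residue and a target set:

| context | target atoms | cutoff |
|---|---|---|
| `ligand_site` | ligand-category residues | 6 Å |
| `dimer_interface` | protein atoms of a *different* chain | 5 Å |
| `dna_interface` | nucleic residues (DNA and RNA alike) | 5 Å |
| `zinc_site` | ZN ions | 5 Å |

The engine (`findNeighbors()`) bins atoms into a uniform grid with cell
size equal to the cutoff and scans the 27-cell neighbourhood, which is
provably equivalent to exhaustive all-pairs search; the tests assert
equality against an $O(N^2)$ oracle on randomized clouds and on fixture
complexes. Flags are independent booleans — a residue can be at a DNA
interface and a zinc site simultaneously — and each true flag carries the
minimal distance and the partner identities (ligand component ids, partner
chain ids). Assemblies are used as given in the file; no symmetry mates are
generated, so interfaces present only in the crystal lattice or in a
biological assembly not stored in the file are not seen.

# Mutation tables, frequencies, disorder

`parseProteinChange()` accepts bare (`R248Q`), HGVS one-letter
(`p.R248Q`) and HGVS three-letter (`p.Arg248Gln`, case-insensitive)
substitutions, plus nonsense (`R306*`, `p.Arg306Ter`). Synonymous,
frameshift, deletion, insertion, duplication, delins and splice-like
notations are *rejected with a typed reason*, not an exception, so the
pipeline can tally skips; the skip log is part of the output.

**Frequency** is defined as count / total accepted missense+nonsense
observations for the gene, after counting each (sample, mutation) pair at
most once when sample identifiers are present (COSMIC exports repeat
samples across studies). Frequencies over unique records therefore sum to
exactly 1. Other prevalence definitions (per-tumour-type, per-study) exist;
this one is stated rather than guessed, and is comparable within a gene.

`validateAgainstReference()` marks each record `consistent`, `mismatched`
or `out_of_range` against the reference sequence — mismatches are reported,
never dropped.

**Coverage** counts, per reference position, the number of *distinct
structures* whose maps cover it (a homodimer's two chains count once), and
reports maximal uncovered segments. **Disorder** is called from the
predicted model: a position is disordered when its residue's mean atomic
pLDDT is below 50. pLDDT-based calls are the standard proxy for predicted
models; 50 separates the "very low" confidence band, and a stricter 70 is
available via `plddtThreshold`. Sequence-based disorder predictors are out
of scope. The disorder-mutation percentage is reported half-up to one
decimal (134 of 752 unique mutations → 17.8).

# Pipeline semantics

`runPipeline()` maps every unique mutation onto every experimental
structure chain covering its position — one row per (mutation × structure ×
chain), because a homodimer's two copies can differ in context — and falls
back to the predicted model only for positions no experimental structure
covers. Accepted = covered + uncovered, and both counts are logged and
reported; per-stage counts (parsed, renumbered, scored, mapped, skipped)
make silent data loss impossible. Outputs are a fixed-header TSV per
structure, a JSON summary (coverage, disorder, per-context unique-mutation
counts at both per-structure and per-chain granularity), and the skip log.
Runs are deterministic: identical inputs give byte-identical outputs.

# The fixture generator

Real inputs require database downloads, so the `fixtures` module generates
everything synthetically, with machine-readable ground truth:

* **Protein chains** are ideal α-helices (rise 1.5 Å, twist 100°/residue,
  Cα radius 2.3 Å) with minimal side-chain stubs — Cβ 1.53 Å radially
  outward plus one placeholder Cγ for residues larger than alanine. No
  rotamers, no physical energetics: context distances are planted against
  specific atoms, so stub geometry exercises every cutoff rule.
* **DNA** is an idealised duplex (rise 3.4 Å, twist 36°/bp, three
  pseudo-atoms per nucleotide). **Zinc** and a three-atom **ligand** are
  placed by translating along the closest-pair direction until the minimal
  heavy-atom distance to the protein equals the request exactly; a spec
  whose anchor cannot be the nearest residue (e.g. a planted distance
  beyond the flagging cutoff) is a generation error, not a silent
  approximation.
* Ground-truth context flags are recomputed post-generation by an
  exhaustive distance check that shares no code with the package's grid
  search; downstream tests consume only that shipped truth.
* Ground-truth burial classes for planted positions come from an
  independent Monte-Carlo SASA (random sphere points, fixed seed); classes
  within 3 percentage points of the 25/80 boundaries are left unasserted,
  since two correct quadratures can legitimately disagree there.
* `caseStudyFixture()` assembles the full scenario: a 300-residue
  reference, a homodimer (chains covering positions 94–292, one chain
  renumbered with an offset) with docked DNA, zinc and ligand; a
  full-length predicted model whose pLDDT marks positions 1–93 and 294–300
  (a third of the sequence) disordered; and a mutation table with 20 unique
  substitutions — including the six classic TP53 hotspot notations R248Q,
  R248W, R273H, R273C, R282W, G245S as parse inputs — plus synonymous,
  frameshift and deletion rows for the skip log.

What the fixtures do **not** emulate: real secondary-structure diversity,
side-chain packing, crystallographic artefacts (altloc clouds, partial
occupancy, missing density mid-chain), or sequence-dependent DNA geometry.
Passing the suite shows the mapping, scoring and counting machinery is
correct on known geometry; it does not validate biological conclusions on
any particular real protein.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by construction:
random neighbor-search clouds use 100–500 atoms over 100 replicates;
renumbering recovery uses 100 corrupted 90-residue fixtures; SASA
cross-validation uses a 30-residue helix and a 60-residue dimer at 960
points; the end-to-end scenario is a ~2500-atom complex plus a 300-residue
predicted model and a 319-row mutation table. Distance comparisons use
exact closed-form arithmetic (squared distances; ties at the cutoff are
inclusive, `<= cutoff`). Percentages shown to users are rounded half away
from zero at one decimal; internal values are never rounded.

# Known limitations

* Chains mapping to multiple UniProt accessions (chimeras) are not split;
  the identity floor rejects them instead.
* No biological-assembly generation: interfaces are judged on the chains in
  the file.
* Disorder requires a predicted model; without one the pipeline reports no
  disorder statistics rather than substituting a sequence-based predictor.
* The SASA implementation targets correctness and auditability over speed;
  very large complexes (>10⁴ heavy atoms) will be slow in pure R.
* Mutant structures are not modelled; the mapping describes the wild-type
  environment of the mutated position.
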