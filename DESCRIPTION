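Package: MutStruct
Title: Structural Mapping and Context Classification of Protein Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps protein-level somatic mutations onto experimental and
    predicted three-dimensional structures. Parses PDB and mmCIF coordinate
    files into a uniform structure model, renumbers structure residues to
    UniProt positions by semi-global sequence alignment, computes
    solvent-accessible surface area with a Shrake-Rupley implementation and
    classifies residue burial, annotates ligand-binding sites, dimer
    interfaces, protein-DNA interfaces and zinc-coordination sites by
    heavy-atom distance cutoffs, parses COSMIC-style mutation tables with
    HGVS protein-change notation, and reports structural coverage, intrinsic
    disorder (via pLDDT) and mutation-frequency statistics. Includes a
    fully ground-truthed synthetic fixture generator so the whole pipeline
    is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralPrediction, SomaticMutation, Software
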