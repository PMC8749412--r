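Package: odltools
Title: Mass-Spectral Acetyl-Site Localization and Genomic Profiling for
    Odilorhabdin Peptide Antibiotics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural and genomic analysis of odilorhabdins
    (ODLs), nonribosomal linear peptide antibiotics carrying
    nonproteinogenic residues and a diaminobutane (Dbt) C-terminal amide.
    Provides an extensible residue-chemistry registry with monoisotopic and
    nominal mass calculus, theoretical b/y fragment-ion ladders including
    the C-terminal diamine neutral losses characteristic of ODLs,
    tolerance-based matching of observed MS/MS peak lists, enumeration of
    primary-amine acetylation sites, and rank-based localization of
    N-acetyl modifications such as those installed by the self-resistance
    acetyltransferase OatA. A seeded synthetic-spectrum generator supports
    localization benchmarking. A companion genomics module covers
    ANI-derived distance matrices, species clustering at a fixed distance
    cutoff, neighbor-joining and UPGMA trees, identity/coverage ortholog
    calling, and microarray-style gene presence/absence profiling with
    Gower (simple matching) similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'atoms.R'
    'residues.R'
    'peptide.R'
    'fragments.R'
    'localize.R'
    'annotate.R'
    'genomics.R'
    'io.R'
    'simulate.R'
    'zzz.R'
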