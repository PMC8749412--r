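---
title: "Methods: acetyl-site localization and genomic profiling for odilorhabdins"
author: "odltools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acetyl-site localization and genomic profiling for odilorhabdins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odltools)
```

# The problem

Odilorhabdins (ODLs) are 10-mer linear cationic peptide antibiotics made
by *Xenorhabdus nematophila* through nonribosomal peptide synthetases.
They carry several nonproteinogenic residues — two
α,γ-diamino-β-hydroxybutyric acids (Dab(βOH), written `Dab(bOH)` in
code), D-ornithine, Z-α,β-dehydroarginine (Dha) — and end in a
secondary amide to α,δ-diaminobutane (Dbt) instead of a free acid. The
producer protects itself with a GNAT acetyltransferase, OatA, that
transfers acetyl groups from acetyl-CoA onto the peptide's primary
amines, abolishing ribosome binding. Which amines are hit is a
structure question answered by MS/MS: each acetyl adds 42.0106 Da, and
the b/y fragment ladder pins the shift to specific residues.

`odltools` implements that analysis end to end — residue-level mass
calculus, theoretical fragment ladders, tolerance-based peak matching,
and a rank-based acetyl-site localizer — plus the genomic-distribution
toolkit used to ask where the self-resistance gene lives: ANI-derived
distances, species clustering, NJ/UPGMA trees, ortholog thresholds, and
presence/absence profiling.

# Mass calculus

Residues are registered by elemental formula (residue = amino acid
minus water); monoisotopic and nominal masses are derived from the
formula, never typed in. A validity check keeps any user-supplied mass
within 1e-4 Da of the formula sum. The neutral molecule is

$$M = \sum_i m_i + m_\mathrm{H} + m_\mathrm{cterm},$$

where the C-terminal group contributes OH for a free acid or the
amide-linked diaminobutane unit (C4H11N2, 87.092 Da) for the Dbt
terminus. With the canonical composition this gives 1263.80 Da for
NOSO-95C, matching the reported 1264 Da molecular weight, and the
monoisotopic scale is the one that reproduces the one-decimal fragment
values — the reason it is the package default (reported molecular
weights do not say monoisotopic or average; only monoisotopic
arithmetic is consistent with the printed ladder). Ions use a proton
mass of 1.00728 Da; the electron mass is neglected, which is harmless
at quadrupole precision.

Two modeling choices deserve a note:

* **Dha** is modeled as the arginine residue minus H2 (C6H10N4O,
  154.0855 Da). Only the name "Z-α,β-dehydroarginine" is published; the
  minus-H2 reading reproduces every fragment that spans position 9.
* **Dbt** is a C-terminal group, not an eleventh chain residue. Its
  neutral-loss mass is the free diamine C4H12N2 (88.100 Da), which is
  exactly what the published "(128 + 88)" composite losses require.

```{r}
p <- odlPeptide("NOSO-95C")
c(mono = neutralMass(p), nominal = neutralMass(p, mode = "nominal"))
round(precursorMzOf(p, charge = 2))   # the [M+2H]2+ species
```

# Fragment ladders

Published ion tables for these peptides number the y series so that the
Dbt group counts as one ladder unit: the all-but-Lys1 ion of the
10-residue chain is y10. `ySeries()` therefore runs over n+1 units for
Dbt-amide peptides. b ions cover N-terminal residues only and never see
the C-terminal group. Beyond b/y, the characteristic secondary losses
are generated: a y ion (its span includes the C-terminus) sheds the Dbt
unit as a neutral diamine — 88.10 Da, or 130.11 Da when the terminal
amine is acetylated — and can then shed further C-terminal residues,
each leaving with its own acetyl when modified. The default depth of 2
(Dbt plus one residue) covers the deepest loss used in practice,
Lys10–Dbt11. No a/c/x/z ions and no water/ammonia losses are generated:
the reference annotation never invokes them, and leaving them out keeps
the match space clean. Only singly charged fragments are emitted; the
precursor is the only multiply charged species.

```{r}
tri <- acetylConfig(p, c(2, 3, 10))
ts <- theoreticalSpectrum(p, tri)
tail(ions(ts)[, c("label", "mz")], 4)
```

# Matching and localization

Observed peak lists (MGF or two-column CSV) carry the printed decimal
precision of every m/z. Matching is greedy nearest-first within a
per-peak tolerance: 0.5 Da by default (a quadrupole-scale figure; the
source instrument's true tolerance is unpublished, so the value is a
configuration default, recorded in every call), widened to 1.0 Da for
integer-printed peaks. The widening is forced by the data: reference
tables mix one-decimal values with integer prints like 1178 whose
theoretical counterpart is 1178.7 — a half-unit window would
systematically miss them. Each observed peak pairs with at most one
theoretical ion and vice versa.

The localizer infers the acetyl count k from the precursor shift
(rounding the neutral-mass excess over the unmodified peptide by
42.0106; residuals beyond 1 Da are an error, not a warning — the
spectrum is then simply not an acetyl series of this peptide). A
user-supplied k that contradicts the precursor is overridden with a
warning, never silently. Candidates are all ways to place k acetyls on
distinct amine-bearing residue positions. Localization is deliberately
residue-level: the α- vs ε-amine of Lys1 are mass-degenerate — their
theoretical spectra are identical — so claiming to resolve them would
be dishonest, and the published assignments are themselves
residue-level. Candidates are ranked by matched-peak count, then by
discriminating matches (peaks no other candidate explains), then by
summed absolute error; exact ties are reported as a joint class. The
scoring is deliberately count-based and auditable rather than
probabilistic: no Ascore-style localization statistics are attempted.

On the packaged ion lists the top classes are {Dab(bOH)2} for the
monoacetylated form, {Dab(bOH)2, Dab(bOH)3} for the biacetylated form
and {Dab(bOH)2, Dab(bOH)3, Lys10} for the triacetylated form — the
published assignments. The discriminating ions for the third site are
the diamine-loss fragments (1174.6 and 687.4): a Dbt-acetylated
candidate predicts them 42 Da away.

```{r}
obs <- readPeakList(odlFixture("table2_tri.mgf"))
head(localizeAcetyl(obs, p), 3)
```

`annotateSpectrum()` renders the classic four-column table (ion, m/z,
neutral loss from previous ion, attribution, assigned structure).
Neutral-loss labels use nominal residue masses (Lys = 128,
AcDab(bOH) = 158, "216 (128 + 88)" for the Lys–Dbt pair); the reference
table's occasional "129" for a Lys loss comes from rounding observed
m/z differences and is treated as a display convention, not replicated.

## A note on one printed value

The monoacetylated reference block prints a y5 ion at 635.9 while its
own neutral-loss column (733.5 minus a 97 Da proline unit) implies
636.5, which is also what residue arithmetic gives (636.44). The two
statements cannot both hold; the package reproduces the arithmetic, and
the 635.9 peak is reported in the unassigned trailer rather than
force-matched.

# Synthetic spectra and the benchmark

The generator plants a known configuration, then degrades the
theoretical ladder: Gaussian m/z jitter (default SD 0.05 Da, the scale
of a one-decimal instrument report), uniform peak dropout (default 0.2,
a typical fraction of low-intensity ladder positions lost in a single
scan), and uniform decoy peaks over the scanned range (default 10
across 200–1400 m/z), sampled outside ±tolerance of true ions unless
collisions are explicitly requested (in which case their count is
reported). The precursor always survives and keeps its exact m/z so
that k remains inferable. Everything is driven by an explicit seed and
restores the session RNG state.

What the generator does **not** emulate: intensities (uniform unit —
the localizer never uses intensity), isotope envelopes, charge-state
envelopes, or chromatography. A green recovery benchmark therefore
establishes that the ranking logic is sound against m/z-level noise; it
says nothing about intensity-dependent effects in real data.

`benchmarkLocalization()` reports, per planted configuration and noise
cell, the fraction of replicates in which the planted class is the
unique top rank, with binomial standard errors. In the noiseless limit
recovery is exactly 1 for every plantable configuration with k ≤ 3 —
an exhaustive test in the suite — and degrades monotonically (within
Monte-Carlo error) in dropout and decoy count.

# Genomic distribution toolkit

The genomics module consumes precomputed distances — sketch-based
genome distances correlate with average nucleotide identity as
D = 1 − ANI — and never recomputes alignments or sketches itself.

* `speciesClusters()` forms single-linkage components at an inclusive
  cutoff (default D ≤ 0.06, about 94% ANI, the conventional species
  boundary). Components, not cliques: the published legend speaks of
  clustering "from all-pair distances ≤ 0.06", and the component
  reading is the one that is label-order invariant and
  reproducible.
* `njTree()` is Saitou–Nei neighbor joining (delegated to \pkg{ape};
  the original analysis also used an off-the-shelf NJ implementation).
  Additive matrices are recovered exactly. Negative branch lengths on
  non-additive input are clamped to zero with a warning.
* `upgmaTree()` is implemented in-package so that merge ties break
  deterministically toward the lexicographically smallest member
  labels (generic average-linkage code ties by input order); node
  heights are half the cophenetic distance, so ultrametric inputs are
  reproduced exactly.
* `orthologCall()` applies the inclusive thresholds identity ≥ 70% and
  coverage ≥ 80%. The coverage denominator ("minLrap") is not formally
  defined in the source; the package defaults to the longer of the two
  sequences — the conservative reading of a minimum length-ratio, and
  the one consistent with "over at least 80% of the total length of
  the protein" — with query- or subject-length options.
* `presenceCall()` is a strict threshold: a target is present when at
  least one of its probes exceeds 1000 signal units (1000 itself is
  absent). `gowerBinarySimilarity()` is the symmetric-binary Gower
  coefficient, i.e. simple matching, feeding UPGMA for profile
  dendrograms.

Maximum-likelihood protein phylogenies are out of scope by design: in
the source analysis they were produced with external software, and
distance methods are the procedures actually defined.

```{r}
d <- matrix(c(0, .02, .10, .02, 0, .09, .10, .09, 0), 3,
            dimnames = list(c("Xn1", "Xn2", "Pl"), c("Xn1", "Xn2", "Pl")))
speciesClusters(d)
ape::write.tree(upgmaTree(d))
```

# Numerical choices and degenerate inputs

* Masses: monoisotopic table to 9 decimals; registry validity 1e-4 Da;
  fragment comparisons in tests at the reference precision (±0.15 Da
  one-decimal, ±1 integer).
* Matching: ties on identical absolute error fall to the earlier peak
  (stable, input-order independent after m/z sorting).
* Empty peak lists localize to an all-tied, explicitly `indeterminate`
  ranking; an all-zero area table and out-of-range thresholds are
  errors, not silent zeros.
* Single-residue peptides have an empty b series; y-series secondary
  losses never strip an ion past its last chain residue.
* NJ requires ≥ 3 taxa, UPGMA ≥ 2; distance matrices are validated for
  symmetry, zero diagonal, finiteness and non-negativity on entry.

# Known limitations

* No intensity model, no isotope clusters, no multiply charged chain
  fragments; spectra from other instrument classes may need a
  different tolerance.
* The localizer assumes at most one acetyl per residue position when
  enumerating candidates (matching the published assignments);
  double-acetylation of the two Lys1 amines, while chemically
  conceivable, is outside the candidate space unless configured
  explicitly via site labels.
* Whether OatA acetylates Lys1's α or ε amine is not decidable from
  chain fragments — the package reports the residue class only.
* The genomics module trusts its inputs: it computes no alignments,
  no sketches, and no ANI values.
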