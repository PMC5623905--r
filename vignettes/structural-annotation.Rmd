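---
title: "Spatial annotation of missense variants in protein complexes"
author: "snv3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial annotation of missense variants in protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snv3d)
```

## The problem

A missense variant substitutes one amino acid in a protein. Whether that
substitution matters often depends on *where* the residue sits in the folded
protein: buried in the hydrophobic core, exposed on the surface, or at an
interface with another protein, a DNA molecule or a small-molecule ligand.
Experimentally resolved structures cover only part of any proteome, so the
usual strategy is homology mapping: find resolved structures of homologous
proteins (*templates*), place the variant position into them through a
sequence alignment, and read its spatial context off the template.

`snv3d` implements that strategy end to end: template search with
identity/coverage filters, alignment-based position mapping, per-residue
distance and accessibility annotation, a five-class spatial assignment,
logistic candidate scoring, randomized and resampling controls, differential
pathway scoring, and networks of complexes with mutations in several
subunits. Because public variant archives and the PDB cannot be bundled, the
package ships a synthetic-structure generator that plants interaction
partners at exact distances, giving every downstream stage a ground truth to
be tested against.

## The annotation model

### Template search

A gene's protein sequence is aligned globally (Needleman–Wunsch, BLOSUM62,
affine gap penalties 10/0.5 — the EMBOSS convention) against every protein
chain of the structure library. A chain is kept as a template when

* sequence identity > 0.35 (identical columns over non-double-gap columns),
* the aligned region exceeds half the shorter sequence's length, **or** is
  longer than 50 residues,
* and, when a pluggable external search supplies e-values, e < 1e-5.

Identity `0.35` is the default (`identity_threshold`); `0.90` reproduces the
high-identity re-analysis. Variant positions are walked through the
alignment columns; a position aligned to a template gap is unmapped in that
template. All passing templates are kept — aggregation, not best-template
selection, decides the final annotation.

Coverage is measured against the *shorter* of the two sequences. Note that
with a global aligner a short aligned region inside two long sequences
essentially cannot occur (dissimilar regions align as mismatches), so the
aligned-length branch mainly matters for fragment chains; the filter
arithmetic is tested on hand-crafted gapped alignments.

### Per-residue context

For a mapped residue, the package computes minimum Euclidean distances over
all non-hydrogen atom pairs to: any retained ligand (SLD), protein atoms of
*other* chains, DNA chains, RNA chains; SCD is the minimum over the
macromolecular categories (DNA included — "any other macromolecule").
Ligands are HETATM groups minus a packaged list of crystallographic buffers
(HOH, GOL, EDO, PEG, SO4, ...); metal and halide ions are kept because their
binding sites are functionally relevant; modified amino acids belong to
their chains. Het codes on a user-supplied drug list are retained but
flagged, so a drug-free re-classification (`reclassify_excluding_ligands()`)
can be run and every class flip logged.

Relative solvent accessibility (RSA) is the Shrake–Rupley accessible area of
the residue (probe 1.4 Å, 960 sphere points per atom, Bondi radii) divided
by the residue type's theoretical maximum (Gly-X-Gly scale) × 100. All atoms
of the entry occlude by default — accessibility is computed in the complex,
matching the distance annotations; `occluders = "chain"` gives the
chain-only view for sensitivity checks. Distances use brute-force vectorized
minima over atom pairs: at the scale of single PDB entries (10² – 10⁴ atoms)
this is exact, simple and fast enough that a spatial index would add nothing.

### Five exclusive classes

With the category minima over all templates:

* any partner closer than 5 Å → the contact class of the *smallest*
  distance ("DNA contact", "Ligand contact", "Protein contact");
* otherwise RSA < 16 % → "Core";
* otherwise "Surface".

Both thresholds are strict inequalities and configurable
(`contact_threshold`, `core_rsa`). Exact distance ties are broken by a
documented fixed priority, DNA > Ligand > Protein — the rarest class wins so
that ties never mask scarce signal. The RSA used for the Core/Surface
decision comes from the template providing the overall minimum distance, or
from the best-scoring template when no contact exists (best-quality
evidence). A non-exclusive "contact multiset" additionally records every
category within 5 Å in any template. Unmapped variants form their own
reporting category and are excluded from class fractions.

### Scores

Template quality combines four attributes on a 0–1 scale:

* sequence identity and target coverage, as fractions;
* `res = 1 / (1 + exp(1.5 · resolution − 4))` — midpoint at 8/3 Å;
* `r = 1 − R-value`.

The published form of their combination is not reproduced in the source
material, so the package uses the arithmetic mean (weights configurable) —
monotone, bounded, and reproducing all stated qualitative dependencies.
Contact weights are logistic in the distances, `lig_cont = 1/(1+exp(SLD−10))`
and `chain_cont = 1/(1+exp(SCD−10))`, 0 when the partner category is absent;
the interaction score IS is their maximum, and the per-variant candidate
score is `template_score × IS` (also pluggable). The protein-level combined
score is, per template, the mean candidate score of the gene's variants
mapped in it, maximized over templates — a few high-scoring mutations beat
many low-scoring ones. Pathway (or GO-term) scores are the mean combined
score of the members present in the data; differential scores subtract the
neutral side from the disease side, and ranking them descending gives the
enrichment tables.

## Statistical machinery

* **Bootstrap**: class fractions are resampled with replacement B = 1000
  times; the per-class SD over resamples quantifies sampling noise.
* **Rank-sum**: distance distributions are compared two-sidedly; the exact
  null distribution is used when both samples have ≤ 25 observations and no
  ties, otherwise the tie-corrected normal approximation. Fully tied data
  give p = 1. Ties never get exact enumeration — a deliberate simplification.
* **Randomized controls**: for each gene, the same number of variants is
  re-drawn at uniformly random coding-sequence positions with a uniformly
  random alternative base, rejecting non-missense outcomes (implemented by
  enumerating all missense sites and sampling uniformly — distributionally
  identical to rejection sampling and immune to infinite loops; a gene with
  no missense site raises an error naming it). Positions in the stop codon
  are rejected: a stop-loss is not missense. Randomized variants may
  coincide with original sites; nothing in the procedure excludes them.
* **Template-count matching**: disease proteins are studied more, so they
  have more templates. Controls are drawn from the neutral pool so that the
  per-variant template-count histogram matches the disease set's bin for
  bin (exact integer bins); exhausted bins fall back to ±1, then ±2
  neighbours (logged), and only then to sampling with replacement if
  allowed.
* **Pair proximity**: whether mutated residues in one complex sit closer
  together than chance. The statistic is the mean pairwise distance between
  residue representatives (Cβ, Cα for glycine; a full-atom-minimum variant
  is available); the null redraws the same number of residues per chain
  uniformly without replacement; `p = (1 + #{null ≤ obs}) / (n_perm + 1)`
  with add-one smoothing, so p is never 0 and equals 1 when the mutated set
  is the whole complex. The null and statistic are the package's own design:
  the simplest exchangeable null that preserves per-chain counts.

## The synthetic generator — what it emulates and what it does not

`make_toy_complex()` realizes a declarative spec: extended pseudo-residue
chains (N, CA, C, O plus one pseudo side-chain atom, 3.8 Å Cα spacing),
with designated residues bulged outward and their partner — a small
ligand, a 2 × 3-nucleotide DNA duplex (P/C1'/N1-N9 atom subsets), or a
short protein stub — placed along the outward normal so that the minimum
inter-atomic distance equals the target exactly (the contact atom is
pinned; the rest of the partner is rigidly jittered within 0.04 Å).
Planted core residues are surrounded by a same-chain atom cage (radius
5 Å, 80 atoms, one extra UNK residue), which is invisible to inter-chain
distances but drives RSA below the core threshold. Non-designated residues
are guaranteed ≥ 8 Å from every partner, which requires target distances
≥ 2 Å and planted residues ≥ 2 positions apart (≥ 3 around cages) —
violations fail loudly at spec construction. Residues adjacent to planted
features have deliberately unasserted truth labels.

These structures have realistic *atom counts* but not realistic folds,
packing or chemistry. Passing tests therefore demonstrate that the
annotation machinery — parsing, distance minima, accessibility,
classification, scoring, statistics — is correct, and that the generator's
ground truth is recovered exactly; they do not demonstrate anything about
biological distributions of real variants. Demonstration sizes (6–25
complexes, 40–80-residue chains, 200–500 variants) were chosen as the
smallest sets on which every class and every code path is exercised with
stable statistics.

## Numerical choices and degenerate inputs

* Distances use all non-hydrogen atoms; hydrogens are dropped at parse time.
* First model of multi-model files; alternate location A only; insertion
  codes preserved in residue identifiers.
* Missing resolution or R-value contribute neutral 0.5 terms to the
  template score.
* Residues with fewer than 4 atoms get RSA flagged low-confidence.
* Identity ties in template ordering are broken by (structure id, chain id)
  for reproducibility.
* Every stochastic function takes an explicit seed and owns a private RNG
  stream, so results are reproducible and independent of the caller's RNG
  state; identical spec + seed produces byte-identical structure files.
* Network edges require identity strictly above 0.90 on *both* chains;
  complex stoichiometry is ignored; a gene mapping to two chains of one
  structure yields a homooligomer self-loop.

## Known limitations

* The template/candidate score combination and the protein-level
  normalisation are declared reconstructions (the original forms are not
  public); both are pluggable.
* The internal search is a global aligner — adequate for a desk-scale
  library; a BLAST-style external backend can be plugged in through the
  e-value interface.
* mmCIF, RNA-contact analysis, biological-assembly generation, disorder
  prediction and secondary-structure assignment are out of scope.
* The five-factor descriptor table is the published Atchley et al. (2005)
  solution, a documented stand-in for the original descriptor set.

## A worked example

```{r demo, eval = FALSE}
st <- demo_study(n_genes = 6, seed = 1)
res <- run_all(st$genes, st$disease, st$neutral, st$library,
               st$annotation, run_config(B = 1000, n_perm = 10000, seed = 1))
res$class_distributions$disease$fractions
res$enrichment[1:5, ]
multi_mutated_complexes(res$network)
```

The README shows this example with the numbers it prints.
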