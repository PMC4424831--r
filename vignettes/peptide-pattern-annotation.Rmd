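---
title: "Conserved-peptide subfamilies and peptide-driven genome annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved-peptide subfamilies and peptide-driven genome annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotpepr)
```

## The method

Large enzyme families — the motivating case are the lytic polysaccharide
monooxygenases (LPMOs) of the CAZy auxiliary-activity families AA9, AA10
and AA11 — are too divergent for a single alignment to describe, yet their
members share short, strongly conserved stretches of sequence. hotpepr
works entirely at the level of those stretches, represented as
**hexapeptides** (6-residue words):

1. **Subfamily building** (`build_subfamilies()`). A family of proteins is
   divided into subfamilies, each defined by a list of up to 70 conserved
   hexapeptides. Every peptide carries a *frequency*: the fraction of
   subfamily members that contain it, in (0, 1]. A protein belongs to a
   subfamily when it contains at least 10 of the subfamily's list peptides.
2. **Scoring** (`score_protein()` / `score_frame()`). A sequence is scored
   against a peptide list by (i) finding all list peptides present, (ii)
   summing their frequencies — the *frequency score* — and (iii) counting
   the residues covered by the union of all their occurrences. Three
   hexapeptides at maximal overlap cover 8 residues; three non-overlapping
   ones cover 18.
3. **Significance** (`is_significant()`). A hit counts only when it has at
   least 3 matched peptides **and** a frequency score strictly above 1.0
   **and** at least 10 covered residues. Because frequencies are presence
   fractions, one perfectly conserved peptide alone scores exactly 1.0 and
   fails the strict inequality; real hits need several jointly conserved
   peptides. The 10-residue floor excludes the degenerate case of three
   maximally overlapping peptides (8 residues).
4. **Genome mining** (`annotate_genome()`), a form of *in silico* PCR with
   the peptide lists as degenerate primers. In *fungal* mode the genome is
   cut into 2000-base fragments overlapping by 100 bases, each fragment is
   translated in all six reading frames, every (frame, subfamily) pair is
   scored, and each fragment keeps at most its best significant hit.
   Same-family hits whose fragment start positions differ by fewer than
   5800 bases — a span that accommodates introns and the fragment
   granularity — are counted as a single gene. In *bacterial* mode
   (intron-free genomes) the whole genome is translated once, open reading
   frames longer than 50 residues are scored, and every significant ORF is
   an independent hit with exact coordinates.
5. **Downstream analytics**: subfamily relatedness as the matrix of shared
   hexapeptides between peptide lists (`shared_peptide_matrix()`) with Ward
   clustering (`ward_dendrogram()`), and positional profiles of the
   conserved peptides (`position_profile()`), which for LPMO-like input
   reveal the conserved regions around residues 80–120 and 140–200.

## The grouping algorithm

The subfamily builder is greedy and fully deterministic; it uses no random
numbers, and all ties are broken lexicographically:

1. Over the unassigned proteins, count for every hexapeptide the number of
   proteins containing it (presence, not occurrences).
2. Take the most common peptide as the seed; the proteins containing it
   form the candidate membership. An alternative — seeding directly with
   the 70 globally most common peptides — fails in the presence of several
   subfamilies of equal size: their motifs all tie at the same presence
   count, the seed list mixes subfamilies, and no protein reaches the
   10-peptide membership threshold. Anchoring the seed in a single peptide
   keeps the initial membership coherent.
3. Rank the top 70 peptides over the current members, recompute membership
   as the unassigned proteins containing at least 10 of them, and iterate
   until the member set is stable (bounded by `max_iterations`).
4. Emit the group if it has at least `min_group_size` members (default 2 —
   the method never states a floor, but frequencies estimated from a single
   sequence are meaningless), remove its members, and continue; a seed
   peptide that fails to grow a group is discarded and the next one tried.
   The pool is exhausted when no seed can reach the floor.

Duplicate sequences are removed before training (so a repeated sequence
cannot dominate the peptide ranking) but retained idempotently: they count
toward group size, are listed as members of their representative's group,
and enter the stored frequencies, which are the exact fraction of members
containing each peptide.

Classification of a protein or fragment is the argmax of the frequency
score over all subfamilies passing the significance conditions; ties are
resolved by the matched-peptide count and then the group id.

## Parameters and their defaults

| parameter | default | unit | role |
|---|---|---|---|
| `peptide_len` | 6 | residues | word length of conserved peptides |
| `peptides_per_protein` | 10 | peptides | membership threshold |
| `peptides_per_group` | 70 | peptides | list size cap per subfamily |
| `min_protein_len` | 51 | residues | training-pool length filter |
| `min_peptides` | 3 | peptides | significance condition 1 |
| `min_score` | 1.0 (strict) | score | significance condition 2 |
| `min_covered_aa` | 10 | residues | significance condition 3 |
| `window` / `overlap` | 2000 / 100 | bases | fungal fragmentation |
| `merge_distance` | 5800 | bases | same-family hit chaining |
| `min_orf_len` | 50 (strict) | residues | bacterial ORF filter |

The 6/10/70 profile is the combination empirically found to predict
protein function best across peptide lengths 3–10, 5–40 peptides per
protein and 30–200 per group; the remaining defaults are the canonical
thresholds of the annotation procedure. All are configurable through
`ppr_config()` and `hotpep_config()`.

## Numerical and boundary conventions

* Coordinates are 1-based and inclusive throughout, the R/Bioconductor
  convention; gene calls and GFF3 output are therefore already in the
  conventional form. All distance arithmetic (fragment steps, the
  5800-base rule) is shift-invariant.
* `min_score` and `min_orf_len` are strict (`>`); `min_peptides` and
  `min_covered_aa` are non-strict (`>=`). A 51-residue ORF passes the
  50-residue filter; a score of exactly 1.0 does not pass.
* Inter-hit distance is measured between fragment *start* positions —
  fragments are the unit of assignment, and any finer localization would
  be invented precision. Strand is ignored during merging.
* A fragment contributes at most one hit: frames are scored individually,
  but the fragment is assigned only to the best significant (frame,
  subfamily) pair.
* Ambiguity codes: codons containing `N` translate to `X`; windows
  containing `X` or `*` never match a peptide, so ambiguity cannot create
  hits.
* Peptide list files print frequencies with 17 significant digits and
  round-trip losslessly; scores in gene-call tables are printed with 6
  decimals, but all threshold comparisons happen before any rounding.
* Shared-count dissimilarity for Ward clustering is `d = L - S` with `L`
  the list-size cap (70): the simplest monotone inversion bounded by the
  list size. The clustering itself is the classical Ward linkage
  (`stats::hclust`, method `ward.D`); rows are ordered lexicographically
  first so tied dissimilarities merge the lexicographically smallest pair.
  Fine branching order depends on this transform and is not meaningful.
* Peptide positions use the 1-based start of the *first* occurrence in
  each protein and the lower median across proteins; bins are `[1, 20]`,
  `[21, 40]`, ... These corner conventions are declared rather than
  prescribed by the method.

## The synthetic generator

`generate_family_pool()` emulates exactly the statistical structure the
method assumes: families of proteins that share planted conserved
hexapeptides at family-consistent positions, with divergent subfamilies
sharing few or no motifs. Each subfamily receives two conserved blocks
whose overlapping hexamer windows are its motifs — block one at residue
81, block two at residue 141, so with 70 motifs the conserved region ends
at residue 180 and, as in real LPMOs, motifs lie before residue 250.
Protein lengths are uniform on 200–350 residues, the scale of LPMO
catalytic domains. Background residues are uniform over the 20 letters,
and any background window that accidentally reproduces a planted motif is
rewritten, making zero inter-subfamily sharing *exact* rather than
probabilistic; requested sharing is realized by overlapping the conserved
blocks of neighboring subfamilies. Mutations are i.i.d. per-residue
substitutions.

`generate_genome()` reverse-translates proteins with uniform synonymous
codons (no codon-bias model — matching operates on translated peptides, so
bias is irrelevant to the tested contracts), frames each coding sequence
with in-frame stops, places it on a random strand and separates genes with
random intergenic sequence. The default spacing is 10000 bases: the merge
rule compares fragment start positions, so two same-family genes remain
distinct calls only when separated by more than `merge_distance + window`
bases; 10000 > 5800 + 2000 guarantees that, while spacings below 5800
exercise the merging path.

What the generator does **not** emulate: real amino-acid composition and
codon usage, introns, GC content, paralog families with partially decayed
motifs, and contaminating non-family domains. Passing tests therefore
demonstrate the correctness of the machinery — exact recovery of planted
structure, specificity on motif-free sequence, the stated boundary
behaviors — not the biological annotation rates achievable on real
genomes, which depend on curation of the training pools.

## Problem sizes used in the test suite

The packaged tests run the full pipeline at deliberately small scale: a
3 families x 4 subfamilies x 20 proteins pool (70 motifs each, no
mutation) for exact partition recovery and 100%-correct family annotation;
a genome with 10 planted genes plus 100 gene-free 12-kb genomes for
sensitivity and specificity; 1000 random instances against brute-force
scoring oracles; and a 5%-mutation pool for robustness (adjusted Rand
index above 0.9). These sizes make the suite fast while keeping every
planted structure non-trivial.

## Known limitations

* The grouping is greedy: an early group can absorb proteins that a later,
  better-fitting group would otherwise claim. At the default thresholds
  this requires heavily shared motif sets between subfamilies.
* Genes of the same family closer than 5800 bases collapse into one call
  by construction of the merge rule; tandem gene clusters are undercounted
  (a documented property, exercised in the tests).
* A gene straddling a fragment boundary is only guaranteed to be seen when
  at least one fragment retains a significant share of its motifs; the
  100-base overlap plus merging recovers all planted cases in the suite,
  but a pathological split of a sparsely conserved gene could be missed.
* Subfamily ids are arbitrary labels in emission order; comparing two runs
  or two training pools requires matching groups by membership or peptide
  content, not by id.
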