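---
title: "Profiling single-nucleotide alterations in satellite DNA monomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling single-nucleotide alterations in satellite DNA monomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satprof)
```

## The data and the model

Satellite DNA families such as CON1, CON2, and COM2 occur as tandem
arrays of near-identical monomers. When a monomer fragment is PCR
amplified from genomic DNA and Sanger sequenced, the chromatogram is a
superposition of the many monomer copies (and, in a diploid, of both
homologues), so the called consensus is a string over the full IUPAC
nucleotide alphabet: a clean base where all copies agree, a two-base
ambiguity code where two variants co-occur, occasionally a three-base
("triplet") code. `satprof` treats this consensus as the unit of
observation — one record per accession per family — and compares it to a
family reference monomer.

The zygosity vocabulary used throughout is purely structural: a call is
*homozygous* if its base set has size 1, *heterozygous* at size 2, a
*triplet* at size 3; `N` and gaps assert no call. Whether a heterozygous
call reflects allelic heterozygosity or variation among tandem monomer
copies within one genome is not decidable from a consensus sequence, and
the package deliberately does not interpret it biologically.

## Alignment and homology

Monomer fragments are near-full-length relative to the reference, so the
package uses deterministic global alignment with free end gaps
(semi-global) rather than local heuristic search: the quantity of
interest is identity over the alignable ("homologous") region, not
database search statistics. The Gotoh affine-gap dynamic program is
implemented in C++; its score provably equals the maximum over all gapped
alignments under the stated convention, which the test suite checks by
exhaustive enumeration on short sequences.

Scoring parameters (all tunable via `alignment_scoring()` or the run
configuration):

| parameter | default | rationale |
|---|---|---|
| match | +1 | identity counting; two states match iff their base sets intersect |
| mismatch | −1 | symmetric penalty at the 93–99% identity regime |
| gap open | −2 | a gap run of length L costs −2 − 0.5(L−1) |
| gap extend | −0.5 | indels in satDNA monomers are rare but can be multi-base |

Set-intersection matching is essential: a consensus R = {A,G} over a
reference A is evidence *for* the reference allele plus a variant, not a
mismatch. Percent homology is reported to the nearest integer percent,
the conventional granularity of BLAST-style homology statements. Since
the original homology figures were produced by local search over
undeposited sequences, the package defines homology over the trimmed
semi-global region and documents that the two need not coincide exactly.

Trimming of the homologous region uses either of two rules: a terminal
window rule (trim single columns from an end while the terminal 10
alignment columns have identity below 0.5 — windows and threshold
tunable), or exact flank lengths when primer lengths are known from the
protocol. With the default scoring, a non-homologous primer flank is
already left out of the aligned core as a free overhang; the window rule
only cleans up residual lucky matches.

Tie-breaks are fixed so runs are byte-reproducible: traceback prefers
diagonal over up (gap in reference) over left (gap in sample), gap-state
predecessors prefer opening from the match state, and the terminal cell
is the maximal-score cell consuming the most of both sequences.

## Alteration columns and profiles

Sample alignments are projected onto reference coordinates
(`build_anchored_msa()`); sample insertions relative to the reference
have no reference coordinate, are dropped from the matrix, and are
counted in the log — consistent with reporting alterations as positions
in the homologous region. A column is an *alteration column* iff at
least one sample's base set differs from the reference state's set.
Three consequences are worth stating explicitly:

- a heterozygous call containing the reference base *is* an alteration
  (the set differs), even though it is compatible for alignment scoring;
- missing states (uncovered, deleted, `N`) never create a column on
  their own, because they assert no base call;
- adjacent alteration positions are reported as separate columns, with
  adjacency noted in the log (the alternative — merging runs into
  multi-nucleotide "fragments" — is not what a column-wise profile
  needs, and no multi-base alteration is documented for these families).

Where the reference call is itself ambiguous, per-sample zygosity labels
are classified against the alphabetically first base of the reference
set. This is a reporting convention only: profile equality and all
distances compare base sets, so no grouping or tree can depend on it.

## Grouping and schematic trees

Two samples belong to one group iff their profiles are identical
column-for-column (missing compares equal to missing). The partition is
an equivalence-class decomposition, so permuting the input order changes
only group numbering — a property the tests assert. A tolerance
parameter (maximum within-group profile distance, greedy first-fit) is
exposed for exploratory use but defaults to 0 and is not used by any
shipped analysis.

The profile distance is the column-wise mean of Jaccard distances on
base sets over shared called columns. On missing-free profiles it is a
metric; with missing data the shared-column mean can mildly violate the
triangle inequality, which is why grouping uses exact equality rather
than a distance threshold.

The schematic tree is built by UPGMA: the source study's trees were
drawn with a commercial package that names no algorithm, and UPGMA is
the natural choice for an ultrametric "schematic" dendrogram over a
profile dissimilarity — these trees summarize profile similarity and are
not model-based phylogenies (no bootstrap, no substitution model). Ties
are broken by merging the candidate pair whose sorted pair of
lexicographically smallest member labels is smallest, making tree output
deterministic. Heights are half the merged distance; serialization is
Newick with branch lengths, and `ape` is used as the independent
round-trip parser in the tests, alongside a cross-check of the
agglomeration against average-linkage `hclust()` on tie-free matrices.

## The synthetic generator

No accession sequences were deposited for this study design, so the
package ships a generator that emulates its data-generating process:

- a pseudo-random canonical-base reference backbone of the family's
  fragment length (333/538/322 bp for CON1/CON2/COM2), reproducible from
  a single seed through named substreams, so module-level tests and full
  pipeline runs draw identical sequences;
- planted columns with per-accession zygosity words (`hom_ref`, `het`,
  `hom_alt`, `het3`, `missing`); each column's alternative allele is the
  next base after the reference allele in A-C-G-T cyclic order and is
  shared by all samples, so zygosity structure — the only thing the text
  documents — drives the grouping rather than allele identity;
- primer flanks attached on both sides (defaults: the one primer pair
  printed for these assays, its forward sequence 5' and the
  reverse-complement of its reverse sequence 3', reused as neutral flank
  material for all families);
- optional background substitutions and 1-bp indels at configurable
  per-position rates, drawn per accession and never landing on planted
  columns, so the emitted truth table is exact by construction. All
  shipped fixtures use rate 0: the documented column counts and group
  structure are only guaranteed at zero noise, and noise levels are part
  of the study conditions, not a tuning dial.

The CON2 fixture encodes the fully documented worked example: 8 columns,
13 samples, reference heterozygous at columns 1/3/4/5/8 and homozygous at
2/6/7, and the four groups with sizes 4/6/2/1. The CON1-style (11
columns, one shared trio profile, one accession one alteration apart,
four triplet-bearing samples) and COM2-style (9 columns, 6 samples, all
profiles unique) configurations reproduce every structural statement
available for those families, but their base identities and column
positions are synthetic placeholders — evenly spaced at
`floor(k·L/(K+1))` — and are flagged as such. Consequently, passing tests
demonstrate that the pipeline recovers planted structure exactly; they do
not validate base-level claims about the real CON1/COM2 matrices, which
exist only as figures.

One source inconsistency is handled explicitly: the CON2 grouping lists
13 samples without *T. phleoides* although CON1 and CON2 consensi are
said to exist for 13 accessions of the 14 studied and the CON1 homology
discussion names *T. phleoides*. Both the CON2 fixture and the CON1-style
configuration use the same 13 grouped samples; *T. phleoides* appears
only in the COM2 panel.

What the generator does not emulate: chromatogram-level noise and base
calling (it starts from called sequences), PCR artifacts, monomer
higher-order structure, and the actual reference monomers of the
original isolation work.

## Degenerate inputs and numerical choices

- Empty sequences, invalid characters (reported with position), and
  duplicate accession ids are rejected before alignment.
- `U` is accepted and mapped to `T` with a warning; lowercase input is
  upper-cased.
- An empty homologous region (after trimming) is an error naming the
  sample; an empty trimmed identity is reported as `NA` homology with a
  warning rather than silently as 0.
- A profile pair sharing no called column is an error naming the pair.
- A single-leaf tree serializes to the degenerate Newick `A:0.0;`.
- All alignment scores are multiples of 0.5, so DP comparisons are exact
  in doubles; UPGMA tie detection uses a 1e-15 slack and Newick
  round-trips are asserted to 1e-9.
- Coordinates are 0-based half-open everywhere internally; 1-based
  "column #k" numbering appears only in reports and printed matrices.

## Problem sizes used by the test suite

The suite exercises: exhaustive alignment enumeration on sequence pairs
up to length 8 (tens of thousands of alignments per pair); full-length
pipeline runs on 13 × 538 bp CON2 panels; planted-profile recovery over
20 seeds; 200 random triples for metric axioms; and 10–15 random
matrices (3–12 leaves) for tree properties. These sizes make the whole
suite run in well under a minute while covering every documented count
exactly; larger panels change nothing structurally, since the pipeline
is linear in samples and quadratic only in the (small) distance-matrix
steps.

## Limitations

- Homology percentages are semi-global identities, not local-search
  statistics; against a diverged reference the two can differ.
- Insertion alterations are logged but not typed as profile columns;
  allele ratios within an amplicon are not estimated.
- The schematic tree is a similarity summary; it should not be read as a
  phylogeny, and no support values are attached.
- Group tolerance > 0 uses greedy first-fit assignment and is order
  dependent by construction; it is for exploration only.
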