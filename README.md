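# satprof — satellite DNA monomer alteration profiling

`satprof` analyzes per-accession consensus sequences of satellite DNA
(satDNA) monomer fragments, such as the CON1/CON2/COM2 repeat families
shared across *Deschampsia* and related Aveneae/Poeae grasses. Each
accession contributes one Sanger-style consensus of a PCR-amplified repeat
fragment (333, 538, and 322 bp for CON1, CON2, and COM2); positions that
vary among the tandem monomer copies within an amplicon appear as IUPAC
ambiguity codes. The package answers the questions a comparative
repeatome study asks of such data:

- how similar is each accession's monomer to the family reference
  (percent homology over the alignable region),
- at which aligned positions does any accession's call differ from the
  reference — the *single-nucleotide alteration columns* — and in what
  zygosity state (homozygous single base, two-base heterozygous, or
  three-base "triplet" ambiguity),
- which accessions share an identical *alteration profile* (the vector of
  states over all alteration columns), partitioning the panel into
  profile groups, and
- what ultrametric *schematic tree* summarizes profile similarity among
  accessions.

## Method

Each sample consensus `s` is aligned to the family reference `r` by a
Gotoh affine-gap dynamic program that is global but end-gap-free
(semi-global), with ambiguity-aware scoring: two states match iff their
IUPAC base sets intersect, so a heterozygous call R = {A,G} is never
penalized against a reference A it contains. Defaults are match +1,
mismatch −1, gap open −2, gap extend −0.5; a gap run of length L costs
−2 − 0.5(L − 1) and terminal gap runs (primer flanks, ragged ends) are
free. Percent homology is the integer-rounded identity over the trimmed
homologous region. The pairwise alignments are projected onto reference
coordinates to form a reference-anchored MSA; a column is an alteration
column iff at least one sample's base set differs from the reference
state's base set (missing states — gaps, uncovered positions, N — never
trigger a column).

Profiles are compared column-wise with the Jaccard distance on base
sets, `d(S1, S2) = 1 − |S1 ∩ S2| / |S1 ∪ S2|`, averaged over columns where
both samples carry a call; samples with identical profiles form one
group. Schematic trees are built by UPGMA over this profile distance,
with a deterministic lexicographic tie-break; node height is half the
merged distance, so trees are ultrametric.

A seeded generator emulates the study design: it plants column-wise
zygosity states into a pseudo-random reference backbone, attaches the
printed primer pair as flank material, optionally adds background
substitutions/indels (never on planted columns), and emits FASTA plus an
exact truth table. The fully text-specified CON2 worked example — 8
columns, 13 accessions, four profile groups — ships as a packaged fixture.

## Worked example

```r
library(satprof)

cfg <- con2_family_config(seed = 1)       # CON2 fixture: 538 bp, 13 accessions
ds  <- generate_dataset(cfg)

alns <- lapply(names(ds$sequences), function(id)
  trim_homologous_region(global_align(ds$sequences[[id]], ds$reference,
                                      sample_id = id)))
names(alns) <- names(ds$sequences)
msa <- build_anchored_msa(alns, ds$reference)
pm  <- build_profile_matrix(detect_alteration_columns(msa),
                            names(ds$sequences), family = "CON2")
pm
#> Alteration-profile matrix [CON2]: 13 samples x 8 columns
#>                #1 #2 #3 #4 #5 #6 #7 #8
#> reference      K  A  K  S  W  T  G  M
#> Da_KEW-0522816 K  M  K  S  W  T  G  M
#> ...
partition_profiles(pm)
#> 4 profile groups [CON2]
#>   group 1 (n=4): Da_KEW-0522816, Da_KEW-0661919, Da_KEW-0521613, Dp_KEW-0661849
#>   group 2 (n=6): Ds_78, Dc_PI-562652, Dc_PI-577069, Dc_PI-371724, De_PI-665545, Df_PI-577075
#>   group 3 (n=2): Hp_KEW-065160, Km_KEW-0096838
#>   group 4 (n=1): Dd_W6-39054
```

The reference row carries two-base codes (K, S, W, M) at columns 1, 3, 4,
5, 8 — the reference consensus is itself heterozygous there — and single
bases at columns 2, 6, 7. Group 1 (the three *D. antarctica* accessions
and *D. parvula*) differs from the reference profile only at column 2;
group 2 matches it only at column 2; group 3 matches at the three
homozygous columns 2, 6, 7; the singleton group 4 differs at six of the
eight columns. `upgma(profile_distance_matrix(pm))` then yields the
schematic tree, in which those four accessions form one clade.

The same analysis runs end to end from a YAML configuration via
`run_pipeline()`, which writes the anchored MSA FASTA, the profile TSV,
a groups JSON, a Newick tree, and a run report per family.

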