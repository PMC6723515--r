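---
title: "Detecting and interpreting mitochondrial stop-codon readthrough polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and interpreting mitochondrial stop-codon readthrough polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopswitch)
```

## The problem

Sea urchin mitochondrial genomes carry the ND6 gene on the L-strand,
head-to-head with ND5 on the H-strand. In camarodont sea urchins two ND6
alleles segregate within and between species: a short (S) allele of 489 bp
whose open reading frame ends at a TAG stop after 162 sense codons, and a
long (L) allele of 498 bp in which the middle base of that stop (position
488, counted from the gene's first base) is G instead of A. TAG thereby
becomes TGG (tryptophan) and translation continues through the 9-nt segment
TTATGATAA to a TAA stop, appending Trp-Leu-Trp to the protein (165 residues;
TGA encodes tryptophan in the echinoderm mitochondrial code, NCBI
translation table 9). Because the extension runs into the neighboring ND5
terminus on the opposite strand, the realized L coding region overlaps ND5
by exactly 9 bp while the S form does not overlap at all.

A polymorphism with this structure raises three questions this package
operationalizes:

1. **Detection.** Given annotated genomes or a cohort of orthologous gene
   sequences, which sequences are S, which are L, where is the stop-switch
   substitution, and what is the realized overlap geometry?
2. **History.** Mapped on a phylogeny, is the S/L polymorphism consistent
   with a single ancestral origin whose alleles persisted through
   speciations (trans-species polymorphism, the signature of balancing
   selection), or does it require repeated independent origins
   (convergence)?
3. **Mechanism.** Is the length difference real at the protein level, or
   could RNA editing or codon reassignment erase it in the transcript? Both
   alternatives predict RNA-DNA differences; direct comparison of reads
   with the gene tests that.

## Variant classification

`classify_variant()` translates a reading-frame sequence under a halt
policy and compares the realized protein length with a reference S length:
equal is S, longer is L, shorter is `other` (flagged `truncated`); a
sequence with no in-frame stop is flagged `no-stop` rather than raising an
error, because annotated mitochondrial CDSs with polyadenylation-completed
stops are common. For an L call, `extension_nt` is the downstream
elongation, i.e. the bases after the former stop codon through the realized
stop inclusive, so the S/L coding-length difference always equals
`nchar(extension_nt)`; `extension_aa` is the set of additional residues and
therefore starts with the translated readthrough codon. With the study
geometry this yields `TTATGATAA` and `WLW`.

`scan_cohort()` derives the S reference as the **minimum well-formed
(stop-found) protein length in the cohort**. A "modal" definition was
considered and rejected: in a cohort with many more L than S sequences (the
second study species has 2 S and 14 L) the modal length is the L length,
which would invert the classification. The minimum rule assumes truncated
pseudogene-like sequences have been excluded upstream — the original
analysis excluded a cidaroid whose ND6 lacks seven terminal residues — and
an explicit `reference_protein_length` overrides it when that assumption is
wrong. L calls longer than the modal L length are additionally flagged
`extra-length:+k` (one deposited sequence carries two extra residues,
Asn-Asp).

`localize_stop_switch()` scans the shared prefix of an S/L pair for
positions where substituting the S base with the L base converts an
in-frame stop codon to a sense codon, and demands that the candidate be
unique; zero or multiple candidates raise an ambiguity error listing them,
because a non-unique switch cannot be reported as "the" polymorphic site.

Site numbering in all outputs is 1-based from the gene's first base on the
reading strand; internal coordinates are 0-based half-open on the forward
strand, with GenBank input converted at the boundary. This removes
off-by-one ambiguity internally while reporting in the convention in which
"488" is meaningful.

## Genetic codes and translation policy

Code tables ship as editable plain-text files (`CODON<TAB>AA-or-*`), with
the echinoderm mitochondrial table as default (TGA=Trp, AGA/AGG=Ser,
AAA=Asn, stops TAA/TAG). Codons containing N translate to `X` unless every
resolution agrees, and an ambiguous possibly-stop codon never halts
translation — a conservative rule that prevents an undetermined base from
fabricating a truncation. Incomplete terminal codons are reported, never
dropped. The `readthrough_once` policy translates the first stop as a
caller-designated residue and continues, modelling the L allele
explicitly.

## Phylogenetic mapping and the TSP test

Distances (p or Jukes-Cantor, pairwise deletion of gaps and N) and
neighbor-joining are delegated to ape behind this package's validated
surface; Jukes-Cantor saturation (p ≥ 0.75) is flagged rather than
silently corrected, and negative NJ branch lengths are clamped to zero with
the deficit recorded. Tree search beyond NJ (likelihood, Bayesian,
bootstrap) is out of scope: the mapping logic is indifferent to how the
topology was obtained, and a user-supplied Newick tree always takes
precedence.

Character mapping uses a generalized Fitch parsimony in which a polymorphic
tip carries the state set {S, L} and may resolve to either state at no
cost (`fitch_map()`, implemented as unit-cost Sankoff dynamic programming).
An alternative mode splits each polymorphic tip into a zero-length S/L
cherry; since the two alleles of a polymorphic tip necessarily differ, that
raw cost exceeds the set-based cost by exactly the number of polymorphic
tips, and the mode reports the cost net of this offset so the two modes
agree (verified against exhaustive enumeration in the tests).

`assess_tsp()` answers the historical question on a second, binary
character: presence of the L allele. Here the package assumes the short
state is ancestral — every echinoderm outside the focal clade carries S
only — by attaching a stem edge in state S above the root. Among
minimum-cost reconstructions of L presence, the minimum number of
S→L gain edges is `min_origins_of_L`. The pattern is called
`tsp_consistent` when at least two tips are polymorphic **and** one origin
suffices at minimum cost; otherwise the reconstruction demands convergent
origins. A single polymorphic species can never establish trans-species
polymorphism, by definition. Note the deliberate asymmetry: `min_changes`
is reported for the free-rooted S/L character (the quantity exhaustive
enumeration checks), while the origins count uses the ancestral-S stem;
the two answers address different questions and the vignette's terms keep
them apart.

Dxy between sequence sets is the mean over between-set pairs of the
per-pair distance. When both sets are a single sequence the standard
deviation degenerates to the per-site binomial SD `sqrt(p(1-p)/n)`
(delta-method transformed under Jukes-Cantor); with ~15.7 kb genomes at
p ≈ 0.008 this evaluates to ≈ 0.0007, the natural uncertainty scale for
such a comparison. This is the package's own documented SD; no equivalence
with any other program's uncertainty is claimed. Both corrected and
uncorrected values are always reported because the appropriate correction
at this divergence is immaterial and unstated in most analyses.

## Transcript concordance

The mapper is a deterministic exact-k-mer seed plus ungapped-extension
aligner (defaults: k = 15, identity ≥ 0.9), deliberately self-contained:
the scientific claim being tested is presence/absence of RNA-DNA
differences, not alignment statistics, and a dependency-free mapper keeps
the test reproducible. Reads are tried in both orientations; reads
extending past a gene end are not placed (transcript reads of an interior
gene segment should lie within it). RDD calling is consensus-style: a
position with depth ≥ 5 whose modal read base differs from the genomic
base at ≥ 80% frequency. The focal stop-switch site, when supplied, is
excluded from RDD scanning: in a polymorphic individual the transcript
pool legitimately mixes both DNA alleles, and at thin coverage the
consensus caller would mistake that mix for editing; allele support at the
focal site is instead reported directly (`count_allele_support()`), which
is also the observation of interest — both S and L transcripts present.
All thresholds are caller-overridable and recorded in the report object.

## The synthetic-data generator

`simulate_dataset()` regenerates the study conditions with known ground
truth. Defaults are the study geometry itself: 162 sense codons, focal TAG
at codon 163, extension TTATGATAA, so the default dataset reproduces the
489/498-bp, 162/165-residue, 9-bp-overlap worked example exactly. Trees are
Yule (height-scaled to 1) over 8 taxa; sequences evolve by Jukes-Cantor at
0.15 substitutions per site per unit height — root-to-tip divergence of
the order seen across the focal sea urchin clade, enough signal for NJ to
recover 8-taxon topologies from a 498-nt gene. Proposals creating an
internal stop are resampled, a deliberate departure from a free JC process
that keeps length classification unconfounded with background stop
turnover; the focal codon and extension are held invariant except for the
scenario-controlled focal base. Under `persistence` a random internal
clade's taxa are polymorphic (each emits an S and an L copy, the single
ancestral origin transmitted); under `convergence` two taxa on opposite
sides of the root are polymorphic, chosen so the S-only taxa do not
collapse into one clade — origins genuinely scattered. Transcript reads
are uniform-start, both strands, configurable depth (30), length (100) and
error rate (0.005), with optional injected editing sites.

What the generator does **not** emulate: within-species allele genealogies
(the L copy of a polymorphic taxon differs from its S copy only at the
focal base), rate heterogeneity, indels, selection, and base-composition
bias. Passing tests therefore demonstrate correctness of the machinery
under the stated model, not robustness to every feature of real data.

## Worked example

```{r example}
ds <- simulate_dataset(sim_config(seed = 42))
code <- load_code("echinoderm_mt")
poly <- ds$aln$truth$polymorphic_taxa[1]
s <- ds$aln$seqs[[paste0(poly, "_S")]]
l <- ds$aln$seqs[[paste0(poly, "_L")]]
classify_variant(s, code, 162)
classify_variant(l, code, 162)
localize_stop_switch(s, l, code)
sc <- scan_cohort(ds$aln$seqs, code, taxa = ds$aln$taxa)
sc$counts
s_only <- ds$aln$seqs[grepl("_S$", names(ds$aln$seqs))]
names(s_only) <- sub("_S$", "", names(s_only))
run_tsp(sc$states, alignment = s_only)
```

## Numerical choices and problem sizes

* Exact Wilcoxon enumeration is used up to n = 25 retained observations
  (tie-free); beyond that, normal approximation with continuity and tie
  corrections. The threshold balances runtime against fidelity; at n = 30
  exact and approximate p agree to < 0.01.
* The Grantham matrix is rebuilt from the published
  composition/polarity/volume formula (constants 1.833, 0.1018, 0.000399,
  scale 50.723); recomputed entries match the published integer table
  within its rounding (±1).
* The Schneider-Wrede physicochemical distance table is not redistributed;
  the shipped `sw_distance_synthetic.tsv` is a synthetic stand-in built in
  the same style (min-max-normalized Euclidean metric over hydrophobicity,
  polarity and volume, range [0, 1]) and is labelled synthetic wherever it
  appears. Upstream descriptor-server p-values are consequently not
  reproduction targets anywhere in this package; feature comparisons are
  property-checked.
* Alignment tie-breaks are fixed (diagonal over up over left) so reports
  are byte-reproducible.
* Test-suite problem sizes: parsimony is verified against exhaustive
  enumeration on 500 random trees of up to 8 leaves; NJ topology recovery
  on 100 additive matrices; stop-switch localization against brute force on
  500 synthetic pairs; the TSP classifier on 100 persistence and 100
  convergence end-to-end simulations (thresholds ≥ 95% / ≤ 5%); transcript
  concordance on 1,000 error-free read sets; round-trip extraction on 200
  random records. These sizes give stable pass/fail behavior at desk
  scale.

## Limitations

* Classification is length-based relative to a single realized stop; body
  indels shift downstream coordinates and are flagged, not resolved (no
  multiple alignment inside the scanner).
* The accession-based checks (deposited cohorts, 15,705-bp genomes,
  Dxy ≈ 0.0083) require a one-time download with
  `scripts/fetch_accessions.R`; nothing in the package fetches data at
  build or test time.
* The TSP verdict is a parsimony statement about minimum origins, not a
  test of balancing selection; introgression and recombination are outside
  this package's scope (and recombination screens in the original analysis
  were negative).
* The transcript check can only bound editing at covered positions;
  uniform-start reads naturally thin out near gene ends, and the verdict
  is `insufficient` rather than `concordant` when the focal site is
  under-covered.
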