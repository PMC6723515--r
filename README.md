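# stopswitch

Detection and phylogenetic analysis of mitochondrial stop-codon readthrough
polymorphisms.

## The problem

In camarodont sea urchins the mitochondrial **ND6** gene (L-strand, adjacent
to ND5 on the H-strand) segregates two alleles of different length. The
short (**S**) allele is 489 bp: 162 sense codons then a TAG stop. In the
long (**L**) allele the middle base of that stop — gene position 488,
numbered from the gene's first base — is G instead of A, so TAG becomes TGG
(tryptophan) and translation reads through the 9-nt downstream segment
`TTATGATAA` to a TAA stop. The L protein is 165 residues, three longer
(Trp-Leu-Trp); under the echinoderm mitochondrial code (NCBI translation
table 9) TGA encodes Trp, which is what makes the tail's middle codon
sense. The realized L coding region overlaps the opposite-strand ND5 gene
by exactly 9 bp; the S form does not overlap it at all.

`stopswitch` packages the full analysis of such a polymorphism for anyone
working on mitochondrial gene-length variants:

* **Scanner** — classify annotated genomes (GenBank flat files) or gene
  cohorts (FASTA) into S / L / other, localize the stop-switch substitution
  (`488A>G` in the motivating system), extract the readthrough extension and
  measure opposite-strand gene overlaps (`classify_variant`,
  `localize_stop_switch`, `scan_cohort`, `compute_overlap`,
  `realized_cds`).
* **Phylogenetics** — p/Jukes-Cantor distances, neighbor-joining, Dxy, and
  a generalized Fitch parsimony with polymorphic tips ({S,L} state sets)
  that assesses whether a shared polymorphism is consistent with a single
  trans-species origin or demands convergent origins (`fitch_map`,
  `assess_tsp`, `dxy`, `nj_tree`).
* **Transcript check** — a deterministic k-mer seed / ungapped-extension
  read mapper, RNA-DNA difference calling and focal-site allele support, to
  test the RNA-editing / codon-reassignment alternatives (`map_reads`,
  `call_rdd`, `count_allele_support`).
* **Protein features** — amino-acid composition, Kyte-Doolittle
  hydrophobicity, Grantham distance profiles (matrix rebuilt from the
  published formula) and a Wilcoxon test with a documented exactness
  contract (`aa_composition`, `grantham_profile`, `wilcoxon_test`).
* **Synthetic data** — a seeded generator that reproduces the study
  geometry with known ground truth: trees, sequence evolution with the
  focal polymorphism maintained under persistence or convergence
  scenarios, two-gene genome records with the 9-bp overlap geometry, and
  transcript read sets (`sim_config`, `simulate_dataset`).

The orchestration functions `run_scan`, `run_tsp`, `run_transcripts`,
`run_features` and `run_dxy` wire the stages together; a thin command-line
wrapper lives in `inst/scripts/stopswitch-cli.R`.

## Worked example

```r
library(stopswitch)

ds   <- simulate_dataset(sim_config(seed = 42, read_depth = 100))
code <- load_code("echinoderm_mt")
poly <- ds$aln$truth$polymorphic_taxa[1]
s <- ds$aln$seqs[[paste0(poly, "_S")]]
l <- ds$aln$seqs[[paste0(poly, "_L")]]

classify_variant(s, code, 162)
#> <variant_call> class S, 162 aa, 489 nt
classify_variant(l, code, 162)
#> <variant_call> class L, 165 aa, 498 nt, extension WLW
localize_stop_switch(s, l, code)   # site 488, ref "A", alt "G"
```

The S call is the 489-bp, 162-residue short form; the L call is 498 bp and
165 residues with the Trp-Leu-Trp tail; the single substitution separating
them sits at gene position 488 (A→G), i.e. the middle base of the former
stop codon.

```r
sc <- scan_cohort(ds$aln$seqs, code, taxa = ds$aln$taxa)
sc$counts
#>   taxon n_S n_L n_other
#> 1    t1   1   1       0
#> 2    t2   1   1       0
#> 3    t3   1   0       0
#> 4    t4   1   1       0
#> ...
s_only <- ds$aln$seqs[grepl("_S$", names(ds$aln$seqs))]
names(s_only) <- sub("_S$", "", names(s_only))
run_tsp(sc$states, alignment = s_only)
#> <tsp_report> min changes 0, min L origins 1, 3 polymorphic tip(s)
#>   tsp_consistent: TRUE
#>   L alleles occur in 3 tip(s); their spanning clade holds 3 tip(s). A single
#>   ancestral stop-switch origin explains the data at minimum cost: consistent
#>   with trans-species persistence.
```

Three taxa carry both alleles, they form a clade, and one ancestral S→L
origin explains the pattern at minimum parsimony cost — the trans-species
persistence signature. The transcript stage maps reads back to the gene:

```r
run_transcripts(s, ds$reads, focal_site = 488)
#> <concordance> verdict concordant: 487 callable position(s), 0 RDD site(s);
#>   focal support S=4 L=6
```

No RNA-DNA differences anywhere, and both S- and L-carrying transcripts
present at the focal site: the length difference is genomic, not an
editing artifact.

## Code-table file format

Genetic codes ship as plain-text files under `inst/extdata/codes/` and can
be swapped or edited: `# name:` and `# starts:` header lines, then one
`CODON<TAB>AA` line per codon with `*` marking stops. `load_code()` accepts
a registry name (`"echinoderm_mt"`, `"invertebrate_mt"`, `"standard"`) or a
file path and validates 64-codon totality.

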