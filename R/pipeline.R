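## Orchestration: wire the IO, translation, scanner, phylogeny, transcript
## and feature modules into the analysis stages a user runs end to end.
## These functions (plus the vignette) are the package's interface; a thin
## command-line wrapper lives in inst/scripts/stopswitch-cli.R.

#' Scan genomes or a gene cohort for S/L readthrough variants
#'
#' Two input modes. Cohort mode (`fasta`): classify a multi-FASTA of
#' orthologous gene sequences with [scan_cohort()]. Genome mode (`genbank`):
#' for each annotated genome, realize the focal gene's coding sequence
#' (extending past an annotated stop that the readthrough allele has lost),
#' classify it, and compute the realized overlap with the opposite-strand
#' neighbor gene.
#'
#' @param fasta path to a gene multi-FASTA (cohort mode).
#' @param genbank character vector of GenBank flat-file paths (genome mode).
#' @param code genetic code name or file (default the echinoderm
#'   mitochondrial code).
#' @param gene,neighbor focal gene and its opposite-strand neighbor.
#' @param taxa optional taxon per sequence (cohort mode); defaults to
#'   stripping a trailing `_S`/`_L` allele suffix from the identifier when
#'   present, else the identifier itself.
#' @param reference_protein_length optional explicit S length.
#' @param out_tsv optional report path (tab-separated; see
#'   [write_report_tsv()]).
#' @param force overwrite an existing report.
#' @return a `cohort_scan` (cohort mode) or a list with `calls` data frame
#'   and `records` (genome mode).
#' @export
run_scan <- function(fasta = NULL, genbank = NULL, code = "echinoderm_mt",
                     gene = "ND6", neighbor = "ND5", taxa = NULL,
                     reference_protein_length = NULL, out_tsv = NULL,
                     force = FALSE) {
  gc <- load_code(code)
  if (is.null(fasta) == is.null(genbank)) {
    ssw_error("provide exactly one of `fasta` or `genbank`", "ssw_input_error")
  }
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    if (is.null(taxa)) taxa <- sub("_(S|L)$", "", names(seqs))
    res <- scan_cohort(seqs, gc, taxa = taxa,
                       reference_protein_length = reference_protein_length)
    if (!is.null(out_tsv)) write_report_tsv(res$calls, out_tsv, force = force)
    return(res)
  }
  records <- lapply(genbank, parse_genbank, quiet = TRUE)
  rows <- lapply(records, function(rec) {
    rc <- realized_cds(rec, gene, gc)
    call <- classify_variant(rc$cds, gc, reference_protein_length,
                             taxon = rec$identifier, id = rec$identifier)
    nb <- rec$features[rec$features$gene_name == neighbor, ]
    ov <- if (nrow(nb) == 1L) {
      compute_overlap(rc$feature, as.list(nb), nchar(rec$sequence),
                      rec$topology)
    } else NA_integer_
    if (rc$no_stop) call$notes <- c(call$notes, "no-stop-after-extension")
    data.frame(id = rec$identifier, variant_class = call$variant_class,
               protein_length_aa = call$protein_length_aa,
               cds_length_nt = call$cds_length_nt,
               extension_aa = call$extension_aa, overlap_bp = ov,
               notes = paste(call$notes, collapse = ";"))
  })
  calls <- do.call(rbind, rows)
  if (!is.null(out_tsv)) write_report_tsv(calls, out_tsv, force = force)
  list(calls = calls, records = records)
}

#' Map the S/L character on a phylogeny and assess trans-species polymorphism
#'
#' A user-supplied tree takes precedence; otherwise a neighbor-joining tree
#' is built from the alignment (JC distances, pairwise deletion). The tree
#' is rooted on `outgroup` when given (midpoint otherwise) and the S/L
#' character mapped with [fitch_map()] / [assess_tsp()].
#'
#' @param states per-taxon states (see [fitch_map()]), e.g. from
#'   [scan_cohort()]`$states`.
#' @param tree optional `phylo` or Newick string/path.
#' @param alignment optional named vector of aligned per-taxon sequences
#'   (used only when `tree` is `NULL`).
#' @param outgroup optional taxon for rooting.
#' @param out_tsv optional report path.
#' @param force overwrite an existing report.
#' @return a `tsp_report` (the built tree attached as attribute `"tree"`).
#' @export
run_tsp <- function(states, tree = NULL, alignment = NULL, outgroup = NULL,
                    out_tsv = NULL, force = FALSE) {
  if (is.null(tree)) {
    if (is.null(alignment)) {
      ssw_error("provide a tree or an alignment", "ssw_input_error")
    }
    dm <- pairwise_distance(alignment, model = "jc")
    tree <- nj_tree(dm)
  } else if (is.character(tree)) {
    tree <- read_newick(tree)
  }
  rep <- assess_tsp(tree, states, outgroup = outgroup, quiet = TRUE)
  attr(rep, "tree") <- tree
  if (!is.null(out_tsv)) {
    df <- data.frame(min_changes = rep$min_changes,
                     min_origins_of_L = rep$min_origins_of_L,
                     n_polymorphic = length(rep$polymorphic_taxa),
                     polymorphic_taxa = paste(rep$polymorphic_taxa,
                                              collapse = ","),
                     tsp_consistent = rep$tsp_consistent,
                     narrative = rep$narrative)
    write_report_tsv(df, out_tsv, force = force)
  }
  rep
}

#' DNA-vs-transcript concordance for a gene
#'
#' Maps transcript reads to the gene, calls RNA-DNA differences, and counts
#' S- and L-supporting reads at the focal stop-switch site.
#'
#' @param gene_seq gene DNA in reading orientation.
#' @param reads read set (data frame or path to FASTQ/FASTA).
#' @param focal_site 1-based stop-switch site (488 in the study system).
#' @param s_allele,l_allele focal alleles.
#' @param k,min_identity,min_depth,min_alt_fraction mapper and caller
#'   thresholds (defaults: 15, 0.9, 5, 0.8).
#' @param out_tsv optional RDD report path.
#' @param force overwrite an existing report.
#' @return a `concordance_report` with allele support filled in.
#' @export
run_transcripts <- function(gene_seq, reads, focal_site = NULL,
                            s_allele = "A", l_allele = "G", k = 15L,
                            min_identity = 0.9, min_depth = 5L,
                            min_alt_fraction = 0.8, out_tsv = NULL,
                            force = FALSE) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) {
      read_fastq(reads)
    } else {
      fa <- read_fasta(reads)
      data.frame(id = names(fa), seq = unname(fa), qual = NA_character_)
    }
  }
  pu <- map_reads(gene_seq, reads, k = k, min_identity = min_identity)
  rep <- call_rdd(pu, min_depth = min_depth,
                  min_alt_fraction = min_alt_fraction,
                  focal_site = focal_site)
  if (!is.null(focal_site)) {
    sup <- count_allele_support(pu, focal_site, s_allele, l_allele)
    rep$s_support <- unname(sup["s_support"])
    rep$l_support <- unname(sup["l_support"])
  }
  if (!is.null(out_tsv)) write_report_tsv(rep$rdd_sites, out_tsv, force = force)
  rep
}

#' Physicochemical comparison of two protein variants
#'
#' Reports amino-acid compositions with a paired Wilcoxon test over the 20
#' residue categories (the only paired construction available for two
#' single proteins), hydrophobicity summaries with an unpaired residue-wise
#' Wilcoxon test, and Grantham / synthetic Schneider-Wrede-style distance
#' profiles over the aligned positions (aligned with [nw_align()] when
#' lengths differ). The distance profiles are summarized, not tested: they
#' measure divergence between the two variants, and positions shared by the
#' S and L forms are identical by construction.
#'
#' @param protein_s,protein_l the two protein sequences.
#' @param scale hydrophobicity scale name.
#' @return list with `composition` (+ `composition_test`), `hydrophobicity`
#'   (+ `hydrophobicity_test`), `grantham`, `schneider_wrede` summaries.
#' @export
run_features <- function(protein_s, protein_l, scale = "kyte_doolittle") {
  comp_s <- aa_composition(protein_s)
  comp_l <- aa_composition(protein_l)
  comp_test <- wilcoxon_test(comp_s, comp_l, paired = TRUE)
  hyd_s <- hydrophobicity_profile(protein_s, scale)
  hyd_l <- hydrophobicity_profile(protein_l, scale)
  hyd_test <- wilcoxon_test(as.numeric(hyd_s), as.numeric(hyd_l))
  if (nchar(protein_s) != nchar(protein_l)) {
    al <- nw_align(protein_s, protein_l)
    pa <- al$a_aligned; pb <- al$b_aligned
  } else {
    pa <- protein_s; pb <- protein_l
  }
  gp <- grantham_profile(pa, pb)
  sp <- schneider_wrede_profile(pa, pb)
  summarize <- function(v) list(mean = mean(v, na.rm = TRUE),
                                max = max(v, na.rm = TRUE),
                                n_nonzero = sum(v > 0, na.rm = TRUE),
                                n_excluded = sum(is.na(v)))
  list(composition = rbind(S = comp_s, L = comp_l),
       composition_test = comp_test,
       hydrophobicity = c(S = attr(hyd_s, "mean"), L = attr(hyd_l, "mean")),
       hydrophobicity_test = hyd_test,
       grantham = summarize(gp), schneider_wrede = summarize(sp))
}

#' Between-genome divergence, both corrections
#'
#' Convenience wrapper reporting Dxy under both the Jukes-Cantor correction
#' and the uncorrected p distance (the appropriate correction for closely
#' related mitochondrial genomes is debatable, so both are always shown).
#'
#' @param seqs_a,seqs_b aligned sequence sets.
#' @return data frame with one row per correction.
#' @export
run_dxy <- function(seqs_a, seqs_b) {
  do.call(rbind, lapply(c("none", "jc"), function(corr) {
    r <- dxy(seqs_a, seqs_b, correction = corr)
    data.frame(correction = corr, estimate = r$estimate, sd = r$sd,
               n_pairs = r$n_pairs)
  }))
}
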