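## DNA-vs-transcript concordance: a deterministic exact-seed + ungapped-
## extension read mapper (self-contained; no external aligner), RNA-DNA
## difference (RDD) calling, and S/L allele support counting at the focal
## stop-switch site. An RDD would be the signature RNA editing leaves; the
## codon-reassignment alternative likewise predicts none.

#' Map transcript reads to a gene by exact k-mer seeding
#'
#' Each read is anchored by exact k-mer seeds (both orientations are tried),
#' candidate offsets are scored by ungapped identity over the full read, and
#' reads below `min_identity` (or extending past either gene end) are
#' discarded and tallied. The result is a per-position pileup of base counts
#' on the gene's reading strand.
#'
#' @param gene gene DNA string (reading orientation).
#' @param reads a read set: data frame with `id`, `seq` (and optional
#'   `qual`), as from [read_fastq()] or [simulate_reads()].
#' @param k seed length, >= 11.
#' @param min_identity minimum fraction of matching bases.
#' @return object of class `pileup`: list with `gene`, `counts` (4 x L
#'   integer matrix, rows A/C/G/T), `depth`, `n_mapped`, `n_discarded`.
#' @export
map_reads <- function(gene, reads, k = 15L, min_identity = 0.9) {
  gene <- toupper(gene)
  check_dna(gene, "gene")
  if (k < 11L) ssw_error("seed length k must be >= 11", "ssw_input_error")
  L <- nchar(gene)
  if (L < k) ssw_error("gene shorter than the seed length", "ssw_input_error")
  reads <- validate_read_set(as.data.frame(reads))

  gkm <- substring(gene, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  index <- split(seq_along(gkm), gkm)
  gchars <- strsplit(gene, "")[[1]]

  counts <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  n_mapped <- 0L; n_discarded <- 0L

  for (i in seq_len(nrow(reads))) {
    rd <- toupper(reads$seq[i])
    best <- list(ident = -1, off = NA_integer_, chars = NULL)
    for (orient in c("fwd", "rev")) {
      rseq <- if (orient == "fwd") rd else reverse_complement(rd)
      rl <- nchar(rseq)
      if (rl < k) next
      rchars <- strsplit(rseq, "")[[1]]
      seed_starts <- unique(c(seq(1L, rl - k + 1L, by = k), rl - k + 1L))
      offsets <- integer()
      for (s in seed_starts) {
        hit <- index[[substring(rseq, s, s + k - 1L)]]
        if (!is.null(hit)) offsets <- c(offsets, hit - s + 1L)
      }
      for (off in unique(offsets)) {
        if (off < 1L || off + rl - 1L > L) next
        ident <- mean(rchars == gchars[off:(off + rl - 1L)])
        if (ident > best$ident) best <- list(ident = ident, off = off,
                                             chars = rchars)
        if (ident == 1) break
      }
      if (best$ident == 1) break
    }
    if (best$ident >= min_identity) {
      n_mapped <- n_mapped + 1L
      pos <- best$off:(best$off + length(best$chars) - 1L)
      bi <- match(best$chars, c("A", "C", "G", "T"))
      keep <- !is.na(bi)
      counts[cbind(bi[keep], pos[keep])] <-
        counts[cbind(bi[keep], pos[keep])] + 1L
    } else {
      n_discarded <- n_discarded + 1L
    }
  }
  structure(list(gene = gene, counts = counts, depth = colSums(counts),
                 n_mapped = n_mapped, n_discarded = n_discarded,
                 k = k, min_identity = min_identity),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d bp gene, %d read(s) mapped, %d discarded, mean depth %.1f\n",
              nchar(x$gene), x$n_mapped, x$n_discarded, mean(x$depth)))
  invisible(x)
}

#' Call RNA-DNA differences from a pileup
#'
#' A position is an RDD site when its depth reaches `min_depth` and the
#' modal read base differs from the genomic base with frequency at least
#' `min_alt_fraction` (consensus-style calling, so the fraction threshold
#' must exceed 0.5). Verdicts: `concordant` when no RDD site is found and
#' the focal site (when given) is adequately covered; `discordant` when any
#' RDD site exists; `insufficient` when the focal site is under-covered.
#'
#' When `focal_site` is given it is excluded from RDD scanning: the focal
#' base is a known DNA polymorphism whose transcript support is assessed
#' separately with [count_allele_support()], so a mixed S/L transcript pool
#' is not mistaken for editing at that site.
#'
#' @param pileup from [map_reads()].
#' @param min_depth minimum depth for a callable position.
#' @param min_alt_fraction consensus threshold in (0.5, 1].
#' @param focal_site optional 1-based focal position (the stop-switch site).
#' @return object of class `concordance_report`: `covered_positions`
#'   (depth >= min_depth), `rdd_sites` (data frame: position, dna_base,
#'   rna_consensus_base, depth, alt_fraction), `s_support`, `l_support`
#'   (`NA` until [count_allele_support()]), `verdict`.
#' @export
call_rdd <- function(pileup, min_depth = 5L, min_alt_fraction = 0.8,
                     focal_site = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  if (min_depth <= 0) ssw_error("min_depth must be positive", "ssw_input_error")
  if (min_alt_fraction <= 0.5 || min_alt_fraction > 1) {
    ssw_error("min_alt_fraction must lie in (0.5, 1] for consensus calling",
              "ssw_input_error")
  }
  dna <- strsplit(pileup$gene, "")[[1]]
  depth <- pileup$depth
  callable <- which(depth >= min_depth)
  rdd <- list()
  for (pos in setdiff(callable, focal_site)) {
    col <- pileup$counts[, pos]
    top <- which(col == max(col))
    ## tie including the genomic base is not a difference
    if (dna[pos] %in% rownames(pileup$counts)[top]) next
    frac <- max(col) / depth[pos]
    if (frac >= min_alt_fraction) {
      rdd[[length(rdd) + 1L]] <-
        data.frame(position = pos, dna_base = dna[pos],
                   rna_consensus_base = rownames(pileup$counts)[top[1L]],
                   depth = depth[pos], alt_fraction = frac)
    }
  }
  rdd <- if (length(rdd)) do.call(rbind, rdd) else
    data.frame(position = integer(), dna_base = character(),
               rna_consensus_base = character(), depth = integer(),
               alt_fraction = numeric())
  verdict <- if (!is.null(focal_site) && depth[focal_site] < min_depth) {
    "insufficient"
  } else if (nrow(rdd) > 0L) "discordant" else "concordant"
  structure(list(covered_positions = length(callable), rdd_sites = rdd,
                 s_support = NA_integer_, l_support = NA_integer_,
                 verdict = verdict, min_depth = min_depth,
                 min_alt_fraction = min_alt_fraction,
                 focal_site = focal_site),
            class = "concordance_report")
}

#' Count transcript reads supporting each allele at the focal site
#'
#' @param pileup from [map_reads()].
#' @param focal_site 1-based position of the stop-switch site within the
#'   gene (488 in the sea urchin ND6 case).
#' @param s_allele,l_allele the two alleles (distinct single bases; A and G
#'   in the sea urchin case).
#' @return named integer vector `c(s_support =, l_support =)`.
#' @export
count_allele_support <- function(pileup, focal_site, s_allele = "A",
                                 l_allele = "G") {
  stopifnot(inherits(pileup, "pileup"))
  if (focal_site < 1L || focal_site > nchar(pileup$gene)) {
    ssw_error("focal site outside the gene", "ssw_input_error")
  }
  s_allele <- toupper(s_allele); l_allele <- toupper(l_allele)
  if (s_allele == l_allele || !all(c(s_allele, l_allele) %in% c("A","C","G","T"))) {
    ssw_error("alleles must be two distinct bases", "ssw_input_error")
  }
  c(s_support = unname(pileup$counts[s_allele, focal_site]),
    l_support = unname(pileup$counts[l_allele, focal_site]))
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance> verdict %s: %d callable position(s), %d RDD site(s)%s\n",
              x$verdict, x$covered_positions, nrow(x$rdd_sites),
              if (!is.na(x$s_support))
                sprintf("; focal support S=%d L=%d", x$s_support, x$l_support)
              else ""))
  if (nrow(x$rdd_sites)) print(x$rdd_sites)
  invisible(x)
}
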