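## The core procedure: classify orthologous mitochondrial genes into S
## (short) and L (long, stop-readthrough) variants, localize the stop-switch
## substitution, and measure overlap with the adjacent opposite-strand gene.
##
## Site numbering in all outputs is 1-based from the gene's first base on the
## reading strand (so the sea urchin ND6 focal site is 488: the middle base
## of the stop codon that follows 162 sense codons).

#' Classify a coding sequence as S, L or other
#'
#' Translates under the halt policy and compares the realized protein length
#' with a reference short-variant length. With a reference of R residues:
#' class `S` when the protein has exactly R residues; `L` when longer (the
#' first stop falls downstream of the reference stop position); `other`
#' otherwise (flagged `truncated`). Input may carry genomic context beyond
#' the realized stop; `cds_length_nt` is always the realized coding length
#' including the stop codon.
#'
#' For an L call, `extension_nt` is the downstream elongation: the segment
#' after the former (reference) stop codon through the realized stop codon
#' inclusive, so `cds_length_nt(L) - cds_length_nt(S) == nchar(extension_nt)`.
#' `extension_aa` is the additional residues, i.e. it starts with the
#' translated readthrough codon (Trp-Leu-Trp in the sea urchin case).
#'
#' @param cds DNA string in reading orientation (see [extract_gene_cds()]),
#'   length >= 6.
#' @param code a [load_code()] genetic code.
#' @param reference_protein_length reference S length in residues, or `NULL`
#'   (class left `NA`; [scan_cohort()] derives the reference from a cohort).
#' @param taxon,id optional labels carried into the call.
#' @return object of class `variant_call` (a list; see fields above plus
#'   `notes`, a character vector of flags).
#' @export
classify_variant <- function(cds, code, reference_protein_length = NULL,
                             taxon = NA_character_, id = NA_character_) {
  cds <- toupper(cds)
  check_dna(cds, "cds")
  if (nchar(cds) < 6L) ssw_error("cds shorter than 6 nt", "ssw_input_error")
  tr <- translate_cds(cds, code, "halt")
  notes <- character()
  call <- list(taxon = taxon, id = id, variant_class = NA_character_,
               cds_length_nt = NA_integer_, protein_length_aa = NA_integer_,
               stop_switch_site = NA_integer_, ref_allele = NA_character_,
               alt_allele = NA_character_, extension_nt = "",
               extension_aa = "", overlap_bp = NA_integer_, notes = notes)
  class(call) <- "variant_call"

  if (is.na(tr$stop_codon)) {
    call$variant_class <- "other"
    call$protein_length_aa <- nchar(tr$protein)
    call$notes <- "no-stop"
    return(call)
  }
  p <- nchar(tr$protein)
  call$protein_length_aa <- p
  call$cds_length_nt <- 3L * p + 3L

  R <- reference_protein_length
  if (is.null(R)) {
    call$notes <- "unclassified:no-reference"
    return(call)
  }
  ## N inside the focal (reference stop) codon makes the S/L state uncallable
  focal_codon <- substring(cds, 3L * R + 1L, 3L * R + 3L)
  if (grepl("N", focal_codon, fixed = TRUE)) notes <- c(notes, "ambiguous")

  if (p == R) {
    call$variant_class <- "S"
  } else if (p > R) {
    call$variant_class <- "L"
    call$extension_nt <- substring(cds, 3L * R + 4L, 3L * p + 3L)
    call$extension_aa <- substring(tr$protein, R + 1L, p)
  } else {
    call$variant_class <- "other"
    notes <- c(notes, "truncated")
  }
  call$notes <- notes
  call
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("<variant_call>%s class %s, %s aa, %s nt%s%s\n",
              if (is.na(x$id)) "" else paste0(" ", x$id, ":"),
              x$variant_class, x$protein_length_aa,
              x$cds_length_nt,
              if (nzchar(x$extension_aa))
                sprintf(", extension %s", x$extension_aa) else "",
              if (length(x$notes)) sprintf(" [%s]",
                                           paste(x$notes, collapse = ";")) else ""))
  invisible(x)
}

#' Localize the stop-switch substitution between an S and an L sequence
#'
#' Scans the shared prefix for the unique position where replacing the S base
#' with the L base converts an in-frame stop codon into a sense codon. The
#' position is reported 1-based from the gene's first base.
#'
#' @param cds_s,cds_l S- and L-form coding sequences sharing the S-region
#'   reading frame (they may differ in length).
#' @param code genetic code.
#' @return list with `site` (1-based), `ref_allele`, `alt_allele`.
#'   Zero or multiple candidate positions raise an ambiguity error listing
#'   the candidates.
#' @export
localize_stop_switch <- function(cds_s, cds_l, code) {
  cds_s <- toupper(cds_s); cds_l <- toupper(cds_l)
  check_dna(cds_s, "cds_s"); check_dna(cds_l, "cds_l")
  n <- min(nchar(cds_s), nchar(cds_l))
  s <- strsplit(substring(cds_s, 1L, n), "")[[1]]
  l <- strsplit(substring(cds_l, 1L, n), "")[[1]]
  tab <- code$codon_to_aa
  cand <- integer()
  for (i in which(s != l)) {
    ci <- (i - 1L) %/% 3L            # 0-based codon index
    a <- 3L * ci + 1L; b <- 3L * ci + 3L
    if (b > nchar(cds_s)) next       # incomplete codon in S
    cod_s <- substring(cds_s, a, b)
    cod_mut <- cod_s
    substr(cod_mut, i - a + 1L, i - a + 1L) <- l[i]
    if (!grepl("N", cod_s, fixed = TRUE) && tab[[cod_s]] == "*" &&
        tab[[cod_mut]] != "*") {
      cand <- c(cand, i)
    }
  }
  if (length(cand) != 1L) {
    ssw_error(sprintf(
      "expected exactly one stop-to-sense substitution; found %d%s",
      length(cand),
      if (length(cand)) paste0(" (candidate positions: ",
                               paste(cand, collapse = ", "), ")") else ""),
      "ssw_ambiguity_error")
  }
  list(site = cand, ref_allele = s[cand], alt_allele = l[cand])
}

#' Overlap in bp between two gene intervals
#'
#' Strand-agnostic intersection of the two forward-strand intervals,
#' circular-aware (features may wrap the origin). Pass the realized
#' (possibly extended) interval for a readthrough gene.
#'
#' @param feature_a,feature_b lists or one-row data frames with `start`,
#'   `end` (0-based half-open) and `wraps_origin`.
#' @param genome_length genome length in bp.
#' @param topology `"linear"` or `"circular"`.
#' @return integer overlap in bp (0 when disjoint).
#' @export
compute_overlap <- function(feature_a, feature_b, genome_length,
                            topology = "circular") {
  spans <- function(f) {
    w <- isTRUE(f$wraps_origin)
    if (w) {
      list(c(f$start, genome_length), c(0L, f$end))
    } else list(c(f$start, f$end))
  }
  total <- 0L
  for (a in spans(as.list(feature_a))) {
    for (b in spans(as.list(feature_b))) {
      total <- total + max(0L, min(a[2], b[2]) - max(a[1], b[1]))
    }
  }
  as.integer(total)
}

#' Scan a cohort of orthologous gene sequences
#'
#' Classifies every sequence against a cohort-derived (or supplied) S
#' reference length and builds the per-taxon S/L character-state map. The S
#' reference is the minimum well-formed (stop-found) protein length observed
#' in the cohort; sequences longer than the reference are L, and L calls
#' longer than the modal L length are additionally flagged
#' `extra-length:+k` (k extra residues). For each L call the stop-switch
#' substitution is localized against an S sequence (same taxon when
#' available) and reported in per-sequence coordinates.
#'
#' @param seqs named character vector of coding sequences in reading
#'   orientation (>= 2 sequences).
#' @param code genetic code.
#' @param taxa taxon label per sequence (defaults to the sequence names, i.e.
#'   each sequence its own taxon); multiple sequences per taxon describe an
#'   intraspecific sample.
#' @param reference_protein_length optional explicit S length.
#' @return list of class `cohort_scan`:
#'   `calls` (data frame, one row per sequence), `states` (named list
#'   taxon -> subset of c("S","L"); sequences classed `other` are excluded
#'   from the map, mirroring the exclusion of truncated genes), and
#'   `counts` (per-taxon class counts).
#' @export
scan_cohort <- function(seqs, code, taxa = names(seqs),
                        reference_protein_length = NULL) {
  if (length(seqs) < 2L) ssw_error("cohort needs >= 2 sequences",
                                   "ssw_input_error")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  stopifnot(length(taxa) == length(seqs))

  pre <- lapply(seqs, function(s) translate_cds(toupper(s), code, "halt"))
  wf <- !vapply(pre, function(t) is.na(t$stop_codon), logical(1))
  if (!any(wf)) ssw_error("no sequence in the cohort reaches a stop codon",
                          "ssw_input_error")
  ref <- reference_protein_length %||%
    min(vapply(pre[wf], function(t) nchar(t$protein), integer(1)))

  calls <- lapply(seq_along(seqs), function(i) {
    classify_variant(seqs[[i]], code, ref, taxon = taxa[[i]],
                     id = names(seqs)[[i]])
  })

  ## flag L calls longer than the modal L protein length
  lp <- vapply(calls, function(cl)
    if (identical(cl$variant_class, "L")) cl$protein_length_aa else NA_integer_,
    integer(1))
  if (any(!is.na(lp))) {
    tab <- table(lp[!is.na(lp)])
    modal_l <- min(as.integer(names(tab)[tab == max(tab)]))
    for (i in which(!is.na(lp) & lp > modal_l)) {
      calls[[i]]$notes <- c(calls[[i]]$notes,
                            sprintf("extra-length:+%d", lp[i] - modal_l))
    }
  }

  ## localize the stop switch for each L call against an S partner
  s_idx <- which(vapply(calls, function(cl)
    identical(cl$variant_class, "S"), logical(1)))
  for (i in which(!is.na(lp))) {
    partner <- s_idx[taxa[s_idx] == taxa[i]][1]
    if (is.na(partner)) partner <- s_idx[1]
    if (is.na(partner)) next
    loc <- tryCatch(localize_stop_switch(seqs[[partner]], seqs[[i]], code),
                    stopswitch_error = function(e) NULL)
    if (is.null(loc)) {
      calls[[i]]$notes <- c(calls[[i]]$notes, "stop-switch-not-localized")
    } else {
      calls[[i]]$stop_switch_site <- loc$site
      calls[[i]]$ref_allele <- loc$ref_allele
      calls[[i]]$alt_allele <- loc$alt_allele
    }
  }

  df <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(taxon = cl$taxon, id = cl$id, variant_class = cl$variant_class,
               protein_length_aa = cl$protein_length_aa,
               cds_length_nt = cl$cds_length_nt,
               stop_switch_site = cl$stop_switch_site,
               ref_allele = cl$ref_allele, alt_allele = cl$alt_allele,
               extension_nt = cl$extension_nt, extension_aa = cl$extension_aa,
               notes = paste(cl$notes, collapse = ";"))
  }))

  states <- lapply(split(df$variant_class, df$taxon), function(v)
    sort(intersect(unique(v), c("S", "L"))))
  states <- states[lengths(states) > 0L]
  counts <- do.call(rbind, lapply(split(df, df$taxon), function(d)
    data.frame(taxon = d$taxon[1], n_S = sum(d$variant_class == "S"),
               n_L = sum(d$variant_class == "L"),
               n_other = sum(d$variant_class == "other"))))
  rownames(counts) <- NULL
  structure(list(calls = df, states = states, counts = counts,
                 reference_protein_length = ref),
            class = "cohort_scan")
}

#' @export
print.cohort_scan <- function(x, ...) {
  cat(sprintf("<cohort_scan> %d sequence(s), S reference %d aa\n",
              nrow(x$calls), x$reference_protein_length))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$calls$variant_class)),
                            table(x$calls$variant_class)), collapse = " ")))
  invisible(x)
}

#' Realize the coding sequence of an annotated gene, extending past the
#' annotated end when no in-frame stop is found
#'
#' Extracts the annotated gene, translates under halt, and, when the
#' annotated span contains no stop (the readthrough allele of a gene
#' annotated in its short form), walks further codons downstream in reading
#' direction (circular-aware) until a stop or `max_extension_codons`.
#'
#' @param record a [genome_record()].
#' @param gene_name gene to realize.
#' @param code genetic code.
#' @param max_extension_codons search limit past the annotated end.
#' @return list: `cds` (realized coding sequence ending at its stop, or the
#'   annotated sequence flagged `no-stop`), `feature` (realized 0-based
#'   forward-strand interval), `extended_nt` (bases added past the
#'   annotation), `no_stop` (logical).
#' @export
realized_cds <- function(record, gene_name, code, max_extension_codons = 50L) {
  f <- record$features[record$features$gene_name == gene_name, ]
  if (nrow(f) != 1L) {
    ssw_error(sprintf("expected one %s feature, found %d", gene_name, nrow(f)),
              "ssw_lookup_error")
  }
  cds <- extract_gene_cds(record, gene_name)
  glen <- nchar(record$sequence)
  tr <- translate_cds(cds, code, "halt")
  extended <- 0L
  while (is.na(tr$stop_codon) && extended < 3L * max_extension_codons) {
    ## fetch the next downstream codon in reading direction
    nxt <- if (f$strand == 1L) {
      genome_slice(record, (f$end + extended) %% glen, 3L)
    } else {
      genome_slice(record, (f$start - extended - 3L) %% glen, 3L)
    }
    if (f$strand == -1L) nxt <- reverse_complement(nxt)
    cds <- paste0(cds, nxt)
    extended <- extended + 3L
    tr <- translate_cds(cds, code, "halt")
  }
  no_stop <- is.na(tr$stop_codon)
  realized_len <- if (no_stop) nchar(cds) else tr$stop_position_nt + 2L
  cds <- substring(cds, 1L, realized_len)
  ann_len <- if (f$wraps_origin) (glen - f$start) + f$end else f$end - f$start
  extra <- realized_len - ann_len
  feature <- as.list(f)
  if (extra > 0L) {
    if (f$strand == 1L) {
      feature$end <- (f$end + extra)
      if (feature$end > glen) { feature$end <- feature$end %% glen
                                feature$wraps_origin <- TRUE }
    } else {
      feature$start <- f$start - extra
      if (feature$start < 0L) { feature$start <- feature$start %% glen
                                feature$wraps_origin <- TRUE }
    }
  } else if (extra < 0L) {
    if (f$strand == 1L) feature$end <- f$end + extra
    else feature$start <- f$start - extra
  }
  list(cds = cds, feature = feature,
       extended_nt = if (extra > 0L) substring(cds, ann_len + 1L) else "",
       no_stop = no_stop)
}
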