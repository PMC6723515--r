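## Readers and writers for the formats the pipeline touches, plus the
## coordinate conversion between GenBank (1-based inclusive) and the internal
## convention (0-based half-open on the forward strand).

#' Construct a genome record
#'
#' @param identifier accession-like string (non-empty).
#' @param sequence uppercase DNA over `{A,C,G,T,N}`.
#' @param topology `"linear"` or `"circular"`.
#' @param features data frame with columns `gene_name`, `start`, `end`
#'   (0-based half-open, forward strand), `strand` (+1/-1), `wraps_origin`.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(identifier, sequence, topology = "linear",
                          features = empty_features()) {
  sequence <- toupper(sequence)
  if (!nzchar(identifier)) ssw_error("empty identifier", "ssw_validation_error")
  if (!nzchar(sequence)) ssw_error("empty sequence", "ssw_validation_error")
  check_dna(sequence, identifier)
  topology <- match.arg(topology, c("linear", "circular"))
  features <- as.data.frame(features)
  glen <- nchar(sequence)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (!nzchar(f$gene_name)) ssw_error("feature with empty gene name",
                                        "ssw_validation_error")
    ok <- if (f$wraps_origin) {
      f$start > f$end && f$start < glen && f$end <= glen
    } else {
      f$start >= 0 && f$start < f$end && f$end <= glen
    }
    if (!ok) {
      ssw_error(sprintf("feature %s [%d,%d) out of bounds for %d-bp genome",
                        f$gene_name, f$start, f$end, glen),
                "ssw_validation_error")
    }
  }
  structure(list(identifier = identifier, sequence = sequence,
                 topology = topology, features = features),
            class = "genome_record")
}

empty_features <- function() {
  data.frame(gene_name = character(), start = integer(), end = integer(),
             strand = integer(), wraps_origin = logical())
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d feature(s)\n", x$identifier,
              nchar(x$sequence), x$topology, nrow(x$features)))
  if (nrow(x$features)) print(x$features)
  invisible(x)
}

## Default synonym table for gene-name normalization; GenBank submitters name
## the NADH dehydrogenase subunits inconsistently (ND6 / NADH6 / nad6 ...).
#' @export
default_gene_synonyms <- function() {
  list(ND5 = c("ND5", "NADH5", "NAD5", "NADH DEHYDROGENASE SUBUNIT 5", "MT-ND5"),
       ND6 = c("ND6", "NADH6", "NAD6", "NADH DEHYDROGENASE SUBUNIT 6", "MT-ND6"))
}

normalize_gene_name <- function(name, synonyms = default_gene_synonyms()) {
  up <- toupper(trimws(name))
  for (canon in names(synonyms)) {
    if (up %in% toupper(synonyms[[canon]])) return(canon)
  }
  up
}

## Parse one GenBank location string into (start0, end0, strand, wraps).
## Supports `a..b`, `complement(...)`, and `join(...)` whose spans are
## contiguous (including join across the origin of a circular genome).
parse_location <- function(loc, glen, feature_label) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  spans <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1]]
  } else loc
  m <- regmatches(spans, regexec("^(\\d+)\\.\\.(\\d+)$", spans))
  single <- regmatches(spans, regexec("^(\\d+)$", spans))
  lo <- hi <- integer(length(spans))
  for (i in seq_along(spans)) {
    if (length(m[[i]]) == 3L) {
      lo[i] <- as.integer(m[[i]][2]); hi[i] <- as.integer(m[[i]][3])
    } else if (length(single[[i]]) == 2L) {
      lo[i] <- hi[i] <- as.integer(single[[i]][2])
    } else {
      ssw_error(sprintf("malformed location '%s' for feature %s",
                        loc, feature_label), "ssw_format_error")
    }
  }
  if (any(hi < lo) || any(hi > glen)) {
    ssw_error(sprintf("location '%s' of feature %s outside 1..%d",
                      loc, feature_label, glen), "ssw_format_error")
  }
  if (length(spans) == 1L) {
    return(list(start = lo - 1L, end = hi, strand = strand, wraps = FALSE))
  }
  ## join: spans must be contiguous; wrap allowed once at the origin
  wraps <- FALSE
  for (i in seq_len(length(spans) - 1L)) {
    if (lo[i + 1L] == hi[i] + 1L) next
    if (hi[i] == glen && lo[i + 1L] == 1L && !wraps) { wraps <- TRUE; next }
    ssw_error(sprintf("non-contiguous join location '%s' for feature %s",
                      loc, feature_label), "ssw_format_error")
  }
  if (wraps) {
    list(start = lo[1L] - 1L, end = hi[length(spans)], strand = strand,
         wraps = TRUE)
  } else {
    list(start = lo[1L] - 1L, end = hi[length(spans)], strand = strand,
         wraps = FALSE)
  }
}

#' Parse a GenBank flat file
#'
#' Reads LOCUS, the `gene`/`CDS` entries of the feature table (other feature
#' keys are ignored with a notice) and ORIGIN. GenBank 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention;
#' `complement(...)` becomes strand -1; a `join(...)` across the origin of a
#' circular genome sets `wraps_origin`. When both a `gene` and a `CDS` entry
#' describe the same gene the CDS span wins (it carries the coding interval).
#'
#' @param text GenBank flat-file content as a single string or character
#'   vector of lines; a path to a file is also accepted.
#' @param synonyms gene-name synonym table, see [default_gene_synonyms()].
#' @param quiet suppress notices about ignored feature keys.
#' @return a [genome_record()].
#' @export
parse_genbank <- function(text, synonyms = default_gene_synonyms(),
                          quiet = FALSE) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) ssw_error("missing LOCUS line", "ssw_format_error")
  locus <- strsplit(trimws(lines[locus_i[1L]]), "\\s+")[[1]]
  identifier <- locus[2L]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) {
    ssw_error(sprintf("record %s lacks an ORIGIN section", identifier),
              "ssw_format_error")
  }
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1L] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) ssw_error("empty ORIGIN section", "ssw_format_error")
  glen <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(feat_i)) {
    block <- lines[(feat_i[1L] + 1L):(origin_i[1L] - 1L)]
    ## feature lines have the key in columns 6-20; qualifier lines start with /
    is_key <- grepl("^ {2,5}\\S", block)
    keys <- which(is_key)
    ignored <- character()
    entries <- list()
    for (j in seq_along(keys)) {
      k <- keys[j]
      to <- if (j < length(keys)) keys[j + 1L] - 1L else length(block)
      key <- sub("^\\s+", "", sub("^(\\s*\\S+).*$", "\\1", block[k]))
      body <- c(sub("^\\s*\\S+\\s*", "", block[k]),
                if (to > k) trimws(block[(k + 1L):to]) else character(0))
      if (!(key %in% c("gene", "CDS"))) { ignored <- c(ignored, key); next }
      ## location = leading text up to the first qualifier line
      qual_start <- grep("^/", body)
      loc_txt <- paste(body[seq_len(if (length(qual_start))
        qual_start[1L] - 1L else length(body))], collapse = "")
      quals <- body[grepl("^/", body)]
      gene_q <- sub('^/gene="?([^"]*)"?$', "\\1",
                    grep("^/gene=", quals, value = TRUE))
      prod_q <- sub('^/product="?([^"]*)"?$', "\\1",
                    grep("^/product=", quals, value = TRUE))
      label <- if (length(gene_q)) gene_q[1L] else if (length(prod_q))
        prod_q[1L] else sprintf("%s_%d", key, j)
      entries[[length(entries) + 1L]] <-
        c(list(key = key, gene_name = normalize_gene_name(label, synonyms)),
          parse_location(loc_txt, glen, label))
    }
    if (length(ignored) && !quiet) {
      ssw_note("ignored feature key(s) in %s: %s", identifier,
               paste(unique(ignored), collapse = ", "))
    }
    if (length(entries)) {
      df <- do.call(rbind, lapply(entries, function(e)
        data.frame(key = e$key, gene_name = e$gene_name, start = e$start,
                   end = e$end, strand = e$strand, wraps_origin = e$wraps)))
      ## prefer the CDS span when both gene and CDS exist for a gene
      keep <- !duplicated(df$gene_name, fromLast = FALSE)
      cds_rows <- df$key == "CDS"
      for (g in unique(df$gene_name)) {
        rows <- which(df$gene_name == g)
        pick <- rows[cds_rows[rows]][1L]
        if (is.na(pick)) pick <- rows[1L]
        keep[rows] <- FALSE; keep[pick] <- TRUE
      }
      feats <- df[keep, c("gene_name", "start", "end", "strand",
                          "wraps_origin")]
      rownames(feats) <- NULL
    }
  }
  genome_record(identifier, sequence, topology, feats)
}

#' Write a genome record as GenBank flat-file text
#'
#' Emits the dialect [parse_genbank()] reads back losslessly: LOCUS, a
#' FEATURES table with one `gene` entry per feature, and ORIGIN.
#'
#' @param record a [genome_record()].
#' @param path optional output file; when `NULL` the text is returned.
#' @return the GenBank text, invisibly when written to `path`.
#' @export
write_genbank <- function(record, path = NULL) {
  glen <- nchar(record$sequence)
  out <- c(sprintf("LOCUS       %s%17d bp    DNA     %s   UNA",
                   record$identifier, glen, record$topology),
           sprintf("DEFINITION  %s synthetic record.", record$identifier),
           "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(record$features))) {
    f <- record$features[i, ]
    loc <- if (f$wraps_origin) {
      sprintf("join(%d..%d,1..%d)", f$start + 1L, glen, f$end)
    } else {
      sprintf("%d..%d", f$start + 1L, f$end)
    }
    if (f$strand == -1L) loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     gene            %s", loc),
             sprintf("                     /gene=\"%s\"", f$gene_name))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, glen, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, glen), by = 10L)
    chunk <- substring(record$sequence, starts, pmin(starts + 9L, glen))
    out <- c(out, sprintf("%9d %s", p, paste(tolower(chunk), collapse = " ")))
  }
  out <- c(out, "//")
  txt <- paste(out, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

## Circular-aware slice of `len` bases starting at 0-based `from0`.
genome_slice <- function(record, from0, len) {
  glen <- nchar(record$sequence)
  idx <- ((from0 + seq_len(len) - 1L) %% glen) + 1L
  if (record$topology == "linear" && (from0 < 0L || from0 + len > glen)) {
    ssw_error("slice outside a linear genome", "ssw_input_error")
  }
  paste(substring(record$sequence, idx, idx), collapse = "")
}

#' Extract the reading-strand sequence of a gene
#'
#' Forward slice for strand +1; reverse complement of the slice for strand
#' -1; a feature wrapping the origin of a circular genome is concatenated
#' across the origin before orientation.
#'
#' @param record a [genome_record()].
#' @param gene_name canonical gene name (after synonym normalization).
#' @return DNA string in reading orientation.
#' @export
extract_gene_cds <- function(record, gene_name) {
  hits <- which(record$features$gene_name == gene_name)
  if (length(hits) != 1L) {
    ssw_error(sprintf(
      "expected exactly one feature named %s in %s; found %d (features: %s)",
      gene_name, record$identifier, length(hits),
      paste(record$features$gene_name, collapse = ", ")), "ssw_lookup_error")
  }
  f <- record$features[hits, ]
  glen <- nchar(record$sequence)
  fwd <- if (f$wraps_origin) {
    genome_slice(record, f$start, (glen - f$start) + f$end)
  } else {
    substring(record$sequence, f$start + 1L, f$end)
  }
  if (f$strand == -1L) reverse_complement(fwd) else fwd
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Identifiers are the token up to the first
#' whitespace; duplicate identifiers are an error; FASTA is written at 70
#' columns.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    ssw_error(sprintf("duplicate FASTA identifier(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "ssw_format_error")
  }
  setNames(toupper(as.character(x)), ids)
}

#' @param seqs named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    ssw_error("all sequences must be named", "ssw_validation_error")
  }
  if (anyDuplicated(names(seqs))) {
    ssw_error("duplicate identifiers in FASTA output", "ssw_format_error")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read FASTQ into a read set
#'
#' @param path FASTQ file.
#' @return data frame with columns `id`, `seq`, `qual` (class `read_set`).
#'   A quality string whose length differs from its read is an error.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    ssw_error(sprintf("malformed FASTQ %s: %d lines is not a multiple of 4",
                      path, length(lines)), "ssw_format_error")
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  if (any(!startsWith(hdr, "@")) || any(!startsWith(plus, "+"))) {
    ssw_error(sprintf("malformed FASTQ %s: record markers out of phase", path),
              "ssw_format_error")
  }
  reads <- data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)),
                      seq = toupper(lines[seq(2L, length(lines), by = 4L)]),
                      qual = lines[seq(4L, length(lines), by = 4L)])
  validate_read_set(reads)
}

validate_read_set <- function(reads) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  if (is.null(reads$qual)) reads$qual <- NA_character_
  bad <- !is.na(reads$qual) & nchar(reads$qual) != nchar(reads$seq)
  if (any(bad)) {
    ssw_error(sprintf("quality length mismatch for read(s): %s",
                      paste(reads$id[bad], collapse = ", ")),
              "ssw_format_error")
  }
  class(reads) <- c("read_set", "data.frame")
  reads
}

write_fastq <- function(reads, path) {
  reads <- validate_read_set(reads)
  qual <- ifelse(is.na(reads$qual), strrep("I", nchar(reads$seq)), reads$qual)
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)),
             path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Wrappers over ape keeping the package's single tree representation
#' (`ape::phylo`).
#' @param x Newick string or file path (`read_newick`); a `phylo`
#'   (`write_newick`).
#' @export
read_newick <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) ssw_error("could not parse Newick input", "ssw_format_error")
  tr
}

#' @param path optional output path.
#' @rdname read_newick
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "phylo"))
  if (is.null(path)) return(ape::write.tree(x))
  ape::write.tree(x, file = path)
  invisible(path)
}

#' Write a tabular report
#'
#' All pipeline reports are tab-separated with a header line and no quoting;
#' existing files are never overwritten silently.
#'
#' @param df data frame.
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_report_tsv <- function(df, path, force = FALSE) {
  if (file.exists(path) && !force) {
    ssw_error(sprintf("refusing to overwrite %s (use force = TRUE)", path),
              "ssw_output_error")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
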