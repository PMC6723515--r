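## Genetic-code tables and conceptual translation, including forced
## readthrough past a designated stop codon.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

#' Load a genetic code table
#'
#' Codes are shipped as plain-text tables (one line per codon,
#' `CODON<TAB>AA-or-*`, with `# name:` and `# starts:` header lines), so users
#' can swap or edit tables. The registry ships `"echinoderm_mt"` (NCBI
#' translation table 9: TGA=Trp, AGA/AGG=Ser, AAA=Asn; stops TAA and TAG),
#' `"invertebrate_mt"` (table 5) and `"standard"` (table 1).
#'
#' @param name_or_file registry name or path to a code-table file.
#' @return an object of class `genetic_code`: list with `name`,
#'   `codon_to_aa` (named character of length 64, `*` marks stops), `stops`,
#'   and `starts`.
#' @examples
#' code <- load_code("echinoderm_mt")
#' code$stops           # "TAA" "TAG"
#' code$codon_to_aa[["TGA"]]  # "W"
#' @export
load_code <- function(name_or_file) {
  registry <- c("echinoderm_mt", "standard", "invertebrate_mt")
  path <- if (name_or_file %in% registry) {
    ssw_extdata("codes", paste0(name_or_file, ".tsv"))
  } else if (file.exists(name_or_file)) {
    name_or_file
  } else {
    ssw_error(sprintf(
      "unknown genetic code '%s' (registry: %s) and no such file",
      name_or_file, paste(registry, collapse = ", ")), "ssw_lookup_error")
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  name <- sub("^#\\s*name:\\s*", "", grep("^#\\s*name:", hdr, value = TRUE))
  starts <- strsplit(sub("^#\\s*starts:\\s*", "",
                         grep("^#\\s*starts:", hdr, value = TRUE)), "\\s+")[[1]]
  body <- lines[!grepl("^#|^\\s*$", lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    ssw_error("malformed code table: expected CODON<TAB>AA lines",
              "ssw_validation_error")
  }
  codons <- toupper(vapply(parts, `[[`, "", 1L))
  aas <- vapply(parts, `[[`, "", 2L)
  tab <- setNames(aas, codons)
  missing <- setdiff(ALL_CODONS, codons)
  if (length(missing) > 0L) {
    ssw_error(sprintf("incomplete code table: missing codon(s) %s",
                      paste(missing, collapse = ",")), "ssw_validation_error")
  }
  if (length(unique(codons)) != 64L || length(codons) != 64L) {
    ssw_error("code table must map exactly the 64 codons once each",
              "ssw_validation_error")
  }
  stops <- sort(names(tab)[tab == "*"])
  if (length(stops) == 0L) {
    ssw_error("code table has an empty stop set", "ssw_validation_error")
  }
  structure(list(name = if (length(name)) name else basename(path),
                 codon_to_aa = tab[ALL_CODONS],
                 stops = stops,
                 starts = if (length(starts)) starts else "ATG"),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> %s\n  stops: %s\n  starts: %s\n", x$name,
              paste(x$stops, collapse = " "), paste(x$starts, collapse = " ")))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' `N` complements to `N`. The operation is an involution.
#'
#' @param seq DNA string over `{A,C,G,T,N}` (lower case accepted).
#' @return reverse-complemented string, upper case.
#' @examples reverse_complement("CTA")  # "TAG"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq, "reverse_complement() input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Resolve one codon to a single-letter residue ('*' for stop).  Codons with N
## are expanded over A/C/G/T; if every resolution agrees the consensus is used,
## otherwise 'X'.  A codon counts as a stop only when *all* resolutions stop.
resolve_codon <- function(codon, tab) {
  if (!grepl("N", codon, fixed = TRUE)) return(tab[[codon]])
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  opts <- lapply(chars, function(b) if (b == "N") c("A", "C", "G", "T") else b)
  combos <- expand.grid(opts, stringsAsFactors = FALSE)
  aas <- unique(tab[apply(combos, 1L, paste0, collapse = "")])
  if (length(aas) == 1L) aas else "X"
}

#' Conceptual translation with configurable stop policy
#'
#' Translates a coding sequence in frame 1. Three stop policies:
#' \describe{
#'   \item{`halt`}{stop at the first (unambiguous) stop codon.}
#'   \item{`readthrough_once`}{translate the first stop as `readthrough_aa`
#'     and continue to the next stop. This models a stop-switch allele read
#'     through its former stop (the sea urchin case is TAG read as Trp after
#'     the focal A-to-G change).}
#'   \item{`translate_through`}{translate every codon; stops appear as `*`.}
#' }
#' Codons containing `N` translate to `X` unless all resolutions agree; an
#' ambiguous codon never halts translation. Incomplete terminal codons (1-2
#' leftover bases) are reported in `trailing_partial`, never silently dropped.
#'
#' @param cds DNA string, length >= 3, reading orientation, frame 1.
#' @param code a [load_code()] object.
#' @param stop_policy one of `"halt"`, `"readthrough_once"`,
#'   `"translate_through"`.
#' @param readthrough_aa residue substituted for the first stop under
#'   `readthrough_once`.
#' @return `translation_result`: list with `protein`, `stop_codon` (or `NA`),
#'   `stop_position_nt` (1-based first base of the realized stop, or `NA`),
#'   and `trailing_partial` (leftover bases, possibly `""`).
#' @examples
#' code <- load_code("echinoderm_mt")
#' translate_cds("TGGTTATGATAA", code)  # protein "WLW", stop TAA at nt 10
#' @export
translate_cds <- function(cds, code,
                          stop_policy = c("halt", "readthrough_once",
                                          "translate_through"),
                          readthrough_aa = "W") {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(code, "genetic_code"))
  cds <- toupper(cds)
  check_dna(cds, "cds")
  n <- nchar(cds)
  if (n < 3L) ssw_error("cds shorter than one codon", "ssw_input_error")
  n_codons <- n %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  tab <- code$codon_to_aa
  aas <- vapply(codons, resolve_codon, "", tab = tab, USE.NAMES = FALSE)

  trailing <- if (n %% 3L) substring(cds, 3L * n_codons + 1L, n) else ""
  res <- function(protein, stop_codon, stop_pos, trail) {
    structure(list(protein = protein, stop_codon = stop_codon,
                   stop_position_nt = stop_pos, trailing_partial = trail),
              class = "translation_result")
  }

  if (stop_policy == "translate_through") {
    first_stop <- match("*", aas)
    return(res(paste(aas, collapse = ""),
               if (is.na(first_stop)) NA_character_ else codons[first_stop],
               if (is.na(first_stop)) NA_integer_ else 3L * (first_stop - 1L) + 1L,
               trailing))
  }

  stops <- which(aas == "*")
  if (stop_policy == "readthrough_once" && length(stops) > 0L) {
    aas[stops[1L]] <- readthrough_aa
    stops <- stops[-1L]
  }
  if (length(stops) == 0L) {
    return(res(paste(aas, collapse = ""), NA_character_, NA_integer_, trailing))
  }
  k <- stops[1L]
  res(paste(aas[seq_len(k - 1L)], collapse = ""), codons[k],
      3L * (k - 1L) + 1L, "")
}

#' @export
print.translation_result <- function(x, ...) {
  cat(sprintf("<translation> %d aa%s%s\n", nchar(x$protein),
              if (is.na(x$stop_codon)) " (no stop found)"
              else sprintf(", stop %s at nt %d", x$stop_codon, x$stop_position_nt),
              if (nzchar(x$trailing_partial))
                sprintf(", trailing partial '%s'", x$trailing_partial) else ""))
  cat(x$protein, "\n")
  invisible(x)
}
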