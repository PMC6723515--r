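## Physicochemical comparison of the putative S and L proteins: amino-acid
## composition, hydrophobicity, Grantham and Schneider-Wrede-style distance
## profiles, and Wilcoxon tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_protein <- function(protein, what = "protein") {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) ssw_error(sprintf("empty %s", what), "ssw_input_error")
  bad <- setdiff(unique(strsplit(toupper(protein), "")[[1]]), c(AA20, "X", "-"))
  if (length(bad)) {
    ssw_error(sprintf("%s contains invalid residue(s): %s", what,
                      paste(bad, collapse = ",")), "ssw_alphabet_error")
  }
  toupper(protein)
}

#' Amino-acid composition
#'
#' Frequency vector over the 20 amino acids in fixed alphabetical order.
#' `X` residues are excluded from the denominator and counted in the
#' `"n_excluded"` attribute.
#'
#' @param protein amino-acid string.
#' @return named numeric vector over the 20 residues summing to 1.
#' @examples aa_composition("WLW")  # W 2/3, L 1/3
#' @export
aa_composition <- function(protein) {
  protein <- check_protein(protein)
  chars <- strsplit(protein, "")[[1]]
  n_x <- sum(!(chars %in% AA20))
  chars <- chars[chars %in% AA20]
  if (length(chars) == 0L) {
    ssw_error("protein has no unambiguous residues", "ssw_input_error")
  }
  v <- table(factor(chars, levels = AA20)) / length(chars)
  structure(as.numeric(v), names = AA20, n_excluded = n_x)
}

load_scale <- function(scale) {
  shipped <- c("kyte_doolittle")
  path <- if (scale %in% shipped) {
    ssw_extdata("scales", paste0(scale, ".tsv"))
  } else if (file.exists(scale)) scale else {
    ssw_error(sprintf("unknown hydrophobicity scale '%s'", scale),
              "ssw_lookup_error")
  }
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  col.names = c("aa", "value"))
  setNames(d$value, d$aa)
}

#' Per-residue hydrophobicity profile
#'
#' @param protein amino-acid string (no `X`).
#' @param scale named scale (`"kyte_doolittle"`, the default) or a path to a
#'   two-column scale file.
#' @return numeric vector of per-residue values, one per position, with the
#'   summary mean in attribute `"mean"`.
#' @export
hydrophobicity_profile <- function(protein, scale = "kyte_doolittle") {
  protein <- check_protein(protein)
  tab <- load_scale(scale)
  chars <- strsplit(protein, "")[[1]]
  if (any(!(chars %in% names(tab)))) {
    ssw_error("profile undefined for ambiguous residues", "ssw_input_error")
  }
  v <- unname(tab[chars])
  structure(v, names = chars, mean = mean(v))
}

## ---- residue distance matrices -------------------------------------------

read_properties <- function() {
  read.delim(ssw_extdata("matrices", "grantham_properties.tsv"),
             comment.char = "#")
}

#' Build the Grantham distance matrix from the published formula
#'
#' `D_ij = rho * sqrt(alpha (c_i-c_j)^2 + beta (p_i-p_j)^2 +
#' gamma (v_i-v_j)^2)` over Grantham's composition/polarity/volume values,
#' with the published constants (alpha 1.833, beta 0.1018, gamma 0.000399,
#' rho 50.723 so the mean distance is about 100). Entries agree with the
#' published integer matrix to within the rounding of the original table.
#'
#' @return 20x20 symmetric numeric matrix, zero diagonal.
#' @export
build_grantham_matrix <- function() {
  pr <- read_properties()
  a <- 1.833; b <- 0.1018; g <- 0.000399; rho <- 50.723
  n <- nrow(pr)
  m <- matrix(0, n, n, dimnames = list(pr$aa, pr$aa))
  for (i in seq_len(n)) {
    m[i, ] <- rho * sqrt(a * (pr$c[i] - pr$c)^2 + b * (pr$p[i] - pr$p)^2 +
                         g * (pr$v[i] - pr$v)^2)
  }
  m[AA20, AA20]
}

#' Build the synthetic Schneider-Wrede-style distance matrix
#'
#' The published Schneider-Wrede physicochemical distance table is not
#' redistributed here; this package ships a synthetic stand-in constructed
#' in the same style: a normalized Euclidean metric over min-max-scaled
#' Kyte-Doolittle hydrophobicity, Grantham polarity and Grantham side-chain
#' volume, giving distances in `[0, 1]`. The shipped file
#' `matrices/sw_distance_synthetic.tsv` freezes this construction.
#'
#' @return 20x20 symmetric numeric matrix in `[0,1]`, zero diagonal.
#' @export
build_sw_matrix <- function() {
  pr <- read_properties()
  kd <- load_scale("kyte_doolittle")[pr$aa]
  norm01 <- function(x) (x - min(x)) / (max(x) - min(x))
  z <- cbind(norm01(kd), norm01(pr$p), norm01(pr$v))
  n <- nrow(pr)
  m <- matrix(0, n, n, dimnames = list(pr$aa, pr$aa))
  for (i in seq_len(n)) {
    m[i, ] <- sqrt(colSums((t(z) - z[i, ])^2) / 3)
  }
  m[AA20, AA20]
}

the_matrices <- new.env(parent = emptyenv())

residue_matrix <- function(kind = c("grantham", "sw")) {
  kind <- match.arg(kind)
  if (is.null(the_matrices[[kind]])) {
    file <- if (kind == "grantham") "grantham_distance.tsv"
            else "sw_distance_synthetic.tsv"
    m <- as.matrix(read.delim(ssw_extdata("matrices", file),
                              comment.char = "#", row.names = 1L,
                              check.names = FALSE))
    the_matrices[[kind]] <- m[AA20, AA20]
  }
  the_matrices[[kind]]
}

profile_from_matrix <- function(protein_a, protein_b, m, label) {
  a <- strsplit(check_protein(protein_a, "protein_a"), "")[[1]]
  b <- strsplit(check_protein(protein_b, "protein_b"), "")[[1]]
  if (length(a) != length(b)) {
    ssw_error(sprintf(
      "%s profile needs aligned proteins of identical length (got %d vs %d); align first (see nw_align)",
      label, length(a), length(b)), "ssw_input_error")
  }
  gap <- a == "-" | b == "-" | a == "X" | b == "X"
  v <- rep(NA_real_, length(a))
  v[!gap] <- m[cbind(a[!gap], b[!gap])]
  structure(v, positions = seq_along(a), n_gap_excluded = sum(gap),
            kind = label)
}

#' Grantham distance profile between two aligned proteins
#'
#' Per aligned position, the Grantham chemical distance between the two
#' residues (0 for identities); gap and `X` positions are excluded (`NA`).
#'
#' @param protein_a,protein_b aligned amino-acid strings of equal length
#'   (gaps `-` allowed).
#' @return numeric vector with `NA` at excluded positions.
#' @export
grantham_profile <- function(protein_a, protein_b) {
  profile_from_matrix(protein_a, protein_b, residue_matrix("grantham"),
                      "grantham")
}

#' Schneider-Wrede-style distance profile (synthetic matrix)
#'
#' As [grantham_profile()] but with the shipped synthetic
#' physicochemical-distance matrix (see [build_sw_matrix()] for its
#' construction and why it is a stand-in).
#'
#' @inheritParams grantham_profile
#' @export
schneider_wrede_profile <- function(protein_a, protein_b) {
  profile_from_matrix(protein_a, protein_b, residue_matrix("sw"), "sw")
}

## ---- Wilcoxon tests -------------------------------------------------------

#' Wilcoxon rank tests with a documented exactness contract
#'
#' Paired: signed-rank with zero differences discarded; exact null
#' enumeration (via the signed-rank distribution) whenever the retained
#' n <= `exact_max_n` and there are no ties among the absolute differences;
#' otherwise normal approximation with continuity and tie correction.
#' Unpaired: rank-sum with mid-ranks for ties; exact when tie-free and both
#' samples are within `exact_max_n`.
#'
#' @param x,y numeric vectors (`paired = TRUE` requires equal length and
#'   n >= 3 after zero-difference removal).
#' @param paired logical.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max_n exactness threshold (default 25, balancing runtime and
#'   fidelity).
#' @return object of class `ssw_test`: `statistic` (V or U), `p_value`,
#'   `method` (`"exact"`, `"normal-approximation"` or `"degenerate"`), `n`,
#'   `alternative`, `note`.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  out <- function(stat, p, method, n, note = NA_character_) {
    structure(list(statistic = stat, p_value = min(1, p), method = method,
                   n = n, alternative = alternative, note = note),
              class = "ssw_test")
  }
  if (paired) {
    if (length(x) != length(y)) {
      ssw_error("paired test requires equal lengths", "ssw_input_error")
    }
    d <- x - y
    n_zero <- sum(d == 0)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) {
      return(out(0, 1, "degenerate", 0L,
                 "all differences zero; no evidence of a shift"))
    }
    if (n < 3L) ssw_error("fewer than 3 non-zero differences",
                          "ssw_input_error")
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    ties <- anyDuplicated(abs(d)) > 0L
    if (!ties && n <= exact_max_n) {
      p <- switch(alternative,
        greater = 1 - psignrank(V - 1, n),
        less = psignrank(V, n),
        two.sided = min(1, 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n))))
      return(out(V, p, "exact", n,
                 if (n_zero) sprintf("%d zero difference(s) discarded", n_zero)
                 else NA_character_))
    }
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    corr <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                   less = -0.5)
    z <- (z - corr) / sqrt(sigma2)
    p <- switch(alternative, two.sided = 2 * min(pnorm(z), 1 - pnorm(z)),
                greater = 1 - pnorm(z), less = pnorm(z))
    return(out(V, p, "normal-approximation", n,
               if (ties) "ties present; mid-ranks with tie correction"
               else NA_character_))
  }
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) ssw_error("empty sample", "ssw_input_error")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && max(m, n) <= exact_max_n) {
    p <- switch(alternative,
      greater = 1 - pwilcox(U - 1, m, n),
      less = pwilcox(U, m, n),
      two.sided = min(1, 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n))))
    return(out(U, p, "exact", c(m, n)))
  }
  mu <- m * n / 2
  tie_tab <- table(r)
  sigma2 <- (m * n / 12) * ((m + n + 1) -
    sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
  z <- U - mu
  corr <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
  z <- (z - corr) / sqrt(sigma2)
  p <- switch(alternative, two.sided = 2 * min(pnorm(z), 1 - pnorm(z)),
              greater = 1 - pnorm(z), less = pnorm(z))
  out(U, p, "normal-approximation", c(m, n),
      if (ties) "ties present; mid-ranks with tie correction" else NA_character_)
}

#' @export
print.ssw_test <- function(x, ...) {
  cat(sprintf("<wilcoxon> stat %.4g, p = %.4g (%s, %s, n = %s)%s\n",
              x$statistic, x$p_value, x$method, x$alternative,
              paste(x$n, collapse = "/"),
              if (!is.na(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}
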