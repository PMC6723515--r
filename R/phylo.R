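## Distance-based tree building and sequence divergence. Neighbor-joining
## and the p/JC distances are delegated to ape behind this module's surface;
## Dxy and the global aligner are implemented here.

#' Pairwise distance matrix from aligned sequences
#'
#' p distance (mismatches / compared sites) or Jukes-Cantor
#' (`-3/4 ln(1 - 4/3 p)`). Sites with a gap or `N` in either member of a
#' pair are excluded pairwise (not listwise). A pair with `p >= 0.75` cannot
#' be JC-corrected (saturation): its entry is set to `saturated_value` and
#' flagged in the `"saturated"` attribute.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (gaps `-` and `N` allowed).
#' @param model `"p"` or `"jc"`.
#' @param saturated_value documented stand-in for saturated JC entries.
#' @return symmetric numeric matrix (zero diagonal) with attributes `model`
#'   and `saturated` (logical matrix).
#' @export
pairwise_distance <- function(seqs, model = c("p", "jc"),
                              saturated_value = 5) {
  model <- match.arg(model)
  if (length(seqs) < 2L) ssw_error("need >= 2 sequences", "ssw_input_error")
  if (length(unique(nchar(seqs))) != 1L) {
    ssw_error("aligned sequences must have equal length", "ssw_input_error")
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  p <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                               pairwise.deletion = TRUE))
  p <- p[names(seqs), names(seqs)]
  sat <- matrix(FALSE, nrow(p), ncol(p), dimnames = dimnames(p))
  d <- p
  if (model == "jc") {
    sat <- p >= 0.75
    d <- ifelse(sat, saturated_value, -0.75 * log(pmax(1 - 4 / 3 * p, 1e-12)))
    diag(d) <- 0
  }
  structure(d, model = model, saturated = sat)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via `ape::nj`) on a validated distance matrix.
#' On an additive matrix the generating topology is recovered exactly.
#' Negative branch lengths are clamped to zero; the clamped deficit is
#' recorded in the `"clamped"` attribute.
#'
#' @param dm symmetric non-negative matrix with zero diagonal, >= 3 taxa.
#' @return an `ape::phylo` (unrooted).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) ssw_error("neighbor-joining needs >= 3 taxa",
                               "ssw_input_error")
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(diag(dm) != 0)) {
    ssw_error("distance matrix must be symmetric with zero diagonal",
              "ssw_validation_error")
  }
  tr <- ape::nj(stats::as.dist(dm))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- deficit
  tr
}

## p distance and number of compared sites for one pair of aligned strings,
## excluding positions with '-' or 'N' in either.
pair_p <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(x) == length(y))
  ok <- !(x %in% c("-", "N")) & !(y %in% c("-", "N"))
  n <- sum(ok)
  if (n == 0L) return(list(p = NA_real_, n = 0L))
  list(p = sum(x[ok] != y[ok]) / n, n = n)
}

jc_correct <- function(p) -0.75 * log(1 - 4 / 3 * p)

#' Between-group nucleotide divergence (Dxy)
#'
#' Average over all between-set pairs of the per-pair distance (Nei's Dxy).
#' When the two sets are identical the self-pairs are excluded and the value
#' is the within-set mean pairwise distance. The uncertainty reported is the
#' standard deviation over the pairwise comparisons; for a single pair it
#' degenerates to the per-site binomial SD `sqrt(p(1-p)/n)` (delta-method
#' transformed under JC), which is this package's own documented SD, not a
#' claim of equivalence with any other program's.
#'
#' @param seqs_a,seqs_b non-empty character vectors of pre-aligned
#'   equal-length sequences.
#' @param correction `"jc"` (default) or `"none"`.
#' @return list: `estimate`, `sd`, `n_pairs`, `correction`.
#' @export
dxy <- function(seqs_a, seqs_b, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  if (length(seqs_a) == 0L || length(seqs_b) == 0L) {
    ssw_error("both sequence sets must be non-empty", "ssw_input_error")
  }
  if (length(unique(nchar(c(seqs_a, seqs_b)))) != 1L) {
    ssw_error("sequences must be aligned to equal length", "ssw_input_error")
  }
  same <- identical(seqs_a, seqs_b)
  pairs <- if (same) {
    if (length(seqs_a) < 2L) {
      ssw_error("within-set mean needs >= 2 sequences", "ssw_input_error")
    }
    which(upper.tri(matrix(0, length(seqs_a), length(seqs_a))), arr.ind = TRUE)
  } else {
    as.matrix(expand.grid(row = seq_along(seqs_a), col = seq_along(seqs_b)))
  }
  pp <- lapply(seq_len(nrow(pairs)), function(k)
    pair_p(seqs_a[[pairs[k, 1]]], seqs_b[[pairs[k, 2]]]))
  p <- vapply(pp, `[[`, 0, "p")
  nn <- vapply(pp, `[[`, 0L, "n")
  sat <- correction == "jc" & p >= 0.75
  d <- if (correction == "jc") ifelse(sat, NA_real_, jc_correct(p)) else p
  est <- mean(d, na.rm = TRUE)
  sdev <- if (sum(!is.na(d)) > 1L) {
    stats::sd(d, na.rm = TRUE)
  } else {
    s <- sqrt(p[1] * (1 - p[1]) / nn[1])
    if (correction == "jc") s / (1 - 4 / 3 * p[1]) else s
  }
  list(estimate = est, sd = sdev, n_pairs = length(d),
       n_saturated = sum(sat), correction = correction)
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under a linear gap penalty with deterministic
#' tie-breaking (diagonal preferred over up over left in the traceback).
#' Works for nucleotide or amino-acid strings.
#'
#' @param a,b non-empty sequences.
#' @param match,mismatch,gap scores (gap is the per-base penalty, typically
#'   negative).
#' @return list: `a_aligned`, `b_aligned` (gapped strings), `score`.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) ssw_error("empty sequence", "ssw_input_error")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- gap * 0:n
  F[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(x[i] == y, match, mismatch)
    row_prev <- F[i, ]
    row <- numeric(m + 1L); row[1L] <- gap * i
    for (j in seq_len(m)) {
      row[j + 1L] <- max(row_prev[j] + sub[j], row_prev[j + 1L] + gap,
                         row[j] + gap)
    }
    F[i + 1L, ] <- row
  }
  ## traceback, diagonal > up > left on ties
  i <- n; j <- m; ga <- character(); gb <- character()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        F[i + 1L, j + 1L] == F[i, j] + ifelse(x[i] == y[j], match, mismatch)) {
      ga <- c(x[i], ga); gb <- c(y[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] + gap) {
      ga <- c(x[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(y[j], gb); j <- j - 1L
    }
  }
  list(a_aligned = paste(ga, collapse = ""),
       b_aligned = paste(gb, collapse = ""), score = F[n + 1L, m + 1L])
}
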