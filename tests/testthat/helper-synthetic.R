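## Shared fixture builders (everything is generated in code) and tiny
## independent oracles used across the suite.

ECHINO <- load_code("echinoderm_mt")

random_sense_body <- function(n_codons, code = ECHINO) {
  sense <- setdiff(stopswitch:::ALL_CODONS, code$stops)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

## An S/L gene-region pair with the study geometry: `n` sense codons, TAG,
## then the 9-nt extension; L differs only at the focal middle base.
make_sl_pair <- function(n = 162L, extension = "TTATGATAA", code = ECHINO) {
  s <- paste0(random_sense_body(n, code), "TAG", extension)
  l <- s
  site <- 3L * n + 2L
  substr(l, site, site) <- "G"
  list(s = s, l = l, site = site, n = n)
}

## Independent brute-force oracle: every position of the shared prefix where
## substituting the S base with the L base turns an in-frame stop codon into
## a sense codon.
brute_stop_switch_scan <- function(s, l, code = ECHINO) {
  tab <- code$codon_to_aa
  n <- min(nchar(s), nchar(l))
  hits <- integer()
  for (i in seq_len(n)) {
    a <- substr(s, i, i); b <- substr(l, i, i)
    if (a == b) next
    ci <- (i - 1L) %/% 3L
    lo <- 3L * ci + 1L; hi <- 3L * ci + 3L
    if (hi > nchar(s)) next
    cod <- substr(s, lo, hi)
    mut <- cod
    substr(mut, i - lo + 1L, i - lo + 1L) <- b
    if (!grepl("N", cod) && tab[[cod]] == "*" && tab[[mut]] != "*") {
      hits <- c(hits, i)
    }
  }
  hits
}

## Exhaustive Fitch oracle: minimum changes over all internal-node state
## assignments, tips constrained to their allowed sets (a polymorphic tip
## resolves to whichever allowed state matches its parent at no cost).
brute_fitch <- function(tree, states) {
  nt <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1L]))
  best <- Inf
  k <- length(internal)
  for (mask in 0:(2^k - 1)) {
    assign <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0, "L", "S")
    names(assign) <- internal
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      par <- as.character(tree$edge[e, 1L])
      ch <- tree$edge[e, 2L]
      ps <- assign[[par]]
      if (ch <= nt) {
        allowed <- states[[tree$tip.label[ch]]]
        if (!(ps %in% allowed)) cost <- cost + 1
      } else if (assign[[as.character(ch)]] != ps) {
        cost <- cost + 1
      }
    }
    best <- min(best, cost)
  }
  best
}

random_state_map <- function(tree, p_poly = 0.3) {
  st <- lapply(tree$tip.label, function(t) {
    r <- runif(1)
    if (r < p_poly) c("S", "L") else if (r < 0.65) "S" else "L"
  })
  setNames(st, tree$tip.label)
}

## Brute-force optimal global alignment score over all gapped alignments
## (tiny sequences only), via recursion.
brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nchar(a)) return(gap * nchar(b))
  if (!nchar(b)) return(gap * nchar(a))
  x <- substr(a, 1, 1); y <- substr(b, 1, 1)
  rest_a <- substr(a, 2, nchar(a)); rest_b <- substr(b, 2, nchar(b))
  max(brute_nw_score(rest_a, rest_b, match, mismatch, gap) +
        ifelse(x == y, match, mismatch),
      brute_nw_score(rest_a, b, match, mismatch, gap) + gap,
      brute_nw_score(a, rest_b, match, mismatch, gap) + gap)
}
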