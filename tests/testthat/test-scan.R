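test_that("the S and L forms of the study geometry classify with the expected lengths and tail", {
  set.seed(1)
  p <- make_sl_pair()
  vs <- classify_variant(p$s, ECHINO, 162L)
  expect_equal(vs$variant_class, "S")
  expect_equal(vs$protein_length_aa, 162L)
  expect_equal(vs$cds_length_nt, 489L)
  expect_equal(vs$extension_nt, "")
  expect_equal(vs$extension_aa, "")

  vl <- classify_variant(p$l, ECHINO, 162L)
  expect_equal(vl$variant_class, "L")
  expect_equal(vl$protein_length_aa, 165L)
  expect_equal(vl$cds_length_nt, 498L)
  expect_equal(vl$extension_nt, "TTATGATAA")
  expect_equal(vl$extension_aa, "WLW")
  ## the L/S length difference equals the extension length
  expect_equal(vl$cds_length_nt - vs$cds_length_nt, nchar(vl$extension_nt))
})

test_that("truncated and stop-less sequences fall into the other class with flags", {
  set.seed(2)
  short <- paste0(random_sense_body(150), "TAA", random_sense_body(12))
  v <- classify_variant(short, ECHINO, 162L)
  expect_equal(v$variant_class, "other")
  expect_true("truncated" %in% v$notes)
  nostop <- random_sense_body(170)
  v2 <- classify_variant(nostop, ECHINO, 162L)
  expect_equal(v2$variant_class, "other")
  expect_true("no-stop" %in% v2$notes)
})

test_that("an L extension re-translated under the active code ends in exactly one stop", {
  set.seed(3)
  for (i in 1:50) {
    p <- make_sl_pair(n = sample(20:200, 1))
    vl <- classify_variant(p$l, ECHINO, p$n)
    ext <- translate_cds(vl$extension_nt, ECHINO, "translate_through")$protein
    expect_equal(substring(ext, nchar(ext)), "*")
    expect_equal(lengths(regmatches(ext, gregexpr("*", ext, fixed = TRUE))), 1L)
    ## protein-length difference equals the extension_aa length
    vs <- classify_variant(p$s, ECHINO, p$n)
    expect_equal(vl$protein_length_aa - vs$protein_length_aa,
                 nchar(vl$extension_aa))
  }
})

test_that("the stop switch localizes to 488 A>G in the study geometry", {
  set.seed(4)
  p <- make_sl_pair()
  loc <- localize_stop_switch(p$s, p$l, ECHINO)
  expect_equal(loc$site, 3L * 162L + 2L)  # = 488, forced by 162 codons
  expect_equal(loc$ref_allele, "A")
  expect_equal(loc$alt_allele, "G")
})

test_that("localization is an ambiguity error for identical sequences and for double switches", {
  set.seed(5)
  p <- make_sl_pair()
  expect_error(localize_stop_switch(p$s, p$s, ECHINO),
               class = "ssw_ambiguity_error")
  ## plant a second stop-to-sense switch inside the body
  s2 <- p$s; l2 <- p$l
  substr(s2, 301, 303) <- "TAA"   # codon 101 becomes a stop in S
  substr(l2, 301, 303) <- "TCA"   # and a sense codon in L (one-base change)
  expect_error(localize_stop_switch(s2, l2, ECHINO), "30[0-9]",
               class = "ssw_ambiguity_error")
})

test_that("localization agrees with the brute-force substitution scan on random pairs", {
  set.seed(6)
  for (i in 1:200) {
    p <- make_sl_pair(n = sample(5:80, 1))
    ## add unrelated body noise to the L copy (sense-preserving)
    l <- p$l
    for (k in sample(p$n, min(3, p$n))) {
      cod <- random_sense_body(1)
      substr(l, 3 * k - 2, 3 * k) <- cod
    }
    hits <- brute_stop_switch_scan(p$s, l)
    if (length(hits) == 1L) {
      loc <- localize_stop_switch(p$s, l, ECHINO)
      expect_equal(loc$site, hits)
    } else {
      expect_error(localize_stop_switch(p$s, l, ECHINO),
                   class = "ssw_ambiguity_error")
    }
  }
})

test_that("interval overlap is exact, symmetric and circular-shift invariant", {
  lin <- function(s, e) list(start = s, end = e, wraps_origin = FALSE)
  expect_equal(compute_overlap(lin(100, 200), lin(150, 250), 1000), 50L)
  expect_equal(compute_overlap(lin(100, 200), lin(200, 300), 1000), 0L)
  set.seed(8)
  glen <- 500L
  for (i in 1:100) {
    a <- sort(sample(0:glen, 2)); b <- sort(sample(0:glen, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    fa <- lin(a[1], a[2]); fb <- lin(b[1], b[2])
    ov <- compute_overlap(fa, fb, glen, "circular")
    expect_equal(compute_overlap(fb, fa, glen, "circular"), ov)
    ## rotate both intervals by a random shift around the circle
    sh <- sample(0:(glen - 1), 1)
    rot <- function(f) {
      s <- (f$start + sh) %% glen; e <- (f$end - 1 + sh) %% glen + 1
      if (s < e) list(start = s, end = e, wraps_origin = FALSE)
      else list(start = s, end = e, wraps_origin = TRUE)
    }
    expect_equal(compute_overlap(rot(fa), rot(fb), glen, "circular"), ov)
  }
})

test_that("cohort scanning reproduces the two in-paper cohort structures on synthetic analogues", {
  set.seed(9)
  p <- make_sl_pair()
  ## nine intraspecific sequences: five S, four L (the first species' sample)
  seqs9 <- c(replicate(5, p$s), replicate(4, p$l))
  names(seqs9) <- sprintf("acc%02d", 1:9)
  sc9 <- scan_cohort(seqs9, ECHINO, taxa = rep("sp1", 9))
  expect_equal(sc9$counts$n_S, 5L)
  expect_equal(sc9$counts$n_L, 4L)
  expect_equal(sc9$states, list(sp1 = c("L", "S")))
  expect_equal(sc9$reference_protein_length, 162L)
  expect_true(all(sc9$calls$stop_switch_site[sc9$calls$variant_class == "L"] == 488L))

  ## sixteen sequences: two S, fourteen L, one of them two codons longer
  extra <- p$l
  ## readthrough continues: replace the realized TAA stop by Asn-Asp then TAA
  extra <- paste0(substring(extra, 1, 489 + 6), "AATGAT", "TAA")
  seqs16 <- c(replicate(2, p$s), replicate(13, p$l), extra)
  names(seqs16) <- sprintf("mn%02d", 1:16)
  sc16 <- scan_cohort(seqs16, ECHINO, taxa = rep("sp2", 16))
  expect_equal(sc16$counts$n_S, 2L)
  expect_equal(sc16$counts$n_L, 14L)
  ext_call <- sc16$calls[sc16$calls$id == "mn16", ]
  expect_match(ext_call$notes, "extra-length:\\+2")
  expect_equal(ext_call$protein_length_aa, 167L)
})

test_that("a uniform cohort yields a single class and state {S}", {
  set.seed(10)
  p <- make_sl_pair()
  seqs <- setNames(rep(p$s, 3), c("a", "b", "c"))
  sc <- scan_cohort(seqs, ECHINO)
  expect_true(all(sc$calls$variant_class == "S"))
  expect_equal(unname(lengths(sc$states)), rep(1L, 3))
  expect_error(scan_cohort(setNames(rep(random_sense_body(20), 2), c("x", "y")),
                           ECHINO),
               class = "ssw_input_error")
})
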