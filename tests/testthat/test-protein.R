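test_that("amino-acid composition is a frequency vector with the documented algebra", {
  comp <- aa_composition("WLW")
  expect_equal(comp[["W"]], 2 / 3)
  expect_equal(comp[["L"]], 1 / 3)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_equal(sum(comp > 0), 2L)
  expect_error(aa_composition(""), class = "ssw_input_error")
  ## concatenation invariance: comp(a+b) is the length-weighted mean
  set.seed(61)
  for (i in 1:20) {
    a <- paste(sample(stopswitch:::AA20, sample(5:30, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(stopswitch:::AA20, sample(5:30, 1), replace = TRUE),
               collapse = "")
    w <- nchar(a) / (nchar(a) + nchar(b))
    expect_equal(as.numeric(aa_composition(paste0(a, b))),
                 w * as.numeric(aa_composition(a)) +
                   (1 - w) * as.numeric(aa_composition(b)),
                 tolerance = 1e-12)
  }
})

test_that("hydrophobicity profiles follow the Kyte-Doolittle scale", {
  prof <- hydrophobicity_profile("IIII")
  expect_equal(as.numeric(prof), rep(4.5, 4))
  expect_error(hydrophobicity_profile("ACD", scale = "no_such_scale"),
               class = "ssw_lookup_error")
  set.seed(62)
  for (i in 1:10) {
    p <- paste(sample(stopswitch:::AA20, 40, replace = TRUE), collapse = "")
    prof <- hydrophobicity_profile(p)
    comp <- aa_composition(p)
    scale <- stopswitch:::load_scale("kyte_doolittle")
    expect_equal(attr(prof, "mean"),
                 sum(comp * scale[stopswitch:::AA20]), tolerance = 1e-12)
  }
})

test_that("the shipped Grantham matrix agrees with the published formula and table", {
  m <- build_grantham_matrix()
  shipped <- stopswitch:::residue_matrix("grantham")
  expect_equal(shipped, m, tolerance = 1e-5)
  ## recompute one entry from the raw property values (independent route)
  pr <- read.delim(system.file("extdata", "matrices",
                               "grantham_properties.tsv",
                               package = "stopswitch"), comment.char = "#")
  rownames(pr) <- pr$aa
  d_sl <- 50.723 * sqrt(1.833 * (pr["S", "c"] - pr["L", "c"])^2 +
                        0.1018 * (pr["S", "p"] - pr["L", "p"])^2 +
                        0.000399 * (pr["S", "v"] - pr["L", "v"])^2)
  expect_equal(m["S", "L"], d_sl, tolerance = 1e-9)
  ## published integer entries (1974 table rounding: within +/- 1)
  published <- c(SL = 145, LI = 5, WC = 215, RK = 26, WG = 184)
  got <- c(m["S", "L"], m["L", "I"], m["W", "C"], m["R", "K"], m["W", "G"])
  expect_true(all(abs(got - published) <= 1))
  ## the scaling constant sets the mean distance near 100
  expect_equal(mean(m[upper.tri(m)]), 100, tolerance = 0.01 * 100)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
})

test_that("distance profiles are zero on identity, symmetric, non-negative, and gap-excluded", {
  set.seed(63)
  p <- paste(sample(stopswitch:::AA20, 30, replace = TRUE), collapse = "")
  expect_true(all(grantham_profile(p, p) == 0))
  expect_true(all(schneider_wrede_profile(p, p) == 0))
  q <- paste(sample(stopswitch:::AA20, 30, replace = TRUE), collapse = "")
  expect_equal(grantham_profile(p, q), grantham_profile(q, p))
  expect_equal(schneider_wrede_profile(p, q), schneider_wrede_profile(q, p))
  expect_true(all(grantham_profile(p, q) >= 0))
  g <- grantham_profile(paste0(substr(p, 1, 29), "-"), q)
  expect_true(is.na(g[30]))
  expect_equal(attr(g, "n_gap_excluded"), 1L)
  expect_error(grantham_profile("ACD", "AC"), class = "ssw_input_error")
})

test_that("the synthetic physicochemical matrix file matches its documented construction", {
  m <- build_sw_matrix()
  shipped <- stopswitch:::residue_matrix("sw")
  expect_equal(shipped, m, tolerance = 1e-5)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(isSymmetric(m))
  ## independent recomputation of one entry from the property files
  pr <- read.delim(system.file("extdata", "matrices",
                               "grantham_properties.tsv",
                               package = "stopswitch"), comment.char = "#")
  rownames(pr) <- pr$aa
  kd <- stopswitch:::load_scale("kyte_doolittle")
  n01 <- function(x) (x - min(x)) / (max(x) - min(x))
  h <- n01(kd[pr$aa]); pp <- n01(pr$p); vv <- n01(pr$v)
  i <- match("A", pr$aa); j <- match("W", pr$aa)
  expect_equal(m["A", "W"],
               sqrt(((h[i] - h[j])^2 + (pp[i] - pp[j])^2 +
                     (vv[i] - vv[j])^2) / 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("profiles between synthetic S/L proteins are zero on the shared prefix and the composition differs only in the tail residues", {
  set.seed(64)
  for (i in 1:20) {
    p <- make_sl_pair(n = sample(30:80, 1))
    ps <- translate_cds(p$s, ECHINO, "halt")$protein
    pl <- translate_cds(p$l, ECHINO, "halt")$protein
    al <- nw_align(ps, pl)
    g <- grantham_profile(al$a_aligned, al$b_aligned)
    shared <- seq_len(nchar(ps))
    expect_true(all(g[shared][!is.na(g[shared])] == 0))
    ## composition difference is exactly the extension's residues
    delta <- (aa_composition(pl) * nchar(pl) - aa_composition(ps) * nchar(ps))
    tail_comp <- table(factor(strsplit("WLW", "")[[1]],
                              levels = stopswitch:::AA20))
    expect_equal(as.numeric(delta), as.numeric(tail_comp), tolerance = 1e-9)
  }
})

test_that("the paired Wilcoxon test is exact where enumeration permits", {
  ## all-positive differences, n = 6: one-sided p = 1/64 by sign enumeration
  x <- c(2, 4, 7, 11, 16, 22); y <- c(1, 2, 3, 4, 5, 6)
  r <- wilcoxon_test(x, y, paired = TRUE, alternative = "greater")
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 64)
  ## degenerate: identical vectors
  r0 <- wilcoxon_test(x, x, paired = TRUE)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$method, "degenerate")
  ## full enumeration oracle for n <= 10 (tie-free)
  set.seed(65)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    d <- round(runif(n, 0.05, 2), 3) * sample(c(-1, 1), n, replace = TRUE)
    while (anyDuplicated(abs(d))) d <- d + runif(n, 0, 1e-4)
    V <- sum(rank(abs(d))[d > 0])
    ## enumerate all 2^n sign patterns under H0
    ranks <- rank(abs(d))
    vs <- vapply(0:(2^n - 1), function(mask) {
      sum(ranks[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    }, 0)
    p_enum <- min(1, 2 * min(mean(vs <= V), mean(vs >= V)))
    r <- wilcoxon_test(d, rep(0, n), paired = TRUE)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, p_enum, tolerance = 1e-12)
  }
})

test_that("exact and approximate Wilcoxon p agree closely at moderate n, and ranks handle ties", {
  set.seed(66)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  exact <- wilcoxon_test(x, y, paired = TRUE, exact_max_n = 30)
  approx <- wilcoxon_test(x, y, paired = TRUE, exact_max_n = 5)
  expect_equal(exact$method, "exact")
  expect_equal(approx$method, "normal-approximation")
  expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  ## cross-check the unpaired path against stats::wilcox.test
  a <- rnorm(12); b <- rnorm(15, 0.5)
  mine <- wilcoxon_test(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  ## and the paired path
  mine2 <- wilcoxon_test(x, y, paired = TRUE, exact_max_n = 30)
  ref2 <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("the S/L feature comparison reports valid statistics of its own", {
  set.seed(67)
  p <- make_sl_pair()
  ps <- translate_cds(p$s, ECHINO, "halt")$protein
  pl <- translate_cds(p$l, ECHINO, "halt")$protein
  res <- run_features(ps, pl)
  expect_true(res$composition_test$p_value >= 0 &&
                res$composition_test$p_value <= 1)
  expect_true(res$hydrophobicity_test$p_value >= 0 &&
                res$hydrophobicity_test$p_value <= 1)
  ## the tail's two tryptophans enrich W in the L composition
  expect_gt(res$composition["L", "W"], res$composition["S", "W"])
  expect_equal(res$grantham$n_nonzero, 0L)   # shared residues identical
  expect_equal(res$grantham$n_excluded, 3L)  # the gapped tail positions
})
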