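test_that("p and JC distances follow their closed forms with pairwise gap/N exclusion", {
  d <- pairwise_distance(c(a = "AAAA", b = "AAAT"), model = "p")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)
  dj <- pairwise_distance(c(a = "AAAA", b = "AAAT"), model = "jc")
  expect_equal(dj["a", "b"], -0.75 * log(1 - 4 / 3 * 0.25), tolerance = 1e-9)
  expect_equal(round(dj["a", "b"], 5), 0.30410)
  ## N in either sequence drops the site for that pair only
  d2 <- pairwise_distance(c(a = "AANA", b = "AATT", c = "AATT"), model = "p")
  expect_equal(d2["a", "b"], 1 / 3)
  expect_equal(d2["b", "c"], 0)
  ## saturation is flagged, not silently corrected
  ds <- pairwise_distance(c(a = "AAAA", b = "TTTT"), model = "jc")
  expect_true(attr(ds, "saturated")["a", "b"])
})

test_that("NJ recovers the generating topology from additive matrices", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    ## reorder rows/cols randomly but consistently
    ord <- sample(rownames(dm))
    nj <- nj_tree(dm[ord, ord])
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
  }
  ## the explicit 4-taxon example
  tr4 <- read_newick("((A:1,B:2):1,(C:3,D:1):1);")
  nj4 <- nj_tree(ape::cophenetic.phylo(tr4))
  expect_equal(ape::dist.topo(ape::unroot(tr4), nj4), 0, ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), class = "ssw_input_error")
  bad <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), class = "ssw_validation_error")
})

test_that("three taxa resolve by the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  ## leaf branch lengths: x=(dab+dac-dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("an ultrametric matrix gives the same unrooted topology as a UPGMA oracle", {
  set.seed(22)
  for (i in 1:10) {
    tr <- ape::rcoal(6)
    dm <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(dm)
    up <- ape::as.phylo(stats::hclust(stats::as.dist(dm), "average"))
    expect_equal(ape::dist.topo(nj, ape::unroot(up)), 0, ignore_attr = TRUE)
  }
})

test_that("Dxy matches hand counts, is symmetric, and its self form is the within-set mean", {
  expect_equal(dxy(c(x = "ACGT"), c(y = "ACGT"), "none")$estimate, 0)
  expect_equal(dxy(c(x = "ACGT"), c(y = "ACGT"), "none")$sd, 0)
  expect_equal(dxy(c(x = "AAAA"), c(y = "AATT"), "none")$estimate, 0.5)
  set.seed(31)
  anc <- random_sense_body(40)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    hit <- sample(length(ch), k)
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  A <- c(a1 = mutate(anc, 5), a2 = mutate(anc, 6))
  B <- c(b1 = mutate(anc, 8), b2 = mutate(anc, 4))
  expect_equal(dxy(A, B, "jc")$estimate, dxy(B, A, "jc")$estimate)
  within <- mean(c(stopswitch:::pair_p(A[1], A[2])$p)) |>
    (\(p) -0.75 * log(1 - 4 / 3 * p))()
  expect_equal(dxy(A, A, "jc")$estimate, within)
  expect_error(dxy(character(0), A), class = "ssw_input_error")
})

test_that("Dxy recovers a planted divergence within 3 SD across simulations", {
  set.seed(32)
  L <- 4000L; target <- 0.01
  ests <- replicate(200, {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    derive <- function() {
      x <- anc
      hit <- runif(L) < target / 2   # each lineage takes half the divergence
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(x, collapse = "")
    }
    dxy(c(a = derive()), c(b = derive()), "none")$estimate
  })
  ## per-simulation binomial SD at p ~ target
  sd1 <- sqrt(target * (1 - target) / L)
  expect_lt(abs(mean(ests) - target * (1 - target / 4)), 3 * sd1)
})

test_that("global alignment is optimal (brute force + Biostrings oracles) and symmetric in score", {
  al <- nw_align("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$a_aligned, "ACGT")
  al2 <- nw_align("ACGT", "AGT")
  expect_equal(al2$score, 1)  # 3 matches - one 2-point gap
  expect_equal(brute_nw_score("ACGT", "AGT"), 1)
  set.seed(41)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:7, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:7, 1), replace = TRUE),
               collapse = "")
    s <- nw_align(a, b)$score
    expect_equal(s, brute_nw_score(a, b))
    expect_equal(s, nw_align(b, a)$score)
    expect_equal(s, Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = sm, gapOpening = 0, gapExtension = 2,
      type = "global")))
  }
  ## aligned strings reproduce the score
  rescore <- function(al, match = 1, mismatch = -1, gap = -2) {
    x <- strsplit(al$a_aligned, "")[[1]]; y <- strsplit(al$b_aligned, "")[[1]]
    sum(ifelse(x == "-" | y == "-", gap, ifelse(x == y, match, mismatch)))
  }
  a <- "ACGTACGGTT"; b <- "ACTTACGT"
  expect_equal(rescore(nw_align(a, b)), nw_align(a, b)$score)
})

test_that("generalized Fitch matches exhaustive enumeration, including polymorphic tips", {
  ## spec'd small cases first
  tr <- read_newick("((A,B),(C,D));")
  st <- list(A = "S", B = "L", C = c("S", "L"), D = c("S", "L"))
  expect_equal(fitch_map(tr, st)$min_changes, 1)
  expect_equal(brute_fitch(tr, st), 1)
  expect_equal(fitch_map(tr, list(A = "S", B = "S", C = "S", D = "S"))$min_changes, 0)
  cat4 <- read_newick("(((A,B),C),D);")
  alt <- list(A = "S", B = "L", C = "S", D = "L")
  expect_equal(fitch_map(cat4, alt)$min_changes, 2)
  expect_equal(brute_fitch(cat4, alt), 2)
  set.seed(51)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    st <- random_state_map(tr)
    expect_equal(fitch_map(tr, st)$min_changes, brute_fitch(tr, st))
  }
  expect_error(fitch_map(tr, st[-1]), class = "ssw_mapping_error")
})

test_that("split-tip mode agrees with set-based Fitch after the per-tip allele offset", {
  set.seed(52)
  for (i in 1:40) {
    tr <- ape::rtree(sample(4:8, 1))
    st <- random_state_map(tr, p_poly = 0.4)
    expect_equal(fitch_map(tr, st, polymorphic = "split")$min_changes,
                 fitch_map(tr, st, polymorphic = "set")$min_changes)
  }
})

test_that("set-based Fitch cost matches the phangorn parsimony oracle on monomorphic tips", {
  set.seed(53)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:8, 1))
    st <- lapply(setNames(tr$tip.label, tr$tip.label),
                 function(t) sample(c("S", "L"), 1))
    dat <- phangorn::phyDat(matrix(unlist(st[tr$tip.label]), ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("S", "L"))
    expect_equal(fitch_map(tr, st)$min_changes,
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("TSP assessment separates persistence-shaped from convergence-shaped patterns", {
  ## two sister polymorphic taxa in an otherwise short-fixed tree
  tr <- read_newick("(((P1,P2),A),(B,C));")
  st <- list(P1 = c("S", "L"), P2 = c("S", "L"), A = "S", B = "S", C = "S")
  rep1 <- assess_tsp(tr, st, quiet = TRUE)
  expect_true(rep1$tsp_consistent)
  expect_equal(rep1$min_origins_of_L, 1)
  ## polymorphic taxa on opposite sides of a short-fixed backbone
  tr2 <- read_newick("((P1,(A,B)),(P2,(C,D)));")
  st2 <- list(P1 = c("S", "L"), P2 = c("S", "L"), A = "S", B = "S",
              C = "S", D = "S")
  rep2 <- assess_tsp(tr2, st2, quiet = TRUE)
  expect_false(rep2$tsp_consistent)
  expect_equal(rep2$min_origins_of_L, 2)
  ## a single polymorphic taxon can never establish TSP
  st3 <- list(P1 = c("S", "L"), P2 = "S", A = "S", B = "S", C = "S", D = "S")
  expect_false(assess_tsp(tr2, st3, quiet = TRUE)$tsp_consistent)
  ## leaf without a state
  expect_error(assess_tsp(tr2, st2[-1], quiet = TRUE),
               class = "ssw_mapping_error")
})

test_that("rooting precedence: outgroup when available, midpoint otherwise", {
  tr <- ape::unroot(read_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);"))
  st <- list(A = "S", B = "S", C = c("S", "L"), D = c("S", "L"), E = "S")
  expect_silent(assess_tsp(tr, st, outgroup = "A", quiet = TRUE))
  r1 <- assess_tsp(tr, st, outgroup = "A", quiet = TRUE)
  r2 <- assess_tsp(tr, st, quiet = TRUE)   # midpoint
  expect_equal(r1$min_changes, r2$min_changes)  # Fitch cost is root-invariant
})
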