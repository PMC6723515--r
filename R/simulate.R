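## Seeded synthetic data with known ground truth: trees, sequence evolution
## with a maintained focal stop/sense polymorphism, two-gene genome records
## with the opposite-strand overlap geometry, and transcript read sets.
##
## Defaults regenerate the study geometry: a 162-codon gene body, the TAG
## stop whose middle base (gene position 488) toggles S/L, and the 9-nt
## downstream extension TTATGATAA, so the L protein is three residues
## (Trp-Leu-Trp) longer and overlaps the opposite-strand neighbor by 9 bp.

#' Simulation configuration
#'
#' @param seed integer seed; one RNG stream drives the whole run.
#' @param n_taxa number of taxa (>= 3).
#' @param tree_shape `"yule"`, `"caterpillar"`, or a Newick string.
#' @param subst_rate substitutions per site per unit branch length (trees
#'   are scaled to height 1, so this is also the expected root-to-tip
#'   divergence).
#' @param gene_length_codons sense codons before the focal stop (162).
#' @param focal_codon_index index of the focal stop codon; must be
#'   `gene_length_codons + 1` (the only geometry the generator emulates).
#' @param extension in-genome downstream segment after the focal stop,
#'   ending in a stop codon (`TTATGATAA`).
#' @param polymorphic_taxa taxa maintained as `{S,L}`; `NULL` lets the
#'   scenario choose (persistence: a random clade of >= 2 leaves;
#'   convergence: leaves scattered across the root).
#' @param scenario `"persistence"` (one ancestral S->L origin, both alleles
#'   transmitted) or `"convergence"` (independent terminal origins).
#' @param read_depth,read_length,error_rate transcript-read simulation.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 8L, tree_shape = "yule",
                       subst_rate = 0.15, gene_length_codons = 162L,
                       focal_codon_index = gene_length_codons + 1L,
                       extension = "TTATGATAA", polymorphic_taxa = NULL,
                       scenario = c("persistence", "convergence"),
                       read_depth = 30L, read_length = 100L,
                       error_rate = 0.005) {
  scenario <- match.arg(scenario)
  if (n_taxa < 3L) ssw_error("n_taxa must be >= 3", "ssw_config_error")
  if (focal_codon_index != gene_length_codons + 1L) {
    ssw_error("focal codon must be the stop codon following the gene body",
              "ssw_config_error")
  }
  if (nchar(extension) %% 3L != 0L || nchar(extension) < 3L) {
    ssw_error("extension must be a whole number of codons", "ssw_config_error")
  }
  if (error_rate < 0 || error_rate > 1 || subst_rate < 0) {
    ssw_error("rates must be probabilities/non-negative", "ssw_config_error")
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 tree_shape = tree_shape, subst_rate = subst_rate,
                 gene_length_codons = as.integer(gene_length_codons),
                 focal_codon_index = as.integer(focal_codon_index),
                 extension = toupper(extension),
                 polymorphic_taxa = polymorphic_taxa, scenario = scenario,
                 read_depth = as.integer(read_depth),
                 read_length = as.integer(read_length),
                 error_rate = error_rate),
            class = "sim_config")
}

#' Simulate a tree
#'
#' Yule (pure-birth) or pectinate (caterpillar) topologies, or a fixed
#' Newick; edge lengths scaled so the tree height is 1. Deterministic under
#' the ambient RNG (seed it, or go through [simulate_dataset()]).
#'
#' @param config a [sim_config()].
#' @return rooted `ape::phylo` with `n_taxa` leaves.
#' @export
simulate_tree <- function(config) {
  tr <- switch(config$tree_shape,
    yule = ape::rphylo(config$n_taxa, birth = 1, death = 0),
    caterpillar = {
      t0 <- ape::stree(config$n_taxa, type = "left")
      t0$edge.length <- rep(1, nrow(t0$edge))
      t0
    },
    read_newick(config$tree_shape))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  h <- max(ape::node.depth.edgelength(tr))
  if (h > 0) tr$edge.length <- tr$edge.length / h
  tr
}

## sample a sense codon (uniform over non-stop codons)
sample_sense_codons <- function(n, code) {
  sense <- setdiff(ALL_CODONS, code$stops)
  sense[sample.int(length(sense), n, replace = TRUE)]
}

## JC evolution of a codon vector along one branch; proposals creating a stop
## are resampled so the gene body stays stop-free (deliberate departure from
## a free JC process, keeping length classification unconfounded).
evolve_branch <- function(codons, t, rate, code) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
  p_mut <- 0.75 * (1 - exp(-4 / 3 * rate * t))
  hit <- which(runif(length(chars)) < p_mut)
  for (i in hit) {
    ci <- (i - 1L) %/% 3L + 1L
    alts <- sample(setdiff(bases, chars[i]))
    for (b in alts) {
      cand <- chars
      cand[i] <- b
      codon <- paste(cand[(3L * ci - 2L):(3L * ci)], collapse = "")
      if (!(codon %in% code$stops)) { chars <- cand; break }
    }
  }
  n <- length(chars) / 3L
  substring(paste(chars, collapse = ""), 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## default polymorphic-taxa selection; see scenario semantics in sim_config()
pick_polymorphic <- function(tree, scenario) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  clade_tips <- function(node) {
    if (node <= nt) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  }
  if (scenario == "persistence") {
    internal <- setdiff(unique(tree$edge[, 2L]), seq_len(nt))
    sizes <- vapply(internal, function(v) length(clade_tips(v)), 0L)
    ok <- internal[sizes >= 2L]
    if (length(ok) == 0L) return(tree$tip.label[1:2])
    clade_tips(ok[sample.int(length(ok), 1L)])
  } else {
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    side1 <- clade_tips(kids[1L]); side2 <- clade_tips(kids[2L])
    pairs <- expand.grid(a = side1, b = side2, stringsAsFactors = FALSE)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    ## prefer pairs whose S-only leaves do not collapse into a single clade,
    ## so the two origins are genuinely scattered
    n_zero_clades <- function(a, b) {
      zero <- setdiff(tree$tip.label, c(a, b))
      if (length(zero) == 0L) return(0L)
      cl <- 0L; left <- zero
      while (length(left)) {
        ## greedily peel maximal all-zero clades
        node <- match(left[1L], tree$tip.label)
        repeat {
          parent <- tree$edge[tree$edge[, 2L] == node, 1L]
          if (length(parent) == 0L) break
          tips <- clade_tips(parent)
          if (all(tips %in% zero)) node <- parent else break
        }
        cl <- cl + 1L
        left <- setdiff(left, clade_tips(node))
      }
      cl
    }
    for (i in seq_len(nrow(pairs))) {
      if (n_zero_clades(pairs$a[i], pairs$b[i]) >= 2L) {
        return(c(pairs$a[i], pairs$b[i]))
      }
    }
    c(pairs$a[1L], pairs$b[1L])
  }
}

#' Evolve the gene region along a tree with a maintained focal polymorphism
#'
#' Jukes-Cantor substitution over a stop-free codon background; the focal
#' stop codon and the downstream extension are held invariant; the scenario
#' controls only the focal middle base of the emitted allele copies. Each
#' polymorphic taxon emits an S and an L sequence (`<taxon>_S`,
#' `<taxon>_L`); other taxa emit a single S sequence (`<taxon>_S`).
#'
#' @param tree from [simulate_tree()].
#' @param config a [sim_config()].
#' @param code genetic code (the echinoderm mitochondrial code).
#' @return list: `seqs` (named vector of gene-region sequences, body + focal
#'   stop + extension), `taxa` (taxon per sequence), `tree`, and `truth`
#'   (`states`, `site`, `ref_allele`, `alt_allele`, `extension`,
#'   `polymorphic_taxa`, `scenario`). Ground-truth consistency (lengths,
#'   localization arithmetic) is checked at generation time.
#' @export
evolve_alignment <- function(tree, config, code = load_code("echinoderm_mt")) {
  poly <- config$polymorphic_taxa %||% pick_polymorphic(tree, config$scenario)
  if (length(poly) == 0L) {
    ssw_error("scenario requires at least one polymorphic taxon",
              "ssw_config_error")
  }
  if (!all(poly %in% tree$tip.label)) {
    ssw_error("polymorphic_taxa must be tree leaves", "ssw_config_error")
  }
  nb <- config$gene_length_codons
  root_codons <- sample_sense_codons(nb, code)
  nt <- length(tree$tip.label)
  tip_codons <- vector("list", nt + tree$Nnode)
  root <- nt + 1L
  tip_codons[[root]] <- root_codons
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1L]; child <- pre$edge[e, 2L]
    tip_codons[[child]] <- evolve_branch(tip_codons[[par]],
                                         pre$edge.length[e],
                                         config$subst_rate, code)
  }
  focal_stop <- "TAG"
  site <- 3L * nb + 2L
  seqs <- character(); taxa <- character()
  for (i in seq_len(nt)) {
    taxon <- tree$tip.label[i]
    body <- paste(tip_codons[[i]], collapse = "")
    s_seq <- paste0(body, focal_stop, config$extension)
    seqs[paste0(taxon, "_S")] <- s_seq
    taxa[paste0(taxon, "_S")] <- taxon
    if (taxon %in% poly) {
      l_seq <- s_seq
      substr(l_seq, site, site) <- "G"
      seqs[paste0(taxon, "_L")] <- l_seq
      taxa[paste0(taxon, "_L")] <- taxon
    }
  }
  truth <- list(states = lapply(setNames(tree$tip.label, tree$tip.label),
                                function(t) if (t %in% poly) c("S", "L") else "S"),
                site = site, ref_allele = "A", alt_allele = "G",
                extension = config$extension, polymorphic_taxa = poly,
                scenario = config$scenario)
  ## generation-time self-validation against the classifier arithmetic
  s_len <- nchar(translate_cds(seqs[[1]], code, "halt")$protein)
  stopifnot(s_len == nb)
  if (length(poly)) {
    l_id <- paste0(poly[1L], "_L")
    loc <- localize_stop_switch(seqs[[paste0(poly[1L], "_S")]],
                                seqs[[l_id]], code)
    stopifnot(loc$site == site, loc$ref_allele == "A", loc$alt_allele == "G")
  }
  list(seqs = seqs, taxa = taxa, tree = tree, truth = truth)
}

#' Assemble a two-gene genome with the opposite-strand overlap geometry
#'
#' Places an ND5-like gene on the forward strand and the focal ND6-like gene
#' on the reverse strand immediately downstream, such that the S-form
#' annotations abut without overlap and the realized L-form coding region
#' overlaps the neighbor by exactly the extension length (9 bp by default):
#' the neighbor's final bases are forced to the reverse complement of the
#' extension (which therefore also provides the neighbor's stop codon).
#'
#' @param nd6_region gene region from [evolve_alignment()] (S or L form;
#'   body + focal stop + extension, reading orientation).
#' @param config a [sim_config()].
#' @param code genetic code.
#' @param nd5_length_codons length of the synthetic neighbor, stop included.
#' @param flank plain intergenic flank added on each side.
#' @param identifier record identifier.
#' @return list: `record` (a [genome_record()] with ND5/ND6 features, S-form
#'   annotation), `truth` (planted feature table, realized L interval,
#'   extension length).
#' @export
assemble_genome <- function(nd6_region, config, code = load_code("echinoderm_mt"),
                            nd5_length_codons = 100L, flank = 30L,
                            identifier = "SYNTH01") {
  ext <- config$extension
  tail_fwd <- reverse_complement(ext)
  ne <- nchar(ext)
  if (ne %% 3L) ssw_error("extension must be codon-sized", "ssw_config_error")
  last <- substring(tail_fwd, ne - 2L, ne)
  if (!(last %in% code$stops)) {
    ssw_error("unsupported geometry: the reverse complement of the extension must end in a stop codon (it doubles as the neighbor's stop)",
              "ssw_config_error")
  }
  body_cod <- nd5_length_codons - ne %/% 3L
  if (body_cod < 1L) ssw_error("neighbor gene too short", "ssw_config_error")
  nd5_body <- paste(sample_sense_codons(body_cod, code), collapse = "")
  ## the forced tail must not introduce an internal stop
  tail_codons <- substring(tail_fwd, 3L * seq_len(ne %/% 3L) - 2L,
                           3L * seq_len(ne %/% 3L))
  if (any(tail_codons[-length(tail_codons)] %in% code$stops)) {
    ssw_error("unsupported geometry: reverse-complemented extension contains an internal stop",
              "ssw_config_error")
  }
  nd5 <- paste0(nd5_body, tail_fwd)
  L5 <- nchar(nd5)
  s_cds_len <- 3L * config$gene_length_codons + 3L
  nd6_fwd <- reverse_complement(substring(nd6_region, 1L, s_cds_len))
  flank_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
  genome <- paste0(flank_seq(flank), nd5, nd6_fwd, flank_seq(flank))
  feats <- data.frame(
    gene_name = c("ND5", "ND6"),
    start = c(flank, flank + L5),
    end = c(flank + L5, flank + L5 + s_cds_len),
    strand = c(1L, -1L),
    wraps_origin = FALSE)
  rec <- genome_record(identifier, genome, topology = "circular",
                       features = feats)
  realized_l <- list(start = flank + L5 - ne, end = flank + L5 + s_cds_len,
                     strand = -1L, wraps_origin = FALSE)
  list(record = rec,
       truth = list(features = feats, realized_l_interval = realized_l,
                    extension_bp = ne))
}

#' Simulate transcript reads
#'
#' Uniform-start reads from both strands at a configured mean depth, with
#' per-base substitution error and optional injected editing sites.
#' Template mixtures (e.g. S and L alleles) are drawn per read by weight.
#'
#' @param templates character vector of template sequences (e.g.
#'   `c(S = ..., L = ...)`); single template for a monomorphic transcript
#'   pool.
#' @param config a [sim_config()] supplying `read_depth`, `read_length`,
#'   `error_rate`.
#' @param weights template mixture weights (default equal).
#' @param edits optional data frame `position`, `to`, `fraction`: each read
#'   drawn from an edited template carries base `to` at `position` with the
#'   given per-read fraction (an RNA-editing model).
#' @return a `read_set` data frame (`id`, `seq`, `qual`) with attribute
#'   `"placement"` (template, strand, start per read).
#' @export
simulate_reads <- function(templates, config, weights = NULL, edits = NULL) {
  templates <- toupper(templates)
  if (is.null(names(templates))) {
    names(templates) <- paste0("tpl", seq_along(templates))
  }
  rl <- config$read_length
  if (any(nchar(templates) < rl)) {
    ssw_error("read length exceeds template length", "ssw_input_error")
  }
  weights <- weights %||% rep(1, length(templates))
  weights <- weights / sum(weights)
  L <- nchar(templates[[1L]])
  n_reads <- ceiling(config$read_depth * L / rl)
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("read%05d", seq_len(n_reads))
  tpl_idx <- sample.int(length(templates), n_reads, replace = TRUE,
                        prob = weights)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  starts <- integer(n_reads)
  out <- character(n_reads)
  for (r in seq_len(n_reads)) {
    tpl <- templates[[tpl_idx[r]]]
    if (!is.null(edits) && nrow(edits)) {
      for (e in seq_len(nrow(edits))) {
        if (runif(1) < edits$fraction[e]) {
          substr(tpl, edits$position[e], edits$position[e]) <- edits$to[e]
        }
      }
    }
    start <- sample.int(nchar(tpl) - rl + 1L, 1L)
    starts[r] <- start
    rd <- substring(tpl, start, start + rl - 1L)
    err <- which(runif(rl) < config$error_rate)
    if (length(err)) {
      ch <- strsplit(rd, "")[[1]]
      for (i in err) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
      rd <- paste(ch, collapse = "")
    }
    if (strands[r] == "-") rd <- reverse_complement(rd)
    out[r] <- rd
  }
  reads <- validate_read_set(data.frame(id = ids, seq = out,
                                        qual = strrep("I", rl)))
  attr(reads, "placement") <- data.frame(
    id = ids, template = names(templates)[tpl_idx], strand = strands,
    start = starts)
  reads
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Seeds the RNG once from the config, then emits a tree, the cohort of gene
#' sequences (S and L copies for polymorphic taxa), S- and L-form two-gene
#' genome records (GenBank text), transcript reads from a polymorphic
#' taxon's 50/50 allele pool, and a ground-truth JSON sidecar. All files are
#' plain text and round-trip through this package's readers.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created); when `NULL` nothing is
#'   written and the objects are returned only.
#' @return invisible list: `config`, `tree`, `aln` (see
#'   [evolve_alignment()]), `genome_s`, `genome_l`, `reads`, `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  code <- load_code("echinoderm_mt")
  tree <- simulate_tree(config)
  aln <- evolve_alignment(tree, config, code)
  poly1 <- aln$truth$polymorphic_taxa[1L]
  s_region <- aln$seqs[[paste0(poly1, "_S")]]
  l_region <- aln$seqs[[paste0(poly1, "_L")]]
  genome_s <- assemble_genome(s_region, config, code, identifier = "SYNTH_S")
  genome_l <- assemble_genome(l_region, config, code, identifier = "SYNTH_L")
  reads <- simulate_reads(c(S = s_region, L = l_region), config)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      tree = file.path(dir, "tree.nwk"),
      cohort = file.path(dir, "nd6_cohort.fasta"),
      genome_s = file.path(dir, "genome_S.gb"),
      genome_l = file.path(dir, "genome_L.gb"),
      reads = file.path(dir, "reads.fastq"),
      truth = file.path(dir, "ground_truth.json"))
    write_newick(tree, paths$tree)
    write_fasta(aln$seqs, paths$cohort)
    write_genbank(genome_s$record, paths$genome_s)
    write_genbank(genome_l$record, paths$genome_l)
    write_fastq(reads, paths$reads)
    truth <- aln$truth
    truth$tree_newick <- write_newick(tree)
    truth$genome = genome_s$truth
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(config = config, tree = tree, aln = aln,
                 genome_s = genome_s, genome_l = genome_l, reads = reads,
                 paths = paths))
}
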