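## Parsimony mapping of the short/long (S/L) character on a phylogeny, with
## polymorphic tips carried as state sets, and the trans-species polymorphism
## (TSP) assessment.
##
## Two characters are analyzed:
##  * the S/L state itself (generalized Fitch, free root) -> min_changes;
##  * presence of the L allele (binary), with the short state assumed
##    ancestral on a stem edge above the root -- the ancestral-S assumption
##    reflects the finding that all echinoderms outside the focal clade carry
##    the short variant only. The minimum number of 0->1 (S->L origin) edges
##    among minimum-cost reconstructions of this character is
##    min_origins_of_L.

normalize_states <- function(states) {
  if (is.character(states)) {
    states <- lapply(states, function(s) {
      s <- toupper(s)
      if (s %in% c("SL", "LS", "{S,L}", "S,L")) c("S", "L")
      else strsplit(s, "")[[1]]
    }) |> setNames(names(states))
  }
  states <- lapply(states, function(s) sort(unique(toupper(s))))
  bad <- !vapply(states, function(s)
    length(s) > 0L && all(s %in% c("S", "L")), logical(1))
  if (any(bad)) {
    ssw_error(sprintf("invalid state set(s) for: %s",
                      paste(names(states)[bad], collapse = ", ")),
              "ssw_mapping_error")
  }
  states
}

## Sankoff DP with unit transition cost; `allowed` is a list (per tip label)
## of allowed states; `state_space` a character vector. Returns the root cost
## vector and, optionally, the per-state minimum number of `gain_from`->
## `gain_to` edges among minimum-cost subtree reconstructions.
sankoff_dp <- function(tree, allowed, state_space, gain_from = NULL,
                       gain_to = NULL) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  k <- length(state_space)
  cost <- matrix(Inf, nn, k)
  gains <- matrix(0, nn, k)
  for (i in seq_len(nt)) {
    st <- allowed[[tree$tip.label[i]]]
    if (is.null(st)) {
      ssw_error(sprintf("leaf '%s' has no assigned state", tree$tip.label[i]),
                "ssw_mapping_error")
    }
    cost[i, match(st, state_space)] <- 0
  }
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  ## postorder: internal nodes children-before-parents, root last
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
  for (v in po) {
    ch <- children[[as.character(v)]]
    for (si in seq_len(k)) {
      tot <- 0; g <- 0
      for (c in ch) {
        trans <- ifelse(seq_len(k) == si, 0, 1)
        vals <- cost[c, ] + trans
        best <- min(vals)
        tot <- tot + best
        cand <- which(vals == best)
        gc <- vapply(cand, function(t) {
          gains[c, t] + as.numeric(!is.null(gain_from) &&
            state_space[si] == gain_from && state_space[t] == gain_to)
        }, 0)
        g <- g + min(gc)
      }
      cost[v, si] <- tot
      gains[v, si] <- g
    }
  }
  root <- po[length(po)]
  list(root_cost = cost[root, ], root_gains = gains[root, ],
       state_space = state_space)
}

#' Generalized Fitch mapping of the S/L character
#'
#' Minimum number of character changes on a (rooted or unrooted) tree where
#' polymorphic tips carry the state set `{S,L}` (a polymorphic tip may
#' resolve to either state at no cost). An alternative `"split"` mode
#' replaces each polymorphic tip by a zero-length cherry of an S and an L
#' leaf; because the two alleles of a polymorphic tip necessarily differ,
#' that raw cost exceeds the set-based cost by exactly the number of
#' polymorphic tips, and the mode reports the cost net of that offset so the
#' two modes agree.
#'
#' @param tree `ape::phylo`; leaf labels must match `names(states)`.
#' @param states named list (taxon -> subset of c("S","L")) or character
#'   vector with entries `"S"`, `"L"`, `"SL"`.
#' @param polymorphic `"set"` (default) or `"split"`.
#' @return list with `min_changes`, `polymorphic_taxa`, `mode`.
#' @export
fitch_map <- function(tree, states, polymorphic = c("set", "split")) {
  polymorphic <- match.arg(polymorphic)
  states <- normalize_states(states)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    ssw_error(sprintf("leaf without a state: %s",
                      paste(missing, collapse = ", ")), "ssw_mapping_error")
  }
  poly <- names(states)[lengths(states) == 2L & names(states) %in% tree$tip.label]
  if (polymorphic == "split" && length(poly)) {
    nwk <- write_newick(tree)
    for (p in poly) {
      nwk <- sub(paste0("(?<![A-Za-z0-9_.])", p, "(?=[:,)])"),
                 sprintf("(%s__S:0,%s__L:0)", p, p), nwk, perl = TRUE)
    }
    tree2 <- read_newick(nwk)
    st2 <- states
    for (p in poly) {
      st2[[paste0(p, "__S")]] <- "S"
      st2[[paste0(p, "__L")]] <- "L"
      st2[[p]] <- NULL
    }
    dp <- sankoff_dp(tree2, st2, c("S", "L"))
    return(list(min_changes = min(dp$root_cost) - length(poly),
                polymorphic_taxa = poly, mode = "split"))
  }
  dp <- sankoff_dp(tree, states, c("S", "L"))
  list(min_changes = min(dp$root_cost), polymorphic_taxa = poly, mode = "set")
}

## Minimum number of S->L origin edges among minimum-cost reconstructions of
## the binary L-presence character, with an S stem above the root.
min_l_origins <- function(tree, states) {
  states <- normalize_states(states)
  allowed <- lapply(states, function(s) if ("L" %in% s) "1" else "0")
  dp <- sankoff_dp(tree, allowed, c("0", "1"), gain_from = "0", gain_to = "1")
  ## stem edge from the assumed ancestral short state ("0")
  tot <- dp$root_cost + c(0, 1)           # transition cost on the stem
  g <- dp$root_gains + c(0, 1)            # a 0->1 stem transition is an origin
  best <- min(tot)
  list(min_cost = best, min_origins = min(g[tot == best]))
}

#' Assess consistency with trans-species polymorphism
#'
#' A shared S/L polymorphism is consistent with trans-species persistence
#' (one ancestral stop-switch origin whose two alleles survived speciation)
#' when at least two tips are polymorphic and a minimum-cost reconstruction
#' of L-allele presence needs at most one S->L origin, ancestral to every
#' polymorphic tip. Otherwise the minimum number of independent origins is
#' reported (the convergence scenario).
#'
#' @param tree `ape::phylo`. An unrooted tree is rooted on `outgroup` when
#'   given, else midpoint-rooted (logged).
#' @param states see [fitch_map()].
#' @param outgroup optional outgroup taxon name used for rooting.
#' @param quiet suppress rooting notices.
#' @return object of class `tsp_report`: `min_changes`, `min_origins_of_L`,
#'   `polymorphic_taxa`, `tsp_consistent`, `narrative`.
#' @export
assess_tsp <- function(tree, states, outgroup = NULL, quiet = FALSE) {
  if (!ape::is.rooted(tree)) {
    if (!is.null(outgroup) && outgroup %in% tree$tip.label) {
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
      if (!quiet) ssw_note("rooted on outgroup '%s'", outgroup)
    } else {
      tree <- phangorn::midpoint(tree)
      if (!quiet) ssw_note("no outgroup given; midpoint-rooted")
    }
  }
  states <- normalize_states(states)
  fm <- fitch_map(tree, states)
  or <- min_l_origins(tree, states)
  poly <- fm$polymorphic_taxa
  consistent <- length(poly) >= 2L && or$min_origins <= 1L
  l_tips <- names(states)[vapply(states, function(s) "L" %in% s, logical(1))]
  l_tips <- intersect(l_tips, tree$tip.label)
  narrative <- if (length(l_tips) == 0L) {
    "No L alleles present; nothing to assess."
  } else {
    span <- if (length(l_tips) >= 2L) {
      mrca <- ape::getMRCA(tree, l_tips)
      clade <- ape::extract.clade(tree, mrca)$tip.label
      sprintf("L alleles occur in %d tip(s); their spanning clade holds %d tip(s)%s.",
              length(l_tips), length(clade),
              if (length(setdiff(clade, l_tips)))
                sprintf(" (%d without L)", length(setdiff(clade, l_tips)))
              else "")
    } else sprintf("L allele confined to tip %s.", l_tips)
    verdict <- if (consistent) {
      "A single ancestral stop-switch origin explains the data at minimum cost: consistent with trans-species persistence."
    } else if (length(poly) < 2L) {
      sprintf("Only %d polymorphic tip(s): trans-species polymorphism cannot be asserted.",
              length(poly))
    } else {
      sprintf("Minimum-cost reconstructions need %d independent S->L origins: convergence, not persistence.",
              or$min_origins)
    }
    paste(span, verdict)
  }
  structure(list(min_changes = fm$min_changes,
                 min_origins_of_L = or$min_origins,
                 polymorphic_taxa = poly,
                 tsp_consistent = consistent,
                 narrative = narrative),
            class = "tsp_report")
}

#' @export
print.tsp_report <- function(x, ...) {
  cat(sprintf("<tsp_report> min changes %d, min L origins %d, %d polymorphic tip(s)\n",
              x$min_changes, x$min_origins_of_L, length(x$polymorphic_taxa)))
  cat(sprintf("  tsp_consistent: %s\n  %s\n", x$tsp_consistent, x$narrative))
  invisible(x)
}
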