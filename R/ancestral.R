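## ---- characters -------------------------------------------------------

## Cluster detection: two tRNAs form a linked pair when, in every karyotype
## where both are present, they occupy consecutive positions in the same
## order. Qualifying pairs are chained into maximal cluster units (the
## S1-S2 cluster of sucking lice is the motivating case). Units that never
## change placement are unaffected by being clustered.
.detectClusters <- function(karyotypes) {
  trnas <- mtGeneSet("tRNA")
  pair_ok <- function(a, b) {
    seen <- FALSE
    for (k in karyotypes) {
      gl <- lapply(k@minichromosomes, function(m) .tokGene(m))
      genes <- unlist(gl)
      if (!(a %in% genes) || !(b %in% genes)) next
      seen <- TRUE
      adjacent <- FALSE
      for (g in gl) {
        ia <- match(a, g); ib <- match(b, g)
        if (!is.na(ia) && !is.na(ib) && ib == ia + 1L) adjacent <- TRUE
      }
      if (!adjacent) return(FALSE)
    }
    seen
  }
  ## collect candidate ordered pairs actually adjacent somewhere
  cand <- list()
  for (k in karyotypes) for (m in k@minichromosomes) {
    g <- .tokGene(m)
    tr <- geneCategory(g) == "tRNA"
    for (i in seq_len(length(g) - 1L))
      if (tr[i] && tr[i + 1L])
        cand[[paste(g[i], g[i + 1L])]] <- c(g[i], g[i + 1L])
  }
  links <- Filter(function(p) pair_ok(p[1], p[2]), cand)
  ## chain links into units
  units <- as.list(trnas)
  names(units) <- trnas
  for (p in links) {
    ua <- NULL; ub <- NULL
    for (nm in names(units)) {
      u <- units[[nm]]
      if (p[1] == u[length(u)]) ua <- nm
      if (p[2] == u[1]) ub <- nm
    }
    if (!is.null(ua) && !is.null(ub) && ua != ub) {
      units[[ua]] <- c(units[[ua]], units[[ub]])
      units[[ub]] <- NULL
    }
  }
  unname(units)
}

#' Extract karyotype characters for ancestral inference
#'
#' Builds the two character families used by the parsimony reconstruction:
#' backbone characters (one per distinct backbone key, scored
#' present/absent per taxon) and tRNA placement characters (one per moving
#' unit, scored by the unit's placement state: host backbone, nearest
#' stable neighbours, orientation). In cluster mode, maximal runs of tRNAs
#' that are adjacent in the same order in every karyotype where they
#' co-occur are treated as one unit.
#'
#' @param karyotypes Named list of \code{\linkS4class{Karyotype}} objects
#'   (at least 2).
#' @param clusterMode Logical; treat linked tRNA runs as single units
#'   (default \code{TRUE}).
#' @return data.frame with columns \code{type} (\code{"backbone"} or
#'   \code{"trna"}), \code{character_id}, \code{taxon}, \code{state}.
#'   Backbone states are \code{"present"}/\code{"absent"}; tRNA states are
#'   placement descriptors, \code{NA} when the unit's genes are missing
#'   from an (incomplete) karyotype.
#' @export
extractCharacters <- function(karyotypes, clusterMode = TRUE) {
  stopifnot(length(karyotypes) >= 2L)
  if (is.null(names(karyotypes)))
    names(karyotypes) <- vapply(karyotypes, taxon, character(1))
  bkeys <- sort(unique(unlist(lapply(karyotypes, backboneKeys))))
  bkeys <- bkeys[nzchar(bkeys)]
  rows <- list()
  for (tx in names(karyotypes)) {
    k <- karyotypes[[tx]]
    own <- backboneKeys(k)
    for (b in bkeys)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "backbone", character_id = b, taxon = tx,
        state = if (b %in% own) "present" else "absent",
        stringsAsFactors = FALSE)
  }
  units <- if (clusterMode) .detectClusters(karyotypes) else
    as.list(mtGeneSet("tRNA"))
  for (u in units) {
    uid <- paste(u, collapse = "-")
    for (tx in names(karyotypes)) {
      st <- .unitState(karyotypes[[tx]], u)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "trna", character_id = uid, taxon = tx,
        state = st, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Placement state of a unit within a single arrangement string's tokens.
.unitStateInTokens <- function(toks, unit) {
  g <- .tokGene(toks)
  pos <- match(unit, g)
  if (any(is.na(pos))) return(NA_character_)
  inverted <- FALSE
  if (length(unit) > 1L) {
    if (all(diff(pos) == 1L)) inverted <- FALSE
    else if (all(diff(pos) == -1L)) inverted <- TRUE
    else return(NA_character_)
  }
  lo <- min(pos); hi <- max(pos)
  cat_ <- geneCategory(g)
  up <- "NCR"
  if (lo > 1L) {
    left <- which(cat_[seq_len(lo - 1L)] != "tRNA")
    if (length(left)) up <- g[max(left)]
  }
  down <- "NCR"
  if (hi < length(g)) {
    right <- which(cat_[seq(hi + 1L, length(g))] != "tRNA") + hi
    if (length(right)) down <- g[min(right)]
  }
  bk <- toks[cat_ != "tRNA"]
  sprintf("host=%s|up=%s|down=%s|rev=%s|inv=%d",
          if (length(bk)) paste(bk, collapse = "-") else "", up, down,
          paste(as.integer(.tokRev(toks[pos])), collapse = ""),
          as.integer(inverted))
}

#' Placement evidence for outgroup species from an arrangement-pair table
#'
#' The non-Polyplax sucking lice are documented by an arrangement-pair
#' table (one row per moving gene, ancestral-context string, derived
#' arrangement string, species, genus) rather than by complete karyotypes.
#' This function turns that table, together with the ancestral karyotype
#' that provides the retained context, into per-species placement states
#' for each tRNA unit: a species' unit state comes from its own derived
#' arrangement when the unit moved, from another derived arrangement that
#' carries the unit along, or from the ancestral arrangement with that
#' species' relocated genes removed. Inconsistent or unresolvable cases
#' give \code{NA}.
#'
#' @param pairs data.frame with columns \code{gene},
#'   \code{mrca_arrangement}, \code{derived_arrangement}, \code{species},
#'   \code{genus} (see \code{\link{readPairTable}}).
#' @param ancestor \code{\linkS4class{Karyotype}}: the ancestral karyotype
#'   the table's arrangements are relative to.
#' @param units List of character vectors: the tRNA units to score.
#' @return data.frame with columns \code{character_id}, \code{taxon},
#'   \code{state}.
#' @export
pairPlacementStates <- function(pairs, ancestor, units) {
  species <- unique(pairs$species)
  rows <- list()
  for (s in species) {
    ps <- pairs[pairs$species == s, , drop = FALSE]
    dstr <- unique(ps$derived_arrangement)
    dtoks <- lapply(dstr, function(x) strsplit(x, "-", fixed = TRUE)[[1]])
    relocated <- unique(.tokGene(unlist(dtoks)))
    for (u in units) {
      uid <- paste(u, collapse = "-")
      st <- NA_character_
      own <- unique(ps$derived_arrangement[ps$gene %in% u])
      if (length(own) == 1L) {
        st <- .unitStateInTokens(strsplit(own, "-", fixed = TRUE)[[1]], u)
      } else if (length(own) == 0L) {
        carry <- dtoks[vapply(dtoks, function(t) all(u %in% .tokGene(t)),
                              logical(1))]
        if (length(carry) >= 1L) {
          sts <- unique(vapply(carry, .unitStateInTokens, character(1),
                               unit = u))
          if (length(sts) == 1L) st <- sts
        } else if (!any(u %in% relocated)) {
          for (m in ancestor@minichromosomes) {
            if (!all(u %in% .tokGene(m))) next
            kept <- m[!(.tokGene(m) %in% setdiff(relocated, u))]
            st <- .unitStateInTokens(kept, u)
            break
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        character_id = uid, taxon = s, state = st, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## ---- candidate rules --------------------------------------------------

#' Candidate ancestral placements for a character
#'
#' A placement state is a candidate for the ingroup's ancestor when it is
#' (rule 1) present in at least one ingroup taxon and also in one or more
#' non-ingroup taxa, or (rule 2) present in every ingroup taxon with data.
#' Taxa with \code{NA} states do not vote. When neither rule nominates any
#' state (as happens for the S1-S2 cluster of Polyplax), every state
#' observed in the ingroup competes, to be resolved by change counts.
#'
#' @param ingroupStates Named character vector: placement state per ingroup
#'   taxon (\code{NA} allowed).
#' @param outgroupStates Character vector of states over non-ingroup taxa
#'   (\code{NA} allowed); may be empty.
#' @return A list with \code{candidates} (character vector of states),
#'   \code{rule} (\code{"rule1"}, \code{"rule2"}, or \code{"fallback"} per
#'   candidate), and \code{fallback} (logical).
#' @export
candidateStates <- function(ingroupStates, outgroupStates = character()) {
  ing <- ingroupStates[!is.na(ingroupStates)]
  if (length(ing) == 0L) stop("uninformative character: all states NA")
  out <- outgroupStates[!is.na(outgroupStates)]
  obs <- unique(ing)
  r1 <- obs[obs %in% out]
  r2 <- obs[vapply(obs, function(s) all(ing == s), logical(1))]
  cand <- union(r1, r2)
  if (length(cand)) {
    rule <- ifelse(cand %in% r2, "rule2", "rule1")
    return(list(candidates = cand, rule = rule, fallback = FALSE))
  }
  list(candidates = obs, rule = rep("fallback", length(obs)),
       fallback = TRUE)
}

## ---- small parsimony --------------------------------------------------

#' Minimal change count for a candidate ancestral state
#'
#' Counts the minimum number of state changes on a rooted tree needed to
#' explain the tip states when the root is fixed to \code{candidate},
#' by exact dynamic programming (Sankoff with unit costs) over the state
#' alphabet observed at the tips plus the candidate. Any state may change
#' into any other in one step; tips with \code{NA} impose no constraint.
#'
#' @param tree A rooted \code{ape::phylo} tree.
#' @param tipStates Named character vector of states; names must cover the
#'   tree's tip labels (\code{NA} = missing data).
#' @param candidate State assigned to the root.
#' @return Integer: the minimal number of changes.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' parsimonyChanges(tr, c(a = "x", b = "x", c = "y", d = "y"), "x")  # 1
#' @export
parsimonyChanges <- function(tree, tipStates, candidate) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(tipStates)))
    stop("tipStates must be named for every tip")
  st <- tipStates[tips]
  alpha <- unique(c(stats::na.omit(st), candidate))
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  cost <- matrix(Inf, nrow = nnode, ncol = length(alpha))
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) cost[i, ] <- 0
    else cost[i, match(st[i], alpha)] <- 0
  }
  ## postorder guarantees children are finished before their parent; child
  ## minima are accumulated into the parent's row as we go
  tre <- stats::reorder(tree, "postorder")
  cost[(ntip + 1L):nnode, ] <- 0
  for (e in seq_len(nrow(tre$edge))) {
    par <- tre$edge[e, 1L]; chl <- tre$edge[e, 2L]
    contrib <- vapply(seq_along(alpha), function(s) {
      min(cost[chl, ] + (seq_along(alpha) != s))
    }, numeric(1))
    cost[par, ] <- cost[par, ] + contrib
  }
  root <- ntip + 1L
  as.integer(cost[root, match(candidate, alpha)])
}

## ---- inference --------------------------------------------------------

.ingroupSubtree <- function(tree, ingroup) {
  stopifnot(all(ingroup %in% tree$tip.label))
  if (length(ingroup) == length(tree$tip.label)) return(tree)
  node <- ape::getMRCA(tree, ingroup)
  sub <- ape::extract.clade(tree, node)
  if (!setequal(sub$tip.label, ingroup))
    stop("ingroup is not monophyletic on the supplied tree")
  sub
}

#' Infer the ancestral karyotype of an ingroup by two-rule parsimony
#'
#' Reconstructs the mitochondrial karyotype of the most recent common
#' ancestor of \code{ingroup} on a fixed rooted tree. Backbone characters
#' (protein-coding/rRNA gene distribution) are resolved first; tRNA unit
#' placements are then resolved conditional on the backbone. For each
#' character, candidate ancestral states are nominated by the two rules of
#' \code{\link{candidateStates}}; conflicts are resolved by the minimal
#' change count on the ingroup subtree (\code{\link{parsimonyChanges}});
#' exact ties are reported as alternatives and expanded into equally
#' parsimonious variant karyotypes, never silently broken.
#'
#' @param tree Rooted \code{ape::phylo} tree whose tips include the ingroup
#'   taxa (and, normally, non-ingroup taxa that supply rule-1 evidence).
#' @param karyotypes Named list of \code{\linkS4class{Karyotype}} objects;
#'   must cover the ingroup, may cover non-ingroup tips.
#' @param ingroup Character vector of ingroup taxon names (a monophyletic
#'   clade of \code{tree}).
#' @param pairs Optional arrangement-pair table
#'   (\code{\link{readPairTable}}) giving placement evidence for
#'   non-ingroup species that lack full karyotypes.
#' @param pairAncestor \code{\linkS4class{Karyotype}} providing the
#'   ancestral context for \code{pairs} (required with \code{pairs}).
#' @param clusterMode Treat linked tRNA runs as single units (default
#'   \code{TRUE}).
#' @param ancestorLabel Taxon label for the reconstructed karyotype.
#' @return A \code{\linkS4class{ReconstructionResult}}.
#' @examples
#' d <- louseData()
#' res <- inferAncestor(d$tree, d$karyotypes, d$ingroup,
#'                      pairs = d$pairs, pairAncestor = d$mrca_sucking_lice)
#' length(minichromosomes(variants(res)[[1]]))  # 11
#' @export
inferAncestor <- function(tree, karyotypes, ingroup, pairs = NULL,
                          pairAncestor = NULL, clusterMode = TRUE,
                          ancestorLabel = "MRCA ingroup") {
  if (is.null(names(karyotypes)))
    names(karyotypes) <- vapply(karyotypes, taxon, character(1))
  if (!all(ingroup %in% names(karyotypes)))
    stop("karyotypes must be supplied for every ingroup taxon")
  ## canonicalize input order so the result is invariant to it
  karyotypes <- karyotypes[order(names(karyotypes))]
  ingroup <- sort(ingroup)
  sub <- .ingroupSubtree(tree, ingroup)
  ingk <- karyotypes[ingroup]
  outk <- karyotypes[setdiff(names(karyotypes), ingroup)]
  if (!is.null(pairs) && is.null(pairAncestor))
    stop("pairAncestor must accompany pairs")

  ## ---- backbone characters -------------------------------------------
  chars <- extractCharacters(ingk, clusterMode = clusterMode)
  bchar <- chars[chars$type == "backbone", , drop = FALSE]
  bkeys <- unique(bchar$character_id)
  chosen_bb <- character()
  changes <- list()
  for (b in sort(bkeys)) {
    stb <- bchar$state[bchar$character_id == b]
    names(stb) <- bchar$taxon[bchar$character_id == b]
    outg <- vapply(outk, function(k) {
      if (b %in% backboneKeys(k)) "present" else "absent"
    }, character(1))
    cand <- candidateStates(stb[ingroup], unname(outg))
    if (!("present" %in% cand$candidates)) next
    nch <- parsimonyChanges(sub, stb, "present")
    genes_b <- .tokGene(strsplit(b, "-", fixed = TRUE)[[1]])
    if (any(genes_b %in% .tokGene(unlist(strsplit(chosen_bb, "-"))))) {
      ## conflicting backbone: keep the earlier (lower-change) choice
      next
    }
    chosen_bb <- c(chosen_bb, b)
    changes[[length(changes) + 1L]] <- data.frame(
      type = "backbone", unit = b, state = "present", changes = nch,
      stringsAsFactors = FALSE)
  }
  ## order backbones deterministically
  chosen_bb <- sort(chosen_bb)

  ## ---- tRNA unit characters ------------------------------------------
  tchar <- chars[chars$type == "trna", , drop = FALSE]
  units <- unique(tchar$character_id)
  punits <- lapply(units, function(u) strsplit(u, "-", fixed = TRUE)[[1]])
  pairEv <- if (!is.null(pairs))
    pairPlacementStates(pairs, pairAncestor, punits) else NULL
  placements <- list()   # unit -> list of tied states
  alt_rows <- list()
  unplaced <- character()
  for (i in seq_along(units)) {
    uid <- units[i]
    stt <- tchar$state[tchar$character_id == uid]
    names(stt) <- tchar$taxon[tchar$character_id == uid]
    if (all(is.na(stt[ingroup]))) { unplaced <- c(unplaced, uid); next }
    outg <- character()
    if (length(outk))
      outg <- c(outg, vapply(outk, .unitState, character(1),
                             unit = punits[[i]]))
    if (!is.null(pairEv))
      outg <- c(outg, pairEv$state[pairEv$character_id == uid])
    cand <- candidateStates(stt[ingroup], outg)
    counts <- vapply(cand$candidates, function(cs)
      parsimonyChanges(sub, stt, cs), integer(1))
    best <- min(counts)
    tied <- cand$candidates[counts == best]
    ## a placement must sit on an inferred ancestral backbone
    hostOf <- function(s) sub("^host=([^|]*)\\|.*$", "\\1", s)
    tied <- tied[vapply(tied, function(s)
      hostOf(s) %in% chosen_bb, logical(1))]
    if (length(tied) == 0L) { unplaced <- c(unplaced, uid); next }
    placements[[uid]] <- tied
    changes[[length(changes) + 1L]] <- data.frame(
      type = "trna", unit = uid, state = paste(tied, collapse = " OR "),
      changes = best, stringsAsFactors = FALSE)
    if (length(tied) > 1L)
      for (s in tied)
        alt_rows[[length(alt_rows) + 1L]] <- data.frame(
          unit = uid, state = s, changes = best, stringsAsFactors = FALSE)
  }

  ## ---- assemble variants ---------------------------------------------
  tie_units <- names(placements)[lengths(placements) > 1L]
  combos <- if (length(tie_units)) {
    do.call(expand.grid, c(lapply(placements[tie_units], seq_along),
                           list(stringsAsFactors = FALSE)))
  } else data.frame(row.names = 1)
  variants <- vector("list", nrow(combos))
  for (v in seq_len(nrow(combos))) {
    pick <- placements
    for (u in tie_units) pick[[u]] <- placements[[u]][combos[v, u][[1]]]
    variants[[v]] <- .assembleKaryotype(
      chosen_bb, pick, punits[match(names(pick), units)], ingk,
      label = if (nrow(combos) > 1L)
        sprintf("%s (variant %d)", ancestorLabel, v) else ancestorLabel)
  }
  methods::new("ReconstructionResult",
               variants = variants,
               changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(),
               alternatives = if (length(alt_rows)) do.call(rbind, alt_rows)
                 else data.frame(unit = character(), state = character(),
                                 changes = integer()),
               unplaced = unplaced)
}

## Build a Karyotype from chosen backbones and unit placements. Units
## sharing a backbone gap are ordered by the gene order observed in an
## ingroup taxon that carries all of them in that gap.
.assembleKaryotype <- function(backbones, pick, punits, ingk, label) {
  names(punits) <- names(pick)
  minis <- lapply(backbones, function(b) strsplit(b, "-", fixed = TRUE)[[1]])
  names(minis) <- backbones
  ## gap key: host|up|down
  gap_units <- list()
  for (uid in names(pick)) {
    s <- pick[[uid]]
    f <- .parseState(s)
    key <- paste(f$host, f$up, f$down, sep = "|")
    gap_units[[key]] <- c(gap_units[[key]], uid)
  }
  for (key in names(gap_units)) {
    us <- gap_units[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    host <- parts[1]; up <- parts[2]; down <- parts[3]
    ## order multiple units by an observed taxon order
    if (length(us) > 1L) {
      ord <- NULL
      for (k in ingk) {
        posn <- vapply(us, function(uid) {
          st <- .unitState(k, punits[[uid]])
          if (identical(st, pick[[uid]])) {
            for (m in k@minichromosomes) {
              p <- match(punits[[uid]][1], .tokGene(m))
              if (!is.na(p)) return(p)
            }
          }
          NA_real_
        }, numeric(1))
        if (!anyNA(posn)) { ord <- order(posn); break }
      }
      if (!is.null(ord)) us <- us[ord]
    }
    toks <- unlist(lapply(us, function(uid) {
      f <- .parseState(pick[[uid]])
      u <- punits[[uid]]
      rev_ <- as.integer(strsplit(f$rev, "")[[1]]) == 1L
      if (f$inv) { u <- rev(u); rev_ <- rev(rev_) }
      .mkTok(u, rev_)
    }))
    bb <- minis[[host]]
    g <- .tokGene(bb)
    if (up == "NCR") pos <- 0L
    else pos <- match(up, g)
    if (is.na(pos)) next
    minis[[host]] <- append(bb, toks, after = pos)
  }
  Karyotype(label, unname(minis), genus = genus(ingk[[1]]))
}

.parseState <- function(s) {
  m <- regmatches(s, regexec(
    "^host=([^|]*)\\|up=([^|]*)\\|down=([^|]*)\\|rev=([^|]*)\\|inv=(\\d)$", s))[[1]]
  list(host = m[2], up = m[3], down = m[4], rev = m[5],
       inv = as.integer(m[6]) == 1L)
}
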