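#' Configuration for the karyotype-evolution simulator
#'
#' The simulator models inter-minichromosomal tRNA translocation on a
#' fixed rooted tree. Per branch, the number of translocation events is
#' Poisson(\code{event_rate}) (equal weight per branch; no branch
#' lengths). Each event removes a random tRNA unit and reinserts it on a
#' different minichromosome: with probability \code{ncr_bias} the
#' destination slot is drawn uniformly from the NCR-adjacent slots, and
#' otherwise uniformly from all available slots, so the chance of an
#' NCR-adjacent destination is \code{ncr_bias + (1 - ncr_bias) *
#' censusFraction}. \code{ncr_bias = 0} is the unbiased null;
#' \code{ncr_bias = 1} is fully directional towards the control-region
#' boundaries.
#'
#' @param event_rate Expected translocation events per branch (Poisson
#'   mean, >= 0).
#' @param ncr_bias Probability in [0,1] that a destination is drawn from
#'   the NCR-adjacent slot class.
#' @param inversion_prob Per-event probability that the moved unit flips
#'   orientation.
#' @param cluster_prob Per-event probability that the moving unit is an
#'   adjacent 2-tRNA block rather than a single gene.
#' @param swap_prob Per-branch probability of an L1/L2-type identity swap.
#' @param seed Integer seed for the pseudorandom stream; identical config
#'   and seed give identical output.
#' @return A list of class \code{"EvolutionConfig"}.
#' @export
evolutionConfig <- function(event_rate = 0.5, ncr_bias = 0.5,
                            inversion_prob = 0.05, cluster_prob = 0.05,
                            swap_prob = 0.01, seed = 1L) {
  stopifnot(event_rate >= 0,
            ncr_bias >= 0, ncr_bias <= 1,
            inversion_prob >= 0, inversion_prob <= 1,
            cluster_prob >= 0, cluster_prob <= 1,
            swap_prob >= 0, swap_prob <= 1)
  structure(list(event_rate = event_rate, ncr_bias = ncr_bias,
                 inversion_prob = inversion_prob,
                 cluster_prob = cluster_prob, swap_prob = swap_prob,
                 seed = as.integer(seed)),
            class = "EvolutionConfig")
}

.emptyEventLog <- function() {
  data.frame(branch = character(), type = character(), unit = character(),
             source_mini = integer(), source_pos = integer(),
             dest_mini = integer(), dest_pos = integer(),
             class = character(), inverted = logical(),
             tokens = character(), stringsAsFactors = FALSE)
}

## One translocation event drawn from the current RNG stream; returns the
## mutated minichromosome list plus a log row, or NULL when no move is
## possible. Minichromosome list order is kept stable so logged indices
## stay valid for replay.
.drawEvent <- function(mins, config, branch) {
  ## candidate units: single tRNAs, or adjacent 2-tRNA blocks
  singles <- list(); pairs <- list()
  for (i in seq_along(mins)) {
    m <- mins[[i]]
    tr <- geneCategory(.tokGene(m)) == "tRNA"
    ## a unit may not empty its minichromosome
    for (j in which(tr))
      if (length(m) > 1L)
        singles[[length(singles) + 1L]] <- list(mini = i, pos = j, len = 1L)
    for (j in seq_len(length(m) - 1L))
      if (tr[j] && tr[j + 1L] && length(m) > 2L)
        pairs[[length(pairs) + 1L]] <- list(mini = i, pos = j, len = 2L)
  }
  if (length(mins) < 2L) stop("no eligible destination: single-minichromosome karyotype")
  use_pair <- length(pairs) > 0L && stats::runif(1) < config$cluster_prob
  pool <- if (use_pair) pairs else singles
  if (!length(pool)) return(NULL)
  u <- pool[[sample.int(length(pool), 1L)]]
  toks <- mins[[u$mini]][u$pos:(u$pos + u$len - 1L)]
  mins[[u$mini]] <- mins[[u$mini]][-(u$pos:(u$pos + u$len - 1L))]
  ## destination slots on other minichromosomes with room for the unit
  ## (minichromosomes carry at most 8 genes)
  targets <- setdiff(seq_along(mins), u$mini)
  targets <- targets[vapply(targets, function(i)
    length(mins[[i]]) + u$len <= 8L, logical(1))]
  slot_mini <- integer(); slot_pos <- integer(); slot_adj <- logical()
  for (i in targets) {
    g <- length(mins[[i]])
    slot_mini <- c(slot_mini, rep(i, g + 1L))
    slot_pos <- c(slot_pos, 0:g)
    slot_adj <- c(slot_adj, c(TRUE, rep(FALSE, max(g - 1L, 0L)), TRUE))
  }
  if (!length(slot_mini)) return(NULL)  # every other minichromosome full
  pickFrom <- if (stats::runif(1) < config$ncr_bias) which(slot_adj)
              else seq_along(slot_mini)
  s <- pickFrom[sample.int(length(pickFrom), 1L)]
  inverted <- stats::runif(1) < config$inversion_prob
  if (inverted)
    toks <- rev(.mkTok(.tokGene(toks), !.tokRev(toks)))
  mins[[slot_mini[s]]] <- append(mins[[slot_mini[s]]], toks,
                                 after = slot_pos[s])
  log <- data.frame(branch = branch, type = "move",
                    unit = paste(.tokGene(toks), collapse = "-"),
                    source_mini = u$mini, source_pos = u$pos,
                    dest_mini = slot_mini[s], dest_pos = slot_pos[s],
                    class = if (slot_adj[s]) "adjacent" else "intergenic",
                    inverted = inverted,
                    tokens = paste(toks, collapse = "-"),
                    stringsAsFactors = FALSE)
  list(mins = mins, log = log)
}

#' Evolve a karyotype along one branch
#'
#' Draws a Poisson(\code{event_rate}) number of translocation events and
#' applies them sequentially (see \code{\link{evolutionConfig}} for the
#' event model), then applies an L1/L2 identity swap with probability
#' \code{swap_prob}. Gene content is conserved. Uses the current RNG
#' state; seed it (or use \code{\link{simulateTree}}, which derives a
#' deterministic per-branch stream) for reproducibility.
#'
#' @param x \code{\linkS4class{Karyotype}} at the parent node.
#' @param config An \code{\link{evolutionConfig}}.
#' @param branch Branch label recorded in the event log.
#' @return A list with \code{karyotype} and \code{log} (data.frame; one
#'   row per event, with the destination slot and realized class).
#' @export
simulateBranch <- function(x, config, branch = "branch") {
  stopifnot(methods::is(x, "Karyotype"))
  mins <- x@minichromosomes
  logs <- list()
  n <- stats::rpois(1, config$event_rate)
  for (i in seq_len(n)) {
    ev <- .drawEvent(mins, config, branch)
    if (is.null(ev)) next
    mins <- ev$mins
    logs[[length(logs) + 1L]] <- ev$log
  }
  if (stats::runif(1) < config$swap_prob) {
    g <- lapply(mins, .tokGene)
    if (all(c("L1", "L2") %in% unlist(g))) {
      for (i in seq_along(mins)) {
        gi <- g[[i]]
        gi[gi == "L1"] <- "@@"; gi[gi == "L2"] <- "L1"; gi[gi == "@@"] <- "L2"
        mins[[i]] <- .mkTok(gi, .tokRev(mins[[i]]))
      }
      logs[[length(logs) + 1L]] <- data.frame(
        branch = branch, type = "swap", unit = "L1/L2",
        source_mini = NA_integer_, source_pos = NA_integer_,
        dest_mini = NA_integer_, dest_pos = NA_integer_,
        class = NA_character_, inverted = FALSE, tokens = "",
        stringsAsFactors = FALSE)
    }
  }
  k <- Karyotype(x@taxon, mins, genus = x@genus)
  list(karyotype = k,
       log = if (length(logs)) do.call(rbind, logs) else .emptyEventLog())
}

## Deterministic per-branch seed from the run seed and a branch identity
## string (kept below 2^31).
.branchSeed <- function(seed, id) {
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 131 + c) %% 2147483629
  as.integer((h + as.numeric(seed) * 7919) %% 2147483629)
}

#' Simulate karyotype evolution over a tree
#'
#' Applies \code{\link{simulateBranch}} along every branch of a rooted
#' tree, depth-first from the root karyotype. The RNG stream of each
#' branch is derived deterministically from the config seed and the
#' branch's identity (the sorted tip set below it), so a subtree's output
#' is stable when the tree is extended elsewhere.
#'
#' @param tree Rooted \code{ape::phylo}.
#' @param root \code{\linkS4class{Karyotype}} at the root (must be
#'   complete).
#' @param config An \code{\link{evolutionConfig}}.
#' @return A list of class \code{"SimulatedDataset"}: \code{tips} (named
#'   list of \code{\linkS4class{Karyotype}}), \code{log} (event
#'   data.frame; branch column names the branch's tip set), and
#'   \code{config}.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),c);")
#' anc <- readKaryotype(system.file("extdata", "mrca_polyplax_v1.kyt",
#'                                  package = "MitoKaryo"))
#' sim <- simulateTree(tr, anc, evolutionConfig(event_rate = 1, seed = 7))
#' names(sim$tips)
#' @export
simulateTree <- function(tree, root, config) {
  stopifnot(inherits(tree, "phylo"), methods::is(root, "Karyotype"))
  ntip <- length(tree$tip.label)
  rootnode <- ntip + 1L
  tipsBelow <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, tipsBelow)))
  }
  tips <- list(); logs <- list()
  recurse <- function(node, k) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (child in kids) {
      id <- paste(tipsBelow(child), collapse = "+")
      set.seed(.branchSeed(config$seed, id))
      res <- simulateBranch(k, config, branch = id)
      if (nrow(res$log)) logs[[length(logs) + 1L]] <<- res$log
      if (child <= ntip) {
        kk <- res$karyotype
        kk@taxon <- tree$tip.label[child]
        tips[[tree$tip.label[child]]] <<- kk
      } else recurse(child, res$karyotype)
    }
  }
  recurse(rootnode, root)
  structure(list(tips = tips,
                 log = if (length(logs)) do.call(rbind, logs)
                       else .emptyEventLog(),
                 config = config),
            class = "SimulatedDataset")
}

#' Replay an event log on a root karyotype
#'
#' Applies the logged events of one branch (or a concatenation of branch
#' logs in root-to-tip order) to a karyotype; reproduces the simulated
#' descendant exactly.
#'
#' @param x Root \code{\linkS4class{Karyotype}}.
#' @param log Event log data.frame (rows in application order).
#' @return \code{\linkS4class{Karyotype}}.
#' @export
replayLog <- function(x, log) {
  mins <- x@minichromosomes
  for (i in seq_len(nrow(log))) {
    if (log$type[i] == "swap") {
      for (j in seq_along(mins)) {
        gj <- .tokGene(mins[[j]])
        gj[gj == "L1"] <- "@@"; gj[gj == "L2"] <- "L1"; gj[gj == "@@"] <- "L2"
        mins[[j]] <- .mkTok(gj, .tokRev(mins[[j]]))
      }
      next
    }
    toks <- strsplit(log$tokens[i], "-", fixed = TRUE)[[1]]
    genes <- .tokGene(toks)
    src <- log$source_mini[i]
    pos <- match(genes[1], .tokGene(mins[[src]]))
    ## the log stores post-inversion tokens; locate by first gene present
    if (is.na(pos)) pos <- match(genes[length(genes)],
                                 .tokGene(mins[[src]]))
    idx <- which(.tokGene(mins[[src]]) %in% genes)
    mins[[src]] <- mins[[src]][-idx]
    mins[[log$dest_mini[i]]] <- append(mins[[log$dest_mini[i]]], toks,
                                       after = log$dest_pos[i])
  }
  Karyotype(x@taxon, mins, genus = x@genus)
}

#' Monte-Carlo calibration of the adjacency statistics
#'
#' Repeatedly simulates karyotype evolution, runs the full detection and
#' testing pipeline (\code{\link{detectEvents}} per tip,
#' \code{\link{adjacencyTable}} against the root,
#' \code{\link{pooledTTest}} of the expected vs observed adjacency
#' columns), and tallies rejections at level \code{alpha}. Replicates in
#' which fewer than two units acquired events (so the two-sample test is
#' undefined) are excluded from the rejection-rate denominator and
#' counted separately.
#'
#' @param tree Rooted \code{ape::phylo}.
#' @param root Complete \code{\linkS4class{Karyotype}}.
#' @param config An \code{\link{evolutionConfig}}; replicate \code{r} uses
#'   seed \code{config$seed + r - 1}.
#' @param replicates Number of replicates (>= 1).
#' @param alpha Rejection level (default 0.05).
#' @return A list with \code{rejection_rate}, \code{ci} (exact binomial
#'   95\% interval), \code{n_tested}, \code{n_skipped},
#'   \code{mean_destination_adjacent} (mean fraction of true logged
#'   destinations in the adjacent class), \code{mean_observed_adjacent}
#'   (the same fraction as seen by the detector in the final karyotypes:
#'   lower at high rates, because a later arrival at a boundary pushes an
#'   earlier one inward), and \code{config}.
#' @export
calibrationExperiment <- function(tree, root, config, replicates,
                                  alpha = 0.05) {
  if (replicates < 1L) stop("replicates must be >= 1")
  rej <- 0L; tested <- 0L; skipped <- 0L
  obs_frac <- numeric(); dest_frac <- numeric()
  for (r in seq_len(replicates)) {
    cfg <- config; cfg$seed <- config$seed + r - 1L
    sim <- simulateTree(tree, root, cfg)
    moves <- sim$log[sim$log$type == "move", , drop = FALSE]
    if (nrow(moves))
      dest_frac <- c(dest_frac, mean(moves$class == "adjacent"))
    ev <- do.call(rbind, lapply(sim$tips, function(tk)
      detectEvents(root, tk, clusterMode = FALSE)))
    if (is.null(ev) || nrow(ev) == 0L) { skipped <- skipped + 1L; next }
    ev <- ev[!ev$identity_swap, , drop = FALSE]
    if (nrow(ev) == 0L) { skipped <- skipped + 1L; next }
    obs_frac <- c(obs_frac, mean(ev$class == "adjacent"))
    tab <- adjacencyTable(ev, root, mode = "T4")
    if (nrow(tab) < 2L) { skipped <- skipped + 1L; next }
    tt <- pooledTTest(tab$expected_adjacent, tab$observed_adjacent)
    tested <- tested + 1L
    if (!is.na(tt$p) && tt$p < alpha) rej <- rej + 1L
  }
  ci <- if (tested > 0L) as.numeric(stats::binom.test(rej, tested)$conf.int)
        else c(NA_real_, NA_real_)
  list(rejection_rate = if (tested > 0L) rej / tested else NA_real_,
       ci = ci, n_tested = tested, n_skipped = skipped,
       mean_destination_adjacent = mean(dest_frac),
       mean_observed_adjacent = mean(obs_frac),
       config = config)
}
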