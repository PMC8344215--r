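## Shared fixtures and independent oracles for the test suite.

ld <- louseData()

miniStrings <- function(k)
  sort(vapply(minichromosomes(k), paste, character(1), collapse = "-"))

## Root-to-tip branch logs of a SimulatedDataset for one tip, in
## application order (branch ids are "+"-joined sorted tip sets).
tipLog <- function(sim, tip) {
  ids <- unique(sim$log$branch)
  onpath <- ids[vapply(ids, function(i)
    tip %in% strsplit(i, "+", fixed = TRUE)[[1]], logical(1))]
  onpath <- onpath[order(-lengths(strsplit(onpath, "+", fixed = TRUE)))]
  if (!length(onpath)) return(NULL)
  do.call(rbind, lapply(onpath, function(i)
    sim$log[sim$log$branch == i, , drop = FALSE]))
}

## Independent brute-force oracle for fixed-root small parsimony: tips are
## fixed to their states (NA tips are free), internal nodes take any state
## from the alphabet; the minimum number of mismatched edges is returned.
bruteForceChanges <- function(tree, tipStates, candidate) {
  tips <- tree$tip.label
  st <- tipStates[tips]
  alpha <- unique(c(st[!is.na(st)], candidate))
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  internal_free <- if (nnode >= ntip + 2L) (ntip + 2L):nnode else integer(0)
  free <- c(which(is.na(st)), internal_free)
  ## node ntip+1 is the root, fixed to the candidate
  assign0 <- rep(NA_character_, nnode)
  assign0[seq_len(ntip)] <- st
  assign0[ntip + 1L] <- candidate
  if (!length(free)) {
    return(sum(assign0[tree$edge[, 1]] != assign0[tree$edge[, 2]]))
  }
  grid <- do.call(expand.grid, c(rep(list(alpha), length(free)),
                                 list(stringsAsFactors = FALSE)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- assign0
    a[free] <- unlist(grid[r, ])
    cost <- sum(a[tree$edge[, 1]] != a[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

## Random rooted tree with n tips labelled t1..tn.
randomTopology <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
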