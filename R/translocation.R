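## ---- event detection --------------------------------------------------

#' Detect tRNA translocation events between two karyotypes
#'
#' Compares a derived karyotype against an ancestral one sharing the same
#' backbone set. A tRNA unit is an event when its placement state (host
#' backbone, flanking stable elements, orientation) differs. Reciprocal
#' anticodon-swap pairs (L1/L2, S1/S2 exchanging placements without
#' physical movement) are flagged \code{identity_swap} and are excluded
#' from translocation statistics downstream, though they still count as
#' genes that changed position. In cluster mode, tRNA runs that are
#' adjacent in the same order in both karyotypes move as one unit.
#'
#' Destinations at either NCR boundary are classed \code{"adjacent"};
#' insertions a short distance inside the NCR are written at the boundary
#' in the karyotype format and therefore also class as adjacent, matching
#' how such cases are scored. All other destinations are
#' \code{"intergenic"}.
#'
#' @param ancestor,derived \code{\linkS4class{Karyotype}} objects with
#'   identical backbone sets.
#' @param clusterMode Logical (default \code{TRUE}).
#' @return data.frame with columns \code{genus}, \code{species},
#'   \code{unit}, \code{source}, \code{destination}, \code{class},
#'   \code{inverted}, \code{identity_swap}. Zero rows when the karyotypes
#'   agree.
#' @examples
#' fx <- system.file("extdata", package = "MitoKaryo")
#' anc <- readKaryotype(file.path(fx, "mrca_polyplax_v1.kyt"))
#' rec <- readKaryotype(file.path(fx, "polyplax_reclinata.kyt"))
#' detectEvents(anc, rec)[, c("unit", "class", "inverted")]
#' @export
detectEvents <- function(ancestor, derived, clusterMode = TRUE) {
  stopifnot(methods::is(ancestor, "Karyotype"),
            methods::is(derived, "Karyotype"))
  bbA <- sort(backboneKeys(ancestor)); bbD <- sort(backboneKeys(derived))
  bbA <- bbA[nzchar(bbA)]; bbD <- bbD[nzchar(bbD)]
  if (!identical(bbA, bbD))
    stop("backbone change: use karyotype-level comparison")
  units <- if (clusterMode) .detectClusters(list(ancestor, derived)) else
    as.list(mtGeneSet("tRNA"))
  rows <- list()
  statesA <- list(); statesD <- list()
  for (u in units) {
    uid <- paste(u, collapse = "-")
    statesA[[uid]] <- .unitState(ancestor, u)
    statesD[[uid]] <- .unitState(derived, u)
  }
  changed <- names(statesA)[vapply(names(statesA), function(uid) {
    a <- statesA[[uid]]; d <- statesD[[uid]]
    !is.na(a) && !is.na(d) && a != d
  }, logical(1))]
  ## identity swaps among anticodon sibling pairs
  swap <- character()
  for (p in list(c("L1", "L2"), c("S1", "S2"))) {
    if (all(p %in% changed) &&
        identical(statesD[[p[1]]], statesA[[p[2]]]) &&
        identical(statesD[[p[2]]], statesA[[p[1]]]))
      swap <- c(swap, p)
  }
  for (uid in changed) {
    u <- strsplit(uid, "-", fixed = TRUE)[[1]]
    fa <- .parseState(statesA[[uid]]); fd <-.parseState(statesD[[uid]])
    rows[[length(rows) + 1L]] <- data.frame(
      genus = derived@genus, species = derived@taxon, unit = uid,
      source = statesA[[uid]], destination = statesD[[uid]],
      class = if (isTRUE(.unitFlanksNCR(derived, u))) "adjacent"
              else "intergenic",
      inverted = (fa$rev != fd$rev) || (fa$inv != fd$inv),
      identity_swap = uid %in% swap,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(genus = character(), species = character(),
                      unit = character(), source = character(),
                      destination = character(), class = character(),
                      inverted = logical(), identity_swap = logical()))
  out <- do.call(rbind, rows)
  out[order(out$unit), , drop = FALSE]
}

#' Detect translocation events from an arrangement-pair table
#'
#' Each table row names a moving tRNA gene, its arrangement string in the
#' ancestor, its arrangement string in a derived species, and the species;
#' every (row x species) is one event. The destination is NCR-adjacent iff
#' the moving gene is first or last in the derived arrangement string.
#'
#' @param rows data.frame with columns \code{gene},
#'   \code{mrca_arrangement}, \code{derived_arrangement}, \code{species},
#'   \code{genus}.
#' @return data.frame with columns \code{genus}, \code{species},
#'   \code{unit}, \code{source}, \code{destination}, \code{class},
#'   \code{inverted}, \code{identity_swap}.
#' @examples
#' pr <- readPairTable(system.file("extdata", "nonpolyplax_pairs.tsv",
#'                                 package = "MitoKaryo"))
#' ev <- detectEventsFromPairs(pr)
#' nrow(ev)
#' @export
detectEventsFromPairs <- function(rows) {
  need <- c("gene", "mrca_arrangement", "derived_arrangement",
            "species", "genus")
  if (!all(need %in% names(rows)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  cls <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    toks <- .tokGene(strsplit(rows$derived_arrangement[i], "-",
                              fixed = TRUE)[[1]])
    p <- match(rows$gene[i], toks)
    if (is.na(p))
      stop(sprintf(
        "malformed row %d: moving gene %s absent from derived arrangement '%s'",
        i, rows$gene[i], rows$derived_arrangement[i]))
    cls[i] <- if (p == 1L || p == length(toks)) "adjacent" else "intergenic"
  }
  data.frame(genus = rows$genus, species = rows$species, unit = rows$gene,
             source = rows$mrca_arrangement,
             destination = rows$derived_arrangement,
             class = cls, inverted = NA, identity_swap = FALSE,
             stringsAsFactors = FALSE)
}

#' Read an arrangement-pair table
#'
#' @param path Tab-separated file with columns \code{gene},
#'   \code{mrca_arrangement}, \code{derived_arrangement}, \code{species},
#'   \code{genus}.
#' @return data.frame.
#' @export
readPairTable <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Group translocation events shared by congeneric species
#'
#' Events are merged into one group (counted as a single evolutionary
#' event) iff they share genus, moving unit and destination arrangement.
#' Species of different genera never merge, even when they share a
#' destination. The grouping is invariant to the input order of events.
#'
#' @param events data.frame as returned by \code{\link{detectEvents}} or
#'   \code{\link{detectEventsFromPairs}}.
#' @return data.frame with one row per group: \code{group_id},
#'   \code{genus}, \code{unit}, \code{destination}, \code{class},
#'   \code{n_species}, \code{species} (comma-collapsed).
#' @export
groupEvents <- function(events) {
  if (!nrow(events))
    return(data.frame(group_id = integer(), genus = character(),
                      unit = character(), destination = character(),
                      class = character(), n_species = integer(),
                      species = character()))
  key <- paste(events$genus, events$unit, events$destination, sep = "\r")
  o <- order(events$unit, events$genus, events$destination, events$species,
             method = "radix")
  events <- events[o, , drop = FALSE]
  key <- key[o]
  idx <- split(seq_len(nrow(events)), factor(key, levels = unique(key)))
  rows <- lapply(seq_along(idx), function(j) {
    e <- events[idx[[j]], , drop = FALSE]
    data.frame(group_id = j, genus = e$genus[1], unit = e$unit[1],
               destination = e$destination[1], class = e$class[1],
               n_species = length(unique(e$species)),
               species = paste(sort(unique(e$species)), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- site census ------------------------------------------------------

#' Insertion-site census for a moving unit
#'
#' Computes the number of NCR-adjacent and intergenic insertion slots
#' available to a moving tRNA unit in a karyotype, and the expected
#' probability that an unbiased translocation lands NCR-adjacent. The base
#' counts are \eqn{2M} adjacent and \eqn{G - M} intergenic slots
#' (\code{\link{enumerateSlots}}), unless \code{base_override} supplies
#' them directly (used when the ancestral gene count is fixed externally).
#'
#' Two census conventions are implemented:
#' \describe{
#'   \item{\code{"T4"} (alias \code{"T6"})}{If the unit currently flanks
#'     the NCR, one adjacent slot is converted to intergenic (the unit's
#'     departure closes its own boundary slot and opens an internal one).
#'     A unit of \eqn{k > 1} genes removes \eqn{k - 1} intergenic slots
#'     (it cannot be split). Class counts always sum to the total.}
#'   \item{\code{"T8"}}{Per-gene convention: the unit's own slot is
#'     removed from its class numerator; the denominator drops by one only
#'     for NCR-resident units. For units resident in an intergenic slot
#'     the two class probabilities deliberately do not sum to one --- the
#'     convention is reproduced as used, and flagged where reported.}
#' }
#'
#' @param x \code{\linkS4class{Karyotype}}: the karyotype in which the
#'   unit currently resides (the ancestor of the comparison).
#' @param unit Character vector of tRNA gene symbols occupying consecutive
#'   positions in \code{x}.
#' @param mode \code{"T4"}, \code{"T6"} or \code{"T8"}.
#' @param base_override Optional integer pair \code{c(adjacent,
#'   intergenic)} replacing the enumerated base counts.
#' @return A list with \code{mode}, \code{adjacent_slots},
#'   \code{intergenic_slots}, \code{total_slots} (the probability
#'   denominator), \code{expected_adjacent_prob} and
#'   \code{expected_intergenic_prob} (fractions in [0,1]).
#' @examples
#' anc <- readKaryotype(system.file("extdata", "mrca_polyplax_v1.kyt",
#'                                  package = "MitoKaryo"))
#' censusSites(anc, "A")$expected_adjacent_prob * 100   # 43.75
#' censusSites(anc, c("S1", "S2"))$total_slots          # 47
#' @export
censusSites <- function(x, unit, mode = c("T4", "T6", "T8"),
                        base_override = NULL) {
  mode <- match.arg(mode)
  stopifnot(methods::is(x, "Karyotype"))
  st <- .unitState(x, unit)
  if (is.na(st))
    stop("unit not found at consecutive positions: ",
         paste(unit, collapse = "-"))
  resident_adj <- isTRUE(.unitFlanksNCR(x, unit))
  if (is.null(base_override)) {
    sl <- enumerateSlots(x)
    adj <- sl$adjacent_count; int <- sl$intergenic_count
  } else {
    stopifnot(length(base_override) == 2L)
    adj <- base_override[1]; int <- base_override[2]
  }
  k <- length(unit)
  if (mode %in% c("T4", "T6")) {
    if (resident_adj) { adj <- adj - 1L; int <- int + 1L }
    int <- int - (k - 1L)
    tot <- adj + int
  } else {
    if (k > 1L) stop("T8 census is defined for single-gene units")
    tot <- adj + int
    if (resident_adj) { adj <- adj - 1L; tot <- tot - 1L }
    else int <- int - 1L
  }
  list(mode = mode, adjacent_slots = as.integer(adj),
       intergenic_slots = as.integer(int), total_slots = as.integer(tot),
       expected_adjacent_prob = adj / tot,
       expected_intergenic_prob = int / tot)
}

#' Expected vs observed NCR-adjacency per moving unit
#'
#' One row per moving unit: the expected probability (from
#' \code{\link{censusSites}} on the ancestral karyotype) that an unbiased
#' translocation lands NCR-adjacent, against the observed fraction of
#' events (or congenerically grouped events) that did. Identity-swap rows
#' in \code{events} are excluded. Pass raw per-species events to count
#' every species (the within-genus analysis) or the output of
#' \code{\link{groupEvents}} reshaped to one row per group (the
#' across-genera analysis).
#'
#' @param events data.frame with at least columns \code{unit} and
#'   \code{class} (one row per counted event).
#' @param ancestor \code{\linkS4class{Karyotype}} used for the census.
#' @param mode Census convention, see \code{\link{censusSites}}.
#' @param base_override Optional base slot counts, see
#'   \code{\link{censusSites}}.
#' @return data.frame with columns \code{unit}, \code{expected_adjacent},
#'   \code{observed_adjacent}, \code{expected_intergenic},
#'   \code{observed_intergenic} (percentages), \code{n_adjacent},
#'   \code{n_events}, \code{adjacent_slots}, \code{intergenic_slots},
#'   \code{total_slots}.
#' @export
adjacencyTable <- function(events, ancestor, mode = "T4",
                           base_override = NULL) {
  if ("identity_swap" %in% names(events))
    events <- events[!events$identity_swap, , drop = FALSE]
  units <- unique(events$unit)
  rows <- list()
  for (uid in units) {
    e <- events[events$unit == uid, , drop = FALSE]
    n <- nrow(e)
    if (n == 0L) { warning("unit with zero events excluded: ", uid); next }
    nadj <- sum(e$class == "adjacent")
    cs <- censusSites(ancestor, strsplit(uid, "-", fixed = TRUE)[[1]],
                      mode = mode, base_override = base_override)
    rows[[length(rows) + 1L]] <- data.frame(
      unit = uid,
      expected_adjacent = 100 * cs$expected_adjacent_prob,
      observed_adjacent = 100 * nadj / n,
      expected_intergenic = 100 * cs$expected_intergenic_prob,
      observed_intergenic = 100 * (n - nadj) / n,
      n_adjacent = nadj, n_events = n,
      adjacent_slots = cs$adjacent_slots,
      intergenic_slots = cs$intergenic_slots,
      total_slots = cs$total_slots,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$unit), , drop = FALSE]
}

## ---- pooled t test ----------------------------------------------------

#' Two-sample Student's t test with pooled variance
#'
#' Computes \eqn{t = (\bar{x} - \bar{y}) / \sqrt{s_p^2 (1/n_1 + 1/n_2)}}
#' with the pooled variance
#' \eqn{s_p^2 = ((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) / (n_1 + n_2 - 2)}
#' and a two-tailed p value from Student's t distribution with
#' \eqn{n_1 + n_2 - 2} degrees of freedom. When the pooled variance is
#' zero, \eqn{t} is defined as 0 for equal means (p = 1) and as signed
#' infinity otherwise (p = 0).
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return A list with \code{t}, \code{df}, \code{p}, \code{mean_x},
#'   \code{mean_y}, \code{sp2}.
#' @examples
#' pooledTTest(c(43.75, 43.75, 45.83, 45.83, 44.68), rep(100, 5))$t
#' @export
pooledTTest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both samples need n >= 2")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
  } else {
    t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_x = mean(x), mean_y = mean(y), sp2 = sp2)
}
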