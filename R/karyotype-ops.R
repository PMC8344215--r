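## ---- canonical strings and placement states ---------------------------

.miniString <- function(m) paste(m, collapse = "-")

.backboneOf <- function(m) m[geneCategory(.tokGene(m)) != "tRNA"]

.backboneKey <- function(m) {
  bk <- .backboneOf(m)
  if (length(bk)) paste(bk, collapse = "-") else ""
}

#' Backbone keys of a karyotype
#'
#' The backbone key of a minichromosome is the ordered, oriented sequence of
#' its protein-coding and rRNA genes with all tRNAs stripped: the stable
#' identity of a minichromosome type. tRNA-only minichromosomes have the
#' empty key \code{""}.
#'
#' @param x A \code{\linkS4class{Karyotype}}.
#' @return Character vector of backbone keys, one per minichromosome.
#' @examples
#' k <- Karyotype("Toy", list(c("A", "cox1", "B"), c("~nad1", "G")))
#' backboneKeys(k)
#' @export
setMethod("backboneKeys", "Karyotype", function(x) {
  vapply(x@minichromosomes, .backboneKey, character(1))
})

#' Project a karyotype onto its backbones
#'
#' Strips all tRNA genes, leaving each minichromosome's backbone (its
#' protein-coding and rRNA genes in order, orientations kept). tRNA-only
#' minichromosomes are retained as placeholders carrying the single token
#' of their first tRNA position replaced by nothing: they are kept as
#' zero-backbone entries and flagged via the \code{"tRNAonly"} attribute on
#' the result (an integer vector of their indices), so the minichromosome
#' count is preserved. Idempotent.
#'
#' @param x A \code{\linkS4class{Karyotype}}.
#' @return A list with elements \code{taxon}, \code{backbones} (list of
#'   token vectors, possibly empty for tRNA-only minichromosomes) and
#'   \code{tRNAonly} (indices of flagged placeholders).
#' @examples
#' k <- readKaryotype(system.file("extdata", "polyplax_reclinata.kyt",
#'                                package = "MitoKaryo"))
#' pb <- projectBackbone(k)
#' lengths(pb$backbones)
#' @export
setMethod("projectBackbone", "Karyotype", function(x) {
  bbs <- lapply(x@minichromosomes, .backboneOf)
  list(taxon = x@taxon,
       backbones = bbs,
       tRNAonly = which(lengths(bbs) == 0L))
})

## State of a tRNA unit: host backbone key, nearest stable (backbone or
## NCR) element on each side, and the unit's orientation pattern. Stable
## neighbours are recorded without orientation prefix. Co-resident tRNAs in
## the same backbone gap are deliberately ignored: a tRNA's placement only
## changes when it moves to a different backbone gap or flips orientation.
.unitState <- function(k, unit) {
  mins <- k@minichromosomes
  for (m in mins) {
    g <- .tokGene(m)
    pos <- match(unit, g)
    if (any(is.na(pos))) next
    inverted <- FALSE
    if (length(unit) > 1L) {
      if (all(diff(pos) == 1L)) inverted <- FALSE
      else if (all(diff(pos) == -1L)) inverted <- TRUE
      else return(NA_character_)  # unit genes split up: no joint state
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
    rev_ <- .tokRev(m[pos])
    return(sprintf("host=%s|up=%s|down=%s|rev=%s|inv=%d",
                   .backboneKey(m), up, down,
                   paste(as.integer(rev_), collapse = ""),
                   as.integer(inverted)))
  }
  NA_character_
}

## State of a backbone gene: its host backbone key, index therein, and
## orientation.
.backboneGeneState <- function(k, gene) {
  for (m in k@minichromosomes) {
    bk <- .backboneOf(m)
    i <- match(gene, .tokGene(bk))
    if (!is.na(i))
      return(sprintf("host=%s|idx=%d|rev=%d", .backboneKey(m), i,
                     as.integer(.tokRev(bk[i]))))
  }
  NA_character_
}

## Placement state of any gene (dispatches on category).
.geneState <- function(k, gene) {
  if (identical(geneCategory(gene), "tRNA")) .unitState(k, gene)
  else .backboneGeneState(k, gene)
}

## Is the unit (consecutive tRNA run) flanking the NCR in k? TRUE when its
## first gene opens or its last gene closes a minichromosome linearization.
.unitFlanksNCR <- function(k, unit) {
  for (m in k@minichromosomes) {
    g <- .tokGene(m)
    pos <- match(unit, g)
    if (any(is.na(pos))) next
    return(min(pos) == 1L || max(pos) == length(g))
  }
  NA
}

## ---- slot enumeration -------------------------------------------------

#' Enumerate insertion slots of a karyotype
#'
#' A minichromosome with \eqn{g} genes offers \eqn{g + 1} insertion slots
#' for a translocating gene: one at each NCR boundary (NCR-adjacent) and
#' \eqn{g - 1} between consecutive genes (intergenic). Over a karyotype
#' with \eqn{G} placed genes on \eqn{M} minichromosomes there are
#' \eqn{2M} NCR-adjacent slots, \eqn{G - M} intergenic slots and
#' \eqn{G + M} slots in total.
#'
#' @param x A \code{\linkS4class{Karyotype}}.
#' @return A list with \code{adjacent_count}, \code{intergenic_count},
#'   \code{total}, and \code{slots}: a data.frame with columns
#'   \code{minichromosome} (index), \code{position} (0 = before the first
#'   gene, g = after the last) and \code{slot_class}
#'   (\code{adjacent_5p}, \code{adjacent_3p} or \code{intergenic}).
#' @examples
#' k <- readKaryotype(system.file("extdata", "mrca_polyplax_v1.kyt",
#'                                package = "MitoKaryo"))
#' enumerateSlots(k)[c("adjacent_count", "intergenic_count", "total")]
#' @export
enumerateSlots <- function(x) {
  stopifnot(methods::is(x, "Karyotype"))
  rows <- lapply(seq_along(x@minichromosomes), function(i) {
    g <- length(x@minichromosomes[[i]])
    pos <- 0:g
    cls <- c("adjacent_5p", rep("intergenic", max(g - 1L, 0L)), "adjacent_3p")
    data.frame(minichromosome = i, position = pos, slot_class = cls,
               stringsAsFactors = FALSE)
  })
  slots <- do.call(rbind, rows)
  adj <- sum(slots$slot_class != "intergenic")
  int <- sum(slots$slot_class == "intergenic")
  list(adjacent_count = adj, intergenic_count = int,
       total = adj + int, slots = slots)
}

## ---- pairwise comparison ----------------------------------------------

#' Shared minichromosomes between two karyotypes
#'
#' Two minichromosomes match iff they are identical in gene content, order
#' and orientation up to the canonical NCR-anchored linearization (an
#' inverted gene is a non-match). Also reports the genes whose placement
#' differs between the karyotypes: a gene differs when its host backbone,
#' flanking stable elements (backbone genes or NCR) or orientation differ.
#' Genes absent from either karyotype are not scored.
#'
#' @param a,b \code{\linkS4class{Karyotype}} objects.
#' @return A list with \code{shared} (character vector of matched canonical
#'   minichromosome strings), \code{n_shared}, and \code{differing_genes}.
#' @examples
#' fx <- system.file("extdata", package = "MitoKaryo")
#' rec <- readKaryotype(file.path(fx, "polyplax_reclinata.kyt"))
#' spi <- readKaryotype(file.path(fx, "polyplax_spinulosa.kyt"))
#' sharedMinichromosomes(rec, spi)$n_shared  # 9
#' @export
sharedMinichromosomes <- function(a, b) {
  stopifnot(methods::is(a, "Karyotype"), methods::is(b, "Karyotype"))
  sa <- vapply(a@minichromosomes, .miniString, character(1))
  sb <- vapply(b@minichromosomes, .miniString, character(1))
  shared <- intersect(sa, sb)
  common <- intersect(.tokGene(unlist(a@minichromosomes)),
                      .tokGene(unlist(b@minichromosomes)))
  diff_g <- common[vapply(common, function(g) {
    !identical(.geneState(a, g), .geneState(b, g))
  }, logical(1))]
  list(shared = sort(shared), n_shared = length(shared),
       differing_genes = sort(diff_g))
}
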