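#' Karyotype: a fragmented mitochondrial genome
#'
#' A \code{Karyotype} represents a species' whole mitochondrial genome as a
#' set of circular minichromosomes. Each minichromosome is stored in its
#' canonical linearization: an ordered character vector of gene tokens,
#' written 5'-to-3' on the majority strand starting at the gene immediately
#' downstream of the non-coding region (NCR); the single NCR implicitly
#' closes the circle at both ends of the vector. A \code{"~"} prefix marks a
#' gene transcribed opposite to the majority strand.
#'
#' @slot taxon Species label.
#' @slot genus Genus label.
#' @slot minichromosomes List of character vectors of gene tokens.
#'
#' @details Validity requires: every token names one of the 37 canonical
#' mitochondrial genes; 1--8 genes per minichromosome; no gene appears twice
#' anywhere in the karyotype. A karyotype is \emph{complete} when the union
#' of its genes is exactly the 37-gene set (see \code{\link{isComplete}});
#' incomplete karyotypes (taxa with unidentified genes) are representable.
#'
#' @seealso \code{\link{parseKaryotype}}, \code{\link{readKaryotype}},
#'   \code{\link{projectBackbone}}, \code{\link{sharedMinichromosomes}}
#' @export
setClass("Karyotype",
         representation(taxon = "character",
                        genus = "character",
                        minichromosomes = "list"))

setValidity("Karyotype", function(object) {
  msgs <- character()
  if (length(object@taxon) != 1L) msgs <- c(msgs, "taxon must be length 1")
  if (length(object@genus) != 1L) msgs <- c(msgs, "genus must be length 1")
  mins <- object@minichromosomes
  if (length(mins) == 0L) msgs <- c(msgs, "karyotype has no minichromosomes")
  all_genes <- character()
  for (i in seq_along(mins)) {
    toks <- mins[[i]]
    if (!is.character(toks) || length(toks) < 1L)
      msgs <- c(msgs, sprintf("minichromosome %d is empty", i))
    if (length(toks) > 8L)
      msgs <- c(msgs, sprintf("minichromosome %d has %d genes (max 8)",
                              i, length(toks)))
    g <- .tokGene(toks)
    bad <- g[is.na(geneCategory(g))]
    if (length(bad))
      msgs <- c(msgs, sprintf("minichromosome %d: unknown gene token(s) %s",
                              i, paste(bad, collapse = ", ")))
    dup <- g[duplicated(g)]
    if (length(dup))
      msgs <- c(msgs, sprintf("minichromosome %d: duplicated gene(s) %s",
                              i, paste(unique(dup), collapse = ", ")))
    all_genes <- c(all_genes, g)
  }
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup))
    msgs <- c(msgs, sprintf("gene(s) on more than one minichromosome: %s",
                            paste(dup, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Karyotype
#'
#' @param taxon Species label.
#' @param minichromosomes List of character vectors of gene tokens (a
#'   \code{"~"} prefix marks reversed orientation), each in canonical
#'   NCR-anchored linearization.
#' @param genus Genus label; defaults to the first word of \code{taxon}.
#' @return A validated \code{\linkS4class{Karyotype}}.
#' @examples
#' k <- Karyotype("Toy species",
#'                list(c("A", "cox1", "B"), c("~nad1", "G")))
#' nGenes(k)
#' @export
Karyotype <- function(taxon, minichromosomes, genus = NULL) {
  if (is.null(genus)) genus <- strsplit(taxon, "[ _]")[[1]][1]
  obj <- new("Karyotype", taxon = taxon, genus = genus,
             minichromosomes = lapply(minichromosomes, as.character))
  validObject(obj)
  obj
}

#' Ancestral karyotype reconstruction
#'
#' Result of \code{\link{inferAncestor}}: one or more equally parsimonious
#' ancestral karyotype variants, the per-character minimal change counts,
#' and any tied alternative placements.
#'
#' @slot variants List of \code{\linkS4class{Karyotype}} objects (one per
#'   equally parsimonious resolution of all tied placements).
#' @slot changes data.frame with columns \code{character_id}, \code{unit},
#'   \code{state}, \code{changes}.
#' @slot alternatives data.frame with columns \code{unit}, \code{state},
#'   \code{changes}; non-empty only when two or more candidates tie.
#' @slot unplaced Character vector of genes for which no ancestral placement
#'   could be nominated.
#' @export
setClass("ReconstructionResult",
         representation(variants = "list",
                        changes = "data.frame",
                        alternatives = "data.frame",
                        unplaced = "character"))

setValidity("ReconstructionResult", function(object) {
  if (length(object@variants) < 1L) return("no ancestral variant")
  for (v in object@variants)
    if (!methods::is(v, "Karyotype")) return("variants must be Karyotype objects")
  TRUE
})
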