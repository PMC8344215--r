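#' @rdname Karyotype-accessors
#' @export
setGeneric("taxon", function(x) standardGeneric("taxon"))

#' @rdname Karyotype-accessors
#' @export
setGeneric("genus", function(x) standardGeneric("genus"))

#' @rdname Karyotype-accessors
#' @export
setGeneric("minichromosomes", function(x) standardGeneric("minichromosomes"))

#' @rdname Karyotype-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname Karyotype-accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname projectBackbone
#' @export
setGeneric("projectBackbone", function(x) standardGeneric("projectBackbone"))

#' @rdname backboneKeys
#' @export
setGeneric("backboneKeys", function(x) standardGeneric("backboneKeys"))

#' Accessors for Karyotype objects
#'
#' \code{taxon} and \code{genus} return the labels; \code{minichromosomes}
#' the list of canonical token vectors; \code{nGenes} the number of placed
#' genes; \code{isComplete} whether the union of genes is exactly the
#' canonical 37-gene set.
#'
#' @param x A \code{\linkS4class{Karyotype}}.
#' @return See description.
#' @name Karyotype-accessors
#' @examples
#' k <- readKaryotype(system.file("extdata", "polyplax_reclinata.kyt",
#'                                package = "MitoKaryo"))
#' taxon(k); nGenes(k); isComplete(k)
NULL

#' @rdname Karyotype-accessors
setMethod("taxon", "Karyotype", function(x) x@taxon)

#' @rdname Karyotype-accessors
setMethod("genus", "Karyotype", function(x) x@genus)

#' @rdname Karyotype-accessors
setMethod("minichromosomes", "Karyotype", function(x) x@minichromosomes)

#' @rdname Karyotype-accessors
setMethod("nGenes", "Karyotype",
          function(x) length(unlist(x@minichromosomes)))

#' @rdname Karyotype-accessors
setMethod("isComplete", "Karyotype", function(x) {
  setequal(.tokGene(unlist(x@minichromosomes)), mtGeneSet())
})

setMethod("show", "Karyotype", function(object) {
  cat(sprintf("Karyotype: %s (genus %s)\n", object@taxon, object@genus))
  cat(sprintf("  %d minichromosomes, %d genes%s\n",
              length(object@minichromosomes), nGenes(object),
              if (isComplete(object)) " (complete)" else " (incomplete)"))
  for (m in object@minichromosomes)
    cat("  ", paste(m, collapse = "-"), "\n", sep = "")
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult: %d variant(s), %d characters\n",
              length(object@variants), nrow(object@changes)))
  if (nrow(object@alternatives))
    cat(sprintf("  equally parsimonious placements for: %s\n",
                paste(unique(object@alternatives$unit), collapse = ", ")))
  if (length(object@unplaced))
    cat("  unplaced:", paste(object@unplaced, collapse = ", "), "\n")
  show(object@variants[[1]])
})

#' @rdname ReconstructionResult-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname ReconstructionResult-accessors
#' @export
setGeneric("alternatives", function(x) standardGeneric("alternatives"))

#' @rdname ReconstructionResult-accessors
#' @export
setGeneric("changeCounts", function(x) standardGeneric("changeCounts"))

#' Accessors for ReconstructionResult objects
#'
#' @param x A \code{\linkS4class{ReconstructionResult}}.
#' @return \code{variants}: list of \code{\linkS4class{Karyotype}};
#'   \code{alternatives} and \code{changeCounts}: data.frames.
#' @name ReconstructionResult-accessors
NULL

#' @rdname ReconstructionResult-accessors
setMethod("variants", "ReconstructionResult", function(x) x@variants)

#' @rdname ReconstructionResult-accessors
setMethod("alternatives", "ReconstructionResult", function(x) x@alternatives)

#' @rdname ReconstructionResult-accessors
setMethod("changeCounts", "ReconstructionResult", function(x) x@changes)
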