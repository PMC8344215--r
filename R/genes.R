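## The canonical 37-gene animal mitochondrial gene set.
## tRNA genes use single-letter abbreviations; the two leucine and two serine
## tRNAs are distinguished by anticodon (L1/tag, L2/taa, S1/tct, S2/tga).

.PCG <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
          "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
.RRNA <- c("rrnS", "rrnL")
.TRNA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
           "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")
.ANTICODON <- c(L1 = "tag", L2 = "taa", S1 = "tct", S2 = "tga")

#' The canonical animal mitochondrial gene set
#'
#' Returns the 37 admissible gene symbols: 13 protein-coding genes, 2 rRNA
#' genes and 22 tRNA genes (single letters, with L1/L2 and S1/S2
#' distinguished by anticodon).
#'
#' @param category Optional filter: one of \code{"PCG"}, \code{"rRNA"},
#'   \code{"tRNA"}.
#' @return Character vector of gene symbols.
#' @examples
#' length(mtGeneSet())          # 37
#' mtGeneSet("rRNA")
#' @export
mtGeneSet <- function(category = NULL) {
  if (is.null(category)) return(c(.PCG, .RRNA, .TRNA))
  switch(match.arg(category, c("PCG", "rRNA", "tRNA")),
         PCG = .PCG, rRNA = .RRNA, tRNA = .TRNA)
}

#' Category of a gene symbol
#'
#' @param gene Character vector of gene symbols (without orientation prefix).
#' @return Character vector with elements \code{"PCG"}, \code{"rRNA"} or
#'   \code{"tRNA"}; unknown symbols give \code{NA}.
#' @examples
#' geneCategory(c("cox1", "rrnS", "L2"))
#' @export
geneCategory <- function(gene) {
  out <- rep(NA_character_, length(gene))
  out[gene %in% .PCG] <- "PCG"
  out[gene %in% .RRNA] <- "rRNA"
  out[gene %in% .TRNA] <- "tRNA"
  out
}

#' Anticodon annotation for duplicated tRNA identities
#'
#' Only L1, L2, S1 and S2 carry an anticodon tag; all other symbols give
#' \code{NA}.
#'
#' @param gene Character vector of gene symbols.
#' @return Character vector of anticodon triplets or \code{NA}.
#' @examples
#' anticodonTag(c("L1", "S2", "M"))
#' @export
anticodonTag <- function(gene) {
  out <- rep(NA_character_, length(gene))
  hit <- gene %in% names(.ANTICODON)
  out[hit] <- unname(.ANTICODON[gene[hit]])
  out
}

## ---- oriented-token helpers (internal) --------------------------------

## A token is a gene symbol optionally prefixed with "~" (reversed
## orientation, i.e. transcribed opposite to the majority strand relative
## to the NCR; the paper's underline).
.tokGene <- function(tok) sub("^~", "", tok)
.tokRev <- function(tok) startsWith(tok, "~")
.mkTok <- function(gene, rev) ifelse(rev, paste0("~", gene), gene)
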