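#' Parse a karyotype document
#'
#' The plain-text karyotype format (conventionally \code{.kyt}, UTF-8) has
#' header lines \code{#taxon=<name>} and \code{#genus=<name>}, then one
#' minichromosome per line: gene tokens joined by \code{"-"}, with a
#' \code{"~"} prefix for genes transcribed opposite to the majority strand
#' (e.g. \code{~nad1-G-nad3-W}). Lines starting with \code{#} (other than
#' the headers) are comments. Each line is the canonical NCR-anchored
#' linearization of one circular minichromosome; the NCR is implicit at both
#' ends of every line.
#'
#' @param text Character vector: the document, either as one string with
#'   newlines or one element per line.
#' @return A validated \code{\linkS4class{Karyotype}}.
#' @examples
#' k <- parseKaryotype(c("#taxon=Toy sp", "A-cox1-B", "~nad1-G"))
#' nGenes(k)
#' @export
parseKaryotype <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  taxon <- NA_character_
  genus <- NA_character_
  mins <- list()
  lineno <- integer()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#taxon=")) { taxon <- sub("^#taxon=", "", ln); next }
    if (startsWith(ln, "#genus=")) { genus <- sub("^#genus=", "", ln); next }
    if (startsWith(ln, "#")) next
    toks <- strsplit(ln, "-", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    if (any(!nzchar(toks)))
      stop(sprintf("karyotype line %d: empty gene token in '%s'", i, ln))
    g <- .tokGene(toks)
    bad <- g[is.na(geneCategory(g))]
    if (length(bad))
      stop(sprintf("karyotype line %d: unknown gene token(s) %s", i,
                   paste(bad, collapse = ", ")))
    if (length(toks) > 8L)
      stop(sprintf("karyotype line %d: %d genes on one minichromosome (max 8)",
                   i, length(toks)))
    if (anyDuplicated(g))
      stop(sprintf("karyotype line %d: gene(s) %s repeated within a minichromosome",
                   i, paste(unique(g[duplicated(g)]), collapse = ", ")))
    mins[[length(mins) + 1L]] <- toks
    lineno[length(lineno) + 1L] <- i
  }
  if (length(mins) == 0L)
    stop("empty karyotype document: no minichromosome lines")
  ## cross-minichromosome duplicates, reported with the offending line
  seen <- character()
  for (j in seq_along(mins)) {
    g <- .tokGene(mins[[j]])
    dup <- intersect(g, seen)
    if (length(dup))
      stop(sprintf("karyotype line %d: gene(s) %s already placed on another minichromosome",
                   lineno[j], paste(dup, collapse = ", ")))
    seen <- c(seen, g)
  }
  if (is.na(taxon)) taxon <- "unknown"
  if (is.na(genus)) genus <- strsplit(taxon, "[ _]")[[1]][1]
  Karyotype(taxon, mins, genus = genus)
}

#' Read a karyotype file
#'
#' @param path Path to a \code{.kyt} file (see \code{\link{parseKaryotype}}
#'   for the format).
#' @return A validated \code{\linkS4class{Karyotype}}.
#' @examples
#' readKaryotype(system.file("extdata", "polyplax_asiatica.kyt",
#'                           package = "MitoKaryo"))
#' @export
readKaryotype <- function(path) {
  if (!file.exists(path)) stop("karyotype file not found: ", path)
  parseKaryotype(readLines(path, encoding = "UTF-8"))
}

#' Write a karyotype file
#'
#' Emits the canonical form: header lines, then one minichromosome per line
#' in canonical linearization, sorted by backbone key (tRNA-only
#' minichromosomes sort last by their full token string). Parsing the
#' output reconstructs an equal karyotype.
#'
#' @param x A \code{\linkS4class{Karyotype}}.
#' @param path Output file path, or \code{NULL} to return the lines.
#' @return Invisibly (or visibly when \code{path} is \code{NULL}) the
#'   character vector of lines written.
#' @export
writeKaryotype <- function(x, path = NULL) {
  stopifnot(methods::is(x, "Karyotype"))
  mins <- x@minichromosomes
  keys <- vapply(mins, function(m) {
    bk <- m[geneCategory(.tokGene(m)) != "tRNA"]
    if (length(bk)) paste(bk, collapse = "-") else
      paste0("zzz~", paste(m, collapse = "-"))
  }, character(1))
  mins <- mins[order(keys, method = "radix")]
  lines <- c(paste0("#taxon=", x@taxon),
             paste0("#genus=", x@genus),
             vapply(mins, paste, character(1), collapse = "-"))
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
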