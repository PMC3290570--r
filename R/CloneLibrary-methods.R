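#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CloneLibrary
#'
#' @param sequences A [Biostrings::DNAStringSet] (or character vector)
#'   named by clone id.  The alphabet is restricted to `A C G T N` plus
#'   `-` in aligned libraries.
#' @param specimen Character vector of specimen ids, one per clone.  If
#'   `NULL`, specimen ids are parsed from the clone ids with
#'   [parseSpecimenIDs()].
#' @param aligned Logical; is the library a gapped MSA?  Default `NA`
#'   auto-detects: a library containing any `-` is taken as aligned.
#' @param specimenDelim Delimiter passed to [parseSpecimenIDs()] when
#'   `specimen` is `NULL`.
#' @return A [CloneLibrary-class] object.
#' @examples
#' lib <- CloneLibrary(c(SP1_clone1 = "ACGT", SP1_clone2 = "ACGA"))
#' nClones(lib)
#' @export
CloneLibrary <- function(sequences, specimen = NULL, aligned = NA,
                         specimenDelim = "_clone") {
  if (is.character(sequences)) {
    .checkResidues(sequences, names(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (length(sequences) == 0L)
    stop("no clones")
  if (is.na(aligned))
    aligned <- any(grepl("-", as.character(sequences), fixed = TRUE))
  if (is.null(specimen))
    specimen <- parseSpecimenIDs(names(sequences), specimenDelim)
  new("CloneLibrary", sequences = sequences, specimen = specimen,
      aligned = aligned)
}

#' Parse specimen ids from clone ids
#'
#' Specimen membership is encoded in GenBank-style clone ids as the token
#' before a delimiter, e.g. `"SP07_clone3"` belongs to specimen `"SP07"`.
#'
#' @param ids Character vector of clone ids.
#' @param delim Delimiter separating the specimen token from the clone
#'   suffix (default `"_clone"`).
#' @return Character vector of specimen ids.
#' @examples
#' parseSpecimenIDs("SP07_clone3")
#' @export
parseSpecimenIDs <- function(ids, delim = "_clone") {
  vapply(strsplit(ids, delim, fixed = TRUE), `[[`, character(1), 1L)
}

.checkResidues <- function(seqs, ids) {
  bad <- regexpr("[^ACGTNacgtn-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid residue '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]),
                 if (is.null(ids)) as.character(i) else ids[i], bad[i]))
  }
  invisible(TRUE)
}

#' @describeIn CloneLibrary Number of clones.
#' @param x A `CloneLibrary`.
#' @export
setMethod("nClones", "CloneLibrary", function(x) length(x@sequences))

#' @describeIn CloneLibrary Clone ids.
#' @export
setMethod("cloneIDs", "CloneLibrary", function(x) names(x@sequences))

#' @describeIn CloneLibrary Specimen id of each clone.
#' @export
setMethod("specimenIDs", "CloneLibrary", function(x) x@specimen)

#' @describeIn CloneLibrary The underlying `DNAStringSet`.
#' @export
setMethod("cloneSeqs", "CloneLibrary", function(x) x@sequences)

#' @describeIn CloneLibrary Is the library a gapped MSA?
#' @export
setMethod("isAligned", "CloneLibrary", function(x) x@aligned)

#' @describeIn CloneLibrary Subset clones.
#' @param i Index vector.
#' @export
setMethod("[", "CloneLibrary", function(x, i) {
  new("CloneLibrary", sequences = x@sequences[i], specimen = x@specimen[i],
      aligned = x@aligned)
})

setMethod("show", "CloneLibrary", function(object) {
  cat(sprintf("CloneLibrary: %d clone(s) from %d specimen(s), %s\n",
              nClones(object), length(unique(object@specimen)),
              if (object@aligned)
                sprintf("aligned (%d columns)",
                        Biostrings::width(object@sequences)[1L])
              else "unaligned"))
})
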