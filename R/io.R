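#' @include AllClasses.R AllGenerics.R CloneLibrary-methods.R
NULL

#' Read a clone library from (possibly gapped) FASTA
#'
#' Accepts wrapped and unwrapped records; residues are uppercased and
#' validated against `A C G T N -`.  The specimen id of each clone is
#' the header token before `specimenDelim` (default `"_clone"`, so
#' `>SP07_clone3` belongs to specimen `SP07`); a two-column sidecar TSV
#' (`clone_id`, `specimen_id`) may override the parsed ids.
#'
#' @param path FASTA file path.
#' @param specimenDelim Delimiter for [parseSpecimenIDs()].
#' @param specimenTable Optional path to a sidecar TSV mapping clone ids
#'   to specimen ids.
#' @param aligned Logical or `NA` (auto-detect; see [CloneLibrary()]).
#' @return A [CloneLibrary-class].
#' @export
readCloneFasta <- function(path, specimenDelim = "_clone",
                           specimenTable = NULL, aligned = NA) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    stop("no clones")
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate clone ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  chr <- toupper(as.character(seqs))
  .checkResidues(chr, ids)
  names(chr) <- ids
  specimen <- NULL
  if (!is.null(specimenTable)) {
    st <- utils::read.delim(specimenTable, stringsAsFactors = FALSE)
    specimen <- st$specimen_id[match(ids, st$clone_id)]
    if (anyNA(specimen))
      stop("specimen table does not cover every clone")
  }
  CloneLibrary(chr, specimen = specimen, aligned = aligned,
               specimenDelim = specimenDelim)
}

#' Write a clone library to FASTA
#'
#' @param library A [CloneLibrary-class].
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
writeCloneFasta <- function(library, path, width = 70L) {
  Biostrings::writeXStringSet(cloneSeqs(library), path, width = width)
  invisible(path)
}

#' Read / write locus definitions as TSV
#'
#' Columns: `label`, `start`, `end` (1-based inclusive alignment
#' columns), `left_flank`, `right_flank`.
#'
#' @param path TSV file path.
#' @return `readLoci`: a [LocusSet-class].
#' @export
readLoci <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  LocusSet(starts = d$start, ends = d$end, labels = d$label,
           leftFlank = d$left_flank, rightFlank = d$right_flank)
}

#' @rdname readLoci
#' @param loci A [LocusSet-class].
#' @export
writeLoci <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ribotype table as TSV
#'
#' One row per theoretical combination (zero rows included), columns =
#' locus labels plus `abundance`, ordered by descending abundance.
#'
#' @param table A [RibotypeTable-class].
#' @param path Output TSV path.
#' @export
writeRibotypeTable <- function(table, path) {
  utils::write.table(abundances(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write allele catalogs as a single TSV
#'
#' Columns: `locus`, `label`, `sequence`, `count`.
#'
#' @param catalogs Named list of [AlleleCatalog-class].
#' @param path Output TSV path.
#' @export
writeAlleleCatalogs <- function(catalogs, path) {
  d <- do.call(rbind, lapply(catalogs, function(ct)
    cbind(locus = locusLabel(ct), alleleTable(ct))))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-clone ribotype assignments as TSV
#'
#' @param assignments A `data.frame` from [assignRibotypes()].
#' @param path Output TSV path.
#' @export
writeAssignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
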