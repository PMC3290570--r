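#' @include AllClasses.R AllGenerics.R core-model.R
NULL

# Hamming distance between equal-length strings.
.hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# ---- allele calling --------------------------------------------------------

#' Call discrete block alleles at one locus
#'
#' Identical blocks are grouped; a minority group (count below
#' `minAlleleCount`) whose sequence lies within Hamming distance
#' `snpTolerance` of a majority group of equal length is absorbed into
#' the nearest such group (ties: larger group, then lexicographically
#' smaller sequence) — singletons one substitution away from a common
#' allele are most parsimoniously PCR/sequencing error.  Length
#' differences are never absorbed: block variants of different length are
#' always distinct alleles.  Remaining groups become alleles labelled
#' `"a"`, `"b"`, ... in descending count (ties by lexicographic block
#' sequence).
#'
#' @param blocks Named character vector (clone id to block sequence) for
#'   one locus; `NA` entries (unanchored clones) are ignored.
#' @param snpTolerance Maximum Hamming distance absorbed (default 1).
#' @param minAlleleCount Minimum group size to stand as an allele without
#'   absorption (default 2).
#' @param locusLabel Label recorded in the catalog.
#' @return An [AlleleCatalog-class].
#' @export
callAlleles <- function(blocks, snpTolerance = 1L, minAlleleCount = 2L,
                        locusLabel = "locus") {
  obs <- blocks[!is.na(blocks)]
  if (length(obs) == 0L)
    stop(sprintf("locus uncallable: no block observed at '%s'", locusLabel))
  tab <- table(obs)
  seqs <- names(tab)
  counts <- as.integer(tab)
  major <- counts >= minAlleleCount
  finalCounts <- counts
  absorbed <- rep(FALSE, length(seqs))
  if (any(major) && any(!major)) {
    majIdx <- which(major)
    for (i in which(!major)) {
      cand <- majIdx[nchar(seqs[majIdx]) == nchar(seqs[i])]
      if (length(cand) == 0L) next
      d <- vapply(seqs[cand], .hamming, integer(1), b = seqs[i])
      cand <- cand[d <= snpTolerance]
      d <- d[d <= snpTolerance]
      if (length(cand) == 0L) next
      # nearest; ties -> larger (original) group, then lexicographic
      o <- order(d, -counts[cand], seqs[cand])
      tgt <- cand[o[1L]]
      finalCounts[tgt] <- finalCounts[tgt] + counts[i]
      absorbed[i] <- TRUE
    }
  }
  keep <- !absorbed
  AlleleCatalog(locusLabel, seqs[keep], finalCounts[keep])
}

#' Call allele catalogs for every locus of a block matrix
#'
#' @param blocks Character matrix from [extractBlocks()] or
#'   [anchorBlocks()] (rows = clones, columns = loci).
#' @inheritParams callAlleles
#' @return Named list of [AlleleCatalog-class], one per locus column.
#' @export
callAllelesAll <- function(blocks, snpTolerance = 1L, minAlleleCount = 2L) {
  loci <- colnames(blocks)
  stats::setNames(lapply(loci, function(lc)
    callAlleles(blocks[, lc], snpTolerance, minAlleleCount, locusLabel = lc)),
    loci)
}

# ---- ribotype assignment ---------------------------------------------------

#' Assign each clone a combinatorial ribotype
#'
#' Per clone and locus: an exact block match takes that allele's label;
#' otherwise the nearest equal-length allele within `snpTolerance`
#' (ties: larger count, then lexicographically smaller sequence);
#' otherwise the locus is left unassigned (`NA`).  A clone is `complete`
#' when every locus received a label.
#'
#' @param blocks Character matrix (rows = clones, columns = loci); `NA`
#'   marks an unanchored block.
#' @param catalogs Named list of [AlleleCatalog-class], one per locus
#'   column of `blocks`.
#' @param snpTolerance Maximum Hamming distance to an allele (default 1).
#' @param specimen Optional character vector of specimen ids per clone;
#'   parsed from row names by default.
#' @param specimenDelim Delimiter for [parseSpecimenIDs()].
#' @return A `data.frame`: `clone_id`, `specimen_id`, one label column
#'   per locus, `complete`.
#' @export
assignRibotypes <- function(blocks, catalogs, snpTolerance = 1L,
                            specimen = NULL, specimenDelim = "_clone") {
  loci <- colnames(blocks)
  stopifnot(!is.null(loci), all(loci %in% names(catalogs)))
  ids <- rownames(blocks)
  if (is.null(specimen))
    specimen <- parseSpecimenIDs(ids, specimenDelim)
  out <- data.frame(clone_id = ids, specimen_id = specimen,
                    stringsAsFactors = FALSE)
  for (lc in loci) {
    al <- alleleTable(catalogs[[lc]])
    out[[lc]] <- vapply(blocks[, lc], .matchAllele, character(1),
                        al = al, tol = snpTolerance, USE.NAMES = FALSE)
  }
  out$complete <- !Reduce(`|`, lapply(out[loci], is.na))
  rownames(out) <- NULL
  out
}

.matchAllele <- function(block, al, tol) {
  if (is.na(block))
    return(NA_character_)
  hit <- match(block, al$sequence)
  if (!is.na(hit))
    return(al$label[hit])
  cand <- which(nchar(al$sequence) == nchar(block))
  if (length(cand) == 0L)
    return(NA_character_)
  d <- vapply(al$sequence[cand], .hamming, integer(1), b = block)
  ok <- d <= tol
  if (!any(ok))
    return(NA_character_)
  cand <- cand[ok]; d <- d[ok]
  o <- order(d, -al$count[cand], al$sequence[cand])
  al$label[cand[o[1L]]]
}
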