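#' @import methods
NULL

.CLONE_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' CloneLibrary: a set of sequenced clones with specimen membership
#'
#' The atomic input of the ESP pipeline: one DNA sequence per sequenced
#' clone, each clone belonging to a specimen (individual organism).  A
#' library is either unaligned (plain clone sequences) or aligned (all
#' sequences padded to equal length with `-`).
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by clone id.
#' @slot specimen Character vector, parallel to `sequences`: specimen id
#'   of each clone.
#' @slot aligned Logical scalar; `TRUE` when the library is a gapped MSA.
#'
#' @seealso [CloneLibrary()], [readCloneFasta()]
#' @exportClass CloneLibrary
setClass("CloneLibrary",
  representation(
    sequences = "DNAStringSet",
    specimen = "character",
    aligned = "logical"
  )
)

setValidity("CloneLibrary", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n == 0L)
    msg <- c(msg, "no clones")
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "every clone must have a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate clone ids: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@specimen) != n)
    msg <- c(msg, "specimen vector must be parallel to sequences")
  if (length(object@aligned) != 1L || is.na(object@aligned))
    msg <- c(msg, "aligned must be TRUE or FALSE")
  if (n > 0L && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "empty sequence(s)")
  if (isTRUE(object@aligned) && n > 0L &&
      length(unique(Biostrings::width(object@sequences))) != 1L)
    msg <- c(msg, "aligned library must have equal-length sequences")
  if (length(msg)) msg else TRUE
})

#' LocusSet: variable block loci with conserved flanking anchors
#'
#' Each locus is an alignment-column interval (1-based, closed, the
#' IRanges convention) holding a hypervariable sequence block, together
#' with the conserved ungapped flank sequences immediately left and right
#' of the block, used for alignment-free anchoring.
#'
#' @slot ranges An [IRanges::IRanges] of alignment spans, named by locus
#'   label (e.g. `"37/f"`).
#' @slot leftFlank,rightFlank Character vectors of ungapped flank
#'   sequences, parallel to `ranges`.
#' @slot allowedLengths A list, parallel to `ranges`; each element an
#'   integer vector of permitted block lengths (bp), or `integer(0)` for
#'   unconstrained.
#'
#' @seealso [LocusSet()], [detectVariableLoci()], [readLoci()]
#' @exportClass LocusSet
setClass("LocusSet",
  representation(
    ranges = "IRanges",
    leftFlank = "character",
    rightFlank = "character",
    allowedLengths = "list"
  )
)

setValidity("LocusSet", function(object) {
  msg <- character()
  n <- length(object@ranges)
  if (length(object@leftFlank) != n || length(object@rightFlank) != n ||
      length(object@allowedLengths) != n)
    msg <- c(msg, "flank and length slots must be parallel to ranges")
  if (n > 0L) {
    if (is.null(names(object@ranges)) || anyDuplicated(names(object@ranges)))
      msg <- c(msg, "loci must carry unique labels")
    if (any(IRanges::width(object@ranges) < 1L))
      msg <- c(msg, "locus spans must be non-empty")
    if (any(nchar(object@leftFlank) == 0L) || any(nchar(object@rightFlank) == 0L))
      msg <- c(msg, "flanks must be non-empty")
    if (n > 1L) {
      s <- IRanges::start(object@ranges)
      e <- IRanges::end(object@ranges)
      if (is.unsorted(s, strictly = TRUE))
        msg <- c(msg, "loci must be sorted by span start")
      else if (any(s[-1L] <= e[-n]))
        msg <- c(msg, "loci must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AlleleCatalog: discrete block alleles called at one locus
#'
#' The set of distinct "homogenous" block sequences observed at one
#' variable locus, labelled `"a"`, `"b"`, ... in descending abundance
#' (ties broken by lexicographic block sequence), with the number of
#' clones carrying each.
#'
#' @slot locusLabel Character scalar: the locus this catalog belongs to.
#' @slot alleles A `data.frame` with columns `label`, `sequence`, `count`.
#'
#' @seealso [callAlleles()]
#' @exportClass AlleleCatalog
setClass("AlleleCatalog",
  representation(
    locusLabel = "character",
    alleles = "data.frame"
  )
)

setValidity("AlleleCatalog", function(object) {
  msg <- character()
  al <- object@alleles
  if (!all(c("label", "sequence", "count") %in% names(al)))
    msg <- c(msg, "alleles must have columns label, sequence, count")
  else {
    if (nrow(al) < 1L)
      msg <- c(msg, "catalog must contain at least one allele")
    if (anyDuplicated(al$sequence))
      msg <- c(msg, "allele block sequences must be unique within a locus")
    if (!identical(al$label, letters[seq_len(nrow(al))]))
      msg <- c(msg, "labels must be consecutive letters starting at 'a'")
    if (any(al$count < 0L))
      msg <- c(msg, "allele counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' RibotypeTable: observed abundance over the ribotype combination space
#'
#' Maps every combination of per-locus allele labels (one allele per
#' locus) to its observed abundance among completely assigned clones,
#' including unobserved combinations at abundance 0.  Rows are ordered by
#' descending abundance, ties broken by lexicographic label tuple.
#'
#' @slot lociLabels Character vector of locus labels, in locus order.
#' @slot table A `data.frame` with one column per locus plus `abundance`.
#' @slot spaceSize Integer: the theoretical number of combinations
#'   (product of per-locus allele counts).
#' @slot incompleteClones Character vector of clone ids excluded because
#'   at least one locus was unassigned.
#'
#' @seealso [tabulateRibotypes()], [enumerateRibotypeSpace()]
#' @exportClass RibotypeTable
setClass("RibotypeTable",
  representation(
    lociLabels = "character",
    table = "data.frame",
    spaceSize = "integer",
    incompleteClones = "character"
  )
)

setValidity("RibotypeTable", function(object) {
  msg <- character()
  tb <- object@table
  if (!all(c(object@lociLabels, "abundance") %in% names(tb)))
    msg <- c(msg, "table must have one column per locus plus 'abundance'")
  else {
    if (nrow(tb) != object@spaceSize)
      msg <- c(msg, "table must enumerate the full combination space")
    if (any(tb$abundance < 0L))
      msg <- c(msg, "abundances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic clone-library generator
#'
#' Describes a clone library drawn from a small number of parental
#' ribotype clusters embedded in a conserved backbone, with uniform SNP
#' noise and PCR template-switch chimeras.
#'
#' @slot seed Integer RNG seed; the generator is bit-reproducible.
#' @slot nSpecimens Integer number of specimens (individuals).
#' @slot cloneRange Integer vector `c(lo, hi)`: clones per specimen drawn
#'   uniformly on `lo:hi`.
#' @slot backboneLength Integer length (bp) of the conserved backbone into
#'   which blocks are inserted.
#' @slot locusSpecs A list, one element per locus: `list(position =
#'   <insertion point in backbone>, alleles = <character vector of block
#'   sequences>)`.  Allele letters `"a"`, `"b"`, ... refer to positions in
#'   `alleles`.
#' @slot ribotypeWeights Named numeric summing to 1; names are allele
#'   tuples such as `"a|b|a"`.
#' @slot snpRate Per-site substitution probability.
#' @slot chimeraRate Per-clone probability of a PCR template switch.
#'
#' @seealso [espSimulationConfig()], [generateLibrary()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nSpecimens = "integer",
    cloneRange = "integer",
    backboneLength = "integer",
    locusSpecs = "list",
    ribotypeWeights = "numeric",
    snpRate = "numeric",
    chimeraRate = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSpecimens < 1L) msg <- c(msg, "nSpecimens must be >= 1")
  if (length(object@cloneRange) != 2L || object@cloneRange[1L] < 1L ||
      object@cloneRange[2L] < object@cloneRange[1L])
    msg <- c(msg, "cloneRange must be c(lo, hi) with 1 <= lo <= hi")
  if (object@backboneLength < 1L) msg <- c(msg, "backboneLength must be >= 1")
  if (length(object@locusSpecs) < 1L) msg <- c(msg, "at least one locus required")
  pos <- vapply(object@locusSpecs, function(s) as.integer(s$position), integer(1))
  if (is.unsorted(pos, strictly = TRUE) || pos[1L] < 1L ||
      pos[length(pos)] > object@backboneLength)
    msg <- c(msg, "locus positions must be strictly increasing within the backbone")
  for (s in object@locusSpecs) {
    if (anyDuplicated(s$alleles))
      msg <- c(msg, "allele sequences at a locus must be pairwise distinct")
  }
  w <- object@ribotypeWeights
  if (length(w) == 0L || abs(sum(w) - 1) > 1e-8 || any(w < 0))
    msg <- c(msg, "ribotypeWeights must be non-negative and sum to 1")
  if (is.null(names(w)) || anyDuplicated(names(w)))
    msg <- c(msg, "ribotypeWeights must have unique tuple names")
  else {
    nall <- vapply(object@locusSpecs, function(s) length(s$alleles), integer(1))
    for (key in names(w)) {
      lab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      if (length(lab) != length(nall) ||
          any(is.na(match(lab, letters)) | match(lab, letters) > nall)) {
        msg <- c(msg, sprintf("weight key '%s' references undefined alleles", key))
        break
      }
    }
  }
  if (object@snpRate < 0 || object@snpRate > 1)
    msg <- c(msg, "snpRate must be in [0,1]")
  if (object@chimeraRate < 0 || object@chimeraRate > 1)
    msg <- c(msg, "chimeraRate must be in [0,1]")
  if (length(msg)) msg else TRUE
})
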