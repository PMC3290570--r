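#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a LocusSet
#'
#' @param starts,ends Integer vectors of alignment spans (1-based,
#'   closed).
#' @param labels Character vector of locus labels.
#' @param leftFlank,rightFlank Character vectors of ungapped conserved
#'   flank sequences.
#' @param allowedLengths Optional list of integer vectors of permitted
#'   block lengths per locus; default unconstrained.
#' @return A [LocusSet-class] object.
#' @examples
#' LocusSet(10, 15, labels = "37/f", leftFlank = "ACGTACGTAC",
#'          rightFlank = "GTACGTACGT")
#' @export
LocusSet <- function(starts, ends, labels = paste0("L", seq_along(starts)),
                     leftFlank, rightFlank, allowedLengths = NULL) {
  if (is.null(allowedLengths))
    allowedLengths <- rep(list(integer(0)), length(starts))
  r <- IRanges::IRanges(start = as.integer(starts), end = as.integer(ends))
  names(r) <- labels
  new("LocusSet", ranges = r, leftFlank = toupper(leftFlank),
      rightFlank = toupper(rightFlank), allowedLengths = allowedLengths)
}

#' @describeIn LocusSet Number of loci.
#' @param x A `LocusSet`.
#' @export
setMethod("length", "LocusSet", function(x) length(x@ranges))

#' @describeIn LocusSet Locus labels.
#' @export
setMethod("lociLabels", "LocusSet", function(x) names(x@ranges))

#' @describeIn LocusSet Alignment spans as an `IRanges`.
#' @export
setMethod("lociRanges", "LocusSet", function(x) x@ranges)

#' @describeIn LocusSet Left flank sequences.
#' @export
setMethod("leftFlanks", "LocusSet", function(x) x@leftFlank)

#' @describeIn LocusSet Right flank sequences.
#' @export
setMethod("rightFlanks", "LocusSet", function(x) x@rightFlank)

#' @describeIn LocusSet Permitted block lengths per locus.
#' @export
setMethod("allowedLengths", "LocusSet", function(x) x@allowedLengths)

#' @describeIn LocusSet Subset loci.
#' @param i Index vector.
#' @export
setMethod("[", "LocusSet", function(x, i) {
  new("LocusSet", ranges = x@ranges[i], leftFlank = x@leftFlank[i],
      rightFlank = x@rightFlank[i], allowedLengths = x@allowedLengths[i])
})

setMethod("show", "LocusSet", function(object) {
  n <- length(object)
  cat(sprintf("LocusSet: %d variable block locus/loci\n", n))
  if (n > 0L)
    print(as.data.frame(object))
})

#' Coerce a LocusSet to a data.frame
#'
#' Columns `label`, `start`, `end` (1-based inclusive alignment columns),
#' `left_flank`, `right_flank` — the on-disk TSV layout of [writeLoci()].
#'
#' @param x A `LocusSet`.
#' @param ... Ignored.
#' @method as.data.frame LocusSet
#' @export
as.data.frame.LocusSet <- function(x, ...) {
  data.frame(
    label = lociLabels(x),
    start = IRanges::start(x@ranges),
    end = IRanges::end(x@ranges),
    left_flank = x@leftFlank,
    right_flank = x@rightFlank,
    stringsAsFactors = FALSE
  )
}
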