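#' @include AllClasses.R AllGenerics.R
NULL

# ---- AlleleCatalog ---------------------------------------------------------

#' Construct an AlleleCatalog from block sequences and counts
#'
#' Orders the alleles by descending count (ties broken by lexicographic
#' block sequence) and assigns labels `"a"`, `"b"`, ...  Usually produced
#' by [callAlleles()]; this raw constructor is handy for declaring known
#' catalogs.
#'
#' @param locusLabel Character scalar.
#' @param sequences Character vector of distinct block sequences.
#' @param counts Integer vector of clone counts, parallel to `sequences`.
#' @return An [AlleleCatalog-class].
#' @examples
#' AlleleCatalog("37/f", c("ACGTAC", "ACGTACGT"), c(5, 3))
#' @export
AlleleCatalog <- function(locusLabel, sequences, counts) {
  sequences <- toupper(sequences)
  o <- order(-as.integer(counts), sequences)
  al <- data.frame(label = letters[seq_along(sequences)],
                   sequence = sequences[o],
                   count = as.integer(counts)[o],
                   stringsAsFactors = FALSE)
  new("AlleleCatalog", locusLabel = as.character(locusLabel), alleles = al)
}

#' @describeIn AlleleCatalog Number of alleles.
#' @param x An `AlleleCatalog`.
#' @export
setMethod("nAlleles", "AlleleCatalog", function(x) nrow(x@alleles))

#' @describeIn AlleleCatalog The label/sequence/count table.
#' @export
setMethod("alleleTable", "AlleleCatalog", function(x) x@alleles)

#' @describeIn AlleleCatalog Label of the locus the catalog belongs to.
#' @export
setMethod("locusLabel", "AlleleCatalog", function(x) x@locusLabel)

setMethod("show", "AlleleCatalog", function(object) {
  cat(sprintf("AlleleCatalog for locus '%s': %d allele(s)\n",
              object@locusLabel, nAlleles(object)))
  print(object@alleles)
})

#' Relabel a catalog with user-supplied allele labels
#'
#' Calling labels alleles by abundance; published labels (e.g. the a/b/c
#' of a figure) may differ.  `map` gives, for each current label, the
#' replacement label; rows are re-sorted so labels stay consecutive
#' letters.
#'
#' @param catalog An [AlleleCatalog-class].
#' @param map Named character vector, e.g. `c(a = "b", b = "a")`.
#' @return A relabelled `AlleleCatalog`.
#' @export
relabelAlleles <- function(catalog, map) {
  al <- alleleTable(catalog)
  if (!setequal(names(map), al$label) || !setequal(map, al$label))
    stop("map must be a bijection over the catalog's labels")
  al$label <- unname(map[al$label])
  al <- al[order(al$label), , drop = FALSE]
  rownames(al) <- NULL
  new("AlleleCatalog", locusLabel = catalog@locusLabel, alleles = al)
}

# ---- combination space -----------------------------------------------------

#' Size of the theoretical ribotype combination space
#'
#' With one allele chosen per locus, the number of possible ribotypes is
#' the product of the per-locus allele counts: 3, 2 and 2 alleles at
#' three loci give a 12-ribotype space.
#'
#' @param catalogs A list of [AlleleCatalog-class] objects, or an integer
#'   vector of per-locus allele counts.
#' @return Integer: the combination-space size.
#' @examples
#' enumerateRibotypeSpace(c(3, 2, 2))
#' @export
enumerateRibotypeSpace <- function(catalogs) {
  counts <- .alleleCounts(catalogs)
  if (length(counts) == 0L)
    stop("no loci")
  if (any(counts < 1L))
    stop("every catalog must contain at least one allele")
  as.integer(prod(counts))
}

.alleleCounts <- function(catalogs) {
  if (is.numeric(catalogs))
    return(as.integer(catalogs))
  vapply(catalogs, nAlleles, integer(1))
}

# ---- ribotype tabulation ---------------------------------------------------

.tupleKey <- function(...) do.call(paste, c(list(...), sep = "|"))

#' Tabulate observed ribotypes over the full combination space
#'
#' Counts, among completely assigned clones, how often each combination
#' of per-locus allele labels occurs.  Every theoretical combination is
#' reported, unobserved ones at abundance 0; rows are ordered by
#' descending abundance with lexicographic tuple tie-break.  Clones with
#' any unassigned locus are excluded from the abundances and reported via
#' [incompleteClones()].
#'
#' @param assignments A `data.frame` as produced by [assignRibotypes()]:
#'   columns `clone_id`, `specimen_id`, one allele-label column per locus
#'   (`NA` = unassigned) and `complete`.
#' @param catalogs Named list of [AlleleCatalog-class], one per locus, in
#'   locus order.
#' @return A [RibotypeTable-class].
#' @export
tabulateRibotypes <- function(assignments, catalogs) {
  loci <- names(catalogs)
  if (is.null(loci) || !all(loci %in% names(assignments)))
    stop("assignments must have one column per locus in 'catalogs'")
  labels <- lapply(catalogs, function(ct) alleleTable(ct)$label)
  for (lc in loci) {
    v <- assignments[[lc]]
    bad <- !is.na(v) & !(v %in% labels[[lc]])
    if (any(bad))
      stop(sprintf("clone '%s' carries unknown allele label '%s' at locus '%s'",
                   assignments$clone_id[which(bad)[1L]],
                   v[which(bad)[1L]], lc))
  }
  complete <- !Reduce(`|`, lapply(assignments[loci], is.na))
  grid <- expand.grid(rev(labels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(loci)), drop = FALSE]
  names(grid) <- loci
  key <- do.call(.tupleKey, grid)
  obs <- do.call(.tupleKey, assignments[complete, loci, drop = FALSE])
  grid$abundance <- as.integer(table(factor(obs, levels = key)))
  o <- do.call(order, c(list(-grid$abundance), grid[loci]))
  grid <- grid[o, , drop = FALSE]
  rownames(grid) <- NULL
  new("RibotypeTable", lociLabels = loci, table = grid,
      spaceSize = as.integer(prod(lengths(labels))),
      incompleteClones = as.character(assignments$clone_id[!complete]))
}

#' @describeIn RibotypeTable Theoretical combination-space size.
#' @param x A `RibotypeTable`.
#' @export
setMethod("spaceSize", "RibotypeTable", function(x) x@spaceSize)

#' @describeIn RibotypeTable The abundance table (all combinations,
#'   descending abundance).
#' @export
setMethod("abundances", "RibotypeTable", function(x) x@table)

#' @describeIn RibotypeTable Locus labels.
#' @export
setMethod("lociLabels", "RibotypeTable", function(x) x@lociLabels)

#' @describeIn RibotypeTable Clone ids excluded for incomplete
#'   assignment.
#' @export
setMethod("incompleteClones", "RibotypeTable", function(x) x@incompleteClones)

setMethod("show", "RibotypeTable", function(object) {
  tb <- object@table
  cat(sprintf(
    "RibotypeTable: %d of %d possible ribotype(s) observed (%d clone(s)%s)\n",
    sum(tb$abundance > 0L), object@spaceSize, sum(tb$abundance),
    if (length(object@incompleteClones))
      sprintf(", %d incomplete excluded", length(object@incompleteClones))
    else ""))
  print(utils::head(tb, 12L))
  if (nrow(tb) > 12L) cat(sprintf("... %d more row(s)\n", nrow(tb) - 12L))
})

#' Observed ribotypes of a table as tuple keys
#'
#' @param table A [RibotypeTable-class].
#' @return Named integer vector of abundances over observed ribotypes
#'   (abundance > 0), names are `"a|b|a"`-style tuple keys.
#' @export
observedRibotypes <- function(table) {
  tb <- abundances(table)
  keep <- tb$abundance > 0L
  stats::setNames(tb$abundance[keep],
                  do.call(.tupleKey, tb[keep, lociLabels(table), drop = FALSE]))
}

# ---- specimen summaries ----------------------------------------------------

#' Per-specimen clone and ribotype counts
#'
#' One row per specimen: the number of clones sequenced and the number of
#' distinct complete ribotypes observed among them.  Specimens with no
#' completely assigned clone are excluded with a message.
#'
#' @param assignments A `data.frame` from [assignRibotypes()].
#' @param loci Character vector of locus column names; defaults to every
#'   column that is not `clone_id`, `specimen_id` or `complete`.
#' @return A `data.frame` with columns `specimen_id`, `n_clones`,
#'   `n_ribotypes`.
#' @export
summarizeSpecimens <- function(assignments, loci = NULL) {
  if (is.null(loci))
    loci <- setdiff(names(assignments), c("clone_id", "specimen_id", "complete"))
  complete <- !Reduce(`|`, lapply(assignments[loci], is.na))
  key <- do.call(.tupleKey, assignments[loci])
  sp <- unique(assignments$specimen_id)
  out <- lapply(sp, function(s) {
    rows <- assignments$specimen_id == s
    ok <- rows & complete
    if (!any(ok)) {
      message(sprintf("specimen '%s' has no complete assignment; excluded", s))
      return(NULL)
    }
    data.frame(specimen_id = s, n_clones = sum(rows),
               n_ribotypes = length(unique(key[ok])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    stop("no specimen has a complete assignment")
  rownames(out) <- NULL
  out
}
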