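#' @include AllClasses.R AllGenerics.R core-model.R
NULL

# ---- chimera flagging ------------------------------------------------------

#' Flag ribotypes explainable as PCR chimeras of two abundant parents
#'
#' A PCR template switch between two abundant ribotypes creates a mosaic
#' amplicon: its alleles left of an inter-locus breakpoint come from one
#' parent, those right of it from the other.  For every observed
#' ribotype, every (parent1, parent2, breakpoint) explanation with both
#' parents observed at abundance at least `minParentRatio` times the
#' ribotype's own abundance is emitted; ribotypes with no such
#' explanation are not flagged.  Breakpoints are reported 1-based: `b`
#' means between locus `b` and locus `b + 1`.
#'
#' @param table A [RibotypeTable-class].
#' @param minParentRatio Minimum parent-to-ribotype abundance ratio
#'   (default 3); PCR chimeras are expected to be minority products.
#' @return A `data.frame`, one row per explanation, sorted by combined
#'   parent abundance: `ribotype`, `parent1`, `parent2`, `breakpoint`,
#'   `abundance`, `parent1_abundance`, `parent2_abundance`,
#'   `abundance_ratio` (min parent abundance over ribotype abundance).
#'   Zero rows when nothing qualifies.
#' @export
flagPutativeChimeras <- function(table, minParentRatio = 3) {
  stopifnot(is(table, "RibotypeTable"), minParentRatio >= 1)
  loci <- lociLabels(table)
  L <- length(loci)
  obs <- observedRibotypes(table)
  empty <- data.frame(ribotype = character(0), parent1 = character(0),
                      parent2 = character(0), breakpoint = integer(0),
                      abundance = integer(0), parent1_abundance = integer(0),
                      parent2_abundance = integer(0),
                      abundance_ratio = numeric(0), stringsAsFactors = FALSE)
  if (L < 2L || length(obs) < 3L)
    return(empty)
  tuples <- strsplit(names(obs), "|", fixed = TRUE)
  rows <- list()
  for (r in seq_along(obs)) {
    abR <- obs[[r]]
    for (p1 in seq_along(obs)) {
      if (p1 == r || obs[[p1]] < minParentRatio * abR) next
      for (p2 in seq_along(obs)) {
        if (p2 == r || obs[[p2]] < minParentRatio * abR) next
        for (bp in seq_len(L - 1L)) {
          splice <- c(tuples[[p1]][seq_len(bp)], tuples[[p2]][(bp + 1L):L])
          if (identical(splice, tuples[[r]]))
            rows[[length(rows) + 1L]] <- data.frame(
              ribotype = names(obs)[r], parent1 = names(obs)[p1],
              parent2 = names(obs)[p2], breakpoint = bp,
              abundance = abR, parent1_abundance = obs[[p1]],
              parent2_abundance = obs[[p2]],
              abundance_ratio = min(obs[[p1]], obs[[p2]]) / abR,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-(out$parent1_abundance + out$parent2_abundance),
                   out$ribotype, out$breakpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- locus-pair compatibility ----------------------------------------------

#' Tree-compatibility of the allele combinations at a pair of loci
#'
#' On a single genealogy without recurrent change, the distinct
#' (allele_i, allele_j) pairs at two loci number at most
#' `a_i + a_j - 1` (the multi-allelic generalisation of the four-gamete
#' bound; for two biallelic loci this is 3, so observing all four
#' combinations signals recombination).  `recombination_signal` is a
#' heuristic indicator, not a proof: recurrent mutation can mimic it.
#'
#' @param assignments A `data.frame` from [assignRibotypes()]; only
#'   complete clones are used.
#' @param locusI,locusJ Locus column names (or indices into the locus
#'   columns).
#' @return A list: `k_observed`, `k_max_treelike`,
#'   `recombination_signal`, and a `note` when a locus is monomorphic.
#' @export
pairwiseCompatibility <- function(assignments, locusI, locusJ) {
  loci <- setdiff(names(assignments), c("clone_id", "specimen_id", "complete"))
  if (is.numeric(locusI)) locusI <- loci[locusI]
  if (is.numeric(locusJ)) locusJ <- loci[locusJ]
  stopifnot(locusI %in% loci, locusJ %in% loci)
  complete <- !Reduce(`|`, lapply(assignments[loci], is.na))
  ai <- assignments[[locusI]][complete]
  aj <- assignments[[locusJ]][complete]
  if (length(ai) == 0L)
    stop("no complete assignment")
  nI <- length(unique(ai))
  nJ <- length(unique(aj))
  kObs <- nrow(unique(data.frame(ai, aj)))
  kMax <- nI + nJ - 1L
  out <- list(k_observed = kObs, k_max_treelike = kMax,
              recombination_signal = kObs > kMax)
  if (nI == 1L || nJ == 1L)
    out$note <- "monomorphic locus: no signal possible"
  out
}

#' Compatibility over every locus pair
#'
#' @param assignments A `data.frame` from [assignRibotypes()].
#' @return A `data.frame` with one row per unordered locus pair:
#'   `locus_i`, `locus_j`, `k_observed`, `k_max_treelike`,
#'   `recombination_signal`.
#' @export
compatibilityMatrix <- function(assignments) {
  loci <- setdiff(names(assignments), c("clone_id", "specimen_id", "complete"))
  pairs <- utils::combn(loci, 2L)
  out <- apply(pairs, 2L, function(p) {
    r <- pairwiseCompatibility(assignments, p[1L], p[2L])
    data.frame(locus_i = p[1L], locus_j = p[2L],
               k_observed = r$k_observed, k_max_treelike = r$k_max_treelike,
               recombination_signal = r$recombination_signal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- minimum parental haplotypes -------------------------------------------

#' Minimum number of non-recombinant parental ribotypes
#'
#' Each parental (non-recombinant) haplotype contributes exactly one
#' allele per locus, so at least `max_l a_l` parents are needed to supply
#' the `a_l` distinct alleles observed at the most polymorphic locus.
#' This lower-bounds the number of hybridizing ribosomal gene clusters.
#'
#' @param x A `data.frame` from [assignRibotypes()] or a
#'   [RibotypeTable-class].
#' @return Integer: the minimum parental haplotype count.
#' @export
minParents <- function(x) {
  if (is(x, "RibotypeTable")) {
    tb <- abundances(x)
    loci <- lociLabels(x)
    keep <- tb$abundance > 0L
    return(max(vapply(loci, function(lc) length(unique(tb[[lc]][keep])),
                      integer(1))))
  }
  loci <- setdiff(names(x), c("clone_id", "specimen_id", "complete"))
  complete <- !Reduce(`|`, lapply(x[loci], is.na))
  if (!any(complete))
    stop("no complete assignment")
  max(vapply(loci, function(lc) length(unique(x[[lc]][complete])), integer(1)))
}
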