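#' @include AllClasses.R AllGenerics.R
NULL

# ---- column profiles -------------------------------------------------------

#' Per-column variability profile of an alignment
#'
#' For each alignment column, `variability` is 1 minus the frequency of
#' the modal symbol over `A C G T -` (gaps count as a fifth symbol, since
#' length-variable blocks show up as gap columns; `N` is excluded so that
#' sequencing ambiguity cannot create spurious variability), and
#' `gap_fraction` is the fraction of gaps.
#'
#' @param msa An aligned [CloneLibrary-class].
#' @return A `data.frame` with columns `column_index`, `variability`,
#'   `gap_fraction`, `modal_symbol`.
#' @export
columnProfiles <- function(msa) {
  stopifnot(is(msa, "CloneLibrary"))
  if (!isAligned(msa))
    stop("columnProfiles requires an aligned library")
  cm <- Biostrings::consensusMatrix(cloneSeqs(msa))
  syms <- c("A", "C", "G", "T", "-")
  cm <- cm[intersect(syms, rownames(cm)), , drop = FALSE]
  tot <- colSums(cm)
  modal <- apply(cm, 2L, max)
  data.frame(
    column_index = seq_len(ncol(cm)),
    variability = ifelse(tot > 0, 1 - modal / tot, 0),
    gap_fraction = if ("-" %in% rownames(cm)) cm["-", ] / nClones(msa)
                   else rep(0, ncol(cm)),
    modal_symbol = rownames(cm)[apply(cm, 2L, which.max)],
    stringsAsFactors = FALSE
  )
}

# ---- detection -------------------------------------------------------------

#' Detect hypervariable block loci in a multiple alignment
#'
#' Conserved "anchor" runs — at least `flankLen` consecutive columns with
#' variability at most `1 - flankConservation` — segment the alignment;
#' every region strictly between two anchors that contains at least
#' `minBlockCols` columns with variability at least `varThreshold`
#' becomes one locus.  Segmenting by anchors (rather than by literal runs
#' of variable columns) keeps a block whole even where its alleles
#' coincide at a few interior columns.  Flank sequences are the modal
#' ungapped sequence of the `flankLen` anchor columns adjacent to the
#' span.
#'
#' @param msa An aligned [CloneLibrary-class] with at least 2 clones.
#' @param varThreshold Minimum column variability counting toward a block
#'   (default 0.15).
#' @param minBlockCols Minimum number of variable columns per locus
#'   (default 4).
#' @param flankLen Anchor length in columns (default 10).
#' @param flankConservation Minimum modal-symbol frequency of an anchor
#'   column (default 0.95).
#' @return A [LocusSet-class]; empty when no locus qualifies.
#' @export
detectVariableLoci <- function(msa, varThreshold = 0.15, minBlockCols = 4L,
                               flankLen = 10L, flankConservation = 0.95) {
  stopifnot(is(msa, "CloneLibrary"))
  if (!isAligned(msa))
    stop("detectVariableLoci requires an aligned library")
  if (nClones(msa) < 2L)
    stop("need at least 2 aligned clones")
  if (varThreshold <= 0 || varThreshold >= 1)
    stop("varThreshold must be in (0, 1)")
  prof <- columnProfiles(msa)
  conserved <- prof$variability <= 1 - flankConservation
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  anchor <- r$values & r$lengths >= flankLen
  aIdx <- which(anchor)
  if (length(aIdx) < 2L)
    return(.emptyLocusSet())
  out <- list()
  for (k in seq_len(length(aIdx) - 1L)) {
    a1 <- aIdx[k]; a2 <- aIdx[k + 1L]
    s <- ends[a1] + 1L
    e <- starts[a2] - 1L
    if (e < s) next
    nvar <- sum(prof$variability[s:e] >= varThreshold)
    if (nvar < minBlockCols) next
    lf <- .modalFlank(prof, (ends[a1] - flankLen + 1L):ends[a1])
    rf <- .modalFlank(prof, starts[a2]:(starts[a2] + flankLen - 1L))
    out[[length(out) + 1L]] <- list(start = s, end = e, lf = lf, rf = rf)
  }
  if (length(out) == 0L)
    return(.emptyLocusSet())
  LocusSet(
    starts = vapply(out, `[[`, integer(1), "start"),
    ends = vapply(out, `[[`, integer(1), "end"),
    labels = paste0("L", seq_along(out)),
    leftFlank = vapply(out, `[[`, character(1), "lf"),
    rightFlank = vapply(out, `[[`, character(1), "rf")
  )
}

.modalFlank <- function(prof, cols) {
  s <- prof$modal_symbol[cols]
  paste(s[s != "-"], collapse = "")
}

.emptyLocusSet <- function() {
  new("LocusSet", ranges = IRanges::IRanges(), leftFlank = character(0),
      rightFlank = character(0), allowedLengths = list())
}

# ---- aligned-path extraction -----------------------------------------------

#' Extract ungapped block sequences from an aligned library
#'
#' Substrings each clone at each locus span and strips gap characters.  A
#' fully deleted block yields the empty string (reported via a message).
#'
#' @param msa An aligned [CloneLibrary-class].
#' @param loci A [LocusSet-class] whose spans lie within the alignment.
#' @return Character matrix, rows = clones (named), columns = loci.
#' @export
extractBlocks <- function(msa, loci) {
  stopifnot(is(msa, "CloneLibrary"), is(loci, "LocusSet"))
  if (!isAligned(msa))
    stop("extractBlocks requires an aligned library; see anchorBlocks")
  w <- Biostrings::width(cloneSeqs(msa))[1L]
  r <- lociRanges(loci)
  if (length(r) && (min(IRanges::start(r)) < 1L || max(IRanges::end(r)) > w))
    stop("locus span out of alignment range")
  seqs <- as.character(cloneSeqs(msa))
  out <- matrix(NA_character_, nrow = nClones(msa), ncol = length(loci),
                dimnames = list(cloneIDs(msa), lociLabels(loci)))
  for (j in seq_along(loci)) {
    block <- substr(seqs, IRanges::start(r)[j], IRanges::end(r)[j])
    out[, j] <- gsub("-", "", block, fixed = TRUE)
  }
  nEmpty <- sum(out == "")
  if (nEmpty > 0L)
    message(sprintf("%d block(s) fully deleted (empty after gap stripping)",
                    nEmpty))
  out
}

# ---- anchored-path extraction ----------------------------------------------

#' Extract blocks from unaligned clones by conserved-flank anchoring
#'
#' For each clone and locus the left and right flank are located by
#' fuzzy search (Hamming distance at most `maxFlankMismatch`, no indels);
#' among hits the minimum-mismatch one is taken, leftmost on ties.  The
#' block is the substring strictly between the flanks.  A clone in which
#' either flank cannot be located — or in which the right flank occurs
#' only before the left — gets `NA` at that locus.
#'
#' @param clones A [CloneLibrary-class] (aligned input is degapped
#'   first).
#' @param loci A [LocusSet-class] carrying flank sequences.
#' @param maxFlankMismatch Maximum substitutions tolerated per flank
#'   (default 1).
#' @return Character matrix, rows = clones, columns = loci; `NA` where a
#'   block could not be anchored.
#' @export
anchorBlocks <- function(clones, loci, maxFlankMismatch = 1L) {
  stopifnot(is(clones, "CloneLibrary"), is(loci, "LocusSet"),
            maxFlankMismatch >= 0L)
  seqs <- as.character(cloneSeqs(clones))
  if (isAligned(clones))
    seqs <- gsub("-", "", seqs, fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(seqs), ncol = length(loci),
                dimnames = list(cloneIDs(clones), lociLabels(loci)))
  nMisordered <- 0L
  for (i in seq_along(seqs)) {
    subj <- Biostrings::DNAString(seqs[i])
    for (j in seq_along(loci)) {
      lf <- .bestFlankHit(leftFlanks(loci)[j], subj, maxFlankMismatch)
      if (is.na(lf)) next
      lfEnd <- lf + nchar(leftFlanks(loci)[j]) - 1L
      rf <- .bestFlankHit(rightFlanks(loci)[j], subj, maxFlankMismatch,
                          minStart = lfEnd + 1L)
      if (is.na(rf)) {
        # right flank present only before the left flank -> unassignable
        if (!is.na(.bestFlankHit(rightFlanks(loci)[j], subj, maxFlankMismatch)))
          nMisordered <- nMisordered + 1L
        next
      }
      out[i, j] <- substr(seqs[i], lfEnd + 1L, rf - 1L)
    }
  }
  if (nMisordered > 0L)
    message(sprintf("%d locus occurrence(s) with right flank before left flank",
                    nMisordered))
  out
}

# Minimum-Hamming occurrence of `pattern` in `subj` (a DNAString), among
# starts >= minStart; leftmost on ties; NA when no hit within maxMM.
.bestFlankHit <- function(pattern, subj, maxMM, minStart = 1L) {
  hits <- Biostrings::matchPattern(pattern, subj, max.mismatch = maxMM,
                                   with.indels = FALSE)
  st <- IRanges::start(hits)
  st <- st[st >= minStart & st + nchar(pattern) - 1L <= length(subj)]
  if (length(st) == 0L)
    return(NA_integer_)
  mm <- Biostrings::neditStartingAt(pattern, subj, starting.at = st)
  st[which.min(mm)]  # which.min is leftmost on ties (st is sorted)
}
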