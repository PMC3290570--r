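#' @include AllClasses.R AllGenerics.R core-model.R
NULL

.BASES <- c("A", "C", "G", "T")

# ---- configuration ---------------------------------------------------------

#' Default simulation configuration emulating an SSU rDNA clone study
#'
#' The defaults reproduce the sampling design of a partial (~800 bp) SSU
#' rDNA clone survey of a benthic foraminifer: 25 specimens with 1-7
#' clones each, three embedded hypervariable block loci with
#' allele-length sets \{6, 8, 10\}, \{32, 34\} and \{11, 14\} bp, uniform
#' SNP noise and PCR template-switch chimeras.  The default ribotype
#' weights place all mass on three parental ribotype clusters —
#' `a|a|a` (0.45), `b|b|b` (0.35) and `c|a|b` (0.20) — jointly carrying
#' every allele, the hybridization scenario the pipeline is built to
#' interrogate; minority mosaic ribotypes then arise through the chimera
#' process.  Use [dirichletRibotypeWeights()] for a random spread over
#' the whole combination space instead.
#'
#' Allele block sequences are drawn uniformly at random from the seed
#' (users may substitute literal sequences).  Because alleles at a locus
#' differ in length, the alignment's right block boundary is always
#' polymorphic; if the drawn alleles happen to share their first base,
#' the first base of the last allele is rotated so that the left
#' boundary is polymorphic too and planted spans stay identifiable.
#'
#' @param seed Integer RNG seed.
#' @param nSpecimens Number of specimens (default 25).
#' @param cloneRange `c(lo, hi)` clones per specimen, uniform (default
#'   `c(1, 7)`).
#' @param backboneLength Conserved backbone length in bp (default 800).
#' @param alleleLengths List of integer vectors: block lengths per locus.
#' @param positions Insertion points of the blocks in the backbone.
#' @param alleleSequences Optional list of character vectors overriding
#'   the random alleles.
#' @param ribotypeWeights Optional named numeric weights over allele
#'   tuples (names like `"a|b|a"`).
#' @param snpRate Per-site substitution probability (default 0.002,
#'   a realistic Taq + Sanger error load).
#' @param chimeraRate Per-clone PCR template-switch probability (default
#'   0.05; real chimera frequencies are unknown, this is illustrative).
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- espSimulationConfig(seed = 1)
#' enumerateRibotypeSpace(vapply(locusSpecs(cfg),
#'                               function(s) length(s$alleles), integer(1)))
#' @export
espSimulationConfig <- function(seed = 1L, nSpecimens = 25L,
                                cloneRange = c(1L, 7L),
                                backboneLength = 800L,
                                alleleLengths = list(c(6L, 8L, 10L),
                                                     c(32L, 34L),
                                                     c(11L, 14L)),
                                positions = c(200L, 400L, 600L),
                                alleleSequences = NULL,
                                ribotypeWeights = NULL,
                                snpRate = 0.002, chimeraRate = 0.05) {
  stopifnot(length(positions) == length(alleleLengths))
  if (is.null(alleleSequences)) {
    set.seed(as.integer(seed))
    alleleSequences <- lapply(alleleLengths, .drawAlleles)
  }
  locusSpecs <- mapply(function(p, a) list(position = as.integer(p),
                                           alleles = a),
                       positions, alleleSequences, SIMPLIFY = FALSE)
  if (is.null(ribotypeWeights)) {
    nall <- lengths(alleleSequences)
    if (length(nall) == 3L && all(nall == c(3L, 2L, 2L))) {
      ribotypeWeights <- c("a|a|a" = 0.45, "b|b|b" = 0.35, "c|a|b" = 0.20)
    } else {
      # fall back: parental cluster per allele rank, equal weights
      k <- max(nall)
      keys <- vapply(seq_len(k), function(i)
        paste(letters[pmin(i, nall)], collapse = "|"), character(1))
      ribotypeWeights <- stats::setNames(rep(1 / k, k), keys)
      ribotypeWeights <- tapply(ribotypeWeights, names(ribotypeWeights), sum)
      ribotypeWeights <- stats::setNames(as.numeric(ribotypeWeights),
                                         names(ribotypeWeights))
    }
  }
  new("SimulationConfig", seed = as.integer(seed),
      nSpecimens = as.integer(nSpecimens),
      cloneRange = as.integer(cloneRange),
      backboneLength = as.integer(backboneLength),
      locusSpecs = locusSpecs, ribotypeWeights = ribotypeWeights,
      snpRate = snpRate, chimeraRate = chimeraRate)
}

# Random length-distinct alleles; left boundary forced polymorphic.
.drawAlleles <- function(lens) {
  al <- vapply(lens, function(l)
    paste(sample(.BASES, l, replace = TRUE), collapse = ""), character(1))
  first <- substr(al, 1L, 1L)
  if (length(unique(first)) == 1L) {
    i <- length(al)
    repl <- .BASES[(match(first[i], .BASES)) %% 4L + 1L]
    substr(al[i], 1L, 1L) <- repl
  }
  al
}

#' Locus specifications of a simulation config
#'
#' @param config A [SimulationConfig-class].
#' @return The list of per-locus `list(position, alleles)` specs.
#' @export
locusSpecs <- function(config) config@locusSpecs

#' Dirichlet-distributed ribotype weights over the full combination space
#'
#' @param config A [SimulationConfig-class] (its locus specs define the
#'   space).
#' @param alpha Dirichlet concentration (default 1: uniform over the
#'   simplex).
#' @param seed RNG seed.
#' @return Named numeric weights over every allele tuple, summing to 1.
#' @export
dirichletRibotypeWeights <- function(config, alpha = 1, seed = 1L) {
  nall <- vapply(config@locusSpecs, function(s) length(s$alleles), integer(1))
  grid <- expand.grid(rev(lapply(nall, function(k) letters[seq_len(k)])),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(nall)), drop = FALSE]
  keys <- do.call(.tupleKey, grid)
  set.seed(as.integer(seed))
  g <- stats::rgamma(length(keys), shape = alpha)
  stats::setNames(g / sum(g), keys)
}

# ---- generation ------------------------------------------------------------

#' Generate a synthetic clone library with ground truth
#'
#' Draws a uniform-random conserved backbone from the seed, inserts at
#' each locus the block allele dictated by the clone's ribotype (sampled
#' from `ribotypeWeights`), applies PCR template-switch chimeras (with
#' probability `chimeraRate` a second template and a uniform inter-locus
#' breakpoint are drawn and the tuples spliced) and uniform per-site SNP
#' substitutions (never inside the 2 bp of backbone adjacent to a block
#' boundary, so flank anchoring stays testable independently of its
#' mismatch tolerance).  The aligned output pads each block with `-` to
#' the per-locus maximum allele length.  A single RNG stream ordered
#' (specimen, clone, site) makes identical seeds give byte-identical
#' libraries.
#'
#' @param config A [SimulationConfig-class].
#' @return A list of class `espSimulation`: `unaligned` and `aligned`
#'   [CloneLibrary-class] objects, `truth` (a `data.frame`: `clone_id`,
#'   `specimen_id`, realized allele letter per locus, `template1`,
#'   `template2`, `breakpoint`, `is_chimera`, `detectable_chimera` —
#'   whether the realized tuple differs from both parent templates —
#'   `n_mutations`, `mutated_positions` in aligned coordinates), `loci`
#'   (the true [LocusSet-class] in aligned coordinates) and `config`.
#' @export
generateLibrary <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  L <- length(config@locusSpecs)
  backbone <- sample(.BASES, config@backboneLength, replace = TRUE)
  tmpl <- .buildTemplates(config, backbone)
  weights <- config@ribotypeWeights
  keys <- names(weights)
  tupleOf <- strsplit(keys, "|", fixed = TRUE)
  rows <- list()
  alignedSeqs <- character(0)
  for (s in seq_len(config@nSpecimens)) {
    nC <- config@cloneRange[1L] +
      sample.int(config@cloneRange[2L] - config@cloneRange[1L] + 1L, 1L) - 1L
    for (cl in seq_len(nC)) {
      k1 <- sample(keys, 1L, prob = weights)
      isChim <- stats::runif(1L) < config@chimeraRate && length(keys) > 1L &&
        L > 1L
      if (isChim) {
        w2 <- weights[keys != k1]
        k2 <- sample(names(w2), 1L, prob = w2)
        bp <- if (L == 2L) 1L else sample(seq_len(L - 1L), 1L)
        t1 <- strsplit(k1, "|", fixed = TRUE)[[1L]]
        t2 <- strsplit(k2, "|", fixed = TRUE)[[1L]]
        realized <- c(t1[seq_len(bp)], t2[(bp + 1L):L])
      } else {
        k2 <- NA_character_
        bp <- NA_integer_
        realized <- strsplit(k1, "|", fixed = TRUE)[[1L]]
      }
      key <- paste(realized, collapse = "|")
      chars <- tmpl$chars[[key]]
      u <- stats::runif(length(chars))
      mut <- which(u < config@snpRate & tmpl$eligible[[key]])
      for (p in mut) {
        cur <- chars[p]
        chars[p] <- sample(setdiff(.BASES, cur), 1L)
      }
      alignedSeqs <- c(alignedSeqs, paste(chars, collapse = ""))
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = sprintf("SP%02d_clone%d", s, cl),
        specimen_id = sprintf("SP%02d", s),
        t(stats::setNames(realized, tmpl$lociLabels)),
        template1 = k1, template2 = k2, breakpoint = bp,
        is_chimera = isChim,
        detectable_chimera = isChim && key != k1 && key != k2,
        n_mutations = length(mut),
        mutated_positions = paste(mut, collapse = ";"),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  names(alignedSeqs) <- truth$clone_id
  aligned <- CloneLibrary(Biostrings::DNAStringSet(alignedSeqs),
                          specimen = truth$specimen_id, aligned = TRUE)
  unaligned <- CloneLibrary(
    Biostrings::DNAStringSet(gsub("-", "", alignedSeqs, fixed = TRUE)),
    specimen = truth$specimen_id, aligned = FALSE)
  structure(list(unaligned = unaligned, aligned = aligned, truth = truth,
                 loci = tmpl$loci, config = config),
            class = "espSimulation")
}

# Aligned template (char vector), SNP-eligible mask per ribotype tuple,
# plus the true LocusSet in aligned coordinates.
.buildTemplates <- function(config, backbone) {
  L <- length(config@locusSpecs)
  pos <- vapply(config@locusSpecs, `[[`, integer(1), "position")
  maxLen <- vapply(config@locusSpecs, function(s) max(nchar(s$alleles)),
                   integer(1))
  # backbone segments between insertion points
  segs <- list()
  prev <- 0L
  for (j in seq_len(L)) {
    segs[[j]] <- backbone[(prev + 1L):pos[j]]
    prev <- pos[j]
  }
  segs[[L + 1L]] <- if (prev < length(backbone))
    backbone[(prev + 1L):length(backbone)] else character(0)
  # aligned spans of the padded blocks
  starts <- integer(L)
  off <- 0L
  for (j in seq_len(L)) {
    off <- off + length(segs[[j]])
    starts[j] <- off + 1L
    off <- off + maxLen[j]
  }
  totalLen <- off + length(segs[[L + 1L]])
  lociLabels <- paste0("locus", seq_len(L))
  loci <- LocusSet(
    starts = starts, ends = starts + maxLen - 1L, labels = lociLabels,
    leftFlank = vapply(segs[seq_len(L)], function(x)
      paste(utils::tail(x, 10L), collapse = ""), character(1)),
    rightFlank = vapply(seq_len(L), function(j) {
      nxt <- segs[[j + 1L]]
      paste(utils::head(nxt, 10L), collapse = "")
    }, character(1)),
    allowedLengths = lapply(config@locusSpecs, function(s)
      sort(unique(nchar(s$alleles))))
  )
  # SNP-eligible backbone mask: backbone TRUE except 2 bp beside blocks
  nall <- vapply(config@locusSpecs, function(s) length(s$alleles), integer(1))
  grid <- expand.grid(rev(lapply(nall, function(k) seq_len(k))),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(nall)), drop = FALSE]
  chars <- list()
  eligible <- list()
  for (g in seq_len(nrow(grid))) {
    idx <- as.integer(grid[g, ])
    key <- paste(letters[idx], collapse = "|")
    cv <- character(0)
    el <- logical(0)
    for (j in seq_len(L)) {
      seg <- segs[[j]]
      segEl <- rep(TRUE, length(seg))
      if (length(segEl) >= 2L)
        segEl[(length(segEl) - 1L):length(segEl)] <- FALSE  # 2 bp left of block
      if (j > 1L && length(segEl) >= 2L)
        segEl[1:2] <- FALSE                                  # 2 bp right of prev
      allele <- strsplit(config@locusSpecs[[j]]$alleles[idx[j]], "")[[1L]]
      pad <- rep("-", maxLen[j] - length(allele))
      cv <- c(cv, seg, allele, pad)
      el <- c(el, segEl, rep(TRUE, length(allele)), rep(FALSE, length(pad)))
    }
    seg <- segs[[L + 1L]]
    segEl <- rep(TRUE, length(seg))
    if (length(segEl) >= 2L) segEl[1:2] <- FALSE
    cv <- c(cv, seg)
    el <- c(el, segEl)
    chars[[key]] <- cv
    eligible[[key]] <- el
  }
  list(chars = chars, eligible = eligible, loci = loci,
       lociLabels = lociLabels, totalLen = totalLen)
}

#' @export
print.espSimulation <- function(x, ...) {
  cat(sprintf(
    "espSimulation: %d clones / %d specimens; %d loci; snpRate=%g chimeraRate=%g seed=%d\n",
    nClones(x$unaligned), length(unique(x$truth$specimen_id)),
    length(x$loci), x$config@snpRate, x$config@chimeraRate, x$config@seed))
  invisible(x)
}

#' Verify that emitted sequences reconstruct from the recorded truth
#'
#' For every clone, the emitted aligned sequence must equal the spliced
#' ribotype template everywhere except exactly at the recorded mutated
#' positions.
#'
#' @param sim An `espSimulation` from [generateLibrary()].
#' @return Logical vector per clone (all `TRUE` for a consistent
#'   simulation).
#' @export
verifySimulationTruth <- function(sim) {
  set.seed(sim$config@seed)
  backbone <- sample(.BASES, sim$config@backboneLength, replace = TRUE)
  tmpl <- .buildTemplates(sim$config, backbone)
  seqs <- as.character(cloneSeqs(sim$aligned))
  vapply(seq_len(nrow(sim$truth)), function(i) {
    key <- paste(sim$truth[i, tmpl$lociLabels], collapse = "|")
    ref <- tmpl$chars[[key]]
    emit <- strsplit(seqs[i], "")[[1L]]
    mut <- if (nzchar(sim$truth$mutated_positions[i]))
      as.integer(strsplit(sim$truth$mutated_positions[i], ";")[[1L]])
    else integer(0)
    diffs <- which(ref != emit)
    setequal(diffs, mut) && all(emit[mut] != ref[mut])
  }, logical(1))
}

# ---- truth comparison ------------------------------------------------------

#' Translate called allele labels into the generator's truth letters
#'
#' Calling labels alleles by abundance, so the label `"a"` at a locus
#' need not be the generator's first allele.  Translation goes through
#' the block sequences: a called label maps to the truth letter of the
#' identical allele sequence (`NA` for a spurious allele absent from the
#' configuration).
#'
#' @param assignments A `data.frame` from [assignRibotypes()].
#' @param catalogs The called catalogs (named list of
#'   [AlleleCatalog-class]).
#' @param config The [SimulationConfig-class] that generated the data.
#' @param lociCols Locus columns of `assignments`, in the same order as
#'   the configured loci; default `names(catalogs)`.
#' @return `assignments` with locus columns rewritten in truth letters.
#' @export
relabelToTruth <- function(assignments, catalogs, config,
                           lociCols = names(catalogs)) {
  specs <- config@locusSpecs
  stopifnot(length(lociCols) == length(specs))
  for (j in seq_along(lociCols)) {
    al <- alleleTable(catalogs[[lociCols[j]]])
    toTruth <- stats::setNames(letters[match(al$sequence, specs[[j]]$alleles)],
                               al$label)
    assignments[[lociCols[j]]] <-
      unname(toTruth[assignments[[lociCols[j]]]])
  }
  assignments
}

#' Score pipeline assignments against the generator truth
#'
#' @inheritParams relabelToTruth
#' @param sim The `espSimulation` the assignments were derived from.
#' @return A `data.frame`: `clone_id`, `is_chimera`,
#'   `detectable_chimera`, `truth_key`, `called_key` (both in truth
#'   letters) and `correct`.
#' @export
compareWithTruth <- function(assignments, catalogs, sim,
                             lociCols = names(catalogs)) {
  tl <- relabelToTruth(assignments, catalogs, sim$config, lociCols)
  tl <- tl[match(sim$truth$clone_id, tl$clone_id), , drop = FALSE]
  truthLoci <- paste0("locus", seq_along(sim$config@locusSpecs))
  calledKey <- apply(tl[lociCols], 1L, function(v)
    if (anyNA(v)) NA_character_ else paste(v, collapse = "|"))
  truthKey <- apply(sim$truth[truthLoci], 1L, paste, collapse = "|")
  data.frame(
    clone_id = sim$truth$clone_id,
    is_chimera = sim$truth$is_chimera,
    detectable_chimera = sim$truth$detectable_chimera,
    truth_key = truthKey,
    called_key = calledKey,
    correct = !is.na(calledKey) & calledKey == truthKey,
    stringsAsFactors = FALSE
  )
}

#' Translate called-label ribotype keys into truth-letter keys
#'
#' @param keys Character vector of `"a|b|a"` keys in called-label space
#'   (e.g. the `ribotype` column of [flagPutativeChimeras()] output).
#' @inheritParams relabelToTruth
#' @return Character vector of keys in truth letters (`NA` where a label
#'   maps to a spurious allele).
#' @export
calledKeysToTruth <- function(keys, catalogs, config,
                              lociCols = names(catalogs)) {
  specs <- config@locusSpecs
  maps <- lapply(seq_along(lociCols), function(j) {
    al <- alleleTable(catalogs[[lociCols[j]]])
    stats::setNames(letters[match(al$sequence, specs[[j]]$alleles)], al$label)
  })
  vapply(strsplit(keys, "|", fixed = TRUE), function(lab) {
    v <- vapply(seq_along(lab), function(j) unname(maps[[j]][lab[j]]),
                character(1))
    if (anyNA(v)) NA_character_ else paste(v, collapse = "|")
  }, character(1))
}
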