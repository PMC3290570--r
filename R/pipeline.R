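#' @include AllClasses.R AllGenerics.R core-model.R locus-detection.R
#' @include ribotyping.R esp-stats.R recombination.R io.R
NULL

#' Run the full ESP analysis pipeline
#'
#' Executes detect -> extract -> call -> assign -> tabulate ->
#' specimen summaries -> statistics -> chimera / recombination screens,
#' in the order the underlying clone-library analysis follows.  Aligned
#' input uses alignment-span extraction after (or instead of) locus
#' detection; unaligned input requires locus definitions with flanks and
#' uses anchored extraction.  Any stage failure aborts with the stage
#' name and cause.
#'
#' @param clones A [CloneLibrary-class] or a FASTA path.
#' @param loci Optional [LocusSet-class]; mandatory for unaligned input.
#' @param varThreshold,minBlockCols,flankLen,flankConservation Locus
#'   detection parameters, see [detectVariableLoci()].
#' @param maxFlankMismatch Anchoring tolerance, see [anchorBlocks()].
#' @param snpTolerance,minAlleleCount Allele-calling parameters, see
#'   [callAlleles()].
#' @param minParentRatio Chimera flagging ratio, see
#'   [flagPutativeChimeras()].
#' @param nPermutations,nBoot,seed Stochastic-test parameters; the seed
#'   governs every stochastic step and is recorded in the report.
#' @param outDir Optional directory; when given, all tables are written
#'   as TSV plus a JSON report and a run log.
#' @return A list of class `espReport`: `library`, `loci`, `blocks`,
#'   `catalogs`, `assignments`, `ribotypeTable`, `specimenSummaries`,
#'   `correlation`, `prevalence` (per locus), `saturation`,
#'   `chimeraCalls`, `compatibility`, `minParents`, `parameters`.
#' @export
runPipeline <- function(clones, loci = NULL,
                        varThreshold = 0.15, minBlockCols = 4L,
                        flankLen = 10L, flankConservation = 0.95,
                        maxFlankMismatch = 1L,
                        snpTolerance = 1L, minAlleleCount = 2L,
                        minParentRatio = 3, nPermutations = 10000L,
                        nBoot = 200L, seed = 1L, outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(clones))
    clones <- stage("read", readCloneFasta(clones))
  stopifnot(is(clones, "CloneLibrary"))
  if (isAligned(clones)) {
    if (is.null(loci))
      loci <- stage("detect", detectVariableLoci(
        clones, varThreshold, minBlockCols, flankLen, flankConservation))
    if (length(loci) == 0L)
      stop("stage 'detect' failed: no variable locus found", call. = FALSE)
    blocks <- stage("extract", extractBlocks(clones, loci))
  } else {
    if (is.null(loci) || length(loci) == 0L)
      stop("stage 'extract' failed: unaligned input requires locus definitions with flanks",
           call. = FALSE)
    blocks <- stage("extract", anchorBlocks(clones, loci, maxFlankMismatch))
  }
  catalogs <- stage("call", callAllelesAll(blocks, snpTolerance, minAlleleCount))
  assignments <- stage("assign", assignRibotypes(
    blocks, catalogs, snpTolerance, specimen = specimenIDs(clones)))
  table <- stage("tabulate", tabulateRibotypes(assignments, catalogs))
  summaries <- stage("summarize", summarizeSpecimens(assignments))
  correlation <- if (nrow(summaries) >= 3L &&
                     length(unique(summaries$n_clones)) > 1L &&
                     length(unique(summaries$n_ribotypes)) > 1L)
    stage("stats", clonesRibotypesCorrelation(summaries, nPermutations, seed))
  else NULL
  lociNames <- lociLabels(loci)
  prevalence <- stage("stats", {
    lapply(stats::setNames(lociNames, lociNames), function(lc) {
      sc <- .specimenAlleleCounts(assignments, lc, catalogs[[lc]])
      allelePrevalenceTest(catalogs[[lc]], specimenCounts = sc,
                           nBoot = nBoot, seed = seed)
    })
  })
  saturation <- stage("stats", ribotypeSaturation(assignments, nBoot, seed))
  chimeraCalls <- stage("recombination",
                        flagPutativeChimeras(table, minParentRatio))
  compatibility <- stage("recombination", compatibilityMatrix(assignments))
  parameters <- list(varThreshold = varThreshold, minBlockCols = minBlockCols,
                     flankLen = flankLen, flankConservation = flankConservation,
                     maxFlankMismatch = maxFlankMismatch,
                     snpTolerance = snpTolerance,
                     minAlleleCount = minAlleleCount,
                     minParentRatio = minParentRatio,
                     nPermutations = nPermutations, nBoot = nBoot,
                     seed = seed)
  report <- structure(list(
    library = clones, loci = loci, blocks = blocks, catalogs = catalogs,
    assignments = assignments, ribotypeTable = table,
    specimenSummaries = summaries, correlation = correlation,
    prevalence = prevalence, saturation = saturation,
    chimeraCalls = chimeraCalls, compatibility = compatibility,
    minParents = minParents(assignments), parameters = parameters
  ), class = "espReport")
  if (!is.null(outDir))
    stage("write", writeReport(report, outDir))
  report
}

# per-specimen x allele count matrix for the cluster bootstrap
.specimenAlleleCounts <- function(assignments, locus, catalog) {
  labs <- alleleTable(catalog)$label
  v <- assignments[[locus]]
  keep <- !is.na(v)
  if (!any(keep))
    return(NULL)
  m <- table(factor(assignments$specimen_id[keep]), factor(v[keep], labs))
  matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
}

#' Write an espReport bundle to a directory
#'
#' Emits `loci.tsv`, `catalogs.tsv`, `assignments.tsv`,
#' `ribotype_table.tsv`, `specimen_summaries.tsv`, `saturation.tsv`,
#' `chimera_calls.tsv`, `compatibility.tsv`, a machine-readable
#' `report.json` (statistics, parameters, seed, package version) and a
#' `run_log.txt`.
#'
#' @param report An `espReport` from [runPipeline()].
#' @param outDir Output directory (created if absent).
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  writeLoci(report$loci, fp("loci.tsv"))
  writeAlleleCatalogs(report$catalogs, fp("catalogs.tsv"))
  writeAssignments(report$assignments, fp("assignments.tsv"))
  writeRibotypeTable(report$ribotypeTable, fp("ribotype_table.tsv"))
  utils::write.table(report$specimenSummaries, fp("specimen_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$saturation, fp("saturation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$chimeraCalls, fp("chimera_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$compatibility, fp("compatibility.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    n_clones = nClones(report$library),
    n_specimens = length(unique(specimenIDs(report$library))),
    n_loci = length(report$loci),
    space_size = spaceSize(report$ribotypeTable),
    n_observed_ribotypes =
      sum(abundances(report$ribotypeTable)$abundance > 0L),
    n_incomplete = length(incompleteClones(report$ribotypeTable)),
    min_parents = report$minParents,
    correlation = if (!is.null(report$correlation))
      unclass(report$correlation),
    prevalence = lapply(report$prevalence, function(p)
      unclass(p)[setdiff(names(unclass(p)), "counts")]),
    n_chimera_explanations = nrow(report$chimeraCalls),
    recombination_signal_pairs =
      sum(report$compatibility$recombination_signal),
    parameters = report$parameters,
    package_version = as.character(utils::packageVersion("ribomosaic"))
  )
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             fp("report.json"))
  writeLines(c(
    sprintf("ribomosaic %s", utils::packageVersion("ribomosaic")),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed %d", report$parameters$seed),
    sprintf("%d clones, %d loci", nClones(report$library),
            length(report$loci)),
    paste("parameters:",
          paste(names(report$parameters), unlist(report$parameters),
                sep = "=", collapse = " "))
  ), fp("run_log.txt"))
  invisible(outDir)
}

#' @export
print.espReport <- function(x, ...) {
  cat("ESP pipeline report\n")
  show(x$library)
  show(x$loci)
  show(x$ribotypeTable)
  cat(sprintf("minimum parental haplotypes: %d\n", x$minParents))
  if (!is.null(x$correlation)) print(x$correlation)
  cat(sprintf("chimera explanations: %d; locus pairs with recombination signal: %d/%d\n",
              nrow(x$chimeraCalls), sum(x$compatibility$recombination_signal),
              nrow(x$compatibility)))
  invisible(x)
}

#' Summary quantities of a published-style ribotype occurrence table
#'
#' Recomputes, from a per-clone assignments table (columns `clone_id`,
#' `specimen_id`, three allele-label columns), the headline quantities of
#' a clone-library ESP survey: total clones, observed ribotypes, top
#' ribotype abundance, missing combinations, allele counts at the first
#' locus, the maximum ribotype richness within one specimen, and the
#' Spearman correlation between clones and ribotypes per specimen.
#'
#' @param assignments A `data.frame` or a TSV path.
#' @param loci Locus column names; default inferred.
#' @return A list: `n_clones`, `n_observed_ribotypes`, `top_abundance`,
#'   `missing_combinations` (tuple keys at abundance 0 over the observed
#'   allele space), `locus1_allele_counts`, `max_ribotypes_per_specimen`,
#'   `spearman_rho`.
#' @export
reproduceStudyValues <- function(assignments, loci = NULL) {
  if (is.character(assignments))
    assignments <- utils::read.delim(assignments, stringsAsFactors = FALSE)
  if (is.null(loci))
    loci <- setdiff(names(assignments),
                    c("clone_id", "specimen_id", "complete"))
  catalogs <- lapply(stats::setNames(loci, loci), function(lc) {
    tab <- table(assignments[[lc]])
    # labels stand in for sequences: the table carries labels only
    al <- data.frame(label = names(tab), sequence = names(tab),
                     count = as.integer(tab), stringsAsFactors = FALSE)
    al <- al[order(-al$count, al$sequence), , drop = FALSE]
    al$sequence <- al$label  # keep published labels
    al <- al[order(al$label), , drop = FALSE]
    rownames(al) <- NULL
    new("AlleleCatalog", locusLabel = lc, alleles = al)
  })
  tb <- tabulateRibotypes(assignments, catalogs)
  ab <- abundances(tb)
  summ <- summarizeSpecimens(assignments, loci)
  corr <- clonesRibotypesCorrelation(summ)
  list(
    n_clones = nrow(assignments),
    n_observed_ribotypes = sum(ab$abundance > 0L),
    top_abundance = max(ab$abundance),
    missing_combinations =
      do.call(.tupleKey, ab[ab$abundance == 0L, loci, drop = FALSE]),
    locus1_allele_counts = stats::setNames(
      alleleTable(catalogs[[1L]])$count, alleleTable(catalogs[[1L]])$label),
    max_ribotypes_per_specimen = max(summ$n_ribotypes),
    spearman_rho = corr$rho,
    spearman_p = corr$p_value
  )
}
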