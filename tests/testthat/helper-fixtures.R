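# Shared fixture builders; everything is generated in code.

# Catalog with k distinct alleles of distinct lengths, counts descending.
makeCatalog <- function(k, locus = "L", lens = seq(4L, by = 2L, length.out = k)) {
  seqs <- vapply(lens, function(l) paste(rep("A", l), collapse = ""), "")
  AlleleCatalog(locus, seqs, counts = rev(seq_len(k)) * 2L)
}

# Assignments data.frame from a named abundance vector of "a|b|a" keys.
makeAssignments <- function(abund, loci = c("L1", "L2", "L3"),
                            specimen = NULL) {
  keys <- rep(names(abund), abund)
  mat <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  d <- data.frame(clone_id = sprintf("SP%02d_clone%d",
                                     seq_along(keys), seq_along(keys)),
                  specimen_id = if (is.null(specimen))
                    sprintf("SP%02d", seq_along(keys)) else specimen,
                  stringsAsFactors = FALSE)
  for (j in seq_along(loci)) d[[loci[j]]] <- mat[, j]
  d$complete <- TRUE
  d
}

# Catalogs with the given allele counts per locus (labels a, b, ...).
makeCatalogs <- function(nAlleles, loci = names(nAlleles)) {
  stats::setNames(lapply(seq_along(loci), function(j)
    makeCatalog(nAlleles[[j]], loci[j])), loci)
}

# Small noise-free simulation shared across detection/ribotyping tests.
nfSim <- local({
  cache <- NULL
  function(seed = 11L) {
    if (is.null(cache))
      cache <<- generateLibrary(espSimulationConfig(
        seed = seed, snpRate = 0, chimeraRate = 0))
    cache
  }
})

# Map a called assignment row to the truth letter tuple via sequences.
calledTupleAsTruth <- function(assignments, catalogs, config,
                               lociCols = names(catalogs)) {
  specs <- locusSpecs(config)
  t(apply(assignments[lociCols], 1L, function(lab) {
    vapply(seq_along(lociCols), function(j) {
      if (is.na(lab[j])) return(NA_character_)
      sq <- alleleTable(catalogs[[j]])$sequence[
        match(lab[j], alleleTable(catalogs[[j]])$label)]
      letters[match(sq, specs[[j]]$alleles)]
    }, character(1))
  }))
}
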