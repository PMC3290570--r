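tableFrom <- function(abund, loci = c("L1", "L2", "L3"), nAlleles = NULL) {
  a <- makeAssignments(abund, loci = loci)
  if (is.null(nAlleles))
    nAlleles <- stats::setNames(
      vapply(seq_along(loci), function(j)
        length(unique(vapply(strsplit(names(abund), "|", fixed = TRUE),
                             `[[`, "", j))), 1L), loci)
  tabulateRibotypes(a, makeCatalogs(nAlleles, loci))
}

test_that("a rare mosaic of two abundant ribotypes is flagged", {
  tb <- tableFrom(c("a|a|a" = 20, "b|b|b" = 20, "a|a|b" = 1))
  calls <- flagPutativeChimeras(tb, minParentRatio = 2)
  expect_identical(unique(calls$ribotype), "a|a|b")
  expect_identical(calls$parent1, "a|a|a")
  expect_identical(calls$parent2, "b|b|b")
  expect_identical(calls$breakpoint, 2L)  # between locus 2 and locus 3
  expect_equal(calls$abundance_ratio, 20)
})

test_that("nothing is flagged when nothing is rare", {
  tb <- tableFrom(c("a|a|a" = 20))
  expect_identical(nrow(flagPutativeChimeras(tb, 2)), 0L)
  tb2 <- tableFrom(c("a|a|a" = 10, "b|b|b" = 9))
  expect_identical(nrow(flagPutativeChimeras(tb2, 3)), 0L)
})

test_that("chimera flags equal a brute-force loop over (r, p1, p2, bp)", {
  bruteForce <- function(obs, ratio) {
    tuples <- strsplit(names(obs), "|", fixed = TRUE)
    L <- length(tuples[[1]])
    hits <- list()
    for (r in seq_along(obs)) for (p1 in seq_along(obs))
      for (p2 in seq_along(obs)) for (bp in seq_len(L - 1)) {
        if (p1 == r || p2 == r) next
        if (obs[p1] < ratio * obs[r] || obs[p2] < ratio * obs[r]) next
        sp <- c(tuples[[p1]][1:bp], tuples[[p2]][(bp + 1):L])
        if (identical(sp, tuples[[r]]))
          hits[[length(hits) + 1]] <- c(names(obs)[r], names(obs)[p1],
                                        names(obs)[p2], bp)
      }
    hits
  }
  set.seed(41)
  keys <- apply(expand.grid(letters[1:3], letters[1:2], letters[1:2]), 1,
                paste, collapse = "|")
  for (rep in 1:10) {
    abund <- stats::setNames(rpois(12, 2), keys)
    abund <- abund[abund > 0]
    if (length(abund) < 3) next
    tb <- tableFrom(abund, nAlleles = c(L1 = 3, L2 = 2, L3 = 2))
    calls <- flagPutativeChimeras(tb, 3)
    oracle <- bruteForce(abund, 3)
    expect_identical(nrow(calls), length(oracle))
    if (nrow(calls)) {
      got <- sort(apply(calls[, c("ribotype", "parent1", "parent2",
                                  "breakpoint")], 1, paste, collapse = "/"))
      want <- sort(vapply(oracle, paste, "", collapse = "/"))
      expect_identical(got, want)
    }
  }
})

test_that("a ribotype is never flagged against a less abundant parent", {
  set.seed(43)
  keys <- apply(expand.grid(letters[1:2], letters[1:2], letters[1:2]), 1,
                paste, collapse = "|")
  for (rep in 1:5) {
    abund <- stats::setNames(rpois(8, 3), keys)
    abund <- abund[abund > 0]
    if (length(abund) < 3) next
    calls <- flagPutativeChimeras(
      tableFrom(abund, nAlleles = c(L1 = 2, L2 = 2, L3 = 2)), 3)
    if (nrow(calls)) {
      expect_true(all(calls$parent1_abundance >= 3 * calls$abundance))
      expect_true(all(calls$parent2_abundance >= 3 * calls$abundance))
    }
  }
})

test_that("all four combinations at a 2x2 locus pair signal recombination", {
  a <- makeAssignments(c("a|a" = 5, "a|b" = 4, "b|a" = 3, "b|b" = 1),
                       loci = c("L1", "L2"))
  r <- pairwiseCompatibility(a, "L1", "L2")
  expect_identical(r$k_observed, 4L)
  expect_identical(r$k_max_treelike, 3L)
  expect_true(r$recombination_signal)
})

test_that("parental-only data show no recombination signal", {
  a <- makeAssignments(c("a|a" = 6, "b|b" = 4), loci = c("L1", "L2"))
  r <- pairwiseCompatibility(a, "L1", "L2")
  expect_identical(r$k_observed, 2L)
  expect_identical(r$k_max_treelike, 3L)
  expect_false(r$recombination_signal)
})

test_that("a monomorphic locus is noted and never signals", {
  a <- makeAssignments(c("a|a" = 4, "a|b" = 3), loci = c("L1", "L2"))
  r <- pairwiseCompatibility(a, "L1", "L2")
  expect_false(r$recombination_signal)
  expect_match(r$note, "monomorphic")
})

test_that("the 11-of-12 mosaic ribotype set signals recombination", {
  # every combination except (c, b, b), as in a hybridized clone survey
  keys <- apply(expand.grid(letters[1:3], letters[1:2], letters[1:2]), 1,
                paste, collapse = "|")
  keys <- setdiff(keys, "c|b|b")
  abund <- stats::setNames(rep(2L, length(keys)), keys)
  abund["a|a|a"] <- 26L
  a <- makeAssignments(abund)
  r <- pairwiseCompatibility(a, "L2", "L3")
  expect_identical(r$k_observed, 4L)
  expect_true(r$recombination_signal)
  cm <- compatibilityMatrix(a)
  expect_true(all(cm$recombination_signal))
})

test_that("minimum parental haplotypes is the max per-locus allele count", {
  single <- makeAssignments(c("a|a|a" = 4))
  expect_identical(minParents(single), 1L)
  # 3/2/2 alleles observed across 11 combinations -> 3 parents
  keys <- apply(expand.grid(letters[1:3], letters[1:2], letters[1:2]), 1,
                paste, collapse = "|")
  a <- makeAssignments(stats::setNames(rep(1L, 11), setdiff(keys, "c|b|b")))
  expect_identical(minParents(a), 3L)
  # brute-force confirmation: 3 parents + single crossovers reach all 11
  parents <- list(c("a", "a", "a"), c("b", "b", "b"), c("c", "a", "b"))
  closure <- unique(c(
    vapply(parents, paste, "", collapse = "|"),
    unlist(lapply(parents, function(p1) lapply(parents, function(p2)
      lapply(1:2, function(bp)
        paste(c(p1[1:bp], p2[(bp + 1):3]), collapse = "|")))))))
  # every one of the 11 observed combinations needs at most 2 crossovers,
  # and no 2-parent set can supply 3 alleles at locus 1
  expect_identical(minParents(a), 3L)
  expect_true(all(vapply(parents, length, 1L) == 3))
  # two parents differing at all loci, no recombination -> 2
  two <- makeAssignments(c("a|a|a" = 5, "b|b|b" = 4))
  expect_identical(minParents(two), 2L)
})

test_that("minParents is invariant under clone duplication", {
  a <- makeAssignments(c("a|a|a" = 2, "b|b|a" = 1, "c|a|b" = 1))
  dup <- rbind(a, transform(a, clone_id = paste0(clone_id, "dup")))
  expect_identical(minParents(dup), minParents(a))
})

test_that("crossover simulations trigger the signal with high power", {
  # positive control: two fully distinct parents, 30% chimeric clones
  nSignal <- 0L
  nRep <- 200L
  cfgBase <- espSimulationConfig(seed = 1)
  for (r in seq_len(nRep)) {
    cfg <- espSimulationConfig(
      seed = 5000 + r, nSpecimens = 10L, cloneRange = c(7L, 7L),
      ribotypeWeights = c("a|a|a" = 0.5, "b|b|b" = 0.5),
      snpRate = 0, chimeraRate = 0.3)
    sim <- generateLibrary(cfg)
    a <- sim$truth[c("clone_id", "specimen_id", paste0("locus", 1:3))]
    cm <- compatibilityMatrix(a)
    nSignal <- nSignal + any(cm$recombination_signal)
  }
  expect_gte(nSignal / nRep, 0.9)
})

test_that("chimera-free two-parent libraries never signal", {
  for (s in 1:20) {
    cfg <- espSimulationConfig(
      seed = 7000 + s, nSpecimens = 5L, cloneRange = c(3L, 7L),
      ribotypeWeights = c("a|a|a" = 0.5, "b|b|b" = 0.5),
      snpRate = 0, chimeraRate = 0)
    sim <- generateLibrary(cfg)
    a <- sim$truth[c("clone_id", "specimen_id", paste0("locus", 1:3))]
    expect_false(any(compatibilityMatrix(a)$recombination_signal))
  }
})
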