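test_that("ribotype space size is the product of per-locus allele counts", {
  expect_identical(enumerateRibotypeSpace(makeCatalogs(c(L1 = 3, L2 = 2, L3 = 2))),
                   12L)
  expect_identical(enumerateRibotypeSpace(c(1, 1, 1)), 1L)
  # brute-force Cartesian enumeration oracle for (4, 3)
  combos <- expand.grid(a1 = letters[1:4], a2 = letters[1:3])
  expect_identical(enumerateRibotypeSpace(c(4, 3)), nrow(combos))
  expect_error(enumerateRibotypeSpace(list()), "no loci")
})

test_that("space size is invariant under allele relabeling", {
  ct <- makeCatalog(3)
  ct2 <- relabelAlleles(ct, c(a = "c", b = "a", c = "b"))
  expect_identical(enumerateRibotypeSpace(list(ct, ct)),
                   enumerateRibotypeSpace(list(ct2, ct)))
  # relabeling is a pure permutation of labels over the same sequences
  expect_setequal(alleleTable(ct2)$sequence, alleleTable(ct)$sequence)
})

test_that("tabulateRibotypes counts complete clones over the full space", {
  cats <- makeCatalogs(c(L1 = 2, L2 = 2, L3 = 2))
  a <- makeAssignments(c("a|a|a" = 3))
  tb <- tabulateRibotypes(a, cats)
  ab <- abundances(tb)
  expect_identical(spaceSize(tb), 8L)
  expect_identical(nrow(ab), 8L)
  expect_identical(ab$abundance[1], 3L)
  expect_identical(unlist(ab[1, c("L1", "L2", "L3")], use.names = FALSE),
                   c("a", "a", "a"))
  expect_true(all(ab$abundance[-1] == 0L))

  a2 <- makeAssignments(c("a|a|a" = 2, "b|b|b" = 1))
  tb2 <- tabulateRibotypes(a2, cats)
  expect_identical(unlist(abundances(tb2)[1, c("L1", "L2", "L3")],
                          use.names = FALSE), c("a", "a", "a"))
  expect_identical(abundances(tb2)$abundance[1:2], c(2L, 1L))
})

test_that("multinomial draws are re-tallied exactly (brute-force recount)", {
  cats <- makeCatalogs(c(L1 = 3, L2 = 2, L3 = 2))
  keys <- apply(expand.grid(letters[1:3], letters[1:2], letters[1:2]), 1,
                paste, collapse = "|")
  set.seed(101)
  draws <- sample(keys, 70, replace = TRUE,
                  prob = c(8, 4, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1) / 23)
  abund <- table(draws)
  a <- makeAssignments(stats::setNames(as.integer(abund), names(abund)))
  tb <- tabulateRibotypes(a, cats)
  obs <- observedRibotypes(tb)
  # independent tally over the same draws
  oracle <- table(draws)
  oracle <- stats::setNames(as.integer(oracle), names(oracle))
  expect_identical(obs[order(names(obs))], oracle[order(names(oracle))])
  expect_identical(sum(abundances(tb)$abundance), 70L)
})

test_that("tabulation is permutation-invariant and conserves clone count", {
  cats <- makeCatalogs(c(L1 = 2, L2 = 2))
  a <- makeAssignments(c("a|a" = 4, "b|a" = 2, "b|b" = 1), loci = c("L1", "L2"))
  set.seed(5)
  perm <- a[sample.int(nrow(a)), , drop = FALSE]
  expect_identical(abundances(tabulateRibotypes(a, cats)),
                   abundances(tabulateRibotypes(perm, cats)))
  expect_identical(sum(abundances(tabulateRibotypes(a, cats))$abundance),
                   nrow(a))
})

test_that("incomplete assignments are excluded but reported", {
  cats <- makeCatalogs(c(L1 = 2, L2 = 2))
  a <- makeAssignments(c("a|a" = 3), loci = c("L1", "L2"))
  a$L2[2] <- NA
  a$complete[2] <- FALSE
  tb <- tabulateRibotypes(a, cats)
  expect_identical(sum(abundances(tb)$abundance), 2L)
  expect_identical(incompleteClones(tb), a$clone_id[2])
})

test_that("unknown allele labels raise an error naming the clone", {
  cats <- makeCatalogs(c(L1 = 2, L2 = 2))
  a <- makeAssignments(c("a|a" = 2), loci = c("L1", "L2"))
  a$L1[2] <- "z"
  expect_error(tabulateRibotypes(a, cats), a$clone_id[2])
})

test_that("ribotype table rows are ordered by abundance then tuple", {
  cats <- makeCatalogs(c(L1 = 2, L2 = 2))
  a <- makeAssignments(c("b|b" = 2, "a|b" = 2, "b|a" = 5),
                       loci = c("L1", "L2"))
  ab <- abundances(tabulateRibotypes(a, cats))
  expect_identical(ab$abundance, c(5L, 2L, 2L, 0L))
  # tie between (a,b) and (b,b): lexicographic tuple order
  expect_identical(ab$L1[2:3], c("a", "b"))
})

test_that("specimen summaries count clones and distinct ribotypes per specimen", {
  a <- makeAssignments(c("a|a" = 3, "b|b" = 1), loci = c("L1", "L2"),
                       specimen = c("S1", "S1", "S1", "S1"))
  s <- summarizeSpecimens(a)
  expect_identical(s$n_clones, 4L)
  expect_identical(s$n_ribotypes, 2L)

  # two specimens sharing a ribotype count it independently
  a2 <- makeAssignments(c("a|a" = 2), loci = c("L1", "L2"),
                        specimen = c("S1", "S2"))
  s2 <- summarizeSpecimens(a2)
  expect_identical(s2$n_ribotypes, c(1L, 1L))

  # specimen with no complete assignment is excluded with a message
  a3 <- makeAssignments(c("a|a" = 2), loci = c("L1", "L2"),
                        specimen = c("S1", "S2"))
  a3$L1[2] <- NA
  expect_message(s3 <- summarizeSpecimens(a3), "S2")
  expect_identical(s3$specimen_id, "S1")
})

test_that("summaries on a simulated library match the generator truth tally", {
  sim <- nfSim()
  loci <- paste0("locus", 1:3)
  truthKey <- apply(sim$truth[loci], 1, paste, collapse = "|")
  oracle <- tapply(truthKey, sim$truth$specimen_id,
                   function(k) length(unique(k)))
  a <- sim$truth[c("clone_id", "specimen_id", loci)]
  s <- summarizeSpecimens(a, loci = loci)
  expect_identical(stats::setNames(s$n_ribotypes, s$specimen_id),
                   stats::setNames(as.integer(oracle), names(oracle)))
  expect_true(all(s$n_ribotypes <= s$n_clones))
})
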