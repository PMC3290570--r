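perfect <- data.frame(n_clones = 1:3, n_ribotypes = 1:3)

test_that("perfectly monotone pairs give rho = 1", {
  r <- clonesRibotypesCorrelation(perfect)
  expect_equal(r$rho, 1)
  expect_identical(r$method, "exact_permutation")
  # only 1 of 3! permutations reaches rho = 1
  expect_equal(r$p_value, 1 / 6)
})

test_that("constant input is rejected as degenerate", {
  expect_error(clonesRibotypesCorrelation(
    data.frame(n_clones = c(2, 2, 2), n_ribotypes = 1:3)), "degenerate")
})

test_that("exact permutation p matches an exhaustive all-720 oracle (n = 6)", {
  oracle <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    perms <- NULL
    # enumerate all 720 permutations by nested loops (independent oracle)
    idx <- 1:6
    rhos <- c()
    for (p in asplit(gtoolsPerms <- {
      # full enumeration via recursive expansion
      f <- function(v) if (length(v) == 1) list(v) else
        do.call(c, lapply(seq_along(v), function(i)
          lapply(f(v[-i]), function(r) c(v[i], r))))
      do.call(rbind, f(idx))
    }, 1))
      rhos <- c(rhos, cor(rx, ry[p]))
    list(rho = rho, p = mean(rhos >= rho - 1e-12))
  }
  set.seed(9)
  for (rep in 1:3) {
    x <- sample(1:7, 6, replace = TRUE)
    y <- sample(1:5, 6, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    r <- clonesRibotypesCorrelation(data.frame(n_clones = x, n_ribotypes = y))
    o <- oracle(x, y)
    expect_equal(r$rho, o$rho)
    expect_equal(r$p_value, o$p)
    expect_identical(r$n_permutations, 720L)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- sample(1:9, 7, replace = TRUE) + 1
  y <- sample(1:5, 7, replace = TRUE) + 1
  r0 <- clonesRibotypesCorrelation(data.frame(n_clones = x, n_ribotypes = y))
  r1 <- clonesRibotypesCorrelation(data.frame(n_clones = exp(x),
                                              n_ribotypes = y^3))
  expect_equal(r1$rho, r0$rho)
  expect_equal(r1$p_value, r0$p_value)
})

test_that("Monte Carlo p agrees with exact enumeration within 3 SE", {
  set.seed(12)
  x <- sample(1:7, 7, replace = TRUE)
  y <- x + sample(0:2, 7, replace = TRUE)
  exact <- clonesRibotypesCorrelation(data.frame(n_clones = x,
                                                 n_ribotypes = y))
  # force the Monte Carlo path through the internal machinery by
  # embedding the same data in a 9-point set is not equivalent; instead
  # draw Monte Carlo manually with the same statistic
  B <- 20000L
  rx <- rank(x); ry <- rank(y)
  rxn <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
  ryn <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
  set.seed(99)
  hits <- sum(replicate(B, sum(rxn * ryn[sample.int(7)])) >= exact$rho - 1e-12)
  pMC <- (1 + hits) / (1 + B)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / B)
  expect_lt(abs(pMC - exact$p_value), 3 * se + 1 / B)
})

test_that("chi-square prevalence test matches hand computation", {
  r0 <- allelePrevalenceTest(c(a = 10, b = 10))
  expect_equal(r0$chisq_statistic, 0)
  expect_equal(r0$p_chisq, 1)
  # counts 24/13/33: sum((o-e)^2/e) with e = 70/3
  r <- allelePrevalenceTest(c(a = 24, b = 13, c = 33))
  e <- 70 / 3
  expect_equal(r$chisq_statistic, sum((c(24, 13, 33) - e)^2 / e))
  expect_equal(r$chisq_statistic, 8.6)
  expect_identical(r$df, 2L)
  expect_lt(r$p_chisq, 0.05)  # pooled test rejects despite the small delta
})

test_that("a single allele is reported monomorphic without a test", {
  r <- allelePrevalenceTest(c(a = 12))
  expect_identical(r$test, "monomorphic")
  expect_null(r$chisq_statistic)
})

test_that("cluster bootstrap does not reject on a balanced library", {
  # exactly balanced pooled counts: the observed delta is 0
  sc0 <- matrix(rep(c(2L, 2L), 10), ncol = 2, byrow = TRUE)
  r0 <- allelePrevalenceTest(c(a = 20, b = 20), specimenCounts = sc0,
                             nBoot = 200, seed = 1)
  expect_equal(r0$p_bootstrap, 1)
  # library simulated under balanced parental weights
  cfg <- espSimulationConfig(seed = 1,
                             ribotypeWeights = c("a|a|a" = 0.5, "b|b|b" = 0.5),
                             snpRate = 0, chimeraRate = 0)
  sim <- generateLibrary(cfg)
  sc <- table(sim$truth$specimen_id, sim$truth$locus2)
  sc <- matrix(as.integer(sc), nrow = nrow(sc))
  r <- allelePrevalenceTest(stats::setNames(colSums(sc), c("a", "b")),
                            specimenCounts = sc, nBoot = 1000, seed = 1)
  expect_gt(r$p_bootstrap, 0.05)
})

test_that("rarefaction equals exhaustive subsample averaging for n <= 8", {
  exhaustive <- function(key, k) {
    subs <- combn(length(key), k)
    mean(apply(subs, 2, function(i) length(unique(key[i]))))
  }
  key <- c("A", "A", "A", "B", "B", "C", "D", "D")
  a <- makeAssignments(stats::setNames(as.integer(table(key)),
                                       paste0(names(table(key)), "|x")),
                       loci = c("L1", "L2"))
  cur <- ribotypeSaturation(a, nBoot = 0)
  pooled <- cur[cur$scope == "pooled", ]
  for (k in 1:8)
    expect_equal(pooled$expected[pooled$depth == k], exhaustive(key, k))
})

test_that("degenerate and identity rarefaction cases", {
  one <- makeAssignments(c("a|a" = 5), loci = c("L1", "L2"))
  cur <- ribotypeSaturation(one, nBoot = 0)
  expect_true(all(cur$expected[cur$scope == "pooled"] == 1))
  mix <- makeAssignments(c("a|a" = 4, "b|a" = 2, "b|b" = 1),
                         loci = c("L1", "L2"))
  cur2 <- ribotypeSaturation(mix, nBoot = 0)
  pooled <- cur2[cur2$scope == "pooled", ]
  expect_equal(pooled$expected[pooled$depth == 7], 3)  # full depth = richness
})

test_that("rarefaction curves are monotone non-decreasing and concave", {
  set.seed(17)
  for (rep in 1:5) {
    counts <- rmultinom(1, 30, prob = runif(6))[, 1]
    counts <- counts[counts > 0]
    keys <- paste0(letters[seq_along(counts)], "|x")
    a <- makeAssignments(stats::setNames(as.integer(counts), keys),
                         loci = c("L1", "L2"))
    e <- ribotypeSaturation(a, nBoot = 0)
    e <- e$expected[e$scope == "pooled"]
    d1 <- diff(e)
    expect_true(all(d1 >= -1e-9))
    expect_true(all(diff(d1) <= 1e-9))
  }
})
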