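#' @include AllClasses.R AllGenerics.R core-model.R
NULL

# ---- Spearman correlation with permutation p -------------------------------

# All permutations of the integers 1..n as an (n! x n) index matrix.
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(i, m, deparse.level = 0L)
  }))
}

#' Spearman correlation between clone number and ribotype richness
#'
#' Tie-corrected Spearman rank correlation between the number of clones
#' sequenced per specimen and the number of distinct ribotypes observed,
#' with a one-sided (positive association: more sampling reveals more
#' ribotypes) permutation p-value: exact enumeration of all n!
#' permutations when n! <= 40320 (n <= 8), otherwise Monte Carlo with a
#' fixed seed.  The asymptotic t-approximation is reported alongside for
#' reference.
#'
#' @param summaries A `data.frame` from [summarizeSpecimens()] (columns
#'   `n_clones`, `n_ribotypes`), or any data.frame whose first two
#'   numeric columns are the paired variables.
#' @param nPermutations Monte Carlo draws when exact enumeration is not
#'   feasible (default 10000).
#' @param seed RNG seed for the Monte Carlo path.
#' @return A list of class `espCorrelation`: `rho`, `p_value`, `method`
#'   (`"exact_permutation"` or `"monte_carlo"`), `n`, `p_asymptotic`,
#'   `n_permutations`, `seed`.
#' @export
clonesRibotypesCorrelation <- function(summaries, nPermutations = 10000L,
                                       seed = 1L) {
  if (all(c("n_clones", "n_ribotypes") %in% names(summaries))) {
    x <- summaries$n_clones
    y <- summaries$n_ribotypes
  } else {
    num <- which(vapply(summaries, is.numeric, logical(1)))[1:2]
    x <- summaries[[num[1L]]]
    y <- summaries[[num[2L]]]
  }
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 specimens")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("degenerate ranks: a variable is constant")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  rxn <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
  ryn <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
  eps <- 1e-12
  if (factorial(n) <= 40320) {
    P <- .allPermutations(n)
    rhoPerm <- as.vector(matrix(ryn[P], nrow = nrow(P)) %*% rxn)
    p <- mean(rhoPerm >= rho - eps)
    method <- "exact_permutation"
    nPermutations <- nrow(P)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPermutations))
      hits <- hits + (sum(rxn * ryn[sample.int(n)]) >= rho - eps)
    p <- (1 + hits) / (1 + nPermutations)
    method <- "monte_carlo"
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, eps))
  structure(list(
    rho = rho, p_value = p, method = method, n = n,
    p_asymptotic = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
    n_permutations = nPermutations, seed = seed
  ), class = "espCorrelation")
}

#' @export
print.espCorrelation <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.3f (n = %d)\none-sided p = %.4g [%s, %d permutations]; asymptotic p = %.4g\n",
    x$rho, x$n, x$p_value, x$method, x$n_permutations, x$p_asymptotic))
  invisible(x)
}

# ---- allele prevalence -----------------------------------------------------

#' Test for prevalence of one block allele over the others at a locus
#'
#' Two complementary views are reported.  (1) A chi-square
#' goodness-of-fit of the pooled allele counts against a uniform
#' distribution (df = k - 1) — simple, but it treats clones as
#' independent although clones within a specimen sample the same genome.
#' (2) A specimen-level cluster bootstrap: specimens are resampled with
#' replacement `nBoot` times and the difference between the most and
#' least frequent allele is re-computed; the bootstrap p is the fraction
#' of null-shifted replicates at or above the observed difference.
#'
#' @param counts Named integer vector of pooled allele counts, or an
#'   [AlleleCatalog-class].
#' @param specimenCounts Optional integer matrix (specimens x alleles) of
#'   per-specimen allele counts, enabling the cluster bootstrap.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `espPrevalenceTest`: `counts`, `chisq_statistic`,
#'   `df`, `p_chisq`, and when `specimenCounts` is given `delta_observed`
#'   (max minus min allele frequency) and `p_bootstrap`.  A single-allele
#'   locus returns `test = "monomorphic"` and no statistic.
#' @export
allelePrevalenceTest <- function(counts, specimenCounts = NULL,
                                 nBoot = 1000L, seed = 1L) {
  if (is(counts, "AlleleCatalog"))
    counts <- stats::setNames(alleleTable(counts)$count,
                              alleleTable(counts)$label)
  counts <- counts[!is.na(counts)]
  if (sum(counts) < 1L)
    stop("total allele count must be at least 1")
  if (length(counts) < 2L)
    return(structure(list(test = "monomorphic", counts = counts),
                     class = "espPrevalenceTest"))
  cs <- suppressWarnings(stats::chisq.test(counts))
  out <- list(test = "chisq_uniform", counts = counts,
              chisq_statistic = unname(cs$statistic),
              df = as.integer(cs$parameter), p_chisq = unname(cs$p.value))
  if (!is.null(specimenCounts)) {
    stopifnot(ncol(specimenCounts) == length(counts))
    dObs <- .prevalenceDelta(colSums(specimenCounts))
    set.seed(seed)
    nSp <- nrow(specimenCounts)
    dStar <- vapply(seq_len(nBoot), function(b) {
      pooled <- colSums(specimenCounts[sample.int(nSp, replace = TRUE), ,
                                       drop = FALSE])
      if (sum(pooled) == 0) NA_real_ else .prevalenceDelta(pooled)
    }, numeric(1))
    # bootstrap distribution recentred at the uniform null (delta = 0)
    out$delta_observed <- dObs
    out$p_bootstrap <- mean(dStar - dObs >= dObs, na.rm = TRUE)
    out$n_boot <- nBoot
    out$seed <- seed
  }
  structure(out, class = "espPrevalenceTest")
}

.prevalenceDelta <- function(pooled) {
  p <- pooled / sum(pooled)
  max(p) - min(p)
}

#' @export
print.espPrevalenceTest <- function(x, ...) {
  if (identical(x$test, "monomorphic")) {
    cat("monomorphic locus: no prevalence test\n")
    return(invisible(x))
  }
  cat(sprintf("pooled chi-square = %.4g (df = %d), p = %.4g\n",
              x$chisq_statistic, x$df, x$p_chisq))
  if (!is.null(x$p_bootstrap))
    cat(sprintf(
      "cluster bootstrap: max-min frequency difference = %.3f, p = %.4g (%d replicates)\n",
      x$delta_observed, x$p_bootstrap, x$n_boot))
  invisible(x)
}

# ---- rarefaction -----------------------------------------------------------

#' Ribotype-richness rarefaction (saturation) curves
#'
#' Expected number of distinct ribotypes at every subsample size 1..n
#' (analytic hypergeometric rarefaction, via [vegan::rarefy()]), pooled
#' over all complete clones and per specimen, with a clone-resampling
#' bootstrap confidence band on the pooled curve.  A rising curve at full
#' depth indicates that ribotype richness is undersampled.
#'
#' @param assignments A `data.frame` from [assignRibotypes()].
#' @param nBoot Bootstrap replicates for the pooled confidence band
#'   (default 200).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @param loci Locus columns; default inferred as in
#'   [summarizeSpecimens()].
#' @return A `data.frame` with columns `scope` (`"pooled"` or a specimen
#'   id), `depth`, `expected`, `lo`, `hi` (bootstrap band, pooled scope
#'   only).
#' @export
ribotypeSaturation <- function(assignments, nBoot = 200L, seed = 1L,
                               conf = 0.95, loci = NULL) {
  if (is.null(loci))
    loci <- setdiff(names(assignments), c("clone_id", "specimen_id", "complete"))
  complete <- !Reduce(`|`, lapply(assignments[loci], is.na))
  if (!any(complete))
    stop("no complete assignment")
  key <- do.call(.tupleKey, assignments[loci])[complete]
  spec <- assignments$specimen_id[complete]
  pooled <- .rarefactionCurve(key)
  pooled$scope <- "pooled"
  if (nBoot > 0L && length(key) > 1L) {
    set.seed(seed)
    boot <- vapply(seq_len(nBoot), function(b)
      .rarefactionCurve(sample(key, replace = TRUE))$expected,
      numeric(nrow(pooled)))
    a <- (1 - conf) / 2
    qs <- apply(boot, 1L, stats::quantile, probs = c(a, 1 - a))
    pooled$lo <- qs[1L, ]
    pooled$hi <- qs[2L, ]
  } else {
    pooled$lo <- NA_real_
    pooled$hi <- NA_real_
  }
  perSpec <- lapply(unique(spec), function(s) {
    cur <- .rarefactionCurve(key[spec == s])
    cur$scope <- s
    cur$lo <- NA_real_
    cur$hi <- NA_real_
    cur
  })
  out <- do.call(rbind, c(list(pooled), perSpec))
  out[, c("scope", "depth", "expected", "lo", "hi")]
}

.rarefactionCurve <- function(key) {
  counts <- as.integer(table(key))
  n <- sum(counts)
  # rarefy emits an advisory whenever the rarest type has count > 1
  exp <- as.numeric(suppressWarnings(
    vegan::rarefy(matrix(counts, nrow = 1L), sample = 1:n)))
  data.frame(depth = 1:n, expected = exp)
}
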