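#' Exact Hardy-Weinberg test (Levene's conditional distribution)
#'
#' Probability test for deviation from Hardy-Weinberg proportions at a
#' multi-allelic locus. Conditionally on the observed allele counts, a
#' genotype table `{n_g}` with `h` heterozygotes has probability
#' `P = n! 2^h prod_a(c_a!) / (prod_g(n_g!) (2n)!)` (Levene); the p-value
#' sums the probabilities of all tables no more probable than the observed
#' one. Tables are fully enumerated while their number stays below
#' `enum_limit`; beyond that a Monte-Carlo sample is drawn by randomly
#' re-pairing the observed gene copies, which samples exactly this
#' conditional distribution.
#'
#' @param a1,a2 allele vectors of the typed genotypes (one entry per
#'   individual; `NA` pairs are dropped), or pass a two-column matrix as
#'   `a1`.
#' @param method `"auto"` (default), `"enumeration"`, or `"montecarlo"`.
#' @param mc_reps Monte-Carlo replicates.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param enum_limit largest table count still enumerated under
#'   `method = "auto"`.
#' @return list with `p`, `method` (`"enumeration"` or `"montecarlo"`),
#'   `n_tables` (enumerated tables, `NA` for Monte-Carlo), `se`
#'   (Monte-Carlo standard error, `NA` for enumeration).
#' @export
hwe_exact_test <- function(a1, a2 = NULL, method = c("auto", "enumeration",
                                                     "montecarlo"),
                           mc_reps = 10000L, seed = 1L, enum_limit = 1e5) {
  method <- match.arg(method)
  if (is.null(a2)) {
    stopifnot(is.matrix(a1), ncol(a1) == 2L)
    a2 <- a1[, 2]; a1 <- a1[, 1]
  }
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0L) stop("no typed genotypes")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) stop("monomorphic locus: exact test undefined")
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  counts <- tabulate(c(i1, i2), nbins = k)      # allele counts, sum = 2n
  lg <- lgamma(seq_len(2L * n + 1L))            # lg[m+1] = log(m!)
  base <- lg[n + 1L] + sum(lg[counts + 1L]) - lg[2L * n + 1L]
  log_prob <- function(lo, hi) {
    # vectorized Levene log-probability from genotype index pairs
    key <- (lo - 1L) * k + hi
    cnt <- tabulate(key, nbins = k * k)
    base + sum(lo != hi) * log(2) - sum(lg[cnt + 1L])
  }
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  log_p_obs <- log_prob(lo, hi)

  do_enum <- switch(method,
    enumeration = TRUE,
    montecarlo = FALSE,
    enum_feasible(counts, enum_limit))
  if (do_enum) {
    logs <- enumerate_tables(counts, n,
                             limit = if (method == "enumeration") Inf
                             else enum_limit)
    if (!is.null(logs)) {
      p <- sum(exp(logs[logs <= log_p_obs + 1e-9]))
      return(list(p = min(1, p), method = "enumeration",
                  n_tables = length(logs), se = NA_real_))
    }
    if (method == "enumeration") stop("too many tables to enumerate")
  }
  # Monte-Carlo: re-pair the 2n observed gene copies uniformly at random
  copies <- c(i1, i2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  thresh <- log_p_obs + 1e-9
  for (r in seq_len(mc_reps)) {
    perm <- sample(copies)
    g1 <- perm[seq_len(n)]; g2 <- perm[n + seq_len(n)]
    if (log_prob(pmin(g1, g2), pmax(g1, g2)) <= thresh) hits <- hits + 1L
  }
  p <- hits / mc_reps
  list(p = p, method = "montecarlo", n_tables = NA_integer_,
       se = sqrt(p * (1 - p) / mc_reps))
}

# quick feasibility screen for full enumeration: exact closed form for two
# alleles; otherwise a product-of-caps overbound (cheap, conservative in the
# sense that a huge bound sends the test down the Monte-Carlo path)
enum_feasible <- function(counts, limit) {
  k <- length(counts)
  if (k == 2L) return(min(counts) %/% 2L + 1L <= limit)
  caps <- numeric(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      caps <- c(caps, (if (i == j) counts[i] %/% 2L else min(counts[i],
                                                            counts[j])) + 1)
    }
  }
  prod(caps) <= 100 * limit
}

# log Levene probability of a genotype count table (upper-triangular matrix)
levene_log_prob <- function(tab, counts, n) {
  h <- sum(tab[upper.tri(tab)])
  lfact(n) + h * log(2) + sum(lfact(counts)) -
    sum(lfact(tab[upper.tri(tab, diag = TRUE)])) - lfact(2 * n)
}

# Enumerate every genotype table consistent with the allele counts; returns
# the vector of log-probabilities, or NULL once `limit` tables are exceeded.
enumerate_tables <- function(counts, n, limit = 1e5) {
  k <- length(counts)
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  # last pair index in which each allele participates, for pruning
  last_use <- vapply(seq_len(k), function(a) {
    max(which(pairs[, 1] == a | pairs[, 2] == a))
  }, integer(1))
  logs <- numeric(0)
  aborted <- FALSE
  tab <- matrix(0L, k, k)
  recurse <- function(idx, rem) {
    if (aborted) return()
    if (idx > nrow(pairs)) {
      if (all(rem == 0L)) {
        if (length(logs) >= limit) { aborted <<- TRUE; return() }
        logs[length(logs) + 1L] <<- levene_log_prob(tab, counts, n)
      }
      return()
    }
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    cap <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (x in 0:cap) {
      tab[i, j] <<- x
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * x
      else { rem2[i] <- rem2[i] - x; rem2[j] <- rem2[j] - x }
      # prune: an allele whose pairs are all placed must be used up
      if ((last_use[i] == idx && rem2[i] != 0L) ||
          (last_use[j] == idx && rem2[j] != 0L)) next
      recurse(idx + 1L, rem2)
      if (aborted) break
    }
    tab[i, j] <<- 0L
  }
  recurse(1L, counts)
  if (aborted) return(NULL)
  logs
}
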