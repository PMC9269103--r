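#' Allele frequencies at one locus
#'
#' Frequencies over the `2 * n_typed` gene copies of individuals with a
#' complete call; missing individuals drop out of the denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus label or index.
#' @return named numeric vector of allele frequencies (names = allele
#'   sizes), summing to 1.
#' @export
allele_frequencies <- function(gm, locus) {
  al <- locus_alleles(gm, locus)
  if (!length(al)) stop("all calls missing at locus ", locus)
  tab <- table(al)
  setNames(as.numeric(tab) / length(al), names(tab))
}

# gene copies (typed individuals only) at one locus
locus_alleles <- function(gm, locus) {
  a1 <- gm$a1[, locus]; a2 <- gm$a2[, locus]
  ok <- !is.na(a1)
  c(a1[ok], a2[ok])
}

#' Observed heterozygosity at one locus
#'
#' Share of typed individuals carrying two different alleles.
#'
#' @inheritParams allele_frequencies
#' @return numeric in `[0, 1]`.
#' @export
observed_heterozygosity <- function(gm, locus) {
  a1 <- gm$a1[, locus]; a2 <- gm$a2[, locus]
  ok <- !is.na(a1)
  if (!any(ok)) stop("all calls missing at locus ", locus)
  mean(a1[ok] != a2[ok])
}

#' Expected heterozygosity (gene diversity)
#'
#' `1 - sum(p_i^2)`, by default with the small-sample (unbiased)
#' correction `2n / (2n - 1)` where `n` is the number of typed
#' individuals.
#'
#' @param freqs allele frequency vector (see [allele_frequencies()]).
#' @param n_typed number of typed individuals (needed for the correction).
#' @param unbiased apply the small-sample correction (default).
#' @return numeric in `[0, 1]`.
#' @export
expected_heterozygosity <- function(freqs, n_typed = NULL, unbiased = TRUE) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9, all(freqs >= 0))
  h <- 1 - sum(freqs^2)
  if (!unbiased) return(h)
  if (is.null(n_typed) || n_typed < 2) {
    stop("unbiased expected heterozygosity needs n_typed >= 2")
  }
  2 * n_typed / (2 * n_typed - 1) * h
}

#' Inbreeding coefficient from the heterozygote deficit
#'
#' `F_IS = 1 - Ho / He`; undefined (`NA`) for a monomorphic locus
#' (`He = 0`).
#'
#' @param ho,he observed and expected heterozygosity.
#' @return numeric, or `NA` when `he == 0`.
#' @export
inbreeding_coefficient <- function(ho, he) {
  ifelse(he > 0, 1 - ho / he, NA_real_)
}

#' Null-allele frequency estimators
#'
#' Two standard heterozygote-deficit estimators: Chakraborty,
#' `(He - Ho) / (He + Ho)`, and Brookfield's first,
#' `(He - Ho) / (1 + He)`. Negative estimates are floored at 0.
#'
#' @param ho,he observed and expected heterozygosity (`he + ho > 0`).
#' @param estimator `"chakraborty"`, `"brookfield1"`, or `"both"`.
#' @return named numeric vector of the requested estimate(s).
#' @export
null_allele_frequency <- function(ho, he, estimator = c("both", "chakraborty",
                                                        "brookfield1")) {
  estimator <- match.arg(estimator)
  if (he + ho <= 0) stop("null-allele estimators need He + Ho > 0")
  out <- c(chakraborty = max(0, (he - ho) / (he + ho)),
           brookfield1 = max(0, (he - ho) / (1 + he)))
  if (estimator == "both") out else out[estimator]
}

#' Polymorphic information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param freqs allele frequency vector.
#' @return numeric in `[0, 1)`.
#' @export
pic <- function(freqs) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  p2 <- freqs^2
  # sum_{i<j} p_i^2 p_j^2 = ((sum p^2)^2 - sum p^4) / 2
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

#' Probability of identity at one locus
#'
#' Chance that two random individuals share a genotype under random
#' mating: `PI = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`.
#'
#' @param freqs allele frequency vector.
#' @return numeric in `(0, 1]`.
#' @export
probability_of_identity <- function(freqs) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  p2 <- freqs^2
  sum(p2^2) + 2 * (sum(p2)^2 - sum(p2^2))
}

#' Combined probability of identity across loci
#'
#' @param pi_values per-locus PI values.
#' @return their product.
#' @export
combined_pi <- function(pi_values) {
  if (!length(pi_values)) stop("no loci supplied")
  prod(pi_values)
}

#' Sequential Bonferroni (Holm) rejection flags
#'
#' Step-down correction: sorted ascending, `p_(i)` is rejected while
#' `p_(i) <= alpha / (m - i + 1)`; the first failure stops the procedure.
#'
#' @param p p-value vector (`NA`s allowed; never rejected, excluded from
#'   `m`).
#' @param alpha family-wise error rate.
#' @return logical vector of rejections in input order.
#' @export
holm_correction <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p.adjust(p, method = "holm")
  out <- !is.na(adj) & adj <= alpha
  out
}

#' Per-locus marker characterization
#'
#' Computes the full per-locus statistics table from a diploid genotype
#' matrix: typed count, allele number, observed and unbiased expected
#' heterozygosity, inbreeding coefficient, exact Hardy-Weinberg p-value
#' with sequential-Bonferroni significance across loci, both null-allele
#' estimators, polymorphic information content and probability of
#' identity.
#'
#' @param gm a [genotype_matrix()].
#' @param alpha family-wise error rate for the Hardy-Weinberg tests.
#' @param mc_reps Monte-Carlo replicates for loci too allele-rich to
#'   enumerate (see [hwe_exact_test()]).
#' @param seed seed for the Monte-Carlo fallback.
#' @param hwe set `FALSE` to skip the Hardy-Weinberg tests (useful in bulk
#'   simulation studies where only the diversity columns are needed).
#' @return `data.frame`, one row per locus: `locus`, `n_typed`, `na`,
#'   `ho`, `he`, `fis`, `hwe_p`, `hwe_significant`, `fnull_chakraborty`,
#'   `fnull_brookfield`, `pic`, `pi`.
#' @export
locus_stats <- function(gm, alpha = 0.05, mc_reps = 10000L, seed = 1L,
                        hwe = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- lapply(gm$loci, function(l) {
    fr <- allele_frequencies(gm, l)
    nt <- sum(!is.na(gm$a1[, l]))
    ho <- observed_heterozygosity(gm, l)
    he <- if (nt >= 2) expected_heterozygosity(fr, nt) else 0
    fn <- if (he + ho > 0) null_allele_frequency(ho, he) else
      c(chakraborty = NA_real_, brookfield1 = NA_real_)
    p <- if (hwe && length(fr) >= 2) {
      hwe_exact_test(gm$a1[, l], gm$a2[, l], mc_reps = mc_reps, seed = seed)$p
    } else NA_real_
    data.frame(locus = l, n_typed = nt, na = length(fr), ho = ho, he = he,
               fis = inbreeding_coefficient(ho, he), hwe_p = p,
               hwe_significant = NA,
               fnull_chakraborty = fn[["chakraborty"]],
               fnull_brookfield = fn[["brookfield1"]],
               pic = pic(fr), pi = probability_of_identity(fr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$hwe_significant <- holm_correction(out$hwe_p, alpha)
  out$hwe_significant[is.na(out$hwe_p)] <- NA
  out
}

#' Panel-level marker summary
#'
#' Aggregates a per-locus statistics table (from [locus_stats()] or an
#' externally computed table with columns `na`, `ho`, `he`, `pic`, `pi`)
#' into panel totals: allele totals and means, mean heterozygosities,
#' mean informativeness, the combined probability of identity (product
#' over loci) and informativeness classes (high `PIC > 0.70`, moderate
#' `0.44 < PIC <= 0.70`, low `PIC < 0.29`).
#'
#' @param stats per-locus statistics table.
#' @return a list of class `panel_summary`.
#' @export
summarize_panel <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1,
            all(c("na", "ho", "he", "pic", "pi") %in% names(stats)))
  structure(list(
    n_loci = nrow(stats),
    total_alleles = sum(stats$na),
    mean_na = mean(stats$na),
    mean_ho = mean(stats$ho),
    mean_he = mean(stats$he),
    mean_pic = mean(stats$pic),
    combined_pi = combined_pi(stats$pi),
    n_high_pic = sum(stats$pic > 0.70),
    n_moderate_pic = sum(stats$pic > 0.44 & stats$pic <= 0.70),
    n_low_pic = sum(stats$pic < 0.29)
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("%d loci, %d alleles (mean %.3f per locus)\n",
              x$n_loci, x$total_alleles, x$mean_na))
  cat(sprintf("mean Ho %.3f, mean He %.3f, mean PIC %.3f\n",
              x$mean_ho, x$mean_he, x$mean_pic))
  cat(sprintf("combined PI %.3g\n", x$combined_pi))
  cat(sprintf("PIC classes: %d high (>0.70), %d moderate (>0.44), %d low (<0.29)\n",
              x$n_high_pic, x$n_moderate_pic, x$n_low_pic))
  invisible(x)
}

#' Bundled marker-characterization table for Dalmatian pyrethrum
#'
#' Per-locus statistics for the 17 genomic SSR markers developed for
#' Dalmatian pyrethrum (*Tanacetum cinerariifolium*), as characterized on
#' 20 individuals of one natural population: allele number, observed and
#' expected heterozygosity, inbreeding coefficient, Hardy-Weinberg
#' significance after sequential Bonferroni correction, null-allele
#' frequency (where detected), polymorphic information content and
#' probability of identity. Useful as a realistic input for
#' [summarize_panel()].
#'
#' @return `data.frame` with columns `locus`, `na`, `ho`, `he`, `fis`,
#'   `hwe_significant`, `fnull`, `pic`, `pi`.
#' @export
tcin_marker_panel <- function() {
  path <- system.file("extdata", "tcin_marker_panel.csv",
                      package = "ssrforge", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$hwe_significant <- as.logical(tab$hwe_significant)
  tab
}
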