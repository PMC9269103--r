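test_that("allele frequencies count gene copies of typed individuals", {
  a1 <- rbind(100L, 100L)
  a2 <- rbind(100L, 102L)
  gm <- genotype_matrix(a1, a2, loci = "L1")
  fr <- allele_frequencies(gm, "L1")
  expect_equal(unname(fr), c(0.75, 0.25))
  expect_equal(names(fr), c("100", "102"))

  mono <- genotype_matrix(rbind(100L, 100L), rbind(100L, 100L), loci = "L1")
  expect_equal(unname(allele_frequencies(mono, "L1")), 1.0)

  # missing individuals leave the denominator
  gm2 <- genotype_matrix(rbind(100L, NA, 102L), rbind(100L, NA, 102L),
                         loci = "L1")
  expect_equal(sum(!is.na(gm2$a1[, 1])), 2L)
  expect_equal(unname(allele_frequencies(gm2, "L1")), c(0.5, 0.5))
  all_na <- genotype_matrix(rbind(NA_integer_), rbind(NA_integer_),
                            loci = "L1")
  expect_error(allele_frequencies(all_na, "L1"), "missing")
})

test_that("observed and expected heterozygosity follow their closed forms", {
  # 12 typed, 1 heterozygote
  a1 <- matrix(rep(100L, 12)); a2 <- matrix(c(102L, rep(100L, 11)))
  gm <- genotype_matrix(a1, a2, loci = "L1")
  expect_equal(observed_heterozygosity(gm, "L1"), 1 / 12)

  het <- genotype_matrix(matrix(rep(100L, 5)), matrix(rep(102L, 5)),
                         loci = "L1")
  expect_equal(observed_heterozygosity(het, "L1"), 1.0)
  hom <- genotype_matrix(matrix(rep(100L, 5)), matrix(rep(100L, 5)),
                         loci = "L1")
  expect_equal(observed_heterozygosity(hom, "L1"), 0.0)

  expect_equal(expected_heterozygosity(c(0.5, 0.5), 10), 20 / 19 * 0.5)
  expect_equal(expected_heterozygosity(c(0.5, 0.5), unbiased = FALSE), 0.5)
  expect_equal(expected_heterozygosity(c(1), 10), 0)
  expect_error(expected_heterozygosity(c(0.5, 0.5), 1), "n_typed")
})

test_that("FIS reproduces the published heterozygote-deficit values", {
  expect_equal(round(inbreeding_coefficient(0.167, 0.235), 2), 0.29)
  expect_equal(round(inbreeding_coefficient(0.542, 0.633), 3), 0.144)
  expect_equal(inbreeding_coefficient(0.5, 0.5), 0)
  expect_true(is.na(inbreeding_coefficient(0, 0)))
})

test_that("null-allele estimators match closed forms and floor at zero", {
  fn <- null_allele_frequency(0.333, 0.505)
  expect_equal(unname(round(fn["chakraborty"], 3)), 0.205)
  expect_equal(unname(round(fn["brookfield1"], 3)), 0.114)
  expect_equal(unname(null_allele_frequency(0.5, 0.5)), c(0, 0))
  expect_equal(unname(null_allele_frequency(0.6, 0.5)), c(0, 0))
  expect_error(null_allele_frequency(0, 0), "He \\+ Ho")
  expect_error(null_allele_frequency(0.3, 0.5, estimator = "bogus"))
})

test_that("PIC and PI follow the Botstein / identity closed forms", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(1)), 0)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_equal(probability_of_identity(c(0.5, 0.5)), 0.375)
  expect_equal(probability_of_identity(c(1)), 1.0)
  # bound checks over random frequency vectors
  set.seed(61)
  for (i in 1:20) {
    p <- as.vector(table(sample(1:6, 50, replace = TRUE))) / 50
    expect_lte(pic(p), 1 - sum(p^2))
    expect_gte(pic(p), 0)
    expect_gt(probability_of_identity(p), 0)
    expect_lte(probability_of_identity(p), 1)
  }
  expect_equal(combined_pi(c(0.5, 0.2)), 0.1)
  expect_error(combined_pi(numeric(0)), "no loci")
})

test_that("the exact HWE test agrees with enumeration on tiny tables", {
  # two heterozygotes: both tables {Aa,Aa} (2/3) and {AA,aa} (1/3) qualify
  r <- hwe_exact_test(c(1L, 1L), c(2L, 2L), method = "enumeration")
  expect_equal(r$p, 1.0)
  expect_equal(r$n_tables, 2L)
  r2 <- hwe_exact_test(c(1L, 2L), c(1L, 2L), method = "enumeration")
  expect_equal(r2$p, 1 / 3)
  expect_error(hwe_exact_test(c(1L, 1L), c(1L, 1L)), "monomorphic")
})

test_that("enumerated p matches an independent brute-force pairing oracle", {
  cases <- list(
    list(a1 = c(1L, 1L, 2L), a2 = c(1L, 2L, 2L)),
    list(a1 = c(1L, 1L, 1L, 2L), a2 = c(1L, 2L, 3L, 3L)),
    list(a1 = c(1L, 2L, 3L), a2 = c(1L, 2L, 3L)))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs$a1, cs$a2, method = "enumeration")$p,
                 hwe_brute_force(cs$a1, cs$a2), tolerance = 1e-10)
  }
})

test_that("Monte-Carlo p converges to the enumerated p", {
  set.seed(71)
  a1 <- sample(1:3, 12, replace = TRUE)
  a2 <- sample(1:3, 12, replace = TRUE)
  if (length(unique(c(a1, a2))) < 2) a2[1] <- a1[1] %% 3L + 1L
  enum <- hwe_exact_test(a1, a2, method = "enumeration")
  mc <- hwe_exact_test(a1, a2, method = "montecarlo", mc_reps = 20000L,
                       seed = 5L)
  expect_equal(mc$method, "montecarlo")
  expect_lt(abs(mc$p - enum$p), 2 * mc$se + 1e-6)
  # reproducible under the same seed
  mc2 <- hwe_exact_test(a1, a2, method = "montecarlo", mc_reps = 20000L,
                        seed = 5L)
  expect_identical(mc$p, mc2$p)
})

test_that("Holm sequential correction rejects stepwise and stops", {
  expect_equal(holm_correction(c(0.01, 0.2, 0.03)), c(TRUE, FALSE, FALSE))
  expect_equal(holm_correction(rep(1, 5)), rep(FALSE, 5))
  expect_equal(holm_correction(0.04), TRUE)
  expect_equal(holm_correction(c(0.001, 0.06, 0.012)),
               c(TRUE, FALSE, TRUE))   # 0.012 <= 0.05/2 keeps the chain alive
})

test_that("locus_stats reproduces hand-computed statistics end to end", {
  # 4 individuals, one locus: genotypes {100/100, 100/102, 100/102, 102/102}
  gm <- genotype_matrix(matrix(c(100L, 100L, 100L, 102L)),
                        matrix(c(100L, 102L, 102L, 102L)), loci = "L1")
  st <- locus_stats(gm)
  expect_equal(st$n_typed, 4L)
  expect_equal(st$na, 2L)
  expect_equal(st$ho, 0.5)
  expect_equal(st$he, 8 / 7 * 0.5)
  expect_equal(st$fis, 1 - 0.5 / (8 / 7 * 0.5))
  expect_equal(st$pic, 0.375)
  expect_equal(st$pi, 0.375)
  expect_false(st$hwe_significant)
})

test_that("parameter recovery under HWE and under null alleles (property)", {
  freqs <- lapply(1:6, function(l) setNames(rep(0.25, 4), c(100, 102, 104, 106)))
  sim <- simulate_genotypes(list(freqs), n_per_pop = 200, seed = 81)
  st <- locus_stats(sim$gm, hwe = FALSE)
  he_true <- expected_heterozygosity(rep(0.25, 4), unbiased = FALSE)
  expect_true(all(abs(st$he - he_true) < 0.05))
  expect_lt(abs(mean(st$fis)), 0.05)

  # null-allele rate 0.2: positive estimates, brookfield1 near the rate
  reps <- vapply(1:50, function(r) {
    s <- simulate_genotypes(list(freqs[1:2]), n_per_pop = 200,
                            null_rate = 0.2, seed = 1000 + r)
    st <- locus_stats(s$gm, hwe = FALSE)
    c(mean(st$fnull_chakraborty), mean(st$fnull_brookfield))
  }, numeric(2))
  expect_true(all(reps > 0))
  expect_lt(abs(mean(reps[2, ]) - 0.2), 0.07)
})

test_that("panel summary matches the bundled marker panel aggregates", {
  tab <- tcin_marker_panel()
  expect_equal(nrow(tab), 17L)
  panel <- summarize_panel(tab)
  expect_equal(panel$total_alleles, 94L)
  expect_equal(round(panel$mean_na, 2), 5.53)
  expect_equal(round(panel$mean_he, 3), 0.545)
  expect_equal(round(panel$mean_pic, 3), 0.492)
  expect_equal(signif(panel$combined_pi, 2), 1.9e-11)
  expect_equal(panel$n_high_pic, 2L)
  expect_equal(panel$n_moderate_pic, 8L)
  expect_equal(panel$n_low_pic, 4L)
  # single locus: totals equal that locus
  one <- summarize_panel(tab[3, ])
  expect_equal(one$total_alleles, tab$na[3])
  expect_equal(one$combined_pi, tab$pi[3])
})
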