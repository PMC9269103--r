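# builds one candidate row with every annotation under direct control
cand_row <- function(id = "c1", unit_len = 2L, repeats = 10L, gc = 0.40,
                     coverage = 12, multimap = 0.1, length = 150L,
                     occurrences = 1L, repeat_hit = FALSE, compound = FALSE,
                     start = 61L) {
  end <- start + unit_len * repeats - 1L
  data.frame(contig_id = id, start = start, end = end,
             motif = substr("ACGTAG", 1L, unit_len),
             unit_len = unit_len, repeats = repeats, class = "x",
             compound = compound, length = length, gc = gc,
             mean_coverage = coverage, multimap_fraction = multimap,
             left_flank = start - 1L, right_flank = length - end,
             repeat_hit = repeat_hit, genome_occurrences = occurrences,
             status = NA_character_, criterion = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("gc_fraction counts G+C over A/C/G/T with N excluded", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_equal(gc_fraction("ACGTN"), 0.5)
  expect_error(gc_fraction("NNN"), "no A/C/G/T")
})

test_that("genome occurrence counting applies identity/coverage and collapses", {
  hit <- function(q_start, q_end, s_start, s_end, subj = "g1", ident = 99) {
    data.frame(query_id = "q1", subject_id = subj, pct_identity = ident,
               align_len = q_end - q_start + 1L, mismatches = 0L,
               gap_opens = 0L, q_start = q_start, q_end = q_end,
               s_start = s_start, s_end = s_end, evalue = 1e-30,
               bit_score = 200, strand = "+", stringsAsFactors = FALSE)
  }
  none <- hit(1, 100, 1, 100)[0, ]
  expect_equal(count_genome_occurrences(none, query_len = 100), 0L)
  two <- rbind(hit(1, 100, 1000, 1099), hit(1, 100, 5000, 5099))
  expect_equal(count_genome_occurrences(two, query_len = 100), 2L)
  # split alignment to the same subject interval collapses to one
  split <- rbind(hit(1, 95, 1000, 1094), hit(3, 98, 1002, 1097))
  expect_equal(count_genome_occurrences(split, query_len = 100), 1L)
  # weak hits do not count
  weak <- rbind(hit(1, 100, 1000, 1099, ident = 85),
                hit(1, 60, 5000, 5059))
  expect_equal(count_genome_occurrences(weak, query_len = 100), 0L)
})

test_that("the cascade passes a candidate satisfying every window", {
  res <- apply_filters(cand_row())
  expect_equal(res$status, "PASS")
  expect_true(is.na(res$criterion))
})

test_that("each violation is attributed to the first failing criterion", {
  cases <- list(
    list(cand_row(compound = TRUE), 1L),
    list(cand_row(repeat_hit = TRUE), 2L),
    list(cand_row(multimap = 0.8), 3L),
    list(cand_row(coverage = 40), 4L),      # outside 0.5-2x of 12.5
    list(cand_row(coverage = 5), 4L),
    list(cand_row(length = 120L, start = 31L), 4L),  # "more than 130" fails
    list(cand_row(start = 10L), 4L),        # flank below 30 nt
    list(cand_row(occurrences = 3L), 5L),
    list(cand_row(occurrences = 0L), 5L),
    list(cand_row(unit_len = 4L, repeats = 6L), 6L),
    list(cand_row(gc = 0.20), 7L),
    list(cand_row(gc = 0.60), 7L),
    # order: a compound candidate that also fails GC reports criterion 1
    list(cand_row(compound = TRUE, gc = 0.20), 1L),
    list(cand_row(repeat_hit = TRUE, occurrences = 5L), 2L))
  for (cs in cases) {
    expect_equal(apply_filters(cs[[1]])$criterion, cs[[2]])
  }
  # boundary: 131 nt ("more than 130") passes, GC exactly at the edge passes
  expect_equal(apply_filters(cand_row(length = 145L, start = 31L,
                                      repeats = 10L))$status, "PASS")
  expect_equal(apply_filters(cand_row(gc = 0.53))$status, "PASS")
  expect_equal(apply_filters(cand_row(gc = 0.33))$status, "PASS")
})

test_that("filtering is order-stable and idempotent (property)", {
  cohort <- do.call(rbind, list(
    cand_row("a"), cand_row("b", compound = TRUE), cand_row("c", gc = 0.2),
    cand_row("d", occurrences = 3L), cand_row("e", multimap = 0.9),
    cand_row("f", unit_len = 4L, repeats = 6L)))
  res <- apply_filters(cohort)
  for (perm in list(6:1, c(3, 1, 5, 2, 6, 4))) {
    res2 <- apply_filters(cohort[perm, ])
    expect_equal(res2$criterion[order(res2$contig_id)],
                 res$criterion[order(res$contig_id)])
  }
  pass <- res[res$status == "PASS", ]
  again <- apply_filters(pass)
  expect_equal(again$status, pass$status)
  expect_equal(sum(attr(res, "attrition")), 5L)
})

test_that("missing coverage annotation is a named error", {
  bad <- cand_row()
  bad$mean_coverage <- NA_real_
  expect_error(apply_filters(bad), "c1")
})

test_that("ranking prefers longer repeats, then GC proximity, then contig id", {
  cohort <- rbind(cand_row("a", repeats = 12L),
                  cand_row("b", repeats = 8L, start = 61L),
                  cand_row("c", repeats = 8L, gc = 0.50),
                  cand_row("d", repeats = 8L, gc = 0.44))
  cohort$end <- cohort$start + cohort$unit_len * cohort$repeats - 1L
  cohort$right_flank <- cohort$length - cohort$end
  res <- rank_candidates(apply_filters(cohort))
  expect_equal(res$contig_id[1], "a")                    # 12 repeats first
  expect_lt(which(res$contig_id == "d"), which(res$contig_id == "c"))
  # identical keys fall back to contig id order
  ties <- rank_candidates(apply_filters(rbind(cand_row("z"), cand_row("y"))))
  expect_equal(ties$contig_id, c("y", "z"))
})

test_that("ssr_summary accounts contigs and the single-SSR percentage", {
  expect_equal(single_ssr_percentage(31380, 3272), 89.6)
  expect_equal(single_ssr_percentage(10, 0), 100.0)
  expect_equal(single_ssr_percentage(4, 1), 75.0)

  plan <- data.frame(contig = c(1, 2, 2), motif = c("AC", "AG", "TA"),
                     repeats = c(9, 9, 10), start = c(NA, 30, 200))
  sim <- simulate_contigs(3, length = 400, ssrs = plan, seed = 31)
  s <- ssr_summary(find_ssrs(sim$contigs), sim$contigs)
  expect_equal(s$total_contigs, 3L)
  expect_equal(s$ssr_contigs, 2L)
  expect_equal(s$multi_ssr_contigs, 1L)
  expect_equal(s$total_ssrs, 3L)
  expect_equal(s$single_ssr_pct, 50.0)
})

test_that("build_candidates wires coverage, annotations and BLAST together", {
  sim <- simulate_contigs(2, length = 200,
                          ssrs = data.frame(contig = 1:2, motif = "AC",
                                            repeats = 9),
                          gc = 0.43, seed = 41)
  contigs <- sim$contigs
  contigs$mean_coverage <- 12
  contigs$multimap_fraction <- 0.1
  loci <- find_ssrs(contigs)
  ann <- data.frame(contig_id = "sim1", start = loci$start[1],
                    end = loci$end[1], repeat_class = "LTR",
                    stringsAsFactors = FALSE)
  hits <- data.frame(query_id = "sim2", subject_id = "g", pct_identity = 99,
                     align_len = 200L, mismatches = 0L, gap_opens = 0L,
                     q_start = 1L, q_end = 200L, s_start = 1L, s_end = 200L,
                     evalue = 0, bit_score = 400, strand = "+",
                     stringsAsFactors = FALSE)
  cand <- build_candidates(loci, contigs, annotations = ann, hits = hits)
  expect_true(cand$repeat_hit[cand$contig_id == "sim1"])
  expect_false(cand$repeat_hit[cand$contig_id == "sim2"])
  expect_equal(cand$genome_occurrences[cand$contig_id == "sim2"], 1L)
  res <- apply_filters(cand)
  expect_equal(res$criterion[res$contig_id == "sim1"], 2L)
})
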