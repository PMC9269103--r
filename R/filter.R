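#' Filter cascade parameters
#'
#' Tunables of the seven-criterion candidate filter. Criteria, evaluated in
#' fixed order for failure attribution:
#' \enumerate{
#'   \item compound SSR loci are removed;
#'   \item contigs with repeat-element annotations overlapping the SSR are
#'     removed;
#'   \item contigs whose pseudo-mapped reads are mostly multi-mapping
#'     (`multimap_fraction > max_multimap_fraction`) are removed;
#'   \item mean coverage must fall inside
#'     `coverage_window * expected_coverage`, contig length must exceed
#'     `min_length - 1` nt, and both SSR flanks must reach `min_flank` nt
#'     (the flank floor makes primers designable and is an extension of the
#'     length rule);
#'   \item `genome_occurrences` must be 1 or up to
#'     `max_genome_occurrences`;
#'   \item only unit sizes in `allowed_unit_lens` (di/tri) are kept;
#'   \item contig GC must lie within `gc_center +/- gc_halfwidth`.
#' }
#'
#' @param expected_coverage expected read depth (x) of single-copy sequence.
#' @param coverage_window multiplier pair; admissible coverage is
#'   `[w1, w2] * expected_coverage`.
#' @param min_length minimum contig length in nt (131 = "more than 130").
#' @param gc_center,gc_halfwidth admissible GC window as fractions.
#' @param max_genome_occurrences largest admissible draft-genome copy count.
#' @param min_flank minimum nt on each side of the SSR.
#' @param allowed_unit_lens admissible repeat unit sizes.
#' @param max_multimap_fraction multi-mapping read share above which a
#'   contig is considered repetitive.
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(expected_coverage = 12.5,
                          coverage_window = c(0.5, 2.0),
                          min_length = 131L,
                          gc_center = 0.43, gc_halfwidth = 0.10,
                          max_genome_occurrences = 2L,
                          min_flank = 30L,
                          allowed_unit_lens = c(2L, 3L),
                          max_multimap_fraction = 0.5) {
  stopifnot(expected_coverage > 0, length(coverage_window) == 2L,
            coverage_window[1] < coverage_window[2],
            gc_halfwidth > 0, max_genome_occurrences >= 1L)
  structure(list(expected_coverage = expected_coverage,
                 coverage_window = coverage_window,
                 min_length = as.integer(min_length),
                 gc_center = gc_center, gc_halfwidth = gc_halfwidth,
                 max_genome_occurrences = as.integer(max_genome_occurrences),
                 min_flank = as.integer(min_flank),
                 allowed_unit_lens = as.integer(allowed_unit_lens),
                 max_multimap_fraction = max_multimap_fraction),
            class = "filter_params")
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator.
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    v <- strsplit(s, "")[[1]]
    acgt <- sum(v %in% DNA_BASES)
    if (acgt == 0L) stop("GC undefined: no A/C/G/T bases")
    sum(v %in% c("G", "C")) / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count draft-genome occurrences from BLAST hits
#'
#' A hit counts as one genomic occurrence when its identity reaches
#' `min_identity` and it covers at least `min_query_cov` of the query;
#' hits landing on the same subject interval (>= 50% reciprocal overlap)
#' collapse to a single occurrence, so split alignments are not
#' double-counted.
#'
#' @param hits BLAST hit table ([parse_blast_tab()]) for a single query.
#' @param query_len query sequence length in nt.
#' @param min_identity minimum percent identity.
#' @param min_query_cov minimum aligned query fraction.
#' @return integer occurrence count.
#' @export
count_genome_occurrences <- function(hits, query_len,
                                     min_identity = 90,
                                     min_query_cov = 0.8) {
  if (!nrow(hits)) return(0L)
  if (length(unique(hits$query_id)) > 1L) {
    stop("hits for more than one query; split first")
  }
  keep <- hits$pct_identity >= min_identity &
    (hits$q_end - hits$q_start + 1L) / query_len >= min_query_cov
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) return(0L)
  h <- h[order(h$subject_id, h$s_start), , drop = FALSE]
  count <- 0L
  cur_subj <- ""
  cur_start <- cur_end <- NA_integer_
  for (i in seq_len(nrow(h))) {
    s <- h$s_start[i]; e <- h$s_end[i]
    same <- FALSE
    if (h$subject_id[i] == cur_subj) {
      ov <- min(e, cur_end) - max(s, cur_start) + 1L
      if (ov >= 0.5 * (e - s + 1L) && ov >= 0.5 * (cur_end - cur_start + 1L)) {
        same <- TRUE
      }
    }
    if (same) {
      cur_end <- max(cur_end, e)
    } else {
      count <- count + 1L
      cur_subj <- h$subject_id[i]; cur_start <- s; cur_end <- e
    }
  }
  count
}

#' Assemble marker candidates from mined loci
#'
#' Joins each SSR locus (simple or compound) with its contig's sequence,
#' coverage annotations, repeat-annotation overlap and draft-genome
#' occurrence count, producing the table [apply_filters()] consumes.
#'
#' @param loci SSR table after [mark_compound()].
#' @param contigs contig table with coverage columns filled (via
#'   [estimate_coverage()] or an external coverage table).
#' @param annotations optional repeat-annotation table
#'   ([parse_repeatmasker_out()]).
#' @param hits optional BLAST hit table ([parse_blast_tab()]) whose
#'   `query_id`s are contig ids.
#' @return candidate `data.frame`: locus columns plus `seq`, `length`,
#'   `gc`, `mean_coverage`, `multimap_fraction`, `repeat_hit`,
#'   `genome_occurrences`, `left_flank`, `right_flank`, `status`,
#'   `criterion`.
#' @export
build_candidates <- function(loci, contigs, annotations = NULL, hits = NULL) {
  idx <- match(loci$contig_id, contigs$id)
  if (anyNA(idx)) {
    stop("loci reference unknown contig(s): ",
         paste(unique(loci$contig_id[is.na(idx)]), collapse = ", "))
  }
  cand <- loci
  cand$seq <- contigs$seq[idx]
  cand$length <- nchar(cand$seq)
  cand$gc <- gc_fraction(cand$seq)
  cand$mean_coverage <- contigs$mean_coverage[idx]
  cand$multimap_fraction <- contigs$multimap_fraction[idx]
  cand$left_flank <- cand$start - 1L
  cand$right_flank <- cand$length - cand$end
  cand$repeat_hit <- FALSE
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in seq_len(nrow(cand))) {
      a <- annotations[annotations$contig_id == cand$contig_id[i], ,
                       drop = FALSE]
      cand$repeat_hit[i] <- any(a$start <= cand$end[i] & a$end >= cand$start[i])
    }
  }
  cand$genome_occurrences <- NA_integer_
  if (!is.null(hits)) {
    for (i in seq_len(nrow(cand))) {
      h <- hits[hits$query_id == cand$contig_id[i], , drop = FALSE]
      cand$genome_occurrences[i] <-
        count_genome_occurrences(h, query_len = cand$length[i])
    }
  }
  cand$status <- NA_character_
  cand$criterion <- NA_integer_
  cand
}

#' Apply the seven-criterion filter cascade
#'
#' Evaluates the criteria in fixed order 1-7 (see [filter_params()]); a
#' failing candidate records the first violated criterion, so attribution
#' is deterministic and independent of input order. Idempotent on a PASS
#' set.
#'
#' @param candidates candidate table from [build_candidates()].
#' @param params a [filter_params()] object.
#' @return `candidates` with `status` (`"PASS"`/`"FAIL"`) and `criterion`
#'   (first violated, `NA` on pass) filled; per-criterion attrition counts
#'   in attribute `attrition`.
#' @export
apply_filters <- function(candidates, params = filter_params()) {
  need <- c("compound", "repeat_hit", "multimap_fraction", "mean_coverage",
            "length", "left_flank", "right_flank", "genome_occurrences",
            "unit_len", "gc")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("candidate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(candidates) && anyNA(candidates$mean_coverage)) {
    stop("missing coverage annotation for candidate(s): ",
         paste(candidates$contig_id[is.na(candidates$mean_coverage)],
               collapse = ", "))
  }
  cov_lo <- params$coverage_window[1] * params$expected_coverage
  cov_hi <- params$coverage_window[2] * params$expected_coverage
  first_fail <- function(i) {
    x <- candidates[i, ]
    if (isTRUE(x$compound)) return(1L)
    if (isTRUE(x$repeat_hit)) return(2L)
    if (x$multimap_fraction > params$max_multimap_fraction) return(3L)
    if (x$mean_coverage < cov_lo || x$mean_coverage > cov_hi ||
        x$length < params$min_length ||
        x$left_flank < params$min_flank ||
        x$right_flank < params$min_flank) return(4L)
    occ <- x$genome_occurrences
    if (!is.na(occ) && (occ < 1L || occ > params$max_genome_occurrences)) {
      return(5L)
    }
    if (!(x$unit_len %in% params$allowed_unit_lens)) return(6L)
    if (abs(x$gc - params$gc_center) > params$gc_halfwidth + 1e-12) return(7L)
    NA_integer_
  }
  crit <- vapply(seq_len(nrow(candidates)), first_fail, integer(1))
  candidates$criterion <- crit
  candidates$status <- ifelse(is.na(crit), "PASS", "FAIL")
  attr(candidates, "attrition") <-
    table(factor(crit, levels = 1:7, labels = paste0("criterion", 1:7)))
  candidates
}

#' Rank passing candidates for primer design
#'
#' Longer repeats first, then GC closest to the target center, then contig
#' id - a fully deterministic ordering.
#'
#' @param candidates candidate table; only `status == "PASS"` rows are
#'   ranked.
#' @param gc_center GC target used for the proximity tie-break.
#' @return the passing rows in rank order, with a `rank_score` column
#'   (repeat count minus GC distance, reported for transparency).
#' @export
rank_candidates <- function(candidates, gc_center = 0.43) {
  p <- candidates[candidates$status == "PASS", , drop = FALSE]
  ord <- order(-p$repeats, abs(p$gc - gc_center), p$contig_id)
  p <- p[ord, , drop = FALSE]
  p$rank_score <- p$repeats - abs(p$gc - gc_center)
  rownames(p) <- NULL
  p
}

#' Contig/SSR accounting summary
#'
#' @param loci SSR table (before compound collapsing; compound rows count
#'   via their members).
#' @param contigs contig table the loci were mined from.
#' @return a list: `total_contigs`, `ssr_contigs`, `multi_ssr_contigs`,
#'   `total_ssrs`, `single_ssr_pct` (percentage of SSR-containing contigs
#'   with exactly one locus, 1 decimal; `NA` when no contig carries an SSR).
#' @export
ssr_summary <- function(loci, contigs) {
  stopifnot(is.data.frame(loci), is.data.frame(contigs))
  n_loci_per <- table(loci$contig_id)
  containing <- length(n_loci_per)
  multi <- sum(n_loci_per > 1L)
  list(total_contigs = nrow(contigs),
       ssr_contigs = containing,
       multi_ssr_contigs = multi,
       total_ssrs = nrow(loci),
       single_ssr_pct = if (containing > 0L) {
         single_ssr_percentage(containing, multi)
       } else NA_real_)
}

#' Percentage of SSR-containing contigs with a single locus
#'
#' @param containing number of SSR-containing contigs.
#' @param multi number of contigs with more than one SSR.
#' @return percentage rounded to 1 decimal.
#' @export
single_ssr_percentage <- function(containing, multi) {
  stopifnot(containing >= multi, containing > 0)
  round((containing - multi) / containing * 100, 1)
}
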