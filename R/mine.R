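#' SSR mining parameters
#'
#' Perfect tandem repeats with unit sizes 2-6 nt are mined; a unit size is
#' reported only when the run reaches its minimum repeat number. The
#' defaults (8, 6, 5, 4, 4 repeats for units of 2-6 nt) are the MISA-style
#' thresholds used throughout this pipeline; mononucleotide runs are never
#' reported.
#'
#' @param min_repeats named integer vector, minimum repeat number per unit
#'   size; names must be exactly "2".."6".
#' @param max_interrupt largest spacer (nt) between neighboring SSRs on one
#'   contig for them to count as a single compound locus.
#' @return a list of class `mining_params`.
#' @export
mining_params <- function(min_repeats = c(`2` = 8L, `3` = 6L, `4` = 5L,
                                          `5` = 4L, `6` = 4L),
                          max_interrupt = 100L) {
  stopifnot(identical(sort(names(min_repeats)), as.character(2:6)),
            all(min_repeats >= 2L), max_interrupt >= 0L)
  structure(list(min_repeats = setNames(as.integer(min_repeats[as.character(2:6)]),
                                        as.character(2:6)),
                 max_interrupt = as.integer(max_interrupt)),
            class = "mining_params")
}

# TRUE when the motif is a repetition of a shorter unit (e.g. "ACAC", "AA")
is_power <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), u %/% d)) {
      return(TRUE)
    }
  }
  FALSE
}

rotations <- function(motif) {
  u <- nchar(motif)
  doubled <- paste0(motif, motif)
  unique(substring(doubled, 1:u, u:(2 * u - 1L)))
}

#' Canonical strand/rotation class of a repeat motif
#'
#' Motifs that differ only by cyclic rotation or by reverse complementation
#' describe the same repeat tract, so frequency reporting uses the
#' equivalence class of a motif under both operations. The label is
#' `"X/Y"` where `X` is the lexicographically smallest member of the class
#' and `Y` the smallest rotation of `X`'s reverse complement (e.g. `TG` ->
#' `"AC/GT"`; the self-complementary `AT` -> `"AT/AT"`).
#'
#' @param motif repeat unit of length 2-6 nt; must be primitive (not itself
#'   a repetition of a shorter unit).
#' @return the class label, vectorized over `motif`.
#' @export
canonical_class <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    if (u < 2L || u > 6L) stop("motif length must be 2-6: ", m)
    if (is_power(m)) stop("non-primitive motif: ", m)
    x <- min(c(rotations(m), rotations(revcomp(m))))
    paste0(x, "/", min(rotations(revcomp(x))))
  }, character(1), USE.NAMES = FALSE)
}

#' Mine perfect microsatellites from contigs
#'
#' Detects maximal perfect tandem repeats with unit sizes 2-6 nt meeting
#' the per-unit minimum repeat numbers. Each run is reported once, under
#' its smallest true unit and leftmost phase (`ACACACAC` is an `(AC)4`-type
#' run, never `(ACAC)2`); a trailing partial unit is excluded, and runs
#' containing `N` are skipped. Coordinates are 1-based inclusive.
#'
#' @param contigs contig table, or a single sequence string with `id`.
#' @param params a [mining_params()] object.
#' @param id contig id used when `contigs` is a bare sequence string.
#' @return a `data.frame` of loci in left-to-right order per contig:
#'   `contig_id`, `start`, `end`, `motif`, `unit_len`, `repeats`, `class`,
#'   `compound` (all `FALSE`; see [mark_compound()]), `members` (list
#'   column, `NULL` for simple loci).
#' @export
find_ssrs <- function(contigs, params = mining_params(), id = "seq1") {
  if (is.character(contigs) && length(contigs) == 1L && !is.data.frame(contigs)) {
    contigs <- contig_table(id, toupper(contigs))
  }
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    find_ssrs_one(contigs$id[i], contigs$seq[i], params)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_ssr_table())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

empty_ssr_table <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             motif = character(), unit_len = integer(), repeats = integer(),
             class = character(), compound = logical(),
             members = I(list()), stringsAsFactors = FALSE)
}

find_ssrs_one <- function(contig_id, seq, params) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  rows <- list()
  for (u in 2:6) {
    if (L < 2L * u) next
    minrep <- params$min_repeats[[as.character(u)]]
    eq <- v[seq_len(L - u)] == v[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]                 # leftmost phase of the periodic tract
      t <- r$lengths[j]
      k <- (t + u) %/% u             # complete units; trailing partial dropped
      if (k < minrep) next
      motif <- substr(seq, s, s + u - 1L)
      if (is_power(motif)) next      # reported under its smaller true unit
      e <- s + u * k - 1L
      if (grepl("N", substr(seq, s, e), fixed = TRUE)) next
      rows[[length(rows) + 1L]] <-
        data.frame(contig_id = contig_id, start = s, end = e,
                   motif = motif, unit_len = u, repeats = k,
                   class = canonical_class(motif), compound = FALSE,
                   members = I(list(NULL)), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res[order(res$start, res$end), , drop = FALSE]
}

#' Merge nearby SSRs into compound loci
#'
#' Two SSRs on the same contig separated by at most `max_interrupt` bases
#' form a compound locus; chains propagate, so a whole cluster collapses to
#' one compound row spanning its members. Compound loci are discarded by
#' filter criterion 1 but are kept here with their members for reporting.
#'
#' @param loci SSR table from [find_ssrs()].
#' @param max_interrupt spacer threshold in nt.
#' @return SSR table in which clustered rows are replaced by compound rows
#'   (`compound = TRUE`, `motif`/`unit_len`/`repeats` `NA`, `members`
#'   holding the constituent rows).
#' @export
mark_compound <- function(loci, max_interrupt = 100L) {
  if (!nrow(loci)) return(loci)
  pieces <- lapply(split(loci, loci$contig_id), function(lc) {
    lc <- lc[order(lc$start), , drop = FALSE]
    gap_ok <- c(FALSE, lc$start[-1L] - lc$end[-nrow(lc)] - 1L <= max_interrupt)
    grp <- cumsum(!gap_ok)
    do.call(rbind, c(lapply(split(lc, grp), function(g) {
      if (nrow(g) == 1L) return(g)
      data.frame(contig_id = g$contig_id[1], start = min(g$start),
                 end = max(g$end), motif = NA_character_,
                 unit_len = NA_integer_, repeats = NA_integer_,
                 class = NA_character_, compound = TRUE,
                 members = I(list(g)), stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  out[order(out$contig_id, out$start), , drop = FALSE]
}

#' Motif-class frequency table
#'
#' Tabulates non-compound loci by unit size and canonical motif class, with
#' percentages over all non-compound loci.
#'
#' @param loci SSR table (possibly after [mark_compound()]).
#' @return `data.frame` with `unit_len`, `class`, `count`, `pct`, sorted by
#'   unit size then descending count.
#' @export
motif_frequency_table <- function(loci) {
  simple <- loci[!loci$compound, , drop = FALSE]
  if (!nrow(simple)) {
    return(data.frame(unit_len = integer(), class = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(count = seq_len(nrow(simple))),
                   by = list(unit_len = simple$unit_len, class = simple$class),
                   FUN = length)
  agg$pct <- 100 * agg$count / sum(agg$count)
  agg[order(agg$unit_len, -agg$count, agg$class), , drop = FALSE]
}
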