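#' Merge parameters for overlapping read pairs
#'
#' @param min_overlap smallest admissible overlap in nt (>= 10).
#' @param max_mismatch_rate largest admissible mismatch fraction within the
#'   overlap.
#' @param dedupe drop exact and reverse-complement duplicates after merging.
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 30L, max_mismatch_rate = 0.1,
                         dedupe = TRUE) {
  stopifnot(min_overlap >= 10L, max_mismatch_rate >= 0,
            max_mismatch_rate <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 dedupe = isTRUE(dedupe)),
            class = "merge_params")
}

#' Merge one read pair across its 3' overlap
#'
#' For a standard FR library, read 2 is reverse-complemented and its 5' end
#' aligned against the 3' end of read 1. Among overlap lengths from
#' `min_overlap` up to the shorter read, the longest one whose mismatch
#' fraction does not exceed `max_mismatch_rate` wins; conflicting bases in
#' the overlap are resolved toward the higher Phred quality (read 1 wins
#' ties). If no admissible overlap exists, or distinct admissible overlaps
#' tie on length, `NULL` is returned.
#'
#' @param seq1,qual1 read 1 sequence and Phred+33 quality string.
#' @param seq2,qual2 read 2 (as sequenced, i.e. reverse strand of the
#'   fragment's 3' end) and its quality string.
#' @param params a [merge_params()] object.
#' @return a list with `seq`, `qual` and `overlap` for a successful merge,
#'   otherwise `NULL` (no admissible overlap).
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, params = merge_params()) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("empty read")
  stopifnot(nchar(seq1) == nchar(qual1), nchar(seq2) == nchar(qual2))
  v1 <- strsplit(seq1, "")[[1]]
  q1 <- utf8ToInt(qual1) - 33L
  v2 <- rev(chartr("ACGTN", "TGCAN", strsplit(seq2, "")[[1]]))
  q2 <- rev(utf8ToInt(qual2) - 33L)
  n1 <- length(v1); n2 <- length(v2)
  omax <- min(n1, n2)
  if (omax < params$min_overlap) return(NULL)
  admissible <- integer(0)
  mism <- integer(0)
  for (o in params$min_overlap:omax) {
    a <- v1[(n1 - o + 1L):n1]
    b <- v2[1:o]
    mm <- sum(a != b)
    if (mm / o <= params$max_mismatch_rate) {
      admissible <- c(admissible, o)
      mism <- c(mism, mm)
    }
  }
  if (!length(admissible)) return(NULL)
  best <- max(admissible)
  if (sum(admissible == best) > 1L) return(NULL)  # ambiguity guard
  o <- best
  i1 <- (n1 - o + 1L):n1
  i2 <- 1:o
  ov_base <- ifelse(q2[i2] > q1[i1], v2[i2], v1[i1])
  ov_qual <- pmax(q1[i1], q2[i2])
  tail2 <- o + seq_len(n2 - o)
  seq <- paste(c(v1[seq_len(n1 - o)], ov_base, v2[tail2]), collapse = "")
  qual <- intToUtf8(c(q1[seq_len(n1 - o)], ov_qual, q2[tail2]) + 33L)
  list(seq = seq, qual = qual, overlap = o)
}

#' Merge a table of read pairs
#'
#' Applies [merge_pair()] to every row and (optionally) deduplicates the
#' merged sequences.
#'
#' @param pairs read-pair table from [read_fastq_pairs()] or
#'   [simulate_read_pairs()].
#' @param params a [merge_params()] object.
#' @return contig table of merged fragments (`source = "merged"`), with an
#'   attribute `n_merged` giving the pre-deduplication merge count.
#' @export
merge_pairs <- function(pairs, params = merge_params()) {
  merged <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    # single-bracket assignment: a NO_MERGE NULL must not shrink the list
    merged[i] <- list(merge_pair(pairs$seq1[i], pairs$qual1[i],
                                 pairs$seq2[i], pairs$qual2[i], params))
  }
  ok <- !vapply(merged, is.null, logical(1))
  seqs <- vapply(merged[ok], `[[`, character(1), "seq")
  ids <- pairs$id[ok]
  if (params$dedupe) {
    keep <- !duplicated(canonical_strand(seqs))
    seqs <- seqs[keep]; ids <- ids[keep]
  }
  out <- contig_table(make.unique(ids), seqs, source = "merged")
  attr(out, "n_merged") <- sum(ok)
  out
}

canonical_strand <- function(seqs) pmin(seqs, revcomp(seqs))

#' Remove exact and reverse-complement duplicate sequences
#'
#' Keeps the first occurrence of each sequence, where a sequence and its
#' reverse complement count as the same; order is otherwise preserved.
#' Idempotent.
#'
#' @param seqs character vector of DNA sequences.
#' @return deduplicated character vector.
#' @export
dedupe_sequences <- function(seqs) {
  seqs[!duplicated(canonical_strand(seqs))]
}

#' Estimate read coverage of contigs by exact k-mer pseudo-mapping
#'
#' Each read is assigned to every contig with which it shares at least one
#' exact k-mer (either strand). Per contig, `mean_coverage` is assigned read
#' bases divided by contig length and `multimap_fraction` is the share of
#' its assigned reads that also matched another contig. This is a
#' lightweight repetitiveness screen, not an aligner; an externally computed
#' coverage table can be substituted at the filtering stage.
#'
#' @param contigs contig table.
#' @param reads character vector of read sequences (give both mates).
#' @param k k-mer size; must not exceed the shortest read.
#' @return `contigs` with `mean_coverage` and `multimap_fraction` filled.
#' @export
estimate_coverage <- function(contigs, reads, k = 31L) {
  k <- as.integer(k)
  if (length(reads) && k > min(nchar(reads))) {
    stop("k = ", k, " exceeds shortest read length ", min(nchar(reads)))
  }
  nc <- nrow(contigs)
  cover_bases <- numeric(nc)
  multi <- numeric(nc)
  assigned <- numeric(nc)
  if (length(reads)) {
    kmers_of <- function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      unique(substring(s, 1:(L - k + 1L), k:L))
    }
    index <- new.env(parent = emptyenv())
    for (ci in seq_len(nc)) {
      for (km in kmers_of(contigs$seq[ci])) {
        index[[km]] <- c(index[[km]], ci)
      }
    }
    for (r in reads) {
      hit <- unique(unlist(lapply(unique(c(kmers_of(r), kmers_of(revcomp(r)))),
                                  function(km) index[[km]]), use.names = FALSE))
      if (!length(hit)) next
      cover_bases[hit] <- cover_bases[hit] + nchar(r)
      assigned[hit] <- assigned[hit] + 1
      if (length(hit) > 1L) multi[hit] <- multi[hit] + 1
    }
  }
  contigs$mean_coverage <- cover_bases / nchar(contigs$seq)
  contigs$multimap_fraction <- ifelse(assigned > 0, multi / assigned, 0)
  contigs
}
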