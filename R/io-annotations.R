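#' Parse a RepeatMasker `.out` annotation file
#'
#' Parses the standard whitespace-aligned RepeatMasker output (3 header
#' lines, then one row per alignment) and groups query intervals per contig.
#' Coordinates are 1-based inclusive, as printed by RepeatMasker.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return a `data.frame` with one row per alignment: `contig_id`, `start`,
#'   `end`, `repeat_class`. Rows for the same contig share its `contig_id`;
#'   use `split()` for a per-contig view.
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker file not found: ", path)
  lines <- readLines(path)
  # body starts after the two header lines + blank separator; be tolerant of
  # files that carry only the body
  body <- grep("^\\s*\\d", lines, value = TRUE)
  if (!length(body)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), repeat_class = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(body), "\\s+")
  n <- lengths(fields)
  if (any(n < 11)) {
    stop("RepeatMasker row with too few columns at body line ",
         which(n < 11)[1])
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  start <- suppressWarnings(as.integer(get(6)))
  end <- suppressWarnings(as.integer(get(7)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric query coordinates at body line ",
         which(is.na(start) | is.na(end))[1])
  }
  if (any(start < 1L | end < start)) {
    stop("invalid interval (start<1 or end<start) at body line ",
         which(start < 1L | end < start)[1])
  }
  data.frame(contig_id = get(5), start = start, end = end,
             repeat_class = get(11), stringsAsFactors = FALSE)
}

#' Parse tabular BLAST output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST format. Subject
#' coordinates on the minus strand (s_start > s_end) are normalized so that
#' starts never exceed ends and the original orientation is kept in the
#' `strand` column.
#'
#' @param path path to a BLAST `-outfmt 6` file.
#' @return a `data.frame` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`, `strand`.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stop("BLAST file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), align_len = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      evalue = numeric(), bit_score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("expected 12 tab-separated columns, got ",
         lengths(fields)[bad[1]], " at row ", bad[1])
  }
  m <- do.call(rbind, fields)
  num <- function(k) as.numeric(m[, k])
  int <- function(k) as.integer(m[, k])
  s_start <- int(9); s_end <- int(10)
  minus <- s_start > s_end
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3), align_len = int(4),
    mismatches = int(5), gap_opens = int(6),
    q_start = int(7), q_end = int(8),
    s_start = ifelse(minus, s_end, s_start),
    s_end = ifelse(minus, s_start, s_end),
    evalue = num(11), bit_score = num(12),
    strand = ifelse(minus, "-", "+"),
    stringsAsFactors = FALSE)
  if (any(hits$q_start > hits$q_end)) stop("query coordinates reversed")
  hits
}
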