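#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzipped) FASTA file into a contig table. Sequence is
#' uppercased; only A/C/G/T/N are accepted. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param source provenance label stored in the \code{source} column, one of
#'   \code{"denovo"} or \code{"merged"}.
#' @return a \code{data.frame} with columns \code{id}, \code{seq},
#'   \code{source}, \code{mean_coverage}, \code{multimap_fraction} (the two
#'   last are \code{NA} until \code{\link{estimate_coverage}} or a coverage
#'   table fills them).
#' @export
read_fasta <- function(path, source = c("denovo", "merged")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in record(s): ",
                     paste(ids[bad], collapse = ", "))
  contig_table(ids, seqs, source)
}

contig_table <- function(id, seq, source = "denovo",
                         mean_coverage = NA_real_,
                         multimap_fraction = NA_real_) {
  stopifnot(all(nzchar(seq)), !anyDuplicated(id))
  data.frame(id = as.character(id), seq = as.character(seq),
             source = source, mean_coverage = mean_coverage,
             multimap_fraction = multimap_fraction,
             stringsAsFactors = FALSE)
}

#' Write contigs to FASTA
#'
#' @param contigs contig table as returned by [read_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' Reads two FASTQ files (R1/R2 of a paired-end library, Phred+33) and pairs
#' records positionally after checking that counts match and that ids agree
#' once any `/1`, `/2` (or trailing mate-number field) suffix is stripped.
#'
#' @param path1,path2 FASTQ paths for read 1 and read 2.
#' @return a `data.frame` with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p) {
    # any structural defect (including quality/sequence length mismatch,
    # which surfaces as a conversion error) is reported as malformed FASTQ;
    # as.character drops the unused quality metadata column with a warning
    tryCatch(suppressWarnings({
      set <- Biostrings::readQualityScaledDNAStringSet(p)
      seq <- toupper(as.character(set))
      qual <- as.character(Biostrings::quality(set))
      stopifnot(all(nchar(seq) == nchar(qual)))
      list(id = names(set), seq = seq, qual = qual)
    }), error = function(e) {
      stop("malformed FASTQ in ", p, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  r1 <- rd(path1); r2 <- rd(path2)
  if (length(r1$id) != length(r2$id)) {
    stop("record count mismatch: ", length(r1$id), " vs ", length(r2$id))
  }
  strip <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- strip(r1$id); id2 <- strip(r2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop("read id mismatch at record ", bad[1], ": '", id1[bad[1]],
         "' vs '", id2[bad[1]], "'")
  }
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Write read pairs to a pair of FASTQ files
#'
#' @param pairs read-pair table as from [read_fastq_pairs()].
#' @param path1,path2 output FASTQ paths for mates 1 and 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  fq <- function(id, seq, qual, mate, path) {
    writeLines(rbind(paste0("@", id, "/", mate), seq, "+", qual), path)
  }
  fq(pairs$id, pairs$seq1, pairs$qual1, 1L, path1)
  fq(pairs$id, pairs$seq2, pairs$qual2, 2L, path2)
  invisible(c(path1, path2))
}
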