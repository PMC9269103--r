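#' Serialize a phylogenetic tree to Newick
#'
#' Writes an `ape` `"phylo"` tree as a Newick string with branch lengths;
#' internal node labels (bootstrap support percentages in this pipeline) are
#' emitted in the standard position after the closing parenthesis. The
#' output round-trips through [ape::read.tree()].
#'
#' @param tree a `"phylo"` object; every tip must be labeled.
#' @param path optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label))) {
    stop("unlabeled leaf in tree")
  }
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Emit Primer3 Boulder-IO input for marker candidates
#'
#' One Boulder-IO record per candidate: the contig sequence as template, the
#' SSR as `SEQUENCE_TARGET=<start>,<length>` (1-based start, per Primer3
#' convention), a single primer pair requested per locus, and the product
#' size range from `params`.
#'
#' @param candidates candidate table (see [build_candidates()]); needs
#'   columns `contig_id`, `seq`, `start`, `end`.
#' @param product_size_range length-2 integer vector, min and max product
#'   size in bp.
#' @param path optional output path.
#' @return character vector of Boulder-IO lines.
#' @export
write_boulder_io <- function(candidates, product_size_range = c(100L, 300L),
                             path = NULL) {
  stopifnot(is.data.frame(candidates),
            all(c("contig_id", "seq", "start", "end") %in% names(candidates)),
            length(product_size_range) == 2L,
            product_size_range[1] <= product_size_range[2])
  lines <- character(0)
  for (i in seq_len(nrow(candidates))) {
    tmpl <- candidates$seq[i]
    s <- candidates$start[i]; e <- candidates$end[i]
    if (s < 1L || e > nchar(tmpl) || s > e) {
      stop("SSR interval ", s, "..", e, " outside template for candidate ",
           candidates$contig_id[i])
    }
    lines <- c(lines,
               paste0("SEQUENCE_ID=", candidates$contig_id[i]),
               paste0("SEQUENCE_TEMPLATE=", tmpl),
               paste0("SEQUENCE_TARGET=", s, ",", e - s + 1L),
               "PRIMER_NUM_RETURN=1",
               paste0("PRIMER_PRODUCT_SIZE_RANGE=", product_size_range[1],
                      "-", product_size_range[2]),
               "=")
  }
  if (!is.null(path)) writeLines(lines, path)
  lines
}
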