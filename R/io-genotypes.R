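#' Construct a diploid genotype matrix
#'
#' The container used by all marker statistics: two integer allele-size
#' matrices (individuals x loci, sizes in bp), an optional population label
#' per individual, and `NA` for missing calls. A call is either complete
#' (both alleles) or missing (both `NA`); half calls are rejected.
#'
#' @param a1,a2 integer matrices of allele sizes, same dimensions, `NA` for
#'   missing. Within a cell the allele order is irrelevant.
#' @param individuals,loci label vectors; default from dimnames.
#' @param population optional character vector of population labels, one per
#'   individual.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, individuals = rownames(a1),
                            loci = colnames(a1), population = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  stopifnot(length(individuals) == nrow(a1), length(loci) == ncol(a1))
  if (anyDuplicated(individuals)) stop("duplicate individual labels")
  if (anyDuplicated(loci)) stop("duplicate locus labels")
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing calls: a1/a2 must be NA together (use ",
         "read_genotype_table() for the coercion rule)")
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE)) {
    stop("allele sizes must be positive")
  }
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  if (!is.null(population)) {
    stopifnot(length(population) == length(individuals))
    population <- as.character(population)
  }
  structure(list(a1 = a1, a2 = a2,
                 individuals = as.character(individuals),
                 loci = as.character(loci),
                 population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci\n")
  if (!is.null(x$population)) {
    cat("populations:", paste(sprintf("%s (%d)", names(table(x$population)),
                                      table(x$population)), collapse = ", "),
        "\n")
  }
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$individuals), length(x$loci))

#' Read a diploid genotype table
#'
#' Reads the two-columns-per-locus interchange layout for codominant SSR
#' data: a header `id,pop,<locus>.1,<locus>.2,...` and one row per
#' individual, allele sizes in bp, missing coded as `0` or blank. A cell
#' with exactly one missing allele is coerced to fully missing with a
#' warning, since the diploid statistics assume complete calls.
#'
#' @param path path to a comma- (or `sep`-) delimited genotype table.
#' @param sep field separator.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 4L) stop("expected id, pop and at least one locus pair")
  if (!identical(tolower(names(tab)[1:2]), c("id", "pop"))) {
    stop("header must start with 'id,pop'")
  }
  acols <- names(tab)[-(1:2)]
  if (length(acols) %% 2L != 0L) {
    stop("odd number of allele columns (", length(acols),
         "); expected two per locus")
  }
  loci <- sub("\\.[12]$", "", acols[seq(1, length(acols), by = 2)])
  exp_cols <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!identical(acols, exp_cols)) {
    stop("allele columns must come in '<locus>.1','<locus>.2' pairs")
  }
  parse_allele <- function(x) {
    x <- trimws(x)
    x[x == ""] <- "0"
    bad <- grepl("[^0-9]", x)
    if (any(bad)) {
      stop("non-integer allele token '", x[bad][1], "' in column")
    }
    v <- as.integer(x)
    v[v == 0L] <- NA_integer_
    v
  }
  vals <- vapply(tab[acols], parse_allele, integer(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab))  # guard the 1-row vapply drop
  a1 <- vals[, seq(1, ncol(vals), by = 2), drop = FALSE]
  a2 <- vals[, seq(2, ncol(vals), by = 2), drop = FALSE]
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)
    warning(sum(half), " half-missing call(s) coerced to missing (e.g. ",
            tab$id[idx[1, 1]], " at ", loci[idx[1, 2]], ")")
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  genotype_matrix(a1, a2, individuals = tab[[1]], loci = loci,
                  population = tab[[2]])
}

#' Write a genotype matrix in the two-columns-per-locus layout
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; missing calls are written as `0`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$individuals); L <- length(gm$loci)
  out <- data.frame(id = gm$individuals,
                    pop = gm$population %||% rep("P1", n),
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    v1 <- gm$a1[, l]; v2 <- gm$a2[, l]
    v1[is.na(v1)] <- 0L; v2[is.na(v2)] <- 0L
    out[[paste0(gm$loci[l], ".1")]] <- v1
    out[[paste0(gm$loci[l], ".2")]] <- v2
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
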