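# Shared fixture builders. Everything is generated in code at test time.

# random DNA convenience (independent of the package's generator so that
# IO/merge tests do not lean on simulate_* internals)
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phred_string <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)

# write a tiny FASTA and return the path
write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile(fileext = ".fa", tmpdir = dir)
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_tmp_lines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small genotype matrix built by hand: 4 individuals, 2 loci
tiny_gm <- function() {
  a1 <- rbind(c(100L, 200L), c(100L, 200L), c(100L, 200L), c(102L, 202L))
  a2 <- rbind(c(100L, 200L), c(102L, 200L), c(100L, 202L), c(102L, 202L))
  genotype_matrix(a1, a2, individuals = paste0("s", 1:4),
                  loci = c("locA", "locB"), population = rep("P1", 4))
}

# independent brute-force oracle for the Levene exact test: enumerate all
# distinct pairings of the gene copies and aggregate by genotype table
hwe_brute_force <- function(a1, a2) {
  copies <- c(a1, a2)
  n <- length(a1)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  tab_key <- function(g1, g2) {
    paste(sort(paste(pmin(g1, g2), pmax(g1, g2))), collapse = ";")
  }
  keys <- vapply(perms(copies), function(p) {
    tab_key(p[seq_len(n)], p[n + seq_len(n)])
  }, character(1))
  probs <- table(keys) / length(keys)
  obs <- tab_key(a1, a2)
  sum(probs[probs <= probs[[obs]] + 1e-12])
}
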