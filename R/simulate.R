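# Seeded simulators for every pipeline stage. All functions restore the
# caller's RNG state on exit, so a fixed seed gives byte-identical output
# regardless of surrounding code.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs[DNA_BASES]),
        collapse = "")
}

#' Simulate contigs with planted microsatellites
#'
#' Generates i.i.d. background sequence (optionally at a GC target) and
#' plants perfect repeats at known positions. The bases flanking each
#' plant are adjusted so the repeat tract cannot extend into the
#' background, making the truth table exact: a "detectable" plant (one
#' meeting the mining thresholds) is recovered by [find_ssrs()] at exactly
#' the recorded coordinates.
#'
#' @param n_contigs number of contigs.
#' @param length contig length in nt (recycled).
#' @param ssrs `data.frame` describing plants: `contig` (index), `motif`,
#'   `repeats`, optional `start` (default: centered).
#' @param gc background GC fraction.
#' @param seed RNG seed (mandatory).
#' @return list with `contigs` (contig table) and `truth` (`data.frame`:
#'   `contig_id`, `start`, `end`, `motif`, `unit_len`, `repeats`,
#'   `detectable` under the default [mining_params()]).
#' @export
simulate_contigs <- function(n_contigs, length = 500L, ssrs = NULL,
                             gc = 0.5, seed) {
  stopifnot(!missing(seed))
  length <- rep_len(as.integer(length), n_contigs)
  params <- mining_params()
  with_seed(seed, {
    seqs <- vapply(length, random_dna, character(1), gc = gc)
    truth <- NULL
    if (!is.null(ssrs) && nrow(ssrs)) {
      for (r in seq_len(nrow(ssrs))) {
        ci <- ssrs$contig[r]
        motif <- toupper(ssrs$motif[r])
        u <- nchar(motif)
        k <- ssrs$repeats[r]
        tract <- strrep(motif, k)
        L <- length[ci]
        if (nchar(tract) + 2L > L) {
          stop("planted SSR (", nchar(tract), " nt) longer than contig ", ci)
        }
        s <- if (!is.null(ssrs$start) && !is.na(ssrs$start[r])) {
          as.integer(ssrs$start[r])
        } else {
          max(2L, (L - nchar(tract)) %/% 2L)
        }
        e <- s + nchar(tract) - 1L
        if (s < 1L || e > L) stop("planted SSR outside contig ", ci)
        v <- strsplit(seqs[ci], "")[[1]]
        v[s:e] <- strsplit(tract, "")[[1]]
        # stop the periodic tract at the recorded boundaries
        if (s > 1L && v[s - 1L] == v[s - 1L + u]) {
          v[s - 1L] <- setdiff(DNA_BASES, c(v[s - 1L + u],
                                            if (s > u) v[s - 1L - u]))[1]
        }
        if (e < L && v[e + 1L] == v[e + 1L - u]) {
          v[e + 1L] <- setdiff(DNA_BASES, c(v[e + 1L - u],
                                            if (e + 1L + u <= L) v[e + 1L + u]))[1]
        }
        seqs[ci] <- paste(v, collapse = "")
        minrep <- params$min_repeats[[as.character(u)]]
        truth <- rbind(truth, data.frame(
          contig_id = paste0("sim", ci), start = s, end = e, motif = motif,
          unit_len = u, repeats = k,
          detectable = u >= 2L && u <= 6L && k >= minrep,
          stringsAsFactors = FALSE))
      }
    }
    list(contigs = contig_table(paste0("sim", seq_len(n_contigs)), seqs),
         truth = truth %||% data.frame())
  })
}

#' Simulate paired-end reads from contigs
#'
#' Fragments are drawn uniformly (contigs weighted by length), read 1 from
#' the fragment's 5' end and read 2 as the reverse complement of its 3'
#' end; sequencing errors are i.i.d. substitutions at `error_rate`, and
#' quality strings carry the Phred value implied by that rate (constant
#' per run).
#'
#' @param contigs contig table.
#' @param n_pairs number of pairs; alternatively give `coverage`.
#' @param coverage target mean depth used to derive `n_pairs` when the
#'   latter is missing.
#' @param read_len read length in nt.
#' @param fragment_len fragment length in nt (must be >= `read_len`; keep
#'   below `2 * read_len` for mergeable pairs).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed (mandatory).
#' @return list with `pairs` (read-pair table) and `truth` (`data.frame`:
#'   `id`, `contig_id`, `frag_start`, `frag_end`, `fragment`).
#' @export
simulate_read_pairs <- function(contigs, n_pairs = NULL, coverage = NULL,
                                read_len = 100L, fragment_len = 150L,
                                error_rate = 0, seed) {
  stopifnot(!missing(seed), error_rate >= 0, error_rate <= 1)
  read_len <- as.integer(read_len)
  fragment_len <- as.integer(fragment_len)
  if (read_len > fragment_len) stop("read length exceeds fragment length")
  if (any(nchar(contigs$seq) < fragment_len)) {
    stop("fragment length exceeds a contig length")
  }
  if (is.null(n_pairs)) {
    if (is.null(coverage)) stop("give n_pairs or coverage")
    n_pairs <- max(1L, round(coverage * sum(nchar(contigs$seq)) /
                               (2 * read_len)))
  }
  qchar <- rawToChar(as.raw(33L + if (error_rate > 0) {
    min(41L, as.integer(round(-10 * log10(error_rate))))
  } else 41L))
  add_errors <- function(s) {
    if (error_rate == 0) return(s)
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < error_rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
    }
    paste(v, collapse = "")
  }
  with_seed(seed, {
    lens <- nchar(contigs$seq)
    ci <- sample.int(nrow(contigs), n_pairs, replace = TRUE,
                     prob = lens - fragment_len + 1L)
    fs <- vapply(ci, function(i) {
      sample.int(lens[i] - fragment_len + 1L, 1L)
    }, integer(1))
    frags <- substring(contigs$seq[ci], fs, fs + fragment_len - 1L)
    seq1 <- vapply(substring(frags, 1L, read_len), add_errors, character(1),
                   USE.NAMES = FALSE)
    seq2 <- vapply(revcomp(substring(frags, fragment_len - read_len + 1L,
                                     fragment_len)),
                   add_errors, character(1), USE.NAMES = FALSE)
    qual <- strrep(qchar, read_len)
    ids <- sprintf("frag%0*d", nchar(n_pairs), seq_len(n_pairs))
    list(pairs = data.frame(id = ids, seq1 = seq1, qual1 = qual,
                            seq2 = seq2, qual2 = qual,
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, contig_id = contigs$id[ci],
                            frag_start = fs, frag_end = fs + fragment_len - 1L,
                            fragment = frags, stringsAsFactors = FALSE))
  })
}

#' Simulate multi-population diploid genotypes
#'
#' Draws diploid calls under Hardy-Weinberg proportions within each
#' population from per-locus allele-frequency vectors. With a null-allele
#' rate `r`, a hidden null allele segregates at frequency `r` at every
#' locus (visible frequencies rescaled to `1 - r`): null homozygotes
#' become missing and null heterozygotes appear as visible homozygotes.
#' Independent random missingness is applied afterwards.
#'
#' @param freqs per-population allele frequencies: a list (one element per
#'   population) of lists (one per locus) of named numeric vectors; names
#'   are allele sizes in bp. A single locus-list is recycled to all
#'   populations.
#' @param n_per_pop individuals per population (recycled).
#' @param loci locus labels; default `locus1..L`.
#' @param null_rate per-locus null-allele frequency.
#' @param missing_rate independent per-call missingness.
#' @param seed RNG seed (mandatory).
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (the visible
#'   allele-frequency vectors as supplied).
#' @export
simulate_genotypes <- function(freqs, n_per_pop = 20L, loci = NULL,
                               null_rate = 0, missing_rate = 0, seed) {
  stopifnot(!missing(seed), null_rate >= 0, null_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.list(freqs[[1]])) freqs <- list(freqs)  # single population
  n_pop <- length(freqs)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pop)
  L <- length(freqs[[1]])
  stopifnot(all(lengths(freqs) == L))
  for (p in seq_len(n_pop)) {
    for (l in seq_len(L)) {
      f <- freqs[[p]][[l]]
      if (abs(sum(f) - 1) > 1e-9 || any(f < 0) || is.null(names(f))) {
        stop("invalid frequency vector (population ", p, ", locus ", l, ")")
      }
    }
  }
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  with_seed(seed, {
    n <- sum(n_per_pop)
    a1 <- matrix(NA_integer_, n, L)
    a2 <- matrix(NA_integer_, n, L)
    pop <- rep(paste0("P", seq_len(n_pop)), n_per_pop)
    row0 <- 0L
    for (p in seq_len(n_pop)) {
      for (l in seq_len(L)) {
        f <- freqs[[p]][[l]]
        sizes <- as.integer(names(f))
        draw <- function(m) {
          # 0 encodes the hidden null allele
          vis <- sample(sizes, m, replace = TRUE, prob = f)
          if (null_rate > 0) vis[runif(m) < null_rate] <- 0L
          vis
        }
        g1 <- draw(n_per_pop[p]); g2 <- draw(n_per_pop[p])
        both_null <- g1 == 0L & g2 == 0L
        one_null <- xor(g1 == 0L, g2 == 0L)
        vis <- pmax(g1, g2)          # the visible allele of a null het
        g1[one_null] <- vis[one_null]
        g2[one_null] <- vis[one_null]
        g1[both_null] <- NA_integer_
        g2[both_null] <- NA_integer_
        idx <- row0 + seq_len(n_per_pop[p])
        a1[idx, l] <- g1
        a2[idx, l] <- g2
      }
      row0 <- row0 + n_per_pop[p]
    }
    if (missing_rate > 0) {
      drop <- matrix(runif(n * L) < missing_rate, n, L)
      a1[drop] <- NA_integer_
      a2[drop] <- NA_integer_
    }
    gm <- genotype_matrix(a1, a2,
                          individuals = sprintf("%s_i%02d", pop,
                                                sequence(n_per_pop)),
                          loci = loci, population = pop)
    list(gm = gm, truth = freqs)
  })
}

#' Disjoint per-population allele pools
#'
#' Convenience builder for strongly diverged synthetic populations: each
#' population receives its own block of allele sizes with uniform
#' frequencies, so populations share no alleles at any locus.
#'
#' @param n_pop populations.
#' @param n_loci loci.
#' @param n_alleles alleles per locus per population.
#' @return a frequency structure for [simulate_genotypes()].
#' @export
disjoint_allele_pools <- function(n_pop = 3L, n_loci = 12L, n_alleles = 4L) {
  lapply(seq_len(n_pop), function(p) {
    lapply(seq_len(n_loci), function(l) {
      sizes <- 100L + 2L * (n_alleles * (p - 1L) + seq_len(n_alleles))
      setNames(rep(1 / n_alleles, n_alleles), sizes)
    })
  })
}
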