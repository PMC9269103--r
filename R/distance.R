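#' Proportion-of-shared-alleles distance between two individuals
#'
#' For each locus typed in both individuals, the number of shared alleles
#' (0, 1 or 2; each allele matched at most once between the two unordered
#' genotypes) is summed and `D = 1 - shared / (2 * L_typed)`. Loci missing
#' in either individual drop out of the denominator (pairwise-complete
#' normalization).
#'
#' @param gm a [genotype_matrix()].
#' @param i,j individual labels or indices.
#' @return numeric in `[0, 1]`.
#' @export
dpsa <- function(gm, i, j) {
  dpsa_matrix(gm)[i, j]
}

# per-locus shared-allele counts for all pairs: shared = best of the two
# pairings of {x1,x2} against {y1,y2} (equals multiset intersection size)
shared_matrices <- function(gm) {
  n <- length(gm$individuals)
  lapply(seq_along(gm$loci), function(l) {
    x1 <- gm$a1[, l]; x2 <- gm$a2[, l]
    e11 <- outer(x1, x1, "=="); e22 <- outer(x2, x2, "==")
    e12 <- outer(x1, x2, "=="); e21 <- outer(x2, x1, "==")
    s <- pmax(e11 + e22, e12 + e21)
    typed <- !is.na(x1)
    t2 <- outer(typed, typed, "&")
    s[!t2] <- 0L
    list(shared = s, typed = t2 * 1L)
  })
}

#' All pairwise proportion-of-shared-alleles distances
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric matrix with individual labels; errors if some pair of
#'   individuals has no locus typed in both.
#' @export
dpsa_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sm <- shared_matrices(gm)
  S <- Reduce(`+`, lapply(sm, `[[`, "shared"))
  Tn <- Reduce(`+`, lapply(sm, `[[`, "typed"))
  if (any(Tn == 0L)) stop("individual pair(s) with no co-typed locus")
  D <- 1 - S / (2 * Tn)
  diag(D) <- 0
  dimnames(D) <- list(gm$individuals, gm$individuals)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration on the Q-criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest pair of
#' (current) node labels, so the output is bit-reproducible. Negative
#' branch lengths are clamped to zero for display; the raw lengths are
#' kept in `attr(tree, "raw_edge_length")`, aligned with `tree$edge`. For
#' an additive matrix the tree reproduces all pairwise path lengths.
#'
#' @param d symmetric numeric matrix with zero diagonal, labeled dimnames,
#'   `n >= 3`, no negative entries.
#' @return an unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-12) stop("asymmetric distance matrix")
  labels <- rownames(d)
  # newick fragment and tie-break key per active node
  frag <- labels
  key <- labels
  D <- d
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    a <- pmin(key[cand[, 1]], key[cand[, 2]])
    b <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- order(a, b)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
                      fmt(lj), ")")
    newkey <- min(key[i], key[j])
    others <- setdiff(seq_len(m), c(i, j))
    newd <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    frag <- c(frag[others], newfrag)
    key <- c(key[others], newkey)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  tree <- ape::read.tree(text = txt)
  raw <- tree$edge.length
  tree$edge.length <- pmax(0, raw)
  attr(tree, "raw_edge_length") <- raw
  tree
}

#' Bootstrapped neighbor-joining tree from genotypes
#'
#' Builds the full-data proportion-of-shared-alleles NJ tree, then
#' resamples loci with replacement `n_reps` times, recomputes distance and
#' tree for each replicate, and annotates every internal edge of the
#' full-data tree with the percentage of replicates containing the same
#' bipartition. A majority-rule consensus of the replicate trees is also
#' returned.
#'
#' @param gm a [genotype_matrix()] with at least 3 individuals and 2 loci.
#' @param n_reps bootstrap replicates.
#' @param seed RNG seed.
#' @return list of class `ssr_boot`: `tree` (full-data NJ with support
#'   percentages as `node.label`), `consensus` (majority-rule), `n_reps`,
#'   `boot_trees` (`multiPhylo`).
#' @export
bootstrap_tree <- function(gm, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(gm$individuals) >= 3L)
  L <- length(gm$loci)
  if (L < 2L) stop("bootstrap over loci needs at least 2 loci")
  sm <- shared_matrices(gm)
  dist_from <- function(idx) {
    S <- Reduce(`+`, lapply(sm[idx], `[[`, "shared"))
    Tn <- Reduce(`+`, lapply(sm[idx], `[[`, "typed"))
    if (any(Tn == 0L)) return(NULL)
    D <- 1 - S / (2 * Tn)
    diag(D) <- 0
    dimnames(D) <- list(gm$individuals, gm$individuals)
    D
  }
  full <- dist_from(seq_len(L))
  if (is.null(full)) stop("individual pair(s) with no co-typed locus")
  tree <- neighbor_joining(full)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  boots <- vector("list", n_reps)
  used <- 0L
  for (r in seq_len(n_reps)) {
    Db <- dist_from(sample.int(L, L, replace = TRUE))
    if (is.null(Db)) next  # replicate left all co-typed loci out for a pair
    used <- used + 1L
    boots[[used]] <- neighbor_joining(Db)
  }
  boots <- boots[seq_len(used)]
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.character(round(100 * counts / used))
  cons <- ape::consensus(boots, p = 0.5)
  structure(list(tree = tree, consensus = cons, n_reps = used,
                 boot_trees = boots),
            class = "ssr_boot")
}

#' @export
print.ssr_boot <- function(x, ...) {
  cat("bootstrapped NJ tree:", length(x$tree$tip.label), "tips,",
      x$n_reps, "replicates\n")
  sup <- suppressWarnings(as.numeric(x$tree$node.label))
  cat("internal-edge support range:", paste(range(sup, na.rm = TRUE),
                                            collapse = "-"), "%\n")
  invisible(x)
}

#' Bootstrap support for the split isolating a set of individuals
#'
#' Percentage of bootstrap replicates in which `group` forms one side of a
#' bipartition (checked by rooting each replicate at an individual outside
#' the group and testing monophyly).
#'
#' @param boot an `ssr_boot` object.
#' @param group character vector of tip labels.
#' @return support percentage.
#' @export
split_support <- function(boot, group) {
  stopifnot(inherits(boot, "ssr_boot"))
  tips <- boot$tree$tip.label
  stopifnot(all(group %in% tips), length(setdiff(tips, group)) > 0L)
  out <- setdiff(tips, group)[1]
  hit <- vapply(boot$boot_trees, function(t) {
    rt <- ape::root(t, outgroup = out, resolve.root = TRUE)
    ape::is.monophyletic(rt, group)
  }, logical(1))
  100 * mean(hit)
}
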