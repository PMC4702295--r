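#' Normalized score distance between two core rows
#'
#' Over co-occupied core columns, `1 - (S - S_rand) / (S_max - S_rand)`,
#' where S is the summed BLOSUM62 score of the pair, S_max the mean of the
#' two self-scores, and S_rand the background expectation of the column score
#' under the BLOSUM62 marginal frequencies. Clipped at 0; symmetric;
#' `d(a, a) = 0`.
#'
#' @param a,b character vectors (core rows) or indices into `alignment`.
#' @param alignment optional [core_alignment()].
#' @return nonnegative distance.
#' @export
score_distance <- function(a, b, alignment = NULL) {
  if (!is.null(alignment)) {
    a <- alignment$core[a, ]; b <- alignment$core[b, ]
  }
  stopifnot(length(a) == length(b))
  occ <- a != GAP_CHAR & b != GAP_CHAR
  if (!any(occ)) stop("no co-occupied core columns")
  B <- blosum62_matrix()
  ai <- match(a[occ], AA_ALPHABET); bi <- match(b[occ], AA_ALPHABET)
  S <- sum(B[cbind(ai, bi)])
  Smax <- (sum(B[cbind(ai, ai)]) + sum(B[cbind(bi, bi)])) / 2
  e_col <- as.numeric(t(AA_BACKGROUND) %*% B %*% AA_BACKGROUND)
  Srand <- sum(occ) * e_col
  if (Smax - Srand <= 0) return(1)
  max(0, 1 - (S - Srand) / (Smax - Srand))
}

#' All-pairs score distance matrix
#' @param alignment a [core_alignment()].
#' @return symmetric matrix with zero diagonal, labelled by sequence id.
#' @export
distance_matrix <- function(alignment) {
  n <- nrow(alignment$core)
  D <- matrix(0, n, n, dimnames = list(rownames(alignment$core),
                                       rownames(alignment$core)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- score_distance(alignment$core[i, ],
                                         alignment$core[j, ])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration with deterministic tie-breaking
#' (first minimal Q pair in taxon order) and negative branch lengths clamped
#' to 0. Exact on additive matrices.
#'
#' @param D symmetric distance matrix with zero diagonal and row names,
#'   n >= 3.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be nonnegative")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nwk <- labs                       # current subtree newick per active node
  act <- seq_len(n)                 # active indices into D
  Dm <- D
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    # first minimal pair in row-major (i < j) order
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    f <- best[1]; g <- best[2]
    bf <- 0.5 * Dm[f, g] + (r[f] - r[g]) / (2 * (m - 2))
    bg <- Dm[f, g] - bf
    bf <- max(0, bf); bg <- max(0, bg)
    du <- 0.5 * (Dm[f, ] + Dm[g, ] - Dm[f, g])
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[f], bf, nwk[g], bg)
    keep <- setdiff(seq_len(m), c(f, g))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    act <- seq_len(m - 1L)
  }
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  b1 <- max(0, (d12 + d13 - d23) / 2)
  b2 <- max(0, (d12 + d23 - d13) / 2)
  b3 <- max(0, (d13 + d23 - d12) / 2)
  ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                nwk[1], b1, nwk[2], b2, nwk[3], b3))
}

#' Bootstrap neighbor-joining trees
#'
#' Each replicate resamples core columns with replacement (columns with more
#' than 50% gaps are excluded from the resampling pool), recomputes the score
#' distance matrix, and rebuilds the NJ tree. Deterministic per seed.
#'
#' @param alignment a [core_alignment()].
#' @param n_reps number of replicates (>= 1).
#' @param rng_seed integer seed.
#' @return list of `ape::phylo` trees of length `n_reps`.
#' @export
bootstrap_trees <- function(alignment, n_reps = 100L, rng_seed = 1L) {
  stopifnot(n_reps >= 1)
  set.seed(rng_seed)
  core <- alignment$core
  gap_frac <- colMeans(core == GAP_CHAR)
  pool <- which(gap_frac <= 0.5)
  if (!length(pool)) stop("no columns with <= 50% gaps to resample")
  lapply(seq_len(n_reps), function(rep) {
    cols <- sample(pool, length(pool), replace = TRUE)
    neighbor_joining(distance_matrix(core_alignment(
      core[, cols, drop = FALSE])))
  })
}

# canonical key of a bipartition: the side not containing the first taxon,
# as sorted indices into `taxa`
.split_key <- function(tipset, taxa) {
  idx <- sort(match(tipset, taxa))
  if (1L %in% idx) idx <- setdiff(seq_along(taxa), idx)
  paste(idx, collapse = ",")
}

# all nontrivial bipartitions of a tree as keys
.tree_splits <- function(tree, taxa) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (cl in pp) {
    if (length(cl) <= 1L || length(cl) >= length(taxa) - 1L) next
    keys <- c(keys, .split_key(labs[cl], taxa))
  }
  unique(keys)
}

#' Extended majority-rule consensus tree
#'
#' Bipartitions of the input trees are sorted by frequency (ties by first
#' occurrence); every bipartition present in more than half the trees is
#' included, then remaining bipartitions are greedily added in order whenever
#' compatible with all those already accepted. Internal node labels carry the
#' support (percentage of input trees containing the bipartition).
#'
#' @param trees list of `ape::phylo` trees on the same taxon set.
#' @return an `ape::phylo` consensus tree with support node labels.
#' @export
extended_majority_consensus <- function(trees) {
  stopifnot(length(trees) >= 1)
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) stop("trees must share one taxon set")
  }
  counts <- integer(0); first_seen <- integer(0); ord_counter <- 0L
  for (tr in trees) {
    for (key in .tree_splits(tr, taxa)) {
      if (is.na(counts[key])) {
        counts[key] <- 0L
        ord_counter <- ord_counter + 1L
        first_seen[key] <- ord_counter
      }
      counts[key] <- counts[key] + 1L
    }
  }
  nt <- length(trees)
  keys <- names(counts)
  ord <- order(-counts, first_seen[keys])
  keys <- keys[ord]
  sets <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1]]))
  compatible <- function(a, b) {
    length(intersect(a, b)) == 0L || all(a %in% b) || all(b %in% a)
  }
  accepted <- list(); acc_support <- numeric(0)
  for (k in seq_along(keys)) {
    freq <- counts[[keys[k]]] / nt
    if (freq > 0.5 ||
        all(vapply(accepted, compatible, logical(1), b = sets[[k]]))) {
      accepted[[length(accepted) + 1L]] <- sets[[k]]
      acc_support <- c(acc_support, 100 * freq)
    }
  }
  # build the laminar cluster tree (every cluster excludes taxon 1)
  build <- function(members, inside) {
    # inside: indices into `accepted` of clusters strictly within `members`
    kids <- inside[order(-lengths(accepted[inside]))]
    maximal <- integer(0)
    for (k in kids) {
      if (!any(vapply(maximal, function(mm)
        all(accepted[[k]] %in% accepted[[mm]]), logical(1))))
        maximal <- c(maximal, k)
    }
    used <- integer(0)
    parts <- character(0)
    for (k in maximal) {
      sub_inside <- setdiff(inside[vapply(inside, function(j)
        all(accepted[[j]] %in% accepted[[k]]) &&
          length(accepted[[j]]) < length(accepted[[k]]), logical(1))], k)
      parts <- c(parts, sprintf("(%s)%g", build(accepted[[k]], sub_inside),
                                round(acc_support[k], 6)))
      used <- c(used, accepted[[k]])
    }
    loose <- setdiff(members, used)
    paste(c(taxa[loose], parts), collapse = ",")
  }
  all_idx <- seq_along(taxa)
  nwk <- sprintf("(%s);", build(all_idx, seq_along(accepted)))
  ape::read.tree(text = nwk)
}

#' Read and write Newick trees
#'
#' Wrappers over ape supporting internal-node support labels.
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Export a distance matrix in PHYLIP format
#' @param D square labelled matrix.
#' @param path file path.
#' @export
write_phylip_dist <- function(D, path) {
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste(formatC(rownames(D)[i], width = 12, flag = "-"),
                     paste(formatC(D[i, ], digits = 6, format = "f"),
                           collapse = " ")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Export core columns in relaxed PHYLIP for external ML tools
#' @param alignment a [core_alignment()].
#' @param path file path.
#' @export
write_phylip_alignment <- function(alignment, path) {
  core <- alignment$core
  lines <- c(sprintf("%d %d", nrow(core), ncol(core)),
             vapply(seq_len(nrow(core)), function(i)
               paste(rownames(core)[i],
                     paste0(core[i, ], collapse = "")), character(1)))
  writeLines(lines, path)
  invisible(path)
}
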