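test_that("score distance is a proper normalized dissimilarity", {
  a <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(score_distance(a, a), 0)
  set.seed(3)
  for (k in 1:5) {
    b <- sample(AA_ALPHABET, 20, replace = TRUE)
    c2 <- sample(AA_ALPHABET, 20, replace = TRUE)
    expect_equal(score_distance(b, c2), score_distance(c2, b))
    expect_gte(score_distance(b, c2), 0)
  }
  # mutation ladder: distance grows with substitutions
  set.seed(8)
  base <- sample(AA_ALPHABET, 60, replace = TRUE)
  d <- vapply(c(0, 5, 15, 30, 45), function(k) {
    mut <- base
    if (k > 0) {
      pos <- seq_len(k)
      mut[pos] <- vapply(base[pos], function(r)
        sample(setdiff(AA_ALPHABET, r), 1), character(1))
    }
    score_distance(base, mut)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_error(score_distance(c("A", "-"), c("-", "A")), "co-occupied")
})

test_that("neighbor joining is exact on a hand-built additive matrix", {
  # tree ((a:2,b:3):1,c:4,d:5) gives pairwise path lengths below
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"),
                              c("a", "b", "c", "d")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(got, D, tolerance = 1e-8)

  # 3 taxa: the unique unrooted topology with exact branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)], D3,
               tolerance = 1e-8)

  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  bad <- D; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("neighbor joining recovers random additive trees exactly", {
  for (seed in 1:20) {
    n <- sample(4:12, 1)
    ra <- random_additive(n, seed + 400)
    est <- neighbor_joining(ra$D)
    got <- ape::cophenetic.phylo(est)
    got <- got[rownames(ra$D), colnames(ra$D)]
    expect_equal(got, ra$D, tolerance = 1e-6)
    # topology identical to the generating tree
    expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(ra$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("taxon order does not change the NJ topology", {
  ra <- random_additive(8, 77)
  t1 <- neighbor_joining(ra$D)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  t2 <- neighbor_joining(ra$D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("NJ agrees with the independent ape implementation", {
  for (seed in c(11, 12, 13)) {
    ra <- random_additive(9, seed)
    mine <- neighbor_joining(ra$D)
    ref <- ape::nj(ra$D)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap replicates are deterministic and support clear clades", {
  # two well-separated clades: big inter-clade distance, tiny intra
  set.seed(5)
  L <- 60L
  a <- sample(AA_ALPHABET, L, replace = TRUE)
  b <- a
  pos <- sample(L, 45)
  b[pos] <- vapply(a[pos], function(r)
    sample(setdiff(AA_ALPHABET, r), 1), character(1))
  jitter_row <- function(base, k) {
    p <- sample(L, k)
    base[p] <- vapply(base[p], function(r)
      sample(setdiff(AA_ALPHABET, r), 1), character(1))
    base
  }
  rows <- rbind(a, jitter_row(a, 3), jitter_row(a, 3),
                b, jitter_row(b, 3), jitter_row(b, 3))
  rownames(rows) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  aln <- core_alignment(rows)

  trees1 <- bootstrap_trees(aln, n_reps = 100, rng_seed = 9)
  trees2 <- bootstrap_trees(aln, n_reps = 100, rng_seed = 9)
  expect_length(trees1, 100L)
  expect_identical(vapply(trees1, ape::write.tree, character(1)),
                   vapply(trees2, ape::write.tree, character(1)))

  cons <- extended_majority_consensus(trees1)
  # the a/b clade bipartition must be present with >= 95 support
  sup <- tree_split_supports(cons)
  expect_true("b1,b2,b3" %in% names(sup))
  expect_gte(sup[["b1,b2,b3"]], 95)
})

test_that("extended majority consensus follows the greedy rule", {
  # all input trees identical: same topology, all supports 100
  t_str <- "((a,b),(c,d),(e,f));"
  trees <- lapply(1:10, function(i) ape::read.tree(text = t_str))
  cons <- extended_majority_consensus(trees)
  expect_equal(ape::dist.topo(ape::unroot(cons),
                              ape::unroot(trees[[1]])), 0,
               ignore_attr = TRUE)
  expect_true(all(as.numeric(cons$node.label[-1]) == 100))

  # a 60% bipartition appears with support 60
  trees2 <- c(lapply(1:6, function(i)
    ape::read.tree(text = "((a,b),c,(d,(e,f)));")),
    lapply(1:4, function(i)
      ape::read.tree(text = "((a,c),b,(d,(e,f)));")))
  cons2 <- extended_majority_consensus(trees2)
  sup2 <- tree_split_supports(cons2)
  # {a,b} keyed by its complement (the side without taxon a)
  expect_true("c,d,e,f" %in% names(sup2))
  expect_equal(sup2[["c,d,e,f"]], 60)
  expect_false("b,d,e,f" %in% names(sup2))  # 40% rival {a,c} excluded

  # two mutually incompatible minority bipartitions: only the more
  # frequent one is admitted (40% {a,b} vs 35% {b,c}; 25% no structure)
  mk <- function(s, k) lapply(seq_len(k), function(i)
    ape::read.tree(text = s))
  trees3 <- c(mk("((a,b),c,d,e);", 8), mk("((b,c),a,d,e);", 7),
              mk("(a,b,c,d,e);", 5))
  cons3 <- extended_majority_consensus(trees3)
  sup3 <- tree_split_supports(cons3)
  expect_true("c,d,e" %in% names(sup3))     # {a,b} by complement
  expect_equal(sup3[["c,d,e"]], 40)
  expect_false("b,c" %in% names(sup3))      # 35% incompatible rival

  expect_error(extended_majority_consensus(list(
    ape::read.tree(text = "((a,b),c,d);"),
    ape::read.tree(text = "((a,b),c,e);"))), "taxon set")
})
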