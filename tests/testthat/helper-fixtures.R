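# shared fixtures: all built in code, deterministic under fixed seeds

# flat 4-group superfamily used across modules
make_flat_superfamily <- function(seqs_per_group = 30L, rng_seed = 7L, ...) {
  generate_superfamily(superfamily_config(
    n_groups = 4L, seqs_per_group = seqs_per_group, rng_seed = rng_seed, ...))
}

# hierarchy spec matching a flat superfamily, with n seeds per leaf group
make_flat_spec <- function(sf, n_seeds = 3L) {
  hierarchy_spec(c("root", "G1", "G2", "G3", "G4"),
                 c(NA, "root", "root", "root", "root"),
                 seeds = lapply(split(sf$sequences$id, sf$sequences$group),
                                head, n_seeds))
}

# core alignment from equal-length strings (no inserts)
aln_from_strings <- function(strings, ids = NULL) {
  core <- do.call(rbind, strsplit(strings, ""))
  if (is.null(ids)) ids <- paste0("s", seq_along(strings))
  rownames(core) <- ids
  core_alignment(core)
}

# brute-force oracle for local profile alignment with affine gaps:
# enumerate every increasing matching between sequence positions and profile
# columns; unmatched flanks are free, internal gaps cost open+(k-1)*ext per
# run, independently on each side
oracle_align_score <- function(scores, codes, gap_open, gap_extend) {
  n <- length(codes); L <- ncol(scores)
  gap_cost <- function(g) if (g == 0) 0 else gap_open + (g - 1) * gap_extend
  best <- 0
  for (k in seq_len(min(n, L))) {
    I <- utils::combn(n, k)
    J <- utils::combn(L, k)
    for (ci in seq_len(ncol(I))) for (cj in seq_len(ncol(J))) {
      ii <- I[, ci]; jj <- J[, cj]
      s <- sum(scores[cbind(codes[ii], jj)])
      if (k > 1) {
        for (t in 2:k) {
          s <- s - gap_cost(ii[t] - ii[t - 1] - 1) -
            gap_cost(jj[t] - jj[t - 1] - 1)
        }
      }
      if (s > best) best <- s
    }
  }
  best
}

# random additive tree and its exact leaf distance matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# tiny deterministic two-group master + frozen state for CHA rendering
make_cha_state <- function() {
  rows <- c(A1 = "DKLAGYSTRDEFWHKNPLQA",
            A2 = "DKLAGYSTRDEFWHINPLQC",
            A3 = "DKMAGYSTRDEYWHKNPLQA",
            B1 = "EKLAGYSTKDEFWHKNALQA",
            B2 = "EKLAGFSTKDEFWHKNALQA",
            B3 = "EKLAGYSTKDQFWHKNALGA")
  master <- aln_from_strings(unname(rows), names(rows))
  master$inserts[[2]] <- c("5" = "GG")
  spec <- hierarchy_spec(c("root", "A", "B"), c(NA, "root", "root"),
                         seeds = list(A = c("A1", "A2", "A3"),
                                      B = c("B1", "B2", "B3")))
  state <- bpps_state(master, spec, rng_seed = 1L, temperature = 0)
  # plant the discriminating pattern by hand: columns 1 and 9 separate A/B
  state$patterns[[2]] <- list(cols = c(1L, 9L),
                              sets = list("D", "R"))
  state$patterns[[3]] <- list(cols = c(1L, 9L),
                              sets = list("E", "K"))
  state <- corekin:::.rebuild_caches(state)
  list(master = master, state = state)
}

# support values per unrooted bipartition: canonical key is the sorted tip
# set on the side NOT containing the alphabetically first taxon
tree_split_supports <- function(tree) {
  taxa <- sort(tree$tip.label)
  out <- list()
  ntip <- length(tree$tip.label)
  for (nd in seq_len(tree$Nnode) + ntip) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    if (length(tips) <= 1L || length(tips) >= length(taxa) - 1L) next
    if (taxa[1] %in% tips) tips <- setdiff(taxa, tips)
    key <- paste(sort(tips), collapse = ",")
    out[[key]] <- suppressWarnings(as.numeric(tree$node.label[nd - ntip]))
  }
  out
}

# three families around engineered representatives: members ~80% identical
# to their representative, representatives ~30% identical to each other
make_three_families <- function(n_members = 6L, seed = 17L) {
  set.seed(seed)
  L <- 50L
  base <- sample(AA_ALPHABET, L, replace = TRUE)
  mutate <- function(row, k) {
    pos <- sample(L, k)
    row[pos] <- vapply(row[pos], function(r)
      sample(setdiff(AA_ALPHABET, r), 1), character(1))
    row
  }
  reps <- list(base, mutate(base, 35L), mutate(mutate(base, 18L), 17L))
  rows <- list(); ids <- character(0); truth <- integer(0)
  for (f in 1:3) {
    for (m in seq_len(n_members)) {
      rows[[length(rows) + 1L]] <- if (m == 1) reps[[f]]
        else mutate(reps[[f]], 10L)
      ids <- c(ids, sprintf("F%d_%d", f, m))
      truth <- c(truth, f)
    }
  }
  core <- do.call(rbind, rows)
  rownames(core) <- ids
  list(aln = core_alignment(core), truth = truth)
}

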