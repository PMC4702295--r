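test_that("a profile's own consensus aligns gap-free over all columns", {
  sf <- make_flat_superfamily(seqs_per_group = 12L)
  p <- build_profile(sf$alignment, name = "all")
  aln <- align_to_profile(p$consensus, p)
  expect_equal(aln$col_map, seq_len(ncol(p$scores)))
  expect_gt(aln$score, 25)
})

test_that("alignment DP equals the brute-force oracle on small instances", {
  set.seed(101)
  for (trial in 1:12) {
    L <- sample(2:8, 1); n <- sample(2:8, 1)
    scores <- matrix(stats::rnorm(20 * L, sd = 3), 20, L,
                     dimnames = list(AA_ALPHABET, NULL))
    codes <- sample(20, n, replace = TRUE)
    prof <- structure(list(scores = scores, consensus = NULL,
                           name = "toy", parent_name = NULL,
                           gap_open = 4, gap_extend = 1), class = "Profile")
    got <- align_to_profile(paste0(AA_ALPHABET[codes], collapse = ""), prof)
    want <- oracle_align_score(scores, codes, 4, 1)
    expect_equal(got$score, want, tolerance = 1e-9)
  }
})

test_that("shuffled sequences fall below the significance threshold", {
  sf <- make_flat_superfamily(seqs_per_group = 30L)
  g1 <- sf$alignment[sf$sequences$group == "G1"]
  p <- build_profile(g1, position_based_weights(g1), name = "G1")
  seq1 <- strsplit(sf$sequences$seq[1], "")[[1]]
  set.seed(13)
  below <- vapply(1:100, function(i) {
    shuf <- paste0(sample(seq1), collapse = "")
    align_to_profile(shuf, p)$score < 25
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("best_profile picks the true group and handles degenerate cases", {
  sf <- make_flat_superfamily(seqs_per_group = 25L)
  idx <- split(seq_len(nrow(sf$alignment$core)), sf$sequences$group)
  profs <- lapply(names(idx), function(nm) {
    a <- sf$alignment[idx[[nm]]]
    build_profile(a, position_based_weights(a), name = nm,
                  parent_name = NULL)
  })
  names(profs) <- names(idx)
  g2seq <- sf$sequences$seq[sf$sequences$group == "G2"][1]
  bp <- best_profile(g2seq, profs)
  expect_identical(bp$profile, "G2")
  expect_identical(bp$status, "classified")

  one <- best_profile(g2seq, profs["G2"])
  expect_identical(one$profile, "G2")

  set.seed(4)
  junk <- paste0(sample(AA_ALPHABET, 40, replace = TRUE,
                        prob = AA_BACKGROUND), collapse = "")
  un <- best_profile(junk, profs)
  expect_identical(un$status, "unclassified")
  expect_true(is.na(un$profile))
})

test_that("core mapping stores inserts at the preceding column and is lossless", {
  # conserved motif columns flanking the insert point anchor the mapping
  ins <- data.frame(after_col = 30L, min_len = 7L, max_len = 7L)
  cfg <- superfamily_config(n_groups = 2L, seqs_per_group = 15L,
                            insert_points = ins, rng_seed = 21L,
                            catalytic_columns = c("1" = "W", "5" = "K",
                                                  "28" = "H", "29" = "R",
                                                  "30" = "D", "31" = "W",
                                                  "32" = "F", "40" = "D",
                                                  "41" = "F", "42" = "G",
                                                  "60" = "W"))
  sf <- generate_superfamily(cfg)
  idx <- split(seq_len(nrow(sf$alignment$core)), sf$sequences$group)
  profs <- lapply(names(idx), function(nm) {
    a <- sf$alignment[idx[[nm]]]
    build_profile(a, position_based_weights(a), name = nm)
  })
  names(profs) <- names(idx)
  cons_rows <- rbind(root = strsplit(consensus_seq(sf$alignment), "")[[1]],
                     do.call(rbind, lapply(profs, function(p)
                       strsplit(p$consensus, "")[[1]])))
  rownames(cons_rows) <- c("root", names(profs))
  tpl <- template_alignment(cons_rows, "root")

  # root consensus maps to itself (identity column map)
  root_prof <- build_profile(sf$alignment, name = "root")
  tpl2 <- template_alignment(
    rbind(root = strsplit(root_prof$consensus, "")[[1]]), "root")
  self <- map_to_core(align_to_profile(root_prof$consensus, root_prof), tpl2)
  expect_identical(unname(self$core[1, ]),
                   strsplit(root_prof$consensus, "")[[1]])

  for (i in seq_len(nrow(sf$sequences))) {
    bp <- best_profile(sf$sequences$seq[i], profs)
    row <- map_to_core(bp$alignment, tpl, id = sf$sequences$id[i])
    # losslessness for every sequence
    expect_identical(degap(row)$seq, sf$sequences$seq[i])
  }
  # the planted 7-residue insert lands at key 30, between the conserved
  # flanking motif columns
  exact <- vapply(seq_len(nrow(sf$sequences)), function(i) {
    bp <- best_profile(sf$sequences$seq[i], profs)
    row <- map_to_core(bp$alignment, tpl)
    identical(names(row$inserts[[1]]), "30") &&
      nchar(row$inserts[[1]][["30"]]) == 7L
  }, logical(1))
  expect_gte(mean(exact), 0.9)
})

test_that("nearly all sequences are assigned their true group profile", {
  sf <- make_flat_superfamily(seqs_per_group = 50L, rng_seed = 31L,
                              fg_match_prob = 0.95, bg_match_prob = 0.05)
  idx <- split(seq_len(nrow(sf$alignment$core)), sf$sequences$group)
  profs <- lapply(names(idx), function(nm) {
    a <- sf$alignment[idx[[nm]]]
    build_profile(a, position_based_weights(a), name = nm)
  })
  names(profs) <- names(idx)
  hits <- vapply(seq_len(nrow(sf$sequences)), function(i)
    identical(best_profile(sf$sequences$seq[i], profs)$profile,
              sf$sequences$group[i]), logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("profile iteration reaches a fixed point and reduces churn", {
  expect_error(iterate_profiles(list(), n_rounds = 0), "n_rounds")

  # noiseless data generated exactly from the group profiles: converged
  # after one round, zero changes at round 2
  no_ins <- data.frame(after_col = integer(0), min_len = integer(0),
                       max_len = integer(0))
  # conserved first and last columns prevent local end-trimming ties
  cfg <- superfamily_config(n_groups = 2L, seqs_per_group = 20L,
                            fg_match_prob = 1, bg_match_prob = 0,
                            insert_points = no_ins, rng_seed = 12L,
                            catalytic_columns = c("1" = "W", "5" = "K",
                                                  "25" = "D", "40" = "D",
                                                  "41" = "F", "42" = "G",
                                                  "60" = "W"))
  sf <- generate_superfamily(cfg)
  groups <- lapply(split(seq_len(nrow(sf$alignment$core)),
                         sf$sequences$group),
                   function(i) sf$alignment[i])
  it <- iterate_profiles(groups, n_rounds = 2)
  expect_equal(it$changes[2], 0L)

  # noisy data: churn does not increase between rounds
  sf2 <- make_flat_superfamily(seqs_per_group = 15L, rng_seed = 14L)
  groups2 <- lapply(split(seq_len(nrow(sf2$alignment$core)),
                          sf2$sequences$group),
                    function(i) sf2$alignment[i])
  it2 <- iterate_profiles(groups2, n_rounds = 2)
  expect_lte(it2$changes[2], it2$changes[1])
  # master is still lossless
  dg <- degap(it2$master)
  orig <- setNames(sf2$sequences$seq, sf2$sequences$id)
  expect_identical(unname(orig[dg$id]), dg$seq)
})

test_that("A2M and Stockholm writers round-trip core structure", {
  sf <- make_flat_superfamily(seqs_per_group = 5L)
  a2m <- tempfile(fileext = ".a2m")
  write_a2m(sf$alignment, a2m)
  back <- read_a2m(a2m)
  expect_identical(back$core, sf$alignment$core)
  expect_identical(degap(back)$seq, sf$sequences$seq)

  sto <- tempfile(fileext = ".sto")
  write_stockholm(sf$alignment, sto)
  backs <- read_stockholm(sto)
  expect_identical(backs$core, sf$alignment$core)
})
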