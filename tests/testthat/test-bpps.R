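test_that("hierarchy parsing handles indentation, markers and validation", {
  spec <- read_hierarchy(text = "ELK?\n  APH\n    APH2\n    APH3\n  CAK")
  expect_identical(spec$names, c("ELK", "APH", "APH2", "APH3", "CAK"))
  expect_identical(spec$names[spec$parent[match("APH2", spec$names)]], "APH")
  expect_true(spec$internal[match("ELK", spec$names)])
  expect_identical(spec$names[spec$is_leaf], c("APH2", "APH3", "CAK"))

  expect_error(hierarchy_spec(c("a", "b"), c(NA, NA)), "exactly one root")
  expect_error(hierarchy_spec(c("a", "b"), c(NA, "a")), "2 leaf")
  expect_error(hierarchy_spec(c("a", "b", "c"), c(NA, "a", "a"),
                              seeds = list(a = "x")), "leaf nodes")
})

test_that("column contrast matches numeric integration and sign contracts", {
  # numeric-quadrature oracle for the beta-binomial evidence ratio
  num_contrast <- function(fm, ft, bm, bt, a = 0.5, b = 0.5) {
    ev <- function(m, t) stats::integrate(function(p)
      p^(m + a - 1) * (1 - p)^(t - m + b - 1), 0, 1,
      rel.tol = 1e-10)$value / beta(a, b)
    log(ev(fm, ft) * ev(bm, bt) / ev(fm + bm, ft + bt))
  }
  cases <- list(c(50, 50, 0, 500), c(25, 50, 250, 500), c(3, 7, 11, 90),
                c(18.5, 20.25, 4.75, 300.5))
  for (cs in cases) {
    expect_equal(column_contrast(cs[1], cs[2], cs[3], cs[4]),
                 num_contrast(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-3)
  }
  expect_gt(column_contrast(50, 50, 0, 500), 0)
  expect_lte(column_contrast(25, 50, 250, 500), 0)
  expect_error(column_contrast(0, 0, 1, 10), "positive")
  expect_error(column_contrast(5, 4, 1, 10), "exceed")
})

# small planted superfamily with a frozen truth-configured state
make_truth_state <- function(seqs_per_group = 30L, rng_seed = 7L) {
  sf <- make_flat_superfamily(seqs_per_group = seqs_per_group,
                              rng_seed = rng_seed)
  spec <- make_flat_spec(sf)
  st <- bpps_state(sf$alignment, spec, rng_seed = 1L, temperature = 0)
  st$z <- match(sf$truth$groups[st$ids], st$spec$names)
  for (g in paste0("G", 1:4)) {
    v <- match(g, st$spec$names)
    pat <- sf$truth$patterns[[g]]
    st$patterns[[v]] <- list(cols = as.integer(names(pat)),
                             sets = lapply(unname(pat), identity))
  }
  st <- corekin:::.rebuild_caches(st)
  st$log_score <- total_log_score(st)
  list(sf = sf, state = st)
}

test_that("node_score rewards true planted patterns column by column", {
  ts <- make_truth_state()
  st <- ts$state
  v <- match("G1", st$spec$names)
  expect_error(node_score(st, "root"), "root")

  full <- node_score(st, "G1")
  empty <- st
  empty$patterns[[v]] <- list(cols = integer(0), sets = list())
  empty <- corekin:::.rebuild_caches(empty)
  expect_equal(node_score(empty, "G1"), 0)

  # removing any single true column strictly lowers the score
  pat <- st$patterns[[v]]
  for (k in seq_along(pat$cols)) {
    st_k <- st
    st_k$patterns[[v]] <- list(cols = pat$cols[-k], sets = pat$sets[-k])
    st_k <- corekin:::.rebuild_caches(st_k)
    expect_lt(node_score(st_k, "G1"), full)
  }

  # a column where fg and bg frequencies are equal lowers the score:
  # catalytic columns are invariant across groups
  cat_col <- 5L  # catalytic K shared by every sequence
  st_c <- st
  st_c$patterns[[v]] <- list(cols = c(pat$cols, cat_col),
                             sets = c(pat$sets, list("K")))
  st_c <- corekin:::.rebuild_caches(st_c)
  expect_lt(node_score(st_c, "G1"), full)
})

test_that("gibbs sweeps respect constraints and are deterministic", {
  sf <- make_flat_superfamily(seqs_per_group = 15L, rng_seed = 19L)
  spec <- make_flat_spec(sf)
  st <- bpps_state(sf$alignment, spec, rng_seed = 2L, temperature = 2)
  seed_rows <- which(!is.na(st$seed_node))
  expect_gt(length(seed_rows), 0)

  st_a <- gibbs_sweep(st, rng_seed = 5L)
  st_b <- gibbs_sweep(st, rng_seed = 5L)
  expect_identical(st_a$z, st_b$z)
  expect_identical(st_a$patterns, st_b$patterns)
  # seed assignments never move
  expect_identical(st_a$z[seed_rows], st$z[seed_rows])

  # candidate-assignment sampling distribution is normalized
  st_rm <- corekin:::.apply_seq(st, 1L, st$z[1L], -1)
  S <- corekin:::.assignment_scores(st_rm, 1L)
  p <- exp((S - max(S)) / st$temperature)
  expect_equal(sum(p / sum(p)), 1)
  expect_length(S, sum(spec$is_leaf))
})

test_that("foreground/background bookkeeping is exact after sweeps", {
  sf <- make_flat_superfamily(seqs_per_group = 12L, rng_seed = 23L)
  spec <- make_flat_spec(sf)
  st <- gibbs_sweep(bpps_state(sf$alignment, spec, rng_seed = 3L,
                               temperature = 1))
  for (v in seq_along(st$spec$names)) {
    if (v == st$root) next
    par <- st$spec$parent[v]
    n_fg <- sum(st$z %in% st$sub[[v]])
    n_bg <- sum(st$z %in% st$sub[[par]]) - n_fg
    expect_equal(n_fg + n_bg, sum(st$z %in% st$sub[[par]]))
    # cached weighted totals agree with direct recomputation
    cc <- st$caches[[v]]
    expect_equal(cc$fgw, sum(st$w[st$z %in% st$sub[[v]]]), tolerance = 1e-9)
    expect_equal(cc$bgw, sum(st$w[st$z %in% st$sub[[par]]]) - cc$fgw,
                 tolerance = 1e-9)
  }
})

test_that("greedy mode never decreases the total log-score", {
  ts <- make_truth_state(seqs_per_group = 12L, rng_seed = 29L)
  st <- ts$state
  # scramble assignments, keep greedy temperature
  set.seed(9)
  free <- is.na(st$seed_node)
  st$z[free] <- sample(st$leaves, sum(free), replace = TRUE)
  st <- corekin:::.rebuild_caches(st)
  st$temperature <- 0
  st$log_score <- total_log_score(st)
  scores <- numeric(50)
  for (k in 1:50) {
    st <- gibbs_sweep(st)
    scores[k] <- st$log_score
  }
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("pattern residue sets always contain the seed-consensus residue", {
  sf <- make_flat_superfamily(seqs_per_group = 20L, rng_seed = 37L)
  spec <- make_flat_spec(sf)
  res <- run_mcbpps(sf$alignment, spec, n_sweeps = 15L, burn_in = 8L,
                    rng_seed = 4L)
  st <- res$state
  for (v in seq_along(st$spec$names)) {
    if (v == st$root) next
    pat <- st$patterns[[v]]
    for (k in seq_along(pat$cols)) {
      cons <- st$seed_cons[v, pat$cols[k]]
      if (!is.na(cons) && cons != "-")
        expect_true(cons %in% pat$sets[[k]])
    }
  }
})

test_that("the sampler recovers planted structure and is deterministic", {
  sf <- make_flat_superfamily(seqs_per_group = 30L, rng_seed = 7L)
  spec <- make_flat_spec(sf)
  res1 <- run_mcbpps(sf$alignment, spec, n_sweeps = 25L, burn_in = 15L,
                     rng_seed = 3L)
  res2 <- run_mcbpps(sf$alignment, spec, n_sweeps = 25L, burn_in = 15L,
                     rng_seed = 3L)
  expect_identical(res1$state$z, res2$state$z)
  expect_identical(res1$state$patterns, res2$state$patterns)
  expect_identical(res1$report, res2$report)

  acc <- mean(res1$assignments[sf$sequences$id] == sf$sequences$group)
  expect_gte(acc, 0.95)
  for (g in paste0("G", 1:4)) {
    planted <- as.integer(names(sf$truth$patterns[[g]]))
    got <- res1$report$column[res1$report$node == g]
    expect_gte(sum(planted %in% got) / length(planted), 0.8)
  }
  # report and markers agree on 1-based columns inside the core
  expect_true(all(res1$report$column >= 1 &
                    res1$report$column <= ncol(sf$alignment$core)))
})
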