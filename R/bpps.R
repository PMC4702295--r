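#' Subgroup hierarchy specification
#'
#' Nodes arranged in a single-rooted tree; each node may carry seed sequence
#' ids (sequences fixed to that subgroup throughout sampling) and an
#' "internal" flag marking higher-level groups, which acquire membership only
#' through their subtrees. Assignment moves operate on leaf nodes.
#'
#' @param names node names (character).
#' @param parents parent name per node (`NA` for the single root).
#' @param internal logical per node; defaults to "has children".
#' @param seeds named list: node name -> character vector of sequence ids.
#' @return object of class `HierarchySpec`.
#' @export
hierarchy_spec <- function(names, parents, internal = NULL, seeds = list()) {
  stopifnot(length(names) == length(parents), !anyDuplicated(names))
  root <- which(is.na(parents))
  if (length(root) != 1L) stop("hierarchy must have exactly one root")
  pidx <- match(parents, names)
  if (any(is.na(pidx) & !is.na(parents))) stop("unknown parent name")
  # acyclicity: walking up from every node must terminate
  for (v in seq_along(names)) {
    seen <- logical(length(names)); u <- v
    while (!is.na(pidx[u])) {
      if (seen[u]) stop("hierarchy contains a cycle")
      seen[u] <- TRUE; u <- pidx[u]
    }
  }
  has_child <- seq_along(names) %in% pidx
  if (is.null(internal)) internal <- has_child
  is_leaf <- !has_child
  if (sum(is_leaf) < 2L) stop("hierarchy must have at least 2 leaf nodes")
  if (length(seeds)) {
    stopifnot(all(names(seeds) %in% names))
    if (anyDuplicated(unlist(seeds)))
      stop("each seed sequence may be assigned to exactly one node")
    bad <- names(seeds)[!names(seeds) %in% names[is_leaf]]
    if (length(bad)) stop("seeds must be attached to leaf nodes: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(names = names, parent = pidx, internal = internal,
                 is_leaf = is_leaf, seeds = seeds),
            class = "HierarchySpec")
}

#' Read a hierarchy from indented plain text
#'
#' One node per line; indentation (two spaces per level, tabs count as one
#' level) gives the parent; a trailing `?` marks a higher-level (internal)
#' group.
#'
#' @param path file path (or use `text =` for a literal string).
#' @param text literal text instead of a file.
#' @return a [hierarchy_spec()].
#' @export
read_hierarchy <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else
    strsplit(text, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  indent <- vapply(lines, function(l) {
    lead <- sub("^([ \t]*).*$", "\\1", l)
    nchar(gsub("\t", "  ", lead)) %/% 2L
  }, integer(1))
  nm <- trimws(lines)
  internal_mark <- grepl("\\?$", nm)
  nm <- sub("\\?$", "", nm)
  parents <- rep(NA_character_, length(nm))
  for (i in seq_along(nm)) {
    if (indent[i] > 0L) {
      j <- max(which(indent[seq_len(i - 1L)] == indent[i] - 1L))
      parents[i] <- nm[j]
    }
  }
  spec <- hierarchy_spec(nm, parents)
  spec$internal <- spec$internal | internal_mark
  spec
}

# subtree leaf indices for every node
subtree_leaves <- function(spec) {
  children <- lapply(seq_along(spec$names),
                     function(v) which(spec$parent == v))
  out <- vector("list", length(spec$names))
  rec <- function(v) {
    if (spec$is_leaf[v]) { out[[v]] <<- v; return(v) }
    lv <- unlist(lapply(children[[v]], rec))
    out[[v]] <<- lv
    lv
  }
  rec(which(is.na(spec$parent)))
  out
}

#' Column contrast: two-binomial vs one-binomial log Bayes factor
#'
#' Log of the beta-binomial marginal evidence for separate foreground and
#' background match rates minus that for a single shared rate, with
#' Beta(alpha, beta) priors (Jeffreys by default). Counts may be real-valued
#' (weighted). Positive values favor distinct rates.
#'
#' @param fg_match,fg_total,bg_match,bg_total (weighted) match counts and
#'   totals; vectors are accepted and recycled.
#' @param alpha,beta prior parameters (default Jeffreys, 0.5/0.5).
#' @return numeric log Bayes factor(s), natural log.
#' @export
column_contrast <- function(fg_match, fg_total, bg_match, bg_total,
                            alpha = 0.5, beta = 0.5) {
  if (any(fg_total <= 0) || any(bg_total <= 0))
    stop("foreground and background totals must be positive")
  if (any(fg_match > fg_total + 1e-9) || any(bg_match > bg_total + 1e-9))
    stop("match counts cannot exceed totals")
  .contrast(fg_match, fg_total, bg_match, bg_total, alpha, beta)
}

# internal vectorized contrast; returns 0 where a side is empty
.contrast <- function(fm, ft, bm, bt, alpha = 0.5, beta = 0.5) {
  fm <- pmin(pmax(fm, 0), ft); bm <- pmin(pmax(bm, 0), bt)
  out <- lbeta(fm + alpha, ft - fm + beta) +
    lbeta(bm + alpha, bt - bm + beta) -
    lbeta(fm + bm + alpha, (ft - fm) + (bt - bm) + beta) -
    lbeta(alpha, beta)
  out[ft <= 0 | bt <= 0] <- 0
  out
}

#' Initialize a Bayesian partitioning-with-pattern-selection state
#'
#' Seed sequences are fixed to their nodes; all other sequences start at
#' random leaf assignments, and every non-root node starts with a random
#' pattern at randomly selected columns (residue sets drawn from the
#' biochemical catalog, constrained to contain the node's seed-consensus
#' residue where seeds exist).
#'
#' @param master a [core_alignment()].
#' @param spec a [hierarchy_spec()].
#' @param rng_seed integer seed.
#' @param rho geometric pattern-size prior parameter (default 0.2); see
#'   [node_score()] for the full per-column penalty.
#' @param temperature initial sampling temperature.
#' @param init_pattern_size initial pattern columns per node.
#' @param init `"random"` (default) starts each node at random columns with
#'   random eligible residue sets; `"seed"` starts at the columns whose seed
#'   alignments most contrast with the rest of the master.
#' @param weights optional [position_based_weights()]; computed if `NULL`.
#' @return object of class `BPPSState`.
#' @export
bpps_state <- function(master, spec, rng_seed = 1L, rho = 0.2,
                       temperature = 3, init_pattern_size = 3L,
                       init = c("random", "seed"), weights = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(master, "CoreAlignment"),
            inherits(spec, "HierarchySpec"))
  set.seed(rng_seed)
  codes <- aa_encode(master$core)
  n <- nrow(codes); L <- ncol(codes)
  ids <- rownames(master$core)
  if (is.null(weights)) weights <- position_based_weights(master)
  w <- unname(resolve_weights(weights, n))

  leaves <- which(spec$is_leaf)
  sub <- subtree_leaves(spec)
  root <- which(is.na(spec$parent))

  seed_node <- rep(NA_integer_, n)
  for (nm in names(spec$seeds)) {
    idx <- match(spec$seeds[[nm]], ids)
    if (anyNA(idx))
      stop("seed sequences missing from master: ",
           paste(spec$seeds[[nm]][is.na(idx)], collapse = ", "))
    seed_node[idx] <- match(nm, spec$names)
  }
  z <- ifelse(is.na(seed_node),
              sample(leaves, n, replace = TRUE), seed_node)

  # per node: seed-consensus residue per column (seeds of the whole subtree)
  seed_cons <- matrix(NA_character_, length(spec$names), L)
  for (v in seq_along(spec$names)) {
    rows <- which(seed_node %in% sub[[v]])
    if (length(rows)) {
      cons <- consensus_seq(core_alignment(
        master$core[rows, , drop = FALSE]))
      seed_cons[v, ] <- strsplit(cons, "")[[1]]
    }
  }

  catalog <- residue_class_catalog()
  patterns <- vector("list", length(spec$names))
  for (v in seq_along(spec$names)) {
    if (v == root) { patterns[[v]] <- list(cols = integer(0), sets = list());
      next }
    if (init == "seed" && any(seed_node %in% sub[[v]])) {
      fg_rows <- which(seed_node %in% sub[[v]])
      bg_rows <- setdiff(seq_len(n), fg_rows)
      fgW <- sum(w[fg_rows]); bgW <- sum(w[bg_rows])
      best_con <- rep(-Inf, L); best_set <- vector("list", L)
      cf <- weighted_counts(aa_decode(codes[fg_rows, , drop = FALSE]),
                            w[fg_rows])$counts
      cb <- weighted_counts(aa_decode(codes[bg_rows, , drop = FALSE]),
                            w[bg_rows])$counts
      for (cc in seq_len(L)) {
        for (s in .eligible_sets(catalog, seed_cons[v, cc])) {
          rows <- match(catalog[[s]], AA_ALPHABET)
          fm <- sum(cf[rows, cc]); bm <- sum(cb[rows, cc])
          if (fm / fgW <= bm / bgW) next
          con <- .contrast(fm, fgW, bm, bgW)
          if (con > best_con[cc]) { best_con[cc] <- con
            best_set[[cc]] <- catalog[[s]] }
        }
      }
      cols <- order(-best_con)[seq_len(min(init_pattern_size, L))]
      cols <- sort(cols[is.finite(best_con[cols])])
      patterns[[v]] <- list(cols = cols, sets = best_set[cols])
    } else {
      cols <- sort(sample(L, min(init_pattern_size, L)))
      sets <- lapply(cols, function(cc) {
        elig <- .eligible_sets(catalog, seed_cons[v, cc])
        catalog[[sample(elig, 1L)]]
      })
      patterns[[v]] <- list(cols = cols, sets = sets)
    }
  }

  # static scenario table: scen[v, leaf] = 1 out, 2 fg, 3 bg
  scen <- matrix(1L, length(spec$names), length(spec$names))
  for (v in seq_along(spec$names)) {
    if (v == root) next
    scen[v, sub[[v]]] <- 2L
    scen[v, setdiff(sub[[spec$parent[v]]], sub[[v]])] <- 3L
  }

  state <- list(codes = codes, ids = ids, w = w,
                weights = weights, spec = spec, sub = sub, root = root,
                leaves = leaves, seed_node = seed_node,
                seed_cons = seed_cons, catalog = catalog,
                z = z, patterns = patterns, scen = scen,
                rho = rho, temperature = temperature, t0 = temperature,
                iteration = 0L)
  class(state) <- "BPPSState"
  state <- .rebuild_caches(state)
  state$log_score <- total_log_score(state)
  state
}

#' @export
print.BPPSState <- function(x, ...) {
  cat(sprintf("BPPSState: %d sequences, %d nodes, iteration %d, log-score %.2f\n",
              length(x$z), length(x$spec$names), x$iteration, x$log_score))
  invisible(x)
}

# eligible catalog set indices at a column given a seed consensus residue
.eligible_sets <- function(catalog, cons_res) {
  if (is.na(cons_res) || cons_res == GAP_CHAR) return(seq_along(catalog))
  which(vapply(catalog, function(s) cons_res %in% s, logical(1)))
}

# match-indicator and weighted count caches per non-root node
.rebuild_caches <- function(state) {
  n <- nrow(state$codes)
  caches <- vector("list", length(state$spec$names))
  for (v in seq_along(state$spec$names)) {
    if (v == state$root) next
    pat <- state$patterns[[v]]
    k <- length(pat$cols)
    M <- matrix(FALSE, n, k)
    if (k) for (j in seq_len(k)) {
      set_codes <- match(pat$sets[[j]], AA_ALPHABET)
      M[, j] <- state$codes[, pat$cols[j]] %in% set_codes
    }
    in_fg <- state$z %in% state$sub[[v]]
    in_bg <- state$z %in% state$sub[[state$spec$parent[v]]] & !in_fg
    caches[[v]] <- list(
      M = M,
      fgw = sum(state$w[in_fg]), bgw = sum(state$w[in_bg]),
      fgm = if (k) colSums(state$w[in_fg] * M[in_fg, , drop = FALSE])
            else numeric(0),
      bgm = if (k) colSums(state$w[in_bg] * M[in_bg, , drop = FALSE])
            else numeric(0))
  }
  state$caches <- caches
  state
}

#' Log-score of one hierarchy node
#'
#' Sum of [column_contrast()] over the node's pattern columns — foreground =
#' subtree of the node, background = rest of the parent's subtree — minus a
#' per-column complexity penalty. The penalty is the full pattern prior: a
#' geometric size prior contributing `log(rho)` per column, plus the
#' column-choice and residue-set-choice factors `-log(L)` and
#' `-log(n eligible sets)` (a pattern of size k also selects which columns
#' and which residue sets, so uniform choice priors act as the Bayesian
#' multiple-testing correction that keeps pattern-free data pattern-free).
#' The root has no parent contrast and is an error.
#'
#' @param state a [bpps_state()].
#' @param node node name or index.
#' @return numeric log-score (0 for an empty pattern).
#' @export
node_score <- function(state, node) {
  if (is.character(node)) node <- match(node, state$spec$names)
  if (is.na(node) || node == state$root)
    stop("node_score is undefined for the root node")
  cc <- state$caches[[node]]
  pat <- state$patterns[[node]]
  k <- length(pat$cols)
  if (k == 0L) return(0)
  sum(.contrast(cc$fgm, rep(cc$fgw, k), cc$bgm, rep(cc$bgw, k))) +
    sum(.col_penalty(state, node, pat$cols))
}

# per-column pattern prior: geometric size term plus uniform column- and
# residue-set-choice terms
.col_penalty <- function(state, v, cols) {
  L <- ncol(state$codes)
  n_elig <- vapply(cols, function(cc)
    length(.eligible_sets(state$catalog, state$seed_cons[v, cc])), numeric(1))
  log(state$rho) - log(L) - log(n_elig)
}

#' Total log-score of a partition state
#' @param state a [bpps_state()].
#' @return sum of [node_score()] over all non-root nodes.
#' @export
total_log_score <- function(state) {
  sum(vapply(setdiff(seq_along(state$spec$names), state$root),
             function(v) node_score(state, v), numeric(1)))
}

# per-sequence candidate-leaf log-scores (up to a constant shared by all
# candidates); used by the assignment phase and by normalization tests
.assignment_scores <- function(state, i) {
  nn <- length(state$spec$names)
  smat <- matrix(0, 3L, nn)   # rows: out, fg, bg
  wi <- state$w[i]
  for (v in seq_len(nn)) {
    if (v == state$root) next
    cc <- state$caches[[v]]
    k <- length(state$patterns[[v]]$cols)
    if (k == 0L) next
    mi <- cc$M[i, ]
    # caches must exclude sequence i when this is called mid-move
    ftv <- rep(cc$fgw, k); btv <- rep(cc$bgw, k)
    smat[1L, v] <- sum(.contrast(cc$fgm, ftv, cc$bgm, btv))
    smat[2L, v] <- sum(.contrast(cc$fgm + wi * mi, ftv + wi, cc$bgm, btv))
    smat[3L, v] <- sum(.contrast(cc$fgm, ftv, cc$bgm + wi * mi, btv + wi))
  }
  vapply(state$leaves, function(lf)
    sum(smat[cbind(state$scen[, lf], seq_len(nn))]), numeric(1))
}

# add/remove sequence i's contribution to the count caches (sign +1/-1),
# given its current leaf assignment
.apply_seq <- function(state, i, leaf, sign) {
  wi <- state$w[i] * sign
  for (v in seq_along(state$spec$names)) {
    if (v == state$root) next
    s <- state$scen[v, leaf]
    if (s == 1L) next
    cc <- state$caches[[v]]
    mi <- cc$M[i, ]
    if (s == 2L) {
      cc$fgw <- cc$fgw + wi
      if (length(mi)) cc$fgm <- cc$fgm + wi * mi
    } else {
      cc$bgw <- cc$bgw + wi
      if (length(mi)) cc$bgm <- cc$bgm + wi * mi
    }
    state$caches[[v]] <- cc
  }
  state
}

#' One full Gibbs sweep over assignments and patterns
#'
#' (a) Every non-seed sequence's leaf assignment is resampled with probability
#' proportional to `exp(delta log-score / T)` (greedy argmax at T = 0).
#' (b) Every non-root node's pattern is resampled column-wise: because the
#' node score is additive over pattern columns, each column's inclusion is
#' conditionally independent and is Gibbs-resampled with probability
#' `sigmoid((contrast + log rho) / T)` using its best eligible residue set
#' (sampled softmax at T > 0); at T = 0 a column is included exactly when its
#' score is positive. Only foreground-enriched columns are eligible, and
#' residue sets always contain the node's seed-consensus residue.
#'
#' @param state a [bpps_state()].
#' @param rng_seed optional; reseeds the RNG for a reproducible single sweep.
#' @return the updated state (iteration counter advanced, log-score updated).
#' @export
gibbs_sweep <- function(state, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  Tt <- state$temperature
  # (a) assignments
  for (i in seq_along(state$z)) {
    if (!is.na(state$seed_node[i])) next
    state <- .apply_seq(state, i, state$z[i], -1)
    S <- .assignment_scores(state, i)
    if (Tt <= 1e-9) {
      # greedy; ties keep the current assignment (coordinate ascent)
      top <- state$leaves[S >= max(S) - 1e-12]
      pick <- if (state$z[i] %in% top) state$z[i] else top[1]
    } else {
      p <- exp((S - max(S)) / Tt)
      pick <- state$leaves[sample.int(length(S), 1L, prob = p)]
    }
    state$z[i] <- pick
    state <- .apply_seq(state, i, pick, +1)
  }
  # (b) patterns, column-wise
  L <- ncol(state$codes)
  for (v in seq_along(state$spec$names)) {
    if (v == state$root) next
    in_fg <- state$z %in% state$sub[[v]]
    in_bg <- state$z %in% state$sub[[state$spec$parent[v]]] & !in_fg
    fgW <- sum(state$w[in_fg]); bgW <- sum(state$w[in_bg])
    if (fgW <= 0 || bgW <= 0) {
      state$patterns[[v]] <- list(cols = integer(0), sets = list())
      next
    }
    cnt_fg <- weighted_counts(aa_decode(state$codes[in_fg, , drop = FALSE]),
                              state$w[in_fg])$counts
    cnt_bg <- weighted_counts(aa_decode(state$codes[in_bg, , drop = FALSE]),
                              state$w[in_bg])$counts
    nset <- length(state$catalog)
    fm <- matrix(0, nset, L); bm <- matrix(0, nset, L)
    for (s in seq_len(nset)) {
      rows <- match(state$catalog[[s]], AA_ALPHABET)
      fm[s, ] <- colSums(cnt_fg[rows, , drop = FALSE])
      bm[s, ] <- colSums(cnt_bg[rows, , drop = FALSE])
    }
    con <- .contrast(fm, matrix(fgW, nset, L), bm, matrix(bgW, nset, L))
    con[fm / fgW <= bm / bgW] <- -Inf       # fg-enriched columns only
    cols <- integer(0); sets <- list()
    for (cc in seq_len(L)) {
      elig <- .eligible_sets(state$catalog, state$seed_cons[v, cc])
      cvals <- con[elig, cc]
      if (all(!is.finite(cvals))) next
      # prior annealing: the geometric size term applies throughout, the
      # column/set choice terms ramp in linearly with the temperature so
      # weak early signals can seed patterns that the full prior later prunes
      frac <- if (state$t0 <= 0) 1 else max(0, min(1, 1 - Tt / state$t0))
      pen <- log(state$rho) - frac * (log(L) + log(length(elig)))
      if (Tt <= 1e-9) {
        sidx <- elig[which.max(cvals)]
        keep <- con[sidx, cc] + pen > 0
      } else {
        p <- exp((cvals - max(cvals[is.finite(cvals)])) / Tt)
        p[!is.finite(p)] <- 0
        sidx <- elig[sample.int(length(elig), 1L, prob = p)]
        sc <- con[sidx, cc] + pen
        keep <- stats::runif(1) < 1 / (1 + exp(-sc / Tt))
      }
      if (keep) {
        cols <- c(cols, cc)
        sets <- c(sets, list(state$catalog[[sidx]]))
      }
    }
    state$patterns[[v]] <- list(cols = cols, sets = sets)
  }
  state <- .rebuild_caches(state)
  state$iteration <- state$iteration + 1L
  state$log_score <- total_log_score(state)
  state
}

#' Run the multiple-category partitioning-with-pattern-selection sampler
#'
#' Starts from random assignments and random patterns, anneals the sampling
#' temperature linearly to zero over `burn_in` sweeps, then continues greedily
#' and returns the highest-scoring state visited after burn-in, together with
#' a per-node pattern report.
#'
#' @param master a [core_alignment()] of all sequences (core columns only are
#'   used).
#' @param spec a [hierarchy_spec()] with seed sequence ids.
#' @param n_sweeps total sweeps.
#' @param burn_in annealing sweeps (temperature reaches 0 here).
#' @param rng_seed integer seed; the whole run is deterministic given it.
#' @param rho pattern-size prior (see [bpps_state()]).
#' @param t0 initial temperature.
#' @param weights optional [position_based_weights()].
#' @return list: `state` (best [bpps_state()]), `report` (data.frame `node`,
#'   `rank`, `column` (1-based), `residue_set`, `fg_match`, `bg_match`,
#'   `contrast`), `assignments` (named node labels per sequence),
#'   `score_trace` (log-score per sweep).
#' @export
run_mcbpps <- function(master, spec, n_sweeps = 60L, burn_in = 30L,
                       rng_seed = 1L, rho = 0.2, t0 = 3, weights = NULL) {
  state <- bpps_state(master, spec, rng_seed = rng_seed, rho = rho,
                      temperature = t0, weights = weights)
  best <- NULL
  trace <- numeric(n_sweeps)
  for (t in seq_len(n_sweeps)) {
    state$temperature <- t0 * max(0, 1 - (t - 1) / max(1, burn_in))
    state <- gibbs_sweep(state)
    trace[t] <- state$log_score
    if (t > burn_in && (is.null(best) || state$log_score > best$log_score))
      best <- state
  }
  if (is.null(best)) best <- state
  report <- bpps_report(best)
  list(state = best, report = report,
       assignments = stats::setNames(best$spec$names[best$z], best$ids),
       score_trace = trace)
}

#' Per-node pattern report
#'
#' One row per (node, pattern column), sorted by contrast within node:
#' 1-based core column, residue set, weighted foreground and background match
#' percentages, and the log contrast.
#'
#' @param state a [bpps_state()].
#' @return data.frame.
#' @export
bpps_report <- function(state) {
  out <- list()
  for (v in seq_along(state$spec$names)) {
    if (v == state$root) next
    pat <- state$patterns[[v]]
    if (!length(pat$cols)) next
    cc <- state$caches[[v]]
    k <- length(pat$cols)
    con <- .contrast(cc$fgm, rep(cc$fgw, k), cc$bgm, rep(cc$bgw, k))
    ord <- order(-con)
    out[[length(out) + 1L]] <- data.frame(
      node = state$spec$names[v],
      rank = seq_len(k),
      column = pat$cols[ord],
      residue_set = vapply(pat$sets[ord], paste0, character(1),
                           collapse = ""),
      fg_match = round(100 * cc$fgm[ord] / cc$fgw, 1),
      bg_match = round(100 * cc$bgm[ord] / cc$bgw, 1),
      contrast = con[ord],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(node = character(0), rank = integer(0),
                      column = integer(0), residue_set = character(0),
                      fg_match = numeric(0), bg_match = numeric(0),
                      contrast = numeric(0)))
  do.call(rbind, out)
}

#' Write a pattern report as tab-separated text
#' @param report data.frame from [bpps_report()].
#' @param path file path.
#' @export
write_bpps_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
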