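#' Position-based sequence weights
#'
#' Henikoff & Henikoff position-based weighting: at each column a sequence
#' receives 1/(r*s), where r is the number of distinct non-gap residues in the
#' column and s the number of sequences sharing its residue; contributions are
#' summed over columns. Weights are normalized to sum to the effective
#' (virtual) sequence count, estimated as the number of greedy
#' single-linkage clusters at 62% identity (the classic profile-HMM
#' effective-sequence-number rule): fully redundant alignments count as one
#' virtual sequence, fully diverse ones as n. Identical sequences receive
#' equal weight; a sequence distinct from a block of identical ones receives
#' strictly more.
#'
#' @param alignment a [core_alignment()].
#' @return object of class `SequenceWeights`: list with `weights` (named,
#'   summing to `effective`) and `effective` (virtual sequence count).
#' @export
position_based_weights <- function(alignment) {
  stopifnot(inherits(alignment, "CoreAlignment"))
  core <- alignment$core
  n <- nrow(core)
  if (n == 0L) stop("empty alignment")
  raw <- numeric(n)
  any_col <- FALSE
  for (j in seq_len(ncol(core))) {
    col <- core[, j]
    ok <- col != GAP_CHAR
    if (!any(ok)) next
    any_col <- TRUE
    tab <- table(col[ok])
    r <- length(tab)
    raw[ok] <- raw[ok] + 1 / (r * as.numeric(tab[col[ok]]))
  }
  if (!any_col) stop("alignment has no non-gap columns")
  neff <- if (n == 1L) 1 else
    max(greedy_cluster(alignment, threshold = 0.62)$cluster_id)
  w <- raw / sum(raw) * neff
  structure(list(weights = stats::setNames(w, rownames(core)),
                 effective = neff),
            class = "SequenceWeights")
}

#' @export
print.SequenceWeights <- function(x, ...) {
  cat(sprintf("SequenceWeights: %d sequences, effective count %.2f\n",
              length(x$weights), x$effective))
  invisible(x)
}

# resolve a weights argument to a plain numeric vector over rows
resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "SequenceWeights")) weights <- weights$weights
  stopifnot(length(weights) == n, all(weights >= 0))
  as.numeric(weights)
}

# weighted residue counts: 20 x L matrix (gaps excluded) plus gap weight row
weighted_counts <- function(core, w) {
  L <- ncol(core)
  counts <- matrix(0, 20L, L, dimnames = list(AA_ALPHABET, NULL))
  gapw <- numeric(L)
  for (a in seq_along(AA_ALPHABET)) {
    counts[a, ] <- colSums(w * (core == AA_ALPHABET[a]))
  }
  gapw <- colSums(w * (core == GAP_CHAR))
  list(counts = counts, gap = gapw)
}

#' Consensus sequence of an alignment
#'
#' Per column, the residue with the greatest (optionally weighted) frequency;
#' ties are broken by alphabetical residue order. A column whose (weighted)
#' gap frequency exceeds 50% emits the gap character.
#'
#' @param alignment a [core_alignment()].
#' @param weights `NULL` (unweighted), a numeric vector, or a
#'   [position_based_weights()] result.
#' @return single amino-acid string, one character per core column.
#' @export
consensus_seq <- function(alignment, weights = NULL) {
  stopifnot(inherits(alignment, "CoreAlignment"))
  core <- alignment$core
  w <- resolve_weights(weights, nrow(core))
  wc <- weighted_counts(core, w)
  alpha_order <- order(AA_ALPHABET)   # alphabetical tie-break
  counts_alpha <- wc$counts[alpha_order, , drop = FALSE]
  total <- colSums(wc$counts) + wc$gap
  out <- vapply(seq_len(ncol(core)), function(j) {
    if (total[j] == 0 || wc$gap[j] > 0.5 * total[j]) return(GAP_CHAR)
    rownames(counts_alpha)[which.max(counts_alpha[, j])]
  }, character(1))
  paste0(out, collapse = "")
}

#' Build a position-specific log-odds profile
#'
#' Per-column log2-odds of pseudocount-smoothed weighted residue frequencies
#' against the background. Pseudocounts are a substitution-matrix mixture: the
#' prior for a column is the BLOSUM62 conditional distribution averaged under
#' the column's observed frequencies, blended with weight
#' `pseudocount_strength` against the (weighted) observed count.
#'
#' @param alignment a [core_alignment()].
#' @param weights as in [consensus_seq()].
#' @param pseudocount_strength positive pseudocount mass (default 5).
#' @param name profile name.
#' @param parent_name optional parent profile name in the hierarchy.
#' @param gap_open,gap_extend affine gap penalties (bits) used when aligning
#'   sequences to this profile.
#' @return object of class `Profile`: `scores` (20 x L matrix, bits),
#'   `consensus`, `name`, `parent_name`, `gap_open`, `gap_extend`.
#' @export
build_profile <- function(alignment, weights = NULL, pseudocount_strength = 5,
                          name = "profile", parent_name = NULL,
                          gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(alignment, "CoreAlignment"))
  if (pseudocount_strength <= 0) stop("pseudocount_strength must be > 0")
  core <- alignment$core
  w <- resolve_weights(weights, nrow(core))
  wc <- weighted_counts(core, w)
  N <- colSums(wc$counts)
  q <- blosum62_conditional()
  p <- AA_BACKGROUND
  L <- ncol(core)
  f <- matrix(0, 20L, L, dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(L)) {
    if (N[j] > 0) {
      fobs <- wc$counts[, j] / N[j]
      prior <- as.numeric(q %*% fobs)
    } else {
      fobs <- p
      prior <- p
    }
    f[, j] <- (N[j] * fobs + pseudocount_strength * prior) /
      (N[j] + pseudocount_strength)
  }
  scores <- log2(f / p)
  structure(list(scores = scores,
                 consensus = consensus_seq(alignment, weights),
                 name = name, parent_name = parent_name,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "Profile")
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("Profile '%s': %d columns%s\n", x$name, ncol(x$scores),
              if (!is.null(x$parent_name))
                paste0(", parent '", x$parent_name, "'") else ""))
  invisible(x)
}

#' Serialize a profile to plain text
#'
#' Header lines (`# key value`) followed by one line per column of 20
#' tab-separated log-odds scores in [AA_ALPHABET] order.
#'
#' @param profile a [build_profile()] result.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  hdr <- c(paste("# name", profile$name),
           if (!is.null(profile$parent_name))
             paste("# parent", profile$parent_name),
           paste("# consensus", profile$consensus),
           paste("# gap_open", profile$gap_open),
           paste("# gap_extend", profile$gap_extend),
           paste("# alphabet", paste(AA_ALPHABET, collapse = "")))
  body <- apply(profile$scores, 2, function(col)
    paste(formatC(col, digits = 6, format = "g"), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- readLines(path)
  hdr <- raw[grepl("^# ", raw)]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  body <- raw[!grepl("^#", raw) & nzchar(raw)]
  scores <- t(vapply(strsplit(body, "\t"), as.numeric, numeric(20)))
  scores <- t(scores)
  rownames(scores) <- AA_ALPHABET
  structure(list(scores = scores, consensus = get("consensus"),
                 name = get("name"), parent_name = get("parent"),
                 gap_open = as.numeric(get("gap_open")),
                 gap_extend = as.numeric(get("gap_extend"))),
            class = "Profile")
}
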