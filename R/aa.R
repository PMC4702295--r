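#' Amino-acid alphabet and background model
#'
#' The 20 standard amino acids in the classic substitution-matrix order,
#' and the BLOSUM62 marginal residue frequencies used as the default
#' background distribution throughout the package.
#'
#' @format `AA_ALPHABET` is a character vector of length 20; `AA_BACKGROUND`
#'   a named numeric vector of frequencies summing to 1.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname AA_ALPHABET
#' @export
AA_BACKGROUND <- local({
  # Henikoff & Henikoff marginal frequencies of the BLOSUM62 data set
  p <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  p / sum(p)
})

GAP_CHAR <- "-"

#' Catalog of biochemically related residue classes
#'
#' Fixed catalog of residue sets eligible as pattern residue sets: acidic,
#' basic, small hydroxyl, amide, hydrophobic and aromatic classes, plus every
#' single amino acid. Mirrors the biochemical coloring classes used in
#' contrast hierarchical alignments.
#'
#' @return A named list of character vectors, each a subset of [AA_ALPHABET].
#' @export
residue_class_catalog <- function() {
  classes <- list(
    acidic      = c("D", "E"),
    basic       = c("K", "R"),
    basic_h     = c("K", "R", "H"),
    hydroxyl    = c("S", "T"),
    amide       = c("N", "Q"),
    hydrophobic = c("I", "L", "V", "M"),
    aromatic    = c("F", "Y", "W"),
    aromatic_h  = c("F", "Y", "W", "H")
  )
  singles <- as.list(AA_ALPHABET)
  names(singles) <- AA_ALPHABET
  c(classes, singles)
}

#' Encode residues as integer codes
#'
#' @param x character vector of single residues (or a matrix of them).
#' @return integer codes 1..20 in [AA_ALPHABET] order; 0 for gap; NA for
#'   anything else.
#' @keywords internal
aa_encode <- function(x) {
  codes <- match(x, AA_ALPHABET)
  codes[x == GAP_CHAR] <- 0L
  if (is.matrix(x)) dim(codes) <- dim(x)
  codes
}

#' @keywords internal
aa_decode <- function(codes) {
  out <- rep(GAP_CHAR, length(codes))
  ok <- !is.na(codes) & codes > 0L
  out[ok] <- AA_ALPHABET[codes[ok]]
  if (is.matrix(codes)) dim(out) <- dim(codes)
  out
}

# cached 20x20 BLOSUM62 score matrix (half-bit units), AA_ALPHABET order
.corekin_env <- new.env(parent = emptyenv())

#' BLOSUM62 score matrix (20 standard residues)
#'
#' @return 20x20 integer matrix in [AA_ALPHABET] order, half-bit units.
#' @export
blosum62_matrix <- function() {
  if (is.null(.corekin_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    .corekin_env$blosum62 <- m
  }
  .corekin_env$blosum62
}

#' Conditional substitution probabilities derived from BLOSUM62
#'
#' Column b gives P(a | b), reconstructed from the half-bit scores via
#' q(a|b) proportional to p_a * 2^(s_ab / 2) and renormalized. Used for
#' substitution-matrix mixture pseudocounts.
#'
#' @return 20x20 matrix, columns summing to 1.
#' @keywords internal
blosum62_conditional <- function() {
  if (is.null(.corekin_env$b62cond)) {
    s <- blosum62_matrix()
    q <- AA_BACKGROUND * 2^(s / 2)
    q <- sweep(q, 2, colSums(q), "/")
    .corekin_env$b62cond <- q
  }
  .corekin_env$b62cond
}
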