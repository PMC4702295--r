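#' Integer-tenths frequency glyph
#'
#' Encodes a match frequency as a single character: `floor(10 * freq)` as a
#' digit (so '8' covers 80-90%), with '!' reserved for exactly 100%
#' (weighted frequency >= 1 - 1e-9).
#'
#' @param freq numeric vector of fractions in `[0, 1]`.
#' @return character vector over `{'0'..'9','!'}`.
#' @export
freq_to_glyph <- function(freq) {
  if (any(is.na(freq)) || any(freq < 0) || any(freq > 1 + 1e-12))
    stop("frequencies must lie in [0, 1]")
  out <- as.character(pmin(floor(10 * freq), 9))
  out[freq >= 1 - 1e-9] <- "!"
  out
}

#' Insertion and deletion glyphs for a core column
#'
#' The (weighted) fraction of sequences with an insert segment immediately
#' after the column and the fraction gapped at the column, each encoded with
#' [freq_to_glyph()].
#'
#' @param alignment a [core_alignment()].
#' @param column core column (1-based); vectorized.
#' @param weights optional sequence weights.
#' @return list with character vectors `insertion` and `deletion`.
#' @export
indel_glyphs <- function(alignment, column = seq_len(ncol(alignment$core)),
                         weights = NULL) {
  stopifnot(all(column >= 1), all(column <= ncol(alignment$core)))
  w <- resolve_weights(weights, nrow(alignment$core))
  W <- sum(w)
  ins_frac <- vapply(column, function(cc) {
    has <- vapply(alignment$inserts, function(ins)
      as.character(cc) %in% names(ins), logical(1))
    sum(w[has]) / W
  }, numeric(1))
  del_frac <- vapply(column, function(cc)
    sum(w[alignment$core[, cc] == GAP_CHAR]) / W, numeric(1))
  list(insertion = freq_to_glyph(ins_frac),
       deletion = freq_to_glyph(del_frac))
}

#' Semi-logarithmic foreground/background divergence bar height
#'
#' The divergence measure is the per-(weighted)-sequence contrast: the KL
#' divergence of Bernoulli(fg) from Bernoulli(bg) when the foreground is
#' enriched, 0 otherwise (this is the large-sample limit of the column
#' contrast per weighted foreground sequence). The height is
#' `max_height * log10(1 + m) / log10(1 + m_max)`, clipped to
#' `[0, max_height]`, with background rates clamped away from 0/1 by 0.005.
#'
#' @param fg_freq,bg_freq match frequencies in `[0, 1]` (vectorized).
#' @param max_height maximum bar height.
#' @return numeric heights; 0 when `fg_freq <= bg_freq`.
#' @export
bar_height <- function(fg_freq, bg_freq, max_height = 9) {
  if (any(fg_freq < 0 | fg_freq > 1 | bg_freq < 0 | bg_freq > 1))
    stop("frequencies must lie in [0, 1]")
  eps <- 0.005
  b <- pmin(pmax(bg_freq, eps), 1 - eps)
  f <- pmin(pmax(fg_freq, 1e-12), 1 - 1e-12)
  m <- f * log(f / b) + (1 - f) * log((1 - f) / (1 - b))
  m[fg_freq <= bg_freq] <- 0
  m_max <- log(1 / eps)
  pmin(max_height, max_height * log10(1 + m) / log10(1 + m_max))
}

#' Per-column information content
#'
#' `log2(20)` minus the Shannon entropy of the (weighted, pseudocount-free)
#' residue distribution of a column.
#'
#' @param counts named numeric vector of residue counts (weighted allowed),
#'   or a character vector of residues (gaps ignored) with optional `weights`.
#' @param weights optional weights when `counts` is a residue vector.
#' @return information content in bits.
#' @export
column_information <- function(counts, weights = NULL) {
  if (is.character(counts)) {
    res <- counts[counts != GAP_CHAR]
    w <- resolve_weights(weights, length(counts))[counts != GAP_CHAR]
    counts <- vapply(split(w, factor(res, levels = AA_ALPHABET)), sum,
                     numeric(1))
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no residues observed")
  p <- counts / sum(counts)
  log2(20) + sum(p * log2(p))
}

#' Render a contrast hierarchical alignment
#'
#' Assembles, for one hierarchy node, the display rows (chosen representative
#' foreground sequences), pattern-position markers, weighted foreground and
#' background pattern-match frequency lines (integer tenths, '!' = 100%),
#' effective (virtual) weighted alignment sizes, insertion and deletion lines,
#' semi-log divergence bar heights, and biochemical color classes for
#' pattern-matching residues.
#'
#' At pattern columns, "match" means the node's pattern residue set; at all
#' other columns it means the foreground's (weighted) majority residue.
#'
#' @param master a [core_alignment()] of all sequences.
#' @param state a [bpps_state()] (typically the best state of [run_mcbpps()]).
#' @param node node name.
#' @param display_ids sequence ids shown as the display alignment; must all
#'   belong to the node's foreground.
#' @return object of class `CHADocument`.
#' @export
render_cha <- function(master, state, node, display_ids) {
  v <- match(node, state$spec$names)
  if (is.na(v)) stop("unknown node: ", node)
  if (v == state$root) stop("the root node has no background to contrast")
  pat <- state$patterns[[v]]
  if (!length(pat$cols)) stop("node '", node, "' has no pattern")
  in_fg <- state$z %in% state$sub[[v]]
  in_bg <- state$z %in% state$sub[[state$spec$parent[v]]] & !in_fg
  ids <- state$ids
  di <- match(display_ids, ids)
  if (anyNA(di) || any(!in_fg[di]))
    stop("display sequences must belong to the node's foreground")
  w <- state$w
  L <- ncol(master$core)

  fg_counts <- weighted_counts(master$core[in_fg, , drop = FALSE],
                               w[in_fg])$counts
  bg_counts <- weighted_counts(master$core[in_bg, , drop = FALSE],
                               w[in_bg])$counts
  fgW <- sum(w[in_fg]); bgW <- sum(w[in_bg])

  # per-column match target: pattern residue set at pattern columns,
  # foreground weighted-majority residue elsewhere
  targets <- vector("list", L)
  maj <- AA_ALPHABET[apply(fg_counts, 2, which.max)]
  for (j in seq_len(L)) targets[[j]] <- maj[j]
  for (k in seq_along(pat$cols)) targets[[pat$cols[k]]] <- pat$sets[[k]]

  fg_freq <- vapply(seq_len(L), function(j)
    sum(fg_counts[match(targets[[j]], AA_ALPHABET), j]) / fgW, numeric(1))
  bg_freq <- vapply(seq_len(L), function(j)
    sum(bg_counts[match(targets[[j]], AA_ALPHABET), j]) / bgW, numeric(1))

  fg_aln <- core_alignment(master$core[in_fg, , drop = FALSE],
                           master$inserts[in_fg])
  ind <- indel_glyphs(fg_aln, weights = w[in_fg])

  markers <- seq_len(L) %in% pat$cols
  bars <- bar_height(fg_freq, bg_freq, max_height = 9)

  # biochemical color class per display cell (pattern-matching residues only)
  class_of <- function(res) {
    for (nm in names(residue_class_catalog())) {
      s <- residue_class_catalog()[[nm]]
      if (length(s) > 1 && res %in% s) return(nm)
    }
    res
  }
  colors <- matrix(NA_character_, length(di), L)
  for (r in seq_along(di)) for (k in seq_along(pat$cols)) {
    j <- pat$cols[k]
    res <- master$core[di[r], j]
    if (res %in% pat$sets[[k]]) colors[r, j] <- class_of(res)
  }

  doc <- list(node = node, columns = L,
              display = master$core[di, , drop = FALSE],
              display_ids = display_ids,
              markers = markers,
              fg_glyphs = freq_to_glyph(pmin(fg_freq, 1)),
              bg_glyphs = freq_to_glyph(pmin(bg_freq, 1)),
              insertion = ind$insertion, deletion = ind$deletion,
              bar_heights = bars,
              fg_effective = fgW, bg_effective = bgW,
              fg_n = sum(in_fg), bg_n = sum(in_bg),
              colors = colors,
              pattern_columns = pat$cols)
  class(doc) <- "CHADocument"
  doc
}

#' Format a contrast hierarchical alignment as fixed-width text
#'
#' One character per core column: a ruler line every 10 columns (1-based),
#' the semi-log divergence bars (rounded heights 0-9), pattern markers (`*`),
#' the display rows, the weighted foreground and background frequency lines
#' labelled with their virtual (down-weighted) sequence counts, and the
#' insertion/deletion lines.
#'
#' @param doc a [render_cha()] document.
#' @return character vector of lines (all of equal body width).
#' @export
format_cha <- function(doc) {
  L <- doc$columns
  lab <- function(s) formatC(s, width = 24, flag = "-")
  ruler <- rep(" ", L)
  marks <- seq(1L, L, by = 10L)
  for (m in marks) {
    digs <- strsplit(as.character(m), "")[[1]]
    to <- min(L, m + length(digs) - 1L)
    ruler[m:to] <- digs[seq_len(to - m + 1L)]
  }
  lines <- c(
    paste0(lab(""), paste0(ruler, collapse = "")),
    paste0(lab("divergence"),
           paste0(as.character(round(doc$bar_heights)), collapse = "")),
    paste0(lab("pattern"),
           paste0(ifelse(doc$markers, "*", " "), collapse = "")))
  for (r in seq_len(nrow(doc$display))) {
    lines <- c(lines, paste0(lab(doc$display_ids[r]),
                             paste0(doc$display[r, ], collapse = "")))
  }
  lines <- c(lines,
             paste0(lab(sprintf("fg (%.1f wt/%d)", doc$fg_effective,
                                doc$fg_n)),
                    paste0(doc$fg_glyphs, collapse = "")),
             paste0(lab(sprintf("bg (%.1f wt/%d)", doc$bg_effective,
                                doc$bg_n)),
                    paste0(doc$bg_glyphs, collapse = "")),
             paste0(lab("insertions"), paste0(doc$insertion, collapse = "")),
             paste0(lab("deletions"), paste0(doc$deletion, collapse = "")))
  lines
}

#' @export
print.CHADocument <- function(x, ...) {
  writeLines(format_cha(x))
  invisible(x)
}

#' Write a contrast hierarchical alignment to text or HTML
#'
#' The HTML render carries identical frequencies and marks pattern-matching
#' residues with their biochemical color class.
#'
#' @param doc a [render_cha()] document.
#' @param path file path.
#' @export
write_cha_text <- function(doc, path) {
  writeLines(format_cha(doc), path)
  invisible(path)
}

#' @rdname write_cha_text
#' @export
write_cha_html <- function(doc, path) {
  palette <- c(acidic = "#d62728", basic = "#17becf", basic_h = "#17becf",
               hydroxyl = "#2ca02c", amide = "#9467bd",
               hydrophobic = "#bcbd22", aromatic = "#e377c2",
               aromatic_h = "#e377c2", H = "#8c564b", G = "#ff7f0e",
               P = "#1f77b4", C = "#7f7f7f")
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  txt <- format_cha(doc)
  n_head <- 3L
  n_rows <- nrow(doc$display)
  body <- txt
  for (r in seq_len(n_rows)) {
    row_chars <- doc$display[r, ]
    colored <- vapply(seq_along(row_chars), function(j) {
      cl <- doc$colors[r, j]
      if (is.na(cl)) esc(row_chars[j])
      else sprintf("<span style=\"background:%s\">%s</span>",
                   if (cl %in% names(palette)) palette[[cl]] else "#dddddd",
                   esc(row_chars[j]))
    }, character(1))
    lab <- substr(txt[n_head + r], 1, 24)
    body[n_head + r] <- paste0(esc(lab), paste0(colored, collapse = ""))
  }
  html <- c("<!DOCTYPE html><html><body><pre style=\"font-family:monospace\">",
            body, "</pre></body></html>")
  writeLines(html, path)
  invisible(path)
}
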