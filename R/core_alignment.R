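#' Core alignments
#'
#' A `CoreAlignment` maps each sequence onto a fixed set of core columns
#' (the shared structural core of the superfamily), storing residues or gaps
#' at every core column and keeping variable-length insert segments between
#' core columns separately. Reconstructing a row (core residues plus inserts,
#' in order) reproduces the raw sequence exactly.
#'
#' @param core character matrix, one row per sequence, one column per core
#'   column; entries are single residues or `"-"`. Row names are sequence ids.
#' @param inserts list, one element per row: a named character vector whose
#'   names are the core column (0 allowed, meaning before the first column)
#'   after which each insert segment occurs, values the insert residues.
#' @param provenance optional data.frame with columns `profile`, `score`,
#'   `status` (one row per sequence).
#' @return an object of class `CoreAlignment`.
#' @export
core_alignment <- function(core, inserts = NULL, provenance = NULL) {
  stopifnot(is.matrix(core), is.character(core))
  if (nrow(core) == 0L) stop("alignment must contain at least one sequence")
  if (is.null(rownames(core)))
    rownames(core) <- paste0("seq", seq_len(nrow(core)))
  if (is.null(inserts)) {
    inserts <- rep(list(character(0)), nrow(core))
  }
  stopifnot(length(inserts) == nrow(core))
  names(inserts) <- rownames(core)
  bad <- !core %in% c(AA_ALPHABET, GAP_CHAR)
  if (any(bad)) stop("invalid residue characters in core matrix: ",
                     paste(unique(core[bad]), collapse = " "))
  for (ins in inserts) {
    if (length(ins)) {
      k <- as.integer(names(ins))
      if (anyNA(k) || any(k < 0L) || any(k > ncol(core)))
        stop("insert keys must be core columns in 0..", ncol(core))
    }
  }
  structure(list(core = core, inserts = inserts, provenance = provenance),
            class = "CoreAlignment")
}

#' @export
print.CoreAlignment <- function(x, ...) {
  cat(sprintf("CoreAlignment: %d sequences x %d core columns (%d insert segments)\n",
              nrow(x$core), ncol(x$core),
              sum(lengths(x$inserts))))
  invisible(x)
}

#' @export
dim.CoreAlignment <- function(x) dim(x$core)

#' Sequence ids of a core alignment
#' @param x a [core_alignment()].
#' @return character vector of row ids.
#' @export
seq_ids <- function(x) rownames(x$core)

#' Subset rows of a core alignment
#' @param x a [core_alignment()].
#' @param i row indices or ids.
#' @param ... unused.
#' @export
`[.CoreAlignment` <- function(x, i, ...) {
  core <- x$core[i, , drop = FALSE]
  core_alignment(core, x$inserts[i],
                 if (!is.null(x$provenance)) x$provenance[i, , drop = FALSE])
}

#' Remove core-column structure and recover the raw sequences
#'
#' Concatenates, for each row, any insert before column 1, then each non-gap
#' core residue followed by the insert attached after that column. This is the
#' exact inverse of core mapping: the result equals the original unaligned
#' sequence.
#'
#' @param alignment a [core_alignment()].
#' @return data.frame with columns `id` and `seq`.
#' @export
degap <- function(alignment) {
  stopifnot(inherits(alignment, "CoreAlignment"))
  L <- ncol(alignment$core)
  seqs <- vapply(seq_len(nrow(alignment$core)), function(i) {
    row <- alignment$core[i, ]
    ins <- alignment$inserts[[i]]
    pieces <- character(L + 1L)
    if (length(ins)) pieces[as.integer(names(ins)) + 1L] <- unname(ins)
    res <- ifelse(row == GAP_CHAR, "", row)
    paste0(paste0(pieces[1L], collapse = ""),
           paste0(res, pieces[-1L], collapse = ""))
  }, character(1))
  data.frame(id = rownames(alignment$core), seq = seqs,
             stringsAsFactors = FALSE)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings for unaligned amino-acid FASTA.
#'
#' @param x data.frame with columns `id`, `seq`.
#' @param path file path.
#' @return `read_fasta` returns a data.frame with columns `id`, `seq`.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::AAStringSet(stats::setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  data.frame(id = names(set), seq = as.character(set),
             stringsAsFactors = FALSE)
}

#' Write a core alignment as aligned FASTA (A2M convention)
#'
#' Core columns are written in upper case (gap `-`); insert segments in lower
#' case at their position between core columns, padded with nothing (ragged
#' inserts are not column-aligned, following the A2M convention).
#'
#' @param alignment a [core_alignment()].
#' @param path file path.
#' @export
write_a2m <- function(alignment, path) {
  L <- ncol(alignment$core)
  lines <- character(0)
  for (i in seq_len(nrow(alignment$core))) {
    row <- alignment$core[i, ]
    ins <- alignment$inserts[[i]]
    pieces <- character(L + 1L)
    if (length(ins)) pieces[as.integer(names(ins)) + 1L] <- tolower(unname(ins))
    body <- paste0(pieces[1L], paste0(row, pieces[-1L], collapse = ""))
    lines <- c(lines, paste0(">", rownames(alignment$core)[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an A2M-style aligned FASTA into a core alignment
#'
#' Upper-case letters and `-` are core columns; lower-case letters are insert
#' residues attached to the preceding core column.
#'
#' @param path file path.
#' @return a [core_alignment()].
#' @export
read_a2m <- function(path) {
  raw <- readLines(path)
  hdr <- grep("^>", raw)
  ids <- sub("^>", "", raw[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(raw))
  rows <- list(); inserts <- list()
  for (k in seq_along(hdr)) {
    body <- paste0(raw[starts[k]:ends[k]], collapse = "")
    ch <- strsplit(body, "")[[1]]
    is_core <- ch == GAP_CHAR | ch %in% AA_ALPHABET
    core_row <- ch[is_core]
    col_of <- cumsum(is_core)      # core column index before/at each char
    ins <- character(0)
    if (any(!is_core)) {
      lows <- which(!is_core)
      key <- col_of[lows]
      for (kk in unique(key)) {
        ins[as.character(kk)] <- paste0(toupper(ch[lows[key == kk]]),
                                        collapse = "")
      }
    }
    rows[[k]] <- core_row
    inserts[[k]] <- ins
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("rows have differing core column counts")
  core <- do.call(rbind, rows)
  rownames(core) <- ids
  core_alignment(core, inserts)
}

#' Write a core alignment in Stockholm format
#'
#' Core columns only (inserts are not representable column-wise and are
#' omitted); one `#=GF` line records the insert count.
#'
#' @param alignment a [core_alignment()].
#' @param path file path.
#' @export
write_stockholm <- function(alignment, path) {
  ids <- rownames(alignment$core)
  w <- max(nchar(ids)) + 2L
  body <- vapply(seq_along(ids), function(i)
    sprintf("%-*s%s", w, ids[i], paste0(alignment$core[i, ], collapse = "")),
    character(1))
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("#=GF CC insert segments omitted (%d total)",
                       sum(lengths(alignment$inserts))),
               body, "//"), path)
  invisible(path)
}

#' Read a Stockholm alignment (core columns only)
#' @param path file path.
#' @return a [core_alignment()] with no inserts.
#' @export
read_stockholm <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & raw != "//" & nzchar(trimws(raw))]
  parts <- strsplit(trimws(raw), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  seqs <- vapply(parts, `[[`, character(1), 2L)
  core <- do.call(rbind, strsplit(toupper(seqs), ""))
  core[core == "."] <- GAP_CHAR
  rownames(core) <- ids
  core_alignment(core)
}
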