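#' Align a sequence to a position-specific profile
#'
#' Optimal local (Smith-Waterman-style) alignment of a sequence against a
#' profile's log-odds columns with affine gap penalties, by dynamic
#' programming with deterministic traceback. A gap run of length k costs
#' `gap_open + (k - 1) * gap_extend`.
#'
#' @param seq amino-acid string (or data.frame row with `id`/`seq`).
#' @param profile a [build_profile()] result.
#' @return list of class `ProfileAlignment`: `score` (bits), `from`/`to`
#'   (aligned sequence window), `col_from`/`col_to` (profile column window),
#'   `col_map` (per sequence position: aligned profile column, 0 for an
#'   inserted residue inside the window, NA outside), `profile` (name).
#' @export
align_to_profile <- function(seq, profile) {
  if (is.list(seq) || is.data.frame(seq)) seq <- seq$seq[1]
  stopifnot(is.character(seq), nchar(seq) >= 1)
  codes <- aa_encode(strsplit(seq, "")[[1]])
  if (anyNA(codes) || any(codes == 0L))
    stop("sequence contains non-standard residues")
  res <- .gotoh_local(profile$scores, codes,
                     profile$gap_open, profile$gap_extend)
  res$profile <- profile$name
  res$seq <- seq
  class(res) <- "ProfileAlignment"
  res
}

profile_depth <- function(profiles) {
  parent <- vapply(profiles, function(p)
    if (is.null(p$parent_name)) NA_character_ else p$parent_name, character(1))
  names(parent) <- vapply(profiles, `[[`, character(1), "name")
  vapply(names(parent), function(nm) {
    d <- 0L
    while (!is.na(parent[nm])) { d <- d + 1L; nm <- parent[nm] }
    d
  }, integer(1))
}

#' Best-matching profile for a sequence
#'
#' Aligns the sequence to every profile in a hierarchy and returns the
#' highest-scoring one; ties are broken by hierarchy depth (deeper wins),
#' then by name order. Scores below the significance threshold yield an
#' `unclassified` status rather than an error.
#'
#' @param seq amino-acid string.
#' @param profiles list of [build_profile()] results (named or not).
#' @param threshold significance cutoff in bits (default 25).
#' @return list: `profile` (name or NA), `score`, `status`
#'   (`"classified"`/`"unclassified"`), `alignment` (the winning
#'   [align_to_profile()] result, even when unclassified).
#' @export
best_profile <- function(seq, profiles, threshold = 25) {
  stopifnot(length(profiles) >= 1)
  alns <- lapply(profiles, function(p) align_to_profile(seq, p))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  depth <- profile_depth(profiles)
  nms <- vapply(profiles, `[[`, character(1), "name")
  ord <- order(-scores, -depth, nms)
  best <- ord[1]
  status <- if (scores[best] >= threshold) "classified" else "unclassified"
  list(profile = if (status == "classified") unname(nms[best])
                else NA_character_,
       score = unname(scores[best]), status = status,
       alignment = alns[[best]])
}

#' Template alignment of profile consensus sequences
#'
#' The template aligns every profile's consensus over a common set of columns;
#' the root row must have no gaps, and its columns define the structural core.
#' Each profile's columns are mapped through the template to root core
#' columns; profile columns falling where the root is gapped map to NA (their
#' residues become inserts attached to the preceding core column).
#'
#' @param rows character matrix of aligned consensus rows (residues/`-`),
#'   row names = profile names.
#' @param root name of the root profile row.
#' @param parents named character vector: child profile -> parent profile
#'   (root absent or NA).
#' @return object of class `TemplateAlignment` with per-profile column maps.
#' @export
template_alignment <- function(rows, root, parents = NULL) {
  stopifnot(is.matrix(rows), root %in% rownames(rows))
  if (anyDuplicated(rownames(rows)))
    stop("each profile consensus must appear exactly once in the template")
  root_row <- rows[root, ]
  if (any(root_row == GAP_CHAR))
    stop("root row must have no gaps in core columns")
  core_of_aln_col <- cumsum(root_row != GAP_CHAR)  # == 1..L here
  maps <- lapply(rownames(rows), function(nm) {
    occ <- which(rows[nm, ] != GAP_CHAR)
    out <- core_of_aln_col[occ]
    out[root_row[occ] == GAP_CHAR] <- NA_integer_
    out
  })
  names(maps) <- rownames(rows)
  structure(list(rows = rows, root = root, parents = parents,
                 core_length = sum(root_row != GAP_CHAR), maps = maps),
            class = "TemplateAlignment")
}

#' Map a profile alignment onto the structural core
#'
#' Transfers residues aligned to profile columns through the template's column
#' map to root core columns. Residues aligned to template-insert columns, or
#' unaligned within/outside the local window, become insert segments attached
#' to the preceding core column (column 0 for leading residues).
#'
#' @param aln an [align_to_profile()] result.
#' @param template a [template_alignment()].
#' @param id sequence id for the resulting row.
#' @return one-row [core_alignment()].
#' @export
map_to_core <- function(aln, template, id = "seq") {
  if (!aln$profile %in% names(template$maps))
    stop("profile '", aln$profile, "' absent from template")
  map <- template$maps[[aln$profile]]
  L <- template$core_length
  chars <- strsplit(aln$seq, "")[[1]]
  core <- rep(GAP_CHAR, L)
  # core column (or 0) each residue lands after/at
  attach_col <- integer(length(chars))
  placed <- logical(length(chars))
  last_core <- 0L
  for (i in seq_along(chars)) {
    cm <- aln$col_map[i]
    if (!is.na(cm) && cm > 0L && !is.na(map[cm])) {
      core[map[cm]] <- chars[i]
      placed[i] <- TRUE
      last_core <- map[cm]
    } else {
      attach_col[i] <- last_core
    }
  }
  # residues after the aligned window keep attaching to the last core column
  ins <- character(0)
  if (any(!placed)) {
    # recompute attachment for positions before the window: they precede the
    # first placed residue's core column only if last_core was 0 at the time;
    # the sequential scan above already handles this.
    for (k in sort(unique(attach_col[!placed]))) {
      ins[as.character(k)] <- paste0(chars[!placed & attach_col == k],
                                     collapse = "")
    }
  }
  m <- matrix(core, 1L, L, dimnames = list(id, NULL))
  core_alignment(m, list(ins),
                 provenance = data.frame(profile = aln$profile,
                                         score = aln$score,
                                         status = "classified",
                                         stringsAsFactors = FALSE))
}

#' Align a set of sequences to a profile hierarchy and build a master core
#' alignment
#'
#' Each sequence is aligned to its best-matching profile and mapped through
#' the template to the structural core. Unclassified sequences (score below
#' threshold) are reported in the classification table and omitted from the
#' master alignment.
#'
#' @param sequences data.frame with `id`, `seq`.
#' @param profiles list of profiles.
#' @param template a [template_alignment()].
#' @param threshold bit-score significance cutoff.
#' @return list: `master` ([core_alignment()]) and `classification`
#'   (data.frame `seq_id`, `profile`, `score`, `status`).
#' @export
align_superfamily <- function(sequences, profiles, template, threshold = 25) {
  rows <- vector("list", nrow(sequences))
  cls <- data.frame(seq_id = sequences$id, profile = NA_character_,
                    score = NA_real_, status = "unclassified",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sequences))) {
    bp <- best_profile(sequences$seq[i], profiles, threshold)
    cls$score[i] <- bp$score
    if (bp$status == "classified") {
      cls$profile[i] <- bp$profile
      cls$status[i] <- "classified"
      rows[[i]] <- map_to_core(bp$alignment, template, id = sequences$id[i])
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no sequence matched any profile significantly")
  rows <- rows[keep]
  core <- do.call(rbind, lapply(rows, `[[`, "core"))
  rownames(core) <- sequences$id[keep]
  inserts <- lapply(rows, function(r) r$inserts[[1]])
  prov <- do.call(rbind, lapply(rows, `[[`, "provenance"))
  list(master = core_alignment(core, inserts, prov), classification = cls)
}

#' Iteratively refine group profiles and the master alignment
#'
#' Alternates, for `n_rounds`: build weighted profiles from the current group
#' alignments; compute each group's consensus; rebuild the template from the
#' consensus rows; re-align every group's (degapped) sequences to its own
#' profile and re-map them to the core. Reports the number of rows whose core
#' mapping changed in each round. A group losing all significant members is
#' frozen at its previous profile with a warning.
#'
#' @param groups named list of [core_alignment()] seed alignments, one per
#'   group, all over the same core columns.
#' @param n_rounds number of refinement rounds (>= 1).
#' @param pseudocount_strength passed to [build_profile()].
#' @param threshold bit-score cutoff for keeping a re-aligned member.
#' @return list: `profiles`, `master` ([core_alignment()]), `template`,
#'   `changes` (integer per round).
#' @export
iterate_profiles <- function(groups, n_rounds = 2, pseudocount_strength = 5,
                             threshold = 25) {
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  L <- ncol(groups[[1]]$core)
  changes <- integer(n_rounds)
  prev_core <- NULL
  profiles <- NULL
  template <- NULL
  for (round in seq_len(n_rounds)) {
    new_profiles <- lapply(names(groups), function(nm) {
      aln <- groups[[nm]]
      build_profile(aln, position_based_weights(aln),
                    pseudocount_strength, name = nm, parent_name = "root")
    })
    names(new_profiles) <- names(groups)
    # master template: unweighted consensus rows over the core columns;
    # root row = consensus of all sequences pooled
    pooled <- core_alignment(do.call(rbind, lapply(groups, `[[`, "core")))
    root_cons <- consensus_seq(pooled)
    cons_rows <- rbind(root = strsplit(root_cons, "")[[1]],
                       do.call(rbind, lapply(new_profiles, function(p)
                         strsplit(p$consensus, "")[[1]])))
    rownames(cons_rows) <- c("root", names(groups))
    if (any(cons_rows["root", ] == GAP_CHAR)) {
      # a core column can only go majority-gap if groups are mostly gapped
      # there; keep the template root dense by backfilling background consensus
      idx <- cons_rows["root", ] == GAP_CHAR
      cons_rows["root", idx] <- names(which.max(AA_BACKGROUND))
    }
    template <- template_alignment(cons_rows, root = "root",
                                   parents = stats::setNames(
                                     rep("root", length(groups)),
                                     names(groups)))
    # re-align each group's members to its own profile
    new_groups <- groups
    for (nm in names(groups)) {
      seqs <- degap(groups[[nm]])
      rows <- list(); kept <- character(0)
      for (i in seq_len(nrow(seqs))) {
        aln <- align_to_profile(seqs$seq[i], new_profiles[[nm]])
        if (aln$score >= threshold) {
          rows[[length(rows) + 1L]] <- map_to_core(aln, template,
                                                   id = seqs$id[i])
          kept <- c(kept, seqs$id[i])
        }
      }
      if (!length(rows)) {
        warning("group '", nm, "' lost all significant members; frozen")
        next
      }
      core <- do.call(rbind, lapply(rows, `[[`, "core"))
      rownames(core) <- kept
      new_groups[[nm]] <- core_alignment(core,
                                         lapply(rows, function(r) r$inserts[[1]]))
    }
    groups <- new_groups
    profiles <- new_profiles
    master_core <- do.call(rbind, lapply(groups, `[[`, "core"))
    if (!is.null(prev_core)) {
      common <- intersect(rownames(master_core), rownames(prev_core))
      changed <- sum(vapply(common, function(id)
        !identical(master_core[id, ], prev_core[id, ]), logical(1)))
      changed <- changed + sum(!rownames(master_core) %in% common)
      changes[round] <- changed
    } else {
      changes[round] <- nrow(master_core)
    }
    prev_core <- master_core
  }
  master <- core_alignment(do.call(rbind, lapply(groups, `[[`, "core")),
                           unlist(lapply(groups, `[[`, "inserts"),
                                  recursive = FALSE))
  list(profiles = profiles, master = master, template = template,
       changes = changes)
}

#' Write per-sequence classification as tab-separated text
#' @param classification data.frame from [align_superfamily()].
#' @param path file path.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
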