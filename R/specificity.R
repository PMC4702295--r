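#' Core-motif annotation of a template
#'
#' Fixed core-column positions of the canonical kinase motifs, as annotated
#' on the curated template (positions are template knowledge, never sequence
#' searches): glycine-rich loop, beta-3 lysine, C-helix glutamate, catalytic
#' loop, and the magnesium-binding DFG region (three motif columns plus the
#' DFG+1 column).
#'
#' @param gly_loop,beta3_lys,chelix_glu,cat_loop,dfg_region integer vectors
#'   of core columns (1-based); `dfg_region` must have length 4 (DFG + the
#'   DFG+1 position).
#' @return named list of class `MotifAnnotation`.
#' @export
motif_annotation <- function(gly_loop = integer(0), beta3_lys = integer(0),
                             chelix_glu = integer(0), cat_loop = integer(0),
                             dfg_region = integer(0)) {
  if (length(dfg_region) && length(dfg_region) != 4L)
    stop("dfg_region must span exactly 4 core columns (DFG + DFG+1)")
  structure(list(gly_loop = as.integer(gly_loop),
                 beta3_lys = as.integer(beta3_lys),
                 chelix_glu = as.integer(chelix_glu),
                 cat_loop = as.integer(cat_loop),
                 dfg_region = as.integer(dfg_region)),
            class = "MotifAnnotation")
}

#' Locate annotated motifs in a core row
#'
#' Returns the residues found at each annotated motif's core columns; a hit
#' is flagged incomplete when the row is gapped anywhere in the span.
#'
#' @param row character vector (one core row) or an index/id into `alignment`.
#' @param annotation a [motif_annotation()].
#' @param alignment optional [core_alignment()].
#' @param id sequence id recorded in the hits.
#' @return data.frame: `motif`, `start_col`, `end_col`, `residues`,
#'   `complete`, `seq_id`.
#' @export
locate_motifs <- function(row, annotation, alignment = NULL, id = "seq") {
  if (!inherits(annotation, "MotifAnnotation"))
    stop("template annotation required")
  if (!is.null(alignment)) {
    id <- if (is.character(row)) row else rownames(alignment$core)[row]
    row <- alignment$core[row, ]
  }
  spans <- annotation[lengths(annotation) > 0]
  if (!length(spans)) stop("annotation contains no motif spans")
  out <- lapply(names(spans), function(nm) {
    cols <- spans[[nm]]
    res <- row[cols]
    data.frame(motif = nm, start_col = min(cols), end_col = max(cols),
               residues = paste0(res, collapse = ""),
               complete = !any(res == GAP_CHAR),
               seq_id = id, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify an APH sequence from its DFG-region residues
#'
#' The residue at the DFG+1 position determines the class and the predicted
#' substrate chemical pattern: an acidic DFG+1 (D, as in DFGD/DFTD; E by
#' charge-class extrapolation) gives APH2 with the OH-NH2-OH substrate
#' pattern; a basic DFG+1 (R, as in DFGR/DNGR; K by extrapolation) gives APH3
#' with OH-OH-NH2; anything else is unassigned. Calls made through the
#' charge-class extrapolation (E or K rather than the observed D or R) are
#' flagged.
#'
#' @param dfg_region string of exactly 4 residues, position 4 = DFG+1.
#' @return list of class `APHCall`: `dfg_region`, `dfg_plus1`, `class`
#'   (`"APH2"`/`"APH3"`/`"unassigned"`), `substrate_motif` (`"OH-NH2-OH"`,
#'   `"OH-OH-NH2"` or `"none"`), `extrapolated` (logical).
#' @export
classify_aph <- function(dfg_region) {
  if (!is.character(dfg_region) || nchar(dfg_region) != 4L)
    stop("dfg_region must be exactly 4 residues")
  plus1 <- substr(dfg_region, 4L, 4L)
  if (plus1 %in% c("D", "E")) {
    cls <- "APH2"; motif <- "OH-NH2-OH"; extra <- plus1 == "E"
  } else if (plus1 %in% c("R", "K")) {
    cls <- "APH3"; motif <- "OH-OH-NH2"; extra <- plus1 == "K"
  } else {
    cls <- "unassigned"; motif <- "none"; extra <- FALSE
  }
  structure(list(dfg_region = dfg_region, dfg_plus1 = plus1,
                 class = cls, substrate_motif = motif,
                 extrapolated = extra),
            class = "APHCall")
}

#' Catalytic-loop basic-residue flag
#'
#' A lysine or arginine anywhere in the annotated catalytic-loop span gives
#' `basic-KR` (the hallmark of protein-phosphorylating kinases); otherwise a
#' histidine gives `basic-H`; otherwise `none`.
#'
#' @param hit one catalytic-loop row of [locate_motifs()] (or a residue
#'   string).
#' @return one of `"basic-KR"`, `"basic-H"`, `"none"`.
#' @export
catalytic_loop_basic <- function(hit) {
  if (is.data.frame(hit)) {
    if (!hit$complete[1]) stop("catalytic-loop hit is incomplete")
    residues <- hit$residues[1]
  } else residues <- hit
  ch <- strsplit(residues, "")[[1]]
  if (any(ch %in% c("K", "R"))) return("basic-KR")
  if ("H" %in% ch) return("basic-H")
  "none"
}

#' Annotate every sequence of a superfamily
#'
#' Per sequence: its subgroup assignment (from a sampler state or a label
#' vector; `NA` allowed — motif annotation is independent of classification),
#' the APH call when the DFG region is complete, and the catalytic-loop flag.
#'
#' @param master a [core_alignment()].
#' @param groups named character vector of group labels per sequence id, or a
#'   [bpps_state()].
#' @param annotation a [motif_annotation()] with at least `dfg_region`.
#' @return data.frame: `seq_id`, `group`, `dfg_region`, `dfg_plus1`,
#'   `aph_class`, `substrate_motif`, `cat_loop_flag`, `extrapolated_flag`.
#' @export
annotate_superfamily <- function(master, groups = NULL, annotation) {
  stopifnot(inherits(master, "CoreAlignment"))
  ids <- rownames(master$core)
  if (inherits(groups, "BPPSState"))
    groups <- stats::setNames(groups$spec$names[groups$z], groups$ids)
  grp <- if (is.null(groups)) rep(NA_character_, length(ids))
         else unname(groups[ids])
  out <- data.frame(seq_id = ids, group = grp,
                    dfg_region = NA_character_, dfg_plus1 = NA_character_,
                    aph_class = NA_character_,
                    substrate_motif = NA_character_,
                    cat_loop_flag = NA_character_,
                    extrapolated_flag = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    row <- master$core[i, ]
    if (length(annotation$dfg_region)) {
      res <- row[annotation$dfg_region]
      if (!any(res == GAP_CHAR)) {
        call <- classify_aph(paste0(res, collapse = ""))
        out$dfg_region[i] <- call$dfg_region
        out$dfg_plus1[i] <- call$dfg_plus1
        out$aph_class[i] <- call$class
        out$substrate_motif[i] <- call$substrate_motif
        out$extrapolated_flag[i] <- call$extrapolated
      }
    }
    if (length(annotation$cat_loop)) {
      res <- row[annotation$cat_loop]
      if (!any(res == GAP_CHAR))
        out$cat_loop_flag[i] <- catalytic_loop_basic(
          paste0(res, collapse = ""))
    }
  }
  out
}

#' Write an annotation table as tab-separated text
#' @param annotations data.frame from [annotate_superfamily()].
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
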