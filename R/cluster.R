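#' Fractional identity between two aligned core rows
#'
#' Fraction of co-occupied core columns (both rows non-gap) at which the
#' residues are identical. Insert segments are excluded: identity is defined
#' over the core domain only.
#'
#' @param a,b character vectors (one residue/gap per core column) or row
#'   indices into `alignment`.
#' @param alignment optional [core_alignment()] supplying the rows.
#' @return fraction in `[0, 1]`; 0 with a warning when no column is
#'   co-occupied.
#' @export
pairwise_identity <- function(a, b, alignment = NULL) {
  if (!is.null(alignment)) {
    a <- alignment$core[a, ]
    b <- alignment$core[b, ]
  }
  stopifnot(length(a) == length(b))
  occ <- a != GAP_CHAR & b != GAP_CHAR
  if (!any(occ)) {
    warning("no co-occupied core columns; identity reported as 0")
    return(0)
  }
  sum(a[occ] == b[occ]) / sum(occ)
}

#' Greedy identity clustering with representative selection
#'
#' CD-HIT-style greedy clustering over core rows: rows are sorted by
#' descending ungapped length (ties by input order); each row joins the first
#' existing representative with identity >= `threshold`, otherwise it founds
#' a new cluster and becomes its representative. Deterministic.
#'
#' @param alignment a [core_alignment()].
#' @param threshold fractional identity in `(0, 1]` (default 0.60).
#' @return data.frame: `cluster_id`, `seq_id`, `is_representative`,
#'   `identity_to_rep`, ordered by cluster then membership.
#' @export
greedy_cluster <- function(alignment, threshold = 0.60) {
  stopifnot(inherits(alignment, "CoreAlignment"),
            threshold > 0, threshold <= 1)
  core <- alignment$core
  len <- rowSums(core != GAP_CHAR)
  ord <- order(-len, seq_len(nrow(core)))
  reps <- integer(0)              # row indices of representatives
  assign_to <- integer(nrow(core))
  ident <- numeric(nrow(core))
  for (i in ord) {
    joined <- FALSE
    for (k in seq_along(reps)) {
      idn <- pairwise_identity(core[i, ], core[reps[k], ])
      if (idn >= threshold) {
        assign_to[i] <- k; ident[i] <- idn; joined <- TRUE; break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      assign_to[i] <- length(reps)
      ident[i] <- 1
    }
  }
  out <- data.frame(cluster_id = assign_to,
                    seq_id = rownames(core),
                    is_representative = seq_len(nrow(core)) %in% reps,
                    identity_to_rep = ident,
                    stringsAsFactors = FALSE)
  out[order(out$cluster_id, -out$is_representative), ]
}

#' Write a cluster table as tab-separated text
#' @param clusters data.frame from [greedy_cluster()].
#' @param path file path.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
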