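#' Run the classification pipeline from a config file
#'
#' Executes, in order, any prefix of: `simulate` (synthetic superfamily),
#' `align` (profiles + hierarchical alignment to the core), `cluster`
#' (identity clustering), `bpps` (pattern sampler), `cha` (contrast
#' alignment render), `tree` (bootstrap NJ + extended-majority consensus),
#' `classify` (DFG+1 and catalytic-loop annotation). Every artifact directory
#' gets a manifest recording the config hash and seed; per-stage row counts
#' are logged to stderr and to `run.log`.
#'
#' Config is YAML. Required top-level keys: `seed` (integer), `stages`
#' (subset of the stage names above, order fixed by the pipeline). Stage
#' sections provide parameters (see the package vignette); `bpps` run on
#' external data requires a `hierarchy` file.
#'
#' Config problems raise condition class `corekin_config_error`; data
#' problems `corekin_data_error` (the command-line wrapper maps these to exit
#' codes 2 and 3).
#'
#' @param config path to a YAML config file, or an already-parsed list.
#' @param out_dir artifact directory (created if missing).
#' @return invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config))
      config_error("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  seed <- as.integer(cfg$seed)
  stage_order <- c("simulate", "align", "cluster", "bpps", "cha",
                   "tree", "classify")
  stages <- stage_order[stage_order %in% cfg$stages]
  writeLines(c(sprintf("config_hash\t%s", config_hash(cfg)),
               sprintf("seed\t%d", seed)),
             file.path(out_dir, "manifest.tsv"))
  logf("pipeline start: stages ", paste(stages, collapse = ", "),
       " (seed ", seed, ", config ", config_hash(cfg), ")")

  sf <- NULL; master <- NULL; state <- NULL
  if ("simulate" %in% stages) {
    sc <- cfg$simulate
    conf <- superfamily_config(
      n_groups = sc$n_groups %||% 4L,
      hierarchy = if (!is.null(sc$hierarchy)) as.integer(sc$hierarchy)
                  else rep(NA_integer_, sc$n_groups %||% 4L),
      seqs_per_group = sc$seqs_per_group %||% 50L,
      core_length = sc$core_length %||% 60L,
      patterns_per_group = sc$patterns_per_group %||% 5L,
      fg_match_prob = sc$fg_match_prob %||% 0.95,
      bg_match_prob = sc$bg_match_prob %||% 0.05,
      rng_seed = seed)
    sf <- generate_superfamily(conf)
    write_fasta(sf$sequences, file.path(out_dir, "sequences.fasta"))
    write_a2m(sf$alignment, file.path(out_dir, "true_alignment.a2m"))
    write_truth_table(sf, file.path(out_dir, "truth.tsv"))
    master <- sf$alignment
    logf("simulate: ", nrow(sf$sequences), " sequences, ",
         ncol(sf$alignment$core), " core columns")
  }
  if ("align" %in% stages) {
    if (is.null(sf))
      data_error("align stage requires the simulate stage in this run")
    groups <- split(seq_len(nrow(master$core)),
                    sf$sequences$group)
    seed_alns <- lapply(groups, function(idx) master[idx])
    it <- iterate_profiles(seed_alns,
                           n_rounds = cfg$align$n_rounds %||% 2L,
                           threshold = cfg$align$threshold %||% 25)
    master <- it$master
    for (nm in names(it$profiles))
      write_profile(it$profiles[[nm]],
                    file.path(out_dir, paste0("profile_", nm, ".txt")))
    write_a2m(master, file.path(out_dir, "master.a2m"))
    logf("align: ", nrow(master$core), " rows; per-round changes ",
         paste(it$changes, collapse = "/"))
  }
  if ("cluster" %in% stages) {
    if (is.null(master)) data_error("cluster stage requires an alignment")
    cl <- greedy_cluster(master, threshold = cfg$cluster$threshold %||% 0.60)
    write_clusters(cl, file.path(out_dir, "clusters.tsv"))
    logf("cluster: ", max(cl$cluster_id), " clusters over ",
         nrow(cl), " rows")
  }
  if ("bpps" %in% stages) {
    if (is.null(master)) data_error("bpps stage requires an alignment")
    spec <- pipeline_hierarchy(cfg, sf)
    res <- run_mcbpps(master, spec,
                      n_sweeps = cfg$bpps$n_sweeps %||% 60L,
                      burn_in = cfg$bpps$burn_in %||% 30L,
                      rng_seed = seed,
                      rho = cfg$bpps$rho %||% 0.2)
    state <- res$state
    write_bpps_report(res$report, file.path(out_dir, "bpps_report.tsv"))
    utils::write.table(
      data.frame(seq_id = names(res$assignments),
                 node = unname(res$assignments)),
      file.path(out_dir, "assignments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    logf("bpps: ", nrow(res$report), " pattern columns over ",
         length(unique(res$report$node)), " nodes")
  }
  if ("cha" %in% stages) {
    if (is.null(state)) data_error("cha stage requires the bpps stage")
    for (nm in unique(bpps_report(state)$node)) {
      fg_ids <- state$ids[state$z %in% state$sub[[match(nm,
                                                        state$spec$names)]]]
      doc <- render_cha(master, state, nm,
                        utils::head(fg_ids, cfg$cha$display_rows %||% 3L))
      write_cha_text(doc, file.path(out_dir, paste0("cha_", nm, ".txt")))
      write_cha_html(doc, file.path(out_dir, paste0("cha_", nm, ".html")))
    }
    logf("cha: rendered contrast alignments")
  }
  if ("tree" %in% stages) {
    if (is.null(master)) data_error("tree stage requires an alignment")
    cl <- greedy_cluster(master, threshold = cfg$cluster$threshold %||% 0.60)
    reps <- cl$seq_id[cl$is_representative]
    if (length(reps) < 3)
      reps <- rownames(master$core)[seq_len(min(8L, nrow(master$core)))]
    rep_aln <- master[reps]
    trees <- bootstrap_trees(rep_aln, n_reps = cfg$tree$n_reps %||% 100L,
                             rng_seed = seed)
    cons <- extended_majority_consensus(trees)
    write_newick(cons, file.path(out_dir, "consensus.nwk"))
    logf("tree: consensus over ", length(trees), " bootstrap replicates, ",
         length(cons$tip.label), " taxa")
  }
  if ("classify" %in% stages) {
    if (is.null(master)) data_error("classify stage requires an alignment")
    ann_cfg <- cfg$classify %||% list()
    annotation <- motif_annotation(
      cat_loop = as.integer(ann_cfg$cat_loop %||% integer(0)),
      dfg_region = as.integer(ann_cfg$dfg_region %||% integer(0)))
    groups <- if (!is.null(state)) state else
      if (!is.null(sf)) sf$truth$groups else NULL
    ann <- annotate_superfamily(master, groups, annotation)
    write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    logf("classify: ", nrow(ann), " sequences annotated")
  }
  logf("pipeline done")
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(...) {
  stop(structure(class = c("corekin_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

data_error <- function(...) {
  stop(structure(class = c("corekin_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) config_error("config must be a YAML mapping")
  if (is.null(cfg$seed)) config_error("config requires an explicit seed")
  if (is.null(cfg$stages) || !length(cfg$stages))
    config_error("config requires a non-empty stages list")
  known <- c("simulate", "align", "cluster", "bpps", "cha", "tree",
             "classify")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) config_error("unknown stages: ", paste(bad, collapse = ", "))
  if ("bpps" %in% cfg$stages && !"simulate" %in% cfg$stages &&
      is.null(cfg$bpps$hierarchy))
    config_error("bpps stage requires a hierarchy file when not simulating")
  invisible(cfg)
}

# hierarchy for the bpps stage: from file, or derived from simulation truth
pipeline_hierarchy <- function(cfg, sf) {
  if (!is.null(cfg$bpps$hierarchy)) {
    if (!file.exists(cfg$bpps$hierarchy))
      config_error("hierarchy file not found: ", cfg$bpps$hierarchy)
    spec <- read_hierarchy(cfg$bpps$hierarchy)
  } else {
    if (is.null(sf)) data_error("no hierarchy available for bpps stage")
    h <- sf$truth$hierarchy
    nms <- paste0("G", seq_along(h))
    parents <- ifelse(is.na(h), "root", nms[h])
    spec <- hierarchy_spec(c("root", nms), c(NA, parents))
  }
  n_seeds <- cfg$bpps$seeds_per_group %||% 3L
  if (!length(spec$seeds) && !is.null(sf)) {
    seeds <- lapply(split(names(sf$truth$groups), sf$truth$groups),
                    utils::head, n_seeds)
    seeds <- seeds[names(seeds) %in% spec$names[spec$is_leaf]]
    spec <- hierarchy_spec(spec$names,
                           ifelse(is.na(spec$parent), NA,
                                  spec$names[spec$parent]),
                           spec$internal, seeds)
  }
  spec
}

# small multiplicative hash of the canonical config serialization
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                           collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
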