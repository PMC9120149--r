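#' Validate a pipeline configuration
#'
#' @param config a named list or a path to a YAML file. Recognised fields:
#'   `input_dir` (a directory in the [write_simulation()] layout),
#'   `out_dir`, `seed`, `rooting` (`"opimoda-diphoda"` or `"unresolved"`),
#'   `leca_threshold` (default 0.5), `gap_threshold` (default 0.9),
#'   `u12_min_species` (default 3), `rates_mode` (default `"per_branch"`),
#'   `u12_predictions` (optional TSV path).
#' @return the completed configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(rooting = "opimoda-diphoda", leca_threshold = 0.5,
                   gap_threshold = 0.9, u12_min_species = 3L,
                   rates_mode = "per_branch", seed = 1L,
                   u12_predictions = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$input_dir) || is.null(config$out_dir)) {
    stop("config requires input_dir and out_dir")
  }
  if (!config$rooting %in% c("opimoda-diphoda", "unresolved")) {
    stop("rooting must be 'opimoda-diphoda' or 'unresolved'")
  }
  if (config$leca_threshold <= 0 || config$leca_threshold > 1) {
    stop("leca_threshold must be in (0, 1]")
  }
  if (config$gap_threshold <= 0 || config$gap_threshold > 1) {
    stop("gap_threshold must be in (0, 1]")
  }
  if (config$u12_min_species < 1) stop("u12_min_species must be >= 1")
  class(config) <- c("pipeline_config", "list")
  config
}

provenance_header <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[sort(setdiff(names(config), "out_dir"))]),
             tmp)
  hash <- unname(tools::md5sum(tmp))
  paste0("# paralintron ",
         as.character(utils::packageVersion("paralintron")),
         "; config=", hash, "; seed=", config$seed)
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map genomic introns onto orthogroup alignments for all species
#'
#' Reads every `<species>.gff3` / `<species>.fa` pair in `genome_dir`,
#' extracts protein-coordinate introns, projects them onto the
#' per-orthogroup alignments in `alignment_dir` (files `<og>.fa`; merged
#' family alignments `*_merged.fa` are skipped here) and builds one
#' intron table per orthogroup.
#'
#' @param genome_dir directory of per-species GFF3 + genome FASTA.
#' @param alignment_dir directory of per-orthogroup aligned FASTA.
#' @param species optional character vector restricting the species set.
#' @return named list of [intron_table()] objects.
#' @export
map_stage <- function(genome_dir, alignment_dir, species = NULL) {
  gffs <- list.files(genome_dir, pattern = "\\.gff3$", full.names = TRUE)
  if (is.null(species)) species <- sub("\\.gff3$", "", basename(gffs))
  introns_by_protein <- list()
  for (sp in species) {
    gpath <- file.path(genome_dir, paste0(sp, ".gff3"))
    fpath <- file.path(genome_dir, paste0(sp, ".fa"))
    genome <- read_gff3(gpath, fpath, species_id = sp)
    for (t in genome$transcripts) {
      if (!t$mapping_ok) {
        introns_by_protein[t$protein_id] <- list(NULL)
        next
      }
      introns_by_protein[[t$protein_id]] <- introns_from_transcript(t)
    }
  }
  aln_files <- list.files(alignment_dir, pattern = "\\.fa$",
                          full.names = TRUE)
  aln_files <- aln_files[!grepl("_merged\\.fa$", aln_files)]
  tables <- list()
  for (f in aln_files) {
    og <- read_alignment(f)
    introns <- list()
    for (sid in names(og$rows)) {
      pin <- introns_by_protein[[sid]]
      if (is.null(pin) && !(sid %in% names(introns_by_protein))) {
        next  # no gene model at all: species row decided by coverage
      }
      if (is.null(pin)) { introns[sid] <- list(NULL); next }
      cols <- vapply(pin$anchor_residue, project_to_alignment,
                     0L, row = og$rows[[sid]])
      ok <- !is.na(cols)
      if (!all(ok)) {
        introns[sid] <- list(NULL)  # anchor beyond sequence: unmappable
      } else {
        introns[[sid]] <- data.frame(column = cols, phase = pin$phase)
      }
    }
    tables[[og$og_id]] <- build_intron_table(og, introns, species)
  }
  tables
}

#' Reconstruction stage: rates, posteriors and LECA calls
#'
#' @param tables named list of intron tables.
#' @param species_tree rooted species tree (`phylo`). For the
#'   unresolved-root variant pass the multifurcating topology; the LECA
#'   node is the root in both cases.
#' @param rates_mode passed to [estimate_rates()].
#' @param leca_threshold LECA calling threshold.
#' @return list with `rates`, `recon` (an `intron_reconstruction`),
#'   `leca` (the [call_leca()] data.frame) and `branch_events`.
#' @export
reconstruct_stage <- function(tables, species_tree,
                              rates_mode = "per_branch",
                              leca_threshold = 0.5) {
  rates <- estimate_rates(tables, species_tree, mode = rates_mode)
  recon <- reconstruct_introns(tables, species_tree, rates)
  leca <- call_leca(recon, threshold = leca_threshold)
  list(rates = rates, recon = recon, leca = leca,
       branch_events = branch_event_counts(recon))
}

#' Shared-intron stage: transfer LECA calls to merged coordinates and
#' classify
#'
#' For every orthogroup with LECA introns, picks a sequence present in
#' both the orthogroup and the merged family alignment, transfers each
#' LECA position to merged coordinates with [transfer_to_merged()], then
#' classifies shared vs unique introns against the acquisition metadata.
#' LECA calls that cannot be transferred (no sequence carries a residue at
#' the orthogroup column) are excluded with a warning.
#'
#' @param leca [call_leca()] output (rows with `is_leca` are used).
#' @param alignment_dir directory holding `<og>.fa` and
#'   `fam<family>_merged.fa`.
#' @param acquisitions metadata data.frame (og_id, family_id,
#'   acquisition_id, ambiguous).
#' @return list with `classification` (a [classify_shared()] result,
#'   including `merged_column`), `control` (a [parallel_gain_control()]
#'   result).
#' @export
shared_stage <- function(leca, alignment_dir, acquisitions) {
  calls <- leca[leca$is_leca, , drop = FALSE]
  rows <- list()
  for (og in unique(calls$og_id)) {
    fam <- acquisitions$family_id[match(og, acquisitions$og_id)]
    og_aln <- read_alignment(file.path(alignment_dir, paste0(og, ".fa")))
    merged <- read_alignment(
      file.path(alignment_dir, paste0(fam, "_merged.fa")))
    sub <- calls[calls$og_id == og, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      col <- sub$column[i]
      # any sequence with a residue at this column links the coordinates
      sid <- NULL
      for (cand in names(og_aln$rows)) {
        if (!(cand %in% names(merged$rows))) next
        if (substr(og_aln$rows[[cand]], col, col) != "-") { sid <- cand
          break }
      }
      if (is.null(sid)) {
        warning("LECA intron ", og, ":", col, ".", sub$phase[i],
                " not transferable to merged coordinates; excluded")
        next
      }
      mcol <- transfer_to_merged(col, og_aln$rows[[sid]],
                                 merged$rows[[sid]], sid)
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og, family_id = fam, column = mcol, phase = sub$phase[i],
        og_column = col, leca_probability = sub$leca_probability[i])
    }
  }
  if (length(rows) == 0L) stop("no transferable LECA introns")
  merged_positions <- do.call(rbind, rows)
  classification <- classify_shared(merged_positions, acquisitions)
  list(classification = classification,
       control = parallel_gain_control(classification))
}

#' Dollo stage: pre-duplication introns on every acquisition gene tree
#'
#' @param classification the `classification` element of [shared_stage()]
#'   (merged-coordinate LECA introns with og and family ids).
#' @param tree_dir directory with `<acquisition>.nwk` gene trees.
#' @param acquisitions metadata data.frame.
#' @return list with `states` (per-acquisition `gene_tree_state`),
#'   `events` (the [count_preduplication_events()] vector) and
#'   `dup_table` (all duplication-node flags).
#' @export
dollo_stage <- function(classification, tree_dir, acquisitions) {
  states <- list()
  for (acq in unique(acquisitions$acquisition_id)) {
    path <- file.path(tree_dir, paste0(acq, ".nwk"))
    if (!file.exists(path)) next  # single-OG acquisition: no gene tree
    gt <- read_annotated_tree(path)
    ogs <- acquisitions$og_id[acquisitions$acquisition_id == acq]
    sets <- list()
    for (og in intersect(ogs, gt$tip.label)) {
      sub <- classification[classification$og_id == og, , drop = FALSE]
      sets[[og]] <- data.frame(column = sub$column, phase = sub$phase)
    }
    states[[acq]] <- dollo_preduplication(gt, sets)
  }
  dup_table <- do.call(rbind, lapply(names(states), function(acq) {
    df <- states[[acq]]$dup_nodes
    if (nrow(df) == 0) return(NULL)
    df$acquisition_id <- acq
    df
  }))
  list(states = states, events = count_preduplication_events(states),
       dup_table = dup_table)
}

#' Statistics stage: relative positions and phase distributions by category
#'
#' Computes gap-masked relative positions for every observed intron, keyed
#' to its category (shared LECA, unique LECA, post-LECA), runs pairwise
#' two-sample Kolmogorov-Smirnov tests between the category distributions
#' and pairwise chi-squared tests between the phase distributions, both
#' with Benjamini-Hochberg adjustment.
#'
#' @param tables named list of intron tables (observed positions).
#' @param leca [call_leca()] output for the same positions.
#' @param classification merged-coordinate classification from
#'   [shared_stage()].
#' @param alignment_dir directory with `<og>.fa` alignments.
#' @param gap_threshold mask threshold (default 0.9).
#' @return list with `intron_stats` (data.frame og/column/phase/category/
#'   relative_position), `ks` (pairwise KS data.frame), `phases` (a
#'   [phase_distribution()] result).
#' @export
stats_stage <- function(tables, leca, classification, alignment_dir,
                        gap_threshold = 0.9) {
  key <- function(og, col, ph) paste(og, col, ph, sep = "/")
  leca_key <- key(leca$og_id, leca$column, leca$phase)
  shared_key <- key(classification$og_id, classification$og_column,
                    classification$phase)[classification$category ==
                                            "shared"]
  rows <- list()
  for (og_id in names(tables)) {
    tb <- tables[[og_id]]
    if (nrow(tb$positions) == 0) next
    og <- read_alignment(file.path(alignment_dir, paste0(og_id, ".fa")))
    mask <- mask_alignment(og, gap_threshold)
    k <- key(og_id, tb$positions$column, tb$positions$phase)
    idx <- match(k, leca_key)
    is_leca <- !is.na(idx) & leca$is_leca[idx]
    category <- ifelse(!is_leca, "post-LECA",
                       ifelse(k %in% shared_key, "shared LECA",
                              "unique LECA"))
    relpos <- vapply(tb$positions$column, relative_position, 0,
                     mask = mask)
    rows[[og_id]] <- data.frame(og_id = og_id,
                                column = tb$positions$column,
                                phase = tb$positions$phase,
                                category = category,
                                relative_position = relpos)
  }
  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  cats <- unique(stats_df$category)
  ks <- NULL
  if (length(cats) >= 2) {
    pairs <- utils::combn(cats, 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      x <- stats_df$relative_position[stats_df$category == pairs[1, j]]
      y <- stats_df$relative_position[stats_df$category == pairs[2, j]]
      res <- ks_two_sample(x, y)
      data.frame(cat1 = pairs[1, j], cat2 = pairs[2, j],
                 D = res$statistic, p = res$p)
    }))
    ks$p_adj <- bh_fdr(ks$p)
  }
  phases <- phase_distribution(stats_df$phase, stats_df$category)
  list(intron_stats = stats_df, ks = ks, phases = phases)
}

#' Run the full analysis pipeline
#'
#' Executes map, reconstruct, shared, dollo and stats in dependency
#' order on an input directory in the [write_simulation()] layout, writing
#' one TSV per stage into `out_dir`. Every output carries a header comment
#' with the package version, a hash of the configuration and the seed;
#' a rerun with identical inputs and config is byte-identical.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by
#'   it).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  set.seed(config$seed)
  ind <- config$input_dir
  for (sub in c("genomes", "alignments", "trees")) {
    if (!dir.exists(file.path(ind, sub))) {
      stop("stage setup: input directory lacks '", sub, "/' (", ind, ")")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- provenance_header(config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tables <- run_stage("map", map_stage(file.path(ind, "genomes"),
                                       file.path(ind, "alignments")))
  for (og in names(tables)) {
    write_intron_table(tables[[og]],
                       file.path(config$out_dir, paste0(og, ".table.tsv")))
  }
  species_tree <- run_stage("reconstruct",
                            read_annotated_tree(file.path(ind, "trees",
                                                          "species.nwk")))
  rec <- run_stage("reconstruct",
                   reconstruct_stage(tables, species_tree,
                                     rates_mode = config$rates_mode,
                                     leca_threshold =
                                       config$leca_threshold))
  write_stage_tsv(rec$leca, file.path(config$out_dir, "leca_calls.tsv"),
                  header)
  write_stage_tsv(rec$branch_events,
                  file.path(config$out_dir, "branch_events.tsv"), header)

  acquisitions <- utils::read.delim(file.path(ind, "metadata.tsv"))
  sh <- run_stage("shared",
                  shared_stage(rec$leca, file.path(ind, "alignments"),
                               acquisitions))
  write_stage_tsv(sh$classification,
                  file.path(config$out_dir, "classification.tsv"), header)

  dl <- run_stage("dollo",
                  dollo_stage(sh$classification, file.path(ind, "trees"),
                              acquisitions))
  write_stage_tsv(data.frame(event = names(dl$events),
                             count = unname(dl$events)),
                  file.path(config$out_dir, "dollo_events.tsv"), header)
  if (!is.null(dl$dup_table)) {
    write_stage_tsv(dl$dup_table,
                    file.path(config$out_dir, "duplications.tsv"), header)
  }

  st <- run_stage("stats",
                  stats_stage(tables, rec$leca, sh$classification,
                              file.path(ind, "alignments"),
                              config$gap_threshold))
  write_stage_tsv(st$intron_stats,
                  file.path(config$out_dir, "intron_stats.tsv"), header)
  if (!is.null(st$ks)) {
    write_stage_tsv(st$ks, file.path(config$out_dir, "ks_tests.tsv"),
                    header)
  }

  u12 <- NULL
  if (!is.null(config$u12_predictions)) {
    preds <- read_u12_predictions(config$u12_predictions)
    u12 <- annotate_u12(preds, rec$leca[rec$leca$is_leca, , drop = FALSE],
                        min_species = config$u12_min_species)
  }

  invisible(list(config = config, tables = tables, reconstruct = rec,
                 shared = sh, dollo = dl, stats = st, u12 = u12))
}
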