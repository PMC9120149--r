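#' Classify LECA introns as shared or unique across paralogous orthogroups
#'
#' Works in merged-family-alignment coordinates: two LECA introns in
#' different orthogroups (OGs) of one family match when they occupy the
#' same (merged column, phase) pair exactly. Matches between OGs of one
#' acquisition are evidence of a pre-duplication intron ("shared");
#' matches across separate acquisitions can only be parallel gains and
#' never make an intron "shared". Introns matched only across separate
#' acquisitions are excluded from both the numerator and the denominator
#' of the shared fraction; OGs flagged ambiguous (an acquisition with
#' another acquisition in its sister group) are excluded from both the
#' paralog and the control sets.
#'
#' @param leca_positions data.frame of LECA introns in merged coordinates:
#'   columns `og_id`, `column`, `phase`, and optionally `family_id`
#'   (matching is always within one family).
#' @param acquisitions data.frame with columns `og_id`, `acquisition_id`
#'   and optionally `family_id` and `ambiguous` (logical). OGs sharing an
#'   `acquisition_id` are proto-eukaryotic paralogs; an OG alone in its
#'   acquisition is separately acquired. The control set consists of
#'   separately acquired OGs with at least one other separately acquired
#'   OG in the family, so that control introns are compared among
#'   separate acquisitions exactly as paralog introns are compared within
#'   an acquisition.
#' @return a data.frame of class `shared_classification`: the input rows
#'   plus `category`, one of `shared`, `unique` (paralog set),
#'   `control_shared`, `control_unique` (separate-acquisition control
#'   set), `excluded_parallel` (an intron whose only matches are across
#'   the paralog/separate-acquisition divide), `excluded_ambiguous`,
#'   `excluded_no_partner` (OG with no eligible comparison partner).
#' @export
classify_shared <- function(leca_positions, acquisitions) {
  df <- as.data.frame(leca_positions)
  need <- c("og_id", "column", "phase")
  stopifnot(all(need %in% names(df)),
            all(c("og_id", "acquisition_id") %in% names(acquisitions)))
  if (!"family_id" %in% names(df)) df$family_id <- "family1"
  if (!"family_id" %in% names(acquisitions)) {
    acquisitions$family_id <- "family1"
  }
  if (!"ambiguous" %in% names(acquisitions)) acquisitions$ambiguous <- FALSE
  unknown <- setdiff(df$og_id, acquisitions$og_id)
  if (length(unknown) > 0) {
    stop("og(s) without acquisition assignment: ",
         paste(unknown, collapse = ", "))
  }
  at <- match(df$og_id, acquisitions$og_id)
  acq <- acquisitions$acquisition_id[at]
  amb <- acquisitions$ambiguous[at]

  # OG-set structure, from the metadata (not from observed introns)
  meta <- acquisitions[!acquisitions$ambiguous, , drop = FALSE]
  acq_size <- table(meta$acquisition_id)
  meta$single <- acq_size[meta$acquisition_id] == 1
  n_single_in_family <- tapply(meta$single, meta$family_id, sum)
  fam_of <- acquisitions$family_id[at]
  is_paralog_set <- !amb & acq_size[acq] >= 2
  is_control_set <- !amb & acq_size[acq] == 1 &
    n_single_in_family[fam_of] >= 2
  single_og <- meta$og_id[meta$single]

  poskey <- paste(df$family_id, df$column, df$phase, sep = "/")
  category <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (amb[i]) { category[i] <- "excluded_ambiguous"; next }
    if (!is_paralog_set[i] && !is_control_set[i]) {
      category[i] <- "excluded_no_partner"
      next
    }
    mates <- which(poskey == poskey[i] & df$og_id != df$og_id[i] & !amb)
    if (is_paralog_set[i]) {
      same_acq <- any(acq[mates] == acq[i])
      cross_acq <- any(acq[mates] != acq[i])
      category[i] <- if (same_acq) "shared"
                     else if (cross_acq) "excluded_parallel"
                     else "unique"
    } else {
      with_control <- any(df$og_id[mates] %in% single_og &
                            acq[mates] != acq[i])
      with_other <- any(!(df$og_id[mates] %in% single_og))
      category[i] <- if (with_control) "control_shared"
                     else if (with_other) "excluded_parallel"
                     else "control_unique"
    }
  }
  df$category <- category
  class(df) <- c("shared_classification", "data.frame")
  df
}

#' Fraction of shared LECA introns among paralogs
#' @param classification a [classify_shared()] result.
#' @return shared / (shared + unique), or `NA` when the paralog set is
#'   empty.
#' @export
shared_fraction <- function(classification) {
  n_shared <- sum(classification$category == "shared")
  n_unique <- sum(classification$category == "unique")
  if (n_shared + n_unique == 0) return(NA_real_)
  n_shared / (n_shared + n_unique)
}

#' Parallel-gain control: shared fractions in paralogs vs separate acquisitions
#'
#' Intron positions shared between separately acquired homologs must be
#' parallel gains, so the shared fraction in the separate-acquisition set
#' estimates the parallel-gain background. The paralog shared fraction is
#' compared against it with a two-sided Fisher exact test on the 2x2 table
#' (shared, unshared) x (paralogs, separate acquisitions).
#'
#' Fractions are reported per intron (every orthogroup's intron counts),
#' but the Fisher table counts distinct positions: one shared position
#' creates a matching intron in at least two orthogroups at once, so
#' counting introns would enter every sharing event twice and overdisperse
#' the test.
#'
#' @param classification a [classify_shared()] result (families may be
#'   concatenated beforehand). When the `family_id`/`column`/`phase`
#'   columns are present the test deduplicates to positions; otherwise it
#'   falls back to intron counts.
#' @return a list of class `parallel_gain_control`: `fraction_paralog`,
#'   `fraction_separate` (per intron), `table` (2x2 position-count
#'   matrix), `fisher` (a [fisher_exact()] result) and `available`. When
#'   the control set is empty, `available` is `FALSE` and `fisher` is
#'   `NULL`.
#' @export
parallel_gain_control <- function(classification) {
  n_shared <- sum(classification$category == "shared")
  n_unique <- sum(classification$category == "unique")
  n_cs <- sum(classification$category == "control_shared")
  n_cu <- sum(classification$category == "control_unique")
  frac_par <- if (n_shared + n_unique > 0) n_shared / (n_shared + n_unique)
              else NA_real_
  if (n_cs + n_cu == 0) {
    message("no separate-acquisition introns: control unavailable")
    return(structure(list(fraction_paralog = frac_par,
                          fraction_separate = NA_real_, table = NULL,
                          fisher = NULL, available = FALSE),
                     class = "parallel_gain_control"))
  }
  n_pos <- function(cat) {
    rows <- classification$category == cat
    if (all(c("family_id", "column", "phase") %in% names(classification))) {
      length(unique(paste(classification$family_id[rows],
                          classification$column[rows],
                          classification$phase[rows])))
    } else {
      sum(rows)
    }
  }
  tab <- matrix(c(n_pos("shared"), n_pos("unique"),
                  n_pos("control_shared"), n_pos("control_unique")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("paralogs", "separate"),
                                c("shared", "unshared")))
  structure(list(fraction_paralog = frac_par,
                 fraction_separate = n_cs / (n_cs + n_cu),
                 table = tab, fisher = fisher_exact(tab), available = TRUE),
            class = "parallel_gain_control")
}

#' Dollo parsimony reconstruction of pre-duplication introns
#'
#' Each intron is allowed exactly one gain and unlimited losses. Its
#' presence is assigned to every node of the minimal spanning subtree
#' connecting the orthogroups (leaves) that carry it; the gain falls on
#' the branch into the root of that subtree and one loss on every branch
#' leaving the subtree towards a non-carrier clade. A duplication node is
#' flagged as having pre-duplication introns when its presence set is
#' non-empty; a secondary flag records whether any more ancestral
#' duplication node was non-empty instead. Multifurcating gene trees are
#' handled on the topology as given.
#'
#' @param gene_tree an annotated gene tree (leaves = LECA orthogroups,
#'   internal nodes labelled `duplication`/`acquisition`).
#' @param leca_intron_sets named list mapping each carrier og_id to a
#'   data.frame with columns `column`, `phase` (LECA introns in merged
#'   coordinates). OGs without introns may be omitted.
#' @return an object of class `gene_tree_state`: list with `tree`,
#'   `presence` (per-node character vectors of `column.phase` keys),
#'   `gains`, `losses` (per-branch, keyed by child node), and `dup_nodes`
#'   (data.frame `node`, `label`, `has_predup_introns`,
#'   `ancestral_dup_has_introns`).
#' @export
dollo_preduplication <- function(gene_tree, leca_intron_sets) {
  stopifnot(inherits(gene_tree, "phylo"))
  tree <- gene_tree
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  carriers_missing <- setdiff(names(leca_intron_sets), tree$tip.label)
  if (length(carriers_missing) > 0) {
    stop("carrier leaf absent from gene tree: ",
         paste(carriers_missing, collapse = ", "))
  }
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  keys_of <- lapply(leca_intron_sets, function(x) {
    if (is.null(x) || nrow(x) == 0) character(0)
    else paste(x$column, x$phase, sep = ".")
  })
  all_keys <- unique(unlist(keys_of))
  presence <- vector("list", n_nodes)
  gains <- vector("list", n_nodes)
  losses <- vector("list", n_nodes)
  children <- split(tree$edge[, 2], tree$edge[, 1])

  for (key in all_keys) {
    carrier_tips <- match(names(keys_of)[vapply(keys_of, function(k)
      key %in% k, TRUE)], tree$tip.label)
    # spanning subtree: walk each carrier up to the common ancestor
    if (length(carrier_tips) == 1L) {
      mrca <- carrier_tips
      sub_nodes <- carrier_tips
    } else {
      paths <- lapply(carrier_tips, function(tp) {
        p <- tp
        while (!is.na(parent[p[length(p)]])) p <- c(p, parent[p[length(p)]])
        p
      })
      common <- Reduce(intersect, paths)
      mrca <- common[1]  # paths list ancestors tipward->rootward
      sub_nodes <- unique(unlist(lapply(paths, function(p)
        p[seq_len(which(p == mrca))])))
    }
    for (v in sub_nodes) presence[[v]] <- c(presence[[v]], key)
    gains[[mrca]] <- c(gains[[mrca]], key)
    for (v in setdiff(sub_nodes, seq_len(ntip))) {
      for (ch in children[[as.character(v)]]) {
        if (!(ch %in% sub_nodes)) losses[[ch]] <- c(losses[[ch]], key)
      }
    }
  }

  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep("duplication", tree$Nnode))
  dup_ids <- which(labels == "duplication")
  dup_ids <- dup_ids[dup_ids > ntip]
  has_predup <- vapply(dup_ids, function(v) length(presence[[v]]) > 0, TRUE)
  anc_has <- vapply(dup_ids, function(v) {
    p <- parent[v]
    while (!is.na(p)) {
      if (labels[p] == "duplication" && length(presence[[p]]) > 0) {
        return(TRUE)
      }
      p <- parent[p]
    }
    FALSE
  }, TRUE)
  structure(list(tree = tree, presence = presence, gains = gains,
                 losses = losses,
                 dup_nodes = data.frame(node = dup_ids,
                                        label = labels[dup_ids],
                                        has_predup_introns = has_predup,
                                        ancestral_dup_has_introns = anc_has)),
            class = "gene_tree_state")
}

#' Count Dollo gains and losses before duplications vs on LECA branches
#'
#' Events on branches entering internal (duplication/acquisition) nodes
#' happened before a duplication; events on branches entering leaves
#' happened on the branches resulting in the LECA orthogroup families. A
#' gain at the root of a gene tree (no incoming branch) is counted as a
#' pre-duplication gain on the stem.
#'
#' @param states a `gene_tree_state` or a list of them.
#' @return a named numeric vector: `gains_before_dup`, `losses_before_dup`,
#'   `gains_to_leca`, `losses_to_leca`.
#' @export
count_preduplication_events <- function(states) {
  if (inherits(states, "gene_tree_state")) states <- list(states)
  out <- c(gains_before_dup = 0, losses_before_dup = 0,
           gains_to_leca = 0, losses_to_leca = 0)
  for (st in states) {
    ntip <- ape::Ntip(st$tree)
    for (v in seq_along(st$gains)) {
      n <- length(st$gains[[v]])
      if (n == 0) next
      if (v > ntip) out["gains_before_dup"] <- out["gains_before_dup"] + n
      else out["gains_to_leca"] <- out["gains_to_leca"] + n
    }
    for (v in seq_along(st$losses)) {
      n <- length(st$losses[[v]])
      if (n == 0) next
      if (v > ntip) out["losses_before_dup"] <- out["losses_before_dup"] + n
      else out["losses_to_leca"] <- out["losses_to_leca"] + n
    }
  }
  out
}

#' Annotate intron positions as U2- or U12-type
#'
#' A position is annotated U12 when at least `min_species` distinct
#' species carry a U12 prediction for it; everything else defaults to U2.
#'
#' @param predictions data.frame as returned by [read_u12_predictions()].
#' @param positions data.frame with columns `og_id`, `column`, `phase`.
#' @param min_species minimum number of distinct predicting species
#'   (default 3).
#' @return character vector over `{"U2", "U12"}`, one entry per row of
#'   `positions`.
#' @export
annotate_u12 <- function(predictions, positions, min_species = 3L) {
  stopifnot(min_species >= 1L)
  pred_key <- paste(predictions$og_id, predictions$alignment_column,
                    predictions$phase, sep = "/")
  pos_key <- paste(positions$og_id, positions$column, positions$phase,
                   sep = "/")
  vapply(pos_key, function(k) {
    hit <- predictions$predicted_type == "U12" & pred_key == k
    n_sp <- length(unique(predictions$species_id[hit]))
    if (n_sp >= min_species) "U12" else "U2"
  }, "", USE.NAMES = FALSE)
}

#' Fractions of a binary outcome across annotation groups
#'
#' Aggregates per-unit binary outcomes (e.g. LECA intron shared vs unique,
#' or duplication with vs without traced pre-duplication introns) by
#' functional category, cellular localisation or phylogenetic origin:
#' builds the group contingency table, tests it with a chi-squared
#' contingency test, runs all pairwise 2x2 Fisher exact tests with
#' Benjamini-Hochberg adjustment, and reports Wilson 95\% intervals per
#' group. Groups below `min_n` units are excluded from the report and the
#' tests.
#'
#' When `main_group_of` is supplied (a named map category -> main group),
#' units whose categories span more than one main group are excluded and
#' grouping is by main group.
#'
#' @param outcomes data.frame with columns `unit` and logical `outcome`.
#' @param metadata data.frame with columns `unit`, `group` (a unit may
#'   appear with several groups).
#' @param min_n minimum group size to report (default 10).
#' @param main_group_of optional named character vector mapping group to
#'   main group.
#' @return a list of class `group_table`: `table` (data.frame `group`,
#'   `n_yes`, `n_no`, `fraction`, `wilson_lo`, `wilson_hi`), `chi2`,
#'   `pairwise` (data.frame with BH-adjusted p), `excluded_units`.
#' @export
group_fractions <- function(outcomes, metadata, min_n = 10L,
                            main_group_of = NULL) {
  stopifnot(all(c("unit", "outcome") %in% names(outcomes)),
            all(c("unit", "group") %in% names(metadata)))
  md <- metadata
  excluded <- character(0)
  if (!is.null(main_group_of)) {
    md$group <- unname(main_group_of[md$group])
    md <- md[!is.na(md$group), , drop = FALSE]
    span <- tapply(md$group, md$unit, function(g) length(unique(g)))
    excluded <- names(span)[span > 1]
    md <- md[!(md$unit %in% excluded), , drop = FALSE]
    md <- unique(md)
  }
  merged <- merge(outcomes, md, by = "unit")
  if (nrow(merged) == 0) stop("no unit has group metadata")
  agg <- stats::aggregate(outcome ~ group, merged,
                          FUN = function(x) c(yes = sum(x), n = length(x)))
  tab <- data.frame(group = agg$group,
                    n_yes = agg$outcome[, "yes"],
                    n_no = agg$outcome[, "n"] - agg$outcome[, "yes"])
  tab <- tab[tab$n_yes + tab$n_no >= min_n, , drop = FALSE]
  if (nrow(tab) == 0) stop("no group reaches min_n = ", min_n)
  ci <- t(mapply(wilson_interval, tab$n_yes, tab$n_yes + tab$n_no))
  tab$fraction <- tab$n_yes / (tab$n_yes + tab$n_no)
  tab$wilson_lo <- ci[, 1]
  tab$wilson_hi <- ci[, 2]
  rownames(tab) <- NULL

  chi2 <- NULL
  if (nrow(tab) >= 2) {
    chi2 <- chi2_contingency(as.matrix(tab[, c("n_yes", "n_no")]))
  }
  pairwise <- NULL
  if (nrow(tab) >= 2) {
    pairs <- utils::combn(seq_len(nrow(tab)), 2)
    pw <- apply(pairs, 2, function(ij) {
      ft <- fisher_exact(as.matrix(tab[ij, c("n_yes", "n_no")]))
      c(p = ft$p, odds_ratio = ft$statistic)
    })
    pairwise <- data.frame(group1 = tab$group[pairs[1, ]],
                           group2 = tab$group[pairs[2, ]],
                           odds_ratio = pw["odds_ratio", ],
                           p = pw["p", ])
    pairwise$p_adj <- bh_fdr(pairwise$p)
  }
  structure(list(table = tab, chi2 = chi2, pairwise = pairwise,
                 excluded_units = excluded),
            class = "group_table")
}
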