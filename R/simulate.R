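#' Configuration for the intron-evolution simulator
#'
#' The simulator runs gene families through a eukaryogenesis stem lineage
#' (acquisition at time 0, LECA at time 1): intron gains arrive as a
#' Poisson process with a phase bias, losses pick present introns with an
#' exponential 3'-positional bias (emulating loss by reverse transcription
#' of the intronless mRNA followed by homologous recombination, which
#' erases introns from the 3' end), and duplications split lineages at
#' sampled times. A family may contain several separate acquisitions
#' (independent stem lineages); parallel gains hit a fixed family-level
#' pool of proto-splice hotspot positions, so independent lineages can
#' gain introns at identical positions - the signal the
#' separate-acquisition control measures. After LECA every intron evolves
#' down the species tree as a two-state chain with per-branch gain/loss
#' probabilities, and new post-LECA positions arise per branch.
#'
#' All randomness flows from `seed` through named streams (per family,
#' per stage), so any subset of the simulation is reproducible on its own.
#'
#' @param seed integer seed (mandatory).
#' @param n_families number of gene families.
#' @param n_species number of species (used when `species_tree` is NULL).
#' @param species_tree optional rooted `phylo`; by default a random
#'   20-species tree is drawn from the seed.
#' @param n_acquisitions sampler (or integer) for the number of separate
#'   acquisitions per family.
#' @param stem_duplications sampler (or integer) for the number of
#'   duplications per acquisition.
#' @param acquisition_plan optional integer vector fixing, for every
#'   family, the number of acquisitions (its length) and the number of
#'   duplications in each (its entries); overrides the two samplers.
#' @param dup_time_sampler function(k) returning k duplication times in
#'   \[0, 1\]; default sorted uniform.
#' @param gain_rate_stem,loss_rate_stem Poisson rates per unit stem time.
#' @param phase_weights probabilities of phases 0/1/2 for new introns.
#' @param loss_3prime_bias exponent b of the loss weighting
#'   `exp(b * relative_position)`; 0 removes the bias.
#' @param parallel_gain_rate probability that a stem gain lands in the
#'   family's hotspot pool rather than at a fresh unique position;
#'   independent hits on one hotspot in different lineages are parallel
#'   gains.
#' @param n_hotspots size of the per-family pool of proto-splice hotspot
#'   positions targeted by parallel gains.
#' @param protein_length ancestral protein length (residues).
#' @param post_leca_gain,post_leca_loss per-branch re-gain and loss
#'   probabilities on the species tree.
#' @param post_leca_new_gain expected number of brand-new post-LECA intron
#'   positions per branch per orthogroup.
#' @param missing_prob probability that a species lacks an orthogroup
#'   entirely (its table row becomes `"?"`).
#' @param indel_rate per-residue probability of an orthogroup-level
#'   deletion (creates gap columns; 0 = substitution-only alignments).
#' @param substitution_rate per-residue per-sequence substitution
#'   probability for emitted proteins.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_families = 50L,
                              n_species = 20L,
                              species_tree = NULL,
                              n_acquisitions = function()
                                sample(1:3, 1, prob = c(0.5, 0.3, 0.2)),
                              stem_duplications = function()
                                sample(0:3, 1,
                                       prob = c(0.3, 0.35, 0.2, 0.15)),
                              acquisition_plan = NULL,
                              dup_time_sampler = function(k)
                                sort(stats::runif(k)),
                              gain_rate_stem = 12,
                              loss_rate_stem = 4,
                              phase_weights = c(0.5, 0.3, 0.2),
                              loss_3prime_bias = 2,
                              parallel_gain_rate = 0.15,
                              n_hotspots = 20L,
                              protein_length = 400L,
                              post_leca_gain = 0.005,
                              post_leca_loss = 0.15,
                              post_leca_new_gain = 0.3,
                              missing_prob = 0.05,
                              indel_rate = 0,
                              substitution_rate = 0.02) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(gain_rate_stem >= 0, loss_rate_stem >= 0,
            loss_3prime_bias >= 0, parallel_gain_rate >= 0,
            parallel_gain_rate <= 1, all(phase_weights >= 0),
            post_leca_gain >= 0, post_leca_loss >= 0,
            post_leca_new_gain >= 0, protein_length >= 30)
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              n_species = as.integer(n_species),
              species_tree = species_tree,
              n_acquisitions = n_acquisitions,
              stem_duplications = stem_duplications,
              acquisition_plan = acquisition_plan,
              dup_time_sampler = dup_time_sampler,
              gain_rate_stem = gain_rate_stem,
              loss_rate_stem = loss_rate_stem,
              phase_weights = phase_weights / sum(phase_weights),
              loss_3prime_bias = loss_3prime_bias,
              parallel_gain_rate = parallel_gain_rate,
              n_hotspots = as.integer(n_hotspots),
              protein_length = as.integer(protein_length),
              post_leca_gain = post_leca_gain,
              post_leca_loss = post_leca_loss,
              post_leca_new_gain = post_leca_new_gain,
              missing_prob = missing_prob,
              indel_rate = indel_rate,
              substitution_rate = substitution_rate)
  class(cfg) <- "simulation_config"
  cfg
}

# Named-stream seed splitter: every stage/family draws from its own
# deterministic substream of the master seed.
stream_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

sample_int <- function(x) if (is.function(x)) x() else as.integer(x)

# Draw a fresh (anchor residue, phase) not yet in `used` (character keys
# "residue.phase"). Anchors 2..(L-1) keep coding offsets >= 3.
draw_position <- function(L, phase_weights, used) {
  repeat {
    r <- sample(2:(L - 1L), 1L)
    ph <- sample(0:2, 1L, prob = phase_weights)
    key <- paste(r, ph, sep = ".")
    if (!(key %in% used)) return(key)
  }
}

key_residue <- function(keys) as.integer(sub("\\..*", "", keys))
key_phase <- function(keys) as.integer(sub(".*\\.", "", keys))

# Evolve one stem lineage's intron set over a time interval. Parallel
# gains target a fixed family-level pool of proto-splice hotspots, so the
# probability that two lineages hit the same position is symmetric across
# every lineage pair.
evolve_stem_segment <- function(introns, dt, cfg, used, events, lineage,
                                hotspots) {
  n_gain <- stats::rpois(1, cfg$gain_rate_stem * dt)
  n_loss <- stats::rpois(1, cfg$loss_rate_stem * dt)
  kinds <- c(rep("gain", n_gain), rep("loss", n_loss))
  if (length(kinds) > 0) kinds <- kinds[sample.int(length(kinds))]
  for (kind in kinds) {
    if (kind == "gain") {
      open_hot <- setdiff(hotspots, introns)
      if (length(open_hot) > 0 &&
          stats::runif(1) < cfg$parallel_gain_rate) {
        key <- sample(open_hot, 1L)
        used <- union(used, key)
      } else {
        key <- draw_position(cfg$protein_length, cfg$phase_weights,
                             c(used, hotspots))
        used <- c(used, key)
      }
      introns <- union(introns, key)
      events <- rbind(events, data.frame(type = "gain", position = key,
                                         lineage = lineage))
    } else if (length(introns) > 0) {
      relpos <- key_residue(introns) / cfg$protein_length
      w <- exp(cfg$loss_3prime_bias * relpos)
      key <- sample(introns, 1L, prob = w)
      introns <- setdiff(introns, key)
      events <- rbind(events, data.frame(type = "loss", position = key,
                                         lineage = lineage))
    }
  }
  list(introns = introns, used = used, events = events)
}

#' Simulate one family's eukaryogenesis stem
#'
#' Runs the configured number of separate acquisitions, each an
#' independent stem lineage from acquisition (t = 0) to LECA (t = 1) with
#' Poisson intron gains (phase-biased, uniform over residues), 3'-biased
#' losses and duplications at sampled times. Returns the
#' duplication-annotated gene tree per acquisition, the LECA intron set
#' per orthogroup, and a truth log holding every event and the true
#' pre-duplication intron set of every duplication node.
#'
#' @param config a [simulation_config()].
#' @param family_id integer or string family identifier.
#' @return a list of class `stem_family`: `family_id`, `og_ids`,
#'   `acquisition_of` (named), `gene_trees` (one annotated tree per
#'   acquisition; `NULL` for a single-OG acquisition), `leca_sets` (named
#'   list og -> data.frame(column, phase)), `dup_truth` (data.frame:
#'   acquisition, leaves, time, present keys as comma string),
#'   `events`, `used_positions`, `protein_length`.
#' @export
simulate_stem <- function(config, family_id) {
  set.seed(stream_seed(config$seed, "stem", family_id))
  plan <- config$acquisition_plan
  n_acq <- if (!is.null(plan)) length(plan)
           else sample_int(config$n_acquisitions)
  hotspots <- character(0)
  if (config$parallel_gain_rate > 0) {
    while (length(hotspots) < config$n_hotspots) {
      hotspots <- union(hotspots,
                        draw_position(config$protein_length,
                                      config$phase_weights, hotspots))
    }
  }
  used <- character(0)
  events <- data.frame(type = character(), position = character(),
                       lineage = character())
  og_ids <- character(0)
  acquisition_of <- character(0)
  og_lineage <- character(0)
  leca_sets <- list()
  gene_trees <- list()
  dup_truth <- data.frame(acquisition = character(), leaves = character(),
                          time = numeric(), present = character())
  og_counter <- 0L

  for (a in seq_len(n_acq)) {
    acq_id <- paste0("fam", family_id, "_acq", a)
    k <- if (!is.null(plan)) plan[a]
         else sample_int(config$stem_duplications)
    dup_times <- if (k > 0) config$dup_time_sampler(k) else numeric(0)
    # node bookkeeping for the gene tree of this acquisition
    nodes <- list()  # each: id, parent, time, label
    new_node <- function(parent, time, label) {
      id <- length(nodes) + 1L
      nodes[[id]] <<- list(id = id, parent = parent, time = time,
                           label = label)
      id
    }
    root_id <- new_node(NA_integer_, 0, "acquisition")
    lineages <- list(list(parent = root_id, t0 = 0,
                          introns = character(0),
                          name = paste0(acq_id, "_l1")))
    times <- c(dup_times, 1)
    t_prev <- 0
    for (ti in seq_along(times)) {
      t_now <- times[ti]
      dt <- t_now - t_prev
      if (dt > 0) {
        for (j in seq_along(lineages)) {
          st <- evolve_stem_segment(lineages[[j]]$introns, dt, config,
                                    used, events, lineages[[j]]$name,
                                    hotspots)
          lineages[[j]]$introns <- st$introns
          used <- st$used
          events <- st$events
        }
      }
      if (ti <= length(dup_times)) {
        j <- sample.int(length(lineages), 1L)
        dn <- new_node(lineages[[j]]$parent, t_now, "duplication")
        base <- lineages[[j]]
        lineages[[j]] <- list(parent = dn, t0 = t_now,
                              introns = base$introns,
                              name = paste0(base$name, "a"))
        lineages[[length(lineages) + 1L]] <-
          list(parent = dn, t0 = t_now, introns = base$introns,
               name = paste0(base$name, "b"))
        attr(nodes[[dn]], "present") <- base$introns
      }
      t_prev <- t_now
    }
    # leaves
    leaf_names <- character(length(lineages))
    for (j in seq_along(lineages)) {
      og_counter <- og_counter + 1L
      og <- paste0("fam", family_id, "_og", og_counter)
      leaf_names[j] <- og
      new_node(lineages[[j]]$parent, 1, og)
      og_ids <- c(og_ids, og)
      acquisition_of[og] <- acq_id
      og_lineage[og] <- lineages[[j]]$name
      keys <- lineages[[j]]$introns
      leca_sets[[og]] <- data.frame(column = key_residue(keys),
                                    phase = key_phase(keys))
    }
    # assemble Newick from the node table
    kids <- split(seq_along(nodes), vapply(nodes, function(n)
      ifelse(is.na(n$parent), 0L, n$parent), 0L))
    to_newick <- function(id) {
      ch <- kids[[as.character(id)]]
      nd <- nodes[[id]]
      if (is.null(ch)) return(nd$label)
      inner <- paste(vapply(ch, to_newick, ""), collapse = ",")
      lab <- if (nd$label %in% c("acquisition", "duplication")) nd$label
             else ""
      paste0("(", inner, ")", lab)
    }
    if (length(lineages) > 1) {
      # the acquisition node is unary (one stem lineage until the first
      # duplication); start the written tree at the first branching node
      eff_root <- root_id
      repeat {
        ch <- kids[[as.character(eff_root)]]
        if (is.null(ch) || length(ch) > 1L) break
        eff_root <- ch
      }
      gt <- parse_annotated_tree(paste0(to_newick(eff_root), ";"))
      # record true pre-duplication sets, keyed by descendant leaf set
      desc_leaves <- function(id) {
        ch <- kids[[as.character(id)]]
        if (is.null(ch)) return(nodes[[id]]$label)
        unlist(lapply(ch, desc_leaves))
      }
      for (nd in nodes) {
        if (nd$label == "duplication") {
          dup_truth <- rbind(dup_truth, data.frame(
            acquisition = acq_id,
            leaves = paste(sort(desc_leaves(nd$id)), collapse = ","),
            time = nd$time,
            present = paste(attr(nd, "present"), collapse = ",")))
        }
      }
      gene_trees[[acq_id]] <- gt
    } else {
      gene_trees[acq_id] <- list(NULL)
    }
  }
  structure(list(family_id = family_id, og_ids = og_ids,
                 acquisition_of = acquisition_of,
                 og_lineage = og_lineage, gene_trees = gene_trees,
                 leca_sets = leca_sets, dup_truth = dup_truth,
                 events = events, used_positions = used,
                 protein_length = config$protein_length),
            class = "stem_family")
}

#' Evolve intron positions down the species tree after LECA
#'
#' Each LECA intron starts present at the root and runs a two-state chain
#' along every branch (loss with `post_leca_loss`, re-gain with
#' `post_leca_gain`); brand-new post-LECA positions arise on branches at
#' rate `post_leca_new_gain` per branch. Positions present in no species
#' are dropped (they are unobservable in real intron tables). Species may
#' lack the orthogroup entirely with probability `missing_prob`.
#'
#' @param leca_set data.frame(column, phase) of LECA introns of one
#'   orthogroup.
#' @param species_tree rooted `phylo`.
#' @param config a [simulation_config()].
#' @param used family-wide occupied position keys (new gains avoid them).
#' @param seed stream seed for this orthogroup.
#' @return a list: `positions` (data.frame `column`, `phase`,
#'   `true_leca`), `states` (matrix species x positions over
#'   `"1"/"0"/"?"`), `missing_species`, `used` (updated).
#' @export
simulate_post_leca <- function(leca_set, species_tree, config, used,
                               seed) {
  set.seed(seed)
  tree <- species_tree
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(po$edge)))

  keys <- if (nrow(leca_set) > 0)
    paste(leca_set$column, leca_set$phase, sep = ".") else character(0)
  n_leca <- length(keys)
  state <- matrix(0L, n_nodes, 0)
  if (n_leca > 0) {
    state <- matrix(0L, n_nodes, n_leca)
    state[root, ] <- 1L
  }
  true_leca <- rep(TRUE, n_leca)
  colnames(state) <- keys

  for (e in pre_edges) {
    v <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (ncol(state) > 0) {
      # scalar probabilities, or per-branch vectors indexed by child node
      lp <- config$post_leca_loss
      gp <- config$post_leca_gain
      if (length(lp) > 1) lp <- lp[ch]
      if (length(gp) > 1) gp <- gp[ch]
      s <- state[v, ]
      flip_loss <- s == 1L & stats::runif(length(s)) < lp
      flip_gain <- s == 0L & stats::runif(length(s)) < gp
      s[flip_loss] <- 0L
      s[flip_gain] <- 1L
      state[ch, ] <- s
    }
    n_new <- stats::rpois(1, config$post_leca_new_gain)
    if (n_new > 0) {
      for (i in seq_len(n_new)) {
        key <- draw_position(config$protein_length, config$phase_weights,
                             c(used, colnames(state)))
        used <- c(used, key)
        col <- rep(0L, n_nodes)
        col[ch] <- 1L
        state <- cbind(state, col)
        colnames(state)[ncol(state)] <- key
        true_leca <- c(true_leca, FALSE)
        # the new position keeps evolving below ch via later edges
      }
    }
  }
  missing_species <- tree$tip.label[
    stats::runif(ntip) < config$missing_prob]
  if (ncol(state) > 0) {
    # observable = detected in >=1 species whose ortholog is present
    vis <- setdiff(seq_len(ntip),
                   match(missing_species, tree$tip.label))
    leaf_present <- colSums(state[vis, , drop = FALSE] == 1L) > 0
    state <- state[, leaf_present, drop = FALSE]
    true_leca <- true_leca[leaf_present]
  }
  ord <- order(key_residue(colnames(state)), key_phase(colnames(state)))
  state <- state[, ord, drop = FALSE]
  true_leca <- true_leca[ord]
  states <- matrix(as.character(state[seq_len(ntip), , drop = FALSE]),
                   ntip, ncol(state),
                   dimnames = list(tree$tip.label, colnames(state)))
  states[missing_species, ] <- "?"
  list(positions = data.frame(column = key_residue(colnames(state)),
                              phase = key_phase(colnames(state)),
                              true_leca = true_leca),
       states = states, missing_species = missing_species, used = used)
}

#' Simulate a complete dataset
#'
#' Drives [simulate_stem()] and [simulate_post_leca()] over all families
#' and assembles per-orthogroup intron tables (in ancestral-residue
#' coordinates), gene trees, acquisition metadata and the truth log.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulated_dataset` with `config`,
#'   `species_tree`, `families` (list of `stem_family` results augmented
#'   with `post_leca` per og), `tables` (named list of [intron_table()]),
#'   `acquisitions` (data.frame og_id/family_id/acquisition_id/ambiguous),
#'   `truth` (data.frame per position per og: og_id, family_id, column,
#'   phase, true_leca).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- config$species_tree
  if (is.null(tree)) {
    set.seed(stream_seed(config$seed, "species_tree"))
    tree <- ape::rtree(config$n_species, rooted = TRUE)
    tree$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
    tree$node.label <- rep("speciation", tree$Nnode)
    class(tree) <- c("annotated_tree", "phylo")
  }
  families <- list()
  tables <- list()
  acq_rows <- list()
  truth_rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- simulate_stem(config, f)
    fam$post_leca <- list()
    for (og in fam$og_ids) {
      pl <- simulate_post_leca(fam$leca_sets[[og]], tree, config,
                               fam$used_positions,
                               stream_seed(config$seed, "postleca", og))
      fam$used_positions <- pl$used
      fam$post_leca[[og]] <- pl
      states <- apply(pl$states, 1, paste, collapse = "")
      tables[[og]] <- intron_table(og, pl$positions[, c("column", "phase")],
                                   states)
      if (nrow(pl$positions) > 0) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          og_id = og, family_id = paste0("fam", f),
          column = pl$positions$column, phase = pl$positions$phase,
          true_leca = pl$positions$true_leca)
      }
    }
    acq_rows[[f]] <- data.frame(og_id = fam$og_ids,
                                family_id = paste0("fam", f),
                                acquisition_id =
                                  unname(fam$acquisition_of[fam$og_ids]),
                                ambiguous = FALSE)
    families[[paste0("fam", f)]] <- fam
  }
  structure(list(config = config, species_tree = tree,
                 families = families, tables = tables,
                 acquisitions = do.call(rbind, acq_rows),
                 truth = do.call(rbind, truth_rows)),
            class = "simulated_dataset")
}

# codon table: amino acid -> codons (stop excluded)
codon_choices <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

random_protein <- function(L) {
  aas <- setdiff(names(codon_choices()), "*")
  paste0("M", paste(sample(aas, L - 1L, replace = TRUE), collapse = ""))
}

substitute_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  aas <- setdiff(names(codon_choices()), "*")
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- hit[hit > 1]  # keep the initial M
  for (i in hit) chars[i] <- sample(setdiff(aas, chars[i]), 1L)
  paste(chars, collapse = "")
}

back_translate <- function(protein) {
  cc <- codon_choices()
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- cc[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Emit genome FASTA, GFF3 and protein FASTA for a simulated dataset
#'
#' Back-translates every leaf protein with uniformly sampled synonymous
#' codons, inserts introns (length 60-120 nt, `GT...AG` boundaries) at the
#' exact coding offsets implied by each planted (anchor residue, phase),
#' places each gene on its own contig with random strand, and writes one
#' GFF3 + genome FASTA + protein FASTA per species.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @param seed stream seed; defaults to a substream of the dataset seed.
#' @return invisibly, a data.frame manifest: species, files, gene counts.
#' @export
emit_genomes <- function(dataset, dir, seed = NULL) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (is.null(seed)) seed <- stream_seed(dataset$config$seed, "genomes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cfg <- dataset$config
  species <- dataset$species_tree$tip.label
  proteins <- emitted_proteins(dataset)

  manifest <- list()
  for (sp in species) {
    gff <- c("##gff-version 3")
    contigs <- character(0)
    prots <- character(0)
    for (og in names(proteins)) {
      rec <- proteins[[og]]
      if (!(sp %in% rownames(rec$presence))) next
      seq_id <- paste0(sp, "|", og)
      prot <- rec$protein[[sp]]
      carried <- rec$positions[rec$presence[sp, ] == "1", , drop = FALSE]
      offsets <- sort((carried$anchor_local - 1L) * 3L + carried$phase +
                        ifelse(carried$phase == 0L, 0L, 0L))
      cds_nt <- paste0(back_translate(prot), "TAA")
      gene <- build_gene(cds_nt, offsets)
      contig_id <- paste0(sp, "_", og)
      strand <- sample(c("+", "-"), 1L)
      flank5 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                      collapse = "")
      flank3 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                      collapse = "")
      contig_seq <- paste0(flank5, gene$seq, flank3)
      seg <- gene$cds_segments + 20L  # 0-based half-open on + strand
      clen <- nchar(contig_seq)
      if (strand == "-") {
        contig_seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(contig_seq)))
        seg <- cbind(clen - seg[, 2], clen - seg[, 1])
        seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      }
      contigs[contig_id] <- contig_seq
      prots[seq_id] <- prot
      tid <- paste0(seq_id, "|t1")
      gff <- c(gff, paste(contig_id, "paralintron_sim", "mRNA",
                          seg[1, 1] + 1L, seg[nrow(seg), 2], ".", strand,
                          ".", paste0("ID=", tid), sep = "\t"))
      # GFF3 phase column: bases to skip to reach a codon boundary
      lens <- seg[, 2] - seg[, 1]
      mrna_order <- if (strand == "+") seq_len(nrow(seg))
                    else rev(seq_len(nrow(seg)))
      cum <- cumsum(c(0L, lens[mrna_order]))[seq_len(nrow(seg))]
      ph <- (3L - cum %% 3L) %% 3L
      ph_genomic <- integer(nrow(seg))
      ph_genomic[mrna_order] <- ph
      for (i in seq_len(nrow(seg))) {
        gff <- c(gff, paste(contig_id, "paralintron_sim", "CDS",
                            seg[i, 1] + 1L, seg[i, 2], ".", strand,
                            ph_genomic[i],
                            paste0("ID=", tid, ".cds;Parent=", tid,
                                   ";protein_id=", seq_id), sep = "\t"))
      }
    }
    gff_path <- file.path(dir, paste0(sp, ".gff3"))
    writeLines(gff, gff_path)
    write_fasta(contigs, file.path(dir, paste0(sp, ".fa")), "DNA")
    write_fasta(prots, file.path(dir, paste0(sp, "_proteins.fa")), "AA")
    manifest[[sp]] <- data.frame(species = sp, n_genes = length(contigs))
  }
  invisible(do.call(rbind, manifest))
}

# Compose exons + introns from a CDS and sorted intron coding offsets.
# Returns the gene sequence and 0-based half-open CDS segments on it.
build_gene <- function(cds_nt, offsets) {
  bounds <- c(0L, offsets, nchar(cds_nt))
  pieces <- character(0)
  seg <- matrix(0L, 0, 2)
  pos <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    exon <- substr(cds_nt, bounds[i] + 1L, bounds[i + 1L])
    seg <- rbind(seg, c(pos, pos + nchar(exon)))
    pieces <- c(pieces, exon)
    pos <- pos + nchar(exon)
    if (i < length(bounds) - 1L) {
      ilen <- sample(60:120, 1L)
      intron <- paste0("GT",
                       paste(sample(c("A", "C", "G", "T"), ilen - 4L, TRUE),
                             collapse = ""), "AG")
      pieces <- c(pieces, intron)
      pos <- pos + ilen
    }
  }
  colnames(seg) <- c("start", "end")
  list(seq = paste(pieces, collapse = ""), cds_segments = seg)
}

# Per-OG emitted sequence data shared by emit_genomes and
# emit_alignments: ancestral protein, per-OG deletion set, per-species
# substituted proteins, local anchor coordinates, presence matrix.
emitted_proteins <- function(dataset) {
  cache <- attr(dataset, "emitted_proteins")
  if (!is.null(cache)) return(cache)
  cfg <- dataset$config
  set.seed(stream_seed(cfg$seed, "proteins"))
  L <- cfg$protein_length
  out <- list()
  for (fam in dataset$families) {
    anc <- random_protein(L)
    anchors_used <- key_residue(fam$used_positions)
    for (og in fam$og_ids) {
      pl <- fam$post_leca[[og]]
      deleted <- integer(0)
      if (cfg$indel_rate > 0) {
        eligible <- setdiff(2:(L - 1L), anchors_used)
        deleted <- eligible[stats::runif(length(eligible)) < cfg$indel_rate]
      }
      keep <- setdiff(seq_len(L), deleted)
      og_prot_anc <- paste(strsplit(anc, "")[[1]][keep], collapse = "")
      pos <- pl$positions
      pos$anchor_local <- match(pos$column, keep)
      protein <- list()
      for (sp in rownames(pl$states)) {
        if (sp %in% pl$missing_species) next
        protein[[sp]] <- substitute_protein(og_prot_anc,
                                            cfg$substitution_rate)
      }
      out[[og]] <- list(og_id = og, family_id = fam$family_id,
                        ancestral_columns = keep, positions = pos,
                        presence = pl$states[
                          setdiff(rownames(pl$states), pl$missing_species),
                          , drop = FALSE],
                        protein = protein)
    }
  }
  out
}

#' Emit per-orthogroup and merged family alignments
#'
#' Writes the true alignments (no aligner is invoked): every sequence is
#' laid out over the ancestral residue coordinates of its family, with
#' `-` at orthogroup-level deletions. The merged family alignment keeps
#' all ancestral columns; each per-orthogroup alignment drops its all-gap
#' columns, so orthogroup and merged coordinates genuinely differ when
#' indels are simulated.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory.
#' @return invisibly, the list of written files.
#' @export
emit_alignments <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- emitted_proteins(dataset)
  L <- dataset$config$protein_length
  files <- character(0)
  for (fam in dataset$families) {
    merged_rows <- character(0)
    for (og in fam$og_ids) {
      rec <- proteins[[og]]
      rows <- character(0)
      for (sp in names(rec$protein)) {
        chars <- rep("-", L)
        chars[rec$ancestral_columns] <- strsplit(rec$protein[[sp]], "")[[1]]
        rows[paste0(sp, "|", og)] <- paste(chars, collapse = "")
      }
      merged_rows <- c(merged_rows, rows)
      # per-OG alignment: drop all-gap columns
      mat <- do.call(rbind, strsplit(unname(rows), ""))
      keep_cols <- which(colSums(mat != "-") > 0)
      og_rows <- apply(mat[, keep_cols, drop = FALSE], 1, paste,
                       collapse = "")
      names(og_rows) <- names(rows)
      f <- file.path(dir, paste0(og, ".fa"))
      write_fasta(og_rows, f, "AA")
      files <- c(files, f)
    }
    f <- file.path(dir, paste0("fam", fam$family_id, "_merged.fa"))
    write_fasta(merged_rows, f, "AA")
    files <- c(files, f)
  }
  invisible(files)
}

#' Write a complete simulated dataset to disk
#'
#' Produces the directory layout the pipeline consumes: `genomes/`
#' (GFF3 + genome FASTA + protein FASTA per species), `alignments/`
#' (per-orthogroup and merged family alignments), `trees/` (species tree
#' and per-acquisition gene trees), `metadata.tsv` (og, family,
#' acquisition), `tables/` (truth intron tables) and `truth.tsv`.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit_genomes(dataset, file.path(dir, "genomes"))
  emit_alignments(dataset, file.path(dir, "alignments"))
  tdir <- file.path(dir, "trees")
  dir.create(tdir, showWarnings = FALSE)
  write_annotated_tree(dataset$species_tree,
                       file.path(tdir, "species.nwk"))
  for (fam in dataset$families) {
    for (acq in names(fam$gene_trees)) {
      gt <- fam$gene_trees[[acq]]
      if (!is.null(gt)) {
        write_annotated_tree(gt, file.path(tdir, paste0(acq, ".nwk")))
      }
    }
  }
  utils::write.table(dataset$acquisitions, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tabdir <- file.path(dir, "tables")
  dir.create(tabdir, showWarnings = FALSE)
  for (og in names(dataset$tables)) {
    write_intron_table(dataset$tables[[og]],
                       file.path(tabdir, paste0(og, ".tsv")))
  }
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
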