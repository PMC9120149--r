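#' Read a genome annotation (GFF3) together with its genome sequence
#'
#' Parses CDS features from a GFF3 file, groups them into transcripts via
#' their `Parent` attribute, and attaches the genome sequence. All
#' coordinates are converted once, at parse time, from the 1-based inclusive
#' GFF3 convention to 0-based half-open; every downstream computation uses
#' the latter. The GFF3 `phase` column is ignored (phases are recomputed
#' from coordinates); a validation warning is emitted when the annotated
#' phase of the first CDS segment disagrees with 0.
#'
#' Transcripts whose concatenated CDS length is not a multiple of 3 are
#' kept but flagged `mapping_ok = FALSE`; they contribute missing data
#' (`"?"`) downstream rather than aborting a run. CDS rows with no
#' resolvable `Parent` are skipped with a warning.
#'
#' @param path path to a GFF3 file containing CDS features.
#' @param genome_fasta_path path to the matching genome FASTA. Every contig
#'   named by a CDS row must be present, otherwise an error names the
#'   offending contig.
#' @param species_id identifier for the species; defaults to the GFF3 file
#'   name without extension.
#' @return an object of class `annotated_genome`: a list with elements
#'   `species_id`, `sequences` (a [Biostrings::DNAStringSet]) and
#'   `transcripts` (a named list; see [transcript()]).
#' @seealso [introns_from_transcript()] for intron extraction,
#'   [translate_transcript()] for the CDS-to-protein check.
#' @export
read_gff3 <- function(path, genome_fasta_path, species_id = NULL) {
  stopifnot(file.exists(path), file.exists(genome_fasta_path))
  if (is.null(species_id)) {
    species_id <- sub("\\.gff3?$", "", basename(path))
  }
  sequences <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(sequences) <- sub("\\s.*$", "", names(sequences))

  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(annotated_genome(species_id, sequences, list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 9L
  if (any(bad)) {
    stop("malformed GFF3 row (expected 9 tab-separated columns) at line ",
         which(bad)[1])
  }
  m <- do.call(rbind, fields)
  cds <- m[m[, 3] == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    return(annotated_genome(species_id, sequences, list()))
  }

  attr_field <- function(attrs, key) {
    pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
    hit <- regmatches(attrs, regexec(pat, attrs))
    vapply(hit, function(h) if (length(h) >= 3) h[3] else NA_character_, "")
  }
  parent <- attr_field(cds[, 9], "Parent")
  protein <- attr_field(cds[, 9], "protein_id")

  missing_parent <- is.na(parent) | !nzchar(parent)
  if (any(missing_parent)) {
    warning(sum(missing_parent),
            " CDS row(s) with unresolvable Parent skipped")
    cds <- cds[!missing_parent, , drop = FALSE]
    parent <- parent[!missing_parent]
    protein <- protein[!missing_parent]
  }
  if (nrow(cds) == 0L) {
    return(annotated_genome(species_id, sequences, list()))
  }

  absent <- setdiff(unique(cds[, 1]), names(sequences))
  if (length(absent) > 0L) {
    stop("contig '", absent[1], "' named in GFF3 but absent from FASTA")
  }

  transcripts <- list()
  for (tid in unique(parent)) {
    idx <- which(parent == tid)
    contig <- unique(cds[idx, 1])
    strand <- unique(cds[idx, 7])
    if (length(contig) != 1L || length(strand) != 1L ||
        !strand %in% c("+", "-")) {
      warning("transcript '", tid,
              "' has inconsistent contig/strand; skipped")
      next
    }
    start1 <- as.integer(cds[idx, 4])
    end1 <- as.integer(cds[idx, 5])
    if (any(is.na(start1)) || any(is.na(end1)) || any(start1 > end1)) {
      warning("transcript '", tid, "' has invalid CDS coordinates; skipped")
      next
    }
    ord <- order(start1)
    start1 <- start1[ord]
    end1 <- end1[ord]
    if (any(start1[-1] <= end1[-length(end1)])) {
      warning("transcript '", tid, "' has overlapping CDS segments; skipped")
      next
    }
    clen <- as.integer(max(end1))
    if (clen > Biostrings::width(sequences)[match(contig, names(sequences))]) {
      stop("CDS of transcript '", tid, "' exceeds contig '", contig,
           "' bounds")
    }
    pid <- protein[idx][1]
    if (is.na(pid) || !nzchar(pid)) pid <- tid
    transcripts[[tid]] <- transcript(
      transcript_id = tid, protein_id = pid, contig = contig,
      strand = strand,
      # 1-based inclusive -> 0-based half-open, the only conversion site
      cds_segments = cbind(start = start1 - 1L, end = end1)
    )
  }
  annotated_genome(species_id, sequences, transcripts)
}

#' Construct a transcript record
#'
#' @param transcript_id,protein_id,contig,strand identifiers; strand is
#'   `"+"` or `"-"`.
#' @param cds_segments integer matrix with columns `start`, `end` holding
#'   0-based half-open genomic coordinates, one row per CDS segment, sorted
#'   in genomic order.
#' @return a list of class `transcript`. `mapping_ok` records whether the
#'   total CDS length is a positive multiple of 3 (transcripts failing this
#'   become `"?"` downstream).
#' @export
transcript <- function(transcript_id, protein_id, contig, strand,
                       cds_segments) {
  stopifnot(strand %in% c("+", "-"),
            is.matrix(cds_segments), ncol(cds_segments) == 2L,
            all(cds_segments[, 2] > cds_segments[, 1]))
  len <- sum(cds_segments[, 2] - cds_segments[, 1])
  structure(
    list(transcript_id = transcript_id, protein_id = protein_id,
         contig = contig, strand = strand, cds_segments = cds_segments,
         cds_length = len, mapping_ok = len > 0L && len %% 3L == 0L),
    class = "transcript")
}

annotated_genome <- function(species_id, sequences, transcripts) {
  structure(list(species_id = species_id, sequences = sequences,
                 transcripts = transcripts),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome '", x$species_id, "': ", length(x$sequences),
      " contig(s), ", length(x$transcripts), " transcript(s)\n", sep = "")
  invisible(x)
}

#' Translate the concatenated CDS of a transcript
#'
#' Concatenates the CDS segments in mRNA order (reverse-complemented for
#' minus-strand transcripts) and translates them. A trailing stop codon is
#' trimmed. Used to validate that parsed gene models reproduce the protein
#' FASTA.
#'
#' @param t a [transcript()].
#' @param genome an `annotated_genome` (or a named [Biostrings::DNAStringSet]).
#' @return the protein sequence as a character scalar, or `NA` when the CDS
#'   length is not a multiple of 3.
#' @export
translate_transcript <- function(t, genome) {
  sequences <- if (inherits(genome, "annotated_genome")) genome$sequences
               else genome
  if (!t$mapping_ok) return(NA_character_)
  contig <- sequences[[t$contig]]
  parts <- lapply(seq_len(nrow(t$cds_segments)), function(i) {
    Biostrings::subseq(contig, t$cds_segments[i, 1] + 1L,
                       t$cds_segments[i, 2])
  })
  cds <- do.call(Biostrings::xscat, parts)
  if (t$strand == "-") cds <- Biostrings::reverseComplement(cds)
  aa <- as.character(suppressWarnings(Biostrings::translate(cds)))
  sub("\\*$", "", aa)
}

#' Read a protein multiple alignment for one orthogroup
#'
#' Sequence names are expected to follow the `species|rest` convention used
#' throughout the package; `species_of` can be supplied explicitly when
#' names follow another scheme.
#'
#' @param path aligned FASTA.
#' @param og_id orthogroup identifier; defaults to the file name.
#' @param species_of optional named character vector mapping sequence id to
#'   species id.
#' @return an object of class `og_alignment` with elements `og_id`, `rows`
#'   (named character vector of equal-length gapped sequences) and
#'   `species_of`.
#' @export
read_alignment <- function(path, og_id = NULL, species_of = NULL) {
  if (is.null(og_id)) og_id <- sub("\\.[^.]*$", "", basename(path))
  aa <- Biostrings::readAAStringSet(path)
  rows <- as.character(aa)
  names(rows) <- sub("\\s.*$", "", names(aa))
  og_alignment(og_id, rows, species_of)
}

#' Construct an orthogroup alignment object
#' @param og_id orthogroup identifier.
#' @param rows named character vector of gapped, equal-length sequences.
#' @param species_of named map sequence id -> species id; derived from the
#'   `species|rest` naming convention when `NULL`.
#' @export
og_alignment <- function(og_id, rows, species_of = NULL) {
  stopifnot(length(rows) > 0L, !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows of '", og_id, "' differ in length")
  }
  if (is.null(species_of)) {
    species_of <- sub("\\|.*$", "", names(rows))
    names(species_of) <- names(rows)
  }
  structure(list(og_id = og_id, rows = rows, species_of = species_of),
            class = "og_alignment")
}

#' Write an intron table to TSV
#'
#' The dialect is: a header row `species` followed by one column per intron
#' position named `<alignmentColumn>.<phase>` (columns 1-based); one row
#' per species holding single characters from `1` (present), `0` (absent),
#' `?` (ortholog missing or intron mapping unsuccessful). A table with zero
#' positions is written as a header-only file.
#'
#' @param table an [intron_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intron_table <- function(table, path) {
  stopifnot(inherits(table, "intron_table"))
  npos <- nrow(table$positions)
  bad <- nchar(table$states) != npos
  if (any(bad)) {
    stop("state string length mismatch for species '",
         names(table$states)[bad][1], "'")
  }
  header <- c("species",
              if (npos > 0)
                paste0(table$positions$column, ".", table$positions$phase))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (npos > 0L) {
    for (sp in names(table$states)) {
      chars <- strsplit(table$states[[sp]], "", fixed = TRUE)[[1]]
      writeLines(paste(c(sp, chars), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read an intron table TSV written by [write_intron_table()]
#'
#' @param path input path.
#' @param og_id orthogroup id to attach; defaults to the file name.
#' @return an [intron_table()].
#' @export
read_intron_table <- function(path, og_id = NULL) {
  if (is.null(og_id)) og_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "species") stop("not an intron table: ", path)
  keys <- header[-1]
  positions <- if (length(keys) == 0) {
    data.frame(column = integer(), phase = integer())
  } else {
    parts <- strsplit(keys, ".", fixed = TRUE)
    data.frame(column = as.integer(vapply(parts, `[`, "", 1L)),
               phase = as.integer(vapply(parts, `[`, "", 2L)))
  }
  states <- character(0)
  if (length(lines) > 1L) {
    rows <- strsplit(lines[-1], "\t", fixed = TRUE)
    states <- vapply(rows, function(r) paste(r[-1], collapse = ""), "")
    names(states) <- vapply(rows, `[`, "", 1L)
  }
  intron_table(og_id, positions, states)
}

#' Read a node-annotated Newick tree
#'
#' Internal-node annotations from `{acquisition, duplication, LECA,
#' speciation}` are accepted either as plain internal-node labels
#' (`(A,B)duplication`) or as bracketed comment tags
#' (`(A,B)[duplication]`, `(A,B)[&&NHX:type=duplication]`). Unlabelled
#' internal nodes default to `speciation` with a warning. A multifurcating
#' root (e.g. the unresolved-root species topology) is accepted and flagged
#' via the `multifurcating` attribute; singleton (unary) nodes are
#' collapsed with a warning.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree of class `c("annotated_tree", "phylo")`
#'   with `node.label` filled for every internal node.
#' @export
read_annotated_tree <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  parse_annotated_tree(txt)
}

#' Parse a node-annotated Newick string
#' @param txt a Newick string (see [read_annotated_tree()]).
#' @return as [read_annotated_tree()].
#' @export
parse_annotated_tree <- function(txt) {
  depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0L)) {
    stop("malformed Newick: unbalanced ')' at character ",
         which(depth < 0L)[1])
  }
  if (depth[length(depth)] != 0L) {
    stop("malformed Newick: ", depth[length(depth)],
         " unclosed '(' at character ", nchar(txt))
  }
  clean <- gsub("\\[&&NHX:[^]]*type=([A-Za-z]+)[^]]*\\]", "\\1", txt)
  clean <- gsub("\\[([A-Za-z]+)\\]", "\\1", clean)
  tree <- tryCatch(ape::read.tree(text = clean),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  n_before <- tree$Nnode
  tree <- ape::collapse.singles(tree)
  if (tree$Nnode < n_before) {
    warning("collapsed ", n_before - tree$Nnode, " unary node(s)")
  }
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  known <- c("acquisition", "duplication", "LECA", "speciation")
  unlabeled <- !(lab %in% known)
  if (any(unlabeled)) {
    warning(sum(unlabeled),
            " unlabeled internal node(s) defaulted to 'speciation'")
    lab[unlabeled] <- "speciation"
  }
  tree$node.label <- lab
  root_children <- tree$edge[tree$edge[, 1] == ape::Ntip(tree) + 1L, 2]
  attr(tree, "multifurcating") <- length(root_children) > 2L
  class(tree) <- c("annotated_tree", "phylo")
  tree
}

#' Write a node-annotated tree to Newick
#' @param tree a `phylo` with node labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(tree, path) {
  class(tree) <- "phylo"
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read per-species U12/U2 intron-type predictions
#'
#' @param path TSV with columns `species_id`, `og_id`, `alignment_column`,
#'   `phase`, `predicted_type` (`U2` or `U12`).
#' @return a data.frame with those columns.
#' @export
read_u12_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("species_id", "og_id", "alignment_column", "phase",
            "predicted_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("U12 prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$predicted_type %in% c("U2", "U12"))) {
    stop("predicted_type must be 'U2' or 'U12'")
  }
  df
}

# Writers used by the simulator and pipeline ---------------------------------

write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs)
       else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write an orthogroup alignment to aligned FASTA
#' @param og an `og_alignment`.
#' @param path output path.
#' @export
write_alignment <- function(og, path) {
  write_fasta(og$rows, path, "AA")
}
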