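#' Extract protein-coordinate introns from a transcript
#'
#' Every gap between two consecutive CDS segments (in mRNA order, i.e.
#' reverse genomic order on the minus strand) is an intron. Its
#' `coding_offset` is the number of coding nucleotides 5' of the intron,
#' its phase is `coding_offset %% 3`, and it is anchored to the residue
#' whose codon contains the first coding nucleotide 3' of the intron: a
#' phase-0 intron is anchored to the residue immediately following it,
#' phase-1/2 introns to the residue they interrupt. In all three cases
#' `anchor_residue = coding_offset %/% 3 + 1`.
#'
#' Introns shorter than 4 nt (below the biological minimum for a
#' spliceable intron) are flagged `suspicious` but still reported.
#'
#' @param t a [transcript()] with `mapping_ok = TRUE`.
#' @return a data.frame of class `protein_introns` with one row per intron:
#'   `protein_id`, `coding_offset`, `phase`, `anchor_residue`,
#'   `intron_length`, `suspicious`, ordered 5' to 3' along the mRNA.
#' @export
introns_from_transcript <- function(t) {
  stopifnot(inherits(t, "transcript"))
  if (!t$mapping_ok) {
    stop("transcript '", t$transcript_id,
         "' failed CDS length checks (mapping unsuccessful)")
  }
  seg <- t$cds_segments
  if (t$strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  n <- nrow(seg)
  if (n <= 1L) {
    return(empty_protein_introns(t$protein_id))
  }
  lens <- seg[, 2] - seg[, 1]
  offsets <- cumsum(lens)[-n]
  if (t$strand == "+") {
    intron_len <- seg[-1L, 1] - seg[-n, 2]
  } else {
    intron_len <- seg[-n, 1] - seg[-1L, 2]
  }
  out <- data.frame(
    protein_id = t$protein_id,
    coding_offset = as.integer(offsets),
    phase = as.integer(offsets %% 3L),
    anchor_residue = as.integer(offsets %/% 3L + 1L),
    intron_length = as.integer(intron_len),
    suspicious = intron_len < 4L,
    stringsAsFactors = FALSE)
  class(out) <- c("protein_introns", "data.frame")
  out
}

empty_protein_introns <- function(protein_id) {
  out <- data.frame(protein_id = character(), coding_offset = integer(),
                    phase = integer(), anchor_residue = integer(),
                    intron_length = integer(), suspicious = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_introns", "data.frame")
  out
}

#' Project a protein intron onto an alignment row
#'
#' @param anchor_residue 1-based index of the anchor residue in the
#'   ungapped protein.
#' @param row the gapped alignment row for that protein.
#' @return the 1-based alignment column of the anchor residue, or `NA`
#'   when the anchor lies beyond the sequence (mapping unsuccessful; the
#'   species contributes `"?"` downstream).
#' @export
project_to_alignment <- function(anchor_residue, row) {
  stopifnot(anchor_residue >= 1L)
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (anchor_residue > length(nongap)) return(NA_integer_)
  nongap[anchor_residue]
}

#' Construct an intron table
#'
#' @param og_id orthogroup identifier.
#' @param positions data.frame with integer columns `column` (1-based
#'   alignment column) and `phase` (0/1/2), unique rows, sorted by
#'   (column, phase).
#' @param states named character vector, one string over `{1,0,?}` per
#'   species, each of length `nrow(positions)`.
#' @return a list of class `intron_table`.
#' @export
intron_table <- function(og_id, positions, states) {
  stopifnot(all(c("column", "phase") %in% names(positions)))
  if (anyDuplicated(positions[, c("column", "phase")])) {
    stop("duplicate (column, phase) positions in intron table")
  }
  if (length(states) > 0 && any(nchar(states) != nrow(positions))) {
    stop("state string length does not match number of positions")
  }
  if (length(states) > 0 &&
      !all(strsplit(paste(states, collapse = ""), "")[[1]]
           %in% c("1", "0", "?"))) {
    stop("states must be strings over {1, 0, ?}")
  }
  structure(list(og_id = og_id,
                 positions = as.data.frame(positions)[, c("column", "phase")],
                 states = states),
            class = "intron_table")
}

#' @export
print.intron_table <- function(x, ...) {
  cat("intron_table '", x$og_id, "': ", nrow(x$positions), " position(s), ",
      length(x$states), " species\n", sep = "")
  invisible(x)
}

#' Build a species-by-position intron table for one orthogroup
#'
#' Positions are the union over all sequences of observed (alignment
#' column, phase) pairs, sorted by column then phase. A species is scored
#' `"1"` at a position when at least one of its sequences carries an intron
#' there, `"0"` when it has at least one mappable sequence but none with an
#' intron at the position, and `"?"` at every position when it has no
#' sequence in the orthogroup or all its sequences are unmappable.
#'
#' @param og an `og_alignment`.
#' @param introns named list mapping sequence id to a data.frame with
#'   columns `column`, `phase` (projected intron positions for that
#'   sequence), or `NULL` for a sequence whose intron mapping failed.
#'   Sequences of `og` absent from `names(introns)` are treated as
#'   unmappable.
#' @param expected_species character vector of species ids to include as
#'   rows (species absent from the orthogroup get all-`"?"` rows).
#' @return an [intron_table()].
#' @export
build_intron_table <- function(og, introns, expected_species) {
  stopifnot(inherits(og, "og_alignment"))
  seq_ids <- names(og$rows)
  pos_list <- Filter(function(x) !is.null(x) && nrow(x) > 0, introns)
  if (length(pos_list) > 0) {
    allpos <- unique(do.call(rbind, lapply(pos_list, function(x)
      x[, c("column", "phase")])))
    aln_len <- nchar(og$rows[[1]])
    if (any(allpos$column < 1 | allpos$column > aln_len)) {
      stop("intron position outside alignment of '", og$og_id, "'")
    }
    allpos <- allpos[order(allpos$column, allpos$phase), , drop = FALSE]
    rownames(allpos) <- NULL
  } else {
    allpos <- data.frame(column = integer(), phase = integer())
  }
  npos <- nrow(allpos)
  key <- function(df) paste(df$column, df$phase, sep = ".")
  pos_keys <- key(allpos)

  states <- vapply(expected_species, function(sp) {
    sp_seqs <- seq_ids[og$species_of[seq_ids] == sp]
    mappable <- sp_seqs[vapply(sp_seqs, function(s)
      !is.null(introns[[s]]), TRUE)]
    if (length(mappable) == 0L) return(strrep("?", npos))
    if (npos == 0L) return("")
    carried <- unique(unlist(lapply(mappable, function(s)
      key(introns[[s]]))))
    paste(ifelse(pos_keys %in% carried, "1", "0"), collapse = "")
  }, "")
  names(states) <- expected_species
  intron_table(og$og_id, allpos, states)
}

#' Transfer an intron position from an orthogroup to a merged alignment
#'
#' The intron keeps its anchor residue; only the gap structure differs
#' between the two rows, so the merged column is the column of the same
#' ungapped residue in the merged row. Phases are untouched.
#'
#' @param column 1-based column of the intron in the orthogroup row.
#' @param og_row gapped orthogroup-alignment row for the sequence.
#' @param merged_row gapped merged-alignment row for the same sequence.
#' @param sequence_id used in error messages.
#' @return the 1-based merged-alignment column.
#' @export
transfer_to_merged <- function(column, og_row, merged_row,
                               sequence_id = "<unnamed>") {
  og_chars <- strsplit(og_row, "", fixed = TRUE)[[1]]
  mg_chars <- strsplit(merged_row, "", fixed = TRUE)[[1]]
  og_res <- og_chars[og_chars != "-"]
  mg_res <- mg_chars[mg_chars != "-"]
  if (length(og_res) != length(mg_res) || !all(og_res == mg_res)) {
    stop("ungapped sequences differ between orthogroup and merged ",
         "alignment for '", sequence_id, "'")
  }
  if (column < 1 || column > length(og_chars) || og_chars[column] == "-") {
    stop("column ", column, " is not a residue of '", sequence_id,
         "' in the orthogroup alignment")
  }
  rank <- sum(og_chars[seq_len(column)] != "-")
  which(mg_chars != "-")[rank]
}

#' Mask high-gap alignment columns
#'
#' Columns whose gap fraction is at least `threshold` (default 0.9, i.e.
#' 90\% or more gaps) are masked; only `'-'` counts as a gap ('X' and
#' ambiguity codes are residues).
#'
#' @param og an `og_alignment`.
#' @param threshold gap-fraction threshold; a column with gap fraction
#'   `>= threshold` is masked.
#' @return a list of class `masked_alignment` with `og_id`, `kept_columns`
#'   (ascending original column indices) and `n_columns`.
#' @export
mask_alignment <- function(og, threshold = 0.9) {
  stopifnot(inherits(og, "og_alignment"), threshold > 0, threshold <= 1)
  mat <- do.call(rbind, strsplit(unname(og$rows), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  structure(list(og_id = og$og_id,
                 kept_columns = which(gap_frac < threshold),
                 n_columns = ncol(mat)),
            class = "masked_alignment")
}

#' Relative position of an intron within a gap-masked alignment
#'
#' The relative position is the rank of the intron's column among the kept
#' (low-gap) columns divided by the number of kept columns, a value in
#' (0, 1] increasing towards the 3' end. An intron falling in a masked
#' column takes the rank of the nearest kept column 5' of it; an intron 5'
#' of every kept column gets 0.
#'
#' @param column 1-based alignment column of the intron.
#' @param mask a [mask_alignment()] result.
#' @return a numeric scalar in \[0, 1\].
#' @export
relative_position <- function(column, mask) {
  stopifnot(inherits(mask, "masked_alignment"))
  kept <- mask$kept_columns
  if (length(kept) == 0L) stop("empty mask: no kept columns")
  if (column < 1 || column > mask$n_columns) {
    stop("column ", column, " outside alignment (", mask$n_columns,
         " columns)")
  }
  rank <- findInterval(column, kept)
  rank / length(kept)
}
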