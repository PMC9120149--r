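mk_transcript <- function(strand, seg1based) {
  transcript("t", "p", "ctg", strand,
             cbind(start = seg1based[, 1] - 1L, end = seg1based[, 2]))
}

test_that("coding offsets, phases and anchors follow the codon walk", {
  # '+' strand, CDS (1,9),(16,24): offset 9 -> phase 0, anchor residue 4
  pi1 <- introns_from_transcript(mk_transcript("+", rbind(c(1, 9),
                                                          c(16, 24))))
  expect_equal(pi1$coding_offset, 9L)
  expect_equal(pi1$phase, 0L)
  expect_equal(pi1$anchor_residue, 4L)

  # first CDS segment of 7 nt: offset 7 -> phase 1, anchor residue 3
  # (a third segment keeps the total CDS length a multiple of 3)
  pi2 <- introns_from_transcript(mk_transcript("+", rbind(c(1, 7),
                                                          c(16, 24),
                                                          c(30, 37))))
  expect_equal(pi2$coding_offset[1], 7L)
  expect_equal(pi2$phase[1], 1L)
  expect_equal(pi2$anchor_residue[1], 3L)

  # '-' strand: mRNA order is reverse genomic order
  pi3 <- introns_from_transcript(mk_transcript("-", rbind(c(101, 109),
                                                          c(120, 128))))
  expect_equal(pi3$coding_offset, 9L)
  expect_equal(pi3$phase, 0L)
  expect_equal(pi3$anchor_residue, 4L)

  # short intron flagged suspicious but reported
  pi4 <- introns_from_transcript(mk_transcript("+", rbind(c(1, 9),
                                                          c(12, 20))))
  expect_true(pi4$suspicious)
  expect_equal(nrow(pi4), 1L)

  # failed CDS-length transcripts refuse intron extraction
  bad <- transcript("t", "p", "ctg", "+", cbind(start = 0L, end = 8L))
  expect_false(bad$mapping_ok)
  expect_error(introns_from_transcript(bad), "mapping unsuccessful")
})

test_that("phase equals coding offset mod 3 over random synthetic
           transcripts, and reverse-complementing preserves introns", {
  set.seed(99)
  for (rep in 1:25) {
    n_seg <- sample(2:6, 1)
    lens <- sample(3:60, n_seg, TRUE)
    total <- sum(lens)
    lens[n_seg] <- lens[n_seg] + (3 - total %% 3) %% 3
    gaps <- sample(10:80, n_seg - 1, TRUE)
    starts <- cumsum(c(1, lens[-n_seg] + gaps))
    seg <- cbind(starts, starts + lens - 1)
    plus <- introns_from_transcript(mk_transcript("+", seg))
    expect_equal(plus$phase, plus$coding_offset %% 3L)
    # mirror the coordinates: gene on the other strand of a G-length axis
    G <- max(seg) + 5L
    seg_rc <- cbind(G - seg[, 2] + 1L, G - seg[, 1] + 1L)
    seg_rc <- seg_rc[rev(seq_len(n_seg)), , drop = FALSE]
    minus <- introns_from_transcript(mk_transcript("-", seg_rc))
    expect_equal(minus$coding_offset, plus$coding_offset)
    expect_equal(minus$phase, plus$phase)
    expect_equal(minus$intron_length, plus$intron_length)
  }
})

test_that("anchors project onto alignment columns by non-gap counting", {
  expect_equal(project_to_alignment(3, "A-CD-EF"), 4L)
  expect_equal(project_to_alignment(1, "---MKLV"), 4L)
  expect_true(is.na(project_to_alignment(10, "MKLVA")))
})

test_that("intron tables implement the at-least-one-sequence and
           missing-ortholog rules", {
  og <- og_alignment("og1",
                     c("spA|og1|s1" = "MKLVAE", "spA|og1|s2" = "MKLVAE",
                       "spC|og1|s1" = "MKLVAE"))
  introns <- list("spA|og1|s1" = data.frame(column = 3L, phase = 0L),
                  "spA|og1|s2" = data.frame(column = integer(),
                                            phase = integer()),
                  "spC|og1|s1" = data.frame(column = 5L, phase = 1L))
  tb <- build_intron_table(og, introns, c("spA", "spB", "spC"))
  expect_equal(tb$positions,
               data.frame(column = c(3L, 5L), phase = c(0L, 1L)))
  expect_equal(tb$states[["spA"]], "10")  # >=1 sequence carries (3,0)
  expect_equal(tb$states[["spB"]], "??")  # ortholog missing
  expect_equal(tb$states[["spC"]], "01")

  # unmappable sequence -> "?" even though the species is in the OG
  introns2 <- list("spA|og1|s1" = NULL, "spA|og1|s2" = NULL,
                   "spC|og1|s1" = data.frame(column = 5L, phase = 1L))
  tb2 <- build_intron_table(og, introns2, c("spA", "spC"))
  expect_equal(tb2$states[["spA"]], "?")
  expect_equal(tb2$states[["spC"]], "1")
})

test_that("transfer to merged coordinates follows the ungapped residue", {
  expect_equal(transfer_to_merged(4, "A-CD-EF", "AC--D-EF"), 5L)
  expect_equal(transfer_to_merged(4, "A-CD-EF", "A-CD-EF"), 4L)
  expect_error(transfer_to_merged(1, "AC", "AG"), "differ")
  # invariant under gap-only edits of both rows
  set.seed(5)
  for (rep in 1:20) {
    res <- paste(sample(LETTERS[1:20], 12, TRUE), collapse = "")
    gap_pad <- function(s) {
      chars <- strsplit(s, "")[[1]]
      out <- character(0)
      for (ch in chars) {
        out <- c(out, sample(c("", "-", "--"), 1), ch)
      }
      paste(out, collapse = "")
    }
    row1 <- gap_pad(res)
    row2 <- gap_pad(res)
    anchor <- sample(1:12, 1)
    col1 <- project_to_alignment(anchor, row1)
    mcol <- transfer_to_merged(col1, row1, row2)
    expect_equal(mcol, project_to_alignment(anchor, row2))
  }
})

test_that("gap masking and relative positions follow the 90% rule", {
  # 10 rows; make 20 of 100 columns carry >= 90% gaps
  set.seed(8)
  masked_cols <- sort(sample(1:100, 20))
  rows <- vapply(1:10, function(i) {
    chars <- sample(LETTERS[1:20], 100, TRUE)
    gap_here <- if (i <= 9) masked_cols else integer(0)
    chars[gap_here] <- "-"
    # exactly 9/10 gaps = 0.9 -> masked (boundary inclusive)
    paste(chars, collapse = "")
  }, "")
  names(rows) <- paste0("sp", 1:10, "|og")
  og <- og_alignment("og", rows)
  mask <- mask_alignment(og, 0.9)
  expect_equal(mask$kept_columns, setdiff(1:100, masked_cols))
  expect_length(mask$kept_columns, 80L)

  kept <- mask$kept_columns
  expect_equal(relative_position(kept[25], mask), 25 / 80)
  expect_equal(relative_position(kept[1], mask), 1 / 80)
  # intron in a masked column inherits the nearest kept column 5' of it
  mc <- masked_cols[masked_cols > kept[1]][1]
  expect_equal(relative_position(mc, mask),
               findInterval(mc, kept) / 80)
  expect_error(relative_position(5, structure(
    list(og_id = "og", kept_columns = integer(), n_columns = 10),
    class = "masked_alignment")), "empty mask")
})

test_that("'X' and ambiguity codes count as residues, not gaps", {
  og <- og_alignment("og", c("a|og" = "X-", "b|og" = "X-"))
  mask <- mask_alignment(og, 0.9)
  expect_equal(mask$kept_columns, 1L)
})

test_that("simulator-planted introns are recovered exactly through the
           genome -> mapping round-trip", {
  cfg <- simulation_config(seed = 23, n_families = 3, n_species = 5,
                           protein_length = 100)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  gdir <- file.path(dir, "genomes"); adir <- file.path(dir, "alignments")
  emit_genomes(ds, gdir)
  emit_alignments(ds, adir)
  tables <- map_stage(gdir, adir, species = ds$species_tree$tip.label)
  n_checked <- 0L
  for (og in names(ds$tables)) {
    truth <- ds$tables[[og]]
    got <- tables[[og]]
    expect_equal(got$positions, truth$positions)
    for (sp in names(truth$states)) {
      expect_equal(got$states[[sp]], truth$states[[sp]])
      n_checked <- n_checked + sum(strsplit(truth$states[[sp]],
                                            "")[[1]] == "1")
    }
  }
  expect_gt(n_checked, 100)
})
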