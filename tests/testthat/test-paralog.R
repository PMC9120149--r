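acq2 <- data.frame(og_id = c("OG1", "OG2"), family_id = "famA",
                   acquisition_id = "acq1", ambiguous = FALSE)

test_that("paralogous LECA introns at one merged position are shared;
           phase mismatches are not", {
  pos <- data.frame(og_id = c("OG1", "OG2"), column = 40L, phase = 0L)
  cl <- classify_shared(pos, acq2)
  expect_equal(cl$category, c("shared", "shared"))

  pos2 <- data.frame(og_id = c("OG1", "OG2"), column = 40L,
                     phase = c(0L, 1L))
  cl2 <- classify_shared(pos2, acq2)
  expect_equal(cl2$category, c("unique", "unique"))
})

test_that("separate acquisitions never make an intron shared and drive
           the control categories", {
  acqs <- data.frame(og_id = c("OG1", "OG2", "OG3", "OG4"),
                     family_id = "famA",
                     acquisition_id = c("acq1", "acq1", "acq2", "acq3"),
                     ambiguous = FALSE)
  # OG1-OG2 paralogous share (40,0); OG3 (separate) also has (40,0)
  pos <- data.frame(og_id = c("OG1", "OG2", "OG3"), column = 40L,
                    phase = 0L)
  cl <- classify_shared(pos, acqs)
  expect_equal(cl$category[cl$og_id %in% c("OG1", "OG2")],
               c("shared", "shared"))
  # OG3's intron only matches paralog-set OGs: parallel-gain evidence
  expect_equal(cl$category[cl$og_id == "OG3"], "excluded_parallel")

  # two single-OG acquisitions sharing a position: the control signal
  pos2 <- data.frame(og_id = c("OG3", "OG4", "OG3"),
                     column = c(10L, 10L, 55L), phase = 0L)
  cl2 <- classify_shared(pos2, acqs)
  expect_equal(cl2$category, c("control_shared", "control_shared",
                               "control_unique"))

  # paralog intron matched only across the divide is excluded from both
  pos3 <- data.frame(og_id = c("OG1", "OG3"), column = 7L, phase = 2L)
  cl3 <- classify_shared(pos3, acqs)
  expect_equal(cl3$category, c("excluded_parallel", "excluded_parallel"))
})

test_that("ambiguous acquisitions and partnerless OGs are excluded", {
  acqs <- data.frame(og_id = c("OG1", "OG2", "OG3"),
                     family_id = c("famA", "famA", "famB"),
                     acquisition_id = c("acq1", "acq2", "acq3"),
                     ambiguous = c(FALSE, TRUE, FALSE))
  pos <- data.frame(og_id = c("OG1", "OG2", "OG3"),
                    column = c(40L, 40L, 9L), phase = 0L,
                    family_id = c("famA", "famA", "famB"))
  cl <- classify_shared(pos, acqs)
  expect_equal(cl$category[cl$og_id == "OG2"], "excluded_ambiguous")
  # OG1's only family mate is ambiguous -> no eligible partner
  expect_equal(cl$category[cl$og_id == "OG1"], "excluded_no_partner")
  # OG3 is alone in its family
  expect_equal(cl$category[cl$og_id == "OG3"], "excluded_no_partner")
})

test_that("the exclusion rule never lowers the shared fraction relative to
           counting cross-acquisition matches as unique", {
  set.seed(31)
  for (rep in 1:20) {
    acqs <- data.frame(og_id = paste0("OG", 1:5), family_id = "fam",
                       acquisition_id = c("a1", "a1", "a2", "a3", "a4"),
                       ambiguous = FALSE)
    pos <- data.frame(og_id = sample(acqs$og_id, 40, TRUE),
                      column = sample(1:12, 40, TRUE), phase = 0L)
    pos <- unique(pos)
    cl <- classify_shared(pos, acqs)
    with_rule <- shared_fraction(cl)
    naive <- sum(cl$category == "shared") /
      sum(cl$category %in% c("shared", "unique", "excluded_parallel"))
    if (!is.na(with_rule)) expect_gte(with_rule, naive)
  }
})

test_that("the worked three-OG Dollo example reconstructs one gain and one
           loss with presence at both duplication nodes", {
  gt <- parse_annotated_tree("((OG_A,OG_B)duplication,OG_C)duplication;")
  sets <- list(OG_A = data.frame(column = 40L, phase = 0L),
               OG_C = data.frame(column = 40L, phase = 0L))
  st <- dollo_preduplication(gt, sets)
  d1 <- 4L; d2 <- 5L  # root and inner duplication in ape numbering
  expect_equal(st$presence[[d1]], "40.0")
  expect_equal(st$presence[[d2]], "40.0")
  expect_equal(st$gains[[d1]], "40.0")  # gain on the branch into D1
  expect_equal(st$losses[[match("OG_B", gt$tip.label)]], "40.0")
  ev <- count_preduplication_events(st)
  expect_equal(unname(ev), c(1, 0, 0, 1))

  # intron in OG_A only: terminal gain, no duplication flagged
  st2 <- dollo_preduplication(gt, list(
    OG_A = data.frame(column = 12L, phase = 1L)))
  expect_equal(st2$gains[[match("OG_A", gt$tip.label)]], "12.1")
  expect_false(any(st2$dup_nodes$has_predup_introns))

  # intron in OG_A and OG_B: present at D2 only; D2's ancestor flag FALSE
  st3 <- dollo_preduplication(gt, list(
    OG_A = data.frame(column = 8L, phase = 0L),
    OG_B = data.frame(column = 8L, phase = 0L)))
  expect_null(st3$presence[[d1]])
  expect_equal(st3$presence[[d2]], "8.0")
  flags <- st3$dup_nodes
  expect_equal(flags$has_predup_introns[flags$node == d2], TRUE)
  expect_equal(flags$has_predup_introns[flags$node == d1], FALSE)
  expect_equal(flags$ancestral_dup_has_introns[flags$node == d1], FALSE)

  expect_error(dollo_preduplication(gt, list(
    OG_X = data.frame(column = 1L, phase = 0L))), "OG_X")
})

test_that("Dollo loss counts equal the exhaustive single-gain minimum on
           random gene trees", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    gt <- ape::rtree(n, rooted = TRUE)
    gt$tip.label <- paste0("OG", seq_len(n))
    gt$node.label <- rep("duplication", gt$Nnode)
    carriers <- sample(seq_len(n), sample(1:n, 1))
    sets <- lapply(gt$tip.label[carriers], function(og)
      data.frame(column = 5L, phase = 0L))
    names(sets) <- gt$tip.label[carriers]
    st <- dollo_preduplication(gt, sets)
    losses <- sum(lengths(st$losses))
    expect_equal(losses, dollo_min_losses(gt, carriers))
    expect_equal(sum(lengths(st$gains)), 1L)
  }
})

test_that("multifurcating gene trees are handled on the topology as-is", {
  gt <- parse_annotated_tree("(OG_A,OG_B,OG_C)duplication;")
  st <- dollo_preduplication(gt, list(
    OG_A = data.frame(column = 3L, phase = 0L),
    OG_C = data.frame(column = 3L, phase = 0L)))
  expect_equal(st$presence[[4L]], "3.0")
  expect_equal(st$losses[[match("OG_B", gt$tip.label)]], "3.0")
})

test_that("U12 annotation requires predictions from at least three
           species", {
  positions <- data.frame(og_id = "og1", column = c(10L, 20L, 30L),
                          phase = 0L)
  preds <- data.frame(
    species_id = c("s1", "s2", "s3", "s1", "s2", "s1"),
    og_id = "og1",
    alignment_column = c(10L, 10L, 10L, 20L, 20L, 30L),
    phase = 0L,
    predicted_type = c("U12", "U12", "U12", "U12", "U12", "U2"))
  expect_equal(annotate_u12(preds, positions), c("U12", "U2", "U2"))
  # no predictions at all -> U2 by default
  expect_equal(annotate_u12(preds[0, ], positions), rep("U2", 3))
  # duplicate predictions from one species count once
  preds2 <- preds[c(1, 1, 1), ]
  expect_equal(annotate_u12(preds2, positions)[1], "U2")
})

test_that("the parallel-gain 2x2 control reproduces exact Fisher values", {
  cl <- data.frame(category = c(rep("shared", 3), rep("unique", 1),
                                rep("control_shared", 1),
                                rep("control_unique", 3)))
  ctl <- parallel_gain_control(cl)
  expect_equal(ctl$fraction_paralog, 0.75)
  expect_equal(ctl$fraction_separate, 0.25)
  expect_equal(ctl$fisher$p, 34 / 70, tolerance = 1e-12)

  expect_message(ctl0 <- parallel_gain_control(
    data.frame(category = c("shared", "unique"))), "unavailable")
  expect_false(ctl0$available)
})

test_that("group fractions: equal groups give chi2 near 0, small groups
           drop out, spanning units are excluded", {
  outcomes <- data.frame(unit = paste0("u", 1:60),
                         outcome = rep(c(TRUE, FALSE), 30))
  metadata <- data.frame(unit = paste0("u", 1:60),
                         group = rep(c("gA", "gB"), each = 30))
  gt <- group_fractions(outcomes, metadata)
  expect_equal(gt$chi2$statistic, 0, tolerance = 1e-12)
  expect_equal(gt$chi2$p, 1, tolerance = 1e-12)
  expect_equal(gt$table$fraction, c(0.5, 0.5))

  # a 5-unit group falls below the reporting threshold
  md2 <- metadata
  md2$group[1:5] <- "tiny"
  gt2 <- group_fractions(outcomes, md2, min_n = 10)
  expect_false("tiny" %in% gt2$table$group)

  # units spanning two main groups are excluded from the main-group test
  mg <- c(translation = "information", transcription = "information",
          energy = "metabolism", lipid = "metabolism")
  md3 <- data.frame(unit = c(rep(paste0("u", 1:40), 1), "u1"),
                    group = c(rep(c("translation", "energy"), 20),
                              "energy"))
  out3 <- data.frame(unit = paste0("u", 1:40),
                     outcome = rep(c(TRUE, FALSE), 20))
  gt3 <- group_fractions(out3, md3, min_n = 5, main_group_of = mg)
  expect_true("u1" %in% gt3$excluded_units)
  expect_false(any(gt3$table$group %in% c("translation", "energy")))
  expect_true(all(gt3$table$group %in% c("information", "metabolism")))
})

test_that("a group with total post-duplication loss is detected against
           the others", {
  set.seed(12)
  # families in group "transport" lose every intron after duplication:
  # their duplications never retain a traceable pre-duplication intron
  units <- paste0("dup", 1:80)
  group <- rep(c("transport", "other"), each = 40)
  outcome <- c(rep(FALSE, 40), stats::runif(40) < 0.5)
  gt <- group_fractions(data.frame(unit = units, outcome = outcome),
                        data.frame(unit = units, group = group))
  frac <- gt$table$fraction[gt$table$group == "transport"]
  expect_equal(frac, 0)
  expect_lt(gt$chi2$p, 0.05)
})
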