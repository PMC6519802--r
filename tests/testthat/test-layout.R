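test_that("the residue axis is an affine, strictly monotone map", {
  p <- layout_params()
  left <- p$margin_left
  right <- p$canvas_width - p$margin_right
  expect_equal(scale_position(1, 393, p), left)
  expect_equal(scale_position(393, 393, p), right)
  expect_equal(scale_position(197, 393, p), (left + right) / 2) # odd length midpoint
  xs <- scale_position(1:393, 393, p)
  expect_true(all(diff(xs) > 0))
  expect_error(scale_position(394, 393, p), regexp = "out of range")
  expect_error(scale_position(0, 393, p), regexp = "out of range")
})

test_that("stem heights are exactly proportional to counts", {
  p <- layout_params()
  h <- stem_heights(tibble::tibble(position = c(175L, 273L),
                                   n_samples = c(4L, 2L)), p)
  expect_equal(h$height[h$position == 175], p$stem_max_height)
  expect_equal(h$height[h$position == 175], 2 * h$height[h$position == 273],
               tolerance = 1e-9)
  single <- stem_heights(tibble::tibble(position = 10L, n_samples = 7L), p)
  expect_equal(single$height, p$stem_max_height)
  eq <- stem_heights(tibble::tibble(position = 1:5, n_samples = rep(3L, 5)), p)
  expect_true(all(eq$height == p$stem_max_height))
})

test_that("a single label sits centered above its anchor with a straight leader", {
  p <- layout_params()
  placed <- place_labels(tibble::tibble(text = "R175H (3)",
                                        anchor_x = 500, anchor_y = 200), p)
  expect_identical(nrow(placed), 1L)
  expect_equal(placed$x + placed$width / 2, 500)
  expect_lt(placed$y + placed$height, 200)
  expect_false(placed$flagged)
  # straight drop: two points, no bend
  expect_length(strsplit(placed$leader, " ")[[1]], 2L)
})

test_that("labels with identical anchors never overlap (oracle-checked)", {
  p <- layout_params()
  placed <- place_labels(tibble::tibble(
    text = c("R175H (3)", "R175L (1)"),
    anchor_x = 500, anchor_y = 200), p)
  expect_identical(count_overlapping_pairs(placed), 0L)
  expect_true(all(!placed$flagged))
})

test_that("20 clustered labels on a narrow axis all place without overlap", {
  p <- layout_params(canvas_width = 420, margin_left = 40, margin_right = 20)
  n <- 20
  labels <- tibble::tibble(
    text = sprintf("R%dH (%d)", 100 + seq_len(n), seq_len(n)),
    anchor_x = 200 + seq_len(n) * 0.9, # near-coincident anchors
    anchor_y = 180)
  placed <- place_labels(labels, p)
  expect_identical(nrow(placed), 20L)
  expect_identical(count_overlapping_pairs(placed), 0L)
  expect_true(all(placed$x >= 0 & placed$x + placed$width <= p$canvas_width))
  expect_true(all(placed$y >= 0))
  # gap contract for non-flagged placements
  expect_true(all(!placed$flagged))
})

test_that("placement is deterministic and order-independent", {
  p <- layout_params()
  labels <- tibble::tibble(
    text = sprintf("G%d (%d)", 1:8, 8:1),
    anchor_x = c(300, 300, 305, 310, 500, 501, 502, 700),
    anchor_y = 200)
  a <- place_labels(labels, p)
  b <- place_labels(labels[sample(8), ], p)
  expect_identical(a, b)
})

test_that("the TP53 worked example yields 3 domain rects, 1 lollipop, 1 label", {
  df <- data.frame(Hugo_Symbol = "TP53", Sample_ID = c("S1", "S2", "S3"),
                   Protein_Change = "p.R175H",
                   Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "TP53")
  lay <- build_layout(prof, tp53_record(), select_highlights(prof, 1))
  expect_identical(nrow(lay$domain_rects), 3L)
  expect_identical(nrow(lay$lollipops), 1L)
  expect_identical(nrow(lay$labels), 1L)
  expect_identical(lay$labels$text, "R175H (3)")
  expect_identical(lay$legend$domains, c("P53_TAD", "P53", "P53_tetramer"))
  # domain rectangles stay inside the axis span
  expect_true(all(lay$domain_rects$x0 >= lay$axis$x_left - 1e-9))
  expect_true(all(lay$domain_rects$x1 <= lay$axis$x_right + 1e-9))
})

test_that("thresholds above the max count leave lollipops but no labels", {
  prof <- aggregate_recurrence(mutation_table(tp53_demo_df()), "TP53")
  lay <- build_layout(prof, tp53_record(), select_highlights(prof, 10))
  expect_gt(nrow(lay$lollipops), 0)
  expect_identical(nrow(lay$labels), 0L)
})

test_that("two co-located highlighted alterations share one lollipop, two labels", {
  df <- data.frame(Hugo_Symbol = "TP53", Sample_ID = c("S1", "S2"),
                   Protein_Change = c("p.R273C", "p.R273H"),
                   Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "TP53")
  lay <- build_layout(prof, tp53_record(), select_highlights(prof, 1))
  expect_identical(nrow(lay$lollipops), 1L)
  expect_identical(nrow(lay$labels), 2L)
  expect_identical(count_overlapping_pairs(lay$labels), 0L)
})

test_that("positions beyond the protein length are excluded with a warning", {
  df <- data.frame(Hugo_Symbol = "TP53", Sample_ID = c("S1", "S2"),
                   Protein_Change = c("p.R175H", "p.Q500H"),
                   Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "TP53")
  expect_warning(lay <- build_layout(prof, tp53_record()), regexp = "Q500H")
  expect_identical(nrow(lay$out_of_range), 1L)
  expect_identical(lay$out_of_range$protein_change, "Q500H")
  expect_identical(nrow(lay$lollipops), 1L)
})

test_that("an empty profile gives a domain-track-only layout with a warning", {
  tb <- mutation_table(tp53_demo_df())
  suppressWarnings(prof <- aggregate_recurrence(tb, "BRAF"))
  prof$gene_symbol <- "TP53"
  expect_warning(lay <- build_layout(prof, tp53_record()), regexp = "empty")
  expect_identical(nrow(lay$domain_rects), 3L)
  expect_identical(nrow(lay$lollipops), 0L)
  expect_identical(nrow(lay$labels), 0L)
})

test_that("overlapping domains are stacked into separate lanes", {
  rec <- protein_record(
    "X1", "G1", length = 300,
    domains = data.frame(name = c("A", "B", "C"),
                         start = c(10L, 50L, 120L), end = c(100L, 110L, 200L)))
  df <- data.frame(Hugo_Symbol = "G1", Sample_ID = "S1",
                   Protein_Change = "p.R20H",
                   Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "G1")
  lay <- build_layout(prof, rec)
  lanes <- stats::setNames(lay$domain_rects$lane, lay$domain_rects$name)
  expect_identical(lanes[["A"]], 1L)
  expect_identical(lanes[["B"]], 2L) # overlaps A
  expect_identical(lanes[["C"]], 1L) # fits back into lane 1
})

test_that("identical inputs serialize to byte-identical layouts", {
  spec <- cohort_spec(n_samples = 25, gene_symbol = "TP53",
                      protein_length = 393,
                      hotspots = data.frame(position = c(175, 273),
                                            fraction = c(0.4, 0.2)),
                      background_rate = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  simulate_mutation_cohort(spec, file = path)
  build_once <- function() {
    tb <- read_mutation_table(path)
    prof <- aggregate_recurrence(tb, "TP53")
    build_layout(prof, tp53_record(), select_highlights(prof, 2))
  }
  expect_identical(serialize_layout(build_once()),
                   serialize_layout(build_once()))
})

test_that("zero label overlap holds across random generated layouts", {
  set.seed(99)
  for (i in 1:15) {
    df <- random_mutation_df(n_rows = sample(10:40, 1), n_samples = 10,
                             n_positions = sample(3:12, 1))
    tb <- mutation_table(df)
    prof <- aggregate_recurrence(tb, "GENEX")
    rec <- protein_record("X1", "GENEX", length = 500)
    lay <- build_layout(prof, rec, select_highlights(prof, 1))
    expect_identical(count_overlapping_pairs(lay$labels), 0L,
                     info = sprintf("iteration %d", i))
  }
})
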