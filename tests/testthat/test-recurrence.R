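test_that("per-alteration and per-position counts follow distinct samples", {
  df <- data.frame(
    Hugo_Symbol = "TP53",
    Sample_ID = c("S1", "S2", "S3", "S4"),
    Protein_Change = c("p.R175H", "p.R175H", "p.R175H", "p.R175L"),
    Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "TP53")
  alt <- tibble::deframe(prof$per_alteration[, c("protein_change", "n_samples")])
  expect_identical(alt, c(R175H = 3L, R175L = 1L))
  expect_identical(prof$per_position$position, 175L)
  expect_identical(prof$per_position$n_samples, 4L)
})

test_that("duplicated rows count once per sample", {
  df <- data.frame(
    Hugo_Symbol = "TP53",
    Sample_ID = c("S1", "S1", "S2", "S3", "S4"),
    Protein_Change = c("p.R175H", "p.R175H", "p.R175H", "p.R175H", "p.R175L"),
    Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "TP53")
  expect_identical(
    prof$per_alteration$n_samples[prof$per_alteration$protein_change == "R175H"],
    3L)
})

test_that("a sample with two alterations at one position counts once for the stem", {
  df <- data.frame(
    Hugo_Symbol = "TP53", Sample_ID = c("S1", "S1"),
    Protein_Change = c("p.R273C", "p.R273H"),
    Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "TP53")
  expect_identical(nrow(prof$per_alteration), 2L)
  expect_identical(prof$per_position$n_samples, 1L)
})

test_that("single-patient cohorts produce a single count of one", {
  df <- data.frame(Hugo_Symbol = "EGFR", Sample_ID = "P1",
                   Protein_Change = "p.L858R",
                   Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "EGFR")
  expect_identical(prof$per_alteration$n_samples, 1L)
  expect_identical(glance(prof)$n_samples_max, 1L)
})

test_that("gene matching is case-insensitive; absent gene warns, empty profile", {
  tb <- mutation_table(tp53_demo_df())
  p1 <- aggregate_recurrence(tb, "tp53")
  expect_identical(nrow(p1$per_alteration), 4L)
  expect_warning(p0 <- aggregate_recurrence(tb, "BRAF"), regexp = "BRAF")
  expect_identical(nrow(p0$per_alteration), 0L)
  expect_identical(nrow(p0$per_position), 0L)
})

test_that("mutation type attribution is majority vote with lexicographic ties", {
  df <- data.frame(
    Hugo_Symbol = "G1",
    Sample_ID = c("S1", "S2", "S3", "S4", "S5"),
    Protein_Change = "p.R10H",
    Mutation_Type = c("TypeB", "TypeB", "TypeA", "TypeZ", "TypeA"))
  prof <- aggregate_recurrence(mutation_table(df), "G1")
  expect_identical(prof$per_alteration$mutation_type, "TypeA") # 2-2 tie -> A
})

test_that("aggregation matches a brute-force recount on random tables", {
  set.seed(101)
  for (i in 1:60) {
    df <- random_mutation_df(n_rows = sample(3:25, 1))
    tb <- mutation_table(df)
    prof <- aggregate_recurrence(tb, "GENEX")
    oracle <- brute_force_recount(tb$records)
    expect_identical(sort(unname(prof$per_alteration$n_samples)),
                     unname(oracle$per_alteration))
    expect_identical(sort(unname(prof$per_position$n_samples)),
                     unname(oracle$per_position))
    # per-position never exceeds the sum of its alterations' counts
    sums <- tapply(prof$per_alteration$n_samples,
                   prof$per_alteration$position, sum)
    pp <- stats::setNames(prof$per_position$n_samples,
                          prof$per_position$position)
    expect_true(all(pp <= sums[names(pp)]))
  }
})

test_that("row order never changes the profile", {
  set.seed(11)
  df <- random_mutation_df(30)
  p1 <- aggregate_recurrence(mutation_table(df), "GENEX")
  p2 <- aggregate_recurrence(mutation_table(df[sample(nrow(df)), ]), "GENEX")
  expect_identical(p1$per_alteration, p2$per_alteration)
  expect_identical(p1$per_position, p2$per_position)
})

test_that("highlight selection is an exact >=-threshold filter", {
  df <- data.frame(
    Hugo_Symbol = "G", Sample_ID = sprintf("S%d", 1:8),
    Protein_Change = c(rep("p.R175H", 3), rep("p.R273C", 5)),
    Mutation_Type = "Missense_Mutation")
  prof <- aggregate_recurrence(mutation_table(df), "G")
  expect_setequal(select_highlights(prof, 1)$members, c("R175H", "R273C"))
  expect_identical(select_highlights(prof, 5)$members, "R273C")
  expect_identical(select_highlights(prof, 6)$members, character(0))
  expect_error(select_highlights(prof, 0), regexp = "threshold")
  expect_error(select_highlights(prof, -3), regexp = "threshold")
})

test_that("cutoff 1 highlights everything; sets shrink monotonically", {
  set.seed(2024)
  for (i in 1:50) {
    df <- random_mutation_df(sample(4:30, 1))
    prof <- aggregate_recurrence(mutation_table(df), "GENEX")
    all_members <- select_highlights(prof, 1)$members
    expect_setequal(all_members, prof$per_alteration$protein_change)
    thresholds <- sort(sample.int(8, 4))
    prev <- all_members
    for (t in thresholds) {
      cur <- select_highlights(prof, t)$members
      expect_true(all(cur %in% prev),
                  info = sprintf("iter %d threshold %d", i, t))
      prev <- cur
    }
  }
})

test_that("the preset menu is 1..5,10,15,20,25,30 and extensible", {
  menu <- preset_thresholds()
  expect_identical(menu, c(1L, 2L, 3L, 4L, 5L, 10L, 15L, 20L, 25L, 30L))
  expect_identical(min(menu), 1L)
  expect_identical(max(menu), 30L)
  expect_true(50L %in% preset_thresholds(extra = 50))
  expect_identical(preset_thresholds(extra = c(5, 30)), menu) # dedup
})
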