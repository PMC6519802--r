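# Shared fixtures and independent oracles used across the suite.

# Brute-force pairwise rectangle-intersection oracle. Boxes are rows of a
# data frame with x, y, width, height; returns the number of pairs whose
# intersection AREA is strictly positive (touching edges do not count).
count_overlapping_pairs <- function(boxes) {
  n <- nrow(boxes)
  if (n < 2) return(0L)
  bad <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- min(boxes$x[i] + boxes$width[i], boxes$x[j] + boxes$width[j]) -
        max(boxes$x[i], boxes$x[j])
      h <- min(boxes$y[i] + boxes$height[i], boxes$y[j] + boxes$height[j]) -
        max(boxes$y[i], boxes$y[j])
      if (w > 0 && h > 0) bad <- bad + 1L
    }
  }
  bad
}

# Brute-force recount of per-alteration and per-position recurrence from a
# raw records data frame (columns sample_id, protein_change, position),
# independent of the dplyr pipeline in aggregate_recurrence().
brute_force_recount <- function(records) {
  alter <- new.env(); posit <- new.env()
  for (i in seq_len(nrow(records))) {
    akey <- records$protein_change[i]
    pkey <- as.character(records$position[i])
    aset <- if (is.null(alter[[akey]])) character() else alter[[akey]]
    pset <- if (is.null(posit[[pkey]])) character() else posit[[pkey]]
    alter[[akey]] <- union(aset, records$sample_id[i])
    posit[[pkey]] <- union(pset, records$sample_id[i])
  }
  list(
    per_alteration = sort(vapply(as.list(alter), length, integer(1))),
    per_position = sort(vapply(as.list(posit), length, integer(1)))
  )
}

# Random small cohort table (single gene) for property tests.
random_mutation_df <- function(n_rows, n_samples = 6, n_positions = 8) {
  positions <- sample.int(500, n_positions)
  data.frame(
    Hugo_Symbol = "GENEX",
    Sample_ID = sprintf("S%d", sample.int(n_samples, n_rows, replace = TRUE)),
    Protein_Change = sprintf(
      "p.%s%d%s",
      sample(c("R", "G", "K", "E"), n_rows, replace = TRUE),
      sample(positions, n_rows, replace = TRUE),
      sample(c("H", "L", "C", "*"), n_rows, replace = TRUE)),
    Mutation_Type = sample(c("Missense_Mutation", "Nonsense_Mutation"),
                           n_rows, replace = TRUE)
  )
}

tp53_fixture_path <- function() {
  system.file("extdata", "TP53_P04637.domains.txt", package = "lollipopr")
}

tp53_record <- function() read_protein_record(tp53_fixture_path())

# Four-column table written to a temp file; returns the path.
write_demo_table <- function(df, delim = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  path
}

tp53_demo_df <- function() {
  data.frame(
    Hugo_Symbol = "TP53",
    Sample_ID = c("S1", "S2", "S3", "S4", "S5", "S6"),
    Protein_Change = c("p.R175H", "p.R175H", "p.R175H", "p.R175L",
                       "p.R273C", "p.R273*"),
    Mutation_Type = c(rep("Missense_Mutation", 5), "Nonsense_Mutation")
  )
}

# Transport stub replaying the bundled synthetic UniProt JSON fixtures.
replay_transport <- function() {
  search_body <- paste(readLines(system.file(
    "extdata", "uniprot_search_TP53.synthetic.json",
    package = "lollipopr")), collapse = "\n")
  entry_body <- paste(readLines(system.file(
    "extdata", "uniprot_entry_TP53.synthetic.json",
    package = "lollipopr")), collapse = "\n")
  function(url) {
    if (grepl("/search", url, fixed = TRUE)) search_body else entry_body
  }
}

# Transport stub that fails like a dead network and records any call.
dead_transport <- function(counter = new.env()) {
  counter$calls <- 0L
  f <- function(url) {
    counter$calls <- counter$calls + 1L
    stop("connection refused")
  }
  attr(f, "counter") <- counter
  f
}
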