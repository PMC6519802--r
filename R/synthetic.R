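# Seeded synthetic cohort generator: test fixture and demo data source.

#' Specify a synthetic mutation cohort
#'
#' Describes a cohort for [simulate_mutation_cohort()]: recurrent hotspot
#' alterations carried by fixed fractions of the cohort, plus a Poisson
#' background of non-recurrent mutations scattered uniformly over the
#' remaining residues. Hotspot counts are exact by construction
#' (`round(fraction * n_samples)` distinct samples carry each hotspot
#' alteration), so downstream aggregation can be checked against the spec
#' without sampling error.
#'
#' @param n_samples Number of samples in the cohort.
#' @param gene_symbol Gene symbol written into every row.
#' @param protein_length Protein length in residues; all generated positions
#'   lie in `[1, protein_length]`.
#' @param hotspots Data frame with columns `position` and `fraction`
#'   (fraction of samples carrying the hotspot, in `[0, 1]`), and optionally
#'   `alteration` (HGVS-short label; generated from the position when
#'   absent) and `mutation_type`. May be `NULL` for a background-only
#'   cohort.
#' @param background_rate Expected number of background mutations per sample
#'   (Poisson); background positions avoid hotspot positions so hotspot
#'   counts stay construction-exact.
#' @param mutation_type_mix Named numeric vector of category proportions for
#'   background mutations (normalized internally).
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   table.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples, gene_symbol = "GENE1",
                        protein_length = 400, hotspots = NULL,
                        background_rate = 0.5,
                        mutation_type_mix = c(Missense_Mutation = 0.6,
                                              Nonsense_Mutation = 0.15,
                                              Frame_Shift_Del = 0.15,
                                              Splice_Site = 0.1),
                        seed = 1L) {
  if (!is.null(hotspots)) {
    hotspots <- tibble::as_tibble(hotspots)
    stopifnot(all(c("position", "fraction") %in% names(hotspots)),
              all(hotspots$fraction >= 0 & hotspots$fraction <= 1),
              all(hotspots$position >= 1 &
                    hotspots$position <= protein_length))
  }
  stopifnot(n_samples >= 1, protein_length >= 1, background_rate >= 0,
            all(mutation_type_mix >= 0), sum(mutation_type_mix) > 0)
  structure(list(n_samples = as.integer(n_samples),
                 gene_symbol = gene_symbol,
                 protein_length = as.integer(protein_length),
                 hotspots = hotspots,
                 background_rate = background_rate,
                 mutation_type_mix = mutation_type_mix,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort mutation table
#'
#' Draws the cohort described by a [cohort_spec()] and returns it in the
#' four-column input format (`Hugo_Symbol`, `Sample_ID`, `Protein_Change`,
#' `Mutation_Type`), optionally writing it to a tab-delimited file readable
#' by [read_mutation_table()]. Generation is fully seeded: the same spec
#' produces the same rows (and bytes, when written) on every run.
#'
#' @param spec A `cohort_spec`.
#' @param file Optional output path for a TSV.
#' @return A tibble of generated rows (invisibly the same rows are written
#'   to `file` when given).
#' @export
simulate_mutation_cohort <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- with_preserved_rng(spec$seed, generate_cohort_rows(spec))
  if (!is.null(file)) {
    readr::write_tsv(rows, file, progress = FALSE)
    return(invisible(rows))
  }
  rows
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

generate_cohort_rows <- function(spec) {
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  hotspot_positions <- integer()
  rows <- list()

  if (!is.null(spec$hotspots) && nrow(spec$hotspots) > 0) {
    hs <- spec$hotspots
    hotspot_positions <- hs$position
    for (i in seq_len(nrow(hs))) {
      n_carriers <- round(hs$fraction[i] * spec$n_samples)
      if (n_carriers == 0) next
      label <- if ("alteration" %in% names(hs) && !is.na(hs$alteration[i])) {
        hs$alteration[i]
      } else {
        random_substitution_label(hs$position[i])
      }
      type <- if ("mutation_type" %in% names(hs) &&
                  !is.na(hs$mutation_type[i])) {
        hs$mutation_type[i]
      } else "Missense_Mutation"
      carriers <- sort(sample(samples, n_carriers))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        Hugo_Symbol = spec$gene_symbol, Sample_ID = carriers,
        Protein_Change = paste0("p.", label), Mutation_Type = type)
    }
  }

  if (spec$background_rate > 0) {
    free_positions <- setdiff(seq_len(spec$protein_length), hotspot_positions)
    mix <- spec$mutation_type_mix / sum(spec$mutation_type_mix)
    if (length(free_positions) > 0) {
      for (s in samples) {
        k <- stats::rpois(1, spec$background_rate)
        if (k == 0) next
        pos <- sample(free_positions, min(k, length(free_positions)))
        for (p in pos) {
          type <- sample(names(mix), 1, prob = mix)
          label <- background_label(p, type)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            Hugo_Symbol = spec$gene_symbol, Sample_ID = s,
            Protein_Change = paste0("p.", label), Mutation_Type = type)
        }
      }
    }
  }

  if (length(rows) == 0) {
    return(tibble::tibble(Hugo_Symbol = character(), Sample_ID = character(),
                          Protein_Change = character(),
                          Mutation_Type = character()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, rank_radix(.data$Sample_ID),
                 rank_radix(.data$Protein_Change))
}

random_substitution_label <- function(position) {
  aa <- sample(AA1, 2)
  paste0(aa[1], position, aa[2])
}

background_label <- function(position, type) {
  ref <- sample(AA1, 1)
  switch(type,
         Nonsense_Mutation = paste0(ref, position, "*"),
         Frame_Shift_Del = paste0(ref, position, "fs"),
         Frame_Shift_Ins = paste0(ref, position, "fs"),
         Splice_Site = paste0(ref, position, "_splice"),
         paste0(ref, position, sample(setdiff(AA1, ref), 1)))
}
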