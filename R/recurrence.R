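# Per-residue and per-alteration sample recurrence for one gene.

#' Aggregate sample recurrence for one gene
#'
#' Counts, for the records of one gene (matched case-insensitively), how many
#' distinct samples carry each distinct alteration and how many distinct
#' samples are mutated at each residue position. A sample contributes at most
#' once per distinct alteration and at most once per position, so duplicated
#' input rows never inflate counts, and a sample carrying two different
#' alterations at one position still counts once toward that position's stem.
#' The mutation type reported for an alteration is the most frequent raw type
#' among its records (ties broken lexicographically).
#'
#' @param table A `mutation_table` (see [read_mutation_table()]).
#' @param gene_symbol Gene to profile; matching is case-insensitive, the
#'   stored spelling is preserved in the output.
#' @return A `recurrence_profile`: list with `gene_symbol`, `per_alteration`
#'   (tibble `protein_change`, `position`, `mutation_type`, `n_samples`) and
#'   `per_position` (tibble `position`, `n_samples`). A gene absent from the
#'   table yields an empty profile with a warning.
#' @examples
#' tb <- mutation_table(data.frame(
#'   Hugo_Symbol = "TP53", Sample_ID = c("S1", "S2", "S3", "S4"),
#'   Protein_Change = c("p.R175H", "p.R175H", "p.R175H", "p.R175L"),
#'   Mutation_Type = "Missense_Mutation"))
#' aggregate_recurrence(tb, "TP53")
#' @export
aggregate_recurrence <- function(table, gene_symbol) {
  stopifnot(inherits(table, "mutation_table"), length(gene_symbol) == 1)
  recs <- dplyr::filter(table$records,
                        toupper(.data$gene_symbol) == toupper(!!gene_symbol))
  stored_symbol <- if (nrow(recs) > 0) recs$gene_symbol[[1]] else gene_symbol
  if (nrow(recs) == 0) {
    warning("gene '", gene_symbol, "' has no records in the mutation table",
            call. = FALSE)
    return(structure(
      list(gene_symbol = stored_symbol,
           per_alteration = tibble::tibble(protein_change = character(),
                                           position = integer(),
                                           mutation_type = character(),
                                           n_samples = integer()),
           per_position = tibble::tibble(position = integer(),
                                         n_samples = integer())),
      class = "recurrence_profile"
    ))
  }

  per_alteration <- recs |>
    dplyr::distinct(.data$sample_id, .data$protein_change, .data$position,
                    .data$mutation_type_raw) |>
    dplyr::group_by(.data$protein_change, .data$position) |>
    dplyr::summarise(
      mutation_type = majority_type(.data$mutation_type_raw),
      n_samples = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$position, .data$protein_change)

  per_position <- recs |>
    dplyr::distinct(.data$sample_id, .data$position) |>
    dplyr::count(.data$position, name = "n_samples") |>
    dplyr::arrange(.data$position)

  structure(
    list(gene_symbol = stored_symbol,
         per_alteration = per_alteration,
         per_position = per_position),
    class = "recurrence_profile"
  )
}

# Most frequent label; ties broken by C-locale lexicographic order.
majority_type <- function(types) {
  tab <- table(types)
  top <- names(tab)[tab == max(tab)]
  sort(top, method = "radix")[[1]]
}

#' @export
print.recurrence_profile <- function(x, ...) {
  cat("<recurrence_profile> ", x$gene_symbol, ": ",
      nrow(x$per_alteration), " alteration(s) over ",
      nrow(x$per_position), " position(s)\n", sep = "")
  invisible(x)
}

#' Tidy a recurrence profile into its per-alteration tibble
#'
#' @param x A `recurrence_profile`.
#' @param ... Unused.
#' @return Tibble with `gene_symbol`, `protein_change`, `position`,
#'   `mutation_type`, `n_samples`.
#' @export
tidy.recurrence_profile <- function(x, ...) {
  dplyr::mutate(x$per_alteration, gene_symbol = x$gene_symbol, .before = 1)
}

#' One-row summary of a recurrence profile
#'
#' @param x A `recurrence_profile`.
#' @param ... Unused.
#' @return One-row tibble with `gene_symbol`, `n_alterations`, `n_positions`,
#'   `n_samples_max` (largest per-alteration count, 0 when empty).
#' @export
glance.recurrence_profile <- function(x, ...) {
  tibble::tibble(
    gene_symbol = x$gene_symbol,
    n_alterations = nrow(x$per_alteration),
    n_positions = nrow(x$per_position),
    n_samples_max = if (nrow(x$per_alteration) > 0)
      max(x$per_alteration$n_samples) else 0L
  )
}

#' Select alterations at or above a recurrence cutoff
#'
#' An alteration is highlighted when its distinct-sample count is greater
#' than or equal to the threshold; with threshold 1 every alteration in the
#' profile is highlighted.
#'
#' @param profile A `recurrence_profile`.
#' @param threshold Positive integer cutoff (any value >= 1, not restricted
#'   to the preset menu of [preset_thresholds()]).
#' @return A `highlight_set`: list with `threshold` and `members` (character
#'   vector of alteration labels with `n_samples >= threshold`).
#' @export
select_highlights <- function(profile, threshold) {
  stopifnot(inherits(profile, "recurrence_profile"))
  threshold <- suppressWarnings(as.integer(threshold))
  if (length(threshold) != 1 || is.na(threshold) || threshold < 1) {
    stop("threshold must be a single integer >= 1", call. = FALSE)
  }
  members <- profile$per_alteration$protein_change[
    profile$per_alteration$n_samples >= threshold]
  structure(list(threshold = threshold, members = members),
            class = "highlight_set")
}

#' @export
print.highlight_set <- function(x, ...) {
  cat("<highlight_set> threshold=", x$threshold, ", ",
      length(x$members), " member(s)\n", sep = "")
  invisible(x)
}

#' The preset highlight-threshold menu
#'
#' The default menu offers cutoffs 1, 2, 3, 4, 5, 10, 15, 20, 25, 30; extra
#' user-chosen cutoffs can be appended and the result is returned sorted and
#' deduplicated. [select_highlights()] itself accepts any positive integer.
#'
#' @param extra Optional integer vector of additional cutoffs.
#' @return Sorted integer vector of menu cutoffs.
#' @export
preset_thresholds <- function(extra = NULL) {
  menu <- c(1L, 2L, 3L, 4L, 5L, 10L, 15L, 20L, 25L, 30L)
  if (!is.null(extra)) {
    extra <- as.integer(extra)
    stopifnot(!anyNA(extra), all(extra >= 1))
    menu <- sort(unique(c(menu, extra)))
  }
  menu
}
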