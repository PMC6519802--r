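# Reading and validation of cohort mutation tables.

REQUIRED_COLUMNS <- c("Hugo_Symbol", "Sample_ID", "Protein_Change", "Mutation_Type")

# The published example input spells the fourth column "Mutaiton_Type"; both
# spellings are accepted and normalized to Mutation_Type.
MUTATION_TYPE_ALIASES <- c("Mutation_Type", "Mutaiton_Type")

#' Read a delimited cohort mutation table
#'
#' Reads a tab- or comma-delimited file with a header row carrying the four
#' required columns `Hugo_Symbol`, `Sample_ID`, `Protein_Change` and
#' `Mutation_Type` (the legacy header spelling `Mutaiton_Type` is accepted
#' and normalized; column order is free and extra columns are ignored). Each
#' data row is parsed with [parse_protein_change()]: rows whose protein
#' change yields a residue position become records, all others are kept in a
#' rejects table with the row index, raw content and a reason, so that
#' records and rejects always partition the input.
#'
#' @param file Path to the delimited file (or a connection).
#' @param delim Field delimiter. Default `NULL` auto-detects tab vs comma
#'   from the header line.
#' @return A `mutation_table` object: a list with `records` (tibble of
#'   `gene_symbol`, `sample_id`, `protein_change_raw`, `mutation_type_raw`,
#'   plus the parsed `protein_change`, `position`, `ref_residue`,
#'   `alt_residue`, `kind` columns) and `rejects` (tibble of `row_index`,
#'   `raw_line`, `reason`).
#' @seealso [mutation_table()] to build the same object from a data frame
#'   already in memory, [validate_mutation_table()] for the summary report.
#' @export
read_mutation_table <- function(file, delim = NULL) {
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty mutation table: no header row found", call. = FALSE)
  }
  if (is.null(delim)) {
    header <- lines[[1]]
    delim <- if (stringr::str_count(header, "\t") >= stringr::str_count(header, ","))
      "\t" else ","
  }
  df <- readr::read_delim(
    I(paste0(lines, collapse = "\n")),
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  mutation_table(df)
}

#' Build a validated mutation table from a data frame
#'
#' @param df Data frame with the four required columns (see
#'   [read_mutation_table()]); names are matched exact-after-trim and
#'   `Mutaiton_Type` is accepted for `Mutation_Type`.
#' @return A `mutation_table` object (see [read_mutation_table()]).
#' @export
mutation_table <- function(df) {
  df <- tibble::as_tibble(df)
  names(df) <- trimws(names(df))
  alias <- names(df) %in% MUTATION_TYPE_ALIASES
  if (any(alias)) names(df)[which(alias)[1]] <- "Mutation_Type"
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[REQUIRED_COLUMNS]

  raw <- tibble::tibble(
    row_index = seq_len(nrow(df)),
    gene_symbol = trimws(as.character(df$Hugo_Symbol)),
    sample_id = trimws(as.character(df$Sample_ID)),
    protein_change_raw = trimws(as.character(df$Protein_Change)),
    mutation_type_raw = trimws(as.character(df$Mutation_Type))
  )
  raw <- dplyr::mutate(raw, dplyr::across(
    c("gene_symbol", "sample_id", "protein_change_raw", "mutation_type_raw"),
    ~ dplyr::if_else(is.na(.x), "", .x)
  ))

  parsed <- parse_protein_change(raw$protein_change_raw)
  empty_field <- raw$gene_symbol == "" | raw$sample_id == "" |
    raw$protein_change_raw == "" | raw$mutation_type_raw == ""
  reason <- dplyr::case_when(
    empty_field ~ "empty required field",
    !parsed$ok ~ "unparseable Protein_Change: no residue position",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)

  records <- dplyr::bind_cols(
    raw[keep, c("gene_symbol", "sample_id", "protein_change_raw", "mutation_type_raw")],
    tibble::tibble(
      protein_change = parsed$label[keep],
      position = parsed$position[keep],
      ref_residue = parsed$ref_residue[keep],
      alt_residue = parsed$alt_residue[keep],
      kind = parsed$kind[keep]
    )
  )
  rejects <- tibble::tibble(
    row_index = raw$row_index[!keep],
    raw_line = purrr::map_chr(which(!keep), function(i) {
      # literal "\t" separators keep the rejects TSV one-field-per-column
      paste(unlist(raw[i, c("gene_symbol", "sample_id",
                            "protein_change_raw", "mutation_type_raw")]),
            collapse = "\\t")
    }),
    reason = reason[!keep]
  )
  structure(
    list(records = records, rejects = rejects, n_rows = nrow(df)),
    class = "mutation_table"
  )
}

#' @export
print.mutation_table <- function(x, ...) {
  cat("<mutation_table> ", nrow(x$records), " record(s), ",
      nrow(x$rejects), " reject(s)\n", sep = "")
  genes <- unique(x$records$gene_symbol)
  if (length(genes) > 0) {
    shown <- paste(utils::head(genes, 8), collapse = ", ")
    cat("genes: ", shown, if (length(genes) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a mutation table into its records tibble
#'
#' @param x A `mutation_table`.
#' @param ... Unused.
#' @return The records tibble (one row per accepted input row).
#' @export
tidy.mutation_table <- function(x, ...) x$records

#' Summarize parsing of a mutation table
#'
#' Counts parsed and rejected rows and emits warnings for duplicated
#' (sample, gene, protein change) triples, which are kept in the table but
#' counted once per sample during recurrence aggregation.
#'
#' @param table A `mutation_table`.
#' @return A `validation_report`: list with `missing_columns`, `n_rows`,
#'   `n_parsed`, `n_rejected` and `warnings`.
#' @export
validate_mutation_table <- function(table) {
  stopifnot(inherits(table, "mutation_table"))
  warnings <- character()
  if (nrow(table$records) > 0) {
    dup <- dplyr::count(table$records, .data$sample_id, .data$gene_symbol,
                        .data$protein_change)
    dup <- dplyr::filter(dup, .data$n > 1)
    if (nrow(dup) > 0) {
      warnings <- paste0(
        "duplicate rows for sample=", dup$sample_id, " gene=", dup$gene_symbol,
        " change=", dup$protein_change, " (", dup$n,
        " rows; counted once in recurrence)")
    }
  }
  structure(
    list(
      missing_columns = character(),
      n_rows = table$n_rows,
      n_parsed = nrow(table$records),
      n_rejected = nrow(table$rejects),
      warnings = warnings
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> rows=", x$n_rows, " parsed=", x$n_parsed,
      " rejected=", x$n_rejected, "\n", sep = "")
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A one-row tibble with `n_rows`, `n_parsed`, `n_rejected`,
#'   `n_warnings`.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_rows = x$n_rows, n_parsed = x$n_parsed,
    n_rejected = x$n_rejected, n_warnings = length(x$warnings)
  )
}

#' Write a mutation table back to delimited text
#'
#' Writes the accepted records in the four-column input format so the file
#' round-trips through [read_mutation_table()].
#'
#' @param table A `mutation_table`.
#' @param file Output path.
#' @param delim Field delimiter (default tab).
#' @return `file`, invisibly.
#' @export
write_mutation_table <- function(table, file, delim = "\t") {
  stopifnot(inherits(table, "mutation_table"))
  out <- tibble::tibble(
    Hugo_Symbol = table$records$gene_symbol,
    Sample_ID = table$records$sample_id,
    Protein_Change = table$records$protein_change_raw,
    Mutation_Type = table$records$mutation_type_raw
  )
  readr::write_delim(out, file, delim = delim, progress = FALSE)
  invisible(file)
}

#' Export rejected rows
#'
#' @param table A `mutation_table`.
#' @param file Output path for a TSV with columns `row_index`, `raw_line`,
#'   `reason`.
#' @return `file`, invisibly.
#' @export
write_rejects <- function(table, file) {
  stopifnot(inherits(table, "mutation_table"))
  readr::write_tsv(table$rejects, file, progress = FALSE)
  invisible(file)
}
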