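# Protein records: length + domain features, with a diff-able text format
# for offline caches and fixtures.

#' Construct a protein record
#'
#' A protein record carries the canonical sequence length of a protein and
#' its annotated domain features, the minimum needed to draw a domain track
#' and scale residue positions. Records come from UniProt
#' ([uniprot_fetch_record()]) or from local text files
#' ([read_protein_record()]) for offline deployments.
#'
#' @param accession UniProt accession (e.g. `"P04637"`).
#' @param gene_symbol Gene symbol the record was resolved from.
#' @param organism_id NCBI taxon identifier (default 9606, human).
#' @param length Protein length in residues (>= 1).
#' @param domains Data frame with columns `name`, `start`, `end`
#'   (1-based, inclusive residue coordinates). May have zero rows.
#' @param retrieved_at Retrieval timestamp string, or `"fixture"` for
#'   locally authored records.
#' @return A `protein_record` object.
#' @export
protein_record <- function(accession, gene_symbol, organism_id = 9606,
                           length, domains = NULL, retrieved_at = "fixture") {
  if (is.null(domains) || nrow(domains) == 0) {
    domains <- tibble::tibble(name = character(),
                              start = integer(), end = integer())
  }
  domains <- tibble::as_tibble(domains)
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  domains <- dplyr::mutate(domains,
                           name = as.character(.data$name),
                           start = as.integer(.data$start),
                           end = as.integer(.data$end))
  length <- as.integer(length)
  if (is.na(length) || length < 1) {
    stop("protein length must be a positive integer", call. = FALSE)
  }
  if (nrow(domains) > 0) {
    bad <- domains$start < 1 | domains$start > domains$end | domains$end > length
    if (any(bad)) {
      stop("invalid domain feature(s) [",
           paste(domains$name[bad], collapse = ", "),
           "]: require 1 <= start <= end <= length (", length, ")",
           call. = FALSE)
    }
    domains <- dplyr::arrange(domains, .data$start, .data$end, .data$name)
  }
  structure(
    list(accession = as.character(accession),
         gene_symbol = as.character(gene_symbol),
         organism_id = as.integer(organism_id),
         length = length,
         domains = domains,
         retrieved_at = as.character(retrieved_at)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$gene_symbol, " (", x$accession, ", taxon ",
      x$organism_id, "), ", x$length, " aa, ", nrow(x$domains),
      " domain(s)\n", sep = "")
  if (nrow(x$domains) > 0) {
    for (i in seq_len(nrow(x$domains))) {
      cat("  ", x$domains$name[i], " [", x$domains$start[i], "-",
          x$domains$end[i], "]\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy a protein record into its domain tibble
#'
#' @param x A `protein_record`.
#' @param ... Unused.
#' @return Tibble with `accession`, `gene_symbol`, `name`, `start`, `end`.
#' @export
tidy.protein_record <- function(x, ...) {
  dplyr::mutate(x$domains, accession = x$accession,
                gene_symbol = x$gene_symbol, .before = 1)
}

#' Write a protein record to the offline cache format
#'
#' The format is a human-readable, diff-able text file: `key: value` header
#' lines (`accession`, `gene`, `taxon`, `length`), then one
#' `domain<TAB>name<TAB>start<TAB>end` line per feature.
#'
#' @param record A `protein_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_record <- function(record, path) {
  stopifnot(inherits(record, "protein_record"))
  lines <- c(
    paste0("accession: ", record$accession),
    paste0("gene: ", record$gene_symbol),
    paste0("taxon: ", record$organism_id),
    paste0("length: ", record$length)
  )
  if (nrow(record$domains) > 0) {
    lines <- c(lines, paste("domain", record$domains$name,
                            record$domains$start, record$domains$end,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein record from the offline cache format
#'
#' Validates the record on load (positive length, domain features inside
#' `[1, length]` with `start <= end`); violations raise an error naming the
#' offending field. `retrieved_at` is always `"fixture"` for loaded records.
#'
#' @param path Path to a file written by [write_protein_record()] (or
#'   hand-authored in the same format).
#' @return A `protein_record`.
#' @export
read_protein_record <- function(path) {
  if (!file.exists(path)) {
    stop("protein record file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) {
      stop("protein record file missing field '", key, "': ", path,
           call. = FALSE)
    }
    trimws(sub(paste0("^", key, ":"), "", hit[[1]]))
  }
  dom_lines <- grep("^domain\t", lines, value = TRUE)
  domains <- if (length(dom_lines) > 0) {
    parts <- stringr::str_split_fixed(dom_lines, "\t", 4)
    tibble::tibble(name = parts[, 2],
                   start = suppressWarnings(as.integer(parts[, 3])),
                   end = suppressWarnings(as.integer(parts[, 4])))
  } else NULL
  if (!is.null(domains) && any(is.na(domains$start) | is.na(domains$end))) {
    stop("protein record file has non-numeric domain coordinates: ", path,
         call. = FALSE)
  }
  protein_record(
    accession = header("accession"),
    gene_symbol = header("gene"),
    organism_id = as.integer(header("taxon")),
    length = as.integer(header("length")),
    domains = domains,
    retrieved_at = "fixture"
  )
}

#' The bundled oncogene / tumor-suppressor gene catalog
#'
#' Returns the gene symbols offered by the gene picker: by default the
#' package's bundled catalog of 409 oncogenes and tumor suppressor genes
#' (one symbol per line), or a user-supplied catalog file in the same
#' one-symbol-per-line format. Symbols are deduplicated case-insensitively
#' (first spelling wins).
#'
#' @param path Optional path to a catalog file; `NULL` uses the bundled one.
#' @return Character vector of unique gene symbols.
#' @export
gene_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_catalog.txt", package = "lollipopr")
  }
  syms <- trimws(readr::read_lines(path))
  syms <- syms[nzchar(syms) & !startsWith(syms, "#")]
  syms[!duplicated(toupper(syms))]
}
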