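# End-to-end pipeline: read -> validate -> resolve domains -> aggregate ->
# highlight -> layout -> render -> export.

#' Pipeline run configuration
#'
#' @param input_path Path to the delimited mutation table.
#' @param gene_symbol Gene to plot (matched case-insensitively).
#' @param threshold Highlight cutoff (positive integer, default 1: highlight
#'   everything).
#' @param organism_id NCBI taxon for UniProt resolution (default 9606).
#' @param offline If `TRUE`, never touch the network; the protein record
#'   must come from `domain_fixture_path` or from `cache_dir`.
#' @param domain_fixture_path Optional path to a local protein record file
#'   (format of [write_protein_record()]).
#' @param cache_dir Optional directory of cached protein records
#'   (`<accession or gene>.domains.txt`); written through on live fetches,
#'   searched on offline runs.
#' @param output_dir Directory for the figure and table files (created if
#'   needed).
#' @param formats Subset of `c("SVG", "PNG", "PDF", "JPEG")`; default SVG.
#' @param export_tables If `TRUE` (default), write the data and domain TSVs.
#' @param params,style Layout and style settings.
#' @return A `run_config` list.
#' @export
run_config <- function(input_path, gene_symbol, threshold = 1L,
                       organism_id = 9606, offline = FALSE,
                       domain_fixture_path = NULL, cache_dir = NULL,
                       output_dir = ".", formats = "SVG",
                       export_tables = TRUE, params = layout_params(),
                       style = style_config()) {
  formats <- toupper(formats)
  bad <- setdiff(formats, SUPPORTED_FORMATS)
  if (length(bad) > 0) {
    stop(config_error(paste0("unsupported format(s): ",
                             paste(bad, collapse = ", "),
                             "; supported: ",
                             paste(SUPPORTED_FORMATS, collapse = ", "))))
  }
  threshold <- suppressWarnings(as.integer(threshold))
  if (is.na(threshold) || threshold < 1) {
    stop(config_error("threshold must be a positive integer"))
  }
  if (offline && is.null(domain_fixture_path) && is.null(cache_dir)) {
    stop(config_error(
      "offline mode requires domain_fixture_path or cache_dir"))
  }
  structure(list(input_path = input_path, gene_symbol = gene_symbol,
                 threshold = threshold, organism_id = organism_id,
                 offline = offline,
                 domain_fixture_path = domain_fixture_path,
                 cache_dir = cache_dir, output_dir = output_dir,
                 formats = formats, export_tables = export_tables,
                 params = params, style = style),
            class = "run_config")
}

config_error <- function(msg) {
  structure(class = c("lollipopr_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

stage_log <- function(stage, ...) {
  message(sprintf("[lollipopr] stage=%s %s", stage,
                  paste0(..., collapse = " ")))
}

resolve_protein_record <- function(config, transport = NULL) {
  if (!is.null(config$domain_fixture_path)) {
    return(read_protein_record(config$domain_fixture_path))
  }
  if (config$offline) {
    # offline: search the cache by gene symbol or accession file name
    hits <- list.files(config$cache_dir, pattern = "\\.domains\\.txt$",
                       full.names = TRUE)
    for (h in sort(hits, method = "radix")) {
      rec <- read_protein_record(h)
      if (toupper(rec$gene_symbol) == toupper(config$gene_symbol)) {
        return(rec)
      }
    }
    stop(lookup_error(paste0("offline mode: no cached protein record for '",
                             config$gene_symbol, "' in ", config$cache_dir)))
  }
  acc <- uniprot_resolve_accession(config$gene_symbol, config$organism_id,
                                   transport = transport)
  uniprot_fetch_record(acc, cache_dir = config$cache_dir,
                       transport = transport)
}

#' Run the full lollipop pipeline
#'
#' Executes read, validate, protein-record resolution (UniProt or local
#' fixture/cache), recurrence aggregation, highlight selection, layout,
#' rendering and export, writing `<gene>_lollipop.<ext>` for every requested
#' format plus `<gene>_data.tsv` and `<gene>_domains.tsv` into the output
#' directory. One structured log line is emitted per stage with its record
#' counts. With `offline = TRUE` the run is fully deterministic: the same
#' config and inputs produce byte-identical SVG and TSV files.
#'
#' @param config A [run_config()].
#' @param transport Optional transport override for UniProt access (testing;
#'   ignored when a fixture file is used).
#' @return A `figure_bundle`: list with `svg_text`, `raster_exports` (named
#'   list of raw vectors for the non-SVG formats), `data_table`,
#'   `domain_table`, `layout`, `report`, and `paths` of the written files.
#' @export
run_lollipop <- function(config, transport = NULL) {
  stopifnot(inherits(config, "run_config"))

  table <- read_mutation_table(config$input_path)
  stage_log("read", "rows=", table$n_rows, " records=", nrow(table$records),
            " rejects=", nrow(table$rejects))
  report <- validate_mutation_table(table)
  stage_log("validate", "parsed=", report$n_parsed,
            " rejected=", report$n_rejected,
            " warnings=", length(report$warnings))

  record <- resolve_protein_record(config, transport = transport)
  stage_log("domains", "accession=", record$accession,
            " length=", record$length, " domains=", nrow(record$domains))

  profile <- aggregate_recurrence(table, config$gene_symbol)
  stage_log("aggregate", "alterations=", nrow(profile$per_alteration),
            " positions=", nrow(profile$per_position))

  highlights <- select_highlights(profile, config$threshold)
  stage_log("highlight", "threshold=", highlights$threshold,
            " members=", length(highlights$members))
  if (nrow(profile$per_alteration) > 0 && length(highlights$members) == 0) {
    warning("no alteration reaches the highlight threshold ",
            config$threshold, "; the figure will carry no labels",
            call. = FALSE)
  }

  layout <- build_layout(profile, record, highlights, config$params)
  stage_log("layout", "lollipops=", nrow(layout$lollipops),
            " labels=", nrow(layout$labels))

  svg_text <- render_svg(layout, config$style)
  stage_log("render", "bytes=", nchar(svg_text, type = "bytes"))

  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  stem <- file.path(config$output_dir, paste0(config$gene_symbol, "_lollipop"))
  paths <- character()
  raster <- list()
  for (fmt in config$formats) {
    bytes <- export_image(svg_text, fmt)
    ext <- tolower(fmt)
    path <- paste0(stem, ".", ifelse(ext == "jpeg", "jpg", ext))
    writeBin(bytes, path)
    paths <- c(paths, path)
    if (fmt != "SVG") raster[[fmt]] <- bytes
  }

  tables <- export_tables(profile, record, highlights)
  if (isTRUE(config$export_tables)) {
    data_path <- file.path(config$output_dir,
                           paste0(config$gene_symbol, "_data.tsv"))
    domain_path <- file.path(config$output_dir,
                             paste0(config$gene_symbol, "_domains.tsv"))
    readr::write_tsv(tables$data_table, data_path, progress = FALSE)
    readr::write_tsv(tables$domain_table, domain_path, progress = FALSE)
    paths <- c(paths, data_path, domain_path)
  }
  stage_log("export", "files=", length(paths))

  structure(list(svg_text = svg_text, raster_exports = raster,
                 data_table = tables$data_table,
                 domain_table = tables$domain_table,
                 layout = layout, report = report, paths = paths),
            class = "figure_bundle")
}

#' @export
print.figure_bundle <- function(x, ...) {
  cat("<figure_bundle> ", length(x$paths), " file(s) written\n", sep = "")
  for (p in x$paths) cat("  ", p, "\n", sep = "")
  invisible(x)
}
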