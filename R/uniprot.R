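# UniProt REST client. All network traffic goes through an injectable
# transport so tests and offline deployments never touch the network.

UNIPROT_SEARCH_URL <- "https://rest.uniprot.org/uniprotkb/search"
UNIPROT_ENTRY_URL <- "https://rest.uniprot.org/uniprotkb"

# transport contract: function(url) -> response body as a single string;
# signals an error on network failure.
default_transport <- function(url) {
  handle <- curl::new_handle(timeout = 30)
  resp <- curl::curl_fetch_memory(url, handle = handle)
  if (resp$status_code >= 400) {
    stop("HTTP ", resp$status_code, " for ", url, call. = FALSE)
  }
  rawToChar(resp$content)
}

transport_error <- function(msg, parent = NULL) {
  structure(
    class = c("lollipopr_transport_error", "error", "condition"),
    list(message = msg, call = NULL, parent = parent)
  )
}

lookup_error <- function(msg) {
  structure(
    class = c("lollipopr_lookup_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

format_error <- function(msg) {
  structure(
    class = c("lollipopr_format_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

fetch_body <- function(url, transport) {
  body <- tryCatch(transport(url),
                   error = function(e) {
                     stop(transport_error(paste0("transport failure for ", url,
                                                 ": ", conditionMessage(e)),
                                          parent = e))
                   })
  body
}

parse_json_body <- function(body, url) {
  force(body) # a transport failure must surface as such, not as a format error
  tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
           error = function(e) {
             stop(format_error(paste0("malformed response body from ", url,
                                      ": ", conditionMessage(e))))
           })
}

#' Resolve a gene symbol to a reviewed UniProt accession
#'
#' Searches UniProtKB for reviewed (Swiss-Prot) entries whose exact gene name
#' matches the symbol in the given organism. When several reviewed entries
#' match, the lexicographically smallest accession is returned so resolution
#' is deterministic.
#'
#' @param gene_symbol Gene symbol (case-insensitive match).
#' @param organism_id NCBI taxon identifier (default 9606, human).
#' @param transport Optional function `function(url) -> body string`
#'   replacing the live HTTP transport (used for offline replay in tests).
#' @return A single accession string.
#' @section Errors: an unknown symbol raises a `lollipopr_lookup_error`; a
#'   network failure raises a `lollipopr_transport_error`; a body that is
#'   not valid JSON raises a `lollipopr_format_error`.
#' @export
uniprot_resolve_accession <- function(gene_symbol, organism_id = 9606,
                                      transport = NULL) {
  transport <- transport %||% default_transport
  query <- sprintf("gene_exact:%s AND organism_id:%d AND reviewed:true",
                   gene_symbol, as.integer(organism_id))
  url <- paste0(UNIPROT_SEARCH_URL, "?query=", utils::URLencode(query, reserved = TRUE),
                "&fields=accession,gene_primary&format=json&size=25")
  data <- parse_json_body(fetch_body(url, transport), url)
  results <- data$results
  if (is.null(results) || length(results) == 0) {
    stop(lookup_error(paste0("no reviewed UniProt entry found for gene '",
                             gene_symbol, "' (taxon ", organism_id, ")")))
  }
  accs <- purrr::map_chr(results, function(r) {
    r$primaryAccession %||% NA_character_
  })
  accs <- sort(accs[!is.na(accs)], method = "radix")
  if (length(accs) == 0) {
    stop(format_error("UniProt search response carried no accessions"))
  }
  accs[[1]]
}

#' Fetch a protein record from UniProt
#'
#' Retrieves the entry for an accession and extracts the canonical sequence
#' length and the features of the configured classes (UniProt `Domain`
#' features by default; `Region` and `Motif` can be added). The record is
#' optionally written through to a local cache directory in the
#' [write_protein_record()] text format so later runs can work offline.
#'
#' @param accession UniProt accession.
#' @param feature_types Character vector of UniProt feature types to keep as
#'   domain-track features (default `"Domain"`).
#' @param cache_dir Optional directory; when given, the fetched record is
#'   saved as `<accession>.domains.txt` inside it.
#' @param transport Optional transport override (see
#'   [uniprot_resolve_accession()]).
#' @return A `protein_record`.
#' @export
uniprot_fetch_record <- function(accession, feature_types = "Domain",
                                 cache_dir = NULL, transport = NULL) {
  transport <- transport %||% default_transport
  url <- paste0(UNIPROT_ENTRY_URL, "/", accession, ".json")
  data <- parse_json_body(fetch_body(url, transport), url)
  if (!is.null(data$messages)) {
    stop(lookup_error(paste0("UniProt entry not found: ", accession)))
  }
  len <- data$sequence$length
  if (is.null(len)) {
    stop(format_error(paste0("UniProt response for ", accession,
                             " lacks sequence length")))
  }
  gene <- tryCatch(data$genes[[1]]$geneName$value, error = function(e) NULL)
  taxon <- data$organism$taxonId %||% NA_integer_
  feats <- data$features %||% list()
  keep <- purrr::keep(feats, function(f) (f$type %||% "") %in% feature_types)
  domains <- if (length(keep) > 0) {
    tibble::tibble(
      name = purrr::map_chr(keep, function(f) f$description %||% f$type),
      start = purrr::map_int(keep, function(f)
        as.integer(f$location$start$value)),
      end = purrr::map_int(keep, function(f)
        as.integer(f$location$end$value))
    )
  } else NULL
  rec <- protein_record(
    accession = data$primaryAccession %||% accession,
    gene_symbol = gene %||% NA_character_,
    organism_id = taxon,
    length = len,
    domains = domains,
    retrieved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    write_protein_record(rec, file.path(cache_dir,
                                        paste0(rec$accession, ".domains.txt")))
  }
  rec
}
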