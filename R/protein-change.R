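# Parsing of protein-change strings (HGVS short form and common MAF variants).

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
         Ter = "*", Sec = "U")

# Replace every three-letter residue code by its one-letter code, leaving the
# rest of the string untouched ("Arg175His" -> "R175H", "Ter" -> "*").
normalize_residue_codes <- function(x) {
  for (code in names(AA3)) {
    x <- gsub(code, AA3[[code]], x, ignore.case = TRUE)
  }
  x
}

#' Parse protein-change strings into structured alterations
#'
#' Accepts HGVS protein short forms with or without the leading `"p."`, with
#' one- or three-letter residue codes, and classifies each string as missense
#' (`R175H`), nonsense (`R273*`), frameshift (`E285fs`, `E285fs*12`),
#' in-frame insertion/deletion/duplication (`K120del`, `S90_E95del`),
#' splice (`X125_splice`), or synonymous (`R175R`, `R175=`). Any other shape
#' containing a residue position is kept with kind `"other"`; strings with no
#' extractable position are flagged as parse failures rather than errors, so
#' the function is total over arbitrary input.
#'
#' @param text Character vector of protein-change strings.
#' @return A tibble with one row per input: `raw`, `label` (normalized
#'   one-letter form without the `p.` prefix), `position` (1-based residue
#'   index), `ref_residue`, `alt_residue`, `kind`, and `ok` (`FALSE` marks a
#'   parse failure; such rows have `NA` fields).
#' @examples
#' parse_protein_change(c("p.R175H", "R273*", "p.Glu285fs", "junk"))
#' @export
parse_protein_change <- function(text) {
  stopifnot(is.character(text) | length(text) == 0)
  out <- purrr::map(text, parse_protein_change_one)
  dplyr::bind_rows(out)
}

parse_protein_change_one <- function(raw) {
  fail <- tibble::tibble(
    raw = if (is.na(raw)) NA_character_ else raw,
    label = NA_character_, position = NA_integer_,
    ref_residue = NA_character_, alt_residue = NA_character_,
    kind = NA_character_, ok = FALSE
  )
  if (is.na(raw)) return(fail)
  x <- trimws(raw)
  if (!nzchar(x)) return(fail)
  # strip leading "p." and surrounding parentheses: p.(R175H) -> R175H
  x <- sub("^[pP]\\.", "", x)
  x <- gsub("[()]", "", x)
  x <- normalize_residue_codes(x)

  done <- function(label, position, ref, alt, kind) {
    position <- suppressWarnings(as.integer(position))
    if (is.na(position) || position < 1) return(fail)
    tibble::tibble(
      raw = raw, label = label, position = position,
      ref_residue = ref, alt_residue = alt, kind = kind, ok = TRUE
    )
  }

  aa <- paste0("[", paste(AA1, collapse = ""), "]")

  # splice: X125_splice or e.g. "e5_splice" / "125_splice"
  if (grepl("_splice$", x, ignore.case = TRUE)) {
    pos <- first_integer(x)
    if (is.na(pos)) return(fail)
    m <- regmatches(x, regexec(paste0("^(", aa, "?)([0-9]+)_splice$"), x, ignore.case = TRUE))[[1]]
    ref <- if (length(m) && nzchar(m[2])) toupper(m[2]) else NA_character_
    return(done(paste0(ifelse(is.na(ref), "", ref), pos, "_splice"),
                pos, ref, NA_character_, "splice"))
  }

  # frameshift: X123fs, X123fs*9, X123Yfs*9
  m <- regmatches(x, regexec(paste0("^(", aa, ")([0-9]+)(", aa, "?)fs(\\*[0-9]*)?$"), x))[[1]]
  if (length(m)) {
    return(done(paste0(m[2], m[3], "fs"), m[3], m[2], NA_character_, "frameshift"))
  }

  # in-frame del/ins/dup/delins: X123del, X123_Y125del, X123_Y124insGLQ, X123dup
  m <- regmatches(x, regexec(
    paste0("^(", aa, ")([0-9]+)(_(", aa, ")([0-9]+))?(delins|del|ins|dup)(", aa, "*)$"), x))[[1]]
  if (length(m)) {
    span <- if (nzchar(m[4])) paste0("_", m[5], m[6]) else ""
    label <- paste0(m[2], m[3], span, m[7], m[8])
    return(done(label, m[3], m[2], NA_character_, "inframe_indel"))
  }

  # substitution: X123Y / X123* / X123= / X123X
  m <- regmatches(x, regexec(paste0("^(", aa, ")([0-9]+)(", aa, "|\\*|=)$"), x))[[1]]
  if (length(m)) {
    ref <- m[2]; pos <- m[3]; alt <- m[4]
    if (alt == "=") {
      return(done(paste0(ref, pos, ref), pos, ref, ref, "synonymous"))
    }
    if (alt == "*") {
      return(done(paste0(ref, pos, "*"), pos, ref, "*", "nonsense"))
    }
    if (alt == ref) {
      return(done(paste0(ref, pos, alt), pos, ref, alt, "synonymous"))
    }
    return(done(paste0(ref, pos, alt), pos, ref, alt, "missense"))
  }

  # anything else with an extractable position
  pos <- first_integer(x)
  if (is.na(pos)) return(fail)
  done(x, pos, NA_character_, NA_character_, "other")
}

first_integer <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+", x))
  if (length(m) == 0 || !nzchar(m)) return(NA_integer_)
  v <- suppressWarnings(as.integer(m))
  if (is.na(v) || v < 1) NA_integer_ else v
}
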