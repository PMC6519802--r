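# SVG rendering, raster/PDF conversion, deterministic color assignment, and
# tabular exports of the plotted data.

#' Style configuration
#'
#' Colors and typography for [render_svg()]. Default palettes are
#' colorblind-safe qualitative sets (Okabe-Ito for mutation types, a pastel
#' qualitative set for domains). Mutation type and domain identity are
#' encoded by color; highlighted lollipops additionally get a thicker stem.
#'
#' @param mutation_type_palette,domain_palette Character vectors of 6-digit
#'   hex colors; cycled when there are more categories than colors.
#' @param font_family Font family name written into the SVG.
#' @param font_size Base font size in points.
#' @param highlight_emphasis Extra stroke width (drawing units) added to the
#'   stems of highlighted positions.
#' @return A `style_config` list.
#' @export
style_config <- function(mutation_type_palette = c(
                           "#E69F00", "#56B4E9", "#009E73", "#F0E442",
                           "#0072B2", "#D55E00", "#CC79A7", "#999999"),
                         domain_palette = c(
                           "#8DD3C7", "#BEBADA", "#FB8072", "#80B1D3",
                           "#FDB462", "#B3DE69", "#FCCDE5", "#D9D9D9"),
                         font_family = "Helvetica", font_size = 11,
                         highlight_emphasis = 1.5) {
  ok_hex <- function(x) length(x) > 0 && all(grepl("^#[0-9A-Fa-f]{6}$", x))
  if (!ok_hex(mutation_type_palette) || !ok_hex(domain_palette)) {
    stop("palettes must be non-empty vectors of 6-digit hex colors",
         call. = FALSE)
  }
  structure(list(mutation_type_palette = mutation_type_palette,
                 domain_palette = domain_palette,
                 font_family = font_family, font_size = font_size,
                 highlight_emphasis = highlight_emphasis),
            class = "style_config")
}

#' Deterministic category-color assignment
#'
#' Categories are sorted lexicographically in the C locale and assigned
#' palette colors cyclically, so the mapping is independent of input order,
#' run, and platform.
#'
#' @param categories Character vector of distinct category labels.
#' @param palette Character vector of colors.
#' @return Named character vector mapping each category to a color.
#' @export
assign_colors <- function(categories, palette) {
  stopifnot(length(palette) > 0, !anyDuplicated(categories))
  cats <- sort(categories, method = "radix")
  stats::setNames(palette[(seq_along(cats) - 1L) %% length(palette) + 1L],
                  cats)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a layout as a canonical SVG document
#'
#' Emits a self-contained SVG 1.1 document with one `<rect>` per domain lane
#' segment, one `<g class="lollipop">` (stem line + head circle) per
#' lollipop, one `<g class="label">` (leader polyline + box + text) per
#' placed label, and a legend listing every mutation type and every domain
#' with its full name and residue span. The output contains no timestamps or
#' generated identifiers, so rendering the same layout and style twice gives
#' byte-identical strings.
#'
#' @param layout A `lollipop_layout` from [build_layout()].
#' @param style A [style_config()].
#' @return The SVG document as a single string.
#' @export
render_svg <- function(layout, style = style_config()) {
  stopifnot(inherits(layout, "lollipop_layout"))
  p <- layout$params
  fs <- style$font_size
  type_colors <- assign_colors(layout$legend$mutation_types,
                               style$mutation_type_palette)
  domain_colors <- assign_colors(unique(layout$legend$domains),
                                 style$domain_palette)

  text_el <- function(x, y, s, size = fs, anchor = "start", weight = NULL,
                      fill = "#000000") {
    paste0("<text x=\"", num(x), "\" y=\"", num(y), "\" font-family=\"",
           style$font_family, "\" font-size=\"", num(size),
           "\" text-anchor=\"", anchor, "\"",
           if (!is.null(weight)) paste0(" font-weight=\"", weight, "\"") else "",
           " fill=\"", fill, "\">", xml_escape(s), "</text>")
  }

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" width=\"",
           num(p$canvas_width), "\" height=\"", num(p$canvas_height),
           "\" viewBox=\"0 0 ", num(p$canvas_width), " ",
           num(p$canvas_height), "\">"),
    paste0("<rect class=\"background\" x=\"0\" y=\"0\" width=\"",
           num(p$canvas_width), "\" height=\"", num(p$canvas_height),
           "\" fill=\"#FFFFFF\"/>"),
    # title and axis
    "<g class=\"axis\">",
    text_el(p$margin_left, p$margin_top - 10,
            paste0(layout$gene_symbol, " (", layout$length, " aa)"),
            size = fs + 3, weight = "bold"),
    paste0("<line x1=\"", num(layout$axis$x_left), "\" y1=\"",
           num(layout$axis$y), "\" x2=\"", num(layout$axis$x_right),
           "\" y2=\"", num(layout$axis$y),
           "\" stroke=\"#333333\" stroke-width=\"1.5\"/>"),
    text_el(layout$axis$x_left, layout$axis$y + 14 +
              18 * max(1, max(c(0, layout$domain_rects$lane))), "1",
            anchor = "middle", size = fs - 1),
    text_el(layout$axis$x_right, layout$axis$y + 14 +
              18 * max(1, max(c(0, layout$domain_rects$lane))),
            as.character(layout$length), anchor = "middle", size = fs - 1)
  )

  # y scale annotation: the most recurrent position's sample count
  if (nrow(layout$lollipops) > 0) {
    max_n <- max(layout$lollipops$n_samples)
    top_y <- layout$axis$y - p$stem_max_height
    out <- c(out,
      paste0("<line x1=\"", num(layout$axis$x_left - 8), "\" y1=\"",
             num(top_y), "\" x2=\"", num(layout$axis$x_left - 8), "\" y2=\"",
             num(layout$axis$y), "\" stroke=\"#333333\" stroke-width=\"1\"/>"),
      text_el(layout$axis$x_left - 12, top_y + fs / 2,
              as.character(max_n), anchor = "end", size = fs - 1),
      text_el(layout$axis$x_left - 12, layout$axis$y, "0",
              anchor = "end", size = fs - 1))
  }
  out <- c(out, "</g>")

  # domain track
  out <- c(out, "<g class=\"domains\">")
  if (nrow(layout$domain_rects) > 0) {
    dr <- layout$domain_rects
    out <- c(out, purrr::map_chr(seq_len(nrow(dr)), function(i) {
      paste0("<rect class=\"domain\" x=\"", num(dr$x0[i]), "\" y=\"",
             num(dr$y0[i]), "\" width=\"", num(dr$x1[i] - dr$x0[i]),
             "\" height=\"", num(dr$y1[i] - dr$y0[i]), "\" fill=\"",
             domain_colors[[dr$name[i]]],
             "\" stroke=\"#555555\" stroke-width=\"0.5\"/>")
    }))
  }
  out <- c(out, "</g>")

  # lollipops
  highlighted_positions <- unique(layout$labels$anchor_x)
  out <- c(out, "<g class=\"lollipops\">")
  if (nrow(layout$lollipops) > 0) {
    lp <- layout$lollipops
    out <- c(out, purrr::map_chr(seq_len(nrow(lp)), function(i) {
      emph <- lp$x[i] %in% highlighted_positions
      sw <- 1.5 + if (emph) style$highlight_emphasis else 0
      paste0("<g class=\"lollipop\" data-position=\"", lp$position[i], "\">",
             "<line x1=\"", num(lp$x[i]), "\" y1=\"", num(layout$axis$y),
             "\" x2=\"", num(lp$x[i]), "\" y2=\"", num(lp$head_y[i]),
             "\" stroke=\"#888888\" stroke-width=\"", num(sw), "\"/>",
             "<circle cx=\"", num(lp$x[i]), "\" cy=\"", num(lp$head_y[i]),
             "\" r=\"", num(p$head_radius), "\" fill=\"",
             type_colors[[lp$mutation_type[i]]],
             "\" stroke=\"#333333\" stroke-width=\"0.75\"/>",
             "</g>")
    }))
  }
  out <- c(out, "</g>")

  # labels
  out <- c(out, "<g class=\"labels\">")
  if (nrow(layout$labels) > 0) {
    lb <- layout$labels
    out <- c(out, purrr::map_chr(seq_len(nrow(lb)), function(i) {
      paste0("<g class=\"label\">",
             "<polyline points=\"", lb$leader[i],
             "\" fill=\"none\" stroke=\"#999999\" stroke-width=\"0.75\"/>",
             "<rect x=\"", num(lb$x[i]), "\" y=\"", num(lb$y[i]),
             "\" width=\"", num(lb$width[i]), "\" height=\"",
             num(lb$height[i]),
             "\" fill=\"#FFFFFF\" stroke=\"#666666\" stroke-width=\"0.5\"/>",
             text_el(lb$x[i] + lb$width[i] / 2, lb$y[i] + lb$height[i] - 5,
                     lb$text[i], anchor = "middle", size = fs - 1),
             "</g>")
    }))
  }
  out <- c(out, "</g>")

  # legend: mutation types, then domains with full names and spans
  legend_y <- layout$axis$y + 18 * max(1, max(c(0, layout$domain_rects$lane))) + 30
  out <- c(out, "<g class=\"legend\">")
  lx <- p$margin_left
  if (length(layout$legend$mutation_types) > 0) {
    out <- c(out, text_el(lx, legend_y, "Mutation type:", weight = "bold",
                          size = fs - 1))
    cx <- lx + 95
    for (ty in layout$legend$mutation_types) {
      out <- c(out,
        paste0("<circle cx=\"", num(cx), "\" cy=\"", num(legend_y - 4),
               "\" r=\"5\" fill=\"", type_colors[[ty]],
               "\" stroke=\"#333333\" stroke-width=\"0.75\"/>"),
        text_el(cx + 9, legend_y, ty, size = fs - 1))
      cx <- cx + 18 + nchar(ty) * (fs - 1) * 0.62
    }
    legend_y <- legend_y + 18
  }
  if (length(layout$legend$domains) > 0) {
    out <- c(out, text_el(lx, legend_y, "Domains:", weight = "bold",
                          size = fs - 1))
    dy <- legend_y
    dr <- layout$domain_rects
    for (i in seq_len(nrow(dr))) {
      out <- c(out,
        paste0("<rect x=\"", num(lx + 70), "\" y=\"", num(dy - 9),
               "\" width=\"14\" height=\"10\" fill=\"",
               domain_colors[[dr$name[i]]],
               "\" stroke=\"#555555\" stroke-width=\"0.5\"/>"),
        text_el(lx + 90, dy,
                paste0(dr$name[i], " (", dr$start[i], "-", dr$end[i], ")"),
                size = fs - 1))
      dy <- dy + 15
    }
  }
  out <- c(out, "</g>", "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

SUPPORTED_FORMATS <- c("SVG", "PNG", "PDF", "JPEG")

#' Convert an SVG document to an output format
#'
#' SVG is the canonical artifact and passes through byte-identically; PNG and
#' PDF conversions delegate to librsvg; JPEG is rasterised with librsvg and
#' encoded with alpha composited on white (JPEG has no alpha channel).
#'
#' @param svg_text SVG document string, e.g. from [render_svg()].
#' @param format One of `"SVG"`, `"PNG"`, `"PDF"`, `"JPEG"`
#'   (case-insensitive).
#' @param scale Raster scale factor relative to the SVG's nominal pixel size
#'   (default 2 for crisper raster output).
#' @return Raw vector of the encoded image bytes.
#' @export
export_image <- function(svg_text, format, scale = 2) {
  fmt <- toupper(format)
  if (length(fmt) != 1 || !fmt %in% SUPPORTED_FORMATS) {
    stop("unsupported format '", format, "'; supported formats: ",
         paste(SUPPORTED_FORMATS, collapse = ", "), call. = FALSE)
  }
  svg_raw <- charToRaw(svg_text)
  if (fmt == "SVG") return(svg_raw)
  dims <- svg_nominal_size(svg_text)
  if (fmt == "PDF") return(rsvg::rsvg_pdf(svg_raw))
  w <- round(dims[["width"]] * scale)
  if (fmt == "PNG") return(rsvg::rsvg_png(svg_raw, width = w))
  # JPEG: rasterise, drop alpha against white, encode
  px <- rsvg::rsvg_raw(svg_raw, width = w) # RGBA, channel-first
  a <- as.numeric(px) / 255
  dim(a) <- dim(px)
  img <- aperm(a, c(2, 3, 1))
  alpha <- img[, , 4]
  rgb <- img[, , 1:3]
  for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] * alpha + (1 - alpha)
  jpeg::writeJPEG(rgb, raw(), quality = 0.95)
}

svg_nominal_size <- function(svg_text) {
  w <- stringr::str_match(svg_text, "<svg[^>]*\\swidth=\"([0-9.]+)\"")[, 2]
  h <- stringr::str_match(svg_text, "<svg[^>]*\\sheight=\"([0-9.]+)\"")[, 2]
  c(width = as.numeric(w), height = as.numeric(h))
}

#' Export the plotted data and domain tables
#'
#' Produces the two tabular companions of a figure: one row per alteration
#' (with its position, attributed mutation type, distinct-sample count and
#' highlight flag) and one row per domain feature of the protein record.
#' Both are plain tibbles; write them with [readr::write_tsv()] or via
#' [run_lollipop()].
#'
#' @param profile A `recurrence_profile`.
#' @param record A `protein_record`.
#' @param highlights A `highlight_set`.
#' @return List with tibbles `data_table` (`gene`, `protein_change`,
#'   `position`, `mutation_type`, `n_samples`, `highlighted`) and
#'   `domain_table` (`name`, `start`, `end`, `accession`).
#' @export
export_tables <- function(profile, record, highlights) {
  stopifnot(inherits(profile, "recurrence_profile"),
            inherits(record, "protein_record"),
            inherits(highlights, "highlight_set"))
  data_table <- tibble::tibble(
    gene = rep(profile$gene_symbol, nrow(profile$per_alteration)),
    protein_change = profile$per_alteration$protein_change,
    position = profile$per_alteration$position,
    mutation_type = profile$per_alteration$mutation_type,
    n_samples = profile$per_alteration$n_samples,
    highlighted = profile$per_alteration$protein_change %in% highlights$members
  )
  domain_table <- tibble::tibble(
    name = record$domains$name,
    start = record$domains$start,
    end = record$domains$end,
    accession = rep(record$accession, nrow(record$domains))
  )
  list(data_table = data_table, domain_table = domain_table)
}

#' @describeIn autoplot-methods ggplot2 view of a lollipop layout.
#' @export
autoplot.lollipop_layout <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, color = "grey30")
  if (nrow(object$domain_rects) > 0) {
    dr <- object$domain_rects
    p <- p + ggplot2::geom_rect(
      data = dr,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.06 * max(1, max(object$lollipops$n_samples, 1)) *
                     .data$lane,
                   ymax = 0, fill = .data$name),
      color = "grey40", linewidth = 0.2)
  }
  if (nrow(object$lollipops) > 0) {
    lp <- object$lollipops
    p <- p +
      ggplot2::geom_segment(
        data = lp,
        ggplot2::aes(x = .data$position, xend = .data$position,
                     y = 0, yend = .data$n_samples),
        color = "grey55") +
      ggplot2::geom_point(
        data = lp,
        ggplot2::aes(x = .data$position, y = .data$n_samples,
                     color = .data$mutation_type), size = 2.5)
  }
  p +
    ggplot2::scale_x_continuous(limits = c(1, object$length)) +
    ggplot2::labs(
      title = paste0(object$gene_symbol, " (", object$length, " aa)"),
      x = "Residue position", y = "Samples", color = "Mutation type",
      fill = "Domain") +
    ggplot2::theme_minimal()
}

#' ggplot2 views of package result objects
#'
#' @name autoplot-methods
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
NULL

#' @describeIn autoplot-methods ggplot2 view of a recurrence profile.
#' @export
autoplot.recurrence_profile <- function(object, ...) {
  df <- object$per_alteration
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$n_samples)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          color = "grey55") +
    ggplot2::geom_point(ggplot2::aes(color = .data$mutation_type),
                        size = 2.5) +
    ggplot2::labs(title = object$gene_symbol, x = "Residue position",
                  y = "Samples", color = "Mutation type") +
    ggplot2::theme_minimal()
}
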