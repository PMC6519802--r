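# Plot geometry: scaled residue axis, domain lanes, stems, and deterministic
# collision-free label placement. All coordinates are drawing units with the
# origin at the top-left corner and y growing downward (SVG convention).

#' Layout parameters
#'
#' Geometry knobs for [build_layout()]. Defaults give a 1000x460 canvas with
#' a 170-unit maximum stem. `label_gap` is the minimum separation enforced
#' between any two label boxes; `max_repel_iterations` bounds the number of
#' candidate slots examined per label before the lowest-overlap slot is used
#' and the label flagged.
#'
#' @param canvas_width,canvas_height Canvas size in drawing units.
#' @param margin_top,margin_right,margin_bottom,margin_left Margins in
#'   drawing units; the residue axis spans the area inside the left/right
#'   margins and sits `margin_bottom` above the canvas bottom.
#' @param stem_max_height Stem height of the most recurrent position.
#' @param head_radius Lollipop head radius (fixed; counts are conveyed by
#'   stem height and label text, not head size).
#' @param label_gap Minimum gap between label boxes.
#' @param max_repel_iterations Candidate-slot budget per label (>= 1).
#' @param label_font_size Font size used to size label boxes.
#' @return A `layout_params` list.
#' @export
layout_params <- function(canvas_width = 1000, canvas_height = 460,
                          margin_top = 30, margin_right = 40,
                          margin_bottom = 120, margin_left = 60,
                          stem_max_height = 170, head_radius = 5,
                          label_gap = 4, max_repel_iterations = 1000,
                          label_font_size = 11) {
  p <- list(
    canvas_width = canvas_width, canvas_height = canvas_height,
    margin_top = margin_top, margin_right = margin_right,
    margin_bottom = margin_bottom, margin_left = margin_left,
    stem_max_height = stem_max_height, head_radius = head_radius,
    label_gap = label_gap,
    max_repel_iterations = as.integer(max_repel_iterations),
    label_font_size = label_font_size
  )
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, logical(1))))
  stopifnot(margin_left + margin_right < canvas_width,
            margin_top + margin_bottom < canvas_height)
  structure(p, class = "layout_params")
}

axis_span <- function(params) {
  c(left = params$margin_left,
    right = params$canvas_width - params$margin_right)
}

axis_baseline <- function(params) params$canvas_height - params$margin_bottom

#' Map a residue position to an axis x coordinate
#'
#' Affine map of residue positions `[1, length]` onto the axis span, so
#' residue 1 sits on the left axis edge and residue `length` on the right
#' one; strictly increasing in position. Positions outside `[1, length]`
#' (e.g. variants annotated beyond the canonical protein) raise an error —
#' [build_layout()] screens those out beforehand.
#'
#' @param position Residue position(s), 1-based.
#' @param length Protein length in residues.
#' @param params A [layout_params()] list.
#' @return Numeric vector of x coordinates in drawing units.
#' @export
scale_position <- function(position, length, params = layout_params()) {
  if (any(position < 1 | position > length)) {
    stop("residue position out of range [1, ", length, "]: ",
         paste(position[position < 1 | position > length], collapse = ", "),
         call. = FALSE)
  }
  span <- axis_span(params)
  if (length == 1) {
    return(rep((span[["left"]] + span[["right"]]) / 2, length(position)))
  }
  span[["left"]] + (position - 1) / (length - 1) *
    (span[["right"]] - span[["left"]])
}

#' Stem heights proportional to per-position recurrence
#'
#' Heights scale linearly with the distinct-sample count: the maximum count
#' maps to `stem_max_height`, equal counts map to equal heights.
#'
#' @param counts Tibble with columns `position` and `n_samples` (as in a
#'   `recurrence_profile$per_position`), or a named numeric vector
#'   (names = positions).
#' @param params A [layout_params()] list.
#' @return Tibble with `position`, `n_samples`, `height`.
#' @export
stem_heights <- function(counts, params = layout_params()) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(position = as.integer(names(counts)),
                             n_samples = as.numeric(counts))
  }
  stopifnot(nrow(counts) > 0)
  tibble::tibble(
    position = counts$position,
    n_samples = counts$n_samples,
    height = counts$n_samples / max(counts$n_samples) * params$stem_max_height
  )
}

# -- label placement ----------------------------------------------------------

label_box_size <- function(text, params) {
  # width model: monospaced-ish estimate, adequate because placement only
  # needs an upper bound per label
  char_w <- params$label_font_size * 0.62
  list(width = nchar(text) * char_w + 8,
       height = params$label_font_size + 6)
}

# gap-aware rejection: boxes a, b given as c(x, y, w, h)
boxes_too_close <- function(a, b, gap) {
  a[1] < b[1] + b[3] + gap && b[1] < a[1] + a[3] + gap &&
    a[2] < b[2] + b[4] + gap && b[2] < a[2] + a[4] + gap
}

box_overlap_area <- function(a, b) {
  w <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  h <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

#' Place annotation labels without overlaps
#'
#' Deterministic greedy placement: labels are sorted by anchor x then text,
#' and each is tried at candidate slots starting directly above its anchor,
#' then shifted left/right, then at higher tiers, until a slot is found that
#' lies inside the canvas and keeps at least `label_gap` from every
#' already-placed box. If the candidate budget (`max_repel_iterations`) is
#' exhausted the lowest-overlap candidate is used and the label is flagged;
#' placement therefore never fails. Each placed label carries a leader
#' polyline back to its anchor (a straight drop when the box sits centered
#' over the anchor).
#'
#' @param labels Tibble with columns `text`, `anchor_x`, `anchor_y` and
#'   optionally `width`, `height` (computed from `text` when absent).
#' @param params A [layout_params()] list.
#' @return The input tibble sorted in placement order with added columns
#'   `x`, `y` (top-left corner of the box), `width`, `height`, `leader`
#'   (space-separated `x,y` polyline points from box to anchor), `flagged`.
#' @export
place_labels <- function(labels, params = layout_params()) {
  labels <- tibble::as_tibble(labels)
  if (nrow(labels) == 0) {
    return(dplyr::mutate(labels, x = numeric(), y = numeric(),
                         width = numeric(), height = numeric(),
                         leader = character(), flagged = logical()))
  }
  if (!all(c("width", "height") %in% names(labels))) {
    sz <- purrr::map(labels$text, label_box_size, params = params)
    labels$width <- purrr::map_dbl(sz, "width")
    labels$height <- purrr::map_dbl(sz, "height")
  }
  labels <- dplyr::arrange(labels, .data$anchor_x,
                           rank_radix(.data$text))
  gap <- params$label_gap
  clearance <- params$head_radius + 3
  placed <- list()
  xs <- ys <- numeric(nrow(labels))
  flagged <- logical(nrow(labels))

  for (i in seq_len(nrow(labels))) {
    w <- labels$width[i]; h <- labels$height[i]
    ax <- labels$anchor_x[i]; ay <- labels$anchor_y[i]
    step <- w / 2 + gap
    k_max <- ceiling(params$canvas_width / step)
    best <- NULL; best_area <- Inf
    tried <- 0L; found <- FALSE
    tier <- 0L
    while (!found && tried < params$max_repel_iterations) {
      y <- ay - clearance - h - tier * (h + gap)
      if (y < 0) break
      for (k in c(0, as.vector(rbind(-seq_len(k_max), seq_len(k_max))))) {
        x <- ax - w / 2 + k * step
        if (x < 0 || x + w > params$canvas_width) next
        tried <- tried + 1L
        cand <- c(x, y, w, h)
        clash <- FALSE; area <- 0
        for (p in placed) {
          if (boxes_too_close(cand, p, gap)) clash <- TRUE
          area <- area + box_overlap_area(cand, p)
        }
        if (!clash) {
          xs[i] <- x; ys[i] <- y; found <- TRUE
          break
        }
        if (area < best_area) { best_area <- area; best <- cand }
        if (tried >= params$max_repel_iterations) break
      }
      tier <- tier + 1L
    }
    if (!found) {
      # budget exhausted or canvas top reached: take the least-bad slot seen
      if (is.null(best)) {
        best <- c(min(max(ax - w / 2, 0), params$canvas_width - w),
                  max(ay - clearance - h, 0), w, h)
      }
      xs[i] <- best[1]; ys[i] <- best[2]
      flagged[i] <- TRUE
    }
    placed[[length(placed) + 1L]] <- c(xs[i], ys[i], w, h)
  }

  labels$x <- xs
  labels$y <- ys
  labels$flagged <- flagged
  labels$leader <- purrr::pmap_chr(
    list(xs, ys, labels$width, labels$height,
         labels$anchor_x, labels$anchor_y),
    function(x, y, w, h, ax, ay) {
      bcx <- x + w / 2; bby <- y + h
      if (abs(bcx - ax) < 0.5) {
        paste0(num(bcx), ",", num(bby), " ", num(ax), ",", num(ay))
      } else {
        midy <- (bby + ay) / 2
        paste0(num(bcx), ",", num(bby), " ", num(bcx), ",", num(midy), " ",
               num(ax), ",", num(ay))
      }
    })
  labels
}

# locale-independent ordering key for character vectors
rank_radix <- function(x) {
  match(x, sort(unique(x), method = "radix"))
}

# fixed-precision coordinate formatting shared by layout serialization and SVG
num <- function(x) {
  x <- round(x, 2)
  x[x == 0] <- 0 # avoid "-0"
  formatC(x, format = "f", digits = 2)
}

# -- full layout --------------------------------------------------------------

#' Build the full lollipop-plot geometry for one gene
#'
#' Combines a recurrence profile, a protein record and a highlight set into
#' resolved geometry: the scaled residue axis, domain rectangles (overlapping
#' domains are stacked into separate lanes rather than blended), one lollipop
#' per distinct mutated position with stem height proportional to its
#' distinct-sample count, one placed label per highlighted alteration (text =
#' alteration plus its count, e.g. `"R175H (3)"`), and legend entries with
#' full, never-truncated names. Variants whose position exceeds the protein
#' length (annotation/isoform mismatches) are excluded with a warning and
#' reported in `out_of_range`.
#'
#' @param profile A `recurrence_profile` for the gene.
#' @param record A `protein_record` for the same gene (case-insensitive
#'   match enforced).
#' @param highlights A `highlight_set` from [select_highlights()]; defaults
#'   to threshold 1 (everything highlighted).
#' @param params A [layout_params()] list.
#' @return A `lollipop_layout` object with fields `gene_symbol`, `length`,
#'   `axis`, `domain_rects`, `lollipops`, `labels`, `legend`,
#'   `out_of_range`, `params`.
#' @export
build_layout <- function(profile, record, highlights = NULL,
                         params = layout_params()) {
  stopifnot(inherits(profile, "recurrence_profile"),
            inherits(record, "protein_record"))
  if (!is.na(record$gene_symbol) && nrow(profile$per_alteration) > 0 &&
      toupper(profile$gene_symbol) != toupper(record$gene_symbol)) {
    stop("profile gene '", profile$gene_symbol,
         "' does not match protein record gene '", record$gene_symbol, "'",
         call. = FALSE)
  }
  highlights <- highlights %||% select_highlights(profile, 1L)
  stopifnot(inherits(highlights, "highlight_set"))

  span <- axis_span(params)
  y_axis <- axis_baseline(params)
  axis <- list(length = record$length,
               x_left = span[["left"]], x_right = span[["right"]],
               y = y_axis)

  # screen out-of-range positions before any scaling
  alt <- profile$per_alteration
  pos <- profile$per_position
  oor <- dplyr::filter(alt, .data$position > record$length)
  if (nrow(oor) > 0) {
    warning("excluding ", nrow(oor), " alteration(s) beyond protein length ",
            record$length, ": ", paste(oor$protein_change, collapse = ", "),
            call. = FALSE)
    alt <- dplyr::filter(alt, .data$position <= record$length)
    pos <- dplyr::filter(pos, .data$position <= record$length)
  }

  # domain lanes: greedy interval stacking in start order
  dr <- record$domains
  if (nrow(dr) > 0) {
    lane_ends <- numeric()
    lane <- integer(nrow(dr))
    for (i in seq_len(nrow(dr))) {
      free <- which(lane_ends < dr$start[i])
      lane[i] <- if (length(free) > 0) free[[1]] else length(lane_ends) + 1L
      lane_ends[lane[i]] <- dr$end[i]
    }
    lane_h <- 18
    domain_rects <- tibble::tibble(
      name = dr$name, start = dr$start, end = dr$end, lane = lane,
      x0 = scale_position(dr$start, record$length, params),
      x1 = scale_position(dr$end, record$length, params),
      y0 = y_axis - lane_h / 2 + (lane - 1L) * (lane_h + 3),
      y1 = y_axis + lane_h / 2 + (lane - 1L) * (lane_h + 3)
    )
  } else {
    domain_rects <- tibble::tibble(name = character(), start = integer(),
                                   end = integer(), lane = integer(),
                                   x0 = numeric(), x1 = numeric(),
                                   y0 = numeric(), y1 = numeric())
  }

  if (nrow(pos) == 0) {
    if (nrow(oor) == 0) {
      warning("empty recurrence profile: layout contains the domain track only",
              call. = FALSE)
    }
    lollipops <- tibble::tibble(position = integer(), x = numeric(),
                                n_samples = integer(), stem_height = numeric(),
                                head_y = numeric(), mutation_type = character(),
                                alterations = character())
    labels <- place_labels(tibble::tibble(text = character(),
                                          anchor_x = numeric(),
                                          anchor_y = numeric()), params)
  } else {
    hts <- stem_heights(pos, params)
    # per-position representative mutation type: type of the most frequent
    # alteration at that position (ties: lexicographically first label)
    rep_type <- alt |>
      dplyr::arrange(.data$position, dplyr::desc(.data$n_samples),
                     rank_radix(.data$protein_change)) |>
      dplyr::distinct(.data$position, .keep_all = TRUE) |>
      dplyr::select("position", "mutation_type")
    alts_by_pos <- alt |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(alterations = paste(.data$protein_change,
                                           collapse = ";"),
                       .groups = "drop")
    lollipops <- hts |>
      dplyr::left_join(rep_type, by = "position") |>
      dplyr::left_join(alts_by_pos, by = "position") |>
      dplyr::mutate(
        x = scale_position(.data$position, record$length, params),
        stem_height = .data$height,
        head_y = y_axis - .data$height
      ) |>
      dplyr::select("position", "x", "n_samples", "stem_height", "head_y",
                    "mutation_type", "alterations") |>
      dplyr::arrange(.data$position)

    hl <- dplyr::filter(alt, .data$protein_change %in% highlights$members)
    labels_in <- hl |>
      dplyr::left_join(dplyr::select(lollipops, "position", "x", "head_y"),
                       by = "position") |>
      dplyr::transmute(
        alteration = .data$protein_change,
        text = sprintf("%s (%d)", .data$protein_change, .data$n_samples),
        anchor_x = .data$x, anchor_y = .data$head_y
      )
    labels <- place_labels(labels_in, params)
  }

  legend <- list(
    mutation_types = sort(unique(lollipops$mutation_type), method = "radix"),
    domains = domain_rects$name
  )

  structure(
    list(gene_symbol = profile$gene_symbol, length = record$length,
         accession = record$accession, axis = axis,
         domain_rects = domain_rects, lollipops = lollipops,
         labels = labels, legend = legend,
         out_of_range = oor, threshold = highlights$threshold,
         params = params),
    class = "lollipop_layout"
  )
}

#' @export
print.lollipop_layout <- function(x, ...) {
  cat("<lollipop_layout> ", x$gene_symbol, " (", x$length, " aa): ",
      nrow(x$domain_rects), " domain rect(s), ", nrow(x$lollipops),
      " lollipop(s), ", nrow(x$labels), " label(s)\n", sep = "")
  invisible(x)
}

#' One-row summary of a lollipop layout
#'
#' @param x A `lollipop_layout`.
#' @param ... Unused.
#' @return One-row tibble with the gene, protein length, element counts and
#'   the number of flagged (budget-exhausted) labels.
#' @export
glance.lollipop_layout <- function(x, ...) {
  tibble::tibble(
    gene_symbol = x$gene_symbol, length = x$length,
    n_domains = nrow(x$domain_rects), n_lollipops = nrow(x$lollipops),
    n_labels = nrow(x$labels), n_flagged_labels = sum(x$labels$flagged),
    n_out_of_range = nrow(x$out_of_range)
  )
}

#' Serialize a layout to structured text
#'
#' Deterministic fixed-precision dump of the resolved geometry; two layouts
#' built from identical inputs serialize byte-identically, which is what the
#' determinism tests assert.
#'
#' @param layout A `lollipop_layout`.
#' @return A single string.
#' @export
serialize_layout <- function(layout) {
  stopifnot(inherits(layout, "lollipop_layout"))
  l <- c(
    paste0("layout gene=", layout$gene_symbol, " length=", layout$length,
           " threshold=", layout$threshold),
    paste0("axis left=", num(layout$axis$x_left), " right=",
           num(layout$axis$x_right), " y=", num(layout$axis$y)),
    purrr::pmap_chr(layout$domain_rects, function(name, start, end, lane,
                                                  x0, x1, y0, y1) {
      paste0("domain name=", name, " span=", start, "-", end, " lane=", lane,
             " rect=", num(x0), ",", num(y0), ",", num(x1), ",", num(y1))
    }),
    purrr::pmap_chr(layout$lollipops, function(position, x, n_samples,
                                               stem_height, head_y,
                                               mutation_type, alterations) {
      paste0("lollipop pos=", position, " x=", num(x), " n=", n_samples,
             " stem=", num(stem_height), " head_y=", num(head_y),
             " type=", mutation_type, " alts=", alterations)
    }),
    purrr::pmap_chr(layout$labels[, c("text", "x", "y", "width", "height",
                                      "leader", "flagged")],
                    function(text, x, y, width, height, leader, flagged) {
      paste0("label text=", text, " box=", num(x), ",", num(y), ",",
             num(width), ",", num(height), " leader=", leader,
             " flagged=", tolower(flagged))
    })
  )
  paste0(paste(l, collapse = "\n"), "\n")
}
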