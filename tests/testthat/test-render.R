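demo_layout <- function(threshold = 1) {
  prof <- aggregate_recurrence(mutation_table(tp53_demo_df()), "TP53")
  build_layout(prof, tp53_record(), select_highlights(prof, threshold))
}

test_that("color assignment is sorted, cyclic and order-stable", {
  pal <- c("#111111", "#222222")
  m <- assign_colors(c("Missense_Mutation", "Nonsense_Mutation"), pal)
  expect_identical(m[["Missense_Mutation"]], "#111111")
  expect_identical(m[["Nonsense_Mutation"]], "#222222")
  m3 <- assign_colors(c("A", "B", "C"), pal)
  expect_identical(m3[["C"]], "#111111") # cycles
  expect_identical(assign_colors(c("B", "C", "A"), pal), m3)
})

test_that("invalid palettes are rejected", {
  expect_error(style_config(mutation_type_palette = character()), "hex")
  expect_error(style_config(domain_palette = "red"), "hex")
})

test_that("SVG is well-formed with element counts matching the layout", {
  lay <- demo_layout()
  svg <- render_svg(lay)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "svg")
  n_dom <- length(xml2::xml_find_all(
    doc, "//svg:rect[@class='domain']", ns))
  n_lolli <- length(xml2::xml_find_all(
    doc, "//svg:g[@class='lollipop']", ns))
  n_label <- length(xml2::xml_find_all(
    doc, "//svg:g[@class='label']", ns))
  expect_identical(n_dom, nrow(lay$domain_rects))
  expect_identical(n_lolli, nrow(lay$lollipops))
  expect_identical(n_label, nrow(lay$labels))
  # legend carries full, untruncated domain names with spans
  svg_text <- as.character(svg)
  expect_match(svg_text, "P53_tetramer (318-358)", fixed = TRUE)
  expect_match(svg_text, "P53_TAD (6-29)", fixed = TRUE)
})

test_that("rendering is byte-deterministic", {
  lay <- demo_layout()
  expect_identical(render_svg(lay), render_svg(lay))
})

test_that("an empty-profile layout renders domain track and legend only", {
  tb <- mutation_table(tp53_demo_df())
  suppressWarnings(prof <- aggregate_recurrence(tb, "BRAF"))
  prof$gene_symbol <- "TP53"
  suppressWarnings(lay <- build_layout(prof, tp53_record()))
  svg <- render_svg(lay)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "svg")
  expect_length(xml2::xml_find_all(doc, "//svg:g[@class='lollipop']", ns), 0L)
  expect_length(xml2::xml_find_all(doc, "//svg:rect[@class='domain']", ns), 3L)
})

test_that("export formats carry the right magic bytes; SVG passes through", {
  svg <- render_svg(demo_layout())
  expect_identical(export_image(svg, "SVG"), charToRaw(svg))
  png_bytes <- export_image(svg, "PNG")
  expect_identical(as.integer(png_bytes[1:4]), c(0x89L, 0x50L, 0x4eL, 0x47L))
  pdf_bytes <- export_image(svg, "PDF")
  expect_identical(rawToChar(pdf_bytes[1:4]), "%PDF")
  jpg_bytes <- export_image(svg, "jpeg") # case-insensitive
  expect_identical(as.integer(jpg_bytes[1:3]), c(0xffL, 0xd8L, 0xffL))
  expect_error(export_image(svg, "TIFF"), regexp = "SVG, PNG, PDF, JPEG")
})

test_that("exported tables mirror the profile and record", {
  prof <- aggregate_recurrence(mutation_table(tp53_demo_df()), "TP53")
  hl <- select_highlights(prof, 3)
  tabs <- export_tables(prof, tp53_record(), hl)
  expect_identical(nrow(tabs$data_table), nrow(prof$per_alteration))
  expect_identical(nrow(tabs$domain_table), 3L)
  expect_identical(tabs$data_table$highlighted,
                   prof$per_alteration$n_samples >= 3)
  # counts column survives a write/read round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tabs$data_table, path, progress = FALSE)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_identical(as.integer(back$n_samples),
                   prof$per_alteration$n_samples)
  # empty highlights -> all false
  none <- export_tables(prof, tp53_record(), select_highlights(prof, 99))
  expect_false(any(none$data_table$highlighted))
})

test_that("autoplot methods return ggplot objects", {
  prof <- aggregate_recurrence(mutation_table(tp53_demo_df()), "TP53")
  lay <- demo_layout()
  expect_s3_class(autoplot(prof), "ggplot")
  expect_s3_class(autoplot(lay), "ggplot")
})
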