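# lollipopr

Protein lollipop diagrams of cohort mutation data, built for clinicians and
researchers who have a table of somatic variants and want a
publication-quality figure without writing plotting code.

Given a tab- or comma-delimited cohort table with four columns —
`Hugo_Symbol`, `Sample_ID`, `Protein_Change`, `Mutation_Type` — lollipopr:

- parses HGVS-style protein changes (`p.R175H`, `R273*`, `p.Glu285fs`,
  `p.S90_E95del`, `X125_splice`, ...) into structured alterations;
- counts **sample recurrence**: for each distinct amino-acid alteration and
  each residue position, the number of *distinct samples* carrying it
  (duplicated rows never inflate counts);
- draws a lollipop diagram: residue positions scaled affinely to the protein
  length, one stem per mutated position with height proportional to its
  sample count, heads colored by mutation type, over a domain track built
  from UniProt `Domain` features (retrieved live or loaded from offline
  cache/fixture files for firewalled deployments);
- highlights every alteration whose count reaches a user-chosen cutoff
  (preset menu 1, 2, 3, 4, 5, 10, 15, 20, 25, 30 — any positive integer is
  accepted) and annotates it as `R175H (12)`;
- places all annotation labels with a **deterministic greedy
  collision-avoidance algorithm**: labels are sorted by anchor position and
  tried directly above their lollipop, then shifted sideways and stacked into
  higher tiers until a slot is found that keeps a minimum gap from every
  placed label — so co-located alterations all stay readable, with zero
  overlapping label boxes;
- exports canonical, byte-deterministic SVG plus PNG / PDF / JPEG
  conversions, and TSVs of the plotted data and the domain information.

A bundled catalog of 409 oncogenes and tumor suppressor genes backs the gene
picker; it is extensible with a one-symbol-per-line file.

## Worked example

Simulate a 40-sample TP53 cohort with three engineered hotspots (R175H in
30% of samples, R273C in 20%, R282W in 10%) over a background of scattered
passenger mutations, then profile it:

```r
library(lollipopr)

spec <- cohort_spec(
  n_samples = 40, gene_symbol = "TP53", protein_length = 393,
  hotspots = data.frame(position = c(175, 273, 282),
                        fraction  = c(0.30, 0.20, 0.10),
                        alteration = c("R175H", "R273C", "R282W")),
  background_rate = 0.6, seed = 7)
simulate_mutation_cohort(spec, file = "cohort.tsv")

tb   <- read_mutation_table("cohort.tsv")
validate_mutation_table(tb)
#> <validation_report> rows=51 parsed=51 rejected=0

prof <- aggregate_recurrence(tb, "TP53")
glance(prof)
#> # A tibble: 1 × 4
#>   gene_symbol n_alterations n_positions n_samples_max
#>   <chr>               <int>       <int>         <int>
#> 1 TP53                   30          29            12

select_highlights(prof, 5)
#> <highlight_set> threshold=5, 2 member(s)
```

The counts are construction-exact: `R175H` is carried by 12 samples
(0.30 × 40) and `R273C` by 8, so cutoff 5 highlights exactly those two.
Build the figure against the bundled offline TP53 record (P04637, 393 aa,
domains P53_TAD, P53, P53_tetramer):

```r
rec <- read_protein_record(system.file("extdata", "TP53_P04637.domains.txt",
                                       package = "lollipopr"))
lay <- build_layout(prof, rec, select_highlights(prof, 5))
glance(lay)
#> # A tibble: 1 × 7
#>   gene_symbol length n_domains n_lollipops n_labels n_flagged_labels
#>   <chr>        <int>     <int>       <int>    <int>            <int>
#> 1 TP53           393         3          29        2                0

writeLines(render_svg(lay), "TP53_lollipop.svg")
autoplot(lay)   # quick ggplot2 view of the same layout
```

Or run the whole pipeline in one call (also available as the CLI script in
`inst/cli/lollipopr`, with a `synth` subcommand for the generator):

```r
cfg <- run_config("cohort.tsv", "TP53", threshold = 5, offline = TRUE,
                  domain_fixture_path = system.file(
                    "extdata", "TP53_P04637.domains.txt", package = "lollipopr"),
                  output_dir = "out", formats = c("SVG", "PNG"))
run_lollipop(cfg)
#> <figure_bundle> 4 file(s) written
#>   out/TP53_lollipop.svg
#>   out/TP53_lollipop.png
#>   out/TP53_data.tsv
#>   out/TP53_domains.tsv
```

Online use replaces the fixture with live UniProt resolution:
`uniprot_resolve_accession("TP53")` then `uniprot_fetch_record(acc,
cache_dir = "cache")`; the cache write-through makes later offline runs
possible.

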