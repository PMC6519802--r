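---
title: "Methods: recurrence counting and deterministic lollipop layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrence counting and deterministic lollipop layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lollipopr)
```

lollipopr turns a cohort mutation table into a protein lollipop diagram:
stems along a linear residue axis, stem height encoding how many samples are
mutated at each position, a domain track underneath, and a text annotation
for every alteration whose recurrence reaches a user-chosen cutoff. This
vignette records the model behind each stage, the parameters that matter,
and the design decisions taken where more than one reasonable choice
existed.

## Input model and protein-change parsing

The input is a MAF-like table reduced to four columns: `Hugo_Symbol`,
`Sample_ID`, `Protein_Change`, `Mutation_Type` (tab- or comma-delimited,
auto-detected from the header; the legacy header spelling `Mutaiton_Type`
seen in circulating example files is accepted and normalized). Extra columns
are ignored and column order is free. Rows are *partitioned*: a row either
becomes a record (its protein change yields a residue position) or lands in
a rejects table with its row index and a reason — nothing is silently
dropped, and `n_parsed + n_rejected = n_rows` always holds.

`parse_protein_change()` is a total function: it classifies HGVS short forms
(with or without `p.`, one- or three-letter residue codes) into missense,
nonsense, frameshift, in-frame indel, splice, and synonymous changes; any
other shape that still contains a residue number is kept as kind `other`
(position = first integer token), and only strings with no extractable
position are parse failures. Positions are 1-based and inclusive throughout,
matching HGVS and UniProt conventions. `Mutation_Type` is treated as free
text and kept verbatim as its own category: restricting it to a fixed
vocabulary would reject valid cohort files for no analytical gain.

## Recurrence: distinct samples, not rows

"Frequency" here is a **distinct-sample count**. For a gene $g$, let
$S(a)$ be the set of samples carrying alteration $a$ and $S(p)$ the set of
samples carrying *any* alteration at position $p$. The profile stores
$n(a) = |S(a)|$ per alteration and $n(p) = |S(p)|$ per position. Two
consequences are deliberate:

- duplicated rows (same sample, gene, alteration) count once — they are
  retained in the table with a warning, because sample-level recurrence is
  the quantity a cohort y-axis should show;
- a sample with two different alterations at one position contributes once
  to $n(p)$, so $n(p) \le \sum_{a \text{ at } p} n(a)$ with equality exactly
  when no sample is multiply mutated there. The test suite checks both
  against a brute-force set-union recount.

The mutation type attributed to an alteration with inconsistent raw types is
the majority type, ties broken lexicographically (C locale) — deterministic
and indifferent to row order.

Highlighting is an exact threshold filter: `members = {a : n(a) >= t}` for a
positive integer `t`. The preset menu `1, 2, 3, 4, 5, 10, 15, 20, 25, 30`
mirrors a GUI drop-down; programmatically any `t >= 1` is allowed and the
menu is user-extensible. Cutoff 1 therefore highlights everything, and
highlight sets shrink monotonically in `t` (property-tested).

## Protein records and the domain track

The domain track needs only a protein length and a list of named features
with 1-based inclusive coordinates. Records come from UniProtKB (REST JSON)
or from a one-record-per-file text cache that is diff-able and trivially
hand-authorable (`accession/gene/taxon/length` header lines plus one
`domain<TAB>name<TAB>start<TAB>end` line per feature). Both paths validate
the same invariants on load: `length >= 1`, `1 <= start <= end <= length`,
features sorted by start. Design choices:

- **Feature classes.** Only UniProt `Domain` features are kept by default;
  `Region`/`Motif` can be opted in via `feature_types=`. The narrow default
  matches what a domain track normally shows and keeps figures uncluttered.
- **Accession tie-break.** When a symbol maps to several reviewed entries,
  the lexicographically smallest accession is chosen. Any rule would do;
  this one is deterministic, documented, and platform-independent.
- **Axis length.** Scaling uses the protein sequence length in residues —
  positions plotted are residue indices, so no other reading is consistent.
- **Organism.** Human (taxon 9606) by default, configurable.

All HTTP goes through an injectable transport function, so firewalled
deployments and the test suite run entirely from local records; transport
failures, unknown accessions, and malformed bodies raise distinct condition
classes (`lollipopr_transport_error`, `lollipopr_lookup_error`,
`lollipopr_format_error`) that the CLI maps to distinct exit codes.

## Layout geometry

Coordinates are SVG-style (origin top-left, y down) on a default
1000 × 460 canvas. The residue axis is the affine map of `[1, length]` onto
the horizontal span inside the margins; it is strictly increasing, and
residue `1`/`length` land exactly on the axis edges. Stem heights are
linear in the per-position count with the maximum count mapped to
`stem_max_height` (170 units by default); proportionality is exact to
floating precision (tested at 1e-9). Head radius is fixed — recurrence is
encoded by stem height and the label text, not by head area, which avoids
the perceptual ambiguity of area scaling. Overlapping domain features are
stacked into separate lanes below the axis by greedy interval scheduling
rather than alpha-blended. Variants whose position exceeds the protein
length (isoform/annotation mismatches) are excluded with a warning and
reported in an `out_of_range` table instead of crashing or silently
plotting outside the axis.

## Deterministic label placement

Force-directed label repulsion gives pleasing results but is seed- and
iteration-order-dependent, which makes figures irreproducible and untestable
byte-for-byte. lollipopr instead uses a deterministic greedy tiered search:

1. labels are ordered by anchor x, then label text (C-locale);
2. each label tries candidate boxes in a fixed order: directly above its
   anchor, then alternating left/right shifts in half-box-width steps, then
   the same sweep one tier higher (a tier is one box height plus
   `label_gap`), and so on toward the canvas top;
3. a candidate is accepted if it lies fully inside the canvas and keeps at
   least `label_gap` (4 units) from every already-placed box;
4. the search is bounded by `max_repel_iterations` (1000 candidates per
   label); on exhaustion the lowest-overlap candidate seen is used and the
   label is *flagged* rather than failing the run.

Greedy placement is not globally optimal — an adversarial instance could
force a flagged label where an optimal packer would fit all — but every
accepted placement is provably non-overlapping, identical inputs give
byte-identical layouts, and the test suite verifies zero overlapping pairs
with an independent $O(n^2)$ rectangle-intersection oracle, including 20
labels crowded onto a 420-unit-wide canvas. Label text is
`"<alteration> (<count>)"`, e.g. `R175H (12)`: including the count keeps the
figure self-contained, at the cost of slightly wider boxes.

## Rendering and export

SVG is the canonical artifact: element structure mirrors the layout (one
rect per domain lane segment, one group per lollipop, one group per label,
legend entries with full, untruncated domain names and residue spans), all
numbers are written with fixed two-decimal formatting, and there are no
timestamps or generated ids — rendering the same layout twice is
byte-identical. Colors are assigned by sorting category labels in the C
locale and cycling through the palette (Okabe–Ito for mutation types, a
pastel qualitative set for domains), so the mapping is stable under input
permutation. PNG and PDF are converted from the SVG by librsvg; JPEG is
rasterised the same way and encoded with alpha composited on white. Raster
outputs are validated by magic bytes and non-emptiness only — pixel-exact
stability across converter versions is deliberately not promised.

## The synthetic cohort generator

`cohort_spec()` + `simulate_mutation_cohort()` generate test and demo
cohorts with known ground truth: each hotspot alteration is assigned to
`round(fraction × n_samples)` *distinct* samples (construction-exact, so
aggregation must recover the count with zero error), and background
passenger mutations are drawn per sample from a Poisson(`background_rate`)
count, uniform over the residues not used by hotspots, with types drawn
from a configurable mix. The defaults used in the demos and the acceptance
run — 40 samples, hotspot fractions 0.30/0.20/0.10 on a 393-residue
protein, background rate 0.6 — give the shape of a mid-sized single-gene
cancer cohort: a dominant hotspot around a tenth to a third of samples and
a tail of singletons. Generation is seeded and byte-reproducible.

What the generator does *not* emulate: positional clustering of passengers,
mutational signatures, transcript isoform mismatches, multi-gene tables
with correlated samples, or real HGVS messiness (nonstandard strings,
genomic coordinates). Passing tests therefore demonstrate the counting,
layout, and rendering contracts — not robustness to every artifact of real
annotation pipelines, which is what the rejects table is for.

## Problem sizes and numerical choices

The property suites run on deliberately small instances — cohorts of 3–40
rows across 6–10 samples, 100 random tables for the recount oracle, 200
random profiles for highlight monotonicity, 20-label adversarial placement —
sizes at which brute-force oracles are exact and instantaneous while still
exercising every code path. Ties are always broken lexicographically in the
C locale (`sort(method = "radix")`), never by locale-dependent collation.
The only floating-point comparison in the geometry (stem proportionality)
is asserted at 1e-9; everything else is integer counting or exact string
equality.

## Known limitations

- Single gene, single track: no multi-gene comparison figures.
- Canonical UniProt entry only; no isoform-aware coordinate mapping.
- Label content and the greedy placement order are fixed conventions, not
  user-tunable aesthetics.
- JPEG output is provided for completeness but is a poor format for line
  art; prefer SVG or PDF for publication.
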