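---
title: "Annotating the human kinome tree: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating the human kinome tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomeviz)
```

# The problem

The human kinome — 518 protein kinases — is conventionally displayed as a
phylogenetic tree whose leaves are catalytic domains, clustered by sequence
similarity into groups, families and subfamilies. A large fraction of
kinase studies, from inhibitor selectivity panels to structural-coverage
surveys, end in a figure that overlays per-kinase data on this tree.
`kinomeviz` turns that figure into a reproducible computation: a plain-text
annotation program (KR syntax) in, a deterministic vector image out.

This vignette explains the data model, the semantics the package commits
to, and the choices made where the conventions of the field leave the
design open.

# The leaf registry

A registry row describes one tree leaf: Manning name, synonyms, full
protein name, UniProt ID, IPI, group/family/subfamily, full protein
sequence and kinase-domain sequence. Two peculiarities of the kinome give
the leaf arithmetic its shape:

* eight **atypical kinases** (BCR, FASTK, G11, H11, TAF1, TAF1L, A6, A6r)
  do not appear on the typical tree;
* thirteen kinases carry **two distinct catalytic domains** (JAK1, JAK2,
  JAK3, MSK1, MSK2, RSK1–RSK4, Tyk2, GCN2, SPEG, Obscn) and therefore own
  two leaves, the second tagged `~b`.

So 518 genes yield 518 − 8 + 13 = 523 typical-tree leaves
(`build_leaf_set()` checks the arithmetic; `leaf_names()` applies it to a
registry). The status of the atypical kinases is genuinely ambiguous in the
field's practice: they are absent from the classic tree, yet extended
renderings carry a small atypical sub-tree. The package resolves this by
letting registries *carry* atypical entries, flagged `is_atypical`, which
receive coordinates only on template 2; `select_template()` forces
template 2 whenever a document annotates one. Typeset sources often print
the second-domain tag with a tilde-operator glyph (`∼b`); it is normalized
to ASCII `~b` on every input path.

Identifier resolution mirrors search-box behaviour: exact, case-insensitive
matching for Manning names, UniProt IDs, IPIs and classification labels;
substring, case-insensitive matching for full protein names and synonyms —
and a name query also reaches the full name and synonyms, so searching the
full protein name of a kinase finds it. Unknown identifiers resolve to an
empty result rather than an error; hard failure is deferred to render
time so batch uploads degrade gracefully.

# The KR language

KR is a line-oriented command language. The one semantic rule that shapes
everything else is **statefulness**: `color` (default black, `(0,0,0)`)
and `scale` (default 10) persist across annotations — and into the legend
— until redefined. `at <kinase>` opens an annotation context; each
drawable command (`text`, `circle`, `circle-filled`, `circle-lined`,
`polygon <n>`, `polygon-filled <n>`, `polygon-lined <n>`) emits one
annotation with the current state.

Decisions the language description leaves open, and what this package
does:

* **Predefined colors.** The named colors map to: black (0,0,0), red
  (1,0,0), green (0,0.67,0), blue (0,0,1), yellow (1,1,0), magenta
  (1,0,1), cyan (0,1,1), orange (1,0.65,0), pink (1,0.75,0.8), grey
  (0.5,0.5,0.5). Green and orange follow the RGB values used in the
  worked examples of the language (`color 0 0.67 0`, `color 1 0.65 0`);
  the rest are the conventional primaries.
* **Scale is an integer** (parse error otherwise), matching the language
  table's "Integer (default 10)".
* **Text payloads** run from the first character after the command's space
  to the end of the line, are symbol-expanded, and must be at most 25
  glyphs *after* expansion — counting glyphs, not bytes. Legend text is
  exempt: the canonical legend example contains a 39-character string, so
  the limit demonstrably applies to kinase annotations only.
* **`boxed`/`underlined`** must appear on the line immediately following
  the text they decorate; anywhere else they are parse errors. Both may
  stack.
* **`kinase-name`** is accepted as sugar for `text <current target>`; the
  "annotate with the kinase's name" option is not a distinct drawable.
* **Comments.** `#`-prefixed lines are accepted as comments and blank
  lines are ignored — a documented extension; the base language defines
  neither.
* **Symbol codes.** All 43 bracketed codes of the special-symbol table
  (Greek letters, set/comparison operators, card suits) expand to their
  Unicode glyphs; unknown codes warn and stay verbatim, and expansion is
  idempotent.

Serialization (`serialize_kr()`) emits the minimal program: `at` only when
the target changes, `color`/`scale` only when the state changes. The
parse ∘ serialize round trip is the identity on documents; the test suite
property-checks this on randomly generated documents.

# Layout

Coordinates are expressed with the **origin at the top-left, y increasing
downward, in points** (1/72 inch) — the convention of SVG and of most
raster formats; the PostScript writer flips y internally.

The classic kinome tree is a piece of artwork whose exact leaf coordinates
are not published, so the package does not attempt to reproduce it.
Instead:

* `read_template()` loads user-supplied coordinate files (e.g. captured
  from artwork the user has rights to): a `#canvas` header, then
  `leaf<TAB>x<TAB>y` rows, validated against the canvas.
* `generate_layout()` produces a deterministic, seed-free schematic
  layout from the classification: leaves sorted by group, family,
  subfamily, name — so groups and families are contiguous runs —
  arranged either as a rectangular dendrogram column or on a circle, with
  uniform branch geometry. Determinism is structural (sorting), so
  permuting registry rows cannot move group boundaries. A configurable
  minimum inter-leaf spacing (default 1 pt) is enforced; a canvas too
  small for it is a layout error, not a silent overlap.
* Template 2 places atypical entries in a detached block anchored at the
  bottom left, mirroring the conventional placement of the atypical
  sub-tree; its coordinate set is a strict superset of template 1's.

The default canvas is 900 × 1250 pt, which gives 523 leaves ≈ 2.2 pt of
vertical spacing in the rectangular style — legible at scale-10 labels
only after zooming, as with any full-kinome figure.

# Rendering

The render plan fixes z-order before any drawing happens: backbone, then
annotations sorted by non-increasing scale (ties keep document order),
then remainder labels, then the legend. Drawing big-first means small
annotations are never hidden, and making the ordering part of the *plan*
rather than the drawing keeps every backend identical.

Scale needs units the language never states. The package uses: for
shapes, **scale = diameter of the bounding circle in points**; for text,
**scale = font size in points**. This makes a scale-10 shape and the fixed
"black, size 10" remainder labels visually commensurate. Polygons are
regular, circumscribed by the scale-diameter circle, one vertex pointing
up (`polygon 4` is a square standing on a corner). Stroke width for
outlined variants, underlines and boxes is fixed at 0.75 pt.

Two writer families produce the output:

* **PostScript and SVG** are emitted by the package's own writers. This
  is what makes renders byte-identical across runs — R's built-in
  `postscript()`/`svg()` devices embed creation timestamps, which would
  break that guarantee. The PostScript writer centers, boxes and
  underlines text using the interpreter's own `stringwidth`, so its text
  metrics are exact for the font the viewer resolves; the SVG writer uses
  `text-anchor="middle"` for centring and a 0.6 em-per-glyph estimate for
  box and underline extents (and for legend flow). Non-ASCII glyphs are
  written as UTF-8; SVG viewers render them reliably, classic PostScript
  interpreters may not — SVG is the recommended vector format when symbol
  codes are used.
* **PDF, PNG, JPG and TIFF** replay the same plan through the
  corresponding R graphics device (raster formats at a configurable DPI,
  default 300). These are faithful but not guaranteed byte-stable, since
  device metadata is outside the package's control.

The legend flows left-to-right from its anchor; `space` inserts a gap of
0.4 × the current element scale, `next-line` drops to a new baseline of
1.3 × the tallest element of the line, and `legendBox` draws a rectangle
with 5 pt padding around the union of element extents. Remainder labels
are centered on their leaf coordinates; no collision avoidance is
attempted, matching the tool tradition this package follows.

# Binding profiles

The affinity-table contract: rows are kinases (Manning name, UniProt or
IPI — resolved through the registry in that order, first hit wins,
unresolved rows reported and skipped), columns are inhibitors, cells are
positive numbers in nM or µM where *lower means stronger*, `-` means
tested with no observed effect, `NA` means untested. A threshold given in
table units reclassifies every value **at or above it** as no-effect — so
with the conventional 3 µM cutoff, only affinities strictly below 3 µM
draw as binders.

No published formula maps affinity to circle size, only the convention
"the bigger the circle, the higher the affinity". Because affinities span
orders of magnitude, the package log-encodes:

$$ s(v) = s_\min + (s_\max - s_\min)\,
   \frac{\log_{10} v_c - \log_{10} v}{\log_{10} v_c - \log_{10} v_f} $$

clamped to $[s_\min, s_\max]$ (defaults 6–36 pt), with $v_c$ the threshold
(or the column maximum) and $v_f$ the column minimum, rounded to the
integer scales KR requires. Only monotonicity is treated as normative:
equal values get equal circles, and a lower value never gets a smaller
circle (rounding can produce ties). No-effect circles are fixed at 4 pt
grey — deliberately below $s_\min$ so they cannot be confused with weak
binders.

Combination plots partition the inhibitors into *consecutive* column
groups of at most 6 (the input column order is the user's grouping
choice), assign each inhibitor a color from the fixed cycle red, blue,
green, orange, magenta, cyan, and drop the grey no-effect circles whenever
a group holds more than one inhibitor — grey circles from several
inhibitors on one leaf would be uninterpretable. Every generated document
is ordinary KR: it serializes, re-parses and can be hand-edited.

# Sequence search

`search_sequence()` aligns a protein query locally (Smith–Waterman)
against every registry full sequence — full sequences deliberately, so
features outside the kinase domain can still identify the protein; a
`use_domain` switch restricts to kinase domains, skipping atypical entries
whose domain sequence is empty. Parameters are the standard protein
defaults: BLOSUM62, gap open 11, gap extend 1. The alignment engine is
`Biostrings::pairwiseAlignment()`; the test suite cross-checks its scores
and rankings against an independent affine-gap dynamic-programming oracle
written for that purpose.

Hits are ranked by an E-value computed with the Karlin–Altschul
approximation ($\lambda = 0.267$, $K = 0.041$, the standard gapped
BLOSUM62 11/1 constants) over the total residue count of the registry.
This is an approximation by design: the ranking (and the reported percent
identity/similarity, both computed over the aligned region including gap
positions, so identity ≤ similarity always) is the contract, not the
absolute E-value of any particular search program. Self-queries always
rank their own entry first at 100% identity.

# The synthetic data generators

`simulate_registry()` emulates a full-scale registry: the real 8 atypical
and 13 dual-domain names (plus a handful of familiar typical-kinase names
so worked examples resolve), synthetic `KIN###` symbols for the rest,
group/family labels cycled over the eight conventional groups, and random
amino-acid sequences (default length 80 — long enough for alignment
statistics to separate self-hits from noise, short enough to keep test
runtimes in seconds). With the defaults (518 genes, 8 atypical, 13 dual)
it reproduces the 523-leaf arithmetic exactly. `simulate_binding_table()`
draws a panel with ~35% binders (log-uniform affinities over 0.001–10 in
table units), ~35% tested-no-effect and ~30% untested cells — proportions
typical of published selectivity panels, where most kinase–inhibitor pairs
are either inactive or untested.

What the generators do *not* emulate: real sequence homology structure
(sequences are i.i.d. random, so there are no families of similar
sequences and no marginal alignment decisions), real synonym vocabularies,
and the true tree geometry. Tests passing on synthetic data therefore
demonstrate the mechanics — arithmetic, parsing, ordering, encoding,
determinism — not biological fidelity of any particular layout.

# Numerical and degenerate-input choices

* Colors are validated to $[0,1]^3$ at parse time; serialization prints
  up to 15 significant digits, which round-trips every value entered as a
  decimal literal.
* Generated layouts snap coordinates to a 10⁻⁶ pt grid so written
  template files re-read bit-exactly.
* Empty documents serialize to empty text and render to a backbone-only
  image; an empty template is valid (it simply cannot host annotations);
  a registry with a header and no rows is a valid empty registry.
* A binder column with a single distinct value (or a floor equal to the
  ceiling) maps every binder to $s_\max$.
* All file writes go through a temp-file-and-rename so a crash never
  leaves a half-written output.

The test suite sizes are deliberate: 500 random documents for the
round-trip property, a 1,000-entry registry for the resolution oracle, 20
sequences of length 150 for the alignment oracle — large enough to
exercise the invariants broadly, small enough that the whole suite runs in
well under a minute on one CPU.

# Known limitations

* The schematic layout is *not* the classic kinome artwork; figures meant
  to overlay that artwork need a user-supplied coordinate template.
* Remainder labels and annotations can overlap; no collision avoidance is
  performed.
* PostScript output of non-Latin glyphs depends on the interpreter's font
  handling; use SVG for symbol-heavy annotations.
* E-values are approximate; do not compare them numerically with BLAST or
  FASTA output.
* Raster/PDF outputs are not guaranteed byte-stable across R versions.
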