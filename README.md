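# kinomeviz

Annotate the human protein kinome tree programmatically.

The human kinome comprises 518 protein kinases, classically drawn as a
phylogenetic tree clustered by catalytic-domain similarity into groups
(TK, TKL, STE, CK1, AGC, CAMK, CMGC, Other), families and subfamilies.
Studies of kinase biology and especially of inhibitor selectivity routinely
project large panels of per-kinase data onto this tree — but assembling such
figures by hand is slow and error-prone. `kinomeviz` automates it: you
describe annotations in a small line-oriented command language (KR syntax)
and the package deterministically overlays text and shape annotations,
legends and inhibitor binding profiles on a schematic kinome tree, written
as PostScript, SVG, PDF, PNG, JPG or TIFF.

It is aimed at chemical biologists, structural biologists and computational
groups who want reproducible, scriptable kinome figures from affinity
panels, screening results or any per-kinase annotation.

## What is in the box

* **Kinase leaf registry.** One entry per tree leaf: Manning name,
  synonyms, full protein name, UniProt ID, IPI, group/family/subfamily and
  protein sequences. Eight atypical kinases (BCR, FASTK, G11, H11, TAF1,
  TAF1L, A6, A6r) are absent from the typical tree, and thirteen kinases
  with two distinct catalytic domains (JAK1/2/3, MSK1/2, RSK1–4, Tyk2,
  GCN2, SPEG, Obscn) contribute a second leaf tagged `~b`, so a full-scale
  registry exposes 518 − 8 + 13 = **523** typical-tree leaves. Identifier
  resolution, batch lists (comma/semicolon/newline separated) and a
  deterministic synthetic-registry generator are included.
* **KR language.** `at <kinase>` opens an annotation; `color` (RGB in
  [0, 1] or a predefined name) and `scale` (integer, default 10) persist
  until redefined; `text` (≤ 25 glyphs, with `[alpha]`-style special-symbol
  codes), `circle`/`circle-filled`/`circle-lined` and
  `polygon[-filled|-lined] <n>` draw; `boxed`/`underlined` decorate the
  preceding text; `remainder` labels every non-annotated kinase in black at
  size 10; `legend` ... `legendBox` builds a legend. Parsing, validation
  and lossless serialization are all exposed.
* **Layout.** Coordinate-template files (TSV, top-left origin, points) and
  a deterministic schematic dendrogram generator ordered by
  group → family → subfamily; template 2 adds the atypical sub-tree at the
  bottom left and is selected automatically whenever an atypical kinase is
  annotated.
* **Rendering.** Annotations are drawn in decreasing scale order so large
  shapes never hide small ones. PostScript and SVG come from the package's
  own writers and are byte-identical across runs; PDF/PNG/JPG/TIFF replay
  the same plan through R's graphics devices.
* **Binding profiles.** Tab-separated affinity matrices (Kd/IC50 in nM or
  µM; `-` = tested with no effect, `NA` = untested, optional no-effect
  threshold) become per-inhibitor plots with log-scaled circle sizes
  (stronger binding = bigger circle, no effect = small grey circle) or
  combination plots of up to 6 inhibitors in distinct colors.
* **Sequence search.** Smith–Waterman local alignment of a protein query
  against every registry sequence (BLOSUM62, gap 11/1), ranked by an
  E-value approximation with percent identity/similarity.
* **CLI.** `inst/cli/kr.R` exposes `render`, `profile`, `fixture` and
  `search` subcommands over the same functions.

## Worked example

```r
library(kinomeviz)

kr  <- system.file("extdata", "quickstart.kr", package = "kinomeviz")
doc <- read_kr(kr)
doc
#> <kr_document> 3 annotation(s), 9 legend item(s), boxed legend
#>   at PINK1        polygon-filled 3 scale 30 color (1, 0, 1)
#>   at MPSK1        circle-lined scale 20 color (0.92, 0.08, 0.08)
#>   at BIKE         text "BIKE" scale 10 color (0, 0.67, 0)
```

Three kinases, three annotation types: a magenta triangle of diameter 30 pt
on PINK1, a red circle with a black outline on MPSK1, and a green "BIKE"
label — note that `color` and `scale` set before each drawable persist
until redefined. Render it on a generated schematic layout:

```r
registry <- simulate_registry()      # deterministic synthetic full-scale registry
registry
#> <kinase_registry> 531 entries (8 atypical, 13 second-domain), 523 leaves on the typical tree

template <- generate_layout(registry, template_id = select_template(doc, registry))
plan <- plan_render(doc, template)
plan
#> <render_plan> 900 x 1250 pt, 3 annotation(s), 0 remainder label(s), 5 legend element(s)
render_kinome(plan, "tree.svg")      # byte-identical on every run
render_kinome(plan, "tree.ps")
```

The plan draws PINK1 (scale 30) first and BIKE (scale 10) last, so smaller
annotations stay visible. A binding-profile example, using the synthetic
panel shipped with the package (10 kinases × 3 inhibitors, µM units, 3 µM
no-effect threshold):

```r
aff <- system.file("extdata", "affinity_synthetic.tsv", package = "kinomeviz")
tb  <- read_binding_table(aff, units = "uM", threshold = 3)
tb
#> <binding_table> 10 kinase(s) x 3 inhibitor(s), units uM, no-effect threshold 3 uM
#>   binders 4, no-effect 14, untested 12

encode_profile(tb, "Inhib03", registry = registry)
#> <kr_document> 7 annotation(s), 9 legend item(s), boxed legend
#>   at KIN311       circle-filled scale 19 color (1, 0, 0)
#>   at KIN218       circle-filled scale 20 color (1, 0, 0)
#>   at KIN014       circle-filled scale 36 color (1, 0, 0)
#>   at KIN064       circle-filled scale 4 color (0.5, 0.5, 0.5)
#>   ...
```

The three affinities below the threshold (0.36, 0.30 and 0.022 µM) map to
red circles of 19, 20 and 36 pt — the log-scaled encoding gives the
strongest binder the largest circle — while tested-but-ineffective kinases
get the fixed 4 pt grey circle and untested cells draw nothing. The result
is an ordinary KR document: serialize it with `write_kr()`, edit it, parse
it back.

From a shell, the same pipeline is:

```sh
Rscript inst/cli/kr.R render --in inst/extdata/quickstart.kr --out tree.svg
Rscript inst/cli/kr.R profile --in inst/extdata/affinity_synthetic.tsv \
    --units uM --threshold 3 --per-plot 1 --outdir plots
```

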