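---
title: "Harmonizing brain-atlas labeling schemes through structural anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing brain-atlas labeling schemes through structural anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasont)
```

## The problem

Neuroimaging atlases parcellate the brain on different principles — surface
morphology (gyri and sulci), cytoarchitecture (Brodmann areas), volumetric
tracing — and each ships its own label vocabulary: the Talairach Daemon's
five-level dotted labels, FreeSurfer/Desikan-Killiany's abbreviated gyral
labels (`ctx-lh-postcentral`), AAL's underscore labels
(`Frontal_superior_right`), and NeuroLex's non-lateralized plain-English
terms. Because the parcellations delimit different entities at different
granularities, there is no one-to-one mapping between label sets; data
annotated in one scheme cannot be compared with data annotated in another on
labels alone. atlasont takes the symbolic route to this concordance problem:
every atlas label is *bound* to a class of a structural anatomy ontology,
and correspondence between labels is recovered by walking the ontology's
relations.

## The ontology model

An ontology is a set of classes plus typed assertions. Each class carries a
preferred name, synonyms, a laterality (`left`/`right`/`unpaired`), and a
category: `material_structure` (gyri, gray matter, tracts, nuclei) or
`anatomical_space` (sulci, ventricle horns). Three structural relations are
modeled:

* `is_a` — taxonomy (`Right superior frontal gyrus` *is_a* `Superior
  frontal gyrus`);
* `part_of` — transitive partonomy;
* `regional_part_of` — spatially delimited regional parts, a transitive
  sub-relation of `part_of`: its assertions count toward the `part_of`
  closure. `has_regional_part` is just the inverse reading
  (`descendants(ont, x, "regional_part_of")`), never a stored kind.

Constitutional parts (2-D boundaries, immaterial constituents) are not
modeled; the atlas vocabularies only exercise regional parts. Each relation
family (`is_a`; `part_of` including `regional_part_of`) is kept irreflexive,
antisymmetric and acyclic *at insertion time*: `assert_structural()` rejects
an edge whose addition would close a cycle and reports the offending path.
The source vocabularies never state this requirement, but machine reasoning
over a partonomy requires it, so it is enforced rather than merely checked.

Identifiers are namespace-prefixed lowercase slugs of the preferred name
(`nfma:brodmann-area-6-of-right-superior-frontal-gyrus`). This makes ids
deterministic, diff-able and stable under serialization; name lookup is
case-insensitive with internal whitespace collapsed because atlas sources
vary in casing.

## Reconciling cytoarchitecture and morphology

A Talairach label such as

```
Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6
```

names an entity neither parcellation holds on its own: the region where
Brodmann area 6 overlaps the gray matter of the right superior frontal
gyrus. `create_intersection_class()` reifies that overlap as a dedicated
class with exactly three assertions — it `is_a` `Segment of Brodmann area
6` (auto-created) and is a `regional_part_of` both the Brodmann-area class
and the gyral gray-matter class. Applied across the fixture this gives the
gray matter of the superior frontal gyrus five Brodmann regional parts
(areas 6, 8, 9, 10, 11) and Brodmann area 6 five gyral overlaps:

```{r}
ont <- build_fixture_ontology()
vapply(descendants(ont, "Brodmann area 6", "regional_part_of"),
       function(id) class_name(ont, id), character(1))
```

Three further patterns complete the modeling vocabulary. `lateralize()`
derives `Left`/`Right` subclasses (`is_a` the unpaired class) without
copying structural knowledge — sided facts are reached through `is_a`
ancestor queries. `create_sulcal_segment()` disambiguates sulci: the sulcus
itself is an anatomical space, the cortex buried in it a material `Sulcal
segment of <gyrus>` that is a regional part of the gyrus; the space/segment
association is kept as a dedicated adjacency record rather than a `part_of`
edge, since a space is not a part of a material gyrus (the sources are
ambiguous here; this was a deliberate choice). `partition_tract()` enforces
*exclusive terms*: annotating both a whole tract and one of its segments
with the same term corrupts machine processing, so segment names must be
unique and distinct from the tract name, and `validate_ontology()` flags
later reuse.

## Label grammars and normalization

`parse_talairach()` enforces the five-level grammar (hemisphere, lobe,
gyrus, tissue, cell), accepting `*` wildcards per level (the daemon emits
partial labels) but requiring all five components and at least one
non-wildcard. `normalize_label()` applies per-scheme splitting (hyphens for
DK, underscores for AAL, whitespace otherwise), lowercases, expands
abbreviations through a per-scheme table, and extracts side words into a
laterality attribute. The shipped tables are seeded from the abbreviations
the schemes are known to use (`ctx`, `lh`, `rh`, `wm`, AAL's
`Sup`/`Inf`/`Mid`, single-letter `R`/`L`) and are extensible via TSV or YAML
config; unknown abbreviation-like tokens pass through verbatim with a
warning record rather than an error, since failing on an unrecognized token
would make whole label files unreadable. The stopwords *of*, *the*, *area*
are retained by normalization (keeping it lossless) and dropped only at
lexical matching time.

## Semi-automatic mapping and curation

`generate_candidates()` proposes classes for a label by four methods with
fixed precedence:

1. **exact** — the unexpanded label text equals a preferred name
   (case-insensitive);
2. **synonym** — it equals a recorded synonym;
3. **abbreviation** — the abbreviation-expanded text equals a name or
   synonym;
4. **lexical** — all label tokens occur among the class-name tokens or vice
   versa, scored by Jaccard overlap (threshold 0.5; the sources name the
   method but no metric, so the simplest symmetric one was chosen).

Mapping is deliberately *semi*-automatic: `apply_curation()` creates
bindings only from curator decisions, may auto-accept single unambiguous
exact matches when explicitly enabled, never auto-accepts ties, honors
curator overrides (a decision for a class not among the candidates) with a
warning, and rejects two decisions accepting different classes for one
`(scheme, label)` pair. Bindings are unique per `(scheme, label)`, live on
specific classes, and are not inherited down `is_a`. One atlas label binding
to a union of classes is not supported — the model forbids it until a
concrete atlas demands it.

## Connectivity and pathway inference

Connectivity kinds span three granularities: neuron level (`innervates`,
`synapses_with` — stored but excluded from region-level inference), tract
level (`projects_to` / `projects_from`, with `terminate_in` /
`originate_in` accepted as aliases), and region level (`sends_output_to` /
`receives_input_from`, declared subproperties of the tract projections, plus
the ternary `has_pathway(A, B, via = tract)`). Endpoints must be material
structures; anatomical spaces carry no connectivity.

The derivation rule in `derive_pathways()` is the literal reading of the
ternary definition: for every tract `T` with `projects_from(T, A)` and
`projects_to(T, B)`, infer `sends_output_to(A, B)` and
`has_pathway(A, B, via = T)` — the full origin-by-termination product — and
then complete the duality `sends_output_to(A, B)` iff
`receives_input_from(B, A)`. Derived edges are flagged
`provenance = "inferred"` so curators can retract over-generation for
multi-origin tracts; derivation never overwrites asserted edges and is
idempotent. Whether tract-level projections should propagate up the tract
partonomy (segment to whole tract) is left unimplemented pending a use case
that needs it.

## Cross-atlas correlation

`correlate_label()` resolves the source label through its binding, then
searches for classes bound in the target scheme: the identical class first
(`identity`), then transitive `part_of` ancestors (`up`), then descendants
(`down` — one coarse label legitimately correlates to many finer ones),
with `is_a` edges joining the search only when the target scheme is
non-lateralized (NeuroLex) or the pure `part_of` search fails. Shortest
paths are returned per target label; ties are broken deterministically
(breadth-first depth, `part_of` edges claim parents before `is_a` ones,
then name order), so the canonical superior-frontal chain comes out as the
sources draw it — one `part_of` hop to DK, two to AAL, and `is_a` last to
NeuroLex:

```{r}
tal <- "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6"
res <- correlate_label(ont, tal, "talairach", "aal")
res[[1]]
```

Granularity levels (`cytoarchitectural_area` < `cortical_gray_matter` <
`gyrus` < `lobe` < `hemisphere`) are assigned from naming patterns alone;
names outside the patterns fall through to `other`. `overlap_query()`
answers annotation-style questions (which parts of the inferior temporal
gyrus are in Brodmann area 20, and does either extend beyond the other) via
closure intersection, and `annotate_table()` applies binding lookup,
granularity and ancestor expansion to whole label tables, flagging unmapped
rows instead of dropping them.

## Fixtures: what the stated world does and does not establish

`build_fixture_ontology()` reconstructs the worked examples exactly — the
frontal partonomy, both Brodmann intersection families, the right-hemisphere
chain, the four-scheme binding star, the SLF I projection facts, the
corticospinal partition, and the middle-frontal sulcal segments — so every
worked-example test runs against it without downloads. Two items the source
figures do not enumerate in text are shipped as clearly synthetic
placeholders: the five corticospinal segment names (brain-to-cord ordering)
and the putamen's edge list (cortex in, globus pallidus out). Tests
touching those assert structure (non-empty inputs/outputs, partition
behavior), never the placeholder content. NeuroLex identifiers are likewise
synthetic (`nlx:synthetic-NNNN`).

`random_ontology()` generates property-test worlds: classes on layers with
every edge pointing strictly shallower, so acyclicity holds by
construction; defaults (100 classes, 6 layers, 1.5 `part_of`-family parents
per class of which a third are regional, 0.3 `is_a` parents, 25 labels) give
sparse, realistically shallow partonomies. The generator returns its own
ground truth — transitive closures computed by topological dynamic
programming, an algorithm independent of the breadth-first reasoner it
tests — and a label table with known true classes under four perturbations
(exact, casing, synonym, abbreviation). A green closure or recovery test
therefore establishes agreement with an independent oracle on layered DAGs
and recoverability of *systematic* label variation; it does not establish
anything about free-text labels, misspellings, or real atlas releases
(reconstructing the full DK-34 or AAL-90 binding tables is out of scope).

## Numerical and determinism choices

* All query output is deterministically ordered (BFS depth, then preferred
  name; canonical sorts in serialization), so CLI output and saved bundles
  are byte-reproducible — two saves of one ontology are identical files.
* The lexical threshold is 0.5 Jaccard; candidates scoring exactly 1 by
  token identity but differing as strings remain `lexical`, not `exact`.
* Degenerate inputs: empty tract partitions are no-ops; labels consisting
  only of side markers are parse errors; a label naming both sides gets
  laterality `unpaired` plus a warning record; empty annotation tables
  return empty tables.
* The serialization is a restricted, canonically ordered Turtle dialect
  (two namespaces, prefixed names, quoted literals; ternary `has_pathway`
  reified as `stmt:cNNNN` nodes numbered in canonical order) with TSV
  sidecars for bindings and connectivity, which curators edit by hand. No
  R RDF tooling ships in this stack, so the dialect is parsed by the
  package itself and deliberately kept small.

## Limitations

Correlation is symbolic: it reports how labels relate through anatomical
structure, not how well their spatial extents agree — no coordinate-based
concordance is computed. The Talairach grammar maps the full five-level
entity only; a gyrus-level partial label correlates through its cell-level
class, not directly at the gyrus. OWL semantics, SPARQL endpoints, and the
full reference anatomy ontology are all out of scope: the package is a
self-contained working model of the harmonization machinery.
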