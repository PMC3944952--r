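# atlasont

Ontology-based harmonization of human brain-atlas labeling schemes.

Brain atlases parcellate the cortex on incompatible principles — surface
morphology, cytoarchitecture, volumetric tracing — and label their regions
with incompatible vocabularies: the Talairach Daemon emits five-level dotted
labels (`Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray
Matter.Brodmann area 6`), FreeSurfer's Desikan-Killiany scheme uses
abbreviated gyral labels (`ctx-rh-superiorfrontal`), AAL uses underscore
labels (`Frontal_superior_right`), and NeuroLex carries non-lateralized
English terms (`Superior frontal gyrus`). There is no one-to-one mapping
between these label sets (the *brain atlas concordance problem*), so data
annotated in different schemes cannot be compared on labels alone.

atlasont harmonizes the schemes symbolically. Atlas labels are bound to
classes of a structural anatomy ontology with taxonomic (*is_a*) and
partonomic (*part_of*, its sub-relation *regional_part_of*) relations, and
correspondence is recovered by walking those relations. The four labels
above all resolve to one chain:

```
Brodmann area 6 of right superior frontal gyrus   (Talairach)
  part_of  Gray matter of right superior frontal gyrus   (DK)
  part_of  Right superior frontal gyrus                  (AAL)
  is_a     Superior frontal gyrus                        (NeuroLex)
```

The package is aimed at neuroinformatics developers and curators who need
to translate labels between schemes, annotate tabular imaging results with
anatomical context, or maintain the ontology content itself. It provides:
label grammars with abbreviation expansion and laterality extraction;
semi-automatic term mapping (exact / synonym / abbreviation / lexical) with
a manual-curation workflow; transitive partonomy/taxonomy reasoning with
integrity validation; the modeling patterns that reconcile parcellations
(Brodmann-by-gyrus intersection classes, lateralization, sulcal segments of
gyri, exclusive-term tract partitions); white-matter connectivity relations
with ternary pathway inference (`has_pathway(A, B, via = tract)`); a
deterministic plain-text serialization (Turtle dialect + TSV); and a CLI.

## Worked example

```r
library(atlasont)
ont <- build_fixture_ontology()
ont
#> <ontology> 75 classes, 80 structural assertions, 9 bindings, 4 connectivity assertions

tal <- "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6"
correlate_label(ont, tal, "talairach", "aal")[[1]]
#> <correlation talairach 'Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6' -> aal 'Frontal_superior_right'> direction=up, 2 hop(s)
#>   nfma:brodmann-area-6-of-right-superior-frontal-gyrus
#>   --part_of--> nfma:gray-matter-of-right-superior-frontal-gyrus
#>   --part_of--> nfma:right-superior-frontal-gyrus
```

The Talairach label resolves to its cytoarchitectural intersection class and
reaches the AAL-bound gyrus two `part_of` hops up: the labels name nested
entities at different granularities, not the same region. Against NeuroLex
the search is allowed to take `is_a` (NeuroLex is non-lateralized) and ends
`--is_a--> nfma:superior-frontal-gyrus`.

Pathway inference derives region-level connectivity from tract projections
(here: the dorsal segment of the superior longitudinal fasciculus, SLF I,
projecting from Brodmann area 6 of the superior frontal gyrus to Brodmann
area 5 of the superior parietal lobule):

```r
connectivity_table(derive_pathways(ont), kind = "has_pathway")
#>                                          subject        kind                                           object                                                     via provenance
#> 1 nfma:brodmann-area-6-of-superior-frontal-gyrus has_pathway nfma:brodmann-area-5-of-superior-parietal-lobule nfma:dorsal-segment-of-superior-longitudinal-fasciculus   inferred
```

The `inferred` flag separates derived edges from asserted ones so curators
can retract over-generation. The same machinery is exposed on the command
line (`inst/cli/atlasont`):

```sh
atlasont correlate --from talairach --to aal --json "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6"
atlasont validate            # "0 violations" on the fixture
atlasont map --scheme neurolex labels.txt
```

See `vignettes/atlas-harmonization.Rmd` for the model, the matching
methods, the derivation rule, and the design choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end surface from scratch — builds and
validates the fixture ontology, parses the five-level Talairach label, runs
the four-scheme correlation star, derives and round-trips connectivity, and
checks the reasoner against generator-side closure truth on a seeded random
ontology — then writes the JSON results manifest to `--out`.
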