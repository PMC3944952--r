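test_that("classes are retrievable by id, name and synonym, case-insensitively", {
  ont <- ontology()
  ont <- add_class(ont, anatomical_class(
    "Gray matter of superior frontal gyrus"))
  id <- make_class_id("Gray matter of superior frontal gyrus")
  expect_identical(resolve_class(ont, "Gray matter of superior frontal gyrus"), id)
  expect_identical(resolve_class(ont, "gray  MATTER of superior frontal gyrus"), id)
  expect_identical(resolve_class(ont, id), id)

  ont <- add_class(ont, anatomical_class(
    "Temporal horn of lateral ventricle",
    synonyms = "Inferior horn of the lateral ventricle",
    category = "anatomical_space"))
  expect_identical(resolve_class(ont, "inferior horn of the lateral ventricle"),
                   make_class_id("Temporal horn of lateral ventricle"))
  expect_identical(resolve_class(ont, "no such structure"), NA_character_)

  ont <- add_class(ont, anatomical_class("Putamen"))
  expect_length(ont$classes, 3L)
})

test_that("duplicate names and ids are rejected, naming the conflict", {
  ont <- add_class(ontology(), anatomical_class("Putamen"))
  err <- expect_error(
    add_class(ont, anatomical_class("PUTAMEN")),
    class = "atlasont_duplicate_class")
  expect_match(conditionMessage(err), "Putamen")
  expect_error(
    add_class(ont, anatomical_class("Other name", id = make_class_id("Putamen"))),
    class = "atlasont_duplicate_class")
  expect_error(anatomical_class("Putamen", synonyms = "putamen"),
               class = "atlasont_bad_name")
})

test_that("structural assertions enforce irreflexivity and acyclicity", {
  ont <- ontology()
  for (x in c("A structure", "B structure", "C structure")) {
    ont <- add_class(ont, anatomical_class(x))
  }
  expect_error(assert_structural(ont, "A structure", "part_of", "A structure"),
               class = "atlasont_irreflexive")

  ont <- assert_structural(ont, "A structure", "part_of", "B structure")
  err <- expect_error(
    assert_structural(ont, "B structure", "part_of", "A structure"),
    class = "atlasont_cycle")
  expect_identical(err$path, make_class_id(c("A structure", "B structure",
                                             "A structure")))
  # the regional_part_of sub-relation counts toward the part_of cycle check
  ont <- assert_structural(ont, "B structure", "regional_part_of", "C structure")
  expect_error(assert_structural(ont, "C structure", "part_of", "A structure"),
               class = "atlasont_cycle")
  # but is_a is an independent family
  ont2 <- assert_structural(ont, "B structure", "is_a", "A structure")
  expect_equal(nrow(ont2$structural), 3L)

  expect_error(assert_structural(ont, "A structure", "part_of", "Nowhere"),
               class = "atlasont_unknown_class")
})

test_that("re-asserting an edge is idempotent down to the serialized bytes", {
  ont <- fixture_ont()
  e <- ont$structural[5L, ]
  ont2 <- assert_structural(ont, e$subject, e$relation, e$object)
  d1 <- file.path(tempdir(), "idem1"); d2 <- file.path(tempdir(), "idem2")
  save_ontology(ont, d1)
  save_ontology(ont2, d2)
  expect_identical(readLines(file.path(d1, "ontology.ttl")),
                   readLines(file.path(d2, "ontology.ttl")))
})

test_that("fixture ancestors climb every granularity level of the Talairach label", {
  ont <- fixture_ont()
  anc <- nm(ont, ancestors(ont, "Brodmann area 6 of right superior frontal gyrus",
                           "part_of"))
  expect_true(all(c("Right superior frontal gyrus", "Right frontal lobe",
                    "Right cerebral hemisphere") %in% anc))
  # leaf class upward-only: no descendants
  expect_length(descendants(ont, "Right cerebral hemisphere", "is_a"), 0L)
})

test_that("ancestors/descendants match naive DFS reachability on a random DAG", {
  fx <- random_ontology(n_classes = 200, n_layers = 8, seed = 42)
  ont <- fx$ontology
  edges <- part_family_edges(ont)
  isa_edges <- ont$structural[ont$structural$relation == "is_a", , drop = FALSE]
  for (id in names(ont$classes)) {
    expect_setequal(ancestors(ont, id, "part_of"), dfs_reach(edges, id, "up"))
    expect_setequal(descendants(ont, id, "part_of"), dfs_reach(edges, id, "down"))
    expect_setequal(ancestors(ont, id, "is_a"), dfs_reach(isa_edges, id, "up"))
  }
})

test_that("regional_part_of closure is contained in part_of closure and dual", {
  fx <- random_ontology(n_classes = 150, seed = 7)
  ont <- fx$ontology
  for (id in names(ont$classes)) {
    expect_true(all(ancestors(ont, id, "regional_part_of") %in%
                      ancestors(ont, id, "part_of")))
  }
  # descendants(x) contains y  <=>  ancestors(y) contains x
  anc <- lapply(setNames(nm = names(ont$classes)),
                function(id) ancestors(ont, id, "part_of"))
  for (x in names(ont$classes)) {
    desc <- descendants(ont, x, "part_of")
    dual <- names(anc)[vapply(anc, function(a) x %in% a, logical(1L))]
    expect_setequal(desc, dual)
  }
})

test_that("deterministic ordering: BFS depth first, then preferred name", {
  ont <- fixture_ont()
  anc <- ancestors(ont, "Brodmann area 6 of right superior frontal gyrus",
                   "part_of")
  # depth 1: the two regional wholes, alphabetical by name
  expect_identical(nm(ont, anc[1:2]),
                   c("Gray matter of right superior frontal gyrus",
                     "Right Brodmann area 6"))
  expect_identical(anc, ancestors(
    ont, "Brodmann area 6 of right superior frontal gyrus", "part_of"))
})

test_that("validate_ontology reports seeded defects and passes the fixture", {
  ont <- fixture_ont()
  expect_identical(nrow(validate_ontology(ont)), 0L)

  # seed a part_of cycle by bypassing the assertion guard
  broken <- ont
  anc_edge <- data.frame(subject = make_class_id("Right cerebral hemisphere"),
                         relation = "part_of",
                         object = make_class_id("Right frontal lobe"),
                         stringsAsFactors = FALSE)
  broken$structural <- rbind(broken$structural, anc_edge)
  v <- validate_ontology(broken)
  expect_identical(sum(v$kind == "cycle"), 1L)

  # a tract segment silently renamed to the whole-tract name
  broken2 <- ont
  seg <- make_class_id("Pontine part of corticospinal tract")
  broken2$classes[[seg]]$preferred_name <- "Corticospinal tract"
  v2 <- validate_ontology(broken2)
  expect_true("non_exclusive_term" %in% v2$kind)
  expect_true("duplicate_name" %in% v2$kind)

  # dangling endpoint
  broken3 <- ont
  broken3$structural$object[[1L]] <- "nfma:ghost"
  expect_true("dangling" %in% validate_ontology(broken3)$kind)
})
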