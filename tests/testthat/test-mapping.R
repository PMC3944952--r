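test_that("candidate generation reproduces the NeuroLex worked matches", {
  ont <- fixture_ont()
  labs <- lapply(c("Right frontal lobe",
                   "Inferior horn of the lateral ventricle",
                   "Lateral occipital cortex"),
                 function(x) normalize_label("neurolex", x))
  cand <- generate_candidates(labs, ont)

  direct <- cand[cand$label == "Right frontal lobe", ][1L, ]
  expect_identical(direct$method, "exact")
  expect_identical(direct$class_id, make_class_id("Right frontal lobe"))
  expect_identical(direct$score, 1)

  syn <- cand[cand$label == "Inferior horn of the lateral ventricle", ][1L, ]
  expect_identical(syn$method, "synonym")
  expect_identical(syn$class_id,
                   make_class_id("Temporal horn of lateral ventricle"))
  expect_identical(syn$score, 1)

  lex <- cand[cand$label == "Lateral occipital cortex", ][1L, ]
  expect_identical(lex$method, "lexical")
  expect_identical(lex$class_id,
                   make_class_id("Cortex of lateral occipital gyrus"))
  expect_true(lex$score >= 0.5 && lex$score < 1)
})

test_that("a label with no match is flagged unmapped, never dropped", {
  ont <- fixture_ont()
  cand <- generate_candidates(normalize_label("neurolex", "Cerebellar vermis"),
                              ont)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$method, "unmapped")
  expect_true(is.na(cand$class_id))
})

test_that("every exact candidate also satisfies the lexical token condition", {
  ont <- fixture_ont()
  labs <- lapply(c("Right frontal lobe", "Superior frontal gyrus", "Putamen"),
                 function(x) normalize_label("neurolex", x))
  cand <- generate_candidates(labs, ont)
  exact <- cand[cand$method == "exact", , drop = FALSE]
  expect_gt(nrow(exact), 0L)
  stop_re <- "^(of|the|area)$"
  for (i in seq_len(nrow(exact))) {
    lt <- strsplit(tolower(exact$label[[i]]), "[^a-z0-9]+")[[1L]]
    lt <- lt[!grepl(stop_re, lt)]
    ct <- strsplit(tolower(class_name(ont, exact$class_id[[i]])), "[^a-z0-9]+")[[1L]]
    ct <- ct[!grepl(stop_re, ct)]
    expect_true(all(lt %in% ct) || all(ct %in% lt))
  }
})

test_that("curation accepts decisions, honors overrides, rejects conflicts", {
  ont <- fixture_ont()
  # drop the shipped bindings so curation starts clean
  ont$bindings <- ont$bindings[0L, ]
  lab <- normalize_label("dk", "ctx-rh-superiorfrontal")
  cand <- generate_candidates(lab, ont)
  gm <- make_class_id("Gray matter of right superior frontal gyrus")

  # curator accepts a class that semantic interpretation, not string
  # matching, identifies -> honored with a warning
  dec <- curation_decision("dk", "ctx-rh-superiorfrontal", gm)
  expect_warning(ont2 <- apply_curation(ont, cand, dec), "override")
  expect_identical(lookup_by_binding(ont2, "dk", "ctx-rh-superiorfrontal"), gm)

  # a Talairach cell-level label binds at the cytoarchitectural class
  ba6 <- make_class_id("Brodmann area 6 of right superior frontal gyrus")
  tal_cand <- data.frame(scheme = "talairach", label = TAL_BA6, class_id = ba6,
                         method = "exact", score = 1, stringsAsFactors = FALSE)
  ont3 <- apply_curation(ont, tal_cand,
                         curation_decision("talairach", TAL_BA6, ba6))
  expect_identical(lookup_by_binding(ont3, "talairach", TAL_BA6), ba6)

  # two decisions accepting different classes for one label
  dec2 <- rbind(dec, curation_decision("dk", "ctx-rh-superiorfrontal",
                                       make_class_id("Putamen")))
  expect_error(suppressWarnings(apply_curation(ont, cand, dec2)),
               class = "atlasont_curation_conflict")
})

test_that("auto-accept binds only unambiguous exact matches", {
  ont <- fixture_ont()
  ont$bindings <- ont$bindings[0L, ]
  labs <- lapply(c("Putamen", "Lateral occipital cortex"),
                 function(x) normalize_label("neurolex", x))
  cand <- generate_candidates(labs, ont)
  ont2 <- apply_curation(ont, cand, auto_accept = TRUE)
  expect_identical(lookup_by_binding(ont2, "neurolex", "Putamen"),
                   make_class_id("Putamen"))
  # the lexical-only label needs a human decision
  expect_error(lookup_by_binding(ont2, "neurolex", "Lateral occipital cortex"),
               class = "atlasont_unmapped")
})

test_that("binding uniqueness holds under any curation sequence", {
  ont <- fixture_ont()
  b <- bindings_table(ont)
  expect_false(anyDuplicated(paste(b$scheme, b$external_label)) > 0L)
  # re-binding the same pair to the same class is idempotent
  ont2 <- add_binding(ont, "Right superior frontal gyrus", "aal",
                      "Frontal_superior_right")
  expect_identical(nrow(ont2$bindings), nrow(ont$bindings))
  # rebinding to a different class is a conflict
  expect_error(add_binding(ont, "Putamen", "aal", "Frontal_superior_right"),
               class = "atlasont_binding_conflict")
})

test_that("bound labels resolve and unbound labels raise a rich unmapped error", {
  ont <- fixture_ont()
  expect_identical(lookup_by_binding(ont, "aal", "Frontal_superior_right"),
                   make_class_id("Right superior frontal gyrus"))
  expect_identical(lookup_by_binding(ont, "neurolex", "Right frontal lobe"),
                   make_class_id("Right frontal lobe"))
  err <- expect_error(lookup_by_binding(ont, "aal", "Cuneus_L"),
                      class = "atlasont_unmapped")
  expect_true(is.null(err$candidates) || is.data.frame(err$candidates))
})

test_that("top-1 recovery is perfect for exact/synonym/abbreviation perturbations", {
  fx <- random_ontology(n_classes = 80, n_labels = 40, seed = 11)
  labs <- lapply(seq_len(nrow(fx$labels)), function(i) {
    normalize_label(fx$labels$scheme[[i]], fx$labels$label[[i]])
  })
  cand <- generate_candidates(labs, fx$ontology)
  for (i in seq_len(nrow(fx$labels))) {
    top <- cand[cand$label == fx$labels$label[[i]], ][1L, ]
    expect_identical(top$class_id, fx$labels$class_id[[i]])
    expect_identical(top$method,
                     switch(fx$labels$perturbation[[i]],
                            exact = "exact", case = "exact",
                            synonym = "synonym",
                            abbreviation = "abbreviation"))
  }
})
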