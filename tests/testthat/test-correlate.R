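test_that("the superior-frontal label correlates across all four schemes", {
  ont <- fixture_ont()

  dk <- correlate_label(ont, TAL_BA6, "talairach", "dk")
  expect_identical(dk[[1L]]$target_label, "ctx-rh-superiorfrontal")
  expect_identical(dk[[1L]]$direction, "up")
  expect_identical(dk[[1L]]$path$relation[-1L], "part_of")

  aal <- correlate_label(ont, TAL_BA6, "talairach", "aal")
  expect_identical(aal[[1L]]$target_label, "Frontal_superior_right")
  expect_identical(aal[[1L]]$path$relation[-1L], c("part_of", "part_of"))

  nlx <- correlate_label(ont, TAL_BA6, "talairach", "neurolex")
  sfg <- Filter(function(r) r$target_label == "Superior frontal gyrus", nlx)
  expect_length(sfg, 1L)
  rels <- sfg[[1L]]$path$relation[-1L]
  expect_identical(rels[length(rels)], "is_a")

  # the delateralized NeuroLex gyrus is one is_a hop from the AAL gyrus
  a2n <- correlate_label(ont, "Frontal_superior_right", "aal", "neurolex")
  sfg2 <- Filter(function(r) r$target_label == "Superior frontal gyrus", a2n)
  expect_identical(sfg2[[1L]]$direction, "lateral_is_a")
  expect_identical(nrow(sfg2[[1L]]$path), 2L)
})

test_that("correlating a label onto its own scheme is the identity", {
  ont <- fixture_ont()
  res <- correlate_label(ont, "ctx-rh-superiorfrontal", "dk", "dk")
  expect_length(res, 1L)
  expect_identical(res[[1L]]$direction, "identity")
  expect_identical(res[[1L]]$target_label, "ctx-rh-superiorfrontal")
  expect_identical(nrow(res[[1L]]$path), 0L)
})

test_that("every reported hop exists in the relation closure", {
  ont <- fixture_ont()
  combos <- list(c("talairach", "dk"), c("talairach", "aal"),
                 c("talairach", "neurolex"), c("aal", "neurolex"),
                 c("dk", "aal"))
  for (co in combos) {
    b <- ont$bindings[ont$bindings$scheme == co[[1L]], , drop = FALSE]
    for (lab in b$external_label) {
      for (r in correlate_label(ont, lab, co[[1L]], co[[2L]])) {
        p <- r$path
        for (i in seq_len(nrow(p))[-1L]) {
          a <- p$class_id[[i - 1L]]; z <- p$class_id[[i]]
          rel <- if (p$relation[[i]] == "is_a") "is_a" else "part_of"
          expect_true(z %in% ancestors(ont, a, rel) ||
                        z %in% descendants(ont, a, rel))
        }
        if (nrow(p)) expect_identical(p$class_id[[nrow(p)]], r$class_id)
      }
    }
  }
})

test_that("unmapped sources and unreachable targets are diagnosed", {
  ont <- fixture_ont()
  expect_error(correlate_label(ont, "Cuneus_L", "aal", "dk"),
               class = "atlasont_unmapped")
  # a bound label whose neighborhood has no DK binding
  res <- correlate_label(ont, "Inferior horn of the lateral ventricle",
                         "neurolex", "dk")
  expect_length(res, 0L)
  expect_true(!is.null(attr(res, "nearest_bound")))
})

test_that("granularity levels follow the naming rules", {
  ont <- fixture_ont()
  expect_identical(
    granularity_level(ont, "Brodmann area 6 of right superior frontal gyrus"),
    "cytoarchitectural_area")
  expect_identical(
    granularity_level(ont, "Gray matter of right superior frontal gyrus"),
    "cortical_gray_matter")
  expect_identical(granularity_level(ont, "Right superior frontal gyrus"),
                   "gyrus")
  expect_identical(granularity_level(ont, "Right frontal lobe"), "lobe")
  expect_identical(granularity_level(ont, "Right cerebral hemisphere"),
                   "hemisphere")
  expect_identical(granularity_level(ont, "Putamen"), "other")
})

test_that("granularity never coarsens back to finer along upward part paths", {
  ont <- fixture_ont()
  ranks <- c(cytoarchitectural_area = 1L, cortical_gray_matter = 2L,
             gyrus = 3L, lobe = 4L, hemisphere = 5L)
  inter <- names(ont$classes)[grepl("^nfma:brodmann-area-[0-9]+-of-",
                                    names(ont$classes))]
  edges <- part_family_edges(ont)
  walk <- function(id, best) {
    lvl <- granularity_level(ont, id)
    if (lvl %in% names(ranks)) {
      expect_gte(ranks[[lvl]], best)
      best <- max(best, ranks[[lvl]])
    }
    for (parent in edges$object[edges$subject == id]) walk(parent, best)
  }
  for (id in inter) walk(id, 0L)
})

test_that("overlap queries match brute-force closure intersection", {
  ont <- fixture_ont()
  ov <- overlap_query(ont, "Gray matter of superior frontal gyrus",
                      "Brodmann area 6")
  expect_identical(nm(ont, ov$shared_parts),
                   "Brodmann area 6 of superior frontal gyrus")
  expect_true(ov$a_only_exists)
  expect_true(ov$b_only_exists)

  self <- overlap_query(ont, "Brodmann area 6", "Brodmann area 6")
  expect_setequal(self$shared_parts,
                  descendants(ont, "Brodmann area 6", "part_of"))
  expect_false(self$a_only_exists)
  expect_false(self$b_only_exists)

  # random cross-check against the DFS closure oracle
  fx <- random_ontology(n_classes = 60, seed = 5)
  ront <- fx$ontology
  edges <- part_family_edges(ront)
  ids <- names(ront$classes)
  set.seed(99)
  for (k in seq_len(20L)) {
    ab <- sample(ids, 2L)
    ov <- overlap_query(ront, ab[[1L]], ab[[2L]])
    da <- dfs_reach(edges, ab[[1L]], "down")
    db <- dfs_reach(edges, ab[[2L]], "down")
    expect_setequal(ov$shared_parts, intersect(da, db))
    expect_identical(ov$a_only_exists,
                     length(setdiff(da, c(db, ab[[2L]]))) > 0L)
    expect_identical(ov$b_only_exists,
                     length(setdiff(db, c(da, ab[[1L]]))) > 0L)
  }
})

test_that("table annotation expands ancestors and flags unmapped rows", {
  ont <- fixture_ont()
  rows <- data.frame(
    scheme = c("talairach", "dk", "aal"),
    label = c(TAL_BA20, "ctx-lh-postcentral", "Unheard_of_region"),
    stringsAsFactors = FALSE)
  out <- suppressMessages(annotate_table(ont, rows))
  expect_identical(nrow(out), 3L)
  expect_match(out$ancestors[[1L]], "Right inferior temporal gyrus")
  expect_match(out$ancestors[[1L]], "Right temporal lobe")
  expect_identical(out$granularity[[1L]], "cytoarchitectural_area")
  expect_identical(out$class_name[[2L]], "Gray matter of left postcentral gyrus")
  expect_false(out$mapped[[3L]])
  expect_identical(attr(out, "n_unmapped"), 1L)

  empty <- suppressMessages(
    annotate_table(ont, rows[0L, , drop = FALSE]))
  expect_identical(nrow(empty), 0L)
})
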