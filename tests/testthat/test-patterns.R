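test_that("intersection pattern emits the three canonical assertions", {
  ont <- ontology()
  ont <- add_class(ont, anatomical_class(
    "Gray matter of right superior frontal gyrus", laterality = "right"))
  ont <- add_class(ont, anatomical_class("Right Brodmann area 6",
                                         laterality = "right"))
  ont <- create_intersection_class(
    ont, "Gray matter of right superior frontal gyrus", "Right Brodmann area 6")

  child <- resolve_class(ont, "Brodmann area 6 of right superior frontal gyrus")
  expect_false(is.na(child))
  st <- ont$structural
  expect_true(any(st$subject == child & st$relation == "is_a" &
                    st$object == make_class_id("Segment of Brodmann area 6")))
  expect_setequal(
    st$object[st$subject == child & st$relation == "regional_part_of"],
    make_class_id(c("Right Brodmann area 6",
                    "Gray matter of right superior frontal gyrus")))
  expect_identical(ont$classes[[child]]$laterality, "right")

  # idempotent: same spec, same class, no duplicate edges
  again <- create_intersection_class(
    ont, "Gray matter of right superior frontal gyrus", "Right Brodmann area 6")
  expect_identical(again$structural, ont$structural)
  expect_identical(names(again$classes), names(ont$classes))
})

test_that("fixture intersections list the five gyral overlaps of area 6", {
  ont <- fixture_ont()
  parts <- nm(ont, descendants(ont, "Brodmann area 6", "regional_part_of"))
  expect_setequal(parts, sprintf("Brodmann area 6 of %s gyrus",
                                 c("precentral", "superior frontal",
                                   "middle frontal", "inferior frontal",
                                   "medial frontal")))
})

test_that("every intersection class has two regional wholes and one is_a parent", {
  ont <- fixture_ont()
  st <- ont$structural
  inter <- names(ont$classes)[grepl("^nfma:brodmann-area-[0-9]+-of-",
                                    names(ont$classes))]
  expect_gt(length(inter), 5L)
  for (id in inter) {
    expect_identical(sum(st$subject == id & st$relation == "regional_part_of"),
                     2L)
    expect_identical(sum(st$subject == id & st$relation == "is_a"), 1L)
  }
})

test_that("lateralization creates sided is_a children exactly once", {
  ont <- add_class(ontology(), anatomical_class("Superior frontal gyrus"))
  ont <- lateralize(ont, "Superior frontal gyrus")
  right <- resolve_class(ont, "Right superior frontal gyrus")
  expect_identical(ont$classes[[right]]$laterality, "right")
  expect_identical(nm(ont, ancestors(ont, right, "is_a")),
                   "Superior frontal gyrus")
  expect_identical(nm(ont, ancestors(ont, "Left superior frontal gyrus", "is_a")),
                   "Superior frontal gyrus")
  expect_error(lateralize(ont, "Superior frontal gyrus"),
               class = "atlasont_pattern")
  expect_error(lateralize(ont, "Right superior frontal gyrus"),
               class = "atlasont_pattern")
})

test_that("sulcal segments are material parts of gyri linked to the sulcus space", {
  ont <- ontology()
  ont <- add_class(ont, anatomical_class("Middle frontal gyrus"))
  ont <- add_class(ont, anatomical_class("Inferior frontal gyrus"))
  ont <- add_class(ont, anatomical_class("Middle frontal sulcus",
                                         category = "anatomical_space"))
  ont <- create_sulcal_segment(ont, "Middle frontal gyrus",
                               "Middle frontal sulcus")
  seg <- resolve_class(ont, "Sulcal segment of middle frontal gyrus")
  expect_false(is.na(seg))
  expect_identical(nm(ont, ancestors(ont, seg, "is_a")),
                   "Segment of gyrus of brain")
  expect_true(make_class_id("Middle frontal gyrus") %in%
                ancestors(ont, seg, "regional_part_of"))

  # the whole sulcus belongs to the segments of both adjoining gyri
  ont <- create_sulcal_segment(ont, "Inferior frontal gyrus",
                               "Middle frontal sulcus")
  expect_length(sulcus_gyri(ont, "Middle frontal sulcus"), 2L)

  # category constraints: a material structure is not a sulcus space
  expect_error(create_sulcal_segment(ont, "Middle frontal gyrus",
                                     "Inferior frontal gyrus"),
               class = "atlasont_category")
})

test_that("tract partition demands exclusive segment terms", {
  ont <- add_class(ontology(), anatomical_class("Corticospinal tract"))
  segs <- c("Pontine part of corticospinal tract",
            "Medullary part of corticospinal tract",
            "Spinal part of corticospinal tract")
  ont <- partition_tract(ont, "Corticospinal tract", segs)
  for (s in segs) {
    expect_true(make_class_id("Corticospinal tract") %in%
                  ancestors(ont, s, "regional_part_of"))
  }
  expect_setequal(nm(ont, descendants(ont, "Corticospinal tract", "part_of")),
                  segs)

  err <- expect_error(
    partition_tract(ont, "Corticospinal tract", "Corticospinal tract"),
    class = "atlasont_non_exclusive_term")
  expect_match(conditionMessage(err), "non-exclusive")
  expect_error(partition_tract(ont, "Corticospinal tract", c("Part x", "Part x")),
               class = "atlasont_pattern")

  # empty partition is a no-op
  expect_identical(partition_tract(ont, "Corticospinal tract", character(0L)),
                   ont)
})
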