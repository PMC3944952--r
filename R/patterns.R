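# Executable ontology-modeling patterns for reconciling parcellation schemes:
# cytoarchitectural x morphological intersection classes, lateralization,
# sulcal segments of gyri, and white-matter tract partonomy.

# "Gray matter of right superior frontal gyrus" -> "right superior frontal gyrus"
strip_gray_matter <- function(name) {
  sub("^[Gg]ray matter of (the )?", "", name)
}

lowercase_first <- function(name) {
  paste0(tolower(substr(name, 1L, 1L)), substr(name, 2L, nchar(name)))
}

# Brodmann area number from a class name like "Right Brodmann area 6"
brodmann_number <- function(name) {
  m <- regmatches(name, regexpr("[Bb]rodmann area ([0-9]+)", name))
  if (!length(m)) {
    ont_stop("pattern", sprintf("'%s' does not name a Brodmann area", name))
  }
  sub(".*area ", "", m)
}

#' Name of the intersection class for a Brodmann area and a gyral gray matter
#'
#' @param ontology an [ontology()].
#' @param gyral_gm_class,brodmann_class identifiers or names of the two
#'   parents.
#' @return The generated preferred name, e.g.
#'   `"Brodmann area 6 of right superior frontal gyrus"`.
#' @export
intersection_class_name <- function(ontology, gyral_gm_class, brodmann_class) {
  gm <- class_name(ontology, gyral_gm_class)
  ba <- class_name(ontology, brodmann_class)
  sprintf("Brodmann area %s of %s", brodmann_number(ba),
          lowercase_first(strip_gray_matter(gm)))
}

#' Create a cytoarchitectural-by-morphological intersection class
#'
#' Gyri are delineated by surface morphology while Brodmann areas are defined
#' by cytoarchitecture, so neither parcellation's classes are parts of the
#' other's.  The overlap is reconciled by a dedicated intersection class,
#' e.g. `Brodmann area 6 of right superior frontal gyrus`, which `is_a`
#' `Segment of Brodmann area 6` (auto-created when absent) and is a
#' `regional_part_of` both the Brodmann-area class and the gyral gray-matter
#' class.
#'
#' @inheritParams intersection_class_name
#' @return The updated ontology.  The new class id is
#'   `make_class_id(intersection_class_name(...))`; re-running the same
#'   pattern is idempotent.
#' @export
#' @examples
#' ont <- ontology()
#' ont <- add_class(ont, anatomical_class("Gray matter of right superior frontal gyrus",
#'                                        laterality = "right"))
#' ont <- add_class(ont, anatomical_class("Right Brodmann area 6", laterality = "right"))
#' ont <- create_intersection_class(ont, "Gray matter of right superior frontal gyrus",
#'                                  "Right Brodmann area 6")
#' class_name(ont, descendants(ont, "Right Brodmann area 6", "regional_part_of"))
create_intersection_class <- function(ontology, gyral_gm_class, brodmann_class) {
  gm_id <- require_class(ontology, gyral_gm_class, "gyral gray matter class")
  ba_id <- require_class(ontology, brodmann_class, "Brodmann area class")
  child_name <- intersection_class_name(ontology, gm_id, ba_id)
  child_id <- resolve_class(ontology, child_name)
  laterality <- ontology$classes[[gm_id]]$laterality
  if (is.na(child_id)) {
    ontology <- add_class(ontology, anatomical_class(
      child_name, laterality = laterality))
    child_id <- make_class_id(child_name)
  }
  segment_name <- sprintf("Segment of Brodmann area %s",
                          brodmann_number(class_name(ontology, ba_id)))
  if (is.na(resolve_class(ontology, segment_name))) {
    ontology <- add_class(ontology, anatomical_class(segment_name))
  }
  ontology <- assert_structural(ontology, child_id, "is_a", segment_name)
  ontology <- assert_structural(ontology, child_id, "regional_part_of", ba_id)
  ontology <- assert_structural(ontology, child_id, "regional_part_of", gm_id)
  ontology
}

#' Lateralize an unpaired class
#'
#' Creates `Left <name>` and `Right <name>` classes, each `is_a` the unpaired
#' class.  Structural knowledge attached to the unpaired class is reached
#' through `is_a` ancestor queries rather than copied onto the children.
#' Non-lateralized vocabularies (NeuroLex) bind at the unpaired class while
#' lateralized atlases bind at the sided children.
#'
#' @inheritParams add_class
#' @param unpaired_class identifier or name of a class with laterality
#'   `"unpaired"` that has not been lateralized yet.
#' @return The updated ontology containing the two sided classes.
#' @export
#' @examples
#' ont <- add_class(ontology(), anatomical_class("Superior frontal gyrus"))
#' ont <- lateralize(ont, "Superior frontal gyrus")
#' class_name(ont, ancestors(ont, "Right superior frontal gyrus", "is_a"))
lateralize <- function(ontology, unpaired_class) {
  id <- require_class(ontology, unpaired_class)
  cls <- ontology$classes[[id]]
  if (cls$laterality != "unpaired") {
    ont_stop("pattern", sprintf(
      "%s is already lateralized (%s)", cls$preferred_name, cls$laterality))
  }
  base <- lowercase_first(cls$preferred_name)
  for (side in c("left", "right")) {
    side_name <- sprintf("%s %s", if (side == "left") "Left" else "Right", base)
    if (!is.na(resolve_class(ontology, side_name))) {
      ont_stop("pattern", sprintf(
        "%s already exists; %s has been lateralized before",
        side_name, cls$preferred_name))
    }
    ontology <- add_class(ontology, anatomical_class(
      side_name, laterality = side, category = cls$category))
    ontology <- assert_structural(ontology, side_name, "is_a", id)
  }
  ontology
}

#' Create the sulcal segment of a gyrus
#'
#' A sulcus is modeled as an anatomical space (the groove), and the cortex
#' buried in it as a material `Sulcal segment of <gyrus>` that `is_a`
#' `Segment of gyrus of brain` and is a `regional_part_of` the gyrus.  The
#' association between the sulcus space and the segment is kept as a
#' dedicated adjacency record (a space is not a part of a material gyrus), so
#' a sulcus bordered by several gyri links to each of their sulcal segments —
#' e.g. the middle frontal sulcus belongs to the sulcal segments of both the
#' middle and the inferior frontal gyri.
#'
#' @inheritParams add_class
#' @param gyrus identifier or name of a material-structure gyrus class.
#' @param sulcus_space identifier or name of an anatomical-space sulcus class.
#' @return The updated ontology.
#' @seealso [sulcus_gyri()]
#' @export
create_sulcal_segment <- function(ontology, gyrus, sulcus_space) {
  gyrus_id <- require_class(ontology, gyrus, "gyrus")
  sulcus_id <- require_class(ontology, sulcus_space, "sulcus")
  if (ontology$classes[[gyrus_id]]$category != "material_structure") {
    ont_stop("category", sprintf(
      "%s is not a material structure", class_name(ontology, gyrus_id)))
  }
  if (ontology$classes[[sulcus_id]]$category != "anatomical_space") {
    ont_stop("category", sprintf(
      "%s is not an anatomical space (sulci are modeled as spaces)",
      class_name(ontology, sulcus_id)))
  }
  seg_name <- sprintf("Sulcal segment of %s",
                      lowercase_first(class_name(ontology, gyrus_id)))
  seg_id <- resolve_class(ontology, seg_name)
  if (is.na(seg_id)) {
    ontology <- add_class(ontology, anatomical_class(
      seg_name, laterality = ontology$classes[[gyrus_id]]$laterality))
    seg_id <- make_class_id(seg_name)
  }
  parent_name <- "Segment of gyrus of brain"
  if (is.na(resolve_class(ontology, parent_name))) {
    ontology <- add_class(ontology, anatomical_class(parent_name))
  }
  ontology <- assert_structural(ontology, seg_id, "is_a", parent_name)
  ontology <- assert_structural(ontology, seg_id, "regional_part_of", gyrus_id)
  sl <- ontology$sulcal_links
  if (!any(sl$sulcus == sulcus_id & sl$segment == seg_id)) {
    ontology$sulcal_links <- rbind(sl, data.frame(
      sulcus = sulcus_id, segment = seg_id, stringsAsFactors = FALSE))
  }
  ontology
}

#' Gyri adjoining a sulcus
#'
#' Lists the gyri whose sulcal segments are linked to the given sulcus space.
#'
#' @inheritParams add_class
#' @param sulcus_space identifier or name of the sulcus.
#' @return Character vector of gyrus class identifiers, sorted by name.
#' @export
sulcus_gyri <- function(ontology, sulcus_space) {
  sulcus_id <- require_class(ontology, sulcus_space, "sulcus")
  segs <- ontology$sulcal_links$segment[
    ontology$sulcal_links$sulcus == sulcus_id]
  st <- ontology$structural
  gyri <- unique(st$object[st$subject %in% segs &
                             st$relation == "regional_part_of"])
  nm <- class_names(ontology)
  gyri[order(nm[gyri], gyri)]
}

#' Partition a white-matter tract into named segments
#'
#' Using one term for both a whole tract and a specific segment of it (a
#' "non-exclusive" term) corrupts machine annotation, so every segment must
#' carry its own unique name, distinct from the whole-tract name.  Each
#' segment becomes a class that is a `regional_part_of` the tract;
#' [validate_ontology()] flags any later reuse of the tract's name for a
#' part.
#'
#' @inheritParams add_class
#' @param tract identifier or name of the whole tract.
#' @param segment_names character vector of distinct segment names; an empty
#'   vector is a no-op.
#' @return The updated ontology.
#' @export
#' @examples
#' ont <- add_class(ontology(), anatomical_class("Corticospinal tract"))
#' ont <- partition_tract(ont, "Corticospinal tract",
#'                        c("Pontine part of corticospinal tract",
#'                          "Medullary part of corticospinal tract"))
partition_tract <- function(ontology, tract, segment_names) {
  tract_id <- require_class(ontology, tract, "tract")
  if (!length(segment_names)) return(ontology)
  tract_name <- class_name(ontology, tract_id)
  if (anyDuplicated(name_key(segment_names))) {
    ont_stop("pattern", "segment names must be pairwise distinct")
  }
  clash <- segment_names[name_key(segment_names) == name_key(tract_name)]
  if (length(clash)) {
    ont_stop("non_exclusive_term", sprintf(
      "segment may not reuse the whole-tract name '%s' (non-exclusive term)",
      tract_name))
  }
  for (seg in segment_names) {
    if (is.na(resolve_class(ontology, seg))) {
      ontology <- add_class(ontology, anatomical_class(
        seg, laterality = ontology$classes[[tract_id]]$laterality))
    }
    ontology <- assert_structural(ontology, seg, "regional_part_of", tract_id)
  }
  ontology
}
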