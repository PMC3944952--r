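# Deterministic fixture builders: the worked mini-ontology covering the
# frontal-lobe partonomy, Brodmann x gyrus intersections, corticospinal
# segments, SLF I connectivity, sulcal segments and the four-scheme binding
# star, plus a seeded random-ontology generator for property tests.

# bulk constructor used by the fixture builders and the Turtle loader;
# callers guarantee (or subsequently validate) integrity
ontology_from_parts <- function(classes, structural = empty_structural(),
                                bindings = empty_bindings(),
                                connectivity = empty_connectivity(),
                                sulcal_links = empty_sulcal_links()) {
  ont <- ontology()
  ont$classes <- classes
  ont$structural <- structural
  ont$bindings <- bindings
  ont$connectivity <- connectivity
  ont$sulcal_links <- sulcal_links
  ont
}

#' Build the worked example mini-ontology
#'
#' A small but complete neuroanatomy ontology exercising every modeling
#' pattern in the package:
#'
#' * the superior-frontal correlation star — the Talairach label
#'   `Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann
#'   area 6` bound at the cytoarchitectural level, DK's
#'   `ctx-rh-superiorfrontal` at the gray-matter level, AAL's
#'   `Frontal_superior_right` at the gyrus level and NeuroLex's non-lateralized
#'   `Superior frontal gyrus` reached by `is_a`;
#' * Brodmann-by-gyrus intersections: the gray matter of the superior frontal
#'   gyrus overlaps Brodmann areas 6, 8, 9, 10 and 11, and Brodmann area 6
#'   overlaps the gray matter of the precentral, superior frontal, middle
#'   frontal, inferior frontal and medial frontal gyri;
#' * a parallel inferior-temporal / Brodmann area 20 branch;
#' * the SLF I connectivity facts (the dorsal segment of the superior
#'   longitudinal fasciculus projects from Brodmann area 6 of the superior
#'   frontal gyrus and projects to Brodmann area 5 of the superior parietal
#'   lobule);
#' * a regional partition of the corticospinal tract (segment names are
#'   synthetic placeholders: the source figure is not enumerated in text);
#' * sulcal segments linking the middle frontal sulcus to the middle and
#'   inferior frontal gyri;
#' * placeholder putamen connectivity, likewise flagged synthetic.
#'
#' The result passes [validate_ontology()] with zero violations and is the
#' single source for every worked-example test in the package.
#'
#' @return An [ontology()].
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' nrow(validate_ontology(ont))
build_fixture_ontology <- function() {
  ont <- ontology()
  cls <- function(...) {
    ont <<- add_class(ont, anatomical_class(...))
  }
  rel <- function(s, r, o) {
    ont <<- assert_structural(ont, s, r, o)
  }

  # --- unpaired morphological hierarchy -----------------------------------
  cls("Frontal lobe")
  gyri <- c("Precentral gyrus", "Superior frontal gyrus",
            "Middle frontal gyrus", "Inferior frontal gyrus",
            "Medial frontal gyrus")
  for (g in gyri) {
    cls(g)
    rel(g, "regional_part_of", "Frontal lobe")
    gm <- sprintf("Gray matter of %s", lowercase_first(g))
    cls(gm)
    rel(gm, "regional_part_of", g)
  }

  # --- Brodmann areas and their gyral intersections -----------------------
  for (n in c(6, 8, 9, 10, 11)) cls(sprintf("Brodmann area %d", n))
  # Brodmann area 6 overlaps the gray matter of five frontal gyri
  for (g in gyri) {
    ont <- create_intersection_class(
      ont, sprintf("Gray matter of %s", lowercase_first(g)), "Brodmann area 6")
  }
  # the gray matter of the superior frontal gyrus overlaps areas 6,8,9,10,11
  for (n in c(8, 9, 10, 11)) {
    ont <- create_intersection_class(
      ont, "Gray matter of superior frontal gyrus",
      sprintf("Brodmann area %d", n))
  }

  # --- lateralized right-hemisphere chain ---------------------------------
  ont <- lateralize(ont, "Superior frontal gyrus")
  ont <- lateralize(ont, "Frontal lobe")
  cls("Right cerebral hemisphere", laterality = "right")
  cls("Gray matter of right superior frontal gyrus", laterality = "right")
  cls("Right Brodmann area 6", laterality = "right")
  rel("Right Brodmann area 6", "is_a", "Brodmann area 6")
  rel("Gray matter of right superior frontal gyrus", "is_a",
      "Gray matter of superior frontal gyrus")
  rel("Gray matter of right superior frontal gyrus", "regional_part_of",
      "Right superior frontal gyrus")
  rel("Right superior frontal gyrus", "regional_part_of", "Right frontal lobe")
  rel("Right frontal lobe", "regional_part_of", "Right cerebral hemisphere")
  ont <- create_intersection_class(
    ont, "Gray matter of right superior frontal gyrus", "Right Brodmann area 6")

  # --- inferior-temporal / Brodmann area 20 branch ------------------------
  cls("Inferior temporal gyrus")
  cls("Gray matter of inferior temporal gyrus")
  rel("Gray matter of inferior temporal gyrus", "regional_part_of",
      "Inferior temporal gyrus")
  cls("Brodmann area 20")
  ont <- create_intersection_class(
    ont, "Gray matter of inferior temporal gyrus", "Brodmann area 20")
  cls("Right temporal lobe", laterality = "right")
  cls("Right inferior temporal gyrus", laterality = "right")
  rel("Right inferior temporal gyrus", "is_a", "Inferior temporal gyrus")
  cls("Gray matter of right inferior temporal gyrus", laterality = "right")
  rel("Gray matter of right inferior temporal gyrus", "is_a",
      "Gray matter of inferior temporal gyrus")
  cls("Right Brodmann area 20", laterality = "right")
  rel("Right Brodmann area 20", "is_a", "Brodmann area 20")
  rel("Gray matter of right inferior temporal gyrus", "regional_part_of",
      "Right inferior temporal gyrus")
  rel("Right inferior temporal gyrus", "regional_part_of",
      "Right temporal lobe")
  rel("Right temporal lobe", "regional_part_of", "Right cerebral hemisphere")
  ont <- create_intersection_class(
    ont, "Gray matter of right inferior temporal gyrus",
    "Right Brodmann area 20")

  # --- postcentral branch for the DK left-hemisphere example --------------
  cls("Postcentral gyrus")
  ont <- lateralize(ont, "Postcentral gyrus")
  cls("Gray matter of left postcentral gyrus", laterality = "left")
  rel("Gray matter of left postcentral gyrus", "regional_part_of",
      "Left postcentral gyrus")

  # --- NeuroLex mapping exercise classes ----------------------------------
  cls("Temporal horn of lateral ventricle",
      synonyms = "Inferior horn of the lateral ventricle",
      category = "anatomical_space")
  cls("Lateral occipital gyrus")
  cls("Cortex of lateral occipital gyrus")
  rel("Cortex of lateral occipital gyrus", "regional_part_of",
      "Lateral occipital gyrus")

  # --- white matter: SLF I and the corticospinal partition ----------------
  cls("Superior longitudinal fasciculus")
  ont <- partition_tract(ont, "Superior longitudinal fasciculus",
                         "Dorsal segment of superior longitudinal fasciculus")
  slf1 <- resolve_class(ont, "Dorsal segment of superior longitudinal fasciculus")
  ont$classes[[slf1]]$synonyms <- "SLF I"

  cls("Superior parietal lobule")
  cls("Gray matter of superior parietal lobule")
  rel("Gray matter of superior parietal lobule", "regional_part_of",
      "Superior parietal lobule")
  cls("Brodmann area 5")
  ont <- create_intersection_class(
    ont, "Gray matter of superior parietal lobule", "Brodmann area 5")
  ont <- assert_connectivity(
    ont, "Dorsal segment of superior longitudinal fasciculus",
    "projects_from", "Brodmann area 6 of superior frontal gyrus")
  ont <- assert_connectivity(
    ont, "Dorsal segment of superior longitudinal fasciculus",
    "projects_to", "Brodmann area 5 of superior parietal lobule")

  cls("Corticospinal tract")
  # segment names are synthetic placeholders (brain-to-cord ordering)
  ont <- partition_tract(ont, "Corticospinal tract", c(
    "Telencephalic part of corticospinal tract",
    "Midbrain part of corticospinal tract",
    "Pontine part of corticospinal tract",
    "Medullary part of corticospinal tract",
    "Spinal part of corticospinal tract"))

  # --- putamen connectivity (synthetic placeholder edges) -----------------
  cls("Putamen")
  cls("Cerebral cortex")
  cls("Globus pallidus")
  ont <- assert_connectivity(ont, "Putamen", "receives_input_from",
                             "Cerebral cortex")
  ont <- assert_connectivity(ont, "Putamen", "sends_output_to",
                             "Globus pallidus")

  # --- sulci as anatomical spaces -----------------------------------------
  cls("Middle frontal sulcus", category = "anatomical_space")
  ont <- create_sulcal_segment(ont, "Middle frontal gyrus",
                               "Middle frontal sulcus")
  ont <- create_sulcal_segment(ont, "Inferior frontal gyrus",
                               "Middle frontal sulcus")

  # --- terminology bindings (the four-scheme star and friends) ------------
  ont <- add_binding(
    ont, "Brodmann area 6 of right superior frontal gyrus", "talairach",
    "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6")
  ont <- add_binding(
    ont, "Brodmann area 20 of right inferior temporal gyrus", "talairach",
    "Right Cerebrum.Temporal Lobe.Inferior Temporal Gyrus.Gray Matter.Brodmann area 20")
  ont <- add_binding(ont, "Gray matter of right superior frontal gyrus", "dk",
                     "ctx-rh-superiorfrontal")
  ont <- add_binding(ont, "Gray matter of left postcentral gyrus", "dk",
                     "ctx-lh-postcentral")
  ont <- add_binding(ont, "Right superior frontal gyrus", "aal",
                     "Frontal_superior_right")
  # NeuroLex ids below are synthetic placeholders, not NeuroLex releases
  ont <- add_binding(ont, "Superior frontal gyrus", "neurolex",
                     "Superior frontal gyrus", "nlx:synthetic-0001")
  ont <- add_binding(ont, "Right frontal lobe", "neurolex",
                     "Right frontal lobe", "nlx:synthetic-0002")
  ont <- add_binding(ont, "Temporal horn of lateral ventricle", "neurolex",
                     "Inferior horn of the lateral ventricle",
                     "nlx:synthetic-0003")
  ont <- add_binding(ont, "Cortex of lateral occipital gyrus", "neurolex",
                     "Lateral occipital cortex", "nlx:synthetic-0004")
  ont
}

# adjective vocabulary with AAL-style abbreviations, used for synthetic names
RANDOM_ADJECTIVES <- c(superior = "sup", inferior = "inf", middle = "mid",
                       medial = "med", anterior = "ant", posterior = "post")

#' Generate a seeded random ontology with ground truth
#'
#' Builds a layered acyclic ontology: classes are placed on layers and every
#' structural edge points from a deeper layer to a strictly shallower one, so
#' each relation family is acyclic by construction.  The generator also
#' returns its own ground truth, computed by topological dynamic programming
#' (independent of the breadth-first search behind [ancestors()]): the full
#' transitive closure per relation family, and a label table with the true
#' class for every synthesized label.
#'
#' Labels are synthesized from class names under four perturbations:
#' `exact` (the name verbatim, as a NeuroLex-style phrase), `case` (random
#' casing), `synonym` (a recorded synonym), and `abbreviation` (an AAL-style
#' underscore label with the leading adjective abbreviated).
#'
#' @param n_classes number of classes (>= 2).
#' @param n_layers number of partonomy layers.
#' @param avg_parents mean number of `part_of`-family parents per non-root
#'   class; a third of these edges are `regional_part_of`.
#' @param avg_isa mean number of `is_a` parents per class.
#' @param n_labels number of synthesized labels.
#' @param perturbations label perturbation kinds to draw from.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list with elements `ontology`, `closure` (data frame `relation`,
#'   `from`, `to` giving the true transitive closure of the `part_of` family
#'   and of `is_a`), and `labels` (data frame `scheme`, `label`, `class_id`,
#'   `perturbation`).
#' @export
#' @examples
#' fx <- random_ontology(n_classes = 30, seed = 1)
#' nrow(fx$closure)
random_ontology <- function(n_classes = 100, n_layers = 6, avg_parents = 1.5,
                            avg_isa = 0.3, n_labels = 25,
                            perturbations = c("exact", "case", "synonym",
                                              "abbreviation"),
                            seed = 1L) {
  if (n_classes < 2L || n_layers < 2L) {
    ont_stop("fixture_spec", "need at least 2 classes on at least 2 layers")
  }
  perturbations <- match.arg(perturbations, several.ok = TRUE)
  set.seed(seed)

  adjectives <- names(RANDOM_ADJECTIVES)
  adj <- sample(adjectives, n_classes, replace = TRUE)
  names <- sprintf("%s structure %03d",
                   paste0(toupper(substr(adj, 1, 1)), substr(adj, 2, 99)),
                   seq_len(n_classes))
  synonyms <- sprintf("structure %03d alias", seq_len(n_classes))
  ids <- vapply(names, make_class_id, character(1L), USE.NAMES = FALSE)
  layer <- sort(sample(seq_len(n_layers), n_classes, replace = TRUE))

  classes <- list()
  for (i in seq_len(n_classes)) {
    classes[[ids[[i]]]] <- anatomical_class(names[[i]],
                                            synonyms = synonyms[[i]])
  }

  # edges point from node i to a parent on a strictly shallower layer
  subj <- character(0L); relk <- character(0L); obj <- character(0L)
  for (i in seq_len(n_classes)) {
    shallower <- which(layer < layer[[i]])
    if (!length(shallower)) next
    n_part <- stats::rpois(1L, avg_parents)
    n_isa <- stats::rpois(1L, avg_isa)
    for (p in seq_len(min(n_part, length(shallower)))) {
      j <- sample(shallower, 1L)
      kind <- if (stats::runif(1L) < 1 / 3) "regional_part_of" else "part_of"
      subj <- c(subj, ids[[i]]); relk <- c(relk, kind); obj <- c(obj, ids[[j]])
    }
    for (p in seq_len(min(n_isa, length(shallower)))) {
      j <- sample(shallower, 1L)
      subj <- c(subj, ids[[i]]); relk <- c(relk, "is_a"); obj <- c(obj, ids[[j]])
    }
  }
  structural <- unique(data.frame(subject = subj, relation = relk,
                                  object = obj, stringsAsFactors = FALSE))
  ont <- ontology_from_parts(classes, structural)

  # ground-truth closure by topological DP over layers (shallow to deep):
  # anc(v) = union over parents p of {p} + anc(p)
  closure_dp <- function(kinds) {
    ed <- structural[structural$relation %in% kinds, , drop = FALSE]
    parents <- split(ed$object, ed$subject)
    anc <- setNames(vector("list", n_classes), ids)
    for (i in order(layer)) {
      id <- ids[[i]]
      ps <- parents[[id]]
      val <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
      anc[[id]] <- if (is.null(val)) character(0L) else val
    }
    pairs <- data.frame(
      from = rep(ids, lengths(anc[ids])),
      to = unlist(anc[ids], use.names = FALSE),
      stringsAsFactors = FALSE)
    pairs
  }
  part_pairs <- closure_dp(c("part_of", "regional_part_of"))
  isa_pairs <- closure_dp("is_a")
  closure <- rbind(
    if (nrow(part_pairs)) cbind(relation = "part_of", part_pairs),
    if (nrow(isa_pairs)) cbind(relation = "is_a", isa_pairs))
  if (is.null(closure)) {
    closure <- data.frame(relation = character(0L), from = character(0L),
                          to = character(0L), stringsAsFactors = FALSE)
  }

  # synthesized labels with known ground truth
  targets <- sample(seq_len(n_classes), min(n_labels, n_classes))
  kinds <- sample(perturbations, length(targets), replace = TRUE)
  labels <- data.frame(scheme = character(0L), label = character(0L),
                       class_id = character(0L), perturbation = character(0L),
                       stringsAsFactors = FALSE)
  random_case <- function(x) {
    ch <- strsplit(x, "")[[1L]]
    flip <- stats::runif(length(ch)) < 0.5
    ch[flip] <- toupper(ch[flip])
    paste(ch, collapse = "")
  }
  for (k in seq_along(targets)) {
    i <- targets[[k]]
    lab <- switch(kinds[[k]],
      exact = list(scheme = "neurolex", label = names[[i]]),
      case = list(scheme = "neurolex", label = random_case(names[[i]])),
      synonym = list(scheme = "neurolex", label = synonyms[[i]]),
      abbreviation = list(
        scheme = "aal",
        label = gsub(" ", "_", sub(
          paste0("^", adj[[i]]), RANDOM_ADJECTIVES[[adj[[i]]]],
          tolower(names[[i]])))))
    labels <- rbind(labels, data.frame(
      scheme = lab$scheme, label = lab$label, class_id = ids[[i]],
      perturbation = kinds[[k]], stringsAsFactors = FALSE))
  }

  list(ontology = ont, closure = closure, labels = labels)
}
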