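# Semi-automatic mapping between atlas labels and ontology classes.
#
# Candidate generation follows the four matching methods used when binding
# atlas vocabularies to anatomical classes: direct string matching, synonymy,
# abbreviation interpretation, and lexical (token-overlap) matching, with
# precedence exact > synonym > abbreviation > lexical.  Candidates feed a
# manual curation step that produces terminology bindings; only unambiguous
# exact matches may be auto-accepted.

MAPPING_METHODS <- c("exact", "synonym", "abbreviation", "lexical")

# minimum Jaccard token overlap for a lexical candidate to be reported
LEXICAL_THRESHOLD <- 0.5

# label text before abbreviation expansion (delimiters -> spaces, lowercased)
raw_phrase <- function(scheme, raw) {
  delim <- scheme_delimiter(scheme)
  tolower(trimws(gsub(delim, " ", raw, fixed = scheme %in% c("dk", "aal"))))
}

# all names a class answers to, keyed for case-insensitive comparison
class_name_keys <- function(cls) {
  name_key(c(cls$preferred_name, cls$synonyms))
}

#' Generate mapping candidates for normalized labels
#'
#' For each label, candidate classes are found by four methods in precedence
#' order: `exact` (the unexpanded label text equals a class's preferred name),
#' `synonym` (it equals a recorded synonym), `abbreviation` (the
#' abbreviation-expanded text equals a preferred name or synonym), and
#' `lexical` (all label tokens, minus the stopwords *of*, *the* and *area*,
#' occur among the class-name tokens or vice versa; scored by Jaccard
#' overlap and reported at 0.5 or above).  Exact and synonym
#' candidates score 1.
#'
#' @param labels a list of [normalize_label()] results (a single
#'   `normalized_label` is also accepted).
#' @param ontology an [ontology()].
#' @return A data frame with columns `scheme`, `label`, `class_id`, `method`,
#'   `score`, sorted per label by method precedence, then score, then class
#'   name.  A label with no candidates contributes one row with method
#'   `"unmapped"` and `NA` class.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' generate_candidates(normalize_label("neurolex", "Lateral occipital cortex"), ont)
generate_candidates <- function(labels, ontology) {
  if (inherits(labels, "normalized_label")) labels <- list(labels)
  stopifnot(all(vapply(labels, inherits, logical(1L), "normalized_label")))
  nm <- class_names(ontology)
  rows <- list()
  for (label in labels) {
    raw_key <- name_key(raw_phrase(label$scheme, label$raw))
    expanded_key <- name_key(label_phrase(label))
    label_toks <- unique(setdiff(label$tokens, MATCH_STOPWORDS))
    if (label$laterality != "unpaired") {
      label_toks <- unique(c(label$laterality, label_toks))
    }
    found <- list()
    for (cls in ontology$classes) {
      keys <- class_name_keys(cls)
      method <- NULL
      score <- 1
      if (raw_key == keys[[1L]]) {
        method <- "exact"
      } else if (raw_key %in% keys[-1L]) {
        method <- "synonym"
      } else if (expanded_key %in% keys) {
        method <- "abbreviation"
      } else {
        cls_toks <- unique(phrase_tokens(cls$preferred_name))
        if (length(label_toks) && length(cls_toks) &&
            (all(label_toks %in% cls_toks) || all(cls_toks %in% label_toks))) {
          score <- length(intersect(label_toks, cls_toks)) /
            length(union(label_toks, cls_toks))
          if (score >= LEXICAL_THRESHOLD && score < 1) method <- "lexical"
          if (score == 1) method <- "lexical"  # same tokens, different order
        }
      }
      if (!is.null(method)) {
        found[[length(found) + 1L]] <- data.frame(
          scheme = label$scheme, label = label$raw, class_id = cls$id,
          method = method, score = score, stringsAsFactors = FALSE)
      }
    }
    if (!length(found)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = label$scheme, label = label$raw, class_id = NA_character_,
        method = "unmapped", score = NA_real_, stringsAsFactors = FALSE)
      next
    }
    grp <- do.call(rbind, found)
    ord <- order(match(grp$method, MAPPING_METHODS), -grp$score,
                 nm[grp$class_id])
    rows[[length(rows) + 1L]] <- grp[ord, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a curation decision table
#'
#' @param scheme,label the atlas scheme and raw label being decided.
#' @param class_id accepted class identifier, or `NA` to reject the label.
#' @param note free-text curator note.
#' @return A data frame with one row per decision.
#' @export
curation_decision <- function(scheme, label, class_id = NA_character_,
                              note = "") {
  data.frame(scheme = scheme, label = label, class_id = class_id, note = note,
             stringsAsFactors = FALSE)
}

#' Record a terminology binding on a class
#'
#' A binding is the slot linking an anatomical class to one scheme's external
#' label (and optional external identifier, e.g. a NeuroLex id).  Each
#' `(scheme, label)` pair may bind to at most one class; one class may carry
#' bindings to several schemes.  Bindings are not inherited along `is_a`.
#'
#' @inheritParams add_class
#' @param class_id class identifier or name.
#' @param scheme one of `"talairach"`, `"dk"`, `"aal"`, `"neurolex"`.
#' @param external_label the scheme's label string, verbatim.
#' @param external_id optional scheme-internal identifier.
#' @return The updated ontology.
#' @export
add_binding <- function(ontology, class_id, scheme, external_label,
                        external_id = NA_character_) {
  scheme <- match.arg(scheme, SCHEME_IDS)
  class_id <- require_class(ontology, class_id)
  b <- ontology$bindings
  same <- b$scheme == scheme & b$external_label == external_label
  if (any(same)) {
    if (all(b$class_id[same] == class_id)) return(ontology)
    ont_stop("binding_conflict", sprintf(
      "(%s, '%s') is already bound to %s", scheme, external_label,
      b$class_id[same][[1L]]))
  }
  ontology$bindings <- rbind(b, data.frame(
    class_id = class_id, scheme = scheme, external_label = external_label,
    external_id = external_id, stringsAsFactors = FALSE))
  ontology
}

#' Apply curation decisions to mapping candidates
#'
#' Bindings are created only for accepted decisions; when `auto_accept` is
#' `TRUE`, labels whose candidate group is a single unambiguous `exact` match
#' are bound without a decision.  Ties between equal-method, equal-score
#' candidates are never auto-accepted.  A curator may accept a class that was
#' not among the candidates; this is honored with a warning.
#'
#' @inheritParams add_class
#' @param candidates output of [generate_candidates()].
#' @param decisions a data frame as built by [curation_decision()] (or read
#'   from TSV with the same columns).
#' @param auto_accept auto-bind unambiguous exact matches.
#' @return The updated ontology with terminology bindings added.
#' @export
apply_curation <- function(ontology, candidates, decisions = NULL,
                           auto_accept = FALSE) {
  if (is.null(decisions)) {
    decisions <- data.frame(scheme = character(0L), label = character(0L),
                            class_id = character(0L), note = character(0L),
                            stringsAsFactors = FALSE)
  }
  accepted <- decisions[!is.na(decisions$class_id), , drop = FALSE]
  for (key in unique(paste(accepted$scheme, accepted$label, sep = "\r"))) {
    grp <- accepted[paste(accepted$scheme, accepted$label, sep = "\r") == key, ]
    if (length(unique(grp$class_id)) > 1L) {
      ont_stop("curation_conflict", sprintf(
        "conflicting decisions accept different classes for (%s, '%s')",
        grp$scheme[[1L]], grp$label[[1L]]))
    }
  }
  for (i in seq_len(nrow(accepted))) {
    d <- accepted[i, ]
    id <- require_class(ontology, d$class_id)
    grp <- candidates[candidates$scheme == d$scheme &
                        candidates$label == d$label, , drop = FALSE]
    if (!id %in% grp$class_id) {
      warning(sprintf(
        "curator override: (%s, '%s') accepted for %s, not among candidates",
        d$scheme, d$label, id), call. = FALSE)
    }
    ontology <- add_binding(ontology, id, d$scheme, d$label)
  }
  if (auto_accept) {
    decided <- paste(decisions$scheme, decisions$label)
    for (key in unique(paste(candidates$scheme, candidates$label))) {
      if (key %in% decided) next
      grp <- candidates[paste(candidates$scheme, candidates$label) == key, ,
                        drop = FALSE]
      exact <- grp[grp$method == "exact", , drop = FALSE]
      if (nrow(exact) == 1L) {
        ontology <- add_binding(ontology, exact$class_id, exact$scheme,
                                exact$label)
      }
    }
  }
  ontology
}

#' Resolve an atlas label through its terminology binding
#'
#' @inheritParams add_class
#' @param scheme the label's scheme.
#' @param external_label the label, verbatim (an exact case-insensitive
#'   fallback is tried before failing).
#' @return The bound class identifier.  An unbound label raises a classed
#'   `atlasont_unmapped` error carrying the nearest candidates (if any) in its
#'   `candidates` field.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' class_name(ont, lookup_by_binding(ont, "aal", "Frontal_superior_right"))
lookup_by_binding <- function(ontology, scheme, external_label) {
  scheme <- match.arg(scheme, SCHEME_IDS)
  b <- ontology$bindings
  hit <- b$scheme == scheme & b$external_label == external_label
  if (!any(hit)) {
    hit <- b$scheme == scheme &
      tolower(b$external_label) == tolower(external_label)
  }
  if (any(hit)) return(b$class_id[hit][[1L]])
  near <- tryCatch(
    generate_candidates(normalize_label(scheme, external_label), ontology),
    error = function(e) NULL)
  ont_stop("unmapped", sprintf(
    "no %s binding for label '%s'", scheme, external_label),
    candidates = near)
}

#' Terminology bindings as a table
#'
#' @inheritParams add_class
#' @return Data frame with columns `class_id`, `scheme`, `external_label`,
#'   `external_id`, sorted canonically.
#' @export
bindings_table <- function(ontology) {
  b <- ontology$bindings
  b <- b[order(b$scheme, b$external_label, b$class_id), , drop = FALSE]
  rownames(b) <- NULL
  b
}
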