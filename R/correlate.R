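# Cross-atlas correlation: resolve a source-scheme label to its bound class
# and walk part_of / is_a relations to classes bound in a target scheme,
# reporting the explanatory path and the granularity level of each class.

GRANULARITY_LEVELS <- c("cytoarchitectural_area", "cortical_gray_matter",
                        "gyrus", "lobe", "hemisphere", "other")

CORRELATION_DIRECTIONS <- c("identity", "up", "down", "lateral_is_a")

#' Granularity level of a class
#'
#' Different atlases label at different granularities (Talairach at the
#' Brodmann-area level, FreeSurfer/DK at the cortical gray matter level, AAL
#' at the gyrus level).  The level is assigned deterministically from the
#' class's naming pattern: `"Brodmann area N of ..."` is a cytoarchitectural
#' area, `"Gray matter of ... gyrus"` cortical gray matter, a name ending in
#' `"gyrus"` a gyrus, then lobe, then hemisphere/cerebrum, else `other`.
#'
#' @inheritParams add_class
#' @param class class identifier or name.
#' @return One of `"cytoarchitectural_area"`, `"cortical_gray_matter"`,
#'   `"gyrus"`, `"lobe"`, `"hemisphere"`, `"other"`.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' granularity_level(ont, "Brodmann area 6 of right superior frontal gyrus")
#' granularity_level(ont, "Right superior frontal gyrus")
granularity_level <- function(ontology, class) {
  name <- tolower(class_name(ontology, class))
  if (grepl("brodmann area [0-9]+ of", name)) return("cytoarchitectural_area")
  if (grepl("^gray matter of .*gyrus$", name)) return("cortical_gray_matter")
  if (grepl("gyrus$", name)) return("gyrus")
  if (grepl("lobe", name)) return("lobe")
  if (grepl("hemisphere|cerebrum", name)) return("hemisphere")
  "other"
}

# bindings of a class in a scheme
class_bindings <- function(ontology, id, scheme) {
  b <- ontology$bindings
  b[b$class_id == id & b$scheme == scheme, , drop = FALSE]
}

# BFS over a mixed relation edge set keeping per-hop relation labels.
# edges: data.frame(from, to, relation).  Returns for each reached node the
# shortest hop path as data.frame(class_id, relation), source row first.
labeled_bfs <- function(edges, start, class_order) {
  parent <- list()
  parent_rel <- list()
  seen <- c(start)
  frontier <- start
  while (length(frontier)) {
    nxt <- character(0L)
    for (node in frontier) {
      hit <- edges[edges$from == node, , drop = FALSE]
      # deterministic expansion: part_of neighbors claim parents before is_a
      # ones (is_a is the fallback relation), then canonical class order
      hit <- hit[order(hit$relation != "part_of",
                       match(hit$to, class_order)), , drop = FALSE]
      for (i in seq_len(nrow(hit))) {
        nb <- hit$to[[i]]
        if (!nb %in% seen) {
          seen <- c(seen, nb)
          parent[[nb]] <- node
          parent_rel[[nb]] <- hit$relation[[i]]
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  paths <- list()
  for (node in setdiff(seen, start)) {
    ids <- node
    rels <- parent_rel[[node]]
    cur <- node
    while (parent[[cur]] != start) {
      cur <- parent[[cur]]
      ids <- c(cur, ids)
      rels <- c(parent_rel[[cur]], rels)
      }
    paths[[node]] <- data.frame(
      class_id = c(start, ids), relation = c(NA_character_, rels),
      stringsAsFactors = FALSE)
  }
  paths
}

# directed relation edges for correlation search
correlation_edges <- function(ontology, relations, direction) {
  st <- edge_table(ontology, relations)
  rel <- ifelse(st$relation == "is_a", "is_a", "part_of")
  if (direction == "up") {
    data.frame(from = st$subject, to = st$object, relation = rel,
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = st$object, to = st$subject, relation = rel,
               stringsAsFactors = FALSE)
  }
}

make_correlation_result <- function(ontology, source_scheme, source_label,
                                    target_scheme, target_label, class_id,
                                    path, direction) {
  structure(
    list(source_scheme = source_scheme, source_label = source_label,
         target_scheme = target_scheme, target_label = target_label,
         class_id = class_id, path = path, direction = direction),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation %s '%s' -> %s '%s'> direction=%s, %d hop(s)\n",
              x$source_scheme, x$source_label, x$target_scheme,
              x$target_label, x$direction, max(nrow(x$path) - 1L, 0L)))
  if (nrow(x$path) > 1L) {
    for (i in seq_len(nrow(x$path))) {
      cat(if (i == 1L) "  " else sprintf("  --%s--> ", x$path$relation[[i]]),
          x$path$class_id[[i]], "\n", sep = "")
    }
  }
  invisible(x)
}

# search one stage; returns results for every bound target class reached
correlation_stage <- function(ontology, start, target, edges, direction_label,
                              source_scheme, source_label, class_order) {
  paths <- labeled_bfs(edges, start, class_order)
  results <- list()
  for (node in names(paths)) {
    tb <- class_bindings(ontology, node, target)
    for (lab in tb$external_label) {
      path <- paths[[node]]
      dir <- if (all(path$relation[-1L] == "is_a")) "lateral_is_a"
             else direction_label
      results[[length(results) + 1L]] <- make_correlation_result(
        ontology, source_scheme, source_label, target, lab, node, path, dir)
    }
  }
  # deterministic: fewest hops first, then target label
  if (length(results)) {
    ord <- order(vapply(results, function(r) nrow(r$path), integer(1L)),
                 vapply(results, `[[`, character(1L), "target_label"))
    results <- results[ord]
  }
  results
}

#' Correlate an atlas label across schemes
#'
#' Resolves `raw` through its terminology binding in the source scheme, then
#' searches for classes bound in the target scheme: first the identical class
#' (direction `"identity"`, empty path), then transitive `part_of` ancestors
#' (`"up"`), then `part_of` descendants (`"down"`; one coarse label
#' legitimately correlates to many finer ones), and finally pure `is_a` hops
#' (`"lateral_is_a"`).  `is_a` edges participate in the up/down searches only
#' when the target scheme is non-lateralized (NeuroLex) or when the pure
#' `part_of` search finds nothing, mirroring how delateralized vocabularies
#' attach to sided classes.  Shortest paths are returned per target label,
#' with deterministic ordering.
#'
#' @inheritParams add_class
#' @param raw the source label, verbatim.
#' @param source,target scheme identifiers (`"talairach"`, `"dk"`, `"aal"`,
#'   `"neurolex"`).
#' @return A list of `correlation_result` objects, each with fields
#'   `source_scheme`, `source_label`, `target_scheme`, `target_label`,
#'   `class_id`, `direction`, and `path` (a data frame of `(class_id,
#'   relation)` hops whose first row is the source-bound class).  An empty
#'   list (with attribute `nearest_bound`) when no bound target class is
#'   reachable.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' res <- correlate_label(ont,
#'   "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6",
#'   source = "talairach", target = "dk")
#' res[[1]]$target_label
correlate_label <- function(ontology, raw, source, target) {
  source <- match.arg(source, SCHEME_IDS)
  target <- match.arg(target, SCHEME_IDS)
  start <- lookup_by_binding(ontology, source, raw)
  nm <- class_names(ontology)
  class_order <- names(ontology$classes)[order(nm, names(ontology$classes))]

  ident <- class_bindings(ontology, start, target)
  if (nrow(ident)) {
    empty_path <- data.frame(class_id = character(0L),
                             relation = character(0L),
                             stringsAsFactors = FALSE)
    return(lapply(ident$external_label, function(lab) {
      make_correlation_result(ontology, source, raw, target, lab, start,
                              empty_path, "identity")
    }))
  }

  allow_is_a <- target == "neurolex" || source == "neurolex"
  part_rels <- c("part_of", "regional_part_of")
  mixed_rels <- c(part_rels, "is_a")

  for (rels in if (allow_is_a) list(mixed_rels) else list(part_rels, mixed_rels)) {
    for (dir in c("up", "down")) {
      res <- correlation_stage(
        ontology, start, target,
        correlation_edges(ontology, rels, dir), dir, source, raw, class_order)
      if (length(res)) return(res)
    }
  }

  # diagnostic: nearest bound ancestors in any scheme
  anc <- ancestors(ontology, start, "part_of")
  bound <- anc[anc %in% ontology$bindings$class_id]
  res <- list()
  attr(res, "nearest_bound") <- bound
  res
}

#' Overlap between two structures through their shared parts
#'
#' Two classes from different parcellation principles (e.g. the gray matter
#' of a gyrus and a Brodmann area) overlap when they share transitive parts.
#' `a_only_exists` reports whether A has a part that is not under B (so part
#' of A lies outside B), and symmetrically for `b_only_exists`.
#'
#' @inheritParams add_class
#' @param class_a,class_b class identifiers or names.
#' @return A list with `shared_parts` (ids, canonically sorted),
#'   `a_only_exists`, `b_only_exists`.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' ov <- overlap_query(ont, "Gray matter of superior frontal gyrus",
#'                     "Brodmann area 6")
#' class_name(ont, ov$shared_parts[1])
overlap_query <- function(ontology, class_a, class_b) {
  a <- require_class(ontology, class_a)
  b <- require_class(ontology, class_b)
  da <- descendants(ontology, a, "part_of")
  db <- descendants(ontology, b, "part_of")
  shared <- intersect(da, db)
  nm <- class_names(ontology)
  list(
    shared_parts = shared[order(nm[shared], shared)],
    a_only_exists = length(setdiff(da, c(db, b))) > 0L,
    b_only_exists = length(setdiff(db, c(da, a))) > 0L
  )
}

#' Annotate a table of atlas labels with ontology knowledge
#'
#' Each row gains the bound class, its granularity level, and the requested
#' ancestor expansion (preferred names, `" | "`-separated, in closure order).
#' Unmapped labels are flagged, never dropped.
#'
#' @inheritParams add_class
#' @param rows data frame with columns `scheme` and `label`.
#' @param expand relation to expand ancestors along (default `"part_of"`).
#' @return The input with additional columns `class_id`, `class_name`,
#'   `granularity`, `ancestors`, `mapped`; the number of unmapped rows is
#'   attached as attribute `n_unmapped` and reported via `message()`.
#' @export
annotate_table <- function(ontology, rows, expand = "part_of") {
  stopifnot(is.data.frame(rows), all(c("scheme", "label") %in% names(rows)))
  n <- nrow(rows)
  out <- rows
  out$class_id <- rep(NA_character_, n)
  out$class_name <- rep(NA_character_, n)
  out$granularity <- rep(NA_character_, n)
  out$ancestors <- rep(NA_character_, n)
  out$mapped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    id <- tryCatch(
      lookup_by_binding(ontology, out$scheme[[i]], out$label[[i]]),
      atlasont_unmapped = function(e) NA_character_)
    if (is.na(id)) next
    anc <- ancestors(ontology, id, expand)
    out$class_id[[i]] <- id
    out$class_name[[i]] <- class_name(ontology, id)
    out$granularity[[i]] <- granularity_level(ontology, id)
    out$ancestors[[i]] <- paste(
      vapply(anc, function(a) class_name(ontology, a), character(1L)),
      collapse = " | ")
    out$mapped[[i]] <- TRUE
  }
  n_unmapped <- sum(!out$mapped)
  if (n) message(sprintf("annotated %d row(s); %d unmapped", n, n_unmapped))
  attr(out, "n_unmapped") <- n_unmapped
  out
}
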