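# In-memory ontology store: anatomical classes plus taxonomic (is_a) and
# partonomic (part_of, regional_part_of) assertions.  The store is a plain
# list with copy semantics: every mutating operation returns a new ontology.

RELATION_KINDS <- c("is_a", "part_of", "regional_part_of")
LATERALITIES <- c("left", "right", "unpaired")
ENTITY_CATEGORIES <- c("material_structure", "anatomical_space")

#' Signal a classed atlasont error
#'
#' @param class short condition class suffix, e.g. `"cycle"`.
#' @param message error message.
#' @param ... fields attached to the condition (e.g. `path`, `candidates`).
#' @noRd
ont_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("atlasont_", class), "atlasont_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Create an empty ontology
#'
#' An ontology holds anatomical classes, structural assertions (`is_a`,
#' `part_of`, `regional_part_of`), terminology bindings to external atlas
#' schemes, connectivity assertions, and sulcus/sulcal-segment adjacency
#' records.
#'
#' @return An object of class `ontology`.
#' @seealso [add_class()], [assert_structural()], [build_fixture_ontology()]
#' @export
#' @examples
#' ont <- ontology()
#' ont <- add_class(ont, anatomical_class("Right frontal lobe",
#'                                        laterality = "right"))
ontology <- function() {
  structure(
    list(
      classes = list(),
      structural = empty_structural(),
      bindings = empty_bindings(),
      connectivity = empty_connectivity(),
      sulcal_links = empty_sulcal_links()
    ),
    class = "ontology"
  )
}

empty_structural <- function() {
  data.frame(subject = character(), relation = character(),
             object = character(), stringsAsFactors = FALSE)
}

empty_bindings <- function() {
  data.frame(class_id = character(), scheme = character(),
             external_label = character(), external_id = character(),
             stringsAsFactors = FALSE)
}

empty_connectivity <- function() {
  data.frame(subject = character(), kind = character(), object = character(),
             via = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

empty_sulcal_links <- function() {
  data.frame(sulcus = character(), segment = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %d classes, %d structural assertions, %d bindings, %d connectivity assertions\n",
    length(x$classes), nrow(x$structural), nrow(x$bindings),
    nrow(x$connectivity)))
  invisible(x)
}

#' Canonical class identifier for a preferred name
#'
#' Identifiers are namespace-prefixed lowercase slugs of the preferred name
#' (e.g. `nfma:brodmann-area-6-of-right-superior-frontal-gyrus`), so they are
#' deterministic and stable under serialization round-trips.
#'
#' @param name preferred name(s) of classes (vectorized).
#' @return A character vector of identifiers.
#' @export
#' @examples
#' make_class_id("Right superior frontal gyrus")
make_class_id <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L, all(nzchar(name)))
  slug <- tolower(trimws(name))
  slug <- gsub("[^a-z0-9]+", "-", slug)
  slug <- gsub("^-+|-+$", "", slug)
  if (any(!nzchar(slug))) {
    ont_stop("bad_name", "class name yields an empty identifier")
  }
  paste0("nfma:", slug)
}

# case-insensitive, whitespace-collapsed name key used for all name lookups
name_key <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Construct an anatomical class
#'
#' @param preferred_name non-empty preferred English name; also determines the
#'   class identifier via [make_class_id()] unless `id` is given.
#' @param synonyms character vector of alternative names (the preferred name
#'   itself is not allowed as a synonym).
#' @param laterality one of `"left"`, `"right"`, `"unpaired"`.
#' @param category `"material_structure"` (gyri, tracts, nuclei, gray matter)
#'   or `"anatomical_space"` (sulci, ventricles).  Connectivity assertions are
#'   only permitted between material structures.
#' @param definition optional free-text definition.
#' @param id optional explicit identifier; defaults to the slug of the name.
#' @return An object of class `anatomical_class`.
#' @export
#' @examples
#' anatomical_class("Temporal horn of lateral ventricle",
#'                  synonyms = "Inferior horn of the lateral ventricle",
#'                  category = "anatomical_space")
anatomical_class <- function(preferred_name, synonyms = character(),
                             laterality = "unpaired",
                             category = "material_structure",
                             definition = NA_character_, id = NULL) {
  if (!is.character(preferred_name) || length(preferred_name) != 1L ||
      !nzchar(trimws(preferred_name))) {
    ont_stop("bad_name", "preferred_name must be a non-empty string")
  }
  laterality <- match.arg(laterality, LATERALITIES)
  category <- match.arg(category, ENTITY_CATEGORIES)
  synonyms <- unique(as.character(synonyms))
  if (any(name_key(synonyms) == name_key(preferred_name))) {
    ont_stop("bad_name", sprintf(
      "preferred name %s may not also be listed as a synonym", preferred_name))
  }
  structure(
    list(
      id = if (is.null(id)) make_class_id(preferred_name) else id,
      preferred_name = preferred_name,
      synonyms = sort(synonyms),
      laterality = laterality,
      category = category,
      definition = definition
    ),
    class = "anatomical_class"
  )
}

#' @export
print.anatomical_class <- function(x, ...) {
  cat(sprintf("<anatomical_class> %s (%s, %s, %s)\n", x$preferred_name,
              x$id, x$laterality, x$category))
  invisible(x)
}

#' Add a class to an ontology
#'
#' The identifier and the preferred name must both be new; name comparison is
#' case-insensitive with internal whitespace collapsed, because atlas sources
#' vary in casing.
#'
#' @param ontology an [ontology()].
#' @param class an [anatomical_class()].
#' @return The updated ontology.  The class is afterwards retrievable by id,
#'   by preferred name, and by any synonym via [resolve_class()].
#' @export
add_class <- function(ontology, class) {
  stopifnot(inherits(ontology, "ontology"), inherits(class, "anatomical_class"))
  if (class$id %in% names(ontology$classes)) {
    ont_stop("duplicate_class", sprintf(
      "a class with id %s already exists (%s)", class$id,
      ontology$classes[[class$id]]$preferred_name))
  }
  existing <- class_names(ontology)
  clash <- names(existing)[name_key(existing) == name_key(class$preferred_name)]
  if (length(clash)) {
    ont_stop("duplicate_class", sprintf(
      "preferred name %s conflicts with existing class %s",
      class$preferred_name, clash[[1L]]))
  }
  ontology$classes[[class$id]] <- class
  ontology
}

#' Does the ontology contain a class?
#'
#' @inheritParams add_class
#' @param id class identifier.
#' @return `TRUE` or `FALSE`.
#' @export
has_class <- function(ontology, id) id %in% names(ontology$classes)

# named character vector id -> preferred name
class_names <- function(ontology) {
  vapply(ontology$classes, `[[`, character(1L), "preferred_name")
}

#' Resolve a class by id, preferred name, or synonym
#'
#' Lookup is case-insensitive with internal whitespace collapsed.
#'
#' @inheritParams add_class
#' @param x an identifier, preferred name, or synonym.
#' @return The class identifier, or `NA_character_` if nothing matches.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' resolve_class(ont, "gray matter of Superior Frontal Gyrus")
resolve_class <- function(ontology, x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% names(ontology$classes)) return(x)
  key <- name_key(x)
  nm <- class_names(ontology)
  hit <- names(nm)[name_key(nm) == key]
  if (length(hit)) return(hit[[1L]])
  for (cls in ontology$classes) {
    if (length(cls$synonyms) && key %in% name_key(cls$synonyms)) return(cls$id)
  }
  NA_character_
}

# resolve or fail; used by operations whose precondition is an existing class
require_class <- function(ontology, x, what = "class") {
  id <- resolve_class(ontology, x)
  if (is.na(id)) {
    ont_stop("unknown_class", sprintf("unknown %s: %s", what, x))
  }
  id
}

#' Preferred name of a class
#'
#' @inheritParams has_class
#' @return The preferred name string.
#' @export
class_name <- function(ontology, id) {
  id <- require_class(ontology, id)
  ontology$classes[[id]]$preferred_name
}

#' Assert a structural relationship between two classes
#'
#' `regional_part_of` is a sub-relation of `part_of`: its assertions count
#' toward the `part_of` transitive closure.  `has_regional_part` is simply the
#' inverse reading of `regional_part_of` and is never stored as its own kind.
#' Each relation family (`is_a`; `part_of` including `regional_part_of`) must
#' stay acyclic and irreflexive; re-asserting an existing edge is a no-op.
#'
#' @inheritParams add_class
#' @param subject,object class identifiers or names; the subject is the part
#'   (or subclass), the object the whole (or superclass).
#' @param relation one of `"is_a"`, `"part_of"`, `"regional_part_of"`.
#' @return The updated ontology.
#' @export
#' @examples
#' ont <- ontology()
#' ont <- add_class(ont, anatomical_class("Right frontal lobe", laterality = "right"))
#' ont <- add_class(ont, anatomical_class("Right cerebral hemisphere", laterality = "right"))
#' ont <- assert_structural(ont, "Right frontal lobe", "regional_part_of",
#'                          "Right cerebral hemisphere")
assert_structural <- function(ontology, subject, relation, object) {
  relation <- match.arg(relation, RELATION_KINDS)
  subject <- require_class(ontology, subject, "subject")
  object <- require_class(ontology, object, "object")
  if (subject == object) {
    ont_stop("irreflexive", sprintf(
      "%s cannot be %s itself", class_name(ontology, subject), relation))
  }
  st <- ontology$structural
  dup <- st$subject == subject & st$relation == relation & st$object == object
  if (any(dup)) return(ontology)
  # adding subject -> object creates a cycle iff object already reaches subject
  fam <- relation_family(relation)
  reach <- bfs_reach(edge_table(ontology, fam), object, "up", parents = TRUE)
  if (subject %in% reach$visited) {
    path <- c(walk_parents(reach$parent, from = object, to = subject), object)
    ont_stop("cycle", sprintf(
      "asserting %s %s %s would create a cycle: %s",
      class_name(ontology, subject), relation, class_name(ontology, object),
      paste(vapply(path, function(i) class_name(ontology, i), character(1L)),
            collapse = " -> ")),
      path = path)
  }
  ontology$structural <- rbind(st, data.frame(
    subject = subject, relation = relation, object = object,
    stringsAsFactors = FALSE))
  ontology
}

# relations contributing edges to a family closure
relation_family <- function(relation) {
  if (relation %in% c("part_of", "regional_part_of")) {
    if (relation == "part_of") c("part_of", "regional_part_of") else relation
  } else {
    "is_a"
  }
}

# structural edges restricted to the given relation kinds
edge_table <- function(ontology, kinds) {
  st <- ontology$structural
  st[st$relation %in% kinds, , drop = FALSE]
}

# Breadth-first reachability over structural edges.
# direction "up" follows subject -> object, "down" object -> subject.
# Returns visited ids (excluding the start) in BFS order with depth ties
# broken by preferred name downstream; optionally parent pointers.
bfs_reach <- function(edges, start, direction = c("up", "down"),
                      parents = FALSE) {
  direction <- match.arg(direction)
  if (direction == "up") {
    from <- edges$subject; to <- edges$object
  } else {
    from <- edges$object; to <- edges$subject
  }
  adj <- split(to, from)
  visited <- character(0L)
  parent <- list()
  seen <- new.env(parent = emptyenv())
  assign(start, TRUE, envir = seen)
  frontier <- start
  while (length(frontier)) {
    nxt <- character(0L)
    for (node in frontier) {
      for (nb in adj[[node]]) {
        if (!exists(nb, envir = seen, inherits = FALSE)) {
          assign(nb, TRUE, envir = seen)
          if (parents) parent[[nb]] <- node
          nxt <- c(nxt, nb)
        }
      }
    }
    visited <- c(visited, list(nxt))
    frontier <- nxt
  }
  list(visited = unlist(visited), levels = visited, parent = parent)
}

# follow parent pointers from `to` back to `from`; returns ids from -> to
walk_parents <- function(parent, from, to) {
  path <- to
  while (path[[1L]] != from) {
    path <- c(parent[[path[[1L]]]], path)
  }
  path
}

# shared driver for ancestors()/descendants(); deterministic order:
# BFS depth, ties broken by preferred name
closure_query <- function(ontology, class, relation, direction) {
  relation <- match.arg(relation, RELATION_KINDS)
  id <- require_class(ontology, class)
  edges <- edge_table(ontology, relation_family(relation))
  reach <- bfs_reach(edges, id, direction)
  nm <- class_names(ontology)
  out <- lapply(reach$levels, function(level) level[order(nm[level], level)])
  unname(unlist(out))
}

#' Transitive ancestors of a class
#'
#' Returns the reflexive-free transitive closure of `class` under `relation`,
#' upward: for `part_of` this walks both `part_of` and `regional_part_of`
#' edges, revealing every granularity level a fine-grained label implicitly
#' encodes (cytoarchitectural area, gray matter, gyrus, lobe, hemisphere).
#' Order is deterministic: breadth-first depth, ties broken by preferred name.
#'
#' @inheritParams add_class
#' @param class class identifier or name.
#' @param relation relation kind; `"part_of"` includes `regional_part_of`
#'   edges.
#' @return Character vector of class identifiers (possibly empty).
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' nms <- vapply(ancestors(ont, "Brodmann area 6 of right superior frontal gyrus",
#'                         "part_of"),
#'               function(id) class_name(ont, id), character(1))
#' nms
ancestors <- function(ontology, class, relation = "part_of") {
  closure_query(ontology, class, relation, "up")
}

#' Transitive descendants of a class
#'
#' The inverse of [ancestors()]: for `relation = "regional_part_of"` this is
#' the `has_regional_part` listing, e.g. the Brodmann-area segments making up
#' the gray matter of a gyrus.
#'
#' @inheritParams ancestors
#' @return Character vector of class identifiers (possibly empty).
#' @export
descendants <- function(ontology, class, relation = "part_of") {
  closure_query(ontology, class, relation, "down")
}

#' Validate the integrity of an ontology
#'
#' Reports (never throws on) content problems: cycles in the `is_a` or
#' `part_of` families, structural/connectivity assertions citing unknown
#' classes, duplicate preferred names, connectivity assertions on
#' anatomical-space classes, and non-exclusive term reuse (a regional part
#' sharing its preferred name with a whole it is a part of, as when the same
#' term labels both a tract and one of its segments).
#'
#' @inheritParams add_class
#' @return A data frame with columns `kind` and `detail`, one row per
#'   violation; zero rows when the ontology is clean.
#' @export
#' @examples
#' validate_ontology(build_fixture_ontology())
validate_ontology <- function(ontology) {
  out <- list()
  add <- function(kind, detail) {
    out[[length(out) + 1L]] <<- data.frame(kind = kind, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  ids <- names(ontology$classes)
  nm <- class_names(ontology)

  # referential integrity
  st <- ontology$structural
  for (col in c("subject", "object")) {
    bad <- setdiff(unique(st[[col]]), ids)
    for (b in bad) add("dangling", sprintf("structural %s cites unknown class %s", col, b))
  }
  cn <- ontology$connectivity
  for (col in c("subject", "object", "via")) {
    vals <- cn[[col]]
    bad <- setdiff(unique(vals[!is.na(vals)]), ids)
    for (b in bad) add("dangling", sprintf("connectivity %s cites unknown class %s", col, b))
  }

  # duplicate preferred names
  keys <- name_key(nm)
  for (k in unique(keys[duplicated(keys)])) {
    add("duplicate_name", sprintf(
      "classes %s share preferred name '%s'",
      paste(ids[keys == k], collapse = ", "), nm[keys == k][[1L]]))
  }

  # cycles per relation family
  st_ok <- st[st$subject %in% ids & st$object %in% ids, , drop = FALSE]
  for (fam in list(c("part_of", "regional_part_of"), "is_a")) {
    edges <- st_ok[st_ok$relation %in% fam, , drop = FALSE]
    for (cyc in find_cycles(edges)) {
      add("cycle", sprintf("%s cycle: %s", fam[[1L]],
                           paste(nm[cyc], collapse = " -> ")))
    }
  }

  # connectivity category constraint: material structures only
  if (nrow(cn)) {
    cats <- vapply(ontology$classes, `[[`, character(1L), "category")
    for (i in seq_len(nrow(cn))) {
      for (col in c("subject", "object", "via")) {
        v <- cn[[col]][[i]]
        if (!is.na(v) && v %in% ids && cats[[v]] != "material_structure") {
          add("connectivity_category", sprintf(
            "connectivity %s(%s, %s) involves anatomical space %s",
            cn$kind[[i]], nm[[cn$subject[[i]]]], nm[[cn$object[[i]]]], nm[[v]]))
        }
      }
    }
  }

  # non-exclusive terms: a part sharing its name with a transitive whole
  part_edges <- st_ok[st_ok$relation %in% c("part_of", "regional_part_of"), ,
                      drop = FALSE]
  if (nrow(part_edges) && !length(find_cycles(part_edges))) {
    for (id in unique(part_edges$subject)) {
      wholes <- bfs_reach(part_edges, id, "up")$visited
      same <- wholes[name_key(nm[wholes]) == name_key(nm[[id]])]
      for (w in same) {
        add("non_exclusive_term", sprintf(
          "part %s reuses the name of whole %s ('%s')", id, w, nm[[id]]))
      }
    }
  }

  if (!length(out)) {
    return(data.frame(kind = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Kahn peeling; every node left over lies on a cycle.  Returns a list of
# cycles (each a character vector of ids, first id repeated at the end).
find_cycles <- function(edges) {
  if (!nrow(edges)) return(list())
  nodes <- unique(c(edges$subject, edges$object))
  out_adj <- split(edges$object, edges$subject)
  indeg <- table(factor(edges$object, levels = nodes))
  indeg <- setNames(as.integer(indeg), nodes)
  queue <- nodes[indeg == 0L]
  alive <- setNames(rep(TRUE, length(nodes)), nodes)
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]
    alive[[n]] <- FALSE
    for (m in out_adj[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- c(queue, m)
    }
  }
  left <- names(alive)[alive]
  in_adj <- split(edges$subject, edges$object)
  cycles <- list()
  remaining <- left
  while (length(remaining)) {
    # every leftover node keeps an in-edge inside the leftover set, so
    # walking predecessors must eventually revisit a node: that is a cycle
    start <- remaining[[1L]]
    path <- start
    node <- start
    repeat {
      prev <- intersect(in_adj[[node]], left)
      node <- prev[[1L]]
      if (node %in% path) {
        cyc <- rev(c(path[seq(match(node, path), length(path))], node))
        cycles[[length(cycles) + 1L]] <- cyc
        remaining <- setdiff(remaining, path)
        break
      }
      path <- c(path, node)
    }
  }
  cycles
}
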