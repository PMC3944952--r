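# White-matter connectivity relations and pathway inference.
#
# Relation kinds span three granularities: neuron level (innervates,
# synapses_with), tract level (projects_to / projects_from: where a fiber
# tract terminates / originates), and gray-matter region level
# (sends_output_to / receives_input_from, declared subproperties of the tract
# projections, plus the ternary has_pathway(A, B, via = tract)).

CONNECTIVITY_KINDS <- c("innervates", "synapses_with", "projects_to",
                        "projects_from", "sends_output_to",
                        "receives_input_from", "has_pathway")

# input aliases canonicalized on load/assertion
CONNECTIVITY_ALIASES <- c(terminate_in = "projects_to",
                          terminates_in = "projects_to",
                          originate_in = "projects_from",
                          originates_in = "projects_from")

# kind -> its superproperty at the tract-projection level
CONNECTIVITY_SUPER <- c(sends_output_to = "projects_to",
                        receives_input_from = "projects_from")

canonical_kind <- function(kind) {
  if (kind %in% names(CONNECTIVITY_ALIASES)) {
    kind <- CONNECTIVITY_ALIASES[[kind]]
  }
  match.arg(kind, CONNECTIVITY_KINDS)
}

require_material <- function(ontology, id, role) {
  if (ontology$classes[[id]]$category != "material_structure") {
    ont_stop("category", sprintf(
      "connectivity %s %s is an anatomical space, not a material structure",
      role, class_name(ontology, id)))
  }
}

#' Assert a connectivity relationship
#'
#' Endpoints (and the `via` tract) must be material structures; anatomical
#' spaces carry no connectivity.  `has_pathway` is ternary and requires
#' `via`, the fiber tract carrying the projection; every other kind forbids
#' it.  The symmetric `synapses_with` is stored once (endpoints in canonical
#' order) and queried in both directions.  `terminate_in` and `originate_in`
#' are accepted as aliases of `projects_to` and `projects_from`.
#'
#' @inheritParams add_class
#' @param subject,object class identifiers or names.
#' @param kind one of `innervates`, `synapses_with`, `projects_to`,
#'   `projects_from`, `sends_output_to`, `receives_input_from`,
#'   `has_pathway`.
#' @param via tract class for `has_pathway`, otherwise `NULL`.
#' @param provenance `"asserted"` (the default) or `"inferred"`.
#' @return The updated ontology.
#' @export
#' @examples
#' ont <- build_fixture_ontology()
#' ont <- assert_connectivity(ont, "Putamen", "sends_output_to", "Globus pallidus")
assert_connectivity <- function(ontology, subject, kind, object, via = NULL,
                                provenance = c("asserted", "inferred")) {
  kind <- canonical_kind(kind)
  provenance <- match.arg(provenance)
  subject <- require_class(ontology, subject, "subject")
  object <- require_class(ontology, object, "object")
  require_material(ontology, subject, "subject")
  require_material(ontology, object, "object")
  if (kind == "has_pathway") {
    if (is.null(via) || is.na(via)) {
      ont_stop("pathway_via", "has_pathway is ternary: the via tract is required")
    }
    via <- require_class(ontology, via, "via tract")
    require_material(ontology, via, "via tract")
  } else {
    if (!is.null(via) && !is.na(via)) {
      ont_stop("pathway_via", sprintf("%s does not take a via tract", kind))
    }
    via <- NA_character_
  }
  if (kind == "synapses_with" && object < subject) {
    tmp <- subject; subject <- object; object <- tmp
  }
  cn <- ontology$connectivity
  dup <- cn$subject == subject & cn$kind == kind & cn$object == object &
    (is.na(cn$via) == is.na(via)) &
    (is.na(cn$via) | cn$via %in% via)
  if (any(dup)) return(ontology)
  ontology$connectivity <- rbind(cn, data.frame(
    subject = subject, kind = kind, object = object, via = via,
    provenance = provenance, stringsAsFactors = FALSE))
  ontology
}

#' Connectivity assertions as a table
#'
#' @inheritParams add_class
#' @param kind optional filter; querying a tract-level projection also
#'   reports its region-level subproperty (`projects_to` includes
#'   `sends_output_to`, `projects_from` includes `receives_input_from`).
#' @param provenance optional filter, `"asserted"` or `"inferred"`.
#' @return Data frame with columns `subject`, `kind`, `object`, `via`,
#'   `provenance`, canonically sorted.
#' @export
connectivity_table <- function(ontology, kind = NULL, provenance = NULL) {
  cn <- ontology$connectivity
  if (!is.null(kind)) {
    kind <- canonical_kind(kind)
    kinds <- c(kind, names(CONNECTIVITY_SUPER)[CONNECTIVITY_SUPER == kind])
    cn <- cn[cn$kind %in% kinds, , drop = FALSE]
  }
  if (!is.null(provenance)) {
    cn <- cn[cn$provenance == provenance, , drop = FALSE]
  }
  cn <- cn[order(cn$kind, cn$subject, cn$object, cn$via,
                 method = "radix", na.last = TRUE), , drop = FALSE]
  rownames(cn) <- NULL
  cn
}

#' Derive region-level pathways from tract projections
#'
#' For every tract `T` asserted to `projects_from` region `A` and
#' `projects_to` region `B`, the origin-by-termination product yields the
#' inferred region-level assertions `sends_output_to(A, B)` and the ternary
#' `has_pathway(A, B, via = T)`; the duality `sends_output_to(A, B)` iff
#' `receives_input_from(B, A)` is then completed over asserted and derived
#' edges alike.  Derived assertions are flagged `provenance = "inferred"` and
#' never overwrite asserted ones; the derivation is monotone and idempotent.
#'
#' @inheritParams add_class
#' @return The updated ontology including the inferred assertions (inspect
#'   them with `connectivity_table(ont, provenance = "inferred")`).
#' @export
#' @examples
#' ont <- derive_pathways(build_fixture_ontology())
#' connectivity_table(ont, kind = "has_pathway")
derive_pathways <- function(ontology) {
  cn <- ontology$connectivity
  tracts <- unique(cn$subject[cn$kind %in% c("projects_from", "projects_to")])
  for (tr in sort(tracts)) {
    origins <- sort(cn$object[cn$subject == tr & cn$kind == "projects_from"])
    targets <- sort(cn$object[cn$subject == tr & cn$kind == "projects_to"])
    for (a in origins) {
      for (b in targets) {
        if (a == b) next
        ontology <- assert_connectivity(ontology, a, "sends_output_to", b,
                                        provenance = "inferred")
        ontology <- assert_connectivity(ontology, a, "has_pathway", b,
                                        via = tr, provenance = "inferred")
      }
    }
  }
  # duality completion: sends_output_to(A,B) <-> receives_input_from(B,A)
  repeat {
    cn <- ontology$connectivity
    before <- nrow(cn)
    snd <- cn[cn$kind == "sends_output_to", , drop = FALSE]
    for (i in seq_len(nrow(snd))) {
      ontology <- assert_connectivity(ontology, snd$object[[i]],
                                      "receives_input_from", snd$subject[[i]],
                                      provenance = "inferred")
    }
    rcv <- cn[cn$kind == "receives_input_from", , drop = FALSE]
    for (i in seq_len(nrow(rcv))) {
      ontology <- assert_connectivity(ontology, rcv$object[[i]],
                                      "sends_output_to", rcv$subject[[i]],
                                      provenance = "inferred")
    }
    if (nrow(ontology$connectivity) == before) break
  }
  ontology
}

# region-level neighbors; direction "in" lists sources, "out" targets.
# A -> B is a flow edge iff sends_output_to(A,B), receives_input_from(B,A),
# or has_pathway(A,B,via); asserted and inferred edges are pooled.
region_neighbors <- function(ontology, region, direction) {
  region <- require_class(ontology, region, "region")
  cn <- ontology$connectivity
  flow <- rbind(
    setNames(cn[cn$kind %in% c("sends_output_to", "has_pathway"),
                c("subject", "object", "via"), drop = FALSE],
             c("from", "to", "via")),
    setNames(cn[cn$kind == "receives_input_from",
                c("object", "subject", "via"), drop = FALSE],
             c("from", "to", "via"))
  )
  if (direction == "in") {
    out <- flow[flow$to == region, c("from", "via"), drop = FALSE]
  } else {
    out <- flow[flow$from == region, c("to", "via"), drop = FALSE]
  }
  names(out) <- c("region", "via")
  out <- unique(out)
  out <- out[order(out$region, out$via, method = "radix", na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-level inputs and outputs
#'
#' Union of asserted and derived region-level edges: `inputs_of(B)` lists `A`
#' (with the carrying tract when known) exactly when `outputs_of(A)` lists
#' `B`.
#'
#' @inheritParams add_class
#' @param region class identifier or name of a gray-matter region.
#' @return Data frame with columns `region` (the other endpoint) and `via`
#'   (tract id or `NA`), canonically sorted.
#' @export
#' @examples
#' ont <- derive_pathways(build_fixture_ontology())
#' inputs_of(ont, "Putamen")
inputs_of <- function(ontology, region) {
  region_neighbors(ontology, region, "in")
}

#' @rdname inputs_of
#' @export
outputs_of <- function(ontology, region) {
  region_neighbors(ontology, region, "out")
}
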