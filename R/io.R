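# Plain-text serialization bundle: a Turtle-dialect ontology file plus TSV
# tables for bindings and connectivity.  The dialect is a restricted,
# canonically ordered subset of W3C Turtle (two namespaces, prefixed names
# and quoted literals only) so that saving the same ontology twice produces
# byte-identical files.  Relation IRIs are named exactly after the relation
# and connectivity kind enums, making files self-describing; the ternary
# has_pathway relation is written as a reified statement node with a stable
# naming scheme (stmt:c0001, ... in canonical order).

TTL_PREFIXES <- c(nfma = "urn:atlasont:class:",
                  rel = "urn:atlasont:relation:",
                  stmt = "urn:atlasont:statement:")

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

ttl_literal <- function(x) sprintf("\"%s\"", ttl_escape(x))

#' Save an ontology as a plain-text bundle
#'
#' Writes `ontology.ttl` (classes, structural assertions, sulcus links and
#' reified connectivity statements, in canonical order), `bindings.tsv` and
#' `connectivity.tsv` into `path`.  Output is deterministic: two saves of the
#' same ontology are byte-identical, and `load_ontology(save_ontology(x))`
#' reproduces `x` structurally.
#'
#' @inheritParams add_class
#' @param path directory to write into (created if needed).
#' @return `path`, invisibly.
#' @seealso [load_ontology()]
#' @export
save_ontology <- function(ontology, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lines <- c(
    "# atlasont ontology bundle",
    sprintf("# writer: atlasont %s",
            as.character(utils::packageVersion("atlasont"))),
    sprintf("@prefix %s: <%s> .", names(TTL_PREFIXES), TTL_PREFIXES),
    "")

  # classes, sorted by id
  for (id in sort(names(ontology$classes))) {
    cls <- ontology$classes[[id]]
    body <- c(
      "a rel:AnatomicalClass",
      sprintf("rel:preferred_name %s", ttl_literal(cls$preferred_name)),
      sprintf("rel:laterality %s", ttl_literal(cls$laterality)),
      sprintf("rel:category %s", ttl_literal(cls$category)),
      if (length(cls$synonyms)) {
        sprintf("rel:synonym %s", vapply(sort(cls$synonyms), ttl_literal,
                                         character(1L)))
      },
      if (!is.na(cls$definition)) {
        sprintf("rel:definition %s", ttl_literal(cls$definition))
      })
    lines <- c(lines, sprintf("%s %s ;", id, body[[1L]]),
               sprintf("    %s %s", body[-1L],
                       c(rep(";", length(body) - 2L), ".")),
               "")
  }

  # structural triples, canonically sorted
  st <- ontology$structural
  st <- st[order(st$relation, st$subject, st$object), , drop = FALSE]
  lines <- c(lines, sprintf("%s rel:%s %s .", st$subject, st$relation,
                            st$object))

  # sulcus <-> sulcal segment adjacency
  sl <- ontology$sulcal_links
  sl <- sl[order(sl$sulcus, sl$segment), , drop = FALSE]
  if (nrow(sl)) {
    lines <- c(lines, "", sprintf("%s rel:has_sulcal_segment %s .",
                                  sl$sulcus, sl$segment))
  }

  # connectivity as reified statements with stable node names
  cn <- connectivity_table(ontology)
  if (nrow(cn)) {
    lines <- c(lines, "")
    for (i in seq_len(nrow(cn))) {
      body <- c(
        "a rel:ConnectivityStatement",
        sprintf("rel:subject %s", cn$subject[[i]]),
        sprintf("rel:kind %s", ttl_literal(cn$kind[[i]])),
        sprintf("rel:object %s", cn$object[[i]]),
        if (!is.na(cn$via[[i]])) sprintf("rel:via %s", cn$via[[i]]),
        sprintf("rel:provenance %s", ttl_literal(cn$provenance[[i]])))
      lines <- c(lines, sprintf("stmt:c%04d %s ;", i, body[[1L]]),
                 sprintf("    %s %s", body[-1L],
                         c(rep(";", length(body) - 2L), ".")),
                 "")
    }
  }

  writeLines(lines, file.path(path, "ontology.ttl"))

  b <- bindings_table(ontology)
  utils::write.table(b, file.path(path, "bindings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cn, file.path(path, "connectivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# tokenizer: quoted literals (with escapes) or runs of non-space characters
ttl_tokens <- function(line) {
  m <- gregexpr('"(\\\\.|[^"\\\\])*"|[^ \t]+', line)[[1L]]
  if (m[[1L]] == -1L) return(character(0L))
  regmatches(line, list(m))[[1L]]
}

parse_stop <- function(lineno, msg) {
  ont_stop("parse", sprintf("ontology.ttl line %d: %s", lineno, msg))
}

# parse the restricted Turtle dialect into raw statement tables
parse_ttl <- function(file) {
  lines <- readLines(file)
  prefixes <- character(0L)
  triples <- list()
  subject <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- ttl_tokens(line)
    if (toks[[1L]] == "@prefix") {
      if (length(toks) != 4L || toks[[4L]] != ".") {
        parse_stop(ln, "malformed @prefix declaration")
      }
      prefixes <- c(prefixes, sub(":$", "", toks[[2L]]))
      next
    }
    terminator <- toks[[length(toks)]]
    if (!terminator %in% c(";", ".")) {
      parse_stop(ln, "statement line must end with ';' or '.'")
    }
    toks <- toks[-length(toks)]
    if (is.null(subject)) {
      if (length(toks) != 3L) {
        parse_stop(ln, "expected 'subject predicate object'")
      }
      subject <- toks[[1L]]
      po <- toks[2:3]
    } else {
      if (length(toks) != 2L) {
        parse_stop(ln, "expected 'predicate object' continuation")
      }
      po <- toks
    }
    pre <- sub(":.*$", "", c(subject, po[[1L]]))
    unknown <- setdiff(pre[grepl(":", c(subject, po[[1L]]), fixed = TRUE)],
                       c(prefixes, "a"))
    if (length(unknown)) {
      parse_stop(ln, sprintf("undeclared prefix '%s'", unknown[[1L]]))
    }
    triples[[length(triples) + 1L]] <- data.frame(
      subject = subject, predicate = po[[1L]], object = po[[2L]], line = ln,
      stringsAsFactors = FALSE)
    if (terminator == ".") subject <- NULL
  }
  if (!is.null(subject)) {
    parse_stop(length(lines), "unterminated statement block")
  }
  if (!length(triples)) {
    return(data.frame(subject = character(0L), predicate = character(0L),
                      object = character(0L), line = integer(0L),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, triples)
}

is_literal <- function(x) startsWith(x, "\"")
literal_value <- function(x) ttl_unescape(sub('^"(.*)"$', "\\1", x))

#' Load an ontology bundle
#'
#' Reads the bundle written by [save_ontology()].  Structural or connectivity
#' statements citing undeclared classes, unknown relation IRIs, and malformed
#' lines raise parse errors with a line number.  When `bindings.tsv` /
#' `connectivity.tsv` are present they are authoritative for bindings and
#' connectivity (curators edit the TSVs by hand); otherwise the reified
#' statements in the Turtle file are used.  Connectivity kind aliases
#' (`terminate_in`, `originate_in`) are canonicalized on load.
#'
#' @param path directory containing `ontology.ttl` (and optionally the TSVs).
#' @return An [ontology()].
#' @export
load_ontology <- function(path) {
  ttl <- file.path(path, "ontology.ttl")
  if (!file.exists(ttl)) {
    ont_stop("io", sprintf("no ontology.ttl under %s", path))
  }
  tr <- parse_ttl(ttl)

  class_rows <- tr[tr$predicate == "a" & tr$object == "rel:AnatomicalClass", ]
  ids <- unique(class_rows$subject)
  classes <- list()
  for (id in ids) {
    mine <- tr[tr$subject == id, , drop = FALSE]
    get1 <- function(pred, default = NA_character_) {
      v <- mine$object[mine$predicate == pred]
      if (!length(v)) return(default)
      literal_value(v[[1L]])
    }
    nm <- get1("rel:preferred_name")
    if (is.na(nm)) {
      parse_stop(mine$line[[1L]], sprintf("class %s has no preferred_name", id))
    }
    classes[[id]] <- anatomical_class(
      nm,
      synonyms = vapply(mine$object[mine$predicate == "rel:synonym"],
                        literal_value, character(1L), USE.NAMES = FALSE),
      laterality = get1("rel:laterality", "unpaired"),
      category = get1("rel:category", "material_structure"),
      definition = get1("rel:definition"),
      id = id)
  }

  known_rel <- paste0("rel:", RELATION_KINDS)
  known_cn <- paste0("rel:", c(CONNECTIVITY_KINDS, names(CONNECTIVITY_ALIASES)))
  stmt_preds <- c("rel:subject", "rel:kind", "rel:object", "rel:via",
                  "rel:provenance")
  meta_preds <- c("a", "rel:preferred_name", "rel:laterality", "rel:category",
                  "rel:synonym", "rel:definition", "rel:has_sulcal_segment")
  edges <- tr[!tr$predicate %in% c(meta_preds, stmt_preds), , drop = FALSE]
  bad <- !edges$predicate %in% c(known_rel, known_cn)
  if (any(bad)) {
    parse_stop(edges$line[bad][[1L]], sprintf(
      "unknown relation IRI %s; accepted: %s", edges$predicate[bad][[1L]],
      paste(c(known_rel, known_cn), collapse = ", ")))
  }

  check_ref <- function(x, line) {
    miss <- !x %in% names(classes)
    if (any(miss)) {
      parse_stop(line[miss][[1L]],
                 sprintf("statement cites undeclared class %s", x[miss][[1L]]))
    }
  }

  st_rows <- edges[edges$predicate %in% known_rel, , drop = FALSE]
  check_ref(st_rows$subject, st_rows$line)
  check_ref(st_rows$object, st_rows$line)
  structural <- unique(data.frame(
    subject = st_rows$subject, relation = sub("^rel:", "", st_rows$predicate),
    object = st_rows$object, stringsAsFactors = FALSE))

  sl_rows <- tr[tr$predicate == "rel:has_sulcal_segment", , drop = FALSE]
  check_ref(sl_rows$subject, sl_rows$line)
  check_ref(sl_rows$object, sl_rows$line)
  sulcal <- unique(data.frame(sulcus = sl_rows$subject,
                              segment = sl_rows$object,
                              stringsAsFactors = FALSE))

  bindings_file <- file.path(path, "bindings.tsv")
  bindings <- if (file.exists(bindings_file)) {
    b <- utils::read.delim(bindings_file, stringsAsFactors = FALSE,
                           na.strings = "", colClasses = "character")
    if (!nrow(b)) empty_bindings() else b
  } else {
    empty_bindings()
  }

  cn_file <- file.path(path, "connectivity.tsv")
  if (file.exists(cn_file)) {
    cn <- utils::read.delim(cn_file, stringsAsFactors = FALSE,
                            na.strings = "", colClasses = "character")
    if (!nrow(cn)) cn <- empty_connectivity()
  } else {
    # fall back to the reified statements in the Turtle file
    stmt_ids <- unique(tr$subject[tr$predicate == "a" &
                                    tr$object == "rel:ConnectivityStatement"])
    cn <- empty_connectivity()
    for (sid in stmt_ids) {
      mine <- tr[tr$subject == sid, , drop = FALSE]
      field <- function(pred) {
        v <- mine$object[mine$predicate == pred]
        if (!length(v)) NA_character_
        else if (is_literal(v[[1L]])) literal_value(v[[1L]]) else v[[1L]]
      }
      cn <- rbind(cn, data.frame(
        subject = field("rel:subject"), kind = field("rel:kind"),
        object = field("rel:object"), via = field("rel:via"),
        provenance = field("rel:provenance"), stringsAsFactors = FALSE))
    }
  }

  ont <- ontology_from_parts(classes, structural,
                             sulcal_links = sulcal)
  for (i in seq_len(nrow(bindings))) {
    ont <- add_binding(ont, bindings$class_id[[i]], bindings$scheme[[i]],
                       bindings$external_label[[i]],
                       bindings$external_id[[i]])
  }
  for (i in seq_len(nrow(cn))) {
    prov <- cn$provenance[[i]]
    if (is.na(prov)) prov <- "asserted"
    ont <- assert_connectivity(ont, cn$subject[[i]], cn$kind[[i]],
                               cn$object[[i]], via = cn$via[[i]],
                               provenance = prov)
  }
  ont
}

#' Structural equality of two ontologies
#'
#' Compares classes, structural assertions, bindings, connectivity and
#' sulcus links, ignoring row order.
#'
#' @param a,b ontologies.
#' @return `TRUE` or `FALSE`.
#' @export
ontology_equal <- function(a, b) {
  sort_df <- function(d) {
    d <- d[do.call(order, d), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  ids_a <- sort(names(a$classes))
  if (!identical(ids_a, sort(names(b$classes)))) return(FALSE)
  for (id in ids_a) {
    if (!identical(a$classes[[id]][order(names(a$classes[[id]]))],
                   b$classes[[id]][order(names(b$classes[[id]]))])) {
      return(FALSE)
    }
  }
  identical(sort_df(a$structural), sort_df(b$structural)) &&
    identical(sort_df(a$bindings), sort_df(b$bindings)) &&
    identical(sort_df(a$connectivity), sort_df(b$connectivity)) &&
    identical(sort_df(a$sulcal_links), sort_df(b$sulcal_links))
}
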