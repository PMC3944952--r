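# Grammars and normalizers for the four terminologies' label strings.
#
# Each scheme has its own delimiter convention: Talairach Daemon labels are
# period-separated five-level hierarchies, Desikan-Killiany (FreeSurfer)
# labels are hyphen-separated with abbreviations (ctx, lh, wm), AAL labels
# are underscore-separated, and NeuroLex terms are plain English phrases.

SCHEME_IDS <- c("talairach", "dk", "aal", "neurolex")
TALAIRACH_LEVELS <- c("hemisphere", "lobe", "gyrus", "tissue", "cell")
LEFT_MARKERS <- c("left", "lh", "l")
RIGHT_MARKERS <- c("right", "rh", "r")
# kept through normalization, dropped only at lexical matching time
MATCH_STOPWORDS <- c("of", "the", "area")

#' Parse a Talairach Daemon label
#'
#' Talairach Daemon labels encode five levels of partonomy separated by
#' periods: hemisphere, lobe, gyrus, tissue type, and cell type, as in
#' `"Right Cerebrum.Temporal Lobe.Inferior Temporal Gyrus.Gray Matter.Brodmann
#' area 20"`.  A level may be the wildcard `"*"` (the daemon emits partial
#' labels), but all five components must be present and at least one must be
#' non-wildcard.
#'
#' @param raw a single label string.
#' @return An object of class `talairach_label` with fields `hemisphere`,
#'   `lobe`, `gyrus`, `tissue`, `cell`.  `format()` re-joins the components
#'   with periods, reproducing the input.
#' @export
#' @examples
#' lab <- parse_talairach(
#'   "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6")
#' lab$cell
parse_talairach <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  parts <- strsplit(raw, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 5L) {
    pos <- min(length(parts) + 1L, 5L)
    ont_stop("parse", sprintf(
      "Talairach label needs 5 period-separated levels, got %d (missing level %d, '%s'): %s",
      length(parts), pos,
      TALAIRACH_LEVELS[[min(pos, 5L)]], raw))
  }
  parts <- trimws(parts)
  if (all(parts == "*")) {
    ont_stop("parse", sprintf("Talairach label is all wildcards: %s", raw))
  }
  if (any(!nzchar(parts))) {
    ont_stop("parse", sprintf("Talairach label has an empty level: %s", raw))
  }
  structure(as.list(setNames(parts, TALAIRACH_LEVELS)),
            class = "talairach_label")
}

#' @export
format.talairach_label <- function(x, ...) {
  paste(unlist(x[TALAIRACH_LEVELS]), collapse = ".")
}

#' @export
print.talairach_label <- function(x, ...) {
  cat("<talairach_label>", format(x), "\n")
  invisible(x)
}

#' Default abbreviation tables for a labeling scheme
#'
#' Seeded from the abbreviations the schemes are known to use (`ctx` for
#' cortex, `lh`/`rh` for the hemispheres, `wm` for white matter, AAL's
#' `Sup`/`Inf`/`Mid` contractions, single-letter `R`/`L`).  Tables are named
#' character vectors mapping a lowercase token to its expansion phrase and can
#' be extended or replaced via [read_abbreviations()].
#'
#' @param scheme one of `"talairach"`, `"dk"`, `"aal"`, `"neurolex"`.
#' @return A named character vector (possibly empty).
#' @export
#' @examples
#' default_abbreviations("dk")
default_abbreviations <- function(scheme = SCHEME_IDS) {
  scheme <- match.arg(scheme)
  switch(scheme,
    dk = c(ctx = "cortex", wm = "white matter", lh = "left", rh = "right"),
    aal = c(sup = "superior", inf = "inferior", mid = "middle",
            med = "medial", ant = "anterior", post = "posterior",
            orb = "orbital", r = "right", l = "left"),
    talairach = c(r = "right", l = "left"),
    neurolex = c(r = "right", l = "left")
  )
}

#' Read an abbreviation table from a TSV or YAML config file
#'
#' TSV files need columns `token` and `expansion`; YAML files map tokens to
#' expansions.  Keys are lowercased.  Expansions may not contain a token that
#' itself expands (no expansion chains), so a single pass suffices.
#'
#' @param path file path ending in `.tsv`/`.txt` or `.yml`/`.yaml`.
#' @return A named character vector usable as the `table` argument of
#'   [normalize_label()].
#' @export
read_abbreviations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      ont_stop("config", "the yaml package is required to read YAML config")
    }
    lst <- yaml::read_yaml(path)
    tab <- vapply(lst, as.character, character(1L))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("token", "expansion") %in% names(df))) {
      ont_stop("config", "abbreviation TSV needs columns 'token' and 'expansion'")
    }
    tab <- setNames(df$expansion, df$token)
  }
  names(tab) <- tolower(names(tab))
  expanded_words <- tolower(unlist(strsplit(unname(tab), "[[:space:]]+")))
  cyclic <- intersect(expanded_words, names(tab))
  cyclic <- cyclic[tab[cyclic] != cyclic]  # a key expanding to itself is fine
  if (length(cyclic)) {
    ont_stop("config", sprintf(
      "abbreviation table is not single-pass: expansion reuses key(s) %s",
      paste(cyclic, collapse = ", ")))
  }
  tab
}

scheme_delimiter <- function(scheme) {
  switch(scheme, dk = "-", aal = "_", "[[:space:]]+")
}

split_tokens <- function(scheme, raw) {
  delim <- scheme_delimiter(scheme)
  fixed <- scheme %in% c("dk", "aal")
  toks <- strsplit(raw, delim, fixed = fixed)[[1L]]
  tolower(toks[nzchar(toks)])
}

# expand abbreviations; returns list(tokens, unknown) where unknown records
# tokens that looked like unexpandable abbreviations (very short, no match)
expand_tokens <- function(tokens, table) {
  out <- character(0L)
  unknown <- character(0L)
  for (tok in tokens) {
    if (!is.null(table) && tok %in% names(table)) {
      out <- c(out, tolower(strsplit(table[[tok]], "[[:space:]]+")[[1L]]))
    } else {
      if (nchar(tok) <= 3L && !tok %in% c(LEFT_MARKERS, RIGHT_MARKERS) &&
          !tok %in% MATCH_STOPWORDS && grepl("^[a-z]+$", tok)) {
        unknown <- c(unknown, tok)
      }
      out <- c(out, tok)
    }
  }
  list(tokens = out, unknown = unknown)
}

# pull laterality out of a token vector; returns list(side, tokens)
extract_laterality <- function(tokens) {
  is_left <- tokens %in% LEFT_MARKERS
  is_right <- tokens %in% RIGHT_MARKERS
  side <- "unpaired"
  if (sum(is_left) >= 1L && sum(is_right) == 0L) side <- "left"
  if (sum(is_right) >= 1L && sum(is_left) == 0L) side <- "right"
  list(side = side, tokens = tokens[!(is_left | is_right)])
}

#' Normalize an atlas label into tokens plus laterality
#'
#' Applies the scheme's splitting convention (hyphens for Desikan-Killiany,
#' underscores for AAL, whitespace for NeuroLex and Talairach components),
#' lowercases, expands abbreviations through `table`, and removes side words
#' (`left`/`lh`/`l`, `right`/`rh`/`r`) into a laterality attribute.  Unknown
#' abbreviation-like tokens are passed through verbatim and recorded in the
#' `warnings` field, never raised as errors.
#'
#' @param scheme one of `"talairach"`, `"dk"`, `"aal"`, `"neurolex"`.
#' @param raw label string.
#' @param table abbreviation table; defaults to [default_abbreviations()] for
#'   the scheme.
#' @return An object of class `normalized_label` with fields `scheme`, `raw`,
#'   `tokens` (lowercase, abbreviations expanded), `laterality`, and
#'   `warnings`.
#' @export
#' @examples
#' normalize_label("dk", "ctx-lh-postcentral")
#' normalize_label("aal", "Frontal_superior_right")
normalize_label <- function(scheme, raw, table = default_abbreviations(scheme)) {
  scheme <- match.arg(scheme, SCHEME_IDS)
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(trimws(raw)))
  tokens <- split_tokens(scheme, raw)
  if (!length(tokens)) {
    ont_stop("parse", sprintf("label '%s' yields no tokens", raw))
  }
  names(table) <- tolower(names(table))
  ex <- expand_tokens(tokens, table)
  lat <- extract_laterality(ex$tokens)
  warnings <- character(0L)
  if (length(ex$unknown)) {
    warnings <- sprintf("unknown abbreviation '%s' passed through verbatim",
                        ex$unknown)
  }
  both <- any(ex$tokens %in% LEFT_MARKERS) && any(ex$tokens %in% RIGHT_MARKERS)
  if (both) warnings <- c(warnings, "label names both sides; laterality unpaired")
  if (!length(lat$tokens)) {
    ont_stop("parse", sprintf("label '%s' has no tokens beyond side markers", raw))
  }
  structure(
    list(scheme = scheme, raw = raw, tokens = lat$tokens,
         laterality = lat$side, warnings = warnings),
    class = "normalized_label"
  )
}

#' @export
format.normalized_label <- function(x, ...) {
  delim <- switch(x$scheme, dk = "-", aal = "_", " ")
  side <- if (x$laterality == "unpaired") character(0L) else x$laterality
  if (x$scheme %in% c("dk", "aal")) {
    # dk convention keeps tissue first, side second; aal appends the side
    toks <- if (x$scheme == "dk" && length(side)) {
      c(x$tokens[1L], side, x$tokens[-1L])
    } else {
      c(x$tokens, side)
    }
  } else {
    toks <- c(side, x$tokens)
  }
  paste(toks, collapse = delim)
}

#' @export
print.normalized_label <- function(x, ...) {
  cat(sprintf("<normalized_label %s> %s -> [%s] (%s)\n", x$scheme, x$raw,
              paste(x$tokens, collapse = ", "), x$laterality))
  invisible(x)
}

# phrase used for matching a normalized label against class names:
# the side word is reinstated in front, the way anatomical names carry it
label_phrase <- function(label) {
  side <- if (label$laterality == "unpaired") character(0L) else label$laterality
  paste(c(side, label$tokens), collapse = " ")
}

# tokens of an arbitrary name/phrase for lexical comparison
phrase_tokens <- function(x, drop_stopwords = TRUE) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (drop_stopwords) toks <- setdiff(toks, MATCH_STOPWORDS)
  toks
}
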