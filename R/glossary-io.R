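#' Path to the shipped glossary XML schema
#'
#' @return Path to the XSD defining the glossary interchange dialect.
#' @export
glossary_schema_path <- function() {
  system.file("extdata", "glossary.xsd", package = "hyperglossary",
              mustWork = TRUE)
}

read_xml_input <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^\\s*<", x)) xml2::read_xml(x) else xml2::read_xml(x[[1]])
}

#' Validate a glossary XML document against the shipped schema
#'
#' @param x Path, XML string, or `xml2` document.
#' @return `TRUE` invisibly; aborts with the validator's messages otherwise.
#' @export
validate_glossary_xml <- function(x) {
  doc <- read_xml_input(x)
  schema <- xml2::read_xml(glossary_schema_path())
  ok <- xml2::xml_validate(doc, schema)
  if (!ok) {
    hg_abort(paste0("glossary XML fails schema validation: ",
                    paste(attr(ok, "errors"), collapse = "; ")),
             "hg_schema_error")
  }
  invisible(TRUE)
}

parse_locked_mask <- function(attr_value, field_count) {
  parts <- strsplit(attr_value, ",", fixed = TRUE)[[1]]
  mask <- str_trim(parts) == "true"
  if (length(mask) != field_count) {
    hg_abort("locked_mask attribute length disagrees with field_count",
             "hg_schema_error")
  }
  mask
}

#' Parse a glossary from the XML interchange dialect
#'
#' Reads a bulk-upload XML document (see [write_glossary_xml()] for the
#' dialect) into a [glossary][create_glossary]. The document is validated
#' against the shipped schema first. Field 1 is locked whenever a
#' glossary-wide source citation is present, matching the canonical-plus-wiki
#' import convention.
#'
#' @param x Path, XML string, or `xml2` document.
#' @return A `glossary`.
#' @export
parse_glossary_xml <- function(x) {
  doc <- read_xml_input(x)
  validate_glossary_xml(doc)
  root <- xml2::xml_root(doc)
  name <- xml2::xml_attr(root, "name")
  field_count <- as.integer(xml2::xml_attr(root, "field_count"))
  citation <- xml2::xml_attr(root, "source_citation")
  if (is.na(citation)) citation <- NULL

  terms <- xml2::xml_find_all(root, "term")
  mask_attr <- xml2::xml_attr(root, "locked_mask")
  if (!is.na(mask_attr)) {
    mask <- parse_locked_mask(mask_attr, field_count)
  } else {
    # derive from per-definition locked attributes
    mask <- rep(FALSE, field_count)
    for (t in terms) {
      defs <- xml2::xml_find_all(t, "definition")
      idx <- as.integer(xml2::xml_attr(defs, "index"))
      locked <- xml2::xml_attr(defs, "locked") == "true"
      mask[idx[locked & idx <= field_count]] <- TRUE
    }
  }
  if (!is.null(citation)) mask[1] <- TRUE

  g <- create_glossary(name, field_count, mask, citation)
  active_attr <- xml2::xml_attr(root, "active")
  if (!is.na(active_attr)) g <- set_active(g, active_attr == "true")
  for (t in terms) {
    t_name <- xml2::xml_text(xml2::xml_find_first(t, "name"))
    wt <- xml2::xml_text(xml2::xml_find_first(t, "word_type"))
    id_node <- xml2::xml_find_first(t, "identifier")
    identifier <- NULL
    if (length(id_node) > 0L && !inherits(id_node, "xml_missing")) {
      identifier <- semantic_identifier(xml2::xml_attr(id_node, "kind"),
                                        str_trim(xml2::xml_text(id_node)))
    }
    defs <- xml2::xml_find_all(t, "definition")
    idx <- as.integer(xml2::xml_attr(defs, "index"))
    if (anyDuplicated(idx)) {
      hg_abort(paste0("term '", t_name, "' repeats a definition index"),
               "hg_schema_error")
    }
    if (any(idx > field_count)) {
      hg_abort(paste0("term '", t_name, "' has a definition index beyond ",
                      "field_count"), "hg_schema_error")
    }
    contents <- character(if (length(idx)) max(idx) else 0L)
    contents[idx] <- xml2::xml_text(defs)
    g <- add_term(g, t_name, wt, identifier, contents)
  }
  g
}

#' Write a glossary in the XML interchange dialect
#'
#' The on-disk (and wire) form of a glossary: root `glossary` element with
#' `name`, `field_count`, optional `source_citation` and a `locked_mask`
#' attribute; one `term` element per term holding `name`, `word_type`, an
#' optional `identifier` (with a `kind` attribute) and numbered `definition`
#' elements whose HTML content travels as CDATA. Only current field content
#' is exported — version history stays local, so a parse/write round trip is
#' identity up to history truncation.
#'
#' @param glossary A glossary.
#' @param path Optional file path; when given the document is written there.
#' @return The `xml2` document, invisibly when `path` is given.
#' @export
write_glossary_xml <- function(glossary, path = NULL) {
  stopifnot(inherits(glossary, "glossary"))
  doc <- xml2::xml_new_root("glossary")
  xml2::xml_set_attr(doc, "name", glossary$name)
  xml2::xml_set_attr(doc, "field_count", glossary$field_count)
  if (!is.null(glossary$source_citation)) {
    xml2::xml_set_attr(doc, "source_citation", glossary$source_citation)
  }
  xml2::xml_set_attr(doc, "locked_mask",
                     paste(ifelse(glossary$locked_mask, "true", "false"),
                           collapse = ","))
  xml2::xml_set_attr(doc, "active", if (glossary$active) "true" else "false")
  for (term in glossary$terms) {
    t <- xml2::xml_add_child(doc, "term")
    xml2::xml_add_child(t, "name", term$name)
    xml2::xml_add_child(t, "word_type", term$word_type)
    if (!is.null(term$identifier)) {
      id <- xml2::xml_add_child(t, "identifier", term$identifier$value)
      xml2::xml_set_attr(id, "kind", term$identifier$kind)
    }
    for (field in term$fields) {
      d <- xml2::xml_add_child(t, "definition")
      xml2::xml_set_attr(d, "index", field$index)
      xml2::xml_set_attr(d, "locked",
                         if (glossary$locked_mask[[field$index]]) "true"
                         else "false")
      xml2::xml_add_child(d, xml2::xml_cdata(current_content(term, field$index)))
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Export a glossary as a CSV-ready table
#'
#' One row per term: name, word type, identifier kind and value, and the
#' current content of each definition field. Written with RFC 4180 quoting
#' when `path` is given, so definitions containing commas, quotes or
#' newlines survive a round trip.
#'
#' @param glossary A glossary.
#' @param path Optional CSV file path.
#' @return A tibble (invisibly when `path` is given).
#' @export
export_csv <- function(glossary, path = NULL) {
  stopifnot(inherits(glossary, "glossary"))
  base <- tidy(glossary)[, c("name", "word_type",
                             "identifier_kind", "identifier_value")]
  for (i in seq_len(glossary$field_count)) {
    base[[paste0("field_", i)]] <-
      map_chr(unname(glossary$terms), current_content, index = i)
  }
  if (!is.null(path)) {
    readr::write_csv(base, path, na = "")
    return(invisible(base))
  }
  base
}

#' Ingest a two-column term/definition table as an untyped glossary
#'
#' The first stage of the bulk-preparation workflow: source glossaries
#' arrive in assorted tabular shapes; this maps the stated columns to terms
#' and definitions and produces a glossary of `no_type` terms awaiting
#' typing by [assign_word_types()].
#'
#' @param rows A data frame.
#' @param term_col,definition_col Column names holding terms / definitions.
#' @param name Name for the new glossary.
#' @return A glossary with one unlocked definition field.
#' @export
ingest_table <- function(rows, term_col = "term",
                         definition_col = "definition", name = "ingested") {
  stopifnot(is.data.frame(rows))
  if (!all(c(term_col, definition_col) %in% names(rows))) {
    hg_abort(paste0("table lacks column(s): ",
                    paste(setdiff(c(term_col, definition_col), names(rows)),
                          collapse = ", ")), "hg_layout_error")
  }
  terms <- as.character(rows[[term_col]])
  defs <- as.character(rows[[definition_col]])
  empty <- which(is.na(terms) | !nzchar(str_trim(terms)))
  if (length(empty) > 0L) {
    hg_abort(paste0("empty term cell at row(s): ",
                    paste(empty, collapse = ", ")), "hg_layout_error")
  }
  keys <- fold_key(terms)
  dup_keys <- unique(keys[duplicated(keys)])
  if (length(dup_keys) > 0L) {
    msgs <- map_chr(dup_keys, function(k) {
      paste0("'", k, "' at rows ", paste(which(keys == k), collapse = ", "))
    })
    hg_abort(paste0("duplicate terms: ", paste(msgs, collapse = "; ")),
             "hg_duplicate_error")
  }
  g <- create_glossary(name, 1L, FALSE)
  for (i in seq_along(terms)) {
    g <- add_term(g, terms[[i]], "no_type", NULL,
                  if (is.na(defs[[i]])) "" else defs[[i]])
  }
  g
}

#' Read a delimited term table from disk
#'
#' Delimiter is taken from the extension (`.tsv`/`.tab` are tab-separated,
#' anything else comma-separated); tab- and comma-delimited encodings of the
#' same table ingest identically.
#'
#' @param path File path.
#' @return A tibble of character columns.
#' @export
read_glossary_table <- function(path) {
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
}
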