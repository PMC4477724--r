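#' Create an empty typed glossary
#'
#' A glossary is the unit of controlled vocabulary a document is processed
#' against. It fixes the definition-field layout shared by all of its terms:
#' between 1 and 5 fields, each either locked (canonical, not editable) or
#' unlocked (wiki, editable with version history). A common layout pairs a
#' locked canonical field 1, with a glossary-wide source citation, with one
#' or more editable wiki fields.
#'
#' @param name Display name of the glossary.
#' @param field_count Number of definition fields per term, 1 to 5.
#' @param locked_mask Logical vector of length `field_count`; `TRUE` marks a
#'   locked (canonical) field.
#' @param source_citation Optional citation applying glossary-wide to field 1
#'   (used when an established glossary is bulk-imported).
#' @return A `glossary` object.
#' @export
#' @examples
#' g <- create_glossary("IUPAC Gold", 2, c(TRUE, FALSE), "IUPAC Gold Book")
#' g
create_glossary <- function(name, field_count = 1L, locked_mask = NULL,
                            source_citation = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    hg_abort("glossary name must be a non-empty string", "hg_limit_error")
  }
  field_count <- as.integer(field_count)
  if (is.na(field_count) || field_count < 1L || field_count > 5L) {
    hg_abort("field_count must be between 1 and 5", "hg_limit_error")
  }
  if (is.null(locked_mask)) locked_mask <- rep(FALSE, field_count)
  locked_mask <- as.logical(locked_mask)
  if (length(locked_mask) != field_count || anyNA(locked_mask)) {
    hg_abort("locked_mask must be a logical vector of length field_count",
             "hg_limit_error")
  }
  if (!is.null(source_citation)) {
    stopifnot(is.character(source_citation), length(source_citation) == 1L)
  }
  structure(
    list(
      name = name,
      source_citation = source_citation,
      field_count = field_count,
      locked_mask = locked_mask,
      active = TRUE,
      terms = list()
    ),
    class = "glossary"
  )
}

new_version <- function(content, author, ordinal,
                        timestamp = format(Sys.time(), tz = "UTC",
                                           "%Y-%m-%dT%H:%M:%SZ")) {
  list(content = content, author = author,
       timestamp = timestamp, ordinal = as.integer(ordinal))
}

#' Add a term to a glossary
#'
#' Stores a term under its case-folded key (unique within the glossary).
#' Each supplied definition becomes version 1 of the corresponding field.
#' Chemical and protein terms must carry an identifier of the matching kind;
#' plain terms must not.
#'
#' @param glossary A [glossary][create_glossary].
#' @param name Display name; the lookup key is its case-folded form.
#' @param word_type One of [word_types()].
#' @param identifier A [semantic_identifier()] or `NULL`.
#' @param definitions Character vector of initial field contents (HTML
#'   fragments), at most `field_count` of them, assigned to fields 1, 2, ...
#' @param author Recorded on the initial versions.
#' @return The updated glossary (pipe-friendly); fetch the stored term with
#'   [glossary_term()].
#' @export
#' @examples
#' g <- create_glossary("demo", 1) |>
#'   add_term("entropy", definitions = "a state function")
#' glossary_term(g, "entropy")$word_type
add_term <- function(glossary, name, word_type = "no_type", identifier = NULL,
                     definitions = character(), author = "import") {
  stopifnot(inherits(glossary, "glossary"))
  if (!is.character(name) || length(name) != 1L || !nzchar(str_trim(name))) {
    hg_abort("term name must be a non-empty string", "hg_term_error")
  }
  check_type_identifier(word_type, identifier)
  key <- fold_key(name)
  if (key %in% names(glossary$terms)) {
    hg_abort(paste0("duplicate term key: ", key), "hg_duplicate_error")
  }
  definitions <- as.character(definitions)
  if (length(definitions) > glossary$field_count) {
    hg_abort(paste0("too many definitions: glossary has ",
                    glossary$field_count, " field(s)"), "hg_limit_error")
  }
  fields <- lapply(seq_along(definitions), function(i) {
    list(index = i, history = list(new_version(definitions[[i]], author, 1L)))
  })
  glossary$terms[[key]] <- structure(
    list(name = name, key = key, word_type = word_type,
         identifier = identifier, fields = fields),
    class = "glossary_term"
  )
  glossary
}

#' Look up a term by name or key
#'
#' @param glossary A glossary.
#' @param name Term name; matched after case folding.
#' @return The `glossary_term`, or an error if absent.
#' @export
glossary_term <- function(glossary, name) {
  stopifnot(inherits(glossary, "glossary"))
  key <- fold_key(name)
  term <- glossary$terms[[key]]
  if (is.null(term)) {
    hg_abort(paste0("no such term: ", name), "hg_missing_term_error")
  }
  term
}

field_or_abort <- function(glossary, term, index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > glossary$field_count) {
    hg_abort(paste0("field index ", index, " outside 1..",
                    glossary$field_count), "hg_range_error")
  }
  idx <- which(map_int(term$fields, "index") == index)
  if (length(idx) == 0L) {
    hg_abort(paste0("term '", term$name, "' has no field ", index),
             "hg_range_error")
  }
  idx
}

#' Edit a definition field
#'
#' Edits are append-only: the new content becomes the current version and the
#' previous one stays in the field's history, so every definition keeps a
#' full audit trail. Locked (canonical) fields reject edits.
#'
#' @param glossary A glossary.
#' @param name Term name.
#' @param index Field index.
#' @param new_content Replacement HTML fragment.
#' @param author Recorded on the new version.
#' @return The updated glossary.
#' @export
edit_field <- function(glossary, name, index, new_content, author) {
  stopifnot(inherits(glossary, "glossary"), is.character(new_content),
            length(new_content) == 1L)
  term <- glossary_term(glossary, name)
  pos <- field_or_abort(glossary, term, index)
  if (glossary$locked_mask[[as.integer(index)]]) {
    hg_abort(paste0("field ", index, " is locked"), "hg_lock_error")
  }
  field <- term$fields[[pos]]
  ord <- length(field$history) + 1L
  field$history[[ord]] <- new_version(new_content, author, ord)
  term$fields[[pos]] <- field
  glossary$terms[[term$key]] <- term
  glossary
}

#' Version history of a definition field
#'
#' @param glossary A glossary.
#' @param name Term name.
#' @param index Field index.
#' @return A tibble with one row per version in ordinal order (current
#'   version last): `ordinal`, `content`, `author`, `timestamp`.
#' @export
field_history <- function(glossary, name, index) {
  term <- glossary_term(glossary, name)
  pos <- field_or_abort(glossary, term, index)
  hist <- term$fields[[pos]]$history
  tibble(
    ordinal = map_int(hist, "ordinal"),
    content = map_chr(hist, "content"),
    author = map_chr(hist, "author"),
    timestamp = map_chr(hist, "timestamp")
  )
}

# current content of a field, "" when the term has no such field yet
current_content <- function(term, index) {
  idx <- which(map_int(term$fields, "index") == as.integer(index))
  if (length(idx) == 0L) return("")
  hist <- term$fields[[idx]]$history
  hist[[length(hist)]]$content
}

#' Activate or deactivate a glossary
#'
#' Inactive glossaries are excluded from matcher construction and document
#' processing, the data-level analogue of retiring a vocabulary without
#' deleting it.
#'
#' @param glossary A glossary.
#' @param active Logical.
#' @return The updated glossary.
#' @export
set_active <- function(glossary, active) {
  stopifnot(inherits(glossary, "glossary"), is.logical(active),
            length(active) == 1L, !is.na(active))
  glossary$active <- active
  glossary
}

#' @export
print.glossary <- function(x, ...) {
  cat("<glossary> ", x$name,
      if (!x$active) " (inactive)" else "",
      ": ", length(x$terms), " term(s), ",
      x$field_count, " field(s) [",
      paste(ifelse(x$locked_mask, "locked", "wiki"), collapse = ", "),
      "]\n", sep = "")
  if (!is.null(x$source_citation)) {
    cat("  source citation: ", x$source_citation, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a glossary into a one-row-per-term tibble
#'
#' @param x A glossary.
#' @param ... Unused.
#' @return Tibble with columns `name`, `key`, `word_type`,
#'   `identifier_kind`, `identifier_value`, `n_fields`.
#' @export
tidy.glossary <- function(x, ...) {
  terms <- unname(x$terms)
  tibble(
    name = map_chr(terms, "name"),
    key = map_chr(terms, "key"),
    word_type = map_chr(terms, "word_type"),
    identifier_kind = map_chr(terms, function(t)
      if (is.null(t$identifier)) NA_character_ else t$identifier$kind),
    identifier_value = map_chr(terms, function(t)
      if (is.null(t$identifier)) NA_character_ else t$identifier$value),
    n_fields = map_int(terms, function(t) length(t$fields))
  )
}

#' One-row summary of a glossary
#'
#' @param x A glossary.
#' @param ... Unused.
#' @return Tibble with `name`, `n_terms`, counts per word type,
#'   `field_count`, `n_locked`, `active`.
#' @export
glance.glossary <- function(x, ...) {
  wt <- map_chr(x$terms, "word_type")
  tibble(
    name = x$name,
    n_terms = length(x$terms),
    n_no_type = sum(wt == "no_type"),
    n_chemical = sum(wt == "chemical"),
    n_protein = sum(wt == "protein"),
    field_count = x$field_count,
    n_locked = sum(x$locked_mask),
    active = x$active
  )
}

#' Word-type composition plot for a glossary
#'
#' @param object A glossary.
#' @param ... Unused.
#' @return A ggplot bar chart of term counts per word type.
#' @export
autoplot.glossary <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$word_type)) +
    ggplot2::geom_bar(fill = "seagreen") +
    ggplot2::labs(x = "word type", y = "terms", title = object$name) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
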