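#' Word types recognised by the glossary model
#'
#' Every glossary term carries a semantic category that decides which
#' identifier it must hold and which tabs its portlet content bundle gets:
#' `"no_type"` (plain vocabulary, definition only), `"chemical"` (requires an
#' InChI identifier) and `"protein"` (requires a PDB id).
#'
#' @return Character vector of the three word types.
#' @export
#' @examples
#' word_types()
word_types <- function() {
  c("no_type", "chemical", "protein")
}

#' Create a semantic identifier
#'
#' Attaches machine-actionable meaning to a typed term: chemicals are
#' identified by an IUPAC InChI string, proteins by a 4-character Protein
#' Data Bank id. The identifier is validated syntactically on construction.
#'
#' @param kind `"inchi"` or `"pdb_id"`.
#' @param value The identifier string. InChIs must start with `"InChI="`;
#'   PDB ids must be exactly 4 alphanumeric characters.
#' @return An object of class `semantic_identifier`: a list with elements
#'   `kind` and `value`.
#' @export
#' @examples
#' semantic_identifier("inchi", "InChI=1S/O3/c1-3-2")
#' semantic_identifier("pdb_id", "1ABC")
semantic_identifier <- function(kind = c("inchi", "pdb_id"), value) {
  kind <- match.arg(kind)
  if (!is.character(value) || length(value) != 1L || is.na(value)) {
    hg_abort("identifier value must be a single string", "hg_identifier_error")
  }
  if (kind == "inchi" && !startsWith(value, "InChI=")) {
    hg_abort("an inchi identifier must start with \"InChI=\"", "hg_identifier_error")
  }
  if (kind == "pdb_id" && !grepl("^[A-Za-z0-9]{4}$", value)) {
    hg_abort("a pdb_id identifier must be 4 alphanumeric characters", "hg_identifier_error")
  }
  structure(list(kind = kind, value = value), class = "semantic_identifier")
}

#' @export
print.semantic_identifier <- function(x, ...) {
  cat("<semantic_identifier> ", x$kind, ": ", x$value, "\n", sep = "")
  invisible(x)
}

is_semantic_identifier <- function(x) inherits(x, "semantic_identifier")

# chemical/protein require an identifier of the matching kind; no_type forbids one
check_type_identifier <- function(word_type, identifier) {
  if (!word_type %in% word_types()) {
    hg_abort(paste0("unknown word type: ", word_type), "hg_type_error")
  }
  if (word_type == "no_type") {
    if (!is.null(identifier)) {
      hg_abort("a no_type term must not carry a semantic identifier", "hg_type_error")
    }
    return(invisible(NULL))
  }
  if (is.null(identifier)) {
    hg_abort(paste0("a ", word_type, " term requires a semantic identifier"),
             "hg_type_error")
  }
  if (!is_semantic_identifier(identifier)) {
    hg_abort("identifier must be created with semantic_identifier()", "hg_type_error")
  }
  expected <- c(chemical = "inchi", protein = "pdb_id")[[word_type]]
  if (identifier$kind != expected) {
    hg_abort(paste0("a ", word_type, " term requires a ", expected,
                    " identifier, got ", identifier$kind), "hg_type_error")
  }
  invisible(NULL)
}

# Unicode-aware case folding used for all term keys
fold_key <- function(x) {
  stringr::str_to_lower(x)
}
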