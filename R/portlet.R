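#' Offline content stores for portlet assembly
#'
#' Portlet assembly never opens network connections; everything it pulls
#' from is an injected store. `curated_store()` is a directory of curated
#' structure files named `<InChIKey>.<ext>` (the preferred 3D source);
#' `pdb_store()` is a directory of `<PDBID>.pdb` files;
#' `local_search_backend()` is a structure-search service backed by a table
#' keyed by InChIKey, whose rows are search results (external id, base64
#' thumbnail, link target).
#'
#' @param dir Directory of store files.
#' @return `curated_store()`/`pdb_store()`: store objects;
#'   `local_search_backend()`: a function `inchikey -> results tibble`.
#' @export
curated_store <- function(dir) {
  stopifnot(dir.exists(dir))
  structure(list(dir = dir), class = "curated_store")
}

#' @rdname curated_store
#' @export
pdb_store <- function(dir) {
  stopifnot(dir.exists(dir))
  structure(list(dir = dir), class = "pdb_store")
}

#' @rdname curated_store
#' @param table Data frame with columns `inchikey`, `id`, `thumbnail_b64`,
#'   `link`.
#' @export
local_search_backend <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("inchikey", "id", "thumbnail_b64", "link") %in% names(table)))
  table <- as_tibble(table)
  function(inchikey) {
    hits <- table[table$inchikey == inchikey,
                  c("id", "thumbnail_b64", "link"), drop = FALSE]
    as_tibble(hits)
  }
}

curated_lookup <- function(store, inchikey) {
  if (is.null(store)) return(NULL)
  stopifnot(inherits(store, "curated_store"))
  hits <- list.files(store$dir, pattern = paste0("^", inchikey, "\\."),
                     full.names = TRUE)
  if (length(hits) == 0L) NULL else hits[[1]]
}

empty_results <- function() {
  tibble(id = character(), thumbnail_b64 = character(), link = character())
}

search_spec <- function(query, results) {
  results <- as_tibble(results)
  list(query = query, results = results, no_results = nrow(results) == 0L)
}

new_tab <- function(kind, title, payload) {
  structure(list(kind = kind, title = title, payload = payload),
            class = "portlet_tab")
}

#' Resolve the 3D structure source for an identifier
#'
#' For a chemical (InChI) identifier the curated store is consulted first by
#' InChIKey; only on a miss is a structure generated with [generate_3d()]
#' and cached. For a protein (PDB id) the file comes from the injected PDB
#' store.
#'
#' @param identifier A [semantic_identifier()].
#' @param curated_store Optional [curated_store()].
#' @param cache A [structure_cache()] for generated structures.
#' @param pdb_store A [pdb_store()], required for protein identifiers.
#' @param seed Passed to [generate_3d()].
#' @return List with `file` (path), `provenance` (`"curated"`,
#'   `"generated"` or `"pdb"`), `identifier` (InChIKey or PDB id) and
#'   `viewer_hint`.
#' @export
resolve_structure3d <- function(identifier, curated_store = NULL,
                                cache = NULL, pdb_store = NULL, seed = 1L) {
  stopifnot(is_semantic_identifier(identifier))
  if (identifier$kind == "pdb_id") {
    if (is.null(pdb_store)) {
      hg_abort("a protein identifier requires a pdb_store", "hg_store_error")
    }
    path <- file.path(pdb_store$dir, paste0(identifier$value, ".pdb"))
    if (!file.exists(path)) {
      hg_abort(paste0("unknown PDB id: ", identifier$value), "hg_store_error")
    }
    return(list(file = path, provenance = "pdb",
                identifier = identifier$value, viewer_hint = "3d-viewer"))
  }
  key <- inchi_to_inchikey(identifier$value)
  hit <- curated_lookup(curated_store, key)
  if (!is.null(hit)) {
    return(list(file = hit, provenance = "curated", identifier = key,
                viewer_hint = "3d-viewer"))
  }
  if (is.null(cache)) cache <- structure_cache()
  list(file = generate_3d(identifier$value, cache, seed = seed),
       provenance = "generated", identifier = key, viewer_hint = "3d-viewer")
}

#' Structure payload for the 2D editor tab
#'
#' The editor currency is SMILES; the payload carries both the SMILES form
#' and the term's InChI, and converting the SMILES back yields that same
#' InChI (checked at assembly time).
#'
#' @param term A chemical `glossary_term`.
#' @return List with `smiles`, `inchi` and `viewer_hint`.
#' @export
editor_payload <- function(term) {
  stopifnot(inherits(term, "glossary_term"))
  if (term$word_type != "chemical") {
    hg_abort("editor payload is only defined for chemical terms",
             "hg_type_error")
  }
  inchi <- term$identifier$value
  smiles <- inchi_to_smiles(inchi)
  back <- smiles_to_inchi(smiles)
  if (!identical(back, inchi)) {
    hg_abort(paste0("editor payload round trip failed for '", term$name,
                    "': ", back, " != ", inchi), "hg_chem_error")
  }
  list(smiles = smiles, inchi = inchi, viewer_hint = "2d-editor")
}

definition_fragment <- function(glossary, term) {
  parts <- character()
  if (!is.null(glossary$source_citation)) {
    parts <- paste0('<div class="hg-citation">',
                    escape_attr(glossary$source_citation), "</div>")
  }
  for (i in seq_len(glossary$field_count)) {
    content <- current_content(term, i)
    if (!nzchar(content)) next
    parts <- c(parts, paste0('<div class="hg-definition" data-field="', i,
                             '">', content, "</div>"))
  }
  paste(parts, collapse = "\n")
}

#' Assemble the per-term portlet content bundle
#'
#' The tab list is a function of the word type: a plain (`no_type`) term
#' gets the definition tab only; a chemical gets definition, structure
#' search, 3D structure and 2D structure; a protein gets definition and 3D
#' structure. Editor-driven search tabs can then accumulate on chemical
#' bundles via [add_editor_search_tab()].
#'
#' @param glossary An active glossary.
#' @param name Term name.
#' @param curated_store,cache,pdb_store,seed Passed to
#'   [resolve_structure3d()].
#' @param search_backend Structure-search backend
#'   (see [local_search_backend()]); when absent the search tab records the
#'   query with no results.
#' @return A `portlet` object: `term_key`, `word_type`, `tabs`.
#' @export
build_portlet <- function(glossary, name, curated_store = NULL, cache = NULL,
                          pdb_store = NULL, search_backend = NULL, seed = 1L) {
  stopifnot(inherits(glossary, "glossary"))
  if (!glossary$active) {
    hg_abort("portlets are only assembled from active glossaries",
             "hg_inactive_error")
  }
  term <- glossary_term(glossary, name)
  if (term$word_type != "no_type") {
    check_type_identifier(term$word_type, term$identifier)
  }
  tabs <- list(new_tab("definition", "Definition",
                       definition_fragment(glossary, term)))
  if (term$word_type == "chemical") {
    key <- inchi_to_inchikey(term$identifier$value)
    results <- if (is.null(search_backend)) empty_results()
               else search_backend(key)
    tabs <- c(tabs, list(
      new_tab("structure_search", "Search", search_spec(key, results)),
      new_tab("structure3d", "3D Structure",
              resolve_structure3d(term$identifier, curated_store, cache,
                                  seed = seed)),
      new_tab("structure2d", "2D Structure", editor_payload(term))
    ))
  } else if (term$word_type == "protein") {
    tabs <- c(tabs, list(
      new_tab("structure3d", "3D Structure",
              resolve_structure3d(term$identifier, pdb_store = pdb_store))
    ))
  }
  structure(list(term_key = term$key, word_type = term$word_type,
                 tabs = tabs),
            class = "portlet")
}

#' Append an editor-driven structure-search tab
#'
#' Models the discovery loop where a reader edits the 2D structure and
#' searches for the result: the SMILES from the editor is converted to an
#' InChIKey and looked up in the search backend; every search appends a new
#' tab (tabs accumulate, never replace), so successive modifications of a
#' molecule each leave their own results tab. An empty lookup yields a tab
#' with a no-results marker.
#'
#' @param bundle A chemical-term `portlet`.
#' @param smiles SMILES of the (possibly edited) structure.
#' @param search_backend See [local_search_backend()].
#' @return The bundle with one more `editor_search` tab; prior tabs are
#'   untouched.
#' @export
add_editor_search_tab <- function(bundle, smiles, search_backend = NULL) {
  stopifnot(inherits(bundle, "portlet"))
  if (bundle$word_type != "chemical") {
    hg_abort("editor search tabs only apply to chemical portlets",
             "hg_type_error")
  }
  key <- inchi_to_inchikey(smiles_to_inchi(smiles))
  results <- if (is.null(search_backend)) empty_results()
             else search_backend(key)
  tab <- new_tab("editor_search", paste0("Search: ", smiles),
                 search_spec(key, results))
  bundle$tabs <- c(bundle$tabs, list(tab))
  bundle
}

#' Decode a base64 thumbnail into a content-addressed PNG file
#'
#' Search services return compound thumbnails as base64 strings; this
#' decodes one, checks the PNG signature, and stores the bytes once under a
#' content-hash key, so repeated decodes of the same payload share a file.
#'
#' @param b64 Base64-encoded PNG bytes.
#' @param out_store Directory for decoded files (created if absent).
#' @return Path to the PNG file.
#' @export
decode_thumbnail <- function(b64, out_store) {
  stopifnot(is.character(b64), length(b64) == 1L)
  if (!dir.exists(out_store)) dir.create(out_store, recursive = TRUE)
  bytes <- tryCatch(jsonlite::base64_dec(b64), error = function(e) NULL)
  if (is.null(bytes) || length(bytes) == 0L) {
    hg_abort("invalid base64 payload", "hg_decode_error")
  }
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 8L || !identical(bytes[1:8], png_sig)) {
    hg_abort("decoded payload is not a PNG", "hg_decode_error")
  }
  tmp <- tempfile(fileext = ".png")
  writeBin(bytes, tmp)
  hash <- unname(tools::md5sum(tmp))
  path <- file.path(out_store, paste0(hash, ".png"))
  if (!file.exists(path)) file.copy(tmp, path)
  unlink(tmp)
  path
}

#' @export
print.portlet <- function(x, ...) {
  cat("<portlet> '", x$term_key, "' (", x$word_type, "), ",
      length(x$tabs), " tab(s):\n", sep = "")
  for (tab in x$tabs) cat("  - [", tab$kind, "] ", tab$title, "\n", sep = "")
  invisible(x)
}

#' @describeIn build_portlet tidy() method: one row per tab.
#' @param x,... For the tidy method.
#' @export
tidy.portlet <- function(x, ...) {
  tibble(
    term_key = x$term_key,
    word_type = x$word_type,
    position = seq_along(x$tabs),
    kind = map_chr(x$tabs, "kind"),
    title = map_chr(x$tabs, "title")
  )
}

tab_to_list <- function(tab) {
  payload <- tab$payload
  if (tab$kind %in% c("structure_search", "editor_search")) {
    payload <- list(query = payload$query,
                    results = lapply(seq_len(nrow(payload$results)),
                                     function(i) as.list(payload$results[i, ])),
                    no_results = payload$no_results)
  }
  list(kind = tab$kind, title = tab$title, payload = payload)
}

tab_from_list <- function(x) {
  payload <- x$payload
  if (x$kind %in% c("structure_search", "editor_search")) {
    results <- if (length(payload$results) == 0L) empty_results()
               else dplyr::bind_rows(lapply(payload$results, as_tibble))
    payload <- search_spec(payload$query, results)
  }
  new_tab(x$kind, x$title, payload)
}

#' Serialize a portlet bundle to a JSON sidecar
#'
#' The sidecar is what a client viewer would consume alongside the tagged
#' document; [read_portlet_json()] restores an identical bundle.
#'
#' @param bundle A `portlet`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_portlet_json <- function(bundle, path) {
  stopifnot(inherits(bundle, "portlet"))
  obj <- list(term_key = bundle$term_key, word_type = bundle$word_type,
              tabs = lapply(bundle$tabs, tab_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_portlet_json
#' @export
read_portlet_json <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(term_key = obj$term_key, word_type = obj$word_type,
                 tabs = lapply(obj$tabs, tab_from_list)),
            class = "portlet")
}
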