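# All structure conversions go through OpenBabel (ChemmineOB). OpenBabel
# signals failure by returning an empty string (and printing to stderr), so
# every call is wrapped to raise a proper condition instead.
ob_convert <- function(from, to, source, options = NULL) {
  out <- tryCatch(
    suppressWarnings(
      if (is.null(options)) {
        ChemmineOB::convertFormat(from, to, source = source)
      } else {
        ChemmineOB::convertFormat(from, to, source = source,
                                  options = options)
      }),
    error = function(e) "")
  out <- str_trim(out %||% "")
  if (!nzchar(out)) {
    hg_abort(paste0("conversion ", from, " -> ", to, " failed for: ",
                    substr(source, 1, 60)), "hg_chem_error")
  }
  out
}

#' Convert an InChI to its InChIKey
#'
#' The InChIKey is the fixed-length hashed form of an InChI
#' (14 + 10 + 1 uppercase letters, hyphen-separated, 27 characters in all)
#' used to key curated-structure lookups and the mol2 cache.
#'
#' @param inchi A standard InChI string (must start with `"InChI="`).
#' @return The 27-character InChIKey.
#' @export
#' @examples
#' inchi_to_inchikey("InChI=1S/O3/c1-3-2")
inchi_to_inchikey <- function(inchi) {
  stopifnot(is.character(inchi), length(inchi) == 1L)
  if (!startsWith(inchi, "InChI=")) {
    hg_abort("not an InChI string", "hg_chem_error")
  }
  key <- ob_convert("INCHI", "INCHIKEY", inchi)
  if (!grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)) {
    hg_abort(paste0("conversion produced a malformed InChIKey: ", key),
             "hg_chem_error")
  }
  key
}

#' SMILES/InChI interconversion
#'
#' For standard InChIs of small organics the round trip
#' `smiles_to_inchi(inchi_to_smiles(x))` returns `x`.
#'
#' @param smiles,inchi Input structure string.
#' @return The converted identifier string.
#' @export
#' @examples
#' smiles_to_inchi("O")
smiles_to_inchi <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  ob_convert("SMI", "INCHI", smiles)
}

#' @rdname smiles_to_inchi
#' @export
inchi_to_smiles <- function(inchi) {
  stopifnot(is.character(inchi), length(inchi) == 1L)
  if (!startsWith(inchi, "InChI=")) {
    hg_abort("not an InChI string", "hg_chem_error")
  }
  ob_convert("INCHI", "SMI", inchi)
}

#' A name-to-InChI resolver backed by a local table
#'
#' Resolvers map a chemical name to an InChI (or nothing). This offline
#' implementation looks names up, case-folded, in a two-column table, and is
#' what the test suite and the preparation pipeline use in place of live
#' structure-resolution web services.
#'
#' @param table Data frame, or path to a delimited file readable by
#'   [read_glossary_table()].
#' @param name_col,inchi_col Column names.
#' @return A function `name -> InChI string or NA`.
#' @export
local_resolver <- function(table, name_col = "name", inchi_col = "inchi") {
  if (is.character(table) && length(table) == 1L) {
    table <- read_glossary_table(table)
  }
  stopifnot(is.data.frame(table),
            all(c(name_col, inchi_col) %in% names(table)))
  lookup <- stats::setNames(as.character(table[[inchi_col]]),
                            fold_key(as.character(table[[name_col]])))
  function(name) {
    hit <- lookup[[fold_key(name)]]
    if (is.null(hit) || is.na(hit) || !nzchar(hit)) NA_character_ else hit
  }
}

#' Resolve a name against several structure resolvers
#'
#' Typing a term as a chemical is trusted only when independent
#' name-to-structure services agree: each resolver is queried and the
#' normalized (trimmed, exact-string) InChIs are compared. Status is
#' `"agreed"` when every resolver answered with the same InChI,
#' `"disagreed"` when two or more distinct InChIs came back, `"partial"`
#' when some but not all resolvers answered (all answers identical), and
#' `"unresolved"` when none answered. Resolver failures are recorded as
#' empty answers, never raised, and the status never depends on resolver
#' order.
#'
#' @param name Chemical name to resolve.
#' @param resolvers A list of resolver functions (see [local_resolver()]),
#'   optionally named.
#' @return A `resolution_result`: list with `name`, `status`, `inchi` (the
#'   agreed InChI or `NA`) and `per_resolver` (named character vector).
#' @export
resolve_name <- function(name, resolvers) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(resolvers), length(resolvers) >= 1L)
  labels <- names(resolvers)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("resolver_", seq_along(resolvers))
  }
  answers <- map_chr(resolvers, function(r) {
    out <- tryCatch(r(name), error = function(e) NA_character_)
    if (is.null(out) || length(out) != 1L || is.na(out)) return(NA_character_)
    out <- str_trim(out)
    if (nzchar(out)) out else NA_character_
  })
  names(answers) <- labels
  answered <- answers[!is.na(answers)]
  distinct <- unique(answered)
  status <- if (length(answered) == 0L) {
    "unresolved"
  } else if (length(distinct) > 1L) {
    "disagreed"
  } else if (length(answered) == length(answers)) {
    "agreed"
  } else {
    "partial"
  }
  structure(
    list(name = name, status = status,
         inchi = if (status == "agreed") distinct else NA_character_,
         per_resolver = answers),
    class = "resolution_result"
  )
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("<resolution_result> '", x$name, "': ", x$status,
      if (!is.na(x$inchi)) paste0(" (", x$inchi, ")") else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn resolve_name tidy() method: one row per resolver.
#' @param x,... For the tidy method.
#' @export
tidy.resolution_result <- function(x, ...) {
  tibble(name = x$name, status = x$status,
         resolver = names(x$per_resolver),
         inchi = unname(x$per_resolver))
}

#' Assign word types to an untyped glossary by resolver agreement
#'
#' Runs [resolve_name()] on every `no_type` term. Terms whose resolvers
#' agree become `chemical` and receive the agreed InChI as identifier;
#' disagreements and (by default) partial answers go onto a review list for
#' a human curator; unresolved terms stay `no_type`. Terms already typed as
#' chemical or protein are never touched.
#'
#' @param glossary A glossary.
#' @param resolvers List of resolver functions.
#' @param partial `"review"` (default) puts single-resolver answers on the
#'   review list; `"accept"` treats them as agreed.
#' @return List with the updated `glossary` and a `review` tibble
#'   (`name`, `key`, `status`).
#' @export
assign_word_types <- function(glossary, resolvers,
                              partial = c("review", "accept")) {
  stopifnot(inherits(glossary, "glossary"))
  partial <- match.arg(partial)
  review <- list()
  for (key in names(glossary$terms)) {
    term <- glossary$terms[[key]]
    if (term$word_type != "no_type") next
    res <- resolve_name(term$name, resolvers)
    accepted <- res$status == "agreed" ||
      (res$status == "partial" && partial == "accept")
    if (accepted) {
      inchi <- res$inchi %||% NA_character_
      if (is.na(inchi)) inchi <- unique(res$per_resolver[!is.na(res$per_resolver)])
      term$word_type <- "chemical"
      term$identifier <- semantic_identifier("inchi", inchi)
      glossary$terms[[key]] <- term
    } else if (res$status %in% c("disagreed", "partial")) {
      review[[length(review) + 1L]] <-
        tibble(name = term$name, key = key, status = res$status)
    }
  }
  review <- if (length(review)) dplyr::bind_rows(review) else
    tibble(name = character(), key = character(), status = character())
  list(glossary = glossary, review = review)
}

#' An InChIKey-keyed cache of generated mol2 structure files
#'
#' 3D structure files are expensive enough to make only once: the cache is a
#' directory of `<InChIKey>.mol2` files plus a generation counter, and a
#' key, once written, is never regenerated.
#'
#' @param dir Cache directory (created if absent).
#' @return A `structure_cache` object.
#' @export
structure_cache <- function(dir = tempfile("mol2cache")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cache <- new.env(parent = emptyenv())
  cache$dir <- dir
  cache$generated <- 0L
  class(cache) <- "structure_cache"
  cache
}

#' @rdname structure_cache
#' @param cache A `structure_cache`.
#' @return `cache_generation_count()`: number of actual generation events.
#' @export
cache_generation_count <- function(cache) {
  stopifnot(inherits(cache, "structure_cache"))
  cache$generated
}

#' @export
print.structure_cache <- function(x, ...) {
  files <- list.files(x$dir, pattern = "\\.mol2$")
  cat("<structure_cache> ", x$dir, ": ", length(files), " file(s), ",
      x$generated, " generation event(s)\n", sep = "")
  invisible(x)
}

#' Number of atoms in a mol2 file
#'
#' @param path Path to a mol2 file (or the mol2 text itself).
#' @return Integer atom count from the `@<TRIPOS>ATOM` block.
#' @export
mol2_atom_count <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else strsplit(paste(path, collapse = "\n"), "\n")[[1]]
  at <- which(lines == "@<TRIPOS>ATOM")
  if (length(at) == 0L) return(0L)
  at <- at[[1]]
  stop_at <- which(seq_along(lines) > at & grepl("^@<TRIPOS>", lines))
  stop_at <- if (length(stop_at)) min(stop_at) else length(lines) + 1L
  block <- lines[seq(at + 1L, stop_at - 1L)]
  sum(nzchar(str_trim(block)))
}

# seeded distance-geometry embedding (RDKit ETKDG) through the system
# Python; returns an MDL mol block with 3D coordinates
rdkit_embed <- function(smiles, seed) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) {
    hg_abort("no python interpreter found for 3D embedding", "hg_chem_error")
  }
  code <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import AllChem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "mol = Chem.MolFromSmiles(sys.argv[1])",
    "if mol is None: sys.exit('unparsable SMILES')",
    "mol = Chem.AddHs(mol)",
    "if AllChem.EmbedMolecule(mol, randomSeed=int(sys.argv[2])) != 0:",
    "    sys.exit('embedding failed')",
    "sys.stdout.write(Chem.MolToMolBlock(mol))",
    sep = "\n")
  out <- suppressWarnings(
    system2(python, c("-c", shQuote(code), shQuote(smiles), seed),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    hg_abort(paste0("3D embedding failed: ",
                    paste(out, collapse = " ")), "hg_chem_error")
  }
  paste(out, collapse = "\n")
}

# MDL mol block -> mol2 text via the obabel command-line tool, a pure
# format translation that preserves the embedded coordinates
molblock_to_mol2 <- function(molblock) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) {
    hg_abort("obabel executable not found for mol2 conversion",
             "hg_chem_error")
  }
  src <- tempfile(fileext = ".mol")
  dst <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(src, dst)))
  writeLines(molblock, src)
  suppressWarnings(system2(obabel, c(src, "-omol2", "-O", dst),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(dst) || file.size(dst) == 0) {
    hg_abort("mol block to mol2 conversion failed", "hg_chem_error")
  }
  paste(readLines(dst), collapse = "\n")
}

#' Generate (or fetch) a cached 3D structure for an InChI
#'
#' Converts the InChI to SMILES, embeds a single 3D conformer with a seeded
#' distance-geometry method (RDKit's ETKDG, run through the system Python —
#' the embedding honours `seed`, so output is byte-identical across runs),
#' and converts the result to mol2 with OpenBabel. The file is stored in
#' the cache under the InChIKey; subsequent calls return the cached file
#' without regenerating.
#'
#' @param inchi InChI of a connectable molecule.
#' @param cache A [structure_cache()].
#' @param seed Integer seed for the conformer embedding.
#' @return Path to the mol2 file.
#' @export
generate_3d <- function(inchi, cache, seed = 1L) {
  stopifnot(inherits(cache, "structure_cache"))
  key <- inchi_to_inchikey(inchi)
  path <- file.path(cache$dir, paste0(key, ".mol2"))
  if (file.exists(path)) return(path)
  mol2 <- tryCatch({
    smiles <- inchi_to_smiles(inchi)
    molblock <- rdkit_embed(smiles, as.integer(seed))
    molblock_to_mol2(molblock)
  }, error = function(e) {
    hg_abort(paste0("3D embedding failed for ", key, ": ",
                    conditionMessage(e)), "hg_chem_error")
  })
  if (mol2_atom_count(mol2) < 1L) {
    hg_abort(paste0("3D embedding produced no atoms for ", key),
             "hg_chem_error")
  }
  writeLines(mol2, path)
  cache$generated <- cache$generated + 1L
  path
}
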