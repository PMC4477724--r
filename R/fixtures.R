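# Packaged demo vocabulary. Names are chosen so no entry is a whole-word
# sub-phrase of another and document filler words never collide with them —
# a planted mention therefore always yields exactly one span.

#' Packaged small-molecule demo list
#'
#' Names and SMILES of common small molecules used by the fixture
#' generator; identifiers are computed from the SMILES at generation time.
#'
#' @return Tibble with columns `name`, `smiles`.
#' @export
demo_molecules <- function() {
  tibble::tribble(
    ~name, ~smiles,
    "methane", "C",
    "ethane", "CC",
    "propane", "CCC",
    "butane", "CCCC",
    "pentane", "CCCCC",
    "hexane", "CCCCCC",
    "heptane", "CCCCCCC",
    "octane", "CCCCCCCC",
    "cyclopropane", "C1CC1",
    "cyclopentane", "C1CCCC1",
    "cyclohexane", "C1CCCCC1",
    "ethylene", "C=C",
    "propylene", "CC=C",
    "acetylene", "C#C",
    "benzene", "c1ccccc1",
    "toluene", "Cc1ccccc1",
    "phenol", "Oc1ccccc1",
    "aniline", "Nc1ccccc1",
    "styrene", "C=Cc1ccccc1",
    "naphthalene", "c1ccc2ccccc2c1",
    "pyridine", "c1ccncc1",
    "furan", "c1ccoc1",
    "thiophene", "c1ccsc1",
    "pyrrole", "c1cc[nH]c1",
    "imidazole", "c1cnc[nH]1",
    "pyrazine", "c1cnccn1",
    "ozone", "[O-][O+]=O",
    "water", "O",
    "ammonia", "N",
    "hydrazine", "NN",
    "methanol", "CO",
    "ethanol", "CCO",
    "propanol", "CCCO",
    "butanol", "CCCCO",
    "glycerol", "OCC(O)CO",
    "methylamine", "CN",
    "ethylamine", "CCN",
    "dimethylamine", "CNC",
    "formaldehyde", "C=O",
    "acetaldehyde", "CC=O",
    "acetone", "CC(C)=O",
    "formamide", "NC=O",
    "urea", "NC(N)=O",
    "glycine", "NCC(=O)O",
    "alanine", "CC(N)C(=O)O",
    "acetic acid", "CC(=O)O",
    "formic acid", "OC=O",
    "chloromethane", "CCl",
    "dichloromethane", "C(Cl)Cl",
    "chloroform", "C(Cl)(Cl)Cl",
    "iodomethane", "CI",
    "fluoromethane", "CF",
    "bromoethane", "CCBr",
    "acetonitrile", "CC#N",
    "tetrahydrofuran", "C1CCOC1",
    "dioxane", "C1COCCO1",
    "chlorobenzene", "Clc1ccccc1",
    "bromobenzene", "Brc1ccccc1",
    "nitrobenzene", "O=[N+]([O-])c1ccccc1",
    "benzaldehyde", "O=Cc1ccccc1",
    "benzamide", "NC(=O)c1ccccc1",
    "caffeine", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    "aspirin", "CC(=O)Oc1ccccc1C(=O)O",
    "ibuprofen", "CC(C)Cc1ccc(cc1)C(C)C(=O)O"
  )
}

#' Packaged protein demo list (synthetic PDB-style ids)
#'
#' Protein names paired with synthetic 4-character PDB-style identifiers
#' for offline fixtures; they are not real Protein Data Bank accessions.
#'
#' @return Tibble with columns `name`, `pdb_id`.
#' @export
demo_proteins <- function() {
  tibble::tribble(
    ~name, ~pdb_id,
    "hemoglobin", "1HEM",
    "myoglobin", "1MYG",
    "insulin", "1INS",
    "lysozyme", "1LYZ",
    "albumin", "1ALB",
    "ferritin", "1FER",
    "collagen", "1COL",
    "keratin", "1KER",
    "actin", "1ACT",
    "myosin", "1MYO"
  )
}

demo_vocabulary <- function() {
  c("entropy", "enthalpy", "equilibrium", "oxidation", "reduction",
    "titration", "solvent", "solute", "molarity", "kinetics", "isotope",
    "polymer", "monomer", "diffusion", "osmosis", "valence", "electron",
    "proton", "neutron", "orbital", "spectroscopy", "chromatography",
    "distillation", "sublimation", "viscosity", "buffer", "electrolyte",
    "catalyst", "ligand", "adsorption")
}

demo_filler <- function() {
  c("the", "a", "this", "each", "observed", "measured", "reported",
    "values", "for", "under", "ambient", "conditions", "during", "its",
    "within", "study", "we", "describe", "results", "and", "their",
    "figure", "shows", "typical", "behaviour", "of", "was", "then")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fixture
#'
#' Fixes the conditions every offline test runs under: glossary size and
#' composition, how many term mentions each demo document plants, whether
#' negative controls (the same terms inside anchors and a script block) are
#' included, and the seed that makes all of it bit-for-bit reproducible.
#'
#' @param n_terms Glossary size.
#' @param fraction_chemical,fraction_protein Composition fractions in
#'   `[0, 1]`, summing to at most 1; counts are `floor(fraction * n_terms)`.
#' @param n_documents Number of demo documents.
#' @param mentions_per_document Planted term mentions per document.
#' @param with_links Include anchor/script negative controls.
#' @param seed Integer seed determining every random choice.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_terms = 10L, fraction_chemical = 0.3,
                         fraction_protein = 0.1, n_documents = 1L,
                         mentions_per_document = 5L, with_links = FALSE,
                         seed = 1L) {
  if (fraction_chemical < 0 || fraction_chemical > 1 ||
      fraction_protein < 0 || fraction_protein > 1 ||
      fraction_chemical + fraction_protein > 1) {
    hg_abort("fractions must lie in [0,1] and sum to at most 1",
             "hg_fixture_error")
  }
  stopifnot(n_terms >= 1L, mentions_per_document >= 0L, n_documents >= 1L)
  structure(
    list(n_terms = as.integer(n_terms),
         fraction_chemical = fraction_chemical,
         fraction_protein = fraction_protein,
         n_documents = as.integer(n_documents),
         mentions_per_document = as.integer(mentions_per_document),
         with_links = isTRUE(with_links),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a typed demo glossary
#'
#' Chemical terms are drawn from [demo_molecules()] with InChIs computed
#' via [smiles_to_inchi()]; protein terms from [demo_proteins()] with their
#' synthetic PDB-style ids; the rest are plain vocabulary. Layout is the
#' canonical-plus-wiki convention: two fields, field 1 locked with a
#' glossary-wide citation, field 2 editable. Output is fully determined by
#' the seed in the fixture specification.
#'
#' @param spec A [fixture_spec()].
#' @return A glossary.
#' @export
make_demo_glossary <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_chem <- floor(spec$fraction_chemical * spec$n_terms)
  n_prot <- floor(spec$fraction_protein * spec$n_terms)
  n_plain <- spec$n_terms - n_chem - n_prot
  mols <- demo_molecules()
  prots <- demo_proteins()
  vocab <- demo_vocabulary()
  if (n_chem > nrow(mols) || n_prot > nrow(prots) || n_plain > length(vocab)) {
    hg_abort("requested more terms than the packaged demo lists hold",
             "hg_fixture_error")
  }
  with_local_seed(spec$seed, {
    mols <- mols[sample.int(nrow(mols), n_chem), , drop = FALSE]
    prots <- prots[sample.int(nrow(prots), n_prot), , drop = FALSE]
    vocab <- sample(vocab, n_plain)
  })
  g <- create_glossary("demo glossary", 2L, c(TRUE, FALSE),
                       "Synthetic demo glossary (canonical field)")
  for (i in seq_len(nrow(mols))) {
    inchi <- smiles_to_inchi(mols$smiles[[i]])
    g <- add_term(g, mols$name[[i]], "chemical",
                  semantic_identifier("inchi", inchi),
                  c(paste0("<p>Canonical definition of ", mols$name[[i]],
                           ".</p>"),
                    paste0("<p>Wiki notes on ", mols$name[[i]], ".</p>")))
  }
  for (i in seq_len(nrow(prots))) {
    g <- add_term(g, prots$name[[i]], "protein",
                  semantic_identifier("pdb_id", prots$pdb_id[[i]]),
                  paste0("<p>Canonical definition of ", prots$name[[i]],
                         ".</p>"))
  }
  for (w in vocab) {
    g <- add_term(g, w, "no_type", NULL,
                  paste0("<p>Canonical definition of ", w, ".</p>"))
  }
  g
}

#' Generate a demo document with planted term mentions
#'
#' Builds an HTML page whose body plants exactly
#' `spec$mentions_per_document` glossary-term mentions in safe text,
#' surrounded by filler words that never collide with the vocabulary.
#' Mentions at even positions are title-cased to exercise case-insensitive
#' matching. With `with_links = TRUE` the same terms also appear inside an
#' anchor and a script block — negative controls that processing must leave
#' untouched. Byte-for-byte reproducible from the seed in the fixture specification.
#'
#' @param glossary A non-empty glossary.
#' @param spec A [fixture_spec()].
#' @return List with `html` (the document) and `manifest` (tibble:
#'   `position`, `mention` as planted, `key` the canonical term key).
#' @export
make_demo_document <- function(glossary, spec) {
  stopifnot(inherits(glossary, "glossary"), inherits(spec, "fixture_spec"))
  if (length(glossary$terms) == 0L) {
    hg_abort("glossary has no terms to plant", "hg_fixture_error")
  }
  names_pool <- map_chr(unname(glossary$terms), "name")
  filler <- demo_filler()
  out <- with_local_seed(spec$seed + 1L, {
    mentions <- sample(names_pool, spec$mentions_per_document,
                       replace = TRUE)
    shown <- ifelse(seq_along(mentions) %% 2L == 0L,
                    stringr::str_to_title(mentions), mentions)
    sentences <- map_chr(seq_along(mentions), function(i) {
      lead <- paste(sample(filler, 4L, replace = TRUE), collapse = " ")
      tail <- paste(sample(filler, 3L, replace = TRUE), collapse = " ")
      paste0(lead, " ", shown[[i]], " ", tail, ".")
    })
    list(mentions = mentions, shown = shown, sentences = sentences)
  })
  body <- paste0("<p>", paste(out$sentences, collapse = " "), "</p>")
  extras <- ""
  if (spec$with_links && length(out$mentions) > 0L) {
    t1 <- out$mentions[[1]]
    extras <- paste0(
      '<p>See <a href="https://example.org/', gsub(" ", "-", t1), '">', t1,
      "</a> in the index.</p>",
      "<script>var terms = [\"", t1, "\"];</script>")
  }
  html <- paste0("<html><head><title>fixture page</title></head><body>",
                 body, extras, "</body></html>")
  manifest <- tibble(
    position = seq_along(out$mentions),
    mention = out$shown,
    key = fold_key(out$mentions)
  )
  list(html = html, manifest = manifest)
}
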