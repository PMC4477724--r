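# Frozen conversion values were computed independently with RDKit and
# cross-checked against OpenBabel before being pinned here.

test_that("InChI to InChIKey matches pinned reference values", {
  expect_identical(inchi_to_inchikey(ozone_inchi), ozone_inchikey)
  expect_identical(inchi_to_inchikey(methane_inchi), methane_inchikey)
  expect_identical(inchi_to_inchikey("InChI=1S/H2O/h1H2"),
                   "XLYOFNOQVPJJNP-UHFFFAOYSA-N")
  # deterministic
  expect_identical(inchi_to_inchikey(ozone_inchi),
                   inchi_to_inchikey(ozone_inchi))
  expect_error(inchi_to_inchikey("InChI=garbage"), class = "hg_chem_error")
  expect_error(inchi_to_inchikey("not an inchi"), class = "hg_chem_error")
})

test_that("SMILES/InChI conversions round-trip small organics", {
  expect_identical(smiles_to_inchi("O"), "InChI=1S/H2O/h1H2")
  expect_identical(smiles_to_inchi(inchi_to_smiles(methane_inchi)),
                   methane_inchi)
  for (inchi in c(ozone_inchi, "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3",
                  "InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H")) {
    expect_identical(smiles_to_inchi(inchi_to_smiles(inchi)), inchi)
  }
  expect_error(smiles_to_inchi(""), class = "hg_chem_error")
  expect_error(smiles_to_inchi("xy(("), class = "hg_chem_error")
  expect_error(inchi_to_smiles("junk"), class = "hg_chem_error")
})

test_that("every packaged demo molecule yields a well-formed InChIKey", {
  mols <- demo_molecules()
  keys <- vapply(mols$smiles, function(s)
    inchi_to_inchikey(smiles_to_inchi(s)), "", USE.NAMES = FALSE)
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", keys)))
  expect_true(all(nchar(keys) == 27L))
  # keys are distinct molecules
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("resolver agreement statuses follow the answer pattern", {
  tab <- tibble::tibble(name = c("ozone", "methane"),
                        inchi = c(ozone_inchi, methane_inchi))
  r1 <- local_resolver(tab)
  r2 <- local_resolver(tab)
  r_wrong <- local_resolver(tibble::tibble(name = "ozone",
                                           inchi = methane_inchi))
  r_silent <- local_resolver(tibble::tibble(name = "nothing", inchi = "x"))
  r_fail <- function(name) stop("service down")

  agreed <- resolve_name("ozone", list(r1, r2))
  expect_identical(agreed$status, "agreed")
  expect_identical(agreed$inchi, ozone_inchi)

  disagreed <- resolve_name("ozone", list(r1, r_wrong))
  expect_identical(disagreed$status, "disagreed")
  expect_true(is.na(disagreed$inchi))

  unresolved <- resolve_name("entropy", list(r1, r2))
  expect_identical(unresolved$status, "unresolved")

  partial <- resolve_name("ozone", list(r1, r_silent))
  expect_identical(partial$status, "partial")

  # resolver failure counts as an empty answer, not an error
  failed <- resolve_name("ozone", list(r1, r_fail))
  expect_identical(failed$status, "partial")
  expect_true(is.na(failed$per_resolver[[2]]))

  td <- tidy(agreed)
  expect_identical(nrow(td), 2L)
  expect_identical(unique(td$status), "agreed")
})

test_that("resolution status is independent of resolver order", {
  tab <- tibble::tibble(name = "ozone", inchi = ozone_inchi)
  pool <- list(
    a = local_resolver(tab),
    b = local_resolver(tibble::tibble(name = "ozone", inchi = methane_inchi)),
    c = local_resolver(tibble::tibble(name = "other", inchi = "x")),
    d = function(name) stop("down")
  )
  set.seed(11)
  for (k in 2:4) {
    subset_names <- utils::combn(names(pool), k, simplify = FALSE)
    for (nm in subset_names) {
      statuses <- vapply(1:5, function(i) {
        resolve_name("ozone", pool[sample(nm)])$status
      }, "")
      expect_identical(length(unique(statuses)), 1L,
                       info = paste(nm, collapse = ","))
    }
  }
})

test_that("assign_word_types promotes agreed chemicals and queues reviews", {
  g <- create_glossary("G", 1) |>
    add_term("ozone", definitions = "gas") |>
    add_term("entropy", definitions = "state function") |>
    add_term("methane", definitions = "ch4")
  tab <- tibble::tibble(name = c("ozone", "methane"),
                        inchi = c(ozone_inchi, methane_inchi))
  conflicting <- tibble::tibble(name = c("ozone", "methane"),
                                inchi = c(ozone_inchi, ozone_inchi))
  out <- assign_word_types(g, list(local_resolver(tab),
                                   local_resolver(conflicting)))
  expect_identical(glossary_term(out$glossary, "ozone")$word_type, "chemical")
  expect_identical(glossary_term(out$glossary, "ozone")$identifier$value,
                   ozone_inchi)
  expect_identical(glossary_term(out$glossary, "entropy")$word_type, "no_type")
  # disagreement leaves the type unchanged and queues a review
  expect_identical(glossary_term(out$glossary, "methane")$word_type, "no_type")
  expect_identical(out$review$key, "methane")
  expect_identical(out$review$status, "disagreed")
})

test_that("assign_word_types handles partials per policy, empty input, and never demotes", {
  tab <- tibble::tibble(name = "ozone", inchi = ozone_inchi)
  silent <- local_resolver(tibble::tibble(name = "none", inchi = "x"))
  g <- create_glossary("G", 1) |> add_term("ozone", definitions = "gas")
  reviewed <- assign_word_types(g, list(local_resolver(tab), silent))
  expect_identical(glossary_term(reviewed$glossary, "ozone")$word_type,
                   "no_type")
  expect_identical(reviewed$review$status, "partial")
  accepted <- assign_word_types(g, list(local_resolver(tab), silent),
                                partial = "accept")
  expect_identical(glossary_term(accepted$glossary, "ozone")$word_type,
                   "chemical")

  empty <- assign_word_types(create_glossary("E", 1), list(local_resolver(tab)))
  expect_identical(length(empty$glossary$terms), 0L)
  expect_identical(nrow(empty$review), 0L)

  # a typed term is never re-resolved or demoted
  gp <- create_glossary("P", 1) |>
    add_term("hemoglobin", "protein", semantic_identifier("pdb_id", "1ABC"),
             "carrier")
  bad <- local_resolver(tibble::tibble(name = "hemoglobin", inchi = ozone_inchi))
  out2 <- assign_word_types(gp, list(bad, bad))
  expect_identical(glossary_term(out2$glossary, "hemoglobin")$word_type,
                   "protein")
})

test_that("3D generation writes a plausible cached mol2 exactly once", {
  cache <- structure_cache(withr::local_tempdir())
  p1 <- generate_3d(methane_inchi, cache, seed = 1L)
  expect_true(file.exists(p1))
  expect_identical(basename(p1), paste0(methane_inchikey, ".mol2"))
  expect_identical(mol2_atom_count(p1), 5L)  # CH4
  bytes1 <- readBin(p1, "raw", file.size(p1))

  p2 <- generate_3d(methane_inchi, cache, seed = 1L)
  expect_identical(p1, p2)
  expect_identical(cache_generation_count(cache), 1L)
  expect_identical(readBin(p2, "raw", file.size(p2)), bytes1)
  expect_identical(length(list.files(cache$dir)), 1L)

  # a fresh cache regenerates byte-identical coordinates
  cache2 <- structure_cache(withr::local_tempdir())
  p3 <- generate_3d(methane_inchi, cache2, seed = 1L)
  expect_identical(readBin(p3, "raw", file.size(p3)), bytes1)
})

test_that("3D coordinates are genuinely three-dimensional", {
  cache <- structure_cache(withr::local_tempdir())
  path <- generate_3d("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", cache)
  lines <- readLines(path)
  at <- which(lines == "@<TRIPOS>ATOM")
  block <- lines[(at + 1):(at + mol2_atom_count(path))]
  coords <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(f)
    as.numeric(f[3:5])))
  expect_true(all(apply(coords, 2, function(v) diff(range(v)) > 0)))
})

test_that("n generate calls cause exactly one generation event per key", {
  cache <- structure_cache(withr::local_tempdir())
  inchis <- c(methane_inchi, ozone_inchi)
  for (i in 1:4) for (inchi in inchis) generate_3d(inchi, cache)
  expect_identical(cache_generation_count(cache), 2L)
  expect_identical(sort(basename(list.files(cache$dir))),
                   sort(paste0(c(methane_inchikey, ozone_inchikey), ".mol2")))
})

test_that("3D generation failures report the InChIKey", {
  cache <- structure_cache(withr::local_tempdir())
  err <- expect_error(generate_3d("InChI=bogus/structure", cache),
                      class = "hg_chem_error")
  expect_identical(cache_generation_count(cache), 0L)
})
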