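# Brute-force matching oracle: enumerates every candidate (start, end) span,
# filters by word boundaries and dictionary membership, and greedily keeps
# leftmost-longest non-overlapping spans. Deliberately independent of the
# package's regex path.

oracle_is_word_char <- function(ch, hyphen_in_word = TRUE) {
  pat <- if (hyphen_in_word) "[\\p{L}\\p{N}-]" else "[\\p{L}\\p{N}]"
  grepl(pat, ch, perl = TRUE)
}

oracle_normalise <- function(x) {
  gsub("\\s+", " ", stringr::str_to_lower(x))
}

oracle_find_matches <- function(text, keys, hyphen_in_word = TRUE) {
  n <- nchar(text)
  keyset <- oracle_normalise(keys)
  if (n == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          matched_text = character(), wordterm = character()))
  }
  max_w <- max(nchar(keyset)) + 10L  # slack for internal whitespace runs
  chars <- strsplit(text, "")[[1]]
  is_word <- oracle_is_word_char(chars, hyphen_in_word)
  starts <- integer(); ends <- integer(); matched <- character()
  i <- 1L
  while (i <= n) {
    if (is_word[[i]] && (i == 1L || !is_word[[i - 1L]])) {
      js <- seq.int(i, min(n, i + max_w))
      at_end <- js == n
      at_end[!at_end] <- !is_word[js[!at_end] + 1L]
      js <- js[at_end]
      subs <- if (length(js)) substring(text, i, js) else character()
      hit <- oracle_normalise(subs) %in% keyset
      if (any(hit)) {
        best <- max(js[hit])   # longest match at this (leftmost) position
        starts <- c(starts, i - 1L)
        ends <- c(ends, best)
        matched <- c(matched, substring(text, i, best))
        i <- best + 1L
        next
      }
    }
    i <- i + 1L
  }
  tibble::tibble(start = starts, end = ends, matched_text = matched,
                 wordterm = oracle_normalise(matched))
}

# random instances for property tests ---------------------------------------

random_word <- function(min_len = 2L, max_len = 6L) {
  paste(sample(letters[1:6], sample(min_len:max_len, 1L), replace = TRUE),
        collapse = "")
}

random_term_set <- function(max_terms = 20L) {
  n <- sample.int(max_terms, 1L)
  terms <- unique(vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(sample.int(3L, 1L, prob = c(.7, .2, .1))),
                 function(j) random_word(), ""), collapse = " ")
  }, ""))
  terms[!duplicated(stringr::str_to_lower(terms))]
}

random_document <- function(terms, max_chars = 500L) {
  vocab <- c(unlist(strsplit(terms, " ")), replicate(8, random_word()),
             paste0(random_word(), "-", random_word()))
  n_tok <- sample(5:60, 1L)
  toks <- sample(vocab, n_tok, replace = TRUE)
  flip <- runif(n_tok) < 0.2
  toks[flip] <- stringr::str_to_title(toks[flip])
  seps <- sample(c(" ", " ", "  ", ", ", ". ", "-", "\n"), n_tok,
                 replace = TRUE, prob = c(.4, .2, .1, .1, .1, .05, .05))
  doc <- paste0(paste0(toks, seps), collapse = "")
  substr(doc, 1, max_chars)
}

random_glossary_from_terms <- function(terms) {
  g <- create_glossary(paste0("rand-", random_word()), 1L)
  for (t in terms) g <- add_term(g, t, definitions = "d")
  g
}

# random glossaries for XML round-trip tests --------------------------------

random_inchi <- function() {
  paste0("InChI=1S/C", sample(1:9, 1L), "H", sample(1:20, 1L),
         "/c1-2-3/h1H", sample(1:4, 1L))
}

random_pdb_id <- function() {
  paste0(sample(1:9, 1L),
         paste(sample(LETTERS, 3L, replace = TRUE), collapse = ""))
}

random_content <- function() {
  bits <- c("plain text", "with, commas", "\"quoted\"", "<b>bold</b>",
            "ampers & and", "line\nbreak", "semi;colon")
  paste(sample(bits, sample.int(3L, 1L), replace = TRUE), collapse = " ")
}

random_full_glossary <- function() {
  fc <- sample.int(5L, 1L)
  mask <- sample(c(TRUE, FALSE), fc, replace = TRUE)
  citation <- if (runif(1) < 0.5) "Random source citation" else NULL
  if (!is.null(citation)) mask[1] <- TRUE
  g <- create_glossary(paste0("G-", random_word()), fc, mask, citation)
  if (runif(1) < 0.2) g <- set_active(g, FALSE)
  for (i in seq_len(sample(0:6, 1L))) {
    wt <- sample(word_types(), 1L)
    id <- switch(wt,
                 no_type = NULL,
                 chemical = semantic_identifier("inchi", random_inchi()),
                 protein = semantic_identifier("pdb_id", random_pdb_id()))
    defs <- replicate(sample.int(fc, 1L), random_content())
    nm <- paste0(random_word(), i)
    g <- tryCatch(add_term(g, nm, wt, id, defs), error = function(e) g)
  }
  g
}

# structural glossary equality, ignoring version history depth
expect_same_glossary <- function(a, b) {
  expect_identical(a$name, b$name)
  expect_identical(a$source_citation, b$source_citation)
  expect_identical(a$field_count, b$field_count)
  expect_identical(a$locked_mask, b$locked_mask)
  expect_identical(a$active, b$active)
  expect_identical(sort(names(a$terms)), sort(names(b$terms)))
  for (k in names(a$terms)) {
    ta <- a$terms[[k]]; tb <- b$terms[[k]]
    expect_identical(ta$name, tb$name)
    expect_identical(ta$word_type, tb$word_type)
    expect_identical(is.null(ta$identifier), is.null(tb$identifier))
    if (!is.null(ta$identifier)) {
      expect_identical(ta$identifier$kind, tb$identifier$kind)
      expect_identical(ta$identifier$value, tb$identifier$value)
    }
    for (i in seq_len(a$field_count)) {
      expect_identical(hyperglossary:::current_content(ta, i),
                       hyperglossary:::current_content(tb, i))
    }
  }
  invisible(TRUE)
}

# offline store fixtures -----------------------------------------------------

tiny_png_b64 <- function() {
  tmp <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 1, 1), tmp)
  jsonlite::base64_enc(readBin(tmp, "raw", file.size(tmp)))
}

fixture_pdb_store <- function(ids = "1ABC") {
  dir <- tempfile("pdbstore")
  dir.create(dir)
  for (id in ids) {
    writeLines(c("HEADER    SYNTHETIC FIXTURE PROTEIN",
                 "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
                 "END"),
               file.path(dir, paste0(id, ".pdb")))
  }
  pdb_store(dir)
}

fixture_search_backend <- function(inchikeys) {
  b64 <- tiny_png_b64()
  local_search_backend(tibble::tibble(
    inchikey = inchikeys,
    id = paste0("CS", seq_along(inchikeys)),
    thumbnail_b64 = b64,
    link = paste0("https://example.org/compound/", seq_along(inchikeys))
  ))
}

ozone_inchi <- "InChI=1S/O3/c1-3-2"
ozone_inchikey <- "CBENFWSGALASAD-UHFFFAOYSA-N"   # frozen reference value
methane_inchi <- "InChI=1S/CH4/h1H4"
methane_inchikey <- "VNWKTOKETHGBQD-UHFFFAOYSA-N" # frozen reference value

chem_glossary <- function() {
  create_glossary("chem demo", 2, c(TRUE, FALSE), "Demo source") |>
    add_term("ozone", "chemical", semantic_identifier("inchi", ozone_inchi),
             c("O3 gas definition", "wiki notes")) |>
    add_term("methane", "chemical",
             semantic_identifier("inchi", methane_inchi), "CH4 definition") |>
    add_term("entropy", definitions = "state function") |>
    add_term("hemoglobin", "protein", semantic_identifier("pdb_id", "1ABC"),
             "oxygen carrier")
}
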