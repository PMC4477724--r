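test_that("segmentation separates text in anchors from free text", {
  s <- segment_document('<a href="x">ozone</a> ozone')
  expect_identical(s$safety, c("unsafe", "safe"))
  expect_identical(s$text[[2]], " ozone")
  expect_identical(s$start, c(0L, 21L))
  expect_identical(s$end, c(21L, 27L))
})

test_that("segments are contiguous and concatenate to the source", {
  sources <- c(
    "plain text only",
    '<html><head><title>t</title></head><body><p>a b</p><script>var x = "<b>";</script>c</body></html>',
    '<p>one <a href="u">two</a> three <!-- four --> five</p>',
    "broken < markup <b>bold</b> 2 < 3",
    '<span class="hg3" context="search" wordterm="k">k</span> rest',
    "<style>p { color: red }</style>text",
    "<textarea>inside</textarea> outside"
  )
  for (src in sources) {
    s <- segment_document(src)
    expect_identical(paste(s$text, collapse = ""), src)
    expect_identical(s$start, c(0L, s$end[-nrow(s)]))
    expect_identical(s$end[[nrow(s)]], nchar(src))
  }
})

test_that("head, title, script, style, comments and markup are unsafe", {
  src <- '<head><title>ozone</title></head><body>ozone<script>"ozone"</script><!-- ozone --></body>'
  s <- segment_document(src)
  safe_text <- paste(s$text[s$safety == "safe"], collapse = "")
  expect_identical(safe_text, "ozone")
})

test_that("empty and markup-free documents segment trivially", {
  expect_identical(nrow(segment_document("")), 0L)
  s <- segment_document("plain text only")
  expect_identical(nrow(s), 1L)
  expect_identical(s$safety, "safe")
  expect_identical(s$end, 15L)
})

test_that("matcher respects word boundaries and hyphen policy", {
  g <- create_glossary("G", 1) |> add_term("ozone", definitions = "gas")
  m <- build_matcher(g)
  hits <- function(txt, matcher = m) {
    nrow(find_matches(matcher, list(text = txt, safety = "safe")))
  }
  expect_identical(hits("Ozone"), 1L)
  expect_identical(hits("ozone."), 1L)
  expect_identical(hits("ozonelayer"), 0L)
  expect_identical(hits("ozone-depleting"), 0L)  # hyphen is a word character
  m2 <- build_matcher(g, hyphen_in_word = FALSE)
  expect_identical(hits("ozone-depleting", m2), 1L)
})

test_that("longer phrases win over their prefixes", {
  g <- create_glossary("G", 1) |>
    add_term("ozone", definitions = "gas") |>
    add_term("ozone layer", definitions = "region")
  m <- build_matcher(g)
  sp <- find_matches(m, list(text = "the ozone layer", safety = "safe"))
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$wordterm, "ozone layer")
  # phrase matching spans whitespace runs, display text preserved
  sp2 <- find_matches(m, list(text = "an Ozone  layer here", safety = "safe"))
  expect_identical(sp2$matched_text, "Ozone  layer")
  expect_identical(sp2$wordterm, "ozone layer")
})

test_that("matcher construction rejects inactive and empty glossaries", {
  empty <- create_glossary("E", 1)
  expect_error(build_matcher(empty), class = "hg_empty_glossary_error")
  g <- add_term(empty, "t", definitions = "d")
  expect_error(build_matcher(set_active(g, FALSE)), class = "hg_inactive_error")
})

test_that("find_matches reports 0-based half-open offsets", {
  g <- create_glossary("G", 1) |> add_term("ozone", definitions = "gas")
  m <- build_matcher(g)
  sp <- find_matches(m, list(text = "ozone and more ozone", safety = "safe"))
  expect_identical(sp$start, c(0L, 15L))
  expect_identical(sp$end, c(5L, 20L))
  expect_identical(sp$matched_text, c("ozone", "ozone"))
  none <- find_matches(m, list(text = "nothing here", safety = "safe"))
  expect_identical(nrow(none), 0L)
  up <- find_matches(m, list(text = "OZONE", safety = "safe"))
  expect_identical(up$wordterm, "ozone")
  expect_error(find_matches(m, list(text = "x", safety = "unsafe")),
               class = "hg_contract_error")
})

test_that("rendering wraps matches in the canonical HG tag dialect", {
  g <- create_glossary("G", 1) |> add_term("ozone", definitions = "gas")
  d <- process_document("ozone is a gas", g)
  expect_identical(
    d$html_out,
    '<span class="hg3" context="search" wordterm="ozone">ozone</span> is a gas')
  # display case preserved, wordterm case-folded
  d2 <- process_document("Ozone rises", g)
  expect_match(d2$html_out,
               '<span class="hg3" context="search" wordterm="ozone">Ozone</span>',
               fixed = TRUE)
  # no matches renders the source unchanged
  d3 <- process_document("inert gases", g)
  expect_identical(d3$html_out, "inert gases")
})

test_that("wordterm attribute values are HTML-escaped", {
  g <- create_glossary("G", 1) |> add_term('a"b', definitions = "odd name")
  d <- process_document('a"b here', g)
  expect_match(d$html_out, 'wordterm="a&quot;b"', fixed = TRUE)
  expect_identical(strip_hg_tags(d$html_out), 'a"b here')
})

test_that("rendering rejects overlapping spans", {
  segs <- segment_document("abcdef")
  spans <- tibble::tibble(
    start = c(0L, 2L), end = c(3L, 5L),
    matched_text = c("abc", "cde"), wordterm = c("abc", "cde"),
    glossary_name = "G", segment = 1L)
  expect_error(render_document("abcdef", segs, spans),
               class = "hg_contract_error")
})

test_that("terms inside pre-existing anchors are not tagged", {
  g <- create_glossary("G", 1) |> add_term("ozone", definitions = "gas")
  src <- '<a href="x">ozone</a> ozone'
  d <- process_document(src, g)
  expect_identical(nrow(d$spans), 1L)
  expect_identical(d$spans$doc_start, 22L)
  expect_match(d$html_out, '^<a href="x">ozone</a> <span')
})

test_that("processing is idempotent: a second pass changes nothing", {
  g <- create_glossary("G", 1) |>
    add_term("ozone", definitions = "gas") |>
    add_term("entropy", definitions = "s")
  src <- "<p>ozone and entropy</p>"
  d1 <- process_document(src, g)
  d2 <- process_document(d1$html_out, g)
  expect_identical(nrow(d2$spans), 0L)
  expect_identical(d2$html_out, d1$html_out)
})

test_that("matcher agrees with the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    terms <- random_term_set()
    doc <- random_document(terms)
    g <- random_glossary_from_terms(terms)
    m <- build_matcher(g)
    got <- find_matches(m, list(text = doc, safety = "safe"))
    want <- oracle_find_matches(doc, names(g$terms))
    expect_identical(got$start, want$start,
                     info = paste("doc:", doc, "| terms:",
                                  paste(terms, collapse = ";")))
    expect_identical(got$end, want$end)
    expect_identical(got$matched_text, want$matched_text)
    expect_identical(got$wordterm, want$wordterm)
  }
})

test_that("visible text and pre-existing anchors survive processing", {
  set.seed(99)
  extract_anchors <- function(html) {
    m <- gregexpr("(?s)<a\\s[^>]*>.*?</a>", html, perl = TRUE)[[1]]
    if (m[1] == -1L) return(character())
    sort(unlist(regmatches(html, list(m))))
  }
  for (rep in 1:20) {
    terms <- random_term_set()
    g <- random_glossary_from_terms(terms)
    body <- random_document(terms)
    t1 <- terms[[1]]
    src <- paste0('<html><body><p>', body, '</p><a href="https://e.org/1">',
                  t1, '</a><script>var q = "', t1, '";</script></body></html>')
    d <- process_document(src, g)
    expect_identical(strip_hg_tags(d$html_out), src)
    expect_identical(extract_anchors(d$html_out), extract_anchors(src))
  }
})

test_that("processed_document methods expose spans and summaries", {
  g <- create_glossary("G", 1) |> add_term("ozone", definitions = "gas")
  d <- process_document("ozone twice: ozone", g)
  expect_identical(tidy(d), d$spans)
  gl <- glance(d)
  expect_identical(gl$n_spans, 2L)
  expect_identical(gl$n_distinct_terms, 1L)
  p <- autoplot(d)
  expect_s3_class(p, "ggplot")
})
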