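#' Segment a document into safe and unsafe regions
#'
#' Term tagging must never disturb what a page already has: pre-existing
#' anchors, scripts, styles, head metadata, comments and all tag markup are
#' "unsafe" and are carried through processing verbatim. Only text-node
#' content outside those contexts is "safe" and eligible for matching.
#' The scanner works directly on the source string so that segments are
#' contiguous, non-overlapping and concatenate exactly back to the source
#' (offsets are 0-based, half-open); malformed HTML is tolerated — an
#' unmatched `<` is treated as text, unclosed raw-text elements run to the
#' end of the document. Plain text with no markup is one safe segment.
#'
#' HG spans from a previous processing pass (`<span class="hg3" ...>`) are
#' unsafe on re-entry, which is what makes processing idempotent.
#'
#' @param source HTML or plain-text string.
#' @param unsafe_tags Elements whose text content is never tagged.
#' @return Tibble with columns `text`, `safety` (`"safe"`/`"unsafe"`),
#'   `start`, `end`. Empty input gives zero rows.
#' @export
#' @examples
#' segment_document('<a href="x">ozone</a> ozone')
segment_document <- function(source,
                             unsafe_tags = c("a", "script", "style", "head",
                                             "title", "textarea")) {
  stopifnot(is.character(source), length(source) == 1L, !is.na(source))
  unsafe_tags <- tolower(unsafe_tags)
  n <- nchar(source)
  if (n == 0L) {
    return(tibble(text = character(), safety = character(),
                  start = integer(), end = integer()))
  }

  void_tags <- c("area", "base", "br", "col", "embed", "hr", "img", "input",
                 "link", "meta", "param", "source", "track", "wbr")
  raw_text_tags <- c("script", "style", "textarea", "title")

  pieces_start <- integer()
  pieces_end <- integer()   # 1-based inclusive, converted at the end
  pieces_safe <- logical()
  add_piece <- function(from, to, safe) {
    if (to < from) return(invisible(NULL))
    k <- length(pieces_start)
    if (k > 0L && pieces_safe[[k]] == safe && pieces_end[[k]] + 1L == from) {
      pieces_end[[k]] <<- to
    } else {
      pieces_start[[k + 1L]] <<- from
      pieces_end[[k + 1L]] <<- to
      pieces_safe[[k + 1L]] <<- safe
    }
    invisible(NULL)
  }

  # element stack: names + whether each open element suppresses tagging
  stack_names <- character()
  stack_unsafe <- logical()
  unsafe_depth <- function() sum(stack_unsafe)

  # end of a tag starting at `<`, honouring quoted attribute values;
  # returns position of `>` or NA
  find_tag_end <- function(from) {
    i <- from
    quote <- ""
    while (i <= n) {
      ch <- substr(source, i, i)
      if (nzchar(quote)) {
        if (ch == quote) quote <- ""
      } else if (ch == '"' || ch == "'") {
        quote <- ch
      } else if (ch == ">") {
        return(i)
      }
      i <- i + 1L
    }
    NA_integer_
  }

  tag_is_hg_span <- function(tag_text) {
    m <- regmatches(tag_text,
      regexpr("class\\s*=\\s*(\"[^\"]*\"|'[^']*'|[^\\s>]+)", tag_text,
              perl = TRUE, ignore.case = TRUE))
    if (length(m) == 0L) return(FALSE)
    cls <- sub("(?i)^class\\s*=\\s*", "", m, perl = TRUE)
    cls <- gsub("^[\"']|[\"']$", "", cls)
    "hg3" %in% strsplit(tolower(cls), "\\s+")[[1]]
  }

  i <- 1L
  while (i <= n) {
    nxt <- regexpr("<", substr(source, i, n), fixed = TRUE)
    if (nxt == -1L) {
      add_piece(i, n, unsafe_depth() == 0L)
      break
    }
    tag_at <- i + as.integer(nxt) - 1L
    add_piece(i, tag_at - 1L, unsafe_depth() == 0L)
    rest <- substr(source, tag_at, min(n, tag_at + 3L))

    if (startsWith(rest, "<!--")) {
      close_at <- regexpr("-->", substr(source, tag_at + 4L, n), fixed = TRUE)
      end_at <- if (close_at == -1L) n else tag_at + 3L + as.integer(close_at) + 2L
      add_piece(tag_at, end_at, FALSE)
      i <- end_at + 1L
    } else if (grepl("^<[!?]", rest)) {
      end_at <- find_tag_end(tag_at)
      if (is.na(end_at)) end_at <- n
      add_piece(tag_at, end_at, FALSE)
      i <- end_at + 1L
    } else if (grepl("^</[A-Za-z]", rest)) {
      end_at <- find_tag_end(tag_at)
      if (is.na(end_at)) end_at <- n
      tag_name <- tolower(sub("^</([A-Za-z][A-Za-z0-9-]*).*$", "\\1",
                              substr(source, tag_at, end_at)))
      hit <- which(stack_names == tag_name)
      if (length(hit) > 0L) {           # pop to the matching open tag
        keep <- seq_len(max(hit) - 1L)
        stack_names <- stack_names[keep]
        stack_unsafe <- stack_unsafe[keep]
      }
      add_piece(tag_at, end_at, FALSE)
      i <- end_at + 1L
    } else if (grepl("^<[A-Za-z]", rest)) {
      end_at <- find_tag_end(tag_at)
      if (is.na(end_at)) end_at <- n
      tag_text <- substr(source, tag_at, end_at)
      tag_name <- tolower(sub("^<([A-Za-z][A-Za-z0-9-]*).*$", "\\1", tag_text))
      self_closing <- grepl("/>$", tag_text) || tag_name %in% void_tags
      add_piece(tag_at, end_at, FALSE)
      i <- end_at + 1L
      if (!self_closing && tag_name %in% raw_text_tags) {
        # raw-text content runs to the matching close tag, all unsafe
        close_pat <- paste0("(?i)</", tag_name, "\\s*>")
        m <- regexpr(close_pat, substr(source, i, n), perl = TRUE)
        if (m == -1L) {
          add_piece(i, n, FALSE)
          i <- n + 1L
        } else {
          close_end <- i + as.integer(m) - 1L + attr(m, "match.length") - 1L
          add_piece(i, close_end, FALSE)
          i <- close_end + 1L
        }
      } else if (!self_closing) {
        unsafe_here <- tag_name %in% unsafe_tags ||
          (tag_name == "span" && tag_is_hg_span(tag_text))
        stack_names <- c(stack_names, tag_name)
        stack_unsafe <- c(stack_unsafe, unsafe_here)
      }
    } else {
      # stray "<": forgiving parser treats it as ordinary text
      add_piece(tag_at, tag_at, unsafe_depth() == 0L)
      i <- tag_at + 1L
    }
  }

  tibble(
    text = substring(source, pieces_start, pieces_end),
    safety = ifelse(pieces_safe, "safe", "unsafe"),
    start = pieces_start - 1L,
    end = pieces_end
  )
}

#' Build a term matcher from a glossary
#'
#' Compiles the glossary's term keys into a single case-insensitive,
#' whole-word regular expression. Alternatives are ordered longest-first so
#' that, combined with a left-to-right scan, matching is leftmost-longest:
#' with both "ozone" and "ozone layer" in the glossary, "the ozone layer"
#' yields the single phrase match. Internal whitespace in multi-word terms
#' matches any whitespace run in the document.
#'
#' A word boundary is a transition between word characters and anything
#' else; by default letters, digits and the hyphen are word characters, so
#' "ozone-depleting" does not match "ozone" (set `hyphen_in_word = FALSE`
#' to change that).
#'
#' @param glossary An active, non-empty glossary.
#' @param hyphen_in_word Treat `-` as a word character (default `TRUE`).
#' @return A `term_matcher` object.
#' @export
build_matcher <- function(glossary, hyphen_in_word = TRUE) {
  stopifnot(inherits(glossary, "glossary"))
  if (!glossary$active) {
    hg_abort(paste0("glossary '", glossary$name, "' is inactive"),
             "hg_inactive_error")
  }
  if (length(glossary$terms) == 0L) {
    hg_abort(paste0("glossary '", glossary$name, "' has no terms"),
             "hg_empty_glossary_error")
  }
  keys <- map_chr(unname(glossary$terms), "key")
  keys <- keys[order(-nchar(keys), keys)]
  escaped <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keys)
  alts <- gsub("\\s+", "\\\\s+", escaped)
  wc <- if (hyphen_in_word) "[\\p{L}\\p{N}-]" else "[\\p{L}\\p{N}]"
  pattern <- paste0("(?i)(?<!", wc, ")(?:", paste(alts, collapse = "|"),
                    ")(?!", wc, ")")
  structure(
    list(pattern = pattern, keys = keys, glossary_name = glossary$name,
         hyphen_in_word = hyphen_in_word),
    class = "term_matcher"
  )
}

#' @export
print.term_matcher <- function(x, ...) {
  cat("<term_matcher> ", length(x$keys), " term(s) from '",
      x$glossary_name, "'\n", sep = "")
  invisible(x)
}

# matched document text -> canonical glossary key
match_to_key <- function(text) {
  stringr::str_replace_all(fold_key(text), "\\s+", " ")
}

#' Find glossary-term matches in a safe segment
#'
#' @param matcher A [build_matcher()] result.
#' @param segment A one-row segment tibble (from [segment_document()]) or a
#'   list with `text` and `safety`; must be safe.
#' @return Tibble of non-overlapping leftmost-longest spans, sorted:
#'   `start`, `end` (0-based half-open offsets into the segment text),
#'   `matched_text`, `wordterm` (canonical key), `glossary_name`.
#' @export
find_matches <- function(matcher, segment) {
  stopifnot(inherits(matcher, "term_matcher"))
  if (is.data.frame(segment)) {
    stopifnot(nrow(segment) == 1L)
    segment <- as.list(segment)
  }
  if (!identical(segment$safety, "safe")) {
    hg_abort("find_matches requires a safe segment", "hg_contract_error")
  }
  text <- segment$text
  m <- gregexpr(matcher$pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(), end = integer(),
                  matched_text = character(), wordterm = character(),
                  glossary_name = character()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  matched <- substring(text, starts, starts + lens - 1L)
  tibble(
    start = starts - 1L,
    end = starts - 1L + lens,
    matched_text = matched,
    wordterm = match_to_key(matched),
    glossary_name = matcher$glossary_name
  )
}

escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

hg_open_tag <- function(wordterm) {
  paste0('<span class="hg3" context="search" wordterm="',
         escape_attr(wordterm), '">')
}

# wrap spans of one safe segment's text; spans segment-relative, validated
render_segment <- function(text, spans) {
  if (nrow(spans) == 0L) return(text)
  spans <- dplyr::arrange(spans, .data$start)
  if (any(spans$start[-1] < spans$end[-nrow(spans)])) {
    hg_abort("overlapping spans", "hg_contract_error")
  }
  at_text <- substring(text, spans$start + 1L, spans$end)
  if (!identical(at_text, spans$matched_text)) {
    hg_abort("span text does not match segment substring", "hg_contract_error")
  }
  out <- character(0)
  cursor <- 0L
  for (r in seq_len(nrow(spans))) {
    out <- c(out,
             substring(text, cursor + 1L, spans$start[[r]]),
             hg_open_tag(spans$wordterm[[r]]),
             spans$matched_text[[r]],
             "</span>")
    cursor <- spans$end[[r]]
  }
  paste0(paste(out, collapse = ""), substring(text, cursor + 1L, nchar(text)))
}

#' Reassemble a document with HG span tags
#'
#' Unsafe segments are emitted verbatim; in safe segments each span becomes
#' `<span class="hg3" context="search" wordterm="KEY">MATCHED</span>`, with
#' the display text preserved and the wordterm attribute HTML-escaped.
#'
#' @param source Original document string.
#' @param segments Segment tibble from [segment_document()].
#' @param spans Span tibble with a `segment` column (row index into
#'   `segments`) plus the [find_matches()] columns.
#' @return The annotated HTML string.
#' @export
render_document <- function(source, segments, spans) {
  out <- character(nrow(segments))
  for (s in seq_len(nrow(segments))) {
    seg_spans <- spans[spans$segment == s, , drop = FALSE]
    if (segments$safety[[s]] == "unsafe") {
      if (nrow(seg_spans) > 0L) {
        hg_abort("spans may not target unsafe segments", "hg_contract_error")
      }
      out[[s]] <- segments$text[[s]]
    } else {
      out[[s]] <- render_segment(segments$text[[s]], seg_spans)
    }
  }
  paste(out, collapse = "")
}

#' Process a document against a glossary
#'
#' The full pipeline: segment the source, match terms in the safe segments,
#' and reassemble with HG span tags. Because HG spans are themselves unsafe
#' on re-entry, processing the output again with the same glossary adds no
#' new tags inside existing ones (idempotence).
#'
#' @param source HTML or plain-text string.
#' @param glossary An active glossary.
#' @inheritParams build_matcher
#' @inheritParams segment_document
#' @return A `processed_document`: list with `source`, `segments` (tibble),
#'   `spans` (tibble, with both segment-relative and document-level
#'   offsets), and `html_out`.
#' @export
#' @examples
#' g <- create_glossary("demo") |> add_term("ozone", definitions = "O3 gas")
#' process_document("ozone is a gas", g)$html_out
process_document <- function(source, glossary, hyphen_in_word = TRUE,
                             unsafe_tags = c("a", "script", "style", "head",
                                             "title", "textarea")) {
  matcher <- build_matcher(glossary, hyphen_in_word = hyphen_in_word)
  segments <- segment_document(source, unsafe_tags = unsafe_tags)
  span_list <- lapply(seq_len(nrow(segments)), function(s) {
    if (segments$safety[[s]] != "safe") return(NULL)
    sp <- find_matches(matcher, segments[s, ])
    if (nrow(sp) == 0L) return(NULL)
    sp$segment <- s
    sp$doc_start <- sp$start + segments$start[[s]]
    sp$doc_end <- sp$end + segments$start[[s]]
    sp
  })
  spans <- dplyr::bind_rows(span_list)
  if (nrow(spans) == 0L) {
    spans <- tibble(start = integer(), end = integer(),
                    matched_text = character(), wordterm = character(),
                    glossary_name = character(), segment = integer(),
                    doc_start = integer(), doc_end = integer())
  }
  structure(
    list(source = source, segments = segments, spans = spans,
         html_out = render_document(source, segments, spans)),
    class = "processed_document"
  )
}

#' Strip HG span tags, keeping the inner text
#'
#' Inverse of tagging for the visible text: removing every HG span tag pair
#' from processed output reproduces the source's visible text exactly.
#'
#' @param html An HTML string.
#' @return The string with all `span.hg3` tags removed.
#' @export
strip_hg_tags <- function(html) {
  gsub("(?s)<span\\s+class=\"hg3\"[^>]*>(.*?)</span>", "\\1", html,
       perl = TRUE)
}

#' @export
print.processed_document <- function(x, ...) {
  cat("<processed_document> ", nchar(x$source), " chars, ",
      sum(x$segments$safety == "safe"), " safe / ",
      sum(x$segments$safety == "unsafe"), " unsafe segment(s), ",
      nrow(x$spans), " tagged term(s)\n", sep = "")
  if (nrow(x$spans) > 0L) {
    tally <- sort(table(x$spans$wordterm), decreasing = TRUE)
    cat("  terms:", paste0(names(tally), " (", tally, ")", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @describeIn process_document tidy() method: the span tibble.
#' @param x,... For the tidy/glance methods.
#' @export
tidy.processed_document <- function(x, ...) x$spans

#' @describeIn process_document glance() method: one-row document summary.
#' @export
glance.processed_document <- function(x, ...) {
  tibble(
    n_chars = nchar(x$source),
    n_segments = nrow(x$segments),
    n_safe_segments = sum(x$segments$safety == "safe"),
    n_spans = nrow(x$spans),
    n_distinct_terms = dplyr::n_distinct(x$spans$wordterm)
  )
}

#' Span-position plot for a processed document
#'
#' @param object A `processed_document`.
#' @param ... Unused.
#' @return A ggplot showing where each tagged term sits in the document.
#' @export
autoplot.processed_document <- function(object, ...) {
  sp <- object$spans
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$doc_start,
                                   xend = .data$doc_end,
                                   y = .data$wordterm,
                                   yend = .data$wordterm)) +
    ggplot2::geom_segment(linewidth = 3, colour = "seagreen") +
    ggplot2::xlim(0, nchar(object$source)) +
    ggplot2::labs(x = "character offset", y = NULL,
                  title = "tagged term positions") +
    ggplot2::theme_minimal()
}
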