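---
title: "Typed-glossary document annotation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed-glossary document annotation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperglossary)
```

`hyperglossary` automates the markup of documents against typed glossaries
and assembles per-term content bundles driven by semantic identifiers. This
vignette is the package's account of how that is modelled, which choices
were genuinely open, and what the offline test fixtures do and do not show.

## The glossary model

A glossary fixes a definition-field layout shared by all its terms: between
1 and 5 fields, each locked (canonical) or unlocked (wiki). The canonical
import convention is a locked field 1 carrying content from an established
source, with a glossary-wide `source_citation`, plus up to four editable
wiki fields beside it. Edits to unlocked fields are append-only: each edit
becomes the current version and the previous content stays in the field's
history with a strictly increasing ordinal, so a definition's provenance is
always auditable. Locked fields reject edits outright; their content is
bit-identical before and after any attempt.

Terms are keyed by the case-folded form of their display name
(`stringr::str_to_lower`, Unicode-aware), unique per glossary. Uniqueness is
scoped to a single glossary: nothing prevents two glossaries from both
defining "ozone", but a document is processed against one glossary at a
time; multi-glossary processing is future work.

Three word types exist. `no_type` terms carry no identifier; `chemical`
terms must carry an InChI; `protein` terms must carry a 4-character PDB id.
The identifier is what makes a term machine-actionable — it keys curated 3D
lookups, the mol2 cache, structure searches and the 2D editor payload.
Identifier checks are syntactic (prefix `InChI=`, 4 alphanumerics); semantic
validity is the concern of the conversion layer, which rejects non-parsing
InChIs when they are actually used.

Authors are free-text strings and timestamps are recorded in UTC; there is
no authentication layer (access control is out of scope — locking is a
data-level property). Persistence is the XML interchange dialect below: one
diffable document per glossary, no database server.

## Safe/unsafe segmentation

Tagging must never disturb what a page already has. The processor therefore
splits the source into contiguous segments that concatenate exactly back to
the source string, each labelled *safe* or *unsafe*:

* unsafe: all tag markup and attributes, comments, doctypes/processing
  instructions, and the text content of `a`, `script`, `style`, `head`,
  `title`, `textarea` — and of any `span` whose class contains `hg3`
  (i.e. HG tags from a previous pass);
* safe: every other text node.

The unsafe tag set is configurable; the default generalises the intent of
preserving pre-existing links and scripts to the other elements where
tagging would corrupt the page. The scanner is hand-written rather than
delegated to an HTML library because the contract is positional: segments
carry 0-based half-open offsets into the *original* string and unsafe
regions are emitted verbatim, which a parse–serialise round trip through a
DOM library does not guarantee. It is forgiving in the HTML5 spirit: a
stray `<` is text, unclosed raw-text elements run to end of input, close
tags pop to the nearest matching open element.

Two consequences are worth stating. Character entities in safe text are not
decoded, so a term spelled with an entity (`&amp;` for `&`) will not match
its literal form. And because HG spans are unsafe on re-entry, processing is
idempotent: a second pass over processed output inserts zero new spans and
returns the identical document.

## Matching

The matcher compiles the glossary's keys into a single case-insensitive
regular expression with word-boundary lookarounds, alternatives ordered
longest-first. Combined with a left-to-right scan this yields greedy
leftmost-longest, non-overlapping matching, with no rescanning inside an
accepted span — with both "ozone" and "ozone layer" in the glossary, "the
ozone layer" produces the single phrase match.

Open choices, and how they were fixed:

* **Case.** Matching is case-insensitive; the display text is preserved in
  the output and the `wordterm` attribute carries the case-folded key.
* **Word characters.** Letters, digits and the hyphen. Hyphen-as-word-char
  means "ozone-depleting" does not match "ozone" — chemical nomenclature is
  hyphen-heavy and a hyphenated compound name is a different token. The
  policy is a one-flag option (`hyphen_in_word = FALSE`) for corpora where
  the opposite convention fits.
* **Whitespace in phrases.** Internal whitespace in a multi-word key
  matches any whitespace run in the document (equivalently: candidates are
  whitespace-normalised before lookup), and the matched display text is
  preserved as found.
* **Offsets.** 0-based, half-open, everywhere.
* **The HG tag.** Canonical output is
  `<span class="hg3" context="search" wordterm="KEY">TEXT</span>` with no
  padding inside attribute values; attribute values are HTML-escaped. The
  `3` in `hg3` is reproduced as the dialect's class name, not interpreted.

The test suite holds the matcher to an independent brute-force oracle that
enumerates every candidate `(start, end)` span, filters by boundaries and
dictionary membership, and greedily selects leftmost-longest spans — on
random documents up to 500 characters against glossaries of up to 20 terms,
plus text-conservation (stripping HG tags reproduces the source), anchor
preservation, and idempotence on the same corpus.

## Interchange formats

The XML dialect has root `glossary` (attributes `name`, `field_count`,
optional `source_citation`, `locked_mask`, `active`) containing `term`
elements (`name`, `word_type`, optional `identifier` with a `kind`
attribute, numbered `definition` elements with `index` and `locked`
attributes). Definitions travel as CDATA so embedded HTML — including
multimedia markup — survives untouched; documents are UTF-8 and validate
against the shipped XSD (`glossary_schema_path()`). A parse of a written
glossary is structurally identical to the original except that only current
field content is exported: version history is local state, not interchange.
Field 1 is locked on import whenever a source citation is present, matching
the canonical-plus-wiki convention.

CSV export is one row per term (name, type, identifier, current field
contents) with RFC 4180 quoting via `readr`. Ingestion starts at the
tabular stage — a two-column term/definition table in CSV or TSV — and
produces an untyped glossary; parsing source glossaries out of PDF or DOC
is out of scope, and the original workflow's macro spreadsheet step is
replaced by plain delimited text with the same information content.

## Chemical semantics

String conversions (SMILES ↔ InChI, InChI → InChIKey) delegate to OpenBabel
through `ChemmineOB`; the package does not reimplement InChI
canonicalisation, and tautomer/salt standardisation is out of scope. The
InChIKey is handled at its standard 27 characters (14–10–1, two hyphens).

Term typing uses dual-resolver agreement. A resolver is just a function
`name -> InChI or NA`; the shipped implementation is a local lookup table,
so the whole pipeline runs offline, and any failure is recorded as an empty
answer rather than raised. Agreement is exact string equality of trimmed
standard InChIs — no layer-dropping, on the view that a disagreement
between services is exactly the signal a curator should see. Statuses:
`agreed` (all resolvers answered identically), `disagreed` (two or more
distinct answers), `partial` (some but not all answered, identically),
`unresolved` (no answers). The tie-break when exactly one resolver answers
was left open by the source workflow; it is exposed as the `partial`
argument of `assign_word_types()` and defaults to the review list rather
than acceptance — automation should not type a term on one service's word
when the point of running two is corroboration. Typed terms are never
re-resolved or demoted.

3D structures: the curated store (keyed by InChIKey) always wins; on a miss
a single conformer is embedded by seeded distance geometry — RDKit's ETKDG,
invoked through the system Python, which honours an explicit random seed —
and converted to mol2 with the `obabel` tool, a pure format translation
that preserves the coordinates. Fixed seed therefore means byte-identical
files across runs. A conformer ensemble (the original pipeline used a
multi-objective conformer generator) is deliberately not attempted: the
contract is plausible display coordinates, cached once per InChIKey, never
regenerated. The cache counts generation events, which is how the
generate-once property is tested.

## Portlet assembly

Tab lists are a pure function of word type — `definition` only; then for
chemicals `structure_search`, `structure3d`, `structure2d`; for proteins
`structure3d` — with fixed titles ("Definition", "Search", "3D Structure",
"2D Structure", "Search: <smiles>"). The protein portlet has the
documented two-tab form; whether the original standalone system also gave
proteins a search tab is not documented, so it is not guessed. The package
emits payloads a client viewer would consume (file references plus a
`viewer_hint` naming the viewer class, SMILES+InChI for the editor); it
bundles no viewer or editor and renders no molecule images.

Editor-driven search tabs model the discovery loop: each searched SMILES is
converted to an InChIKey, looked up in the injected search backend, and
appended as a new tab — tabs accumulate and prior tabs are never mutated,
so successively chlorinating methane (CH~4~ → CH~3~Cl → CH~2~Cl~2~ →
CHCl~3~ → CCl~4~) leaves five search tabs side by side. An empty lookup is
a tab with a no-results marker, not an error. Thumbnails arrive as base64,
are validated against the PNG signature and stored once under a
content-hash key. Bundles serialise to JSON sidecars and round-trip
losslessly.

## The synthetic fixture generator

`fixture_spec()` fixes the study conditions: 10 terms per demo glossary
with 30 % chemical and 10 % protein composition (counts by
`floor(fraction × n)`), 5 planted mentions per document, and a seed that
determines every byte of output. Chemical fixture terms draw from a
packaged list of 64 small molecules (name + SMILES, identifiers computed at
generation time); protein fixtures use synthetic 4-character PDB-style ids,
documented as such; filler words are disjoint from the vocabulary by
construction, so a planted mention yields exactly one span and the manifest
is an exact oracle. Negative controls (`with_links = TRUE`) plant the same
terms inside an anchor and a script block, which must contribute zero
spans.

What the fixtures do *not* emulate: entity-encoded text, deeply broken
markup beyond the forgiving-parser cases exercised in tests, very large
pages, non-Latin scripts, and chemical names whose tokenisation is itself
contested (e.g. names split across line breaks). Passing tests show the
segmentation/matching contracts hold, not that recall on arbitrary web
pages matches a curated corpus.

## Problem sizes and numerical choices

The property suites run 200 random matcher instances (documents ≤ 500
characters, glossaries ≤ 20 terms), 50 random XML round trips, and the
InChIKey format invariant over 50 packaged molecules — sizes at which the
brute-force oracle is exact and the whole suite stays well under a minute
of matcher time on one CPU. All randomised tests fix their seeds. There are
no floating-point tolerances anywhere: every comparison in the package and
its tests is exact (strings, integers, bytes), which is a deliberate
property of the domain — offsets, keys and serialised artifacts either
match or are wrong.

## Known limitations

* One glossary per processing pass; no cross-glossary collision policy.
* Entities in safe text are matched literally, not decoded.
* Live resolvers, structure searches and PDB retrieval are interface points
  only; the package ships no network client, and the offline stores are the
  supported path.
* The wiki editing surface (WYSIWYG, roles, login) is out of scope; the
  model stops at lock flags, authorship strings and version history.
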