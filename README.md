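# hyperglossary

Automated hyperlinking of domain terms in documents against **typed
glossaries**, for the chemical-education / cheminformatics setting where the
vocabulary of a discipline is the index into its data.

Reading an expert-level document, a novice constantly hits terms whose
meaning — and whose associated data — live elsewhere. `hyperglossary`
processes an HTML page or plain text against a chosen glossary and returns
the document with every glossary term wrapped in an *HG tag*:

```html
<span class="hg3" context="search" wordterm="ozone">ozone</span>
```

A client overlay (a "portlet") can then pull, per tagged term, a content
bundle whose tabs depend on the term's semantic type: a plain term carries a
definition only; a *chemical* term (identified by its IUPAC InChI) adds a
structure search, a 3D structure and an editable 2D structure; a *protein*
term (identified by a PDB id) adds a 3D structure. Everything runs offline:
structure searches, curated-structure lookups and PDB files come from
injected local stores.

## What the package does

* **Glossary model** — terms keyed by case-folded name, up to 5 definition
  fields each, with per-field locking (canonical vs wiki fields), append-only
  version history, a glossary-wide source citation, and activation state.
* **Document processor** — segments a document into *safe* text and *unsafe*
  regions (pre-existing anchors, scripts, styles, head, comments, markup),
  matches glossary terms case-insensitively, whole-word, leftmost-longest in
  the safe text only, and reassembles the page with unsafe regions preserved
  byte-for-byte. Processing is idempotent: HG spans are unsafe on re-entry.
* **Glossary interchange** — an XML dialect with a shipped XSD for bulk
  upload/download, CSV export (RFC 4180), and ingestion of two-column
  term/definition tables.
* **Chemical semantics** — SMILES/InChI/InChIKey conversions (OpenBabel),
  dual-resolver name-to-InChI agreement for typing terms as chemicals, and
  seeded, deterministic 3D structure generation into an InChIKey-keyed mol2
  cache.
* **Portlet assembly** — per-term tab bundles, accumulating editor-driven
  structure-search tabs, base64 thumbnail decoding, JSON sidecars.
* **Fixtures & CLI** — a seeded synthetic fixture generator (demo glossaries
  and documents with planted mentions and negative controls) and a `whg`
  command-line tool covering processing, glossary management, the
  glossary-preparation pipeline, portlets and fixtures.

## Matching model

A glossary defines a set of keys \(K\) (case-folded term names). A word
boundary is a transition between word characters (letters, digits, and by
default the hyphen) and anything else. Matching selects, scanning left to
right over each safe segment, the longest whole-word substring at each
position whose whitespace-normalised case-folding is in \(K\), never
overlapping an accepted span (leftmost-longest greedy). Multi-word terms
match across internal whitespace runs. The matcher is verified against a
brute-force oracle that enumerates every candidate span.

A term is typed *chemical* only on **dual-resolver agreement**: independent
name-to-structure resolvers must return the same standard InChI; partial or
conflicting answers go to a review list.

## Worked example

```r
library(hyperglossary)

g <- create_glossary("IUPAC demo", 2, c(TRUE, FALSE), "Demo source citation") |>
  add_term("ozone", "chemical",
           semantic_identifier("inchi", "InChI=1S/O3/c1-3-2"),
           c("<p>Triatomic oxygen, O3.</p>", "<p>Wiki notes.</p>")) |>
  add_term("entropy", definitions = "<p>A state function.</p>")

doc <- process_document(
  'Ozone levels and entropy were discussed. See <a href="https://epa.gov">ozone</a>.',
  g)
doc
#> <processed_document> 81 chars, 2 safe / 1 unsafe segment(s), 2 tagged term(s)
#>   terms: entropy (1), ozone (1)
cat(doc$html_out)
#> <span class="hg3" context="search" wordterm="ozone">Ozone</span> levels and
#> <span class="hg3" context="search" wordterm="entropy">entropy</span> were
#> discussed. See <a href="https://epa.gov">ozone</a>.
```

Two mentions were tagged — display case preserved, `wordterm` case-folded —
while the mention inside the pre-existing anchor was left untouched.
`tidy(doc)` returns the span table (0-based half-open offsets):

```r
tidy(doc)
#> # A tibble: 2 × 8
#>   start   end matched_text wordterm glossary_name segment doc_start doc_end
#> 1     0     5 Ozone        ozone    IUPAC demo          1         0       5
#> 2    17    24 entropy      entropy  IUPAC demo          1        17      24
```

The chemical term's portlet carries the four type-determined tabs:

```r
build_portlet(g, "ozone", cache = structure_cache())
#> <portlet> 'ozone' (chemical), 4 tab(s):
#>   - [definition] Definition
#>   - [structure_search] Search
#>   - [structure3d] 3D Structure
#>   - [structure2d] 2D Structure
```

The same operations are available from the shell via the installed
`exec/whg` script, e.g.

```sh
whg fixtures --out-dir fx --terms 10 --seed 1
whg process --glossary fx/glossary.xml --file fx/document.html --out tagged.html --spans spans.json
whg prep --resolvers local:service_a.csv,local:service_b.csv raw.tsv prepared.xml
```

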