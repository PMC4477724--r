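Package: hyperglossary
Title: Typed-Glossary Hyperlinking of Chemistry Documents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the hyperlinking of domain terms in HTML or plain-text
    documents against typed glossaries, in the hyperglossary tradition of
    chemical-education tooling. Documents are segmented into safe and unsafe
    regions so pre-existing links and scripts are preserved byte-for-byte,
    glossary terms are matched leftmost-longest in safe text and wrapped in
    HG span tags. Glossaries carry up to five definition fields per term with
    locking and per-field version history, round-trip through an XML
    interchange dialect with a shipped schema, and export to CSV. Chemical
    terms are typed by dual-resolver name-to-InChI agreement; InChI, InChIKey
    and SMILES conversions and deterministic 3D structure generation (mol2,
    cached by InChIKey) are backed by OpenBabel. Per-term portlet content
    bundles (definition, structure search, 3D and 2D structure tabs, and
    accumulating editor-driven search tabs) are assembled per word type and
    serialized as JSON sidecars. Includes a seeded synthetic fixture
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    rlang,
    readr,
    xml2,
    jsonlite,
    generics,
    ggplot2,
    ChemmineOB,
    tools,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
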