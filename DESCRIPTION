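Package: ontoverb
Title: Verbalise OWL Ontologies into English Glossary Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates English text definitions from the logical axioms of an
    OWL ontology. Parses OWL Functional Syntax into a term model, derives a
    lexicon (part of speech, singular and plural forms) for every atomic
    entity from its label or identifier, selects the axioms describing each
    entity, aggregates axioms that share a common pattern into list-valued
    sentences, and realises each group as an English sentence, assembling the
    results into an alphabetical glossary. Axioms outside the supported
    fragment are emitted verbatim in functional syntax. Includes a seeded
    synthetic-ontology generator for property-based testing and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
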