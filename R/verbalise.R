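# End-to-end pipeline: ontology in, glossary out.

#' Verbalise an ontology
#'
#' Runs the whole pipeline: parse (unless given a parsed document), build
#' the lexicon (label segmentation follows the style profile), plan the
#' document, and realise the alphabetical glossary.
#'
#' @param input Path to an OWL Functional Syntax file, document text, or an
#'   `owl_document`.
#' @param style A `style_profile` or name (`"survey2"`, `"survey1-legacy"`,
#'   `"vp-first"`).
#' @param mode `"grouped"` (aggregation on) or `"flat"` (one sentence per
#'   axiom).
#' @param overrides Optional lexicon overrides (named list from
#'   [read_lexicon()]).
#' @return An `owl_glossary`: list with `text` (the glossary document),
#'   `plan`, `lexicon`, `doc`, `sentences` (per-unit `owl_sentence`s, in
#'   entry order), `n_fallback`, and `style`.
#' @examples
#' g <- verbalise(c(
#'   "Prefix(:=<http://example.org/x#>)",
#'   "SubClassOf(:genetic_disorder :disease)"
#' ))
#' cat(g$text)
#' @export
verbalise <- function(input, style = "survey2",
                      mode = c("grouped", "flat"), overrides = NULL) {
  mode <- match.arg(mode)
  style <- .as_style(style)
  doc <- if (inherits(input, "owl_document")) input else parse_ontology(input)
  lexicon <- build_lexicon(
    doc, overrides = overrides,
    label_mode = if (style$label_segmentation == "capital-splitting")
      "split" else "preserve")
  plan <- plan_document(doc, lexicon, mode = mode)
  sentences <- list()
  for (e in plan$entries) {
    for (u in e$units) {
      sentences[[length(sentences) + 1L]] <- realise_unit(u, lexicon, style)
    }
  }
  n_fallback <- sum(vapply(sentences, function(s) s$kind == "fallback", TRUE))
  structure(list(
    text = generate_glossary(plan, lexicon, style),
    plan = plan,
    lexicon = lexicon,
    doc = doc,
    sentences = sentences,
    n_fallback = n_fallback,
    style = style
  ), class = "owl_glossary")
}

#' Extract one entity's paragraph from a glossary
#'
#' @param glossary An `owl_glossary` from [verbalise()].
#' @param entity An IRI, an identifier local name, or an English name as it
#'   appears in the glossary.
#' @return The paragraph text, or `NULL` when the entity has no entry.
#' @export
entity_paragraph <- function(glossary, entity) {
  for (e in glossary$plan$entries) {
    if (identical(e$entity$iri, entity) ||
        identical(e$entity$local_name, entity) ||
        identical(e$name, entity)) {
      return(realise_entry(e$entity, e$units, glossary$lexicon,
                           glossary$style))
    }
  }
  NULL
}

#' @export
print.owl_glossary <- function(x, ...) {
  cat(x$text)
  invisible(x)
}
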