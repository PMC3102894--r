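# Sentence realisation: pattern-indexed grammar rules that turn
# (possibly aggregated) axioms into English sentences, with a
# functional-syntax fallback for anything the grammar does not cover.

#' Style profiles
#'
#' A named bundle of rendering choices. `"survey2"` (the default) preserves
#' label-internal case and lists subclasses as plural subjects
#' ("B117Hs, and B140Hs are ..."). `"survey1-legacy"` applies
#' capital-splitting segmentation to labels as well as identifiers and uses
#' the "kinds of" subclass template ("A b117h, and a b140h are kinds of
#' ..."). `"vp-first"` is survey2 plus a rule that realises an aggregated
#' run of restrictions with verb phrases ("A HeLa derives from a cervix,
#' and derives from an epithelial cell.") instead of "something that" noun
#' phrases.
#'
#' @param name One of `"survey2"`, `"survey1-legacy"`, `"vp-first"`.
#' @return A `style_profile` with fields `name`, `label_segmentation`
#'   (`"label-preserving"` or `"capital-splitting"`),
#'   `subclass_listing` (`"plural-subjects"` or `"kinds-of"`), `vp_first`.
#' @export
style_profile <- function(name = c("survey2", "survey1-legacy", "vp-first")) {
  name <- match.arg(name)
  switch(name,
    "survey2" = structure(list(name = name,
      label_segmentation = "label-preserving",
      subclass_listing = "plural-subjects", vp_first = FALSE),
      class = "style_profile"),
    "survey1-legacy" = structure(list(name = name,
      label_segmentation = "capital-splitting",
      subclass_listing = "kinds-of", vp_first = FALSE),
      class = "style_profile"),
    "vp-first" = structure(list(name = name,
      label_segmentation = "label-preserving",
      subclass_listing = "plural-subjects", vp_first = TRUE),
      class = "style_profile"))
}

.as_style <- function(style) {
  if (inherits(style, "style_profile")) style else style_profile(style)
}

#' Choose the indefinite article
#'
#' `"an"` iff the first character of the phrase, case-folded, is one of
#' a, e, i, o, u; otherwise (consonants, digits, symbols) `"a"`.
#'
#' @param phrase A character string or word vector.
#' @return `"a"` or `"an"`.
#' @export
indefinite_article <- function(phrase) {
  first <- tolower(substring(paste(phrase, collapse = " "), 1L, 1L))
  if (first %in% c("a", "e", "i", "o", "u")) "an" else "a"
}

# condition signalled when a construct has no grammar rule
.fallback_required <- function(what) {
  cond <- structure(
    class = c("ontoverb_fallback", "error", "condition"),
    list(message = paste0("no grammar rule for ", what), call = NULL))
  stop(cond)
}

.with_article <- function(np) paste(indefinite_article(np), np)

# comma list with ", and " before the last item (also for two items)
.and_list <- function(items) {
  n <- length(items)
  if (n == 1L) return(items)
  paste0(paste(items[-n], collapse = ", "), ", and ", items[n])
}

#' Realise a class expression as a noun phrase
#'
#' Atomic classes become their (singular or plural) noun, optionally with
#' the indefinite article; restrictions become "something that" plus a verb
#' phrase; unions join members with " or "; intersections use "both X, and
#' Y" for two members and "all of the following: ..." for three or more.
#' Complements, enumerations and unsupported nodes have no grammar rule and
#' signal fallback for the whole sentence.
#'
#' @param expr An `owl_expr` (or `owl_entity`).
#' @param lexicon An `owl_lexicon` covering the entities in `expr`.
#' @param number `"singular"` or `"plural"`.
#' @param article Prepend the indefinite article (singular common nouns
#'   only)?
#' @return A character string.
#' @export
noun_phrase <- function(expr, lexicon, number = "singular", article = TRUE) {
  if (inherits(expr, "owl_entity")) {
    return(.entity_np(expr$iri, lexicon, number, article))
  }
  switch(expr$type,
    atomic = .entity_np(expr$entity$iri, lexicon, number, article),
    some_values = paste("something that",
                        verb_phrase(expr, lexicon, "singular")),
    has_value = paste("something that",
                      verb_phrase(expr, lexicon, "singular")),
    union = paste(vapply(expr$members, noun_phrase, "", lexicon = lexicon,
                         number = number, article = article),
                  collapse = " or "),
    intersection = {
      nps <- vapply(expr$members, noun_phrase, "", lexicon = lexicon,
                    number = number, article = article)
      if (length(nps) == 2L) paste0("both ", nps[1], ", and ", nps[2])
      else paste0("all of the following: ", .and_list(nps))
    },
    .fallback_required(paste0("class expression '", expr$type, "'"))
  )
}

.entity_np <- function(iri, lexicon, number, article) {
  e <- .lex_entry(lexicon, iri)
  if (e$pos == "proper-name") {
    return(paste(e$singular, collapse = " "))
  }
  if (e$pos == "transitive-verb") {
    .fallback_required("a property used as a noun")
  }
  if (number == "plural") {
    paste(e$plural, collapse = " ")
  } else {
    np <- paste(e$singular, collapse = " ")
    if (article) .with_article(np) else np
  }
}

#' Realise a restriction as a verb phrase
#'
#' The property's verb form for the requested number, followed by a noun
#' phrase for the filler (existential restriction) or the proper name of
#' the individual (has-value restriction).
#'
#' @param restriction An `owl_expr` of type `some_values` or `has_value`.
#' @param lexicon An `owl_lexicon`.
#' @param number `"singular"` or `"plural"`.
#' @return A character string.
#' @export
verb_phrase <- function(restriction, lexicon, number = "singular") {
  stopifnot(restriction$type %in% c("some_values", "has_value"))
  e <- .lex_entry(lexicon, restriction$property$iri)
  if (e$pos != "transitive-verb") {
    stop("property <", restriction$property$iri,
         "> is not lexicalised as a transitive verb", call. = FALSE)
  }
  verb <- paste(if (number == "plural") e$plural else e$singular,
                collapse = " ")
  obj <- if (restriction$type == "some_values") {
    noun_phrase(restriction$filler, lexicon, "singular", article = TRUE)
  } else {
    paste(.lex_entry(lexicon, restriction$individual$iri)$singular,
          collapse = " ")
  }
  paste(verb, obj)
}

.cap_first <- function(text) {
  paste0(toupper(substring(text, 1L, 1L)), substring(text, 2L))
}

.sentence <- function(text, kind = "english") {
  structure(list(text = text, kind = kind), class = "owl_sentence")
}

.english <- function(text) .sentence(paste0(.cap_first(text), "."), "english")

.is_restriction <- function(x) {
  inherits(x, "owl_expr") && x$type %in% c("some_values", "has_value")
}
.is_atomic_expr <- function(x) {
  inherits(x, "owl_expr") && identical(x$type, "atomic")
}
.expr_iri <- function(x) {
  if (inherits(x, "owl_entity")) x$iri
  else if (.is_atomic_expr(x)) x$entity$iri
  else NA_character_
}

#' Realise one unit as a sentence
#'
#' Dispatches on the axiom pattern and the subject's position. Covered
#' patterns: subclass axioms (atomic superclass, restriction superclass
#' realised as a direct verb phrase, aggregated restriction lists,
#' subclass listings from the superclass position), equivalences
#' ("is defined as"), disjointness ("No S is ..."), and class assertions.
#' Any uncovered pattern — including individual-level property assertions
#' and property hierarchy axioms, for which no grammar rule exists — is
#' emitted verbatim in OWL Functional Syntax as a fallback sentence.
#'
#' @param unit A `realisation_unit`.
#' @param lexicon An `owl_lexicon`.
#' @param style A `style_profile` or profile name.
#' @return An `owl_sentence` with fields `text` and `kind` (`"english"` or
#'   `"fallback"`).
#' @export
realise_unit <- function(unit, lexicon, style = style_profile()) {
  style <- .as_style(style)
  tryCatch(
    .realise_unit_impl(unit, lexicon, style),
    ontoverb_fallback = function(cond) {
      texts <- vapply(.unit_axioms(unit), render_functional, "")
      .sentence(paste(texts, collapse = " "), "fallback")
    })
}

.realise_unit_impl <- function(unit, lexicon, style) {
  if (unit$kind == "single") {
    .realise_single(unit$axiom, unit$subject_iri, lexicon, style)
  } else {
    .realise_aggregated(unit, lexicon, style)
  }
}

.subject_np <- function(iri, lexicon) {
  .with_article(.lex_singular(lexicon, iri))
}

.realise_single <- function(ax, subject, lexicon, style) {
  switch(ax$functor,
    sub_class_of = {
      a <- ax$args[[1]]; b <- ax$args[[2]]
      if (identical(.expr_iri(a), subject)) {
        if (.is_restriction(b)) {
          # lone restriction: direct verb phrase ("A 22rv1 derives from a
          # Homo sapiens.")
          .english(paste(.subject_np(subject, lexicon),
                         verb_phrase(b, lexicon, "singular")))
        } else {
          .english(paste(.subject_np(subject, lexicon), "is",
                         noun_phrase(b, lexicon, "singular", article = TRUE)))
        }
      } else if (identical(.expr_iri(b), subject)) {
        .subclass_listing(list(a), subject, lexicon, style)
      } else .fallback_required("a subclass axiom without the subject")
    },
    equivalent_classes = {
      others <- Filter(function(x) !identical(.expr_iri(x), subject), ax$args)
      if (length(others) == length(ax$args)) {
        .fallback_required("an equivalence without the subject")
      }
      defs <- vapply(others, function(d) paste0(
        .cap_first(paste(.subject_np(subject, lexicon), "is defined as",
                         noun_phrase(d, lexicon, "singular", article = TRUE))),
        "."), "")
      .sentence(paste(defs, collapse = " "), "english")
    },
    disjoint_classes = .disjointness(
      Filter(function(x) !identical(.expr_iri(x), subject), ax$args),
      subject, lexicon),
    class_assertion = {
      cls <- ax$args[[1]]; ind <- ax$args[[2]]
      .english(paste(paste(.lex_entry(lexicon, ind$iri)$singular,
                           collapse = " "), "is",
                     noun_phrase(cls, lexicon, "singular", article = TRUE)))
    },
    .fallback_required(paste0("functor '", ax$fs_name, "'"))
  )
}

.subclass_listing <- function(sub_exprs, subject, lexicon, style) {
  iris <- vapply(sub_exprs, .expr_iri, "")
  if (anyNA(iris)) .fallback_required("a complex subclass listing")
  if (style$subclass_listing == "kinds-of") {
    items <- vapply(iris, function(i)
      .with_article(.lex_singular(lexicon, i)), "")
    verb <- if (length(items) == 1L) "is a kind of" else "are kinds of"
    .english(paste(.and_list(items), verb, .lex_plural(lexicon, subject)))
  } else {
    items <- vapply(iris, function(i) .lex_plural(lexicon, i), "")
    .english(paste(.and_list(items), "are", .lex_plural(lexicon, subject)))
  }
}

.disjointness <- function(others, subject, lexicon) {
  nps <- vapply(others, noun_phrase, "", lexicon = lexicon,
                number = "singular", article = TRUE)
  s <- .lex_singular(lexicon, subject)
  if (length(nps) == 1L) {
    .english(paste("no", s, "is", nps))
  } else {
    .english(paste0("no ", s, " is any of the following: ",
                    paste(nps, collapse = " or ")))
  }
}

.realise_aggregated <- function(unit, lexicon, style) {
  subject <- unit$subject_iri
  fillers <- unit$fillers
  switch(unit$functor,
    sub_class_of = {
      if (unit$hole == 2L && identical(.expr_iri(unit$args[[1]]), subject)) {
        if (style$vp_first && all(vapply(fillers, .is_restriction, TRUE))) {
          vps <- vapply(fillers, verb_phrase, "", lexicon = lexicon,
                        number = "singular")
          .english(paste(.subject_np(subject, lexicon), .and_list(vps)))
        } else {
          nps <- vapply(fillers, noun_phrase, "", lexicon = lexicon,
                        number = "singular", article = TRUE)
          head <- .subject_np(subject, lexicon)
          if (length(nps) == 2L) {
            .english(paste0(head, " is both ", nps[1], ", and ", nps[2]))
          } else {
            .english(paste0(head, " is all of the following: ",
                            .and_list(nps)))
          }
        }
      } else if (unit$hole == 1L &&
                 identical(.expr_iri(unit$args[[2]]), subject)) {
        .subclass_listing(fillers, subject, lexicon, style)
      } else .fallback_required("an aggregated subclass pattern")
    },
    equivalent_classes = {
      fixed <- Filter(function(x) !identical(.expr_iri(x), subject),
                      unit$args[-unit$hole])
      nps <- vapply(c(fillers, fixed), noun_phrase, "", lexicon = lexicon,
                    number = "singular", article = TRUE)
      body <- if (length(nps) == 1L) nps
      else if (length(nps) == 2L) paste0("both ", nps[1], ", and ", nps[2])
      else paste0("all of the following: ", .and_list(nps))
      .english(paste(.subject_np(subject, lexicon), "is defined as", body))
    },
    disjoint_classes = .disjointness(
      c(fillers, Filter(function(x) !identical(.expr_iri(x), subject),
                        unit$args[-unit$hole])),
      subject, lexicon),
    class_assertion = {
      if (unit$hole == 2L) {
        # several individuals asserted to the subject class
        names_ <- vapply(fillers, function(f)
          paste(.lex_entry(lexicon, .expr_iri(f))$singular, collapse = " "),
          "")
        verb <- if (length(names_) == 1L) "is" else "are"
        .english(paste(.and_list(names_), verb,
                       if (length(names_) == 1L)
                         .with_article(.lex_singular(lexicon, subject))
                       else .lex_plural(lexicon, subject)))
      } else {
        nps <- vapply(fillers, noun_phrase, "", lexicon = lexicon,
                      number = "singular", article = TRUE)
        ind <- paste(.lex_entry(lexicon, subject)$singular, collapse = " ")
        body <- if (length(nps) == 2L) {
          paste0("both ", nps[1], ", and ", nps[2])
        } else paste0("all of the following: ", .and_list(nps))
        .english(paste(ind, "is", body))
      }
    },
    .fallback_required(paste0("aggregated functor '", unit$functor, "'"))
  )
}

#' Realise an entity's paragraph
#'
#' Realises each unit in order and joins the sentences with single spaces.
#'
#' @param entity An `owl_entity` or IRI (recorded subject of the units).
#' @param units Ordered list of `realisation_unit`.
#' @param lexicon An `owl_lexicon`.
#' @param style A `style_profile` or profile name.
#' @return A single character string (the paragraph).
#' @export
realise_entry <- function(entity, units, lexicon, style = style_profile()) {
  style <- .as_style(style)
  texts <- vapply(units, function(u) realise_unit(u, lexicon, style)$text, "")
  paste(texts, collapse = " ")
}

#' Generate the glossary document
#'
#' One entry per planned entity: a header line with the entity's singular
#' English name (disambiguated with the identifier local name in
#' parentheses when two entities share a name), followed by its paragraph,
#' with a blank line between entries.
#'
#' @param plan An `owl_plan` from [plan_document()].
#' @param lexicon An `owl_lexicon`.
#' @param style A `style_profile` or profile name.
#' @return The glossary as a single character string.
#' @export
generate_glossary <- function(plan, lexicon, style = style_profile()) {
  style <- .as_style(style)
  if (!length(plan$entries)) return("")
  nms <- vapply(plan$entries, function(e) e$name, "")
  dup <- nms %in% nms[duplicated(nms)]
  blocks <- vapply(seq_along(plan$entries), function(i) {
    e <- plan$entries[[i]]
    header <- if (dup[i]) {
      paste0(e$name, " (", e$entity$local_name, ")")
    } else e$name
    paste0(header, "\n",
           realise_entry(e$entity, e$units, lexicon, style))
  }, "")
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' @export
print.owl_sentence <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$kind, x$text))
  invisible(x)
}
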