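lex_from <- function(...) {
  doc <- parse_ontology(ofn_doc(...))
  list(doc = doc, lex = build_lexicon(doc))
}

test_that("the indefinite article follows the vowel-letter rule", {
  expect_equal(indefinite_article("Ara-C-resistant murine leukemia"), "an")
  expect_equal(indefinite_article("uninfected"), "an")
  expect_equal(indefinite_article("4470"), "a")
  expect_equal(indefinite_article("HeLa"), "a")
  expect_equal(indefinite_article("epithelial cell"), "an")
})

test_that("noun phrases cover atomic classes, restrictions and lists", {
  f <- lex_from(
    "AnnotationAssertion(rdfs:label :cervix \"cervix\")",
    "AnnotationAssertion(rdfs:label :cc \"cervical carcinoma\")",
    "AnnotationAssertion(rdfs:label :B117H \"B117H\")",
    "SubClassOf(:x ObjectSomeValuesFrom(:bearer_of :cc))",
    "SubClassOf(:x ObjectUnionOf(:cervix :B117H))",
    "SubClassOf(:x ObjectIntersectionOf(:cervix :cc :B117H))",
    "SubClassOf(:y ObjectIntersectionOf(:cervix :cc))"
  )
  doc <- f$doc; lex <- f$lex
  cervix <- doc$axioms[[2]]$args[[2]]$members[[1]]
  expect_equal(noun_phrase(cervix, lex), "a cervix")
  expect_equal(noun_phrase(cervix, lex, number = "plural", article = FALSE),
               "cervixes")
  restr <- doc$axioms[[1]]$args[[2]]
  expect_equal(noun_phrase(restr, lex),
               "something that is bearer of a cervical carcinoma")
  b117h <- doc$axioms[[2]]$args[[2]]$members[[2]]
  expect_equal(noun_phrase(b117h, lex, number = "plural"), "B117Hs")
  expect_equal(noun_phrase(doc$axioms[[2]]$args[[2]], lex),
               "a cervix or a B117H")
  expect_equal(noun_phrase(doc$axioms[[3]]$args[[2]], lex),
               "all of the following: a cervix, a cervical carcinoma, and a B117H")
  expect_equal(noun_phrase(doc$axioms[[4]]$args[[2]], lex),
               "both a cervix, and a cervical carcinoma")
})

test_that("verb phrases agree in number and embed the filler", {
  f <- lex_from(
    "AnnotationAssertion(rdfs:label :male \"male\")",
    "AnnotationAssertion(rdfs:label :mm \"Mus musculus\")",
    "SubClassOf(:x ObjectSomeValuesFrom(:has_quality :male))",
    "SubClassOf(:x ObjectSomeValuesFrom(:derives_from :mm))"
  )
  expect_equal(verb_phrase(f$doc$axioms[[1]]$args[[2]], f$lex),
               "has as quality a male")
  expect_equal(verb_phrase(f$doc$axioms[[2]]$args[[2]], f$lex),
               "derives from a Mus musculus")
  expect_equal(verb_phrase(f$doc$axioms[[2]]$args[[2]], f$lex,
                           number = "plural"),
               "derive from a Mus musculus")
})

test_that("sentence templates match the worked patterns", {
  f <- lex_from(
    "AnnotationAssertion(rdfs:label :gd \"genetic disorder\")",
    "SubClassOf(:gd :disease)",
    "EquivalentClasses(:gd :illness)",
    "ClassAssertion(:disease :Patient1)",
    "DisjointClasses(:gd :normal)",
    "InverseObjectProperties(:p :q)"
  )
  doc <- f$doc; lex <- f$lex
  unit <- function(i, subj) structure(
    list(kind = "single", axiom = doc$axioms[[i]],
         subject_iri = paste0(EX, subj), source_index = i),
    class = "realisation_unit")

  s <- realise_unit(unit(1, "gd"), lex)
  expect_equal(s$text, "A genetic disorder is a disease.")
  expect_equal(s$kind, "english")

  expect_equal(realise_unit(unit(2, "gd"), lex)$text,
               "A genetic disorder is defined as an illness.")
  expect_equal(realise_unit(unit(3, "disease"), lex)$text,
               "Patient1 is a disease.")
  expect_equal(realise_unit(unit(4, "gd"), lex)$text,
               "No genetic disorder is a normal.")

  # uncovered functor: verbatim functional-syntax fallback
  fb <- realise_unit(unit(5, "p"), lex)
  expect_equal(fb$kind, "fallback")
  expect_equal(fb$text, render_functional(doc$axioms[[5]]))
})

test_that("subclass listings follow the style profile", {
  f <- lex_from(
    "AnnotationAssertion(rdfs:label :araC \"Ara-C-resistant murine leukemia\")",
    "AnnotationAssertion(rdfs:label :b117h \"B117H\")",
    "AnnotationAssertion(rdfs:label :b140h \"B140H\")",
    "SubClassOf(:b117h :araC)",
    "SubClassOf(:b140h :araC)"
  )
  subject <- paste0(EX, "araC")
  units <- aggregate_axioms(select_axioms(f$doc, subject), subject)
  expect_length(units, 1)
  expect_equal(realise_unit(units[[1]], f$lex)$text,
               "B117Hs, and B140Hs are Ara-C-resistant murine leukemias.")

  legacy_doc <- parse_ontology(ofn_doc(
    "AnnotationAssertion(rdfs:label :araC \"ara c resistant murine leukemia\")",
    "AnnotationAssertion(rdfs:label :b117h \"b117h\")",
    "AnnotationAssertion(rdfs:label :b140h \"b140h\")",
    "SubClassOf(:b117h :araC)",
    "SubClassOf(:b140h :araC)"
  ))
  legacy_lex <- build_lexicon(legacy_doc, label_mode = "split")
  units <- aggregate_axioms(select_axioms(legacy_doc, subject), subject)
  expect_equal(realise_unit(units[[1]], legacy_lex, "survey1-legacy")$text,
               "A b117h, and a b140h are kinds of ara c resistant murine leukemias.")
})

test_that("vp-first realises aggregated restrictions with verb phrases", {
  doc <- parse_ontology(fixture_22rv1())
  lex <- build_lexicon(doc)
  subject <- paste0(EX, "22rv1")
  units <- aggregate_axioms(select_axioms(doc, subject), subject)
  expect_equal(realise_unit(units[[2]], lex, "vp-first")$text,
               paste0("A 22rv1 is bearer of a prostate carcinoma, ",
                      "derives from a homo sapiens, and derives from a prostate."))
  # default keeps the noun-phrase list
  expect_match(realise_unit(units[[2]], lex, "survey2")$text,
               "all of the following: something that")
})

test_that("paragraphs join sentences in unit order", {
  g <- verbalise(survey2_path())
  expect_equal(
    entity_paragraph(g, "4470"),
    paste("A 4470 is both something that derives from a Mus musculus,",
          "and something that derives from a bone marrow. A 4470 is a cell line."))
  expect_null(entity_paragraph(g, "no such thing"))
})

test_that("glossary entries are alphabetical with digits before letters", {
  g <- verbalise(survey2_path())
  headers <- vapply(g$plan$entries, function(e) e$name, "")
  # independent collation oracle: case-folded byte comparison
  expected <- headers[order(vapply(tolower(headers), function(x)
    paste(sprintf("%03d", utf8ToInt(x)), collapse = " "), ""))]
  expect_equal(headers, expected)
  first4 <- strsplit(g$text, "\n\n", fixed = TRUE)[[1]][1:2]
  expect_match(first4[1], "^4470\n")
  expect_match(first4[2], "^Ara-C-resistant murine leukemia\n")
})

test_that("an empty plan yields an empty document", {
  doc <- parse_ontology(ofn_doc())
  plan <- plan_document(doc, build_lexicon(doc))
  expect_equal(generate_glossary(plan, build_lexicon(doc)), "")
})

test_that("duplicate English names are disambiguated in headers only", {
  g <- verbalise(ofn_doc(
    "AnnotationAssertion(rdfs:label :tumour_a \"tumour\")",
    "AnnotationAssertion(rdfs:label :tumour_b \"tumour\")",
    "SubClassOf(:tumour_a :disease)",
    "SubClassOf(:tumour_b :disease)"
  ))
  expect_match(g$text, "tumour (tumour_a)", fixed = TRUE)
  expect_match(g$text, "tumour (tumour_b)", fixed = TRUE)
  expect_false(grepl("A tumour (tumour_a) is", g$text, fixed = TRUE))
})

test_that("aggregation preserves the set of mentioned entity names", {
  doc <- parse_ontology(fixture_22rv1())
  lex <- build_lexicon(doc)
  subject <- paste0(EX, "22rv1")
  units <- aggregate_axioms(select_axioms(doc, subject), subject)
  agg <- units[[2]]
  agg_text <- realise_unit(agg, lex)$text
  singles <- lapply(agg$members, function(ax) structure(
    list(kind = "single", axiom = ax, subject_iri = subject,
         source_index = ax$source_index), class = "realisation_unit"))
  single_text <- paste(vapply(singles, function(u)
    realise_unit(u, lex)$text, ""), collapse = " ")
  mentioned <- function(text) {
    Filter(function(nm) grepl(nm, text, fixed = TRUE),
           vapply(names(lex$entries), function(iri)
             paste(lex$entries[[iri]]$singular, collapse = " "), ""))
  }
  expect_setequal(names(mentioned(agg_text)), names(mentioned(single_text)))
})

test_that("every unit yields exactly one sentence of a known kind", {
  doc <- parse_ontology(generate_fixture(fixture_params(n_axioms = 120,
                                                        seed = 3)))
  g <- verbalise(doc)
  n_units <- sum(vapply(g$plan$entries, function(e) length(e$units), 0L))
  expect_length(g$sentences, n_units)
  kinds <- vapply(g$sentences, function(s) s$kind, "")
  expect_true(all(kinds %in% c("english", "fallback")))
  english <- vapply(Filter(function(s) s$kind == "english", g$sentences),
                    function(s) s$text, "")
  expect_true(all(grepl("^[A-Z0-9]", english)))
  expect_true(all(grepl("\\.$", english)))
})
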