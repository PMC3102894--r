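test_that("axioms are selected when the entity is a top-level argument", {
  doc <- parse_ontology(ofn_doc(
    "SubClassOf(:genetic_disorder :disease)",
    "DisjointClasses(:genetic_disorder :normal)",
    "DisjointClasses(:genetic_disorder :uninfected)",
    "SubClassOf(:other ObjectSomeValuesFrom(:p :genetic_disorder))"
  ))
  sel <- select_axioms(doc, paste0(EX, "genetic_disorder"))
  # the restriction filler occurrence (axiom 4) does not count
  expect_equal(vapply(sel, function(a) a$source_index, 0L), 1:3)
  expect_error(select_axioms(doc, "http://nowhere/q"), "unknown entity")
})

test_that("a subclass axiom is selected for both of its sides", {
  doc <- parse_ontology(ofn_doc("SubClassOf(:b117h :araC)"))
  expect_length(select_axioms(doc, paste0(EX, "b117h")), 1)
  expect_length(select_axioms(doc, paste0(EX, "araC")), 1)
})

test_that("top-level selection agrees with a serialisation-based oracle", {
  doc <- parse_ontology(ofn_doc(
    "SubClassOf(:a :b)",
    "SubClassOf(:a ObjectSomeValuesFrom(:p :c))",
    "EquivalentClasses(:b ObjectIntersectionOf(:c :d))",
    "ClassAssertion(:a :i)",
    "DisjointClasses(:b :d :e)"
  ))
  for (iri in names(doc$entities)) {
    expected <- Filter(function(ax)
      iri %in% oracle_top_level_iris(render_functional(ax)), doc$axioms)
    got <- select_axioms(doc, iri)
    expect_equal(vapply(got, render_functional, ""),
                 vapply(expected, render_functional, ""), info = iri)
  }
})

test_that("structurally similar axioms aggregate into one unit", {
  doc <- parse_ontology(fixture_22rv1())
  subject <- paste0(EX, "22rv1")
  units <- aggregate_axioms(select_axioms(doc, subject), subject)
  expect_length(units, 2)
  # the atomic superclass stays single; the three restrictions merge
  expect_equal(units[[1]]$kind, "single")
  expect_equal(units[[2]]$kind, "aggregated")
  expect_equal(units[[2]]$hole, 2L)
  expect_length(units[[2]]$fillers, 3)
  expect_equal(vapply(units[[2]]$members, function(a) a$source_index, 0L),
               2:4)
})

test_that("pairwise disjointness axioms aggregate over the varying member", {
  doc <- parse_ontology(ofn_doc(
    "SubClassOf(:genetic_disorder :disease)",
    "DisjointClasses(:genetic_disorder :normal)",
    "DisjointClasses(:genetic_disorder :uninfected)"
  ))
  subject <- paste0(EX, "genetic_disorder")
  units <- aggregate_axioms(select_axioms(doc, subject), subject)
  expect_length(units, 2)
  expect_equal(units[[2]]$kind, "aggregated")
  expect_equal(vapply(units[[2]]$fillers,
                      function(f) f$entity$local_name, ""),
               c("normal", "uninfected"))
})

test_that("single axioms and identical duplicates stay single", {
  doc <- parse_ontology(ofn_doc("SubClassOf(:a :b)", "SubClassOf(:a :b)"))
  units <- aggregate_axioms(select_axioms(doc, paste0(EX, "a")),
                            paste0(EX, "a"))
  # zero differing positions: not mergeable, both units survive
  expect_equal(vapply(units, function(u) u$kind, ""), c("single", "single"))
  units1 <- aggregate_axioms(doc$axioms[1], paste0(EX, "a"))
  expect_length(units1, 1)
  expect_equal(units1[[1]]$kind, "single")
})

test_that("atomic and complex constituents never merge", {
  doc <- parse_ontology(ofn_doc(
    "SubClassOf(:a :b)",
    "SubClassOf(:a ObjectSomeValuesFrom(:p :c))"
  ))
  units <- aggregate_axioms(select_axioms(doc, paste0(EX, "a")),
                            paste0(EX, "a"))
  expect_equal(vapply(units, function(u) u$kind, ""), c("single", "single"))
})

test_that("plan entries are alphabetical and unit order follows the source", {
  # restrictions before the atomic superclass: aggregated unit comes first
  doc <- parse_ontology(ofn_doc(
    "AnnotationAssertion(rdfs:label :HeLa \"HeLa\")",
    "SubClassOf(:HeLa ObjectSomeValuesFrom(:bearer_of :cervical_carcinoma))",
    "SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :HomoSapiens))",
    "SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :epithelial_cell))",
    "SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :cervix))",
    "SubClassOf(:HeLa :cell_line)"
  ))
  lex <- build_lexicon(doc)
  plan <- plan_document(doc, lex)
  hela <- Filter(function(e) e$name == "HeLa", plan$entries)[[1]]
  expect_equal(vapply(hela$units, function(u) u$kind, ""),
               c("aggregated", "single"))
  expect_length(hela$units[[1]]$fillers, 4)

  # superclass first: single unit comes first
  doc2 <- parse_ontology(fixture_22rv1())
  plan2 <- plan_document(doc2, build_lexicon(doc2))
  e22 <- Filter(function(e) e$name == "22rv1", plan2$entries)[[1]]
  expect_equal(vapply(e22$units, function(u) u$kind, ""),
               c("single", "aggregated"))

  # flat mode: one unit per selected axiom
  plan_flat <- plan_document(doc2, build_lexicon(doc2), mode = "flat")
  e22f <- Filter(function(e) e$name == "22rv1", plan_flat$entries)[[1]]
  expect_length(e22f$units, 4)
  expect_true(all(vapply(e22f$units, function(u) u$kind, "") == "single"))
})

test_that("entries sort case-insensitively with digits before letters", {
  doc <- parse_ontology(survey2_path())
  plan <- plan_document(doc, build_lexicon(doc))
  nms <- vapply(plan$entries, function(e) e$name, "")
  expect_equal(nms[1:4], c("4470", "Ara-C-resistant murine leukemia",
                           "B117H", "B140H"))
  expect_equal(nms, nms[order(tolower(nms), method = "radix")])
})

test_that("pattern frequencies abstract entities and sum to the axiom count", {
  doc <- parse_ontology(fixture_22rv1())
  freq <- pattern_frequency(doc)
  expect_equal(sum(freq), 4L)
  expect_length(freq, 2)
  expect_equal(unname(freq["SubClassOf(□ ObjectSomeValuesFrom(□ □))"]), 3L)
  expect_equal(unname(freq["SubClassOf(□ □)"]), 1L)
  # report is sorted by descending count
  expect_equal(pattern_report(freq)[1],
               "SubClassOf(□ ObjectSomeValuesFrom(□ □))\t3")

  expect_length(pattern_frequency(parse_ontology(ofn_doc())), 0)

  same <- parse_ontology(ofn_doc(
    "SubClassOf(:a :b)", "SubClassOf(:c :d)", "SubClassOf(:a :d)"))
  expect_equal(unname(pattern_frequency(same)), 3L)
})

test_that("flattening plan units reproduces the selected axiom multiset", {
  for (seed in c(11, 12, 13, 14, 15)) {
    doc <- parse_ontology(generate_fixture(
      fixture_params(n_axioms = 80, seed = seed)))
    lex <- build_lexicon(doc)
    plan <- plan_document(doc, lex)
    plan_flat <- plan_document(doc, lex, mode = "flat")
    flat_by_name <- stats::setNames(
      lapply(plan_flat$entries, function(e) e$units),
      vapply(plan_flat$entries, function(e) e$entity$iri, ""))
    for (e in plan$entries) {
      got <- flatten_units(e$units)
      expected <- Filter(function(ax)
        e$entity$iri %in% oracle_top_level_iris(render_functional(ax)),
        doc$axioms)
      expect_setequal(vapply(got, function(a) a$source_index, 0L),
                      vapply(expected, function(a) a$source_index, 0L))
      # unit order follows first appearance; members stay in source order
      expect_true(all(diff(vapply(e$units, function(u) u$source_index, 0L))
                      > 0))
      for (u in e$units) {
        idx <- vapply(flatten_units(list(u)), function(a) a$source_index, 0L)
        expect_true(all(diff(idx) > 0))
      }
      # flat mode has exactly one unit per selected axiom
      expect_length(flat_by_name[[e$entity$iri]], length(expected))
    }
    # subject coverage: every axiom is in some entry or orphaned
    covered <- unlist(lapply(plan$entries, function(e)
      vapply(flatten_units(e$units), function(a) a$source_index, 0L)))
    orphan_idx <- vapply(plan$orphaned, function(a) a$source_index, 0L)
    expect_setequal(union(covered, orphan_idx), seq_along(doc$axioms))
  }
})
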