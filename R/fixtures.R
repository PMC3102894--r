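# Seeded synthetic-ontology generator for property-based testing. Emits
# OWL Functional Syntax documents over entities whose identifiers and
# labels mix CamelCase, underscores, spaces, hyphens, Latin binomials and
# alphanumeric codes, exercising every supported axiom pattern plus a
# configurable fraction of unsupported functors.

.default_pattern_mix <- c(
  sub_class_of_atomic = 0.34,
  sub_class_of_restriction = 0.30,
  equivalent_classes = 0.08,
  disjoint_classes = 0.08,
  class_assertion = 0.06,
  object_property_assertion = 0.05,
  sub_object_property_of = 0.04,
  unsupported = 0.05
)

.default_naming_mix <- c(
  camel = 0.25, underscore = 0.20, spaced = 0.25,
  hyphenated = 0.10, binomial = 0.10, code = 0.10
)

#' Parameters for the synthetic-ontology generator
#'
#' @param n_classes,n_properties,n_individuals Entity pool sizes.
#' @param n_axioms Number of logical axioms to emit.
#' @param pattern_mix Named probability vector over axiom patterns
#'   (`sub_class_of_atomic`, `sub_class_of_restriction`,
#'   `equivalent_classes`, `disjoint_classes`, `class_assertion`,
#'   `object_property_assertion`, `sub_object_property_of`,
#'   `unsupported`); must sum to 1.
#' @param naming_mix Named probability vector over naming conventions
#'   (`camel`, `underscore`, `spaced`, `hyphenated`, `binomial`, `code`);
#'   must sum to 1.
#' @param label_fraction Fraction of entities that get an `rdfs:label`
#'   annotation.
#' @param seed Integer seed; the same parameters and seed always produce
#'   an identical document.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(n_classes = 30L, n_properties = 6L,
                           n_individuals = 6L, n_axioms = 60L,
                           pattern_mix = .default_pattern_mix,
                           naming_mix = .default_naming_mix,
                           label_fraction = 0.7, seed = 1L) {
  pattern_mix <- pattern_mix[names(.default_pattern_mix)]
  pattern_mix[is.na(pattern_mix)] <- 0
  names(pattern_mix) <- names(.default_pattern_mix)
  if (abs(sum(pattern_mix) - 1) > 1e-8) {
    stop("pattern_mix probabilities must sum to 1", call. = FALSE)
  }
  naming_mix <- naming_mix[names(.default_naming_mix)]
  naming_mix[is.na(naming_mix)] <- 0
  names(naming_mix) <- names(.default_naming_mix)
  if (abs(sum(naming_mix) - 1) > 1e-8) {
    stop("naming_mix probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(n_classes >= 3L, n_properties >= 1L, n_individuals >= 1L,
            n_axioms >= 0L, label_fraction >= 0, label_fraction <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_properties = as.integer(n_properties),
                 n_individuals = as.integer(n_individuals),
                 n_axioms = as.integer(n_axioms),
                 pattern_mix = pattern_mix, naming_mix = naming_mix,
                 label_fraction = label_fraction,
                 seed = as.integer(seed)),
            class = "fixture_params")
}

.syllables <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ra",
                "su", "ti", "vo", "xa", "ze", "lo", "ke", "mu", "sa", "re")

.rand_word <- function() {
  paste(sample(.syllables, sample(2:3, 1L), replace = TRUE), collapse = "")
}

.cap <- function(w) paste0(toupper(substring(w, 1, 1)), substring(w, 2))

# identifier + optional label for one entity under a naming convention
.make_name <- function(convention) {
  switch(convention,
    camel = {
      words <- replicate(sample(1:3, 1L), .rand_word())
      id <- paste(vapply(words, .cap, ""), collapse = "")
      list(id = id, label = id)
    },
    underscore = {
      words <- replicate(sample(1:3, 1L), .rand_word())
      list(id = paste(words, collapse = "_"),
           label = paste(words, collapse = "_"))
    },
    spaced = {
      words <- replicate(sample(1:3, 1L), .rand_word())
      list(id = paste(words, collapse = "_"),
           label = paste(words, collapse = " "))
    },
    hyphenated = {
      words <- replicate(sample(2:3, 1L), .rand_word())
      nm <- paste(words, collapse = "-")
      list(id = nm, label = nm)
    },
    binomial = {
      nm <- paste(.cap(.rand_word()), .rand_word())
      list(id = gsub(" ", "_", nm), label = nm)
    },
    code = {
      id <- paste0(sample(LETTERS, 1L),
                   paste(sample(0:9, sample(2:4, 1L), replace = TRUE),
                         collapse = ""),
                   sample(LETTERS, 1L))
      list(id = id, label = id)
    })
}

.q <- function(id) paste0(":", id)

#' Generate a synthetic ontology document
#'
#' Produces OWL Functional Syntax text exercising the supported axiom
#' patterns in proportion to `pattern_mix`, over entities named under the
#' conventions of `naming_mix`, plus declarations and labels. Unsupported
#' functors (property characteristics such as
#' `FunctionalObjectProperty`) are emitted with atomic top-level arguments
#' so they surface as fallback sentences. Deterministic per seed: the
#' caller's RNG state is saved and restored.
#'
#' @param params A `fixture_params` object.
#' @return The document as a single character string.
#' @export
generate_fixture <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  mk_pool <- function(n) {
    ids <- character(0); labels <- character(0)
    conventions <- sample(names(params$naming_mix), n, replace = TRUE,
                          prob = params$naming_mix)
    for (k in seq_len(n)) {
      nm <- .make_name(conventions[k])
      id <- nm$id
      if (id %in% ids) id <- paste0(id, k)   # enforce unique identifiers
      ids <- c(ids, id)
      labels <- c(labels, nm$label)
    }
    has_label <- stats::runif(n) < params$label_fraction
    list(ids = ids, labels = labels, has_label = has_label)
  }

  classes <- mk_pool(params$n_classes)
  # properties follow identifier-style conventions only
  props <- list(ids = character(0))
  prop_stems <- c("derives_from", "bearer_of", "has_quality", "part_of",
                  "located_in", "connects_to", "regulates", "has_part")
  for (k in seq_len(params$n_properties)) {
    stem <- if (k <= length(prop_stems)) prop_stems[k] else
      paste0(.rand_word(), "_of")
    props$ids <- c(props$ids, stem)
  }
  inds <- mk_pool(params$n_individuals)

  pick_class <- function(n = 1L) sample(classes$ids, n)
  pick_prop <- function() sample(props$ids, 1L)
  pick_ind <- function(n = 1L) sample(inds$ids, n)

  restriction <- function() {
    r <- stats::runif(1)
    if (r < 0.70) {
      sprintf("ObjectSomeValuesFrom(%s %s)", .q(pick_prop()),
              .q(pick_class()))
    } else if (r < 0.80) {
      sprintf("ObjectHasValue(%s %s)", .q(pick_prop()), .q(pick_ind()))
    } else if (r < 0.90) {
      cs <- pick_class(2L)
      sprintf("ObjectIntersectionOf(%s %s)", .q(cs[1]), .q(cs[2]))
    } else {
      cs <- pick_class(2L)
      sprintf("ObjectUnionOf(%s %s)", .q(cs[1]), .q(cs[2]))
    }
  }

  unsupported_axiom <- function() {
    r <- stats::runif(1)
    if (r < 0.4) {
      sprintf("FunctionalObjectProperty(%s)", .q(pick_prop()))
    } else if (r < 0.7) {
      sprintf("SymmetricObjectProperty(%s)", .q(pick_prop()))
    } else {
      cs <- pick_class(3L)
      sprintf("DisjointUnion(%s %s %s)", .q(cs[1]), .q(cs[2]), .q(cs[3]))
    }
  }

  patterns <- sample(names(params$pattern_mix), params$n_axioms,
                     replace = TRUE, prob = params$pattern_mix)
  axioms <- vapply(patterns, function(p) {
    switch(p,
      sub_class_of_atomic = {
        cs <- pick_class(2L)
        sprintf("SubClassOf(%s %s)", .q(cs[1]), .q(cs[2]))
      },
      sub_class_of_restriction =
        sprintf("SubClassOf(%s %s)", .q(pick_class()), restriction()),
      equivalent_classes = {
        if (stats::runif(1) < 0.5) {
          cs <- pick_class(2L)
          sprintf("EquivalentClasses(%s %s)", .q(cs[1]), .q(cs[2]))
        } else {
          sprintf("EquivalentClasses(%s %s)", .q(pick_class()), restriction())
        }
      },
      disjoint_classes = {
        k <- sample(2:3, 1L)
        cs <- pick_class(k)
        sprintf("DisjointClasses(%s)",
                paste(vapply(cs, .q, ""), collapse = " "))
      },
      class_assertion =
        sprintf("ClassAssertion(%s %s)", .q(pick_class()), .q(pick_ind())),
      object_property_assertion = {
        is_ <- pick_ind(min(2L, params$n_individuals))
        if (length(is_) < 2L) is_ <- c(is_, is_)
        sprintf("ObjectPropertyAssertion(%s %s %s)", .q(pick_prop()),
                .q(is_[1]), .q(is_[2]))
      },
      sub_object_property_of = {
        p1 <- pick_prop(); p2 <- pick_prop()
        sprintf("SubObjectPropertyOf(%s %s)", .q(p1), .q(p2))
      },
      unsupported = unsupported_axiom()
    )
  }, "")

  decls <- c(
    sprintf("Declaration(Class(%s))", vapply(classes$ids, .q, "")),
    sprintf("Declaration(ObjectProperty(%s))", vapply(props$ids, .q, "")),
    sprintf("Declaration(NamedIndividual(%s))", vapply(inds$ids, .q, ""))
  )
  lbl <- function(pool) {
    w <- which(pool$has_label)
    sprintf("AnnotationAssertion(rdfs:label %s \"%s\")",
            vapply(pool$ids[w], .q, ""),
            gsub("\"", "\\\\\"", pool$labels[w]))
  }
  labels <- c(lbl(classes), lbl(inds))

  paste(c(
    "Prefix(:=<http://example.org/synth#>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    "Ontology(<http://example.org/synth>",
    decls, labels, axioms,
    ")"
  ), collapse = "\n")
}
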