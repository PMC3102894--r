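# OWL Functional Syntax reader.
#
# The native input format is a subset of OWL 2 Functional Syntax: Prefix
# declarations, an optional Ontology(...) wrapper, Declaration, SubClassOf,
# EquivalentClasses, DisjointClasses, ClassAssertion,
# ObjectPropertyAssertion, SubObjectPropertyOf and
# AnnotationAssertion(rdfs:label ...). Any other functor is preserved as an
# "unsupported" node so the axiom can be re-serialised verbatim.

RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"

# Prefixes the functional-syntax grammar predeclares.
.builtin_prefixes <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  owl  = "http://www.w3.org/2002/07/owl#"
)

.ofn_token_re <- paste0(
  "<[^<>\"{}|^`\\\\\\x00-\\x20]*>",                  # full IRI
  "|\"(?:[^\"\\\\]|\\\\.)*\"",                       # quoted literal
  "|\\^\\^",                                         # datatype marker
  "|@[A-Za-z][A-Za-z0-9-]*",                         # language tag
  "|(?:[A-Za-z][A-Za-z0-9._-]*)?:[A-Za-z0-9._-]*",   # prefixed name
  "|[A-Za-z][A-Za-z0-9]*",                           # bare word (functor)
  "|\\(|\\)|="
)

ofn_tokenise <- function(text) {
  m <- gregexpr(.ofn_token_re, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
  }
  toks <- substring(text, starts, starts + lens - 1L)
  # everything between tokens must be whitespace
  gap_start <- c(1L, starts + lens)
  gap_end <- c(starts - 1L, nchar(text))
  gaps <- substring(text, gap_start, gap_end)
  bad <- which(grepl("[^[:space:]]", gaps))
  if (length(bad)) {
    pos <- gap_start[bad[1]] + regexpr("[^[:space:]]", gaps[bad[1]]) - 1L
    lc <- .pos_linecol(text, pos)
    stop(sprintf("malformed syntax at line %d, column %d: unexpected character '%s'",
                 lc[1], lc[2], substring(text, pos, pos)), call. = FALSE)
  }
  first <- substring(toks, 1L, 1L)
  type <- ifelse(first == "<", "IRI",
          ifelse(first == "\"", "STRING",
          ifelse(toks == "(", "LP",
          ifelse(toks == ")", "RP",
          ifelse(toks == "=", "EQ",
          ifelse(toks == "^^", "CARET",
          ifelse(first == "@", "LANG",
          ifelse(grepl(":", toks, fixed = TRUE), "PNAME", "WORD"))))))))
  list(text = toks, type = type, start = starts, n = length(toks))
}

.pos_linecol <- function(text, pos) {
  prefix <- substring(text, 1L, pos - 1L)
  nl <- gregexpr("\n", prefix, fixed = TRUE)[[1]]
  if (nl[1] == -1L) c(1L, pos) else {
    line <- length(nl) + 1L
    col <- pos - nl[length(nl)]
    c(line, as.integer(col))
  }
}

.parse_error <- function(state, what) {
  if (state$i <= state$tokens$n) {
    pos <- state$tokens$start[state$i]
    lc <- .pos_linecol(state$text, pos)
    stop(sprintf("malformed syntax at line %d, column %d: expected %s, found '%s'",
                 lc[1], lc[2], what, state$tokens$text[state$i]), call. = FALSE)
  }
  stop(sprintf("malformed syntax: unexpected end of document, expected %s", what),
       call. = FALSE)
}

.peek <- function(state) {
  if (state$i > state$tokens$n) NA_character_ else state$tokens$type[state$i]
}
.peek_text <- function(state) {
  if (state$i > state$tokens$n) NA_character_ else state$tokens$text[state$i]
}
.advance <- function(state) {
  t <- state$tokens$text[state$i]
  state$i <- state$i + 1L
  t
}
.expect <- function(state, type, what = type) {
  if (!identical(.peek(state), type)) .parse_error(state, what)
  .advance(state)
}

.expand_pname <- function(state, pname) {
  colon <- regexpr(":", pname, fixed = TRUE)
  prefix <- substring(pname, 1L, colon - 1L)
  local <- substring(pname, colon + 1L)
  ns <- state$prefixes[[if (prefix == "") ":" else prefix]]
  if (is.null(ns)) {
    stop(sprintf("undeclared prefix '%s:' in '%s'", prefix, pname), call. = FALSE)
  }
  paste0(ns, local)
}

# raw term grammar: term := WORD '(' arg* ')' ; arg := term | iri | literal
.p_arg <- function(state) {
  ty <- .peek(state)
  if (is.na(ty)) .parse_error(state, "an argument")
  if (ty == "WORD") return(.p_term(state))
  if (ty == "IRI") {
    t <- .advance(state)
    return(list(type = "iri", iri = substring(t, 2L, nchar(t) - 1L)))
  }
  if (ty == "PNAME") {
    t <- .advance(state)
    return(list(type = "iri", iri = .expand_pname(state, t)))
  }
  if (ty == "STRING") {
    t <- .advance(state)
    lex <- gsub("\\\\(.)", "\\1", substring(t, 2L, nchar(t) - 1L))
    lit <- list(type = "literal", lexical = lex, datatype = NULL, lang = NULL)
    if (identical(.peek(state), "CARET")) {
      .advance(state)
      dt <- .p_arg(state)
      if (!identical(dt$type, "iri")) .parse_error(state, "a datatype IRI")
      lit$datatype <- dt$iri
    } else if (identical(.peek(state), "LANG")) {
      lit$lang <- substring(.advance(state), 2L)
    }
    return(lit)
  }
  .parse_error(state, "an argument")
}

.p_term <- function(state) {
  functor <- .expect(state, "WORD", "a functor name")
  .expect(state, "LP", "'('")
  args <- list()
  while (!identical(.peek(state), "RP")) {
    if (is.na(.peek(state))) .parse_error(state, "')'")
    args[[length(args) + 1L]] <- .p_arg(state)
  }
  .advance(state)
  list(type = "term", functor = functor, args = args)
}

#' Parse an OWL Functional Syntax document
#'
#' Reads an ontology document into the internal axiom term model. Logical
#' axioms are kept in file order; `rdfs:label` annotation assertions are
#' routed into the label table; prefixes, declarations and other annotations
#' are excluded from the axiom list. Functors outside the supported fragment
#' are preserved as unsupported nodes so that [render_functional()] can
#' re-serialise them verbatim.
#'
#' @param source Path to a `.ofn` file, or a character vector of document
#'   text (a single string or one element per line).
#' @param source_name Name recorded on the returned document; defaults to
#'   the file name or `"<text>"`.
#' @return An object of class `owl_document` with components `axioms`
#'   (ordered list of `owl_axiom`), `entities` (atomic entities in first
#'   occurrence order), `labels` (named character vector, IRI -> preferred
#'   label), `source_name`, and statement counts.
#' @examples
#' doc <- parse_ontology(c(
#'   "Prefix(:=<http://example.org/x#>)",
#'   "SubClassOf(:genetic_disorder :disease)"
#' ))
#' length(doc$axioms)
#' @export
parse_ontology <- function(source, source_name = NULL) {
  if (length(source) == 1L && file.exists(source) &&
      !grepl("\n", source, fixed = TRUE)) {
    if (is.null(source_name)) source_name <- basename(source)
    text <- paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  } else {
    if (is.null(source_name)) source_name <- "<text>"
    text <- paste(source, collapse = "\n")
  }

  state <- new.env(parent = emptyenv())
  state$text <- text
  state$tokens <- ofn_tokenise(text)
  state$i <- 1L
  state$prefixes <- as.list(.builtin_prefixes)

  # Prefix declarations
  while (identical(.peek_text(state), "Prefix")) {
    .advance(state); .expect(state, "LP", "'('")
    pn <- .expect(state, "PNAME", "a prefix name")
    if (!grepl(":$", pn)) .parse_error(state, "a prefix name ending in ':'")
    .expect(state, "EQ", "'='")
    iri_tok <- .expect(state, "IRI", "a namespace IRI")
    .expect(state, "RP", "')'")
    pfx <- sub(":$", "", pn)
    state$prefixes[[if (pfx == "") ":" else pfx]] <-
      substring(iri_tok, 2L, nchar(iri_tok) - 1L)
  }

  wrapped <- identical(.peek_text(state), "Ontology")
  if (wrapped) {
    .advance(state); .expect(state, "LP", "'('")
    while (.peek(state) %in% c("IRI", "PNAME")) .advance(state)  # ontology/version IRI
  }
  raw <- list()
  while (!is.na(.peek(state)) && !identical(.peek(state), "RP")) {
    raw[[length(raw) + 1L]] <- .p_term(state)
  }
  if (wrapped) .expect(state, "RP", "')'")
  if (!is.na(.peek(state))) .parse_error(state, "end of document")

  .build_document(raw, source_name)
}

# ---- conversion from raw terms to the axiom model ----

.decl_kinds <- c(Class = "class", ObjectProperty = "object-property",
                 DataProperty = "data-property",
                 NamedIndividual = "individual", Datatype = "datatype",
                 AnnotationProperty = "annotation-property")

.build_document <- function(raw, source_name) {
  ctx <- new.env(parent = emptyenv())
  ctx$kinds <- new.env(parent = emptyenv())     # iri -> declared kind
  ctx$entities <- new.env(parent = emptyenv())  # iri -> owl_entity
  ctx$order <- character(0)
  ctx$labels <- character(0)
  ctx$n_label_stmts <- 0L
  ctx$n_other_annotation <- 0L
  ctx$n_declarations <- 0L

  # pass 1: declarations fix entity kinds
  for (t in raw) {
    if (identical(t$functor, "Declaration") && length(t$args) == 1L &&
        identical(t$args[[1]]$type, "term") &&
        t$args[[1]]$functor %in% names(.decl_kinds) &&
        length(t$args[[1]]$args) == 1L &&
        identical(t$args[[1]]$args[[1]]$type, "iri")) {
      assign(t$args[[1]]$args[[1]]$iri, .decl_kinds[[t$args[[1]]$functor]],
             envir = ctx$kinds)
    }
  }

  axioms <- list()
  for (t in raw) {
    if (identical(t$functor, "Declaration")) {
      ctx$n_declarations <- ctx$n_declarations + 1L
      next
    }
    if (identical(t$functor, "AnnotationAssertion")) {
      .route_annotation(t, ctx)
      next
    }
    ax <- .axiom_from_raw(t, ctx)
    ax$source_index <- length(axioms) + 1L
    axioms[[length(axioms) + 1L]] <- ax
  }

  entities <- lapply(ctx$order, function(iri) get(iri, envir = ctx$entities))
  names(entities) <- ctx$order
  structure(list(
    axioms = axioms,
    entities = entities,
    labels = ctx$labels,
    source_name = source_name,
    n_annotation_statements = ctx$n_label_stmts + ctx$n_other_annotation,
    n_label_statements = ctx$n_label_stmts
  ), class = "owl_document")
}

.route_annotation <- function(t, ctx) {
  a <- t$args
  if (length(a) == 3L && identical(a[[1]]$type, "iri") &&
      identical(a[[1]]$iri, RDFS_LABEL) &&
      identical(a[[2]]$type, "iri") && identical(a[[3]]$type, "literal")) {
    ctx$n_label_stmts <- ctx$n_label_stmts + 1L
    if (!a[[2]]$iri %in% names(ctx$labels)) {     # first rdfs:label wins
      ctx$labels[a[[2]]$iri] <- a[[3]]$lexical
    }
  } else {
    ctx$n_other_annotation <- ctx$n_other_annotation + 1L
  }
}

.strip_namespace <- function(iri) {
  sub(".*[#/:]", "", iri)
}

.ref_entity <- function(iri, ctx, hint = "class") {
  if (!exists(iri, envir = ctx$entities, inherits = FALSE)) {
    kind <- if (exists(iri, envir = ctx$kinds, inherits = FALSE)) {
      get(iri, envir = ctx$kinds)
    } else hint
    ent <- structure(list(iri = iri, local_name = .strip_namespace(iri),
                          kind = kind), class = "owl_entity")
    assign(iri, ent, envir = ctx$entities)
    ctx$order <- c(ctx$order, iri)
  }
  get(iri, envir = ctx$entities, inherits = FALSE)
}

# register entities occurring anywhere inside a raw (unsupported) term
.scan_raw_entities <- function(x, ctx) {
  if (identical(x$type, "iri")) {
    .ref_entity(x$iri, ctx)
  } else if (identical(x$type, "term")) {
    for (a in x$args) .scan_raw_entities(a, ctx)
  }
  invisible(NULL)
}

.expr_from_raw <- function(x, ctx) {
  if (identical(x$type, "iri")) {
    return(structure(list(type = "atomic",
                          entity = .ref_entity(x$iri, ctx, hint = "class")),
                     class = "owl_expr"))
  }
  if (!identical(x$type, "term")) {
    .scan_raw_entities(x, ctx)
    return(structure(list(type = "unsupported", functor = NA_character_,
                          raw = x), class = "owl_expr"))
  }
  f <- x$functor
  a <- x$args
  node <- switch(f,
    ObjectSomeValuesFrom = if (length(a) == 2L && identical(a[[1]]$type, "iri")) {
      list(type = "some_values",
           property = .ref_entity(a[[1]]$iri, ctx, hint = "object-property"),
           filler = .expr_from_raw(a[[2]], ctx))
    },
    ObjectHasValue = if (length(a) == 2L && identical(a[[1]]$type, "iri") &&
                         identical(a[[2]]$type, "iri")) {
      list(type = "has_value",
           property = .ref_entity(a[[1]]$iri, ctx, hint = "object-property"),
           individual = .ref_entity(a[[2]]$iri, ctx, hint = "individual"))
    },
    ObjectIntersectionOf = if (length(a) >= 2L) {
      list(type = "intersection",
           members = lapply(a, .expr_from_raw, ctx = ctx))
    },
    ObjectUnionOf = if (length(a) >= 2L) {
      list(type = "union", members = lapply(a, .expr_from_raw, ctx = ctx))
    },
    ObjectComplementOf = if (length(a) == 1L) {
      list(type = "complement", expr = .expr_from_raw(a[[1]], ctx))
    },
    ObjectOneOf = if (all(vapply(a, function(z) identical(z$type, "iri"), TRUE))) {
      list(type = "one_of",
           individuals = lapply(a, function(z)
             .ref_entity(z$iri, ctx, hint = "individual")))
    },
    NULL)
  if (is.null(node)) {
    .scan_raw_entities(x, ctx)
    node <- list(type = "unsupported", functor = f, raw = x)
  }
  structure(node, class = "owl_expr")
}

.supported_axioms <- c(
  SubClassOf = "sub_class_of",
  EquivalentClasses = "equivalent_classes",
  DisjointClasses = "disjoint_classes",
  ClassAssertion = "class_assertion",
  ObjectPropertyAssertion = "object_property_assertion",
  SubObjectPropertyOf = "sub_object_property_of"
)
.fs_names <- stats::setNames(names(.supported_axioms), .supported_axioms)

.axiom_from_raw <- function(t, ctx) {
  f <- t$functor
  a <- t$args
  ok <- FALSE
  args <- NULL
  if (f %in% names(.supported_axioms)) {
    functor <- .supported_axioms[[f]]
    if (functor == "sub_class_of" && length(a) == 2L) {
      args <- lapply(a, .expr_from_raw, ctx = ctx); ok <- TRUE
    } else if (functor %in% c("equivalent_classes", "disjoint_classes") &&
               length(a) >= 2L) {
      args <- lapply(a, .expr_from_raw, ctx = ctx); ok <- TRUE
    } else if (functor == "class_assertion" && length(a) == 2L &&
               identical(a[[2]]$type, "iri")) {
      args <- list(.expr_from_raw(a[[1]], ctx),
                   .ref_entity(a[[2]]$iri, ctx, hint = "individual"))
      ok <- TRUE
    } else if (functor == "object_property_assertion" && length(a) == 3L &&
               all(vapply(a, function(z) identical(z$type, "iri"), TRUE))) {
      args <- list(.ref_entity(a[[1]]$iri, ctx, hint = "object-property"),
                   .ref_entity(a[[2]]$iri, ctx, hint = "individual"),
                   .ref_entity(a[[3]]$iri, ctx, hint = "individual"))
      ok <- TRUE
    } else if (functor == "sub_object_property_of" && length(a) == 2L &&
               all(vapply(a, function(z) identical(z$type, "iri"), TRUE))) {
      args <- lapply(a, function(z)
        .ref_entity(z$iri, ctx, hint = "object-property"))
      ok <- TRUE
    }
  }
  if (ok) {
    structure(list(functor = functor, fs_name = f, args = args,
                   source_index = NA_integer_), class = "owl_axiom")
  } else {
    .scan_raw_entities(t, ctx)
    structure(list(functor = "unsupported", fs_name = f, args = t$args,
                   source_index = NA_integer_), class = "owl_axiom")
  }
}
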