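# Axiom term model: accessors and functional-syntax serialisation.

#' Atomic entities of a document
#'
#' Every distinct atomic entity (class, property, individual or datatype)
#' occurring at any depth in the document's axioms, deduplicated by IRI and
#' listed in first-occurrence order.
#'
#' @param doc An `owl_document` from [parse_ontology()].
#' @return A named list of `owl_entity` objects (names are IRIs).
#' @export
atomic_entities <- function(doc) {
  stopifnot(inherits(doc, "owl_document"))
  doc$entities
}

.escape_literal <- function(x) {
  gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x))
}

.render_raw <- function(x) {
  if (identical(x$type, "iri")) return(paste0("<", x$iri, ">"))
  if (identical(x$type, "literal")) {
    out <- paste0("\"", .escape_literal(x$lexical), "\"")
    if (!is.null(x$datatype)) out <- paste0(out, "^^<", x$datatype, ">")
    if (!is.null(x$lang)) out <- paste0(out, "@", x$lang)
    return(out)
  }
  paste0(x$functor, "(", paste(vapply(x$args, .render_raw, ""), collapse = " "),
         ")")
}

.render_entity <- function(ent, anon = FALSE) {
  if (anon) "□" else paste0("<", ent$iri, ">")
}

.render_expr <- function(expr, anon = FALSE) {
  switch(expr$type,
    atomic = .render_entity(expr$entity, anon),
    some_values = paste0("ObjectSomeValuesFrom(",
                         .render_entity(expr$property, anon), " ",
                         .render_expr(expr$filler, anon), ")"),
    has_value = paste0("ObjectHasValue(", .render_entity(expr$property, anon),
                       " ", .render_entity(expr$individual, anon), ")"),
    intersection = paste0("ObjectIntersectionOf(",
                          paste(vapply(expr$members, .render_expr, "",
                                       anon = anon), collapse = " "), ")"),
    union = paste0("ObjectUnionOf(",
                   paste(vapply(expr$members, .render_expr, "", anon = anon),
                         collapse = " "), ")"),
    complement = paste0("ObjectComplementOf(",
                        .render_expr(expr$expr, anon), ")"),
    one_of = paste0("ObjectOneOf(",
                    paste(vapply(expr$individuals, .render_entity, "",
                                 anon = anon), collapse = " "), ")"),
    unsupported = if (anon) .render_raw_anon(expr$raw) else .render_raw(expr$raw),
    stop("unknown expression type: ", expr$type)
  )
}

.render_raw_anon <- function(x) {
  if (identical(x$type, "iri")) return("□")
  if (identical(x$type, "literal")) return(.render_raw(x))
  paste0(x$functor, "(",
         paste(vapply(x$args, .render_raw_anon, ""), collapse = " "), ")")
}

.render_arg <- function(x, anon = FALSE) {
  if (inherits(x, "owl_entity")) return(.render_entity(x, anon))
  if (inherits(x, "owl_expr")) return(.render_expr(x, anon))
  if (anon) .render_raw_anon(x) else .render_raw(x)
}

#' Serialise an axiom to OWL Functional Syntax
#'
#' Deterministic single-line serialisation with full IRIs. For an axiom
#' parsed from functional syntax the output is content-equivalent to the
#' input (same functor nesting, same argument order), so parsing it again
#' yields an identical term tree. Used as the fallback "sentence" for
#' constructs the realisation grammar does not cover.
#'
#' @param axiom An `owl_axiom`.
#' @return A single character string.
#' @export
render_functional <- function(axiom) {
  stopifnot(inherits(axiom, "owl_axiom"))
  paste0(axiom$fs_name, "(",
         paste(vapply(axiom$args, .render_arg, ""), collapse = " "), ")")
}

# Structural key with entities anonymised; two axioms share a key iff their
# trees are isomorphic ignoring entity identity.
.pattern_key <- function(axiom) {
  paste0(axiom$fs_name, "(",
         paste(vapply(axiom$args, .render_arg, "", anon = TRUE),
               collapse = " "), ")")
}

# top-level constructor class of an argument: atomic entity vs complex tree
.arg_kind <- function(x) {
  if (inherits(x, "owl_entity")) return("atomic")
  if (inherits(x, "owl_expr")) {
    return(if (identical(x$type, "atomic")) "atomic" else "complex")
  }
  if (identical(x$type, "iri")) "atomic" else "complex"
}

# IRIs of atomic entities occurring as direct arguments of the axiom functor
.axiom_subjects <- function(axiom) {
  iris <- character(0)
  for (x in axiom$args) {
    if (inherits(x, "owl_entity")) {
      iris <- c(iris, x$iri)
    } else if (inherits(x, "owl_expr")) {
      if (identical(x$type, "atomic")) iris <- c(iris, x$entity$iri)
    } else if (identical(x$type, "iri")) {
      iris <- c(iris, x$iri)
    }
  }
  unique(iris)
}

#' @export
print.owl_document <- function(x, ...) {
  cat(sprintf("<owl_document '%s': %d axioms, %d entities, %d labels>\n",
              x$source_name, length(x$axioms), length(x$entities),
              length(x$labels)))
  invisible(x)
}

#' @export
print.owl_axiom <- function(x, ...) {
  cat(render_functional(x), "\n")
  invisible(x)
}

#' @export
print.owl_entity <- function(x, ...) {
  cat(sprintf("<%s> (%s)\n", x$iri, x$kind))
  invisible(x)
}
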