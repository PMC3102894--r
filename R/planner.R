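# Text planning: per-entity axiom selection, aggregation of structurally
# similar axioms into list-valued units, document ordering, and axiom
# pattern statistics.

#' Select the axioms describing an entity
#'
#' Returns, in source order, every axiom in which the entity occurs as a
#' top-level argument of the axiom functor. For class-expression arguments
#' only an atomic expression counts: an entity buried inside a restriction
#' filler is not a subject of that axiom. An axiom may be selected for
#' several entities (e.g. both sides of a SubClassOf).
#'
#' @param doc An `owl_document`.
#' @param entity An `owl_entity` or an IRI string; must occur in the
#'   document.
#' @return Ordered list of `owl_axiom`.
#' @export
select_axioms <- function(doc, entity) {
  stopifnot(inherits(doc, "owl_document"))
  iri <- if (inherits(entity, "owl_entity")) entity$iri else entity
  if (!iri %in% names(doc$entities)) {
    stop("unknown entity: <", iri, ">", call. = FALSE)
  }
  doc$axioms[vapply(doc$axioms,
                    function(ax) iri %in% .axiom_subjects(ax), TRUE)]
}

# per-axiom comparison data used by the aggregator
.agg_profile <- function(ax) {
  list(functor = ax$functor,
       arity = length(ax$args),
       keys = vapply(ax$args, .render_arg, ""),
       kinds = vapply(ax$args, .arg_kind, ""))
}

#' Aggregate axioms sharing a common pattern
#'
#' Greedy grouping in source order: two axioms are mergeable iff they have
#' the same functor and arity, their argument trees differ at exactly one
#' position, and the two differing constituents are of the same top-level
#' kind (both atomic, or both complex expressions). Each maximal group of
#' two or more becomes one aggregated unit — the shared skeleton with the
#' varying constituent replaced by an ordered filler list — placed at the
#' position of its first member; everything else stays a single unit.
#' Axioms with an unsupported functor are never merged.
#'
#' @param axioms Ordered list of axioms selected for `subject`.
#' @param subject The described `owl_entity` (or IRI string).
#' @return Ordered list of `realisation_unit` objects.
#' @export
aggregate_axioms <- function(axioms, subject) {
  subject_iri <- if (inherits(subject, "owl_entity")) subject$iri else subject
  n <- length(axioms)
  if (n == 0L) return(list())
  prof <- lapply(axioms, .agg_profile)
  used <- logical(n)
  units <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    group <- i
    hole <- NA_integer_
    if (prof[[i]]$functor != "unsupported") {
      for (j in seq_len(n)[-seq_len(i)]) {
        if (used[j]) next
        pj <- prof[[j]]
        pi <- prof[[i]]
        if (pj$functor != pi$functor || pj$arity != pi$arity) next
        diffs <- which(pi$keys != pj$keys)
        if (is.na(hole)) {
          if (length(diffs) == 1L &&
              pi$kinds[diffs] == pj$kinds[diffs]) {
            hole <- diffs
            group <- c(group, j)
            used[j] <- TRUE
          }
        } else if (length(diffs) == 1L && diffs == hole &&
                   pi$kinds[hole] == pj$kinds[hole]) {
          group <- c(group, j)
          used[j] <- TRUE
        }
      }
    }
    first <- axioms[[group[1]]]
    if (length(group) >= 2L) {
      units[[length(units) + 1L]] <- structure(list(
        kind = "aggregated",
        functor = first$functor,
        fs_name = first$fs_name,
        args = first$args,
        hole = hole,
        fillers = lapply(group, function(k) axioms[[k]]$args[[hole]]),
        members = axioms[group],
        subject_iri = subject_iri,
        source_index = first$source_index
      ), class = "realisation_unit")
    } else {
      units[[length(units) + 1L]] <- structure(list(
        kind = "single",
        axiom = first,
        subject_iri = subject_iri,
        source_index = first$source_index
      ), class = "realisation_unit")
    }
  }
  units
}

# expand a unit back to its member axioms
.unit_axioms <- function(unit) {
  if (unit$kind == "single") list(unit$axiom) else unit$members
}

#' Build the document plan
#'
#' One entry per atomic entity with at least one selected axiom, ordered
#' case-insensitively by the entity's singular English name (byte order
#' after lower-casing, so digits sort before letters). In grouped mode each
#' entry carries the aggregated units of its selected axioms; in flat mode
#' every selected axiom is its own unit (a straight axiom-to-sentence
#' verbalisation with no grouping). Axioms with no top-level atomic
#' argument belong to no entry and are recorded as orphaned.
#'
#' @param doc An `owl_document`.
#' @param lexicon An `owl_lexicon` covering the document's entities.
#' @param mode `"grouped"` (default) or `"flat"`.
#' @return An `owl_plan`: list with `entries` (each a list with `entity`,
#'   `name`, `units`), `mode`, and `orphaned` (list of axioms).
#' @export
plan_document <- function(doc, lexicon, mode = c("grouped", "flat")) {
  stopifnot(inherits(doc, "owl_document"), inherits(lexicon, "owl_lexicon"))
  mode <- match.arg(mode)

  # one pass over the axioms builds the selection index
  sel <- new.env(parent = emptyenv())
  orphaned <- list()
  for (k in seq_along(doc$axioms)) {
    subs <- .axiom_subjects(doc$axioms[[k]])
    if (!length(subs)) {
      orphaned[[length(orphaned) + 1L]] <- doc$axioms[[k]]
      next
    }
    for (iri in subs) {
      assign(iri, c(if (exists(iri, envir = sel, inherits = FALSE))
        get(iri, envir = sel), k), envir = sel)
    }
  }

  iris <- names(doc$entities)
  iris <- iris[vapply(iris, exists, TRUE, envir = sel, inherits = FALSE)]
  nm <- vapply(iris, function(iri) .lex_singular(lexicon, iri), "")
  iris <- iris[order(tolower(nm), method = "radix")]

  entries <- lapply(iris, function(iri) {
    axs <- doc$axioms[get(iri, envir = sel)]
    units <- if (mode == "grouped") {
      aggregate_axioms(axs, iri)
    } else {
      lapply(axs, function(ax) structure(
        list(kind = "single", axiom = ax, subject_iri = iri,
             source_index = ax$source_index),
        class = "realisation_unit"))
    }
    list(entity = doc$entities[[iri]],
         name = .lex_singular(lexicon, iri),
         units = units)
  })

  structure(list(entries = entries, mode = mode, orphaned = orphaned),
            class = "owl_plan")
}

#' Frequency of axiom patterns
#'
#' Abstracts every axiom by replacing each atomic entity with a placeholder
#' and counts axioms per resulting structural pattern. Counts sum to the
#' number of axioms in the document.
#'
#' @param doc An `owl_document`.
#' @return Named integer vector: pattern (functional syntax with `□`
#'   placeholders) -> count, sorted by descending count then pattern text.
#' @export
pattern_frequency <- function(doc) {
  stopifnot(inherits(doc, "owl_document"))
  if (!length(doc$axioms)) return(stats::setNames(integer(0), character(0)))
  keys <- vapply(doc$axioms, .pattern_key, "")
  tab <- table(keys)
  counts <- as.integer(tab)
  pats <- names(tab)
  ord <- order(-counts, pats, method = "radix")
  stats::setNames(counts[ord], pats[ord])
}

#' Format a pattern-frequency report
#'
#' @param freq Result of [pattern_frequency()].
#' @return Character vector of `pattern<TAB>count` lines.
#' @export
pattern_report <- function(freq) {
  paste0(names(freq), "\t", freq)
}

#' @export
print.owl_plan <- function(x, ...) {
  cat(sprintf("<owl_plan (%s): %d entries, %d orphaned axioms>\n",
              x$mode, length(x$entries), length(x$orphaned)))
  invisible(x)
}
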