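# Lexicon induction: part of speech, singular and plural forms for every
# atomic entity, derived from its annotation label (preferred) or from its
# identifier, with optional hand-edited overrides.
#
# Identifiers and labels are segmented differently: identifiers use capital
# letters and underscores as word boundaries ("partOf" -> "part of"), while
# labels use only spaces and underscores, so a technical term like "HeLa"
# survives intact. The legacy (survey1) style applies identifier-style
# segmentation to labels as well.

.irregular_plurals <- c(
  man = "men", woman = "women", child = "children", foot = "feet",
  tooth = "teeth", mouse = "mice", person = "people"
)

#' Segment an identifier into words
#'
#' Splits an identifier local name at underscores and at camel-case
#' boundaries, lower-casing the result. A boundary falls before an
#' upper-case letter that follows a lower-case letter or digit
#' (`"partOf"` -> `"part of"`, `"HeLa"` -> `"he la"`), and between two
#' upper-case letters when a lower-case letter follows (`"BCell"` ->
#' `"b cell"`); runs of capitals or digits otherwise stay together
#' (`"GM18507"` -> `"gm18507"`, `"BDCM"` -> `"bdcm"`).
#'
#' @param local_name Non-empty identifier text (namespace already removed).
#' @return Character vector of lower-case words.
#' @export
segment_identifier <- function(local_name) {
  if (length(local_name) != 1L || is.na(local_name) || !nzchar(local_name)) {
    stop("cannot segment an empty identifier", call. = FALSE)
  }
  x <- gsub("[_ ]+", " ", local_name)
  x <- gsub("(?<=[a-z0-9])(?=[A-Z])", " ", x, perl = TRUE)
  x <- gsub("(?<=[A-Z])(?=[A-Z][a-z])", " ", x, perl = TRUE)
  words <- strsplit(trimws(tolower(x)), " +")[[1]]
  words[nzchar(words)]
}

#' Segment a label into words
#'
#' Labels are split at spaces and underscores only; case, hyphens and
#' digits are preserved verbatim, so `"HeLa"` stays one word and
#' `"Ara-C-resistant murine leukemia"` yields three.
#'
#' @param label Non-empty label text.
#' @return Character vector of words.
#' @export
segment_label <- function(label) {
  if (length(label) != 1L || is.na(label) || !nzchar(label)) {
    stop("cannot segment an empty label", call. = FALSE)
  }
  words <- strsplit(trimws(label), "[_ ]+")[[1]]
  words[nzchar(words)]
}

# survey1-legacy behaviour: labels go through identifier segmentation too
.segment_label_legacy <- function(label) {
  segment_identifier(gsub(" ", "_", trimws(label)))
}

#' Pluralise a noun phrase
#'
#' Pluralises the final word only: consonant + `y` becomes `ies`; words
#' ending in `s`, `x`, `z`, `ch` or `sh` take `es`; a small irregular table
#' (man/men, woman/women, child/children, foot/feet, tooth/teeth,
#' mouse/mice, person/people) applies; anything else takes `s`.
#'
#' @param phrase Character vector of words (the singular form).
#' @return Character vector of words with the final word pluralised.
#' @export
pluralise <- function(phrase) {
  stopifnot(length(phrase) >= 1L)
  n <- length(phrase)
  w <- phrase[n]
  lw <- tolower(w)
  phrase[n] <- if (lw %in% names(.irregular_plurals)) {
    .irregular_plurals[[lw]]
  } else if (grepl("[^aeiou]y$", lw)) {
    paste0(substring(w, 1L, nchar(w) - 1L), "ies")
  } else if (grepl("(s|x|z|ch|sh)$", lw)) {
    paste0(w, "es")
  } else {
    paste0(w, "s")
  }
  phrase
}

#' Build one lexical entry from an entity kind and a word sequence
#'
#' Individuals become proper names (no plural); classes and datatypes
#' become common nouns with a regular plural; object and data properties
#' become transitive verbs. Property phrases are massaged so they can take
#' a subject and an object: `has X` becomes "has as X" / "have as X-pl";
#' `X of` (where the head of X does not end in `-s`) becomes "is X of" /
#' "are X-pl of"; any other phrase is used as is, with the plural verb
#' formed by stripping a trailing `s` from the first word ("derives from"
#' -> "derive from"; "has" -> "have").
#'
#' @param kind Entity kind: one of `"class"`, `"object-property"`,
#'   `"data-property"`, `"individual"`, `"datatype"`.
#' @param words Non-empty character vector of words.
#' @return A `lexical_entry`: list with `pos` (one of `"proper-name"`,
#'   `"common-noun"`, `"transitive-verb"`), `singular` and `plural` word
#'   vectors (`plural` is `NULL` for proper names).
#' @export
make_entry <- function(kind, words) {
  stopifnot(length(words) >= 1L, all(nzchar(words)))
  if (kind == "individual") {
    return(structure(list(pos = "proper-name", singular = words,
                          plural = NULL), class = "lexical_entry"))
  }
  if (kind %in% c("object-property", "data-property")) {
    n <- length(words)
    if (words[1] == "has" && n > 1L) {
      x <- words[-1]
      sg <- c("has", "as", x)
      pl <- c("have", "as", pluralise(x))
    } else if (words[n] == "of" && n > 1L &&
               !grepl("s$", words[n - 1L])) {
      x <- words[-n]
      sg <- c("is", x, "of")
      pl <- c("are", pluralise(x), "of")
    } else {
      sg <- words
      pl <- words
      pl[1] <- if (words[1] == "has") "have" else sub("s$", "", words[1])
    }
    return(structure(list(pos = "transitive-verb", singular = sg,
                          plural = pl), class = "lexical_entry"))
  }
  # classes, datatypes and anything else nominal
  structure(list(pos = "common-noun", singular = words,
                 plural = pluralise(words)), class = "lexical_entry")
}

#' Build the lexicon for a document
#'
#' Derives one lexical entry per atomic entity. An override entry (see
#' [read_lexicon()]) wins outright; otherwise a label, if present, is
#' segmented (preserving its internal case by default, or with
#' identifier-style capital splitting under the legacy style); otherwise
#' the identifier local name is segmented. Provenance is recorded per
#' entry.
#'
#' @param doc An `owl_document`.
#' @param overrides Optional named list of `lexical_entry` objects keyed by
#'   IRI, as returned by [read_lexicon()]. Overrides whose IRI does not
#'   occur in the document produce a warning and are ignored.
#' @param label_mode `"preserve"` (default) or `"split"` (legacy
#'   capital-splitting of labels).
#' @return An `owl_lexicon`: named list `entries` (IRI -> `lexical_entry`)
#'   plus a `provenance` character vector with values `"override"`,
#'   `"from-label"` or `"from-identifier"`.
#' @export
build_lexicon <- function(doc, overrides = NULL,
                          label_mode = c("preserve", "split")) {
  stopifnot(inherits(doc, "owl_document"))
  label_mode <- match.arg(label_mode)
  iris <- names(doc$entities)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), iris)
    if (length(unknown)) {
      warning("lexicon override for unknown IRI ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      overrides <- overrides[setdiff(names(overrides), unknown)]
    }
  }
  entries <- vector("list", length(iris))
  names(entries) <- iris
  provenance <- stats::setNames(character(length(iris)), iris)
  for (iri in iris) {
    ent <- doc$entities[[iri]]
    if (!is.null(overrides) && iri %in% names(overrides)) {
      entries[[iri]] <- overrides[[iri]]
      provenance[[iri]] <- "override"
    } else if (iri %in% names(doc$labels)) {
      words <- if (label_mode == "preserve") {
        segment_label(doc$labels[[iri]])
      } else {
        .segment_label_legacy(doc$labels[[iri]])
      }
      entries[[iri]] <- make_entry(ent$kind, words)
      provenance[[iri]] <- "from-label"
    } else {
      entries[[iri]] <- make_entry(ent$kind,
                                   segment_identifier(ent$local_name))
      provenance[[iri]] <- "from-identifier"
    }
  }
  structure(list(entries = entries, provenance = provenance),
            class = "owl_lexicon")
}

.lex_entry <- function(lexicon, iri) {
  e <- lexicon$entries[[iri]]
  if (is.null(e)) stop("no lexical entry for <", iri, ">", call. = FALSE)
  e
}

.lex_singular <- function(lexicon, iri) {
  paste(.lex_entry(lexicon, iri)$singular, collapse = " ")
}

.lex_plural <- function(lexicon, iri) {
  e <- .lex_entry(lexicon, iri)
  if (is.null(e$plural)) paste(e$singular, collapse = " ")
  else paste(e$plural, collapse = " ")
}

#' Read a lexicon override file
#'
#' Tab-separated UTF-8 file with four columns mirroring the lexical entry:
#' IRI, part of speech (`proper-name`, `common-noun` or `transitive-verb`),
#' singular form and plural form (empty allowed for proper names). Lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @return Named list of `lexical_entry` objects keyed by IRI, suitable for
#'   the `overrides` argument of [build_lexicon()].
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("malformed lexicon line (need >= 3 tab-separated fields): ", ln,
           call. = FALSE)
    }
    pos <- f[2]
    if (!pos %in% c("proper-name", "common-noun", "transitive-verb")) {
      stop("unknown part of speech '", pos, "' in lexicon line: ", ln,
           call. = FALSE)
    }
    plural <- if (length(f) >= 4L && nzchar(f[4])) {
      strsplit(f[4], " +")[[1]]
    } else NULL
    if (is.null(plural) && pos != "proper-name") {
      stop(pos, " entry requires a plural form: ", ln, call. = FALSE)
    }
    out[[f[1]]] <- structure(
      list(pos = pos, singular = strsplit(f[3], " +")[[1]], plural = plural),
      class = "lexical_entry")
  }
  out
}

#' Write a lexicon to a tab-separated file
#'
#' Dumps a lexicon in the override-file format of [read_lexicon()], so a
#' provisional machine-derived lexicon can be hand-edited and fed back in.
#'
#' @param lexicon An `owl_lexicon` (or a named list of `lexical_entry`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  entries <- if (inherits(lexicon, "owl_lexicon")) lexicon$entries else lexicon
  lines <- c("# IRI\tpos\tsingular\tplural")
  for (iri in names(entries)) {
    e <- entries[[iri]]
    lines <- c(lines, paste(
      iri, e$pos, paste(e$singular, collapse = " "),
      if (is.null(e$plural)) "" else paste(e$plural, collapse = " "),
      sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.owl_lexicon <- function(x, ...) {
  cat(sprintf("<owl_lexicon: %d entries (%s)>\n", length(x$entries),
              paste(sprintf("%s %d", names(table(x$provenance)),
                            as.integer(table(x$provenance))),
                    collapse = ", ")))
  invisible(x)
}
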