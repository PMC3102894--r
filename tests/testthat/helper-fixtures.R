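# Shared fixtures and independent oracles.

EX <- "http://example.org/x#"

ofn_doc <- function(...) {
  paste(c(sprintf("Prefix(:=<%s>)", EX),
          "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
          ...),
        collapse = "\n")
}

survey2_path <- function() {
  system.file("extdata", "survey2_cell_lines.ofn", package = "ontoverb",
              mustWork = TRUE)
}
survey1_path <- function() {
  system.file("extdata", "survey1_cell_lines.ofn", package = "ontoverb",
              mustWork = TRUE)
}

# the survey-1 22rv1 axiom set (shared by planner and realiser tests)
fixture_22rv1 <- function() {
  ofn_doc(
    "SubClassOf(:22rv1 :cell_line)",
    "SubClassOf(:22rv1 ObjectSomeValuesFrom(:bearer_of :prostate_carcinoma))",
    "SubClassOf(:22rv1 ObjectSomeValuesFrom(:derives_from :HomoSapiens))",
    "SubClassOf(:22rv1 ObjectSomeValuesFrom(:derives_from :prostate))"
  )
}

# Independent oracle: the IRIs occurring as top-level arguments of a
# rendered functional-syntax axiom, found by bracket-depth scanning of the
# serialised text (no use of the term model's accessors).
oracle_top_level_iris <- function(rendered) {
  chars <- strsplit(rendered, "", fixed = TRUE)[[1]]
  depth <- 0L
  iris <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "<" && depth == 1L) {
      j <- i
      while (chars[j] != ">") j <- j + 1L
      iris <- c(iris, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j
    } else if (ch == "\"") {
      j <- i + 1L
      while (chars[j] != "\"" || chars[j - 1L] == "\\") j <- j + 1L
      i <- j
    }
    i <- i + 1L
  }
  unique(iris)
}

# flatten a plan entry's units back to member axioms
flatten_units <- function(units) {
  out <- list()
  for (u in units) {
    ms <- if (u$kind == "single") list(u$axiom) else u$members
    out <- c(out, ms)
  }
  out
}
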