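# ontoverb

`ontoverb` turns the logical axioms of an OWL ontology into an English
glossary: one coherent paragraph of text definition per class, property or
individual. It is aimed at ontology developers — particularly in the
biomedical space, where textual definitions are an OBO Foundry criterion —
whose logical axiomatisation runs ahead of their hand-written definitions.

## What it does

For each atomic entity the pipeline

1. parses OWL Functional Syntax into a term model (one functor/argument
   tree per axiom; `rdfs:label` annotations feed a label table);
2. derives a lexical entry — part of speech, singular, plural — from the
   entity's label or, failing that, its identifier (`partOf` → *part of*,
   `derives_from` → "derives from" / "derive from", `has part` →
   "has as part" / "have as parts");
3. selects the axioms in which the entity occurs as a top-level argument
   (both `A ⊑ B` and the superclass side, which becomes a subclass
   listing);
4. aggregates axioms that share a pattern and differ in exactly one
   constituent of the same kind, e.g. three restriction superclasses
   `A ⊑ ∃p.C₁`, `A ⊑ ∃p.C₂`, `A ⊑ ∃q.C₃` merge into one list-valued
   sentence;
5. realises each (possibly aggregated) unit through a pattern-indexed
   grammar — `SubClassOf` → "A S is a D.", `EquivalentClasses` → "A S is
   defined as …", `DisjointClasses` → "No S is …" — and emits any
   uncovered construct verbatim in OWL Functional Syntax as a fallback
   sentence.

Entries are ordered alphabetically by English name (case-insensitive,
digits first) and the whole run is byte-deterministic.

## Worked example

The packaged fixture `survey2_cell_lines.ofn` transcribes a set of EFO
cell-line and disease class axioms:

```r
library(ontoverb)
g <- verbalise(system.file("extdata", "survey2_cell_lines.ofn",
                           package = "ontoverb"))
cat(entity_paragraph(g, "HeLa"))
#> A HeLa is all of the following: something that is bearer of a cervical
#> carcinoma, something that derives from a Homo sapiens, something that
#> derives from an epithelial cell, and something that derives from a
#> cervix. A HeLa is a cell line.
cat(entity_paragraph(g, "genetic disorder"))
#> A genetic disorder is a disease. No genetic disorder is any of the
#> following: a normal or an uninfected.
```

The HeLa paragraph shows aggregation (four restriction axioms in one
"all of the following" list, the plain subclass axiom kept separate) and
label-preserving lexicalisation ("HeLa", "Homo sapiens"). `mode = "flat"`
disables aggregation (one sentence per axiom); `style = "survey1-legacy"`
reproduces the older capital-splitting behaviour ("A he la is a cell
line."); `style = "vp-first"` coordinates verb phrases instead of
"something that" noun phrases. `write_lexicon()` dumps the derived
lexicon for hand editing; overrides are fed back with the `overrides`
argument or `--lexicon-in`.

From a shell:

```sh
Rscript inst/cli/verbalise.R --input efo.ofn --output efo-glossary.txt \
    --style survey2 --mode grouped --lexicon-out lexicon.tsv \
    --pattern-stats patterns.tsv
Rscript inst/cli/make-fixture.R --seed 42 --out synthetic.ofn
```

`--pattern-stats` writes an axiom-pattern frequency table (patterns with
entities replaced by `□`); `--entity NAME` prints one paragraph.

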