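---
title: "Verbalising OWL ontologies as English glossaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verbalising OWL ontologies as English glossaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoverb)
```

## The task

Bio-ontologies such as the Experimental Factor Ontology carry rich logical
descriptions of their classes — subclass axioms, existential restrictions
(`p some C`), equivalences, disjointness — while human-readable text
definitions often lag behind. `ontoverb` generates those text definitions
automatically: for every atomic entity it collects the axioms that describe
it, merges axioms that share a structural pattern, and realises each group
as one English sentence, assembling the sentences into a paragraph and the
paragraphs into an alphabetical glossary. The output is deterministic: the
same ontology, lexicon and options always produce byte-identical text.

The pipeline has five phases, each exposed as ordinary functions so any
intermediate object can be inspected:

1. **Parsing** (`parse_ontology()`): OWL Functional Syntax is read into a
   term model in which each axiom is one functor-plus-arguments tree.
   Prefixes, declarations and annotations are not axioms; `rdfs:label`
   assertions are routed into a label table (first label per entity wins).
2. **Lexicon construction** (`build_lexicon()`): one lexical entry —
   part of speech, singular and plural form — per atomic entity, derived
   from its label (preferred) or identifier.
3. **Selection** (`select_axioms()`): the axioms describing an entity are
   those in which it occurs as a top-level argument of the axiom functor.
4. **Aggregation** (`aggregate_axioms()`): axioms sharing a pattern and
   differing in exactly one constituent merge into one list-valued unit.
5. **Realisation** (`realise_unit()`, `generate_glossary()`): a grammar
   keyed on logical patterns turns each unit into a sentence, consulting
   the lexicon for atomic entities; anything the grammar does not cover is
   emitted verbatim in functional syntax.

## The lexicon

Individuals are realised as proper names, classes as common nouns with
singular and plural forms, and properties as transitive verbs with subject
and object slots. The raw material is the entity's name, and the two name
sources are segmented differently:

* **Identifiers** use underscores and capital letters as word boundaries
  and are lower-cased: `partOf` → *part of*, `derives_from` → *derives
  from*. A camel-case boundary falls before an upper-case letter that
  follows a lower-case letter or digit, and between two capitals when a
  lower-case letter follows; an unbroken run of capitals or digits stays
  together. So `HeLa` → *he la* and `BCell` → *b cell*, but `BDCM` →
  *bdcm* and `GM18507` → *gm18507*. The simpler "split before every
  capital" rule would shatter acronyms (*b d c m*), which is visibly not
  what glossaries want.
* **Labels** are split only at spaces and underscores, preserving internal
  case, hyphens and digits: the label `HeLa` stays *HeLa*, and
  `Ara-C-resistant murine leukemia` keeps its hyphenated first word. The
  legacy `survey1-legacy` style (below) instead pushes labels through the
  identifier rule, reproducing the older *he la* behaviour.

Property phrases are massaged into verb forms by two patterns: *has X*
becomes "has as X" / "have as X-plural" (*has part* → "has as part" /
"have as parts"), and *X of* — when the head of X does not end in *-s*,
i.e. is not already a present-tense verb — becomes "is X of" / "are
X-plural of" (*part of* → "is part of" / "are parts of"). Anything else is
used as is, with the plural verb formed by stripping a trailing *s* from
the first word ("derives from" → "derive from"). Pluralisation handles
consonant-*y* (*quality* → *qualities*), sibilant endings (+*es*), and a
small irregular table (man, woman, child, foot, tooth, mouse, person);
everything else takes *s*. Latin binomials get the regular rule
(*Homo sapienses* would be produced if a plural were ever needed); no
plural of a binomial occurs in any output we generate, so no special rule
is warranted. The derived lexicon can be dumped with `write_lexicon()`,
hand-edited, and fed back via `read_lexicon()`; override entries win
outright.

Two entities may share an English name; the glossary keeps both entries
and disambiguates only the header line by appending the identifier local
name in parentheses, so paragraph text stays fluent and output order stays
deterministic.

## Selection and aggregation

"Describing an entity" means occurring as a direct argument of the axiom
functor, where for class-expression arguments only an atomic expression
counts. An entity buried inside a restriction filler is not a subject of
that axiom: `SubClassOf(HeLa, derives_from some cervix)` describes HeLa,
not cervix. One axiom can describe several entities — a subclass axiom is
selected for both sides, so `SubClassOf(B117H, AraC)` yields "A B117H is
an Ara-C-resistant murine leukemia." under B117H and contributes to the
subclass listing "B117Hs, and B140Hs are Ara-C-resistant murine
leukemias." under the superclass. Axioms with no top-level atomic argument
belong to no entry; they are reported as orphaned.

Aggregation is greedy in source order: a unit opens with the earliest
unmerged axiom, and a later axiom joins it iff both share functor and
arity, their trees differ at exactly one argument position (the same
position for every member), and the two differing constituents are of the
same top-level kind — both atomic, or both complex expressions. The kind
requirement is what keeps "A 22rv1 is a cell line." as its own sentence
while the three restriction superclasses merge into one "all of the
following" list: the atomic superclass differs from a restriction in the
same argument position, but not in kind. Groups are maximal and no
optimal-grouping search is attempted; with no ordering heuristics beyond
source order, greedy grouping is the only deterministic choice that
reproduces the worked outputs. Expanding an aggregated unit (substituting
each filler back into the hole) regenerates its member axioms exactly —
this soundness property is enforced by the test suite against a
serialisation-based oracle that re-derives top-level arguments by bracket
matching on the rendered functional syntax.

Unsupported-functor axioms never merge: they are rendered verbatim, and
merging them would have to invent a list syntax for constructs the grammar
does not know.

## Realisation

Sentence templates are fixed by pattern; list punctuation is deliberate
and inconsistent between constructs because the target output is:
noun-phrase lists use commas with ", and " before the last item even for
two items ("both X, and Y"), disjointness lists use " or " with no commas,
and subclass listings use ", and ". The indefinite article is "an" iff the
phrase's first character, case-folded, is a vowel letter — digits and
consonants take "a" ("a 4470", "an Ara-C-resistant murine leukemia").
Sentence-initial capitalisation touches only the first character, so
label-internal case like "B117Hs" survives.

A lone restriction axiom is realised with the verb phrase directly — "An
Ara-C-resistant murine leukemia derives from a Mus musculus." — in every
style; the "something that" wrapper appears only where a restriction must
serve as a noun phrase, i.e. inside aggregation lists, equivalence objects
and assertion objects. Aggregated restriction lists under the default
style read "A S is both something that …, and something that …" (two
members) or "A S is all of the following: …" (three or more); the
`vp-first` style instead coordinates verb phrases ("A HeLa is bearer of a
cervical carcinoma, derives from a Homo sapiens, …"), trading a little
uniformity for less repetition of *something*. Equivalences read "A C is
defined as NP"; disjointness reads "No S is a D." or "No S is any of the
following: a D1 or a D2."; class assertions read "Name is a C."

Three style profiles bundle these choices: `survey2` (default:
label-preserving lexicalisation, plural-subject subclass listings),
`survey1-legacy` (capital-splitting labels, "A x, and a y are kinds of
z-plural." listings — kept to reproduce the older output style), and
`vp-first` (survey2 plus the verb-phrase-first aggregation rule).

Everything else falls back: the sentence is the axiom's canonical
functional-syntax serialisation, flagged so callers can count or filter
fallbacks. Individual-level property assertions and property-hierarchy
axioms are parsed into the term model (they participate in pattern
statistics and round-trip serialisation) but are also realised via the
fallback — no printed example anchors an English wording for them, and a
wrong guess is worse than a transparent formula. Enumerations
(`ObjectOneOf`), complements and inverse-property constructs likewise fall
back, mirroring the coverage boundary of the system the package models.

## Degenerate inputs and numerical choices

Empty documents produce empty glossaries. Duplicate axioms stay separate
units (they differ in zero positions, and merging requires exactly one).
Undeclared entities take their kind from axiom position (restriction
property → object property, assertion second argument → individual,
otherwise class). Multiple `rdfs:label`s keep the first in file order.
Entry order uses byte-wise comparison of the lower-cased English name, so
digits sort before letters and case is ignored; this collation is fixed,
not locale-dependent, to keep output byte-stable across machines. There
are no tolerances anywhere: every computation is exact string and tree
manipulation.

## The synthetic generator

`generate_fixture()` emulates the shape of an application bio-ontology for
property-based testing: a pool of classes, properties and individuals
named under a mix of conventions (CamelCase, under_scores, spaced labels,
hyphenated names, Latin binomials, alphanumeric codes like `B117H`), a
configurable fraction of entities left unlabelled so the identifier path
is exercised, and axioms drawn from a pattern mix covering every supported
functor plus a fraction of unsupported ones (property characteristics,
disjoint unions) whose top-level arguments are atomic, so they surface as
fallback sentences in some entity's entry. Output is a functional-syntax
document, identical for identical parameters and seed; the generator
restores the caller's RNG state.

The defaults (30 classes, 6 properties, 6 individuals, 60 axioms, 70%
labelled, ~5% unsupported) give small, dense documents in which most
entities attract several axioms — the regime where aggregation actually
fires. What the generator does **not** emulate: real annotation practice
(synonyms, curation metadata), imports, anonymous individuals, data
ranges, or the skewed degree distributions of real ontologies where a few
upper-level classes dominate. Passing the property suites therefore shows
the pipeline's invariants hold over diverse well-formed inputs, not that
real-ontology text will read well; the byte-exact worked examples carry
that burden.

The invariant suites run on 200 generated ontologies of 25–1000 axioms
(the acceptance script uses 98, plus one 3000-axiom document for the scale
check); these sizes keep the whole suite comfortably fast while covering
two orders of magnitude in document size.

## Known limitations

* Lexicon inference is rule-based with no dictionary or part-of-speech
  analysis; a class whose label is a verb phrase will be treated as a
  noun.
* The only annotation property consulted is `rdfs:label`; ontologies
  using bespoke label properties need a hand-edited lexicon file.
* No reasoning: the glossary contains inferred statements only if they
  are already asserted in the input.
* Sentence order within a paragraph is source order; no discourse
  planning or sub-heading grouping is attempted.
* No elision ("a medial or lateral geniculate nucleus") and no
  alternative property wordings ("bears", "carries") beyond the override
  lexicon.
* RDF/XML input is out of scope; convert to functional syntax first (any
  OWL API-based tool can do this).
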