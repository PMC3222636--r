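---
title: "Meta-knowledge annotation of bio-events: model, tagger, statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-knowledge annotation of bio-events: model, tagger, statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamk)
```

## The scheme

A bio-event — trigger span, event type, role-labelled participants — is a
proposition whose interpretation depends on its textual context. `metamk`
models that context as five mutually exclusive, complete dimensions
attached to every event:

* **KT** (Knowledge Type): `Investigation`, `Observation`, `Analysis`,
  `Method`, `Fact`, or the default `Other` (events with no independent
  interpretation, typically nested participant events).
* **CL** (Certainty Level): a three-point scale. `L3` (default) means no
  expressed uncertainty; `L2` slight hedging or "frequently but not
  always"; `L1` considerable speculation or rare occurrence. The scheme
  intends CL for `Analysis` events; the model nevertheless *permits*
  non-`L3` values elsewhere and downgrades them to a validation warning,
  because real annotations contain a handful of such events.
* **Polarity**: `Positive` (default) or `Negative` — the event is denied,
  absent, or non-existent.
* **Manner**: `High`, `Low`, or `Neutral` (default) — expressed rate,
  level, strength or intensity.
* **Source**: `Current` study (default) or `Other` (previous work).

Every non-default value the scheme ties to lexical evidence must carry at
least one **clue span**: `Analysis` and `Investigation` KT values, any
non-`L3` CL, `Negative` polarity, and explicit `High`/`Low` manner.
`Observation` and `Fact` clues are optional (in practice only ~7% and ~5%
of such events have one); `Method` is signalled by the trigger word itself
(an experimental-method verb), and `Source = Other` clues are typical but
not mandated. `validate_corpus()` enforces exactly this contract, plus
structural sanity (0-based half-open character spans inside the document,
ordered non-overlapping sentences, unique ids, resolvable acyclic
participant references). Offsets are character-based over the UTF-8-decoded
text; the convention is fixed here because serialized corpora must
round-trip bit-exactly.

Two **hyper-dimensions** are derived, never stored, so they can never
drift out of sync with the annotated values:

* New Knowledge: `source == Current & kt %in% c(Observation, Analysis) & cl == L3`
* Hypothesis: `kt == Investigation | (kt == Analysis & cl %in% c(L1, L2))`

Both exist in two forms: ordered wildcard rule tables
(`new_knowledge_rules()`, `hypothesis_rules()`; `"X"` matches anything,
first match wins) and the closed-form predicates above. The tables are the
authoritative implementation; the predicates are the simplification, and
the test suite proves the two agree on all 2 × 6 × 3 = 36 value
combinations and that no combination is both new knowledge and hypothesis.
Keeping both guards against transcription drift in either form.

## Serialization

Two dialects, both deterministic (canonical row order, fixed attribute
order, LF newlines — repeated writes are byte-identical):

* `genia_mk_xml` — a compact GENIA-style XML dialect with `<document>`,
  `<text>`, `<sentence>`, `<term>`, `<event>` (five optional dimension
  attributes defaulting to the scheme defaults), nested `<participant>`
  and `<clue>` elements. Clues are child elements rather than attributes
  so one event can carry several spans per dimension.
* `event_jsonl` — one document per line as a JSON object mirroring the
  model; numeric offsets only.

The reader is tolerant of unknown elements and attributes (skipped with a
warning) but strict about category labels and span bounds — an unknown
`cl="L4"` or an out-of-range span is a parse error naming the document,
because silently coercing annotation categories corrupts statistics
downstream. Readers accept scheme-invalid annotation (so that `metamk
validate` can report on it); the writer refuses to emit a corpus whose
validation report contains errors. Hyper-dimension values are never
serialized.

## The clue lexicon and baseline tagger

The packaged lexicon (`inst/extdata/clue_lexicon.tsv`, ~145 entries) lists
the most common clue expressions per dimension value: analysis verbs
(*suggest*, *demonstrate*, *revealed*, *thus*), investigation markers
(*examined*, *to determine*), observation verbs (*found*, *observed*,
*detectable*), *known* for facts, hedges for L2 (*can*, *likely*,
*normally*) and L1 (*may*, *might*, *perhaps*, *rarely*), negation cues
(*not*, *no*, *without*, *failed*), degree expressions for manner
(*significantly*, *markedly* / *partially*, *weakly*, *no significant*)
including numeral patterns (`{NUM}-fold` is High; `{NUM}-fold lower` Low),
and attribution cues (*previously*, *has been*, *previous studies*). Three
design points deserve comment:

* **Dual-role cues.** *suggest* and *indicate* simultaneously express
  analysis and slight speculation; *may* expresses analysis and L1. They
  appear once per dimension they license, and one matched span may be
  recorded as the clue for two dimensions.
* **Event-type conditions.** *independent(ly)* denotes negation only for
  `Correlation`/`Regulation`/`Positive_Regulation` events; *normal* and
  *silent* negate only in contrast to `Negative_Regulation` /
  `Positive_Regulation` events. Conditioned entries are inert on any other
  event type.
* **Editability.** The lexicon is a documented TSV; annotation clue lists
  grow in practice, and users are expected to extend it. The file is
  validated on load (legal values, no duplicate pattern–dimension pairs,
  patterns must assign non-default values).

Matching (`match_clues()`) is case-insensitive, whole-word, left to right.
A match strictly contained in a longer match is suppressed *across*
dimensions: in *"had no significant influence"*, the Low-manner cue *no
significant* silences both the *no* negation cue and the *significant*
high-manner cue — negating an intensifier lowers intensity, it does not
negate the event.

`tag_corpus()` assigns meta-knowledge from scratch: clue–trigger linking
scope is the **trigger's sentence** (cross-sentence links need grammatical
analysis beyond a lexicon baseline and are out of scope). Per dimension,
precedence is: longer match over contained shorter match, then entry
priority, then proximity to the trigger, then leftmost. The proximity
tie-break is this package's decision — the scheme itself does not define
how to choose between two same-dimension cues with different values in one
sentence — and it is what makes worked examples like *"... suggested a
less important ROLE in the rapid production of IL-8"* come out `Low`
rather than `High`. An optional tense heuristic (off by default, because
tense is a typical correlate of `Observation`/`Fact`, not part of their
definition) fills clue-free KT from trigger morphology: *-ed* triggers
become `Observation`, present-tense triggers of concrete process types
become `Fact`. The tagger's output always satisfies the validation
contract, and because it reads only document text, it is idempotent.

Known limitations, by construction: no syntactic scope resolution (a clue
anywhere in the sentence can win), no cross-sentence linking, no semantic
disambiguation of polysemous cues. These are the cases the scheme's
human-annotation discussion flags as hard even for people.

## Statistics

`dimension_distribution()`, `kt_cross_tab()`, `clue_frequency()` and
`hyperdim_distribution()` recompute the standard corpus summary tables.
All percentages flow through one function, `mk_round_pct()`: round half
up, one decimal. This choice reproduces the vast majority of the reference
tables' printed ratios; a few printed cells (e.g. 12821/36858 printed as
34.7% where half-up gives 34.8%) are internally inconsistent with the
others — they appear truncated — and no single rule reproduces every cell,
so the package documents half-up and applies it uniformly rather than
chasing individual cells. Zero-count categories are always listed (no
category of the scheme is redundant), and empty denominators are reported
as 0 with an explicit flag rather than NaN.

## Inter-annotator agreement

`per_dimension_agreement()` aligns two annotations of the same documents
(by event id, falling back to unique (trigger span, event type) matches;
events present in only one annotation are excluded from kappa but
reported) and computes **unweighted Cohen's kappa** per dimension:
`kappa = (p_o - p_e) / (1 - p_e)` with `p_e` the product-of-marginals
chance agreement. Unweighted, because the reference evaluation reports a
single kappa per dimension and ignores CL's ordinal structure; clue-span
disagreements with identical category values are not counted as
disagreements. Degenerate cases follow an explicit contract: `p_o = p_e =
1` is kappa 1; `p_e = 1` with `p_o < 1` is undefined and flagged rather
than invented. The published per-dimension kappas themselves (0.84–0.93)
require the two annotators' raw double annotations, which are not
redistributable; the package instead verifies kappa on hand-computable
contingency fixtures and on generator-produced annotator pairs whose
expected kappa is known in closed form from the confusion matrix.

## The synthetic-corpus generator

`generate_corpus()` exists to provide ground truth. Its defaults
(`default_corpus_spec()`) are the reference corpus's published conditions:
1000 documents averaging 36.858 events; the KT marginal
(Observation .348, Other .313, Analysis .178, Fact .081, Investigation
.053, Method .026); certainty confined to Analysis events (33.7% L2,
11.6% L1 of analyses); per-KT negation rates (10.6% of observations down
to ~1% of methods); per-KT explicit-manner rates with an 81% High share;
and a 1.5% `Source = Other` marginal. Where a clue is optional the
insertion probabilities default to the published coverage (7.3% of
Observation, 4.6% of Fact events).

Sentences are template-built — `"PROT1 [clues] activated GENE2 ."` with
placeholder entity names — because the generator's job is textual
*validity* of spans and a recoverable signal, not linguistic realism.
Consequences for interpretation: passing tagger tests on generated corpora
demonstrates correct span bookkeeping, clue linking, precedence and
conditioning, **not** performance on real prose, which has scope
ambiguity, long-distance links and polysemous cues the generator never
produces. Clue words inserted for an event are chosen so that every
lexicon role of the word matches the event's truth (a dual-role cue like
*suggest* is only used when the event is a hedged analysis), and the
curated insertion vocabulary avoids words that could concatenate with a
neighbour into a longer lexicon pattern; distractor sentences, when
enabled, dump clue words into an event-free sentence to verify the
sentence-scope property. Ground truth is returned in a sidecar tibble, so
re-tagging the corpus cannot overwrite it. A single random stream per call
is derived from the seed; identical (spec, seed) give byte-identical
serialized corpora.

`perturb_annotations()` emulates a second annotator with known error
rates: per-dimension confusion matrices relabel each event independently;
clue spans are dropped when a value becomes default and a suitable clue
word is spliced into the trigger's sentence (shifting all downstream
spans) when a value becomes non-default, so perturbed corpora remain
valid.

## Problem sizes and numerical choices

The test suite checks convergence properties at sizes chosen to make
binomial noise negligible relative to the asserted tolerances: marginal
fidelity at ~50,000 events against a 1% band (binomial 4-sigma for the
largest category is ~0.9%), kappa recovery at ~20,000 event pairs against
a 3-sigma band derived from the flip rate, serialization round-trips over
200 fuzzed corpora, and exact (1e-12) agreement for the closed-form kappa
fixtures. Probability vectors must sum to 1 within 1e-9; the percentage
rounding epsilon (1e-9) guards against binary-float representations of
exact halves. Ties in the tagger are broken deterministically (priority,
proximity, leftmost), so identical inputs always produce identical output.

## Scope

Out of scope, deliberately: machine-learned tagging, syntactic parsing and
scope resolution, Fleiss' kappa for more than two annotators, span-level
agreement on clue extents, modelling of the event-type ontology hierarchy,
and generation of linguistically realistic abstracts.
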