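# metamk

Multi-dimensional meta-knowledge annotation for biomedical event corpora.

## The problem

Event-annotated biomedical corpora represent facts and findings as
structured *bio-events*: a trigger phrase, an ontological event type, and
role-labelled participants (Theme, Cause). The event structure alone does
not say *how* a statement should be interpreted: is it an established fact,
a direct experimental observation, a speculative analysis, a planned
investigation? Is it negated? Stated at high or low intensity? Attributed
to the current study or to earlier work? This interpretative layer —
*meta-knowledge* — is what separates database-curatable new findings from
hypotheses and background citations.

`metamk` implements a five-dimension event-level meta-knowledge scheme and
the machinery around it, for corpus builders and text-mining researchers
who need to create, check, analyse or simulate such annotations:

| Dimension | Values (default first) | Marks |
|---|---|---|
| KT (Knowledge Type) | Other, Observation, Analysis, Fact, Investigation, Method | general information content |
| CL (Certainty Level) | L3, L2, L1 | expressed (un)certainty / frequency |
| Polarity | Positive, Negative | explicit negation |
| Manner | Neutral, High, Low | rate / strength / intensity |
| Source | Current, Other | attribution to current vs. previous work |

Non-default values are licensed by *clue expressions* in the event's
context (*suggest*, *not*, *partially*, *previously*, ...), which are
annotated as text spans alongside the category values.

Two boolean **hyper-dimensions** are derived — never stored — from the
annotated values:

```
NewKnowledge(source, kt, cl) = (source = Current) ∧ (kt ∈ {Observation, Analysis}) ∧ (cl = L3)
Hypothesis(kt, cl)           = (kt = Investigation) ∨ (kt = Analysis ∧ cl ∈ {L1, L2})
```

The package provides:

* a tidy stand-off data model (`mk_corpus`: tibbles for documents,
  sentences, entities, events, participants, clue spans) with scheme
  validation (`validate_corpus()`);
* readers/writers for a GENIA-style XML dialect and a JSON-lines
  interchange format (`read_corpus()` / `write_corpus()`, byte-stable
  output);
* hyper-dimension inference as both rule tables and closed-form predicates
  (`infer_new_knowledge()`, `infer_hypothesis()`,
  `infer_hyperdimensions()`);
* a packaged clue lexicon plus a rule-based baseline tagger
  (`default_clue_lexicon()`, `match_clues()`, `tag_corpus()`);
* corpus statistics (`dimension_distribution()`, `kt_cross_tab()`,
  `clue_frequency()`, `hyperdim_distribution()`);
* inter-annotator agreement with Cohen's kappa and discrepancy reports
  (`per_dimension_agreement()`, with `tidy()`/`glance()`/`autoplot()`);
* a seeded synthetic-corpus generator with ground truth
  (`generate_corpus()`, `perturb_annotations()`) for testing taggers and
  agreement pipelines;
* a command-line interface (`exec/metamk`) wrapping all of the above.

## Worked example

```r
library(metamk)

corp <- mk_corpus(
  documents = tibble::tibble(
    doc_id = "d1",
    text = "The results suggest that the narL gene product activates the nitrate reductase operon ."),
  sentences = tibble::tibble(doc_id = "d1", start = 0L, end = 87L),
  events = tibble::tibble(doc_id = "d1", event_id = "E1",
                          event_type = "Positive_Regulation",
                          trigger_start = 47L, trigger_end = 56L)
)

tagged <- tag_corpus(corp)
tagged$events[, c("event_id", "kt", "cl", "polarity", "manner", "source")]
#> # A tibble: 1 × 6
#>   event_id kt       cl    polarity manner  source
#>   <chr>    <chr>    <chr> <chr>    <chr>   <chr>
#> 1 E1       Analysis L2    Positive Neutral Current

infer_hyperdimensions(tagged)[, c("event_id", "new_knowledge", "hypothesis")]
#> # A tibble: 1 × 3
#>   event_id new_knowledge hypothesis
#>   <chr>    <lgl>         <lgl>
#> 1 E1       FALSE         TRUE
```

The hedging verb *suggest* licenses both `KT = Analysis` and `CL = L2` from
a single clue span, so the event is a hedged analysis — a hypothesis, not
yet new knowledge.

Simulation and agreement in three lines:

```r
sim  <- generate_corpus(mk_generation_spec(n_documents = 50), seed = 1)
flip <- matrix(c(.95, .05, .05, .95), 2, byrow = TRUE,
               dimnames = rep(list(c("Positive", "Negative")), 2))
tidy(per_dimension_agreement(sim$corpus,
                             perturb_annotations(sim, list(Polarity = flip),
                                                 seed = 2)))
```

## Command line

```sh
metamk simulate --seed 7 --documents 20 --out corpus.xml
metamk validate --input corpus.xml
metamk tag      --input corpus.xml --out tagged.xml
metamk stats    --input corpus.xml --report hyperdims
metamk agree    --a ann1.xml --b ann2.xml
```

Exit codes: 0 success, 1 validation errors found, 2 usage errors.

## Documentation

The methods vignette (`vignettes/meta-knowledge-annotation.Rmd`) describes
the scheme, the tagger's linking and precedence rules, the generator's
distributions, and the package's numerical conventions and limitations.
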