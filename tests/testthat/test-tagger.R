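# The classic bio-event example sentences around "the narL gene product
# activates the nitrate reductase operon", plus harder negation/manner
# interaction cases.

tag1 <- function(sentences, trigger, type = "Positive_Regulation",
                 sentence = 1, ...) {
  corp <- one_doc_corpus(sentences,
                         list(list(event_id = "E1", trigger = trigger,
                                   type = type, sentence = sentence)))
  tag_event(corp, "d1", "E1", ...)
}

test_that("hedged analysis: 'suggest' sets both KT and CL from one clue", {
  r <- tag1(paste("The results suggest that the narL gene product",
                  "activates the nitrate reductase operon ."), "activates")
  expect_identical(r$mk$kt, "Analysis")
  expect_identical(r$mk$cl, "L2")
  expect_identical(r$mk$polarity, "Positive")
  expect_identical(r$mk$manner, "Neutral")
  expect_identical(r$mk$source, "Current")
  # both dimensions point at the same clue span
  expect_identical(nrow(r$clues), 2L)
  expect_identical(unique(r$clues$start), r$clues$start[1])
})

test_that("negated event: 'not' flips Polarity only", {
  r <- tag1(paste("The narL gene product did not activate the nitrate",
                  "reductase operon ."), "activate")
  expect_identical(r$mk$polarity, "Negative")
  expect_identical(r$mk$manner, "Neutral")
  expect_identical(r$mk$kt, "Other")
})

test_that("'partially' marks Low manner without negating", {
  r <- tag1(paste("The narL gene product partially activated the nitrate",
                  "reductase operon ."), "activated")
  expect_identical(r$mk$manner, "Low")
  expect_identical(r$mk$polarity, "Positive")
})

test_that("low-impact event is Low manner, not Negative (clause-scoped)", {
  sents <- c(paste("AP-1 but not NF-IL-6 DNA binding activity was also",
                   "detected in C5a-stimulated PBMC ;"),
             paste("however , its delayed expression ( maximal at 4 hours )",
                   "suggested a less important role in the rapid production",
                   "of IL-8 ."))
  r <- tag1(sents, trigger = "role", sentence = 2)
  expect_identical(r$mk$manner, "Low")
  expect_identical(r$mk$polarity, "Positive")
})

test_that("'independent' negates only correlation/regulation events", {
  sent <- paste("An alteration in the E2F-4 profile was independent of",
                "viral gene expression .")
  r <- tag1(sent, trigger = "independent", type = "Regulation")
  expect_identical(r$mk$polarity, "Negative")
  r <- tag1(sent, trigger = "independent", type = "Correlation")
  expect_identical(r$mk$polarity, "Negative")
  # outside the condition set the cue is inert
  r <- tag1(sent, trigger = "expression", type = "Gene_Expression")
  expect_identical(r$mk$polarity, "Positive")
})

test_that("'no significant' yields Low manner and leaves polarity positive", {
  r <- tag1(paste("Changes of any cysteine residue of the hRAR alpha-LBD",
                  "had no significant influence on the binding of",
                  "all-trans RA or 9-cis RA ."),
            trigger = "influence", type = "Regulation")
  expect_identical(r$mk$manner, "Low")
  expect_identical(r$mk$polarity, "Positive")
})

test_that("clue-free sentences and triggerless events give all defaults", {
  r <- tag1("PROT1 activated GENE2 .", "activated")
  expect_identical(as.list(r$mk), as.list(default_metaknowledge()))
  corp <- one_doc_corpus("PROT1 activated GENE2 .",
                         list(list(event_id = "E1")))
  r <- tag_event(corp, "d1", "E1")
  expect_identical(as.list(r$mk), as.list(default_metaknowledge()))
  expect_identical(nrow(r$clues), 0L)
})

test_that("tense heuristic is off by default and only fills clue-free KT", {
  r <- tag1("PROT1 activated GENE2 .", "activated")
  expect_identical(r$mk$kt, "Other")
  r <- tag1("PROT1 activated GENE2 .", "activated", tense_heuristic = TRUE)
  expect_identical(r$mk$kt, "Observation")
  r <- tag1("PROT1 expresses GENE2 .", "expresses", type = "Gene_Expression",
            tense_heuristic = TRUE)
  expect_identical(r$mk$kt, "Fact")
  # an explicit clue always beats the heuristic
  r <- tag1("The results suggest PROT1 activated GENE2 .", "activated",
            tense_heuristic = TRUE)
  expect_identical(r$mk$kt, "Analysis")
})

test_that("per-dimension ties break by proximity to the trigger", {
  # "strongly" (High) is nearer the trigger than "weakly" (Low)
  r <- tag1("GENE2 was weakly transcribed but PROT1 strongly bound GENE3 .",
            trigger = "bound", type = "Binding")
  expect_identical(r$mk$manner, "High")
})

test_that("tag_corpus re-tags every event, is pure and idempotent", {
  sim <- small_sim(seed = 11, n_documents = 6, events_per_doc = 5,
                   kt_optional_clue_prob = c(Observation = 1, Fact = 1))
  before <- sim$corpus$events
  tagged <- tag_corpus(sim$corpus)
  expect_identical(sim$corpus$events, before)  # input untouched
  expect_identical(nrow(tagged$events), nrow(before))
  twice <- tag_corpus(tagged)
  expect_true(corpus_equal(tagged, twice))
  expect_identical(nrow(tag_corpus(mk_corpus())$events), 0L)
  # tagger output must itself satisfy the scheme invariants
  expect_identical(sum(validate_corpus(tagged)$severity == "error"), 0L)
})

test_that("tagger recovers generator ground truth exactly when every clue
           is present, with or without distractor sentences", {
  for (distractor in c(0, 1)) {
    sim <- generate_corpus(
      mk_generation_spec(n_documents = 30, events_per_doc = 5,
                         kt_optional_clue_prob = c(Observation = 1,
                                                   Fact = 1),
                         distractor_prob = distractor),
      seed = 101)
    tagged <- tag_corpus(sim$corpus)
    got <- tagged$events
    truth <- sim$truth
    key <- paste(got$doc_id, got$event_id)
    truth <- truth[match(key, paste(truth$doc_id, truth$event_id)), ]
    for (col in c("kt", "cl", "polarity", "manner", "source")) {
      expect_identical(got[[col]], truth[[col]])
    }
  }
})
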