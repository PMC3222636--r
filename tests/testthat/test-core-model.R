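test_that("default meta-knowledge tuple has the scheme defaults and is pure", {
  mk <- default_metaknowledge()
  expect_equal(as.list(mk),
               list(kt = "Other", cl = "L3", polarity = "Positive",
                    manner = "Neutral", source = "Current"))
  expect_identical(default_metaknowledge(), default_metaknowledge())
})

test_that("a clue-free event with all defaults validates cleanly", {
  corp <- one_doc_corpus("PROT1 activated GENE2 .",
                         list(list(event_id = "E1", trigger = "activated")))
  expect_identical(nrow(validate_corpus(corp)), 0L)
})

test_that("non-default values require clue spans, with KT exceptions", {
  base <- function(kt = "Other", cl = "L3", polarity = "Positive",
                   manner = "Neutral", clues = list()) {
    one_doc_corpus(
      "The results suggest PROT1 partially activated GENE2 not found .",
      list(list(event_id = "E1", trigger = "activated", kt = kt, cl = cl,
                polarity = polarity, manner = manner, clues = clues)))
  }
  v <- validate_corpus(base(kt = "Analysis"))
  expect_true("KT_CLUE_REQUIRED" %in% v$code)
  v <- validate_corpus(base(kt = "Analysis", clues = list(KT = "suggest")))
  expect_false("KT_CLUE_REQUIRED" %in% v$code)
  # clues are optional for Fact and Observation
  expect_identical(nrow(validate_corpus(base(kt = "Fact"))), 0L)
  expect_identical(nrow(validate_corpus(base(kt = "Observation"))), 0L)
  # CL, Polarity, Manner each demand evidence
  expect_true("CL_CLUE_REQUIRED" %in% validate_corpus(base(cl = "L2"))$code)
  expect_true("POLARITY_CLUE_REQUIRED" %in%
                validate_corpus(base(polarity = "Negative"))$code)
  expect_true("MANNER_CLUE_REQUIRED" %in%
                validate_corpus(base(manner = "Low"))$code)
  # with a clue inside the trigger's sentence the event is valid
  ok <- base(kt = "Analysis", cl = "L2",
             clues = list(KT = "suggest", CL = "suggest"))
  expect_identical(sum(validate_corpus(ok)$severity == "error"), 0L)
})

test_that("non-L3 certainty outside Analysis warns but does not error", {
  corp <- one_doc_corpus(
    "PROT1 may be activated by GENE2 .",
    list(list(event_id = "E1", trigger = "activated", kt = "Observation",
              cl = "L1", clues = list(CL = "may"))))
  v <- validate_corpus(corp)
  expect_true("CL_WITHOUT_ANALYSIS" %in% v$code)
  expect_identical(unique(v$severity[v$code == "CL_WITHOUT_ANALYSIS"]),
                   "warning")
  expect_identical(sum(v$severity == "error"), 0L)
})

test_that("structural damage is reported deterministically as violations", {
  expect_identical(nrow(validate_corpus(mk_corpus())), 0L)

  dup <- one_doc_corpus("PROT1 activated GENE2 .",
                        list(list(event_id = "E1", trigger = "activated"),
                             list(event_id = "E1", trigger = "GENE2")))
  v <- validate_corpus(dup)
  expect_identical(sum(v$code == "DUPLICATE_ID"), 1L)

  # unresolvable participant reference is a violation, not an exception
  bad_ref <- one_doc_corpus("PROT1 activated GENE2 .",
                            list(list(event_id = "E1",
                                      trigger = "activated")))
  bad_ref$participants <- tibble::tibble(doc_id = "d1", event_id = "E1",
                                         role = "Theme", ref = "T99")
  expect_true("UNRESOLVED_REF" %in% validate_corpus(bad_ref)$code)

  # participant cycles through event references are detected
  cyc <- one_doc_corpus("PROT1 activated GENE2 .",
                        list(list(event_id = "E1", trigger = "activated"),
                             list(event_id = "E2", trigger = "GENE2")))
  cyc$participants <- tibble::tibble(
    doc_id = "d1", event_id = c("E1", "E2"), role = "Theme",
    ref = c("E2", "E1"))
  expect_identical(sum(validate_corpus(cyc)$code == "PARTICIPANT_CYCLE"), 2L)

  # out-of-range spans
  oor <- one_doc_corpus("PROT1 activated GENE2 .",
                        list(list(event_id = "E1", trigger = "activated")))
  oor$entities <- tibble::tibble(doc_id = "d1", entity_id = "T1",
                                 start = 5L, end = 999L, type = "protein")
  expect_true("SPAN_OUT_OF_RANGE" %in% validate_corpus(oor)$code)

  # same inputs, same violation list (purity)
  expect_identical(validate_corpus(dup), validate_corpus(dup))
})

test_that("clue outside the trigger's sentence is a warning only", {
  corp <- one_doc_corpus(
    c("The results suggest something .", "PROT1 activated GENE2 ."),
    list(list(event_id = "E1", trigger = "activated", sentence = 2,
              kt = "Analysis", clues = list(KT = "suggest"),
              clue_sentence = 1)))
  v <- validate_corpus(corp)
  expect_true("CLUE_OUTSIDE_SENTENCE" %in% v$code)
  expect_identical(sum(v$severity == "error"), 0L)
})

test_that("validate_event filters the corpus report to one event", {
  corp <- one_doc_corpus(
    "PROT1 activated GENE2 .",
    list(list(event_id = "E1", trigger = "activated", kt = "Analysis"),
         list(event_id = "E2", trigger = "GENE2")))
  v <- validate_event(corp, "d1", "E1")
  expect_true(all(v$event_id == "E1", na.rm = TRUE))
  expect_true("KT_CLUE_REQUIRED" %in% v$code)
  expect_identical(nrow(validate_event(corp, "d1", "E2")), 0L)
  expect_error(validate_event(corp, "d1", "E9"), "not found")
})

test_that("generated corpora satisfy all scheme invariants", {
  sim <- small_sim(seed = 7, n_documents = 8, events_per_doc = 6)
  expect_identical(nrow(validate_corpus(sim$corpus)), 0L)
})
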