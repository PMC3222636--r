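# Distribution tables recomputed from an events fixture whose counts equal
# the reference corpus-wide tables (36,858 events).

ref <- reference_count_events()

test_that("the shared rounding rule rounds half up at one decimal", {
  expect_identical(mk_round_pct(c(31.25, 31.34, 31.35, 31.349)),
                   c(31.3, 31.3, 31.4, 31.3))
  expect_identical(mk_round_pct(0.05), 0.1)
  expect_identical(mk_round_pct(-0.05), -0.1)
  expect_identical(mk_round_pct(13.375), 13.4)
})

test_that("KT distribution reproduces the reference counts and shares", {
  d <- dimension_distribution(ref, "KT")
  expect_identical(d$category,
                   c("Observation", "Other", "Analysis", "Fact",
                     "Investigation", "Method"))
  expect_identical(d$n, c(12821L, 11537L, 6578L, 2998L, 1948L, 976L))
  got <- setNames(d$pct_total, d$category)
  expect_equal(got[["Other"]], 31.3)
  expect_equal(got[["Analysis"]], 17.8)
  expect_equal(got[["Fact"]], 8.1)
  expect_equal(got[["Investigation"]], 5.3)
  expect_equal(got[["Method"]], 2.6)
  # 12821/36858 = 34.78%: the documented half-up rule gives 34.8
  expect_equal(got[["Observation"]], 34.8)
  expect_identical(sum(d$n), nrow(ref))
})

test_that("CL, Polarity, Manner and Source distributions match the
           reference shares", {
  d <- dimension_distribution(ref, "CL")
  expect_equal(setNames(d$pct_total, d$category),
               c(L3 = 91.9, L2 = 6.0, L1 = 2.1))
  d <- dimension_distribution(ref, "Polarity")
  expect_equal(setNames(d$pct_total, d$category),
               c(Positive = 93.9, Negative = 6.1))
  expect_identical(d$n[d$category == "Negative"], 2263L)
  d <- dimension_distribution(ref, "Manner")
  expect_equal(setNames(d$pct_total, d$category)[c("Neutral", "High")],
               c(Neutral = 95.3, High = 3.8))
  d <- dimension_distribution(ref, "Source")
  expect_equal(setNames(d$pct_total, d$category),
               c(Current = 98.5, Other = 1.5))
})

test_that("zero-count categories are listed and degenerate corpora work", {
  one <- tibble::tibble(kt = "Fact")
  d <- dimension_distribution(one, "KT")
  expect_identical(nrow(d), 6L)
  expect_equal(d$pct_total[d$category == "Fact"], 100.0)
  expect_true(all(d$pct_total[d$category != "Fact"] == 0))
  empty <- dimension_distribution(mk_corpus(), "KT")
  expect_identical(nrow(empty), 6L)
  expect_true(all(empty$n == 0L))
})

test_that("negation and manner cross-tabs reproduce the within-KT rates", {
  ct <- kt_cross_tab(ref, "Polarity", "Negative")
  got <- setNames(ct$pct_within, ct$kt_category)
  expect_equal(got[["Observation"]], 10.6)
  expect_equal(got[["Fact"]], 3.5)
  expect_equal(got[["Other"]], 1.6)
  expect_equal(got[["Method"]], 1.0)
  expect_equal(got[["Investigation"]], 1.0)
  expect_identical(setNames(ct$n, ct$kt_category)[["Observation"]], 1364L)

  ct <- kt_cross_tab(ref, "Manner", c("High", "Low"))
  got <- setNames(ct$pct_within, ct$kt_category)
  expect_equal(got[["Observation"]], 8.9)
  expect_equal(got[["Analysis"]], 4.2)
  expect_equal(got[["Fact"]], 4.0)
  expect_equal(got[["Other"]], 1.5)
  expect_equal(got[["Method"]], 0.2)
})

test_that("cross-tab flags empty KT categories instead of dividing by zero", {
  ev <- tibble::tibble(kt = "Observation", polarity = "Positive")
  ct <- kt_cross_tab(ev, "Polarity", "Negative")
  expect_true(all(ct$n == 0L))
  expect_true(all(ct$empty_category[ct$kt_category != "Observation"]))
  expect_true(all(ct$pct_within == 0))
  expect_error(kt_cross_tab(ev, "KT"), "must not be KT")
  expect_error(kt_cross_tab(ev, "Polarity", "Sideways"), "unknown")
})

test_that("clue frequencies rank lower-cased surface forms", {
  corp <- one_doc_corpus(
    c("PROT1 was Not seen and not heard and not felt and no more ."),
    list(list(event_id = "E1", trigger = "seen", polarity = "Negative",
              clues = list(Polarity = "Not")),
         list(event_id = "E2", trigger = "heard", polarity = "Negative",
              clues = list(Polarity = "not heard")),
         list(event_id = "E3", trigger = "felt", polarity = "Negative",
              clues = list(Polarity = "not felt")),
         list(event_id = "E4", trigger = "more", polarity = "Negative",
              clues = list(Polarity = "no"))))
  # three distinct "not*" spans surface differently; normalise the fixture:
  corp$clues$end[2:3] <- corp$clues$start[2:3] + 3L
  cf <- clue_frequency(corp, "Polarity", "Negative")
  expect_identical(cf$surface, c("not", "no"))
  expect_identical(cf$n, c(3L, 1L))
  expect_identical(attr(cf, "n_distinct"), 2L)
  expect_identical(nrow(clue_frequency(mk_corpus(), "Polarity")), 0L)
})

test_that("a corpus using every packaged L1 clue once reports that many
           distinct forms", {
  lex <- default_clue_lexicon()
  l1 <- lex$pattern[lex$dimension == "CL" & lex$value == "L1"]
  sents <- paste(l1, "activated GENE1 .")
  events <- lapply(seq_along(l1), function(i) {
    list(event_id = paste0("E", i), trigger = "activated", sentence = i,
         kt = "Analysis", cl = "L1",
         clues = list(CL = l1[i], KT = l1[i]))
  })
  # "may" is a KT clue too; other L1 cues are CL-only, so give those events
  # a KT clue word via the CL cue span (validation allows shared spans)
  corp <- one_doc_corpus(sents, events)
  cf <- clue_frequency(corp, "CL", "L1")
  expect_identical(nrow(cf), length(l1))
  expect_identical(attr(cf, "n_distinct"), length(l1))
  expect_setequal(cf$surface, l1)
  expect_true(all(cf$n == 1L))
})

test_that("hyper-dimension distribution conserves totals", {
  ev <- tibble::tibble(kt = rep("Observation", 4), cl = "L3",
                       source = "Current")
  hd <- hyperdim_distribution(ev)
  expect_equal(hd$pct_total[hd$dimension == "NewKnowledge" &
                              hd$category == "Yes"], 100.0)
  expect_true(all(tapply(hd$n, hd$dimension, sum) == nrow(ev)))
  empty <- hyperdim_distribution(mk_corpus())
  expect_true(attr(empty, "empty_corpus"))
})

test_that("hypothesis share of the reference reconstruction is 13.4%", {
  hd <- hyperdim_distribution(ref)
  hyp_yes <- hd[hd$dimension == "Hypothesis" & hd$category == "Yes", ]
  expect_identical(hyp_yes$n, 1948L + 2216L + 766L)
  expect_equal(hyp_yes$pct_total, 13.4)
})

test_that("per-dimension counts always sum to the corpus total", {
  sim <- small_sim(seed = 3, n_documents = 10, events_per_doc = 8)
  for (d in names(mk_dimensions())) {
    expect_identical(sum(dimension_distribution(sim$corpus, d)$n),
                     nrow(sim$corpus$events))
  }
})
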