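# Rule-based baseline tagger. The scope of clue-trigger linking is the
# trigger's sentence: the annotation scheme itself allows extended context,
# but long-distance links need grammatical analysis that is beyond a
# lexicon baseline. Per dimension the winning match is chosen by priority,
# then proximity to the trigger, then leftmost position; overlapping
# longest-match resolution already happened in match_clues().

#' Tag one event with meta-knowledge from its sentence's clue expressions
#'
#' Starts from [default_metaknowledge()] and lets eligible clue matches in
#' the trigger's sentence set non-default values. Eligibility requires the
#' entry's event-type condition (if any) to cover the event's type.
#' Per dimension the highest-priority match wins, ties broken by distance to
#' the trigger and then leftmost position; the winning span is recorded as
#' the dimension's clue. Triggerless events keep all defaults.
#'
#' With `tense_heuristic = TRUE`, an event whose sentence carries no KT clue
#' falls back on trigger morphology: a past-tense-looking trigger (ending
#' *-ed*) is tagged `Observation`; a present-tense trigger of a concrete
#' biological-process type (e.g. `Gene_Expression`, `Binding`,
#' `Phosphorylation`) is tagged `Fact`. Both KT values tolerate absent
#' clues. The heuristic is off by default: tense is a typical correlate of
#' those categories, not part of their definition.
#'
#' @param corpus An [mk_corpus()].
#' @param doc_id,event_id Identify the event to tag.
#' @param lexicon An `mk_lexicon` (default: packaged lexicon).
#' @param tense_heuristic Logical; enable the KT tense fallback.
#' @return A list with `mk` (one-row tibble of dimension values) and
#'   `clues` (tibble of clue spans: `dimension`, `start`, `end`).
#' @seealso [tag_corpus()] to tag every event at once.
#' @export
tag_event <- function(corpus, doc_id, event_id,
                      lexicon = default_clue_lexicon(),
                      tense_heuristic = FALSE) {
  assert_mk_corpus(corpus)
  ev <- corpus$events[corpus$events$doc_id == doc_id &
                        corpus$events$event_id == event_id, , drop = FALSE]
  if (nrow(ev) != 1) {
    abort(paste0("event '", event_id, "' not found once in document '",
                 doc_id, "'"))
  }
  doc_text <- corpus$documents$text[corpus$documents$doc_id == doc_id]
  sen <- corpus$sentences[corpus$sentences$doc_id == doc_id, , drop = FALSE]
  tag_event_impl(ev, doc_text, sen, lexicon, tense_heuristic)
}

tag_event_impl <- function(ev, doc_text, sentences, lexicon, tense_heuristic) {
  mk <- default_metaknowledge()
  no_clues <- tibble(dimension = character(), start = integer(),
                     end = integer())
  if (is.na(ev$trigger_start) || length(doc_text) != 1) {
    return(list(mk = mk, clues = no_clues))
  }
  sent <- sentences[sentences$start <= ev$trigger_start &
                      ev$trigger_start < sentences$end, , drop = FALSE]
  if (nrow(sent) == 0) return(list(mk = mk, clues = no_clues))
  sent <- sent[1, ]
  sent_text <- substr(doc_text, sent$start + 1L, sent$end)
  hits <- match_clues(sent_text, sent$start, lexicon)

  # event-type conditions
  if (nrow(hits) > 0) {
    ok <- purrr::map_lgl(hits$event_types, function(cond) {
      is.null(cond) || ev$event_type %in% cond
    })
    hits <- hits[ok, , drop = FALSE]
  }

  clues <- list(no_clues)
  cols <- mk_dimension_columns()
  if (nrow(hits) > 0) {
    # gap between clue span and trigger span (0 when adjacent/overlapping)
    gap <- pmax(0L, hits$start - ev$trigger_end, ev$trigger_start - hits$end)
    hits$gap <- gap
    for (d in unique(hits$dimension)) {
      h <- hits[hits$dimension == d, , drop = FALSE]
      h <- h[order(-h$priority, h$gap, h$start), , drop = FALSE]
      mk[[cols[[d]]]] <- h$value[1]
      clues <- c(clues, list(tibble(dimension = d, start = h$start[1],
                                    end = h$end[1])))
    }
  }

  if (tense_heuristic && mk$kt == "Other" && !"KT" %in% hits$dimension) {
    trig <- substr(doc_text, ev$trigger_start + 1L, ev$trigger_end)
    process_types <- c("Gene_Expression", "Transcription", "Binding",
                       "Localization", "Phosphorylation", "Protein_Catabolism")
    if (grepl("ed$", trig, ignore.case = TRUE)) {
      mk$kt <- "Observation"
    } else if (ev$event_type %in% process_types &&
                 grepl("(s|es)$", trig, ignore.case = TRUE)) {
      mk$kt <- "Fact"
    }
  }
  list(mk = mk, clues = bind_rows(clues))
}

#' Tag every event in a corpus
#'
#' Replaces each event's meta-knowledge annotation (dimension values and
#' clue spans) with the baseline tagger's output; the input corpus is left
#' untouched. Because the tagger reads only the document text, it is
#' idempotent: tagging a tagged corpus changes nothing.
#'
#' @param corpus An [mk_corpus()].
#' @param lexicon An `mk_lexicon` (default: packaged lexicon).
#' @param tense_heuristic Logical; see [tag_event()].
#' @return A new `mk_corpus` with re-tagged events.
#' @examples
#' corp <- mk_corpus(
#'   documents = tibble::tibble(doc_id = "d1",
#'     text = "The results suggest that IkBa inhibits NFkB."),
#'   sentences = tibble::tibble(doc_id = "d1", start = 0L, end = 44L),
#'   events = tibble::tibble(doc_id = "d1", event_id = "E1",
#'     event_type = "Negative_Regulation",
#'     trigger_start = 30L, trigger_end = 38L)
#' )
#' tag_corpus(corp)$events[, c("event_id", "kt", "cl")]
#' @export
tag_corpus <- function(corpus, lexicon = default_clue_lexicon(),
                       tense_heuristic = FALSE) {
  assert_mk_corpus(corpus)
  out <- corpus
  ev <- corpus$events
  if (nrow(ev) == 0) {
    out$clues <- empty_mk_table("clues")
    return(out)
  }
  text_by_doc <- setNames(corpus$documents$text, corpus$documents$doc_id)
  sen_by_doc <- split(corpus$sentences, corpus$sentences$doc_id)

  results <- purrr::map(seq_len(nrow(ev)), function(i) {
    row <- ev[i, , drop = FALSE]
    sen <- sen_by_doc[[row$doc_id]]
    if (is.null(sen)) sen <- empty_mk_table("sentences")
    tag_event_impl(row, unname(text_by_doc[row$doc_id]), sen, lexicon,
                   tense_heuristic)
  })

  mk_tbl <- bind_rows(purrr::map(results, "mk"))
  for (col in names(mk_tbl)) out$events[[col]] <- mk_tbl[[col]]
  clue_tbl <- purrr::map2(results, seq_len(nrow(ev)), function(r, i) {
    if (nrow(r$clues) == 0) return(NULL)
    tibble(doc_id = ev$doc_id[i], event_id = ev$event_id[i],
           dimension = r$clues$dimension,
           start = r$clues$start, end = r$clues$end)
  })
  out$clues <- coerce_mk_table(bind_rows(clue_tbl), "clues")
  out
}
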