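# Scheme validation. Violations are data, not conditions: structural damage
# and broken annotation invariants are reported as rows so a whole corpus can
# be audited in one pass. severity "error" breaks the scheme's invariants;
# "warning" flags combinations the scheme permits but considers unusual.

violation_row <- function(doc_id, event_id, dimension, code, severity, message) {
  tibble(doc_id = as.character(doc_id),
         event_id = as.character(event_id),
         dimension = as.character(dimension),
         code = code, severity = severity, message = message)
}

empty_violations <- function() {
  tibble(doc_id = character(), event_id = character(), dimension = character(),
         code = character(), severity = character(), message = character())
}

# which dimension values require a supporting clue span
clue_required <- function(dim, value) {
  switch(dim,
         KT = value %in% c("Analysis", "Investigation"),
         CL = value != "L3",
         Polarity = value == "Negative",
         Manner = value %in% c("High", "Low"),
         Source = FALSE)  # Source=Other clues are typical, not mandatory
}

#' Validate a corpus against the annotation scheme's invariants
#'
#' Checks structural integrity (span bounds, sentence ordering, id
#' uniqueness, participant reference resolution, absence of participant
#' cycles) and the scheme's annotation invariants: every dimension holds
#' exactly one legal category, and non-default values that the scheme ties to
#' lexical evidence (`KT` of `Analysis`/`Investigation`, `CL` other than
#' `L3`, `Polarity = Negative`, `Manner` of `High`/`Low`) carry at least one
#' clue span. `KT` clues remain optional for `Fact` and `Observation`, where
#' explicit clues are rare in practice.
#'
#' Two checks yield warnings rather than errors: a non-`L3` certainty level
#' on a non-`Analysis` event (the scheme intends CL for analyses, but a
#' handful of exceptions exist) and a clue located outside the trigger's
#' sentence (extended context is legitimate but unusual).
#'
#' @param corpus An [mk_corpus()].
#' @return A tibble of violations with columns `doc_id`, `event_id`,
#'   `dimension`, `code`, `severity` (`"error"`/`"warning"`), `message`,
#'   sorted by document then event id. Zero rows with severity `"error"`
#'   means the corpus is valid.
#' @examples
#' ev <- tibble::tibble(doc_id = "d1", event_id = "E1", event_type = "Binding",
#'                      trigger_start = 0L, trigger_end = 4L, kt = "Analysis")
#' corp <- mk_corpus(
#'   documents = tibble::tibble(doc_id = "d1", text = "IkBa binds NFkB."),
#'   sentences = tibble::tibble(doc_id = "d1", start = 0L, end = 16L),
#'   events = ev
#' )
#' validate_corpus(corp)  # KT_CLUE_REQUIRED: Analysis without a clue span
#' @export
validate_corpus <- function(corpus) {
  assert_mk_corpus(corpus)
  out <- list(empty_violations())
  docs <- corpus$documents
  text_len <- setNames(nchar(docs$text), docs$doc_id)

  check_doc <- function(tbl, what) {
    bad <- !tbl$doc_id %in% docs$doc_id
    if (!any(bad)) return(NULL)
    violation_row(tbl$doc_id[bad], NA, NA, "UNKNOWN_DOCUMENT", "error",
                  paste0(what, " refers to unknown document"))
  }
  out <- c(out, lapply(
    list(sentences = corpus$sentences, entities = corpus$entities,
         events = corpus$events, clues = corpus$clues),
    check_doc, what = "record"))

  # duplicate ids (one violation per duplicated id)
  dup_ev <- corpus$events %>% count(.data$doc_id, .data$event_id) %>%
    filter(.data$n > 1)
  if (nrow(dup_ev) > 0) {
    out <- c(out, list(violation_row(dup_ev$doc_id, dup_ev$event_id, NA,
                                     "DUPLICATE_ID", "error",
                                     "duplicate event id within document")))
  }
  dup_en <- corpus$entities %>% count(.data$doc_id, .data$entity_id) %>%
    filter(.data$n > 1)
  if (nrow(dup_en) > 0) {
    out <- c(out, list(violation_row(dup_en$doc_id, NA, NA, "DUPLICATE_ID",
                                     "error", paste0("duplicate entity id: ",
                                                     dup_en$entity_id))))
  }

  span_ok <- function(doc_id, start, end) {
    len <- text_len[doc_id]
    !is.na(start) & !is.na(end) & !is.na(len) &
      start >= 0L & start < end & end <= len
  }

  # sentence spans: in range, ordered, non-overlapping
  sen <- corpus$sentences %>% filter(.data$doc_id %in% docs$doc_id)
  if (nrow(sen) > 0) {
    bad <- !span_ok(sen$doc_id, sen$start, sen$end)
    if (any(bad)) {
      out <- c(out, list(violation_row(sen$doc_id[bad], NA, NA,
                                       "SPAN_OUT_OF_RANGE", "error",
                                       "sentence span outside document text")))
    }
    overlap <- sen %>% arrange(.data$doc_id, .data$start) %>%
      group_by(.data$doc_id) %>%
      filter(row_number() > 1 & .data$start < dplyr::lag(.data$end)) %>%
      ungroup()
    if (nrow(overlap) > 0) {
      out <- c(out, list(violation_row(overlap$doc_id, NA, NA,
                                       "SENTENCE_OVERLAP", "error",
                                       "overlapping sentence spans")))
    }
  }

  ent <- corpus$entities %>% filter(.data$doc_id %in% docs$doc_id)
  if (nrow(ent) > 0) {
    bad <- !span_ok(ent$doc_id, ent$start, ent$end)
    if (any(bad)) {
      out <- c(out, list(violation_row(ent$doc_id[bad], NA, NA,
                                       "SPAN_OUT_OF_RANGE", "error",
                                       paste0("entity span outside document: ",
                                              ent$entity_id[bad]))))
    }
  }

  # per-event checks
  ev <- corpus$events %>% filter(.data$doc_id %in% docs$doc_id)
  dims <- mk_dimensions()
  cols <- mk_dimension_columns()
  for (d in names(dims)) {
    v <- ev[[cols[[d]]]]
    bad <- is.na(v) | !v %in% dims[[d]]
    if (any(bad)) {
      out <- c(out, list(violation_row(ev$doc_id[bad], ev$event_id[bad], d,
                                       "INVALID_CATEGORY", "error",
                                       paste0("illegal ", d, " value: ",
                                              v[bad]))))
    }
  }

  has_trigger <- !is.na(ev$trigger_start) | !is.na(ev$trigger_end)
  if (any(has_trigger)) {
    tev <- ev[has_trigger, ]
    bad <- !span_ok(tev$doc_id, tev$trigger_start, tev$trigger_end)
    if (any(bad)) {
      out <- c(out, list(violation_row(tev$doc_id[bad], tev$event_id[bad], NA,
                                       "SPAN_OUT_OF_RANGE", "error",
                                       "trigger span outside document text")))
    }
    # trigger must sit inside a single sentence
    tok <- tev[!bad, , drop = FALSE]
    if (nrow(tok) > 0) {
      inside <- purrr::map_lgl(seq_len(nrow(tok)), function(i) {
        s <- sen[sen$doc_id == tok$doc_id[i], ]
        any(s$start <= tok$trigger_start[i] & tok$trigger_end[i] <= s$end)
      })
      if (any(!inside)) {
        out <- c(out, list(violation_row(tok$doc_id[!inside],
                                         tok$event_id[!inside], NA,
                                         "TRIGGER_CROSSES_SENTENCE", "error",
                                         "trigger not contained in one sentence")))
      }
    }
  }

  # clue spans: known dimension, in range, required where mandated
  cl <- corpus$clues %>% filter(.data$doc_id %in% docs$doc_id)
  if (nrow(cl) > 0) {
    bad_dim <- !cl$dimension %in% names(dims)
    if (any(bad_dim)) {
      out <- c(out, list(violation_row(cl$doc_id[bad_dim], cl$event_id[bad_dim],
                                       cl$dimension[bad_dim],
                                       "INVALID_DIMENSION", "error",
                                       "unknown clue dimension")))
    }
    bad <- !span_ok(cl$doc_id, cl$start, cl$end)
    if (any(bad)) {
      out <- c(out, list(violation_row(cl$doc_id[bad], cl$event_id[bad],
                                       cl$dimension[bad], "SPAN_OUT_OF_RANGE",
                                       "error", "clue span outside document text")))
    }
    orphan <- !paste(cl$doc_id, cl$event_id) %in% paste(ev$doc_id, ev$event_id)
    if (any(orphan)) {
      out <- c(out, list(violation_row(cl$doc_id[orphan], cl$event_id[orphan],
                                       cl$dimension[orphan], "UNRESOLVED_REF",
                                       "error", "clue attached to unknown event")))
    }
    # clue outside the trigger's sentence: extended context, warn only
    ok <- !bad & !orphan & !bad_dim
    if (any(ok)) {
      clk <- cl[ok, , drop = FALSE]
      trig <- ev %>% select("doc_id", "event_id", "trigger_start")
      clk <- left_join(clk, trig, by = c("doc_id", "event_id"))
      outside <- purrr::map_lgl(seq_len(nrow(clk)), function(i) {
        if (is.na(clk$trigger_start[i])) return(FALSE)
        s <- sen[sen$doc_id == clk$doc_id[i], ]
        trig_sent <- s[s$start <= clk$trigger_start[i] &
                         clk$trigger_start[i] < s$end, , drop = FALSE]
        if (nrow(trig_sent) == 0) return(FALSE)
        !any(trig_sent$start <= clk$start[i] & clk$end[i] <= trig_sent$end)
      })
      if (any(outside)) {
        out <- c(out, list(violation_row(clk$doc_id[outside],
                                         clk$event_id[outside],
                                         clk$dimension[outside],
                                         "CLUE_OUTSIDE_SENTENCE", "warning",
                                         "clue lies outside the trigger's sentence")))
      }
    }
  }

  # non-default value => clue span present
  clue_key <- paste(cl$doc_id, cl$event_id, cl$dimension)
  for (d in names(dims)) {
    v <- ev[[cols[[d]]]]
    needs <- vapply(v, function(x) !is.na(x) && clue_required(d, x), logical(1))
    if (any(needs)) {
      missing <- !paste(ev$doc_id[needs], ev$event_id[needs], d) %in% clue_key
      if (any(missing)) {
        idx <- which(needs)[missing]
        out <- c(out, list(violation_row(ev$doc_id[idx], ev$event_id[idx], d,
                                         paste0(toupper(d), "_CLUE_REQUIRED"),
                                         "error",
                                         paste0(d, "=", v[idx],
                                                " requires a clue span"))))
      }
    }
  }

  # CL marking outside Analysis: permitted but flagged
  odd_cl <- !is.na(ev$cl) & ev$cl != "L3" & ev$kt != "Analysis"
  if (any(odd_cl)) {
    out <- c(out, list(violation_row(ev$doc_id[odd_cl], ev$event_id[odd_cl],
                                     "CL", "CL_WITHOUT_ANALYSIS", "warning",
                                     "non-L3 certainty on a non-Analysis event")))
  }

  # participant references and cycles
  pa <- corpus$participants %>% filter(.data$doc_id %in% docs$doc_id)
  if (nrow(pa) > 0) {
    ent_key <- paste(ent$doc_id, ent$entity_id)
    ev_key <- paste(ev$doc_id, ev$event_id)
    ref_key <- paste(pa$doc_id, pa$ref)
    unresolved <- !(ref_key %in% ent_key | ref_key %in% ev_key)
    if (any(unresolved)) {
      out <- c(out, list(violation_row(pa$doc_id[unresolved],
                                       pa$event_id[unresolved], NA,
                                       "UNRESOLVED_REF", "error",
                                       paste0("participant ref not found: ",
                                              pa$ref[unresolved]))))
    }
    # cycles along event->event participant edges, per document
    ev_refs <- pa[paste(pa$doc_id, pa$ref) %in% ev_key, , drop = FALSE]
    for (docid in unique(ev_refs$doc_id)) {
      edges <- ev_refs[ev_refs$doc_id == docid, c("event_id", "ref")]
      cyc <- find_cycle_nodes(edges$event_id, edges$ref)
      if (length(cyc) > 0) {
        out <- c(out, list(violation_row(docid, sort(cyc), NA,
                                         "PARTICIPANT_CYCLE", "error",
                                         "event participates in a reference cycle")))
      }
    }
  }

  bind_rows(out) %>% arrange(.data$doc_id, .data$event_id, .data$dimension,
                             .data$code)
}

# nodes on at least one directed cycle (iterative leaf-stripping)
find_cycle_nodes <- function(from, to) {
  nodes <- unique(c(from, to))
  edges <- data.frame(from = from, to = to)
  repeat {
    out_deg <- table(factor(edges$from, levels = nodes))
    leaves <- nodes[out_deg == 0]
    if (length(leaves) == 0) break
    nodes <- setdiff(nodes, leaves)
    edges <- edges[edges$to %in% nodes & edges$from %in% nodes, , drop = FALSE]
    if (length(nodes) == 0) break
  }
  nodes
}

#' Validate a single event
#'
#' Runs the full corpus validation and returns the rows concerning one event.
#'
#' @param corpus An [mk_corpus()] containing the event.
#' @param doc_id,event_id Identify the event.
#' @return A tibble of violations (see [validate_corpus()]).
#' @export
validate_event <- function(corpus, doc_id, event_id) {
  assert_mk_corpus(corpus)
  if (!any(corpus$events$doc_id == doc_id &
             corpus$events$event_id == event_id)) {
    abort(paste0("event '", event_id, "' not found in document '", doc_id, "'"))
  }
  validate_corpus(corpus) %>%
    filter(.data$doc_id == .env$doc_id,
           is.na(.data$event_id) | .data$event_id == .env$event_id)
}
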