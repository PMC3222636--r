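# Hyper-dimensions are never stored on events: New Knowledge and Hypothesis
# are deterministic functions of the annotated (Source, KT, CL) triple,
# expressed as ordered wildcard rule tables ("X" = any value, first matching
# row wins). The tables are the authoritative form; closed-form predicates
# exist as a tested simplification.

#' Inference rule tables for the two hyper-dimensions
#'
#' `new_knowledge_rules()` maps (Source, KT, CL) to New Knowledge;
#' `hypothesis_rules()` maps (KT, CL) to Hypothesis. `"X"` is a wildcard
#' matching any value and the first matching row decides. The rule sets are
#' consistent, so row order does not actually affect the outcome (an
#' exhaustively tested property), but first-match is the documented
#' semantics.
#'
#' @return A tibble of rules; the final column `value` is logical.
#' @examples
#' new_knowledge_rules()
#' hypothesis_rules()
#' @export
new_knowledge_rules <- function() {
  tibble(
    source = c("Other", "X", "X", "Current", "Current", "X", "X", "X", "X"),
    kt = c("X", "X", "X", "Observation", "Analysis", "Fact", "Method",
           "Other", "Investigation"),
    cl = c("X", "L2", "L1", "L3", "L3", "X", "X", "X", "X"),
    value = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' @rdname new_knowledge_rules
#' @export
hypothesis_rules <- function() {
  tibble(
    kt = c("Fact", "Method", "Other", "Observation", "Analysis", "Analysis",
           "Analysis", "Investigation"),
    cl = c("X", "X", "X", "X", "L3", "L2", "L1", "X"),
    value = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

# first-match lookup of one (source, kt, cl) triple in a wildcard rule table
match_rules <- function(rules, values) {
  keys <- setdiff(names(rules), "value")
  for (i in seq_len(nrow(rules))) {
    hit <- all(vapply(keys, function(k) {
      rules[[k]][i] == "X" || rules[[k]][i] == values[[k]]
    }, logical(1)))
    if (hit) return(rules$value[i])
  }
  abort("no rule matched; rule table is not exhaustive")
}

check_dim_values <- function(x, dimension) {
  legal <- mk_dimension_values(dimension)
  bad <- unique(x[is.na(x) | !x %in% legal])
  if (length(bad) > 0) {
    abort(paste0("illegal ", dimension, " value(s): ",
                 paste(bad, collapse = ", ")))
  }
}

#' Infer the New Knowledge hyper-dimension
#'
#' An event counts as new knowledge when it is attributed to the current
#' study, its knowledge type is an experimental `Observation` or a
#' straightforward `Analysis`, and it is stated without expressed
#' uncertainty (`CL = L3`). Speculative analyses, cited work, facts, methods
#' and investigations are excluded.
#'
#' @param source,kt,cl Character vectors (recycled to common length) of
#'   Source, KT and CL values.
#' @return Logical vector.
#' @examples
#' infer_new_knowledge("Current", "Observation", "L3")  # TRUE
#' infer_new_knowledge("Other", "Observation", "L3")    # FALSE
#' @export
infer_new_knowledge <- function(source, kt, cl) {
  n <- max(length(source), length(kt), length(cl))
  source <- rep_len(source, n); kt <- rep_len(kt, n); cl <- rep_len(cl, n)
  check_dim_values(source, "Source"); check_dim_values(kt, "KT")
  check_dim_values(cl, "CL")
  rules <- new_knowledge_rules()
  # authoritative rule-table lookup, memoised over the 24 distinct triples
  key <- paste(source, kt, cl)
  uk <- unique(key)
  lut <- vapply(uk, function(k) {
    p <- strsplit(k, " ", fixed = TRUE)[[1]]
    match_rules(rules, list(source = p[1], kt = p[2], cl = p[3]))
  }, logical(1))
  unname(lut[key])
}

#' Infer the Hypothesis hyper-dimension
#'
#' An event is a hypothesis when its knowledge type is `Investigation`
#' (an enquiry whose outcome is unknown) or when it is an `Analysis` hedged
#' at certainty level `L1` or `L2` (a speculative inference awaiting firmer
#' evidence).
#'
#' @param kt,cl Character vectors (recycled) of KT and CL values.
#' @return Logical vector.
#' @examples
#' infer_hypothesis("Investigation", "L3")  # TRUE
#' infer_hypothesis("Analysis", "L2")       # TRUE
#' infer_hypothesis("Analysis", "L3")       # FALSE
#' @export
infer_hypothesis <- function(kt, cl) {
  n <- max(length(kt), length(cl))
  kt <- rep_len(kt, n); cl <- rep_len(cl, n)
  check_dim_values(kt, "KT"); check_dim_values(cl, "CL")
  rules <- hypothesis_rules()
  key <- paste(kt, cl)
  uk <- unique(key)
  lut <- vapply(uk, function(k) {
    p <- strsplit(k, " ", fixed = TRUE)[[1]]
    match_rules(rules, list(kt = p[1], cl = p[2]))
  }, logical(1))
  unname(lut[key])
}

# closed-form equivalents of the rule tables; kept internal, proven
# equivalent to the tables over all 36 combinations in the test suite
nk_closed_form <- function(source, kt, cl) {
  source == "Current" & kt %in% c("Observation", "Analysis") & cl == "L3"
}

hyp_closed_form <- function(kt, cl) {
  kt == "Investigation" | (kt == "Analysis" & cl %in% c("L1", "L2"))
}

#' Derive hyper-dimensions for every event
#'
#' Applies both inference tables to each event's annotated (Source, KT, CL)
#' values and returns the events with two appended logical columns. The
#' derived values are never written back into a stored corpus.
#'
#' @param x An [mk_corpus()] or an events data frame (see [as_mk_events()]).
#' @return A tibble of events with columns `new_knowledge` and `hypothesis`
#'   appended.
#' @examples
#' ev <- tibble::tibble(doc_id = "d", event_id = "E1", kt = "Observation",
#'                      cl = "L3", source = "Current")
#' infer_hyperdimensions(ev)[, c("kt", "new_knowledge", "hypothesis")]
#' @export
infer_hyperdimensions <- function(x) {
  ev <- as_mk_events(x)
  ev$new_knowledge <- if (nrow(ev) == 0) logical(0) else
    infer_new_knowledge(ev$source, ev$kt, ev$cl)
  ev$hypothesis <- if (nrow(ev) == 0) logical(0) else
    infer_hypothesis(ev$kt, ev$cl)
  ev
}
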