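# Seeded generator of valid annotated corpora. Sentences are template-built
# ("<ENT> <clues> <trigger> <ENT> .") around placeholder biomedical entity
# names; linguistic realism is not a goal, but every span is textually valid
# and every non-default annotation carries a clue actually present in the
# trigger's sentence, so generated corpora always validate cleanly and give
# the tagger, statistics and agreement code a known ground truth.

#' Specification for the synthetic corpus generator
#'
#' Collects the marginal and conditional category distributions the
#' generator draws from, plus clue-insertion behaviour. All probability
#' vectors must sum to 1 (tolerance 1e-9). With `cl_analysis_only = TRUE`
#' (the default) any non-`L3` certainty mass outside `Analysis` events is
#' rejected, reflecting the scheme's intent that CL marks analyses.
#'
#' @param n_documents Number of documents.
#' @param events_per_doc Mean events per document (Poisson).
#' @param kt_marginal Named probability vector over the six KT values.
#' @param cl_given_kt Named list: for each KT value, a named probability
#'   vector over `L3`, `L2`, `L1`.
#' @param polarity_given_kt Named numeric: probability of `Negative` per KT
#'   value.
#' @param manner_given_kt Named numeric: probability of non-`Neutral` manner
#'   per KT value.
#' @param manner_high_share Share of non-neutral manner that is `High`
#'   (the remainder is `Low`).
#' @param source_marginal Named probability pair over `Current`, `Other`.
#' @param clue_insertion_prob Named per-dimension probability that an
#'   optional clue is inserted. Values whose validity requires a clue
#'   (`Analysis`/`Investigation` KT, non-`L3` CL, `Negative` polarity,
#'   `High`/`Low` manner) always receive one, whatever this says.
#' @param kt_optional_clue_prob Named probabilities of a clue on
#'   `Observation` and `Fact` events, where clues are optional.
#' @param distractor_prob Probability of appending an event-free sentence
#'   full of distractor clue words to a document.
#' @param cl_analysis_only Logical; restrict non-`L3` certainty mass to
#'   `Analysis` events, the scheme's intended use of the CL dimension.
#' @return An object of class `mk_generation_spec` (a validated list).
#' @seealso [default_corpus_spec()] for the GENIA-abstract-like defaults,
#'   [generate_corpus()].
#' @export
mk_generation_spec <- function(n_documents = 100,
                               events_per_doc = 36.858,
                               kt_marginal = NULL,
                               cl_given_kt = NULL,
                               polarity_given_kt = NULL,
                               manner_given_kt = NULL,
                               manner_high_share = 1392 / 1715,
                               source_marginal = NULL,
                               clue_insertion_prob = NULL,
                               kt_optional_clue_prob = NULL,
                               distractor_prob = 0,
                               cl_analysis_only = TRUE) {
  defaults <- default_corpus_spec_values()
  spec <- list(
    n_documents = as.integer(n_documents),
    events_per_doc = events_per_doc,
    kt_marginal = kt_marginal %||% defaults$kt_marginal,
    cl_given_kt = cl_given_kt %||% defaults$cl_given_kt,
    polarity_given_kt = polarity_given_kt %||% defaults$polarity_given_kt,
    manner_given_kt = manner_given_kt %||% defaults$manner_given_kt,
    manner_high_share = manner_high_share,
    source_marginal = source_marginal %||% defaults$source_marginal,
    clue_insertion_prob = modifyList(
      as.list(defaults$clue_insertion_prob),
      as.list(clue_insertion_prob %||% list())),
    kt_optional_clue_prob = modifyList(
      as.list(defaults$kt_optional_clue_prob),
      as.list(kt_optional_clue_prob %||% list())),
    distractor_prob = distractor_prob,
    cl_analysis_only = isTRUE(cl_analysis_only)
  )
  validate_generation_spec(spec)
  structure(spec, class = "mk_generation_spec")
}

# category proportions of the reference annotated-abstract corpus:
# KT and Source marginals from the corpus-wide distribution tables;
# CL | Analysis and per-KT negation / explicit-manner rates from the
# published conditional tables; optional-KT clue rates from the reported
# clue coverage of Observation and Fact events.
default_corpus_spec_values <- function() {
  total <- 36858
  kt <- c(Observation = 12821, Other = 11537, Analysis = 6578,
          Fact = 2998, Investigation = 1948, Method = 976)
  cl_analysis <- c(L3 = 1 - (2216 + 766) / 6578,
                   L2 = 2216 / 6578, L1 = 766 / 6578)
  cl_default <- c(L3 = 1, L2 = 0, L1 = 0)
  list(
    kt_marginal = kt / total,
    cl_given_kt = list(
      Observation = cl_default, Other = cl_default, Analysis = cl_analysis,
      Fact = cl_default, Investigation = cl_default, Method = cl_default),
    polarity_given_kt = c(Observation = 1364 / 12821, Other = 187 / 11537,
                          Analysis = 577 / 6578, Fact = 105 / 2998,
                          Investigation = 20 / 1948, Method = 10 / 976),
    manner_given_kt = c(Observation = 1141 / 12821, Other = 171 / 11537,
                        Analysis = 276 / 6578, Fact = 120 / 2998,
                        Investigation = 5 / 1948, Method = 2 / 976),
    source_marginal = c(Current = 1 - 545 / 36858, Other = 545 / 36858),
    clue_insertion_prob = c(KT = 1, CL = 1, Polarity = 1, Manner = 1,
                            Source = 1),
    kt_optional_clue_prob = c(Observation = 937 / 12821, Fact = 139 / 2998)
  )
}

#' Generation spec matching the reference corpus proportions
#'
#' Returns an [mk_generation_spec()] whose marginals equal the published
#' proportions of the meta-knowledge-annotated GENIA abstract corpus:
#' 1000 documents averaging 36.858 events each, the KT and Source marginals
#' of the corpus-wide tables, certainty mass confined to `Analysis` events
#' (33.7% L2, 11.6% L1 of analyses), and per-KT negation and explicit-manner
#' rates from the published cross-tabulations.
#'
#' @param n_documents Number of documents (default 1000, the reference
#'   corpus size; scale down for quick experiments).
#' @return An `mk_generation_spec`.
#' @examples
#' spec <- default_corpus_spec(n_documents = 5)
#' round(spec$kt_marginal, 3)
#' @export
default_corpus_spec <- function(n_documents = 1000) {
  mk_generation_spec(n_documents = n_documents)
}

validate_generation_spec <- function(spec) {
  kt_values <- mk_dimension_values("KT")
  chk_prob_vec <- function(v, nm, levels) {
    if (!all(levels %in% names(v))) {
      abort(paste0(nm, " must be named with: ", paste(levels, collapse = ", ")))
    }
    v <- v[levels]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      abort(paste0(nm, " must be a probability vector summing to 1"))
    }
    v
  }
  chk_prob_vec(spec$kt_marginal, "kt_marginal", kt_values)
  chk_prob_vec(spec$source_marginal, "source_marginal", c("Current", "Other"))
  for (k in kt_values) {
    v <- chk_prob_vec(spec$cl_given_kt[[k]], paste0("cl_given_kt$", k),
                      c("L3", "L2", "L1"))
    if (spec$cl_analysis_only && k != "Analysis" && sum(v[c("L2", "L1")]) > 0) {
      abort("cl_analysis_only spec: non-L3 certainty mass outside Analysis")
    }
  }
  for (nm in c("polarity_given_kt", "manner_given_kt")) {
    v <- spec[[nm]]
    if (!all(kt_values %in% names(v)) || any(v < 0 | v > 1)) {
      abort(paste0(nm, " must be probabilities named by KT value"))
    }
  }
  probs <- c(unlist(spec$clue_insertion_prob),
             unlist(spec$kt_optional_clue_prob),
             spec$distractor_prob, spec$manner_high_share)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (spec$n_documents < 0 || spec$events_per_doc < 0) {
    abort("n_documents and events_per_doc must be non-negative")
  }
  invisible(spec)
}

# clue surface forms the generator may insert for a (dimension, value).
# Restricted to patterns whose every lexicon role matches the event's truth
# (dual-role cues like "suggest" are only used when both of their roles
# hold), and to words that cannot concatenate with a neighbouring inserted
# word into a longer lexicon pattern.
generator_clue_candidates <- function(dim, value, kt = "Other", cl = "L3") {
  switch(paste(dim, value),
    "KT Analysis" = if (cl == "L2") c("suggest", "indicate", "suggesting")
      else if (cl == "L1") "may"
      else c("demonstrated", "showed", "revealed", "shown", "thus"),
    "KT Investigation" = c("examined", "investigated", "tested", "measured"),
    "KT Observation" = c("found", "observed", "detected", "seen", "noted"),
    "KT Fact" = "known",
    "CL L2" = if (kt == "Analysis") c("suggest", "indicate", "suggesting")
      else c("likely", "probably", "normally", "often", "frequently"),
    "CL L1" = if (kt == "Analysis") "may"
      else c("perhaps", "possibly", "sometimes", "rarely", "potentially"),
    "Polarity Negative" = c("not", "failed", "neither", "unable", "without"),
    "Manner High" = c("strongly", "markedly", "rapidly", "dramatically",
                      "highly"),
    "Manner Low" = c("partially", "weakly", "barely", "slightly"),
    "Source Other" = c("previously", "recently", "earlier"),
    abort(paste0("no clue candidates for ", dim, "=", value))
  )
}

generator_event_types <- function() {
  c(Gene_Expression = "expressed", Positive_Regulation = "activated",
    Negative_Regulation = "inhibited", Regulation = "regulated",
    Binding = "bound", Correlation = "correlated",
    Localization = "localized", Transcription = "transcribed",
    Phosphorylation = "phosphorylated")
}

sample_cat <- function(n, probs) {
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic annotated corpus
#'
#' Draws event annotations from the spec's distributions, builds one
#' template sentence per event with the appropriate clue expressions placed
#' in the trigger's sentence, and returns the annotated corpus together
#' with a ground-truth sidecar. Where the scheme ties a non-default value to
#' lexical evidence, a clue is always inserted (the corpus must validate);
#' clues on `Observation`/`Fact` events and `Source = Other` events follow
#' the spec's optional-clue probabilities. Output is fully determined by
#' `(spec, seed)`.
#'
#' @param spec An [mk_generation_spec()].
#' @param seed Integer seed for the single random stream of the call.
#' @return An object of class `mk_simulation`: list with `corpus` (an
#'   [mk_corpus()]) and `truth` (tibble of the generated dimension values
#'   per event, identical to the corpus annotation — kept separately so
#'   re-tagging experiments cannot overwrite it).
#' @examples
#' sim <- generate_corpus(mk_generation_spec(n_documents = 2,
#'                                           events_per_doc = 3), seed = 1)
#' sim$corpus
#' @export
generate_corpus <- function(spec, seed) {
  if (!inherits(spec, "mk_generation_spec")) {
    abort("`spec` must be an mk_generation_spec")
  }
  set.seed(as.integer(seed))
  kt_values <- mk_dimension_values("KT")
  n_ev_doc <- rpois(spec$n_documents, spec$events_per_doc)
  total <- sum(n_ev_doc)

  kt <- sample_cat(total, spec$kt_marginal)
  cl <- character(total)
  for (k in kt_values) {
    idx <- which(kt == k)
    cl[idx] <- sample_cat(length(idx), spec$cl_given_kt[[k]])
  }
  polarity <- ifelse(runif(total) < spec$polarity_given_kt[kt],
                     "Negative", "Positive")
  manner <- ifelse(runif(total) < spec$manner_given_kt[kt],
                   ifelse(runif(total) < spec$manner_high_share,
                          "High", "Low"),
                   "Neutral")
  source <- sample_cat(total, spec$source_marginal)
  types <- generator_event_types()
  event_type <- sample(names(types), total, replace = TRUE)

  cip <- spec$clue_insertion_prob
  opt_rate <- unlist(spec$kt_optional_clue_prob)
  kt_clue <- ifelse(
    kt %in% c("Analysis", "Investigation"), TRUE,
    ifelse(kt %in% c("Observation", "Fact"),
           runif(total) < ifelse(is.na(opt_rate[kt]), 0, opt_rate[kt]) *
             (cip$KT > 0),
           FALSE))
  src_clue <- source == "Other" & runif(total) < cip$Source

  # event/document bookkeeping (fully vectorized; one template sentence
  # per event, slots: entA [Source] [CL] [Polarity] [Manner] [KT] trig entB .)
  doc_ids <- sprintf("doc%04d", seq_len(spec$n_documents))
  if (total == 0) {
    # zero-length vectors recycle unpredictably through paste()/rbind();
    # build the empty corpus explicitly
    events_tbl <- NULL; sents_tbl <- NULL; ents_tbl <- NULL
    parts_tbl <- NULL; clues_tbl <- NULL
    doc_text <- rep("", spec$n_documents)
    docs_tbl <- tibble(doc_id = doc_ids, text = doc_text)
  } else {
  doc_idx <- rep.int(seq_len(spec$n_documents), n_ev_doc)
  j <- sequence(n_ev_doc)  # event index within document
  docid <- doc_ids[doc_idx]
  evid <- paste0("E", j)
  ent_a <- paste0("T", 2L * j - 1L); ent_b <- paste0("T", 2L * j)
  name_a <- sprintf("PROT%d", 2L * j - 1L)
  name_b <- sprintf("GENE%d", 2L * j)

  pick <- function(present, cand_fun) {
    out <- rep(NA_character_, total)
    idx <- which(present)
    if (length(idx) == 0) return(out)
    key <- cand_fun(idx)  # list of candidate vectors per index
    out[idx] <- vapply(key, function(cand) {
      if (length(cand) == 1) cand else sample(cand, 1)
    }, character(1))
    out
  }
  shared_cl <- kt == "Analysis" & cl != "L3"
  w_src <- pick(src_clue, function(idx)
    rep(list(generator_clue_candidates("Source", "Other")), length(idx)))
  w_cl <- pick(cl != "L3" & !shared_cl, function(idx)
    lapply(idx, function(i) generator_clue_candidates("CL", cl[i], kt[i])))
  w_pol <- pick(polarity == "Negative", function(idx)
    rep(list(generator_clue_candidates("Polarity", "Negative")), length(idx)))
  w_man <- pick(manner != "Neutral", function(idx)
    lapply(idx, function(i) generator_clue_candidates("Manner", manner[i])))
  w_kt <- pick(kt_clue, function(idx)
    lapply(idx, function(i) generator_clue_candidates("KT", kt[i], kt[i],
                                                      cl[i])))
  # Method knowledge is signalled by the trigger word itself (an
  # experimental-method verb), not by a separate clue expression
  w_trig <- ifelse(kt == "Method", "stimulated", unname(types[event_type]))

  # build sentences slot by slot, recording relative spans as we go
  txt <- name_a
  add_slot <- function(txt, w) {
    rel_start <- ifelse(is.na(w), NA_integer_, nchar(txt) + 1L)
    list(txt = ifelse(is.na(w), txt, paste(txt, w)),
         start = rel_start, end = rel_start + nchar(w))
  }
  s_src <- add_slot(txt, w_src); txt <- s_src$txt
  s_cl <- add_slot(txt, w_cl); txt <- s_cl$txt
  s_pol <- add_slot(txt, w_pol); txt <- s_pol$txt
  s_man <- add_slot(txt, w_man); txt <- s_man$txt
  s_kt <- add_slot(txt, w_kt); txt <- s_kt$txt
  s_trig <- add_slot(txt, w_trig); txt <- s_trig$txt
  s_entb <- add_slot(txt, name_b); txt <- s_entb$txt
  # paste() recycles zero-length inputs, so keep the empty case explicit
  txt <- if (total == 0) character(0) else paste(txt, ".")
  sent_len <- nchar(txt)

  # absolute sentence starts: sentences joined by single spaces per document
  sent_start <- stats::ave(sent_len + 1L, doc_idx,
                           FUN = function(x) cumsum(x) - x)
  sent_end <- sent_start + sent_len

  events_tbl <- tibble(
    doc_id = docid, event_id = evid, event_type = event_type,
    trigger_start = sent_start + s_trig$start,
    trigger_end = sent_start + s_trig$end,
    kt = kt, cl = cl, polarity = polarity, manner = manner, source = source)
  sents_tbl <- tibble(doc_id = docid, start = sent_start, end = sent_end)
  ents_tbl <- tibble(
    doc_id = rep(docid, each = 2),
    entity_id = as.vector(rbind(ent_a, ent_b)),
    start = as.vector(rbind(sent_start, sent_start + s_entb$start)),
    end = as.vector(rbind(sent_start + nchar(name_a),
                          sent_start + s_entb$end)),
    type = rep(c("protein", "gene"), total))
  parts_tbl <- tibble(
    doc_id = rep(docid, each = 2),
    event_id = rep(evid, each = 2),
    role = rep(c("Cause", "Theme"), total),
    ref = as.vector(rbind(ent_a, ent_b)))

  clue_rows <- function(slot, dim) {
    ok <- !is.na(slot$start)
    tibble(doc_id = docid[ok], event_id = evid[ok], dimension = dim,
           start = sent_start[ok] + slot$start[ok],
           end = sent_start[ok] + slot$end[ok])
  }
  kt_dim_rows <- clue_rows(s_kt, "KT")
  # a dual-role cue in the KT slot also licenses the CL value
  shared_rows <- clue_rows(s_kt, "CL")[shared_cl[!is.na(s_kt$start)], ,
                                       drop = FALSE]
  clues_tbl <- bind_rows(kt_dim_rows, shared_rows, clue_rows(s_cl, "CL"),
                         clue_rows(s_pol, "Polarity"),
                         clue_rows(s_man, "Manner"),
                         clue_rows(s_src, "Source"))

  doc_text <- vapply(split(txt, factor(doc_idx,
                                       levels = seq_len(spec$n_documents))),
                     paste, character(1), collapse = " ")
  docs_tbl <- tibble(doc_id = doc_ids, text = unname(doc_text))
  }

  # optional distractor sentence (event-free, stuffed with clue words)
  has_distractor <- runif(spec$n_documents) < spec$distractor_prob
  if (any(has_distractor)) {
    distractor <- "Previous studies may suggest no significant findings ."
    dlen <- nchar(doc_text[has_distractor])
    dstart <- ifelse(dlen > 0, dlen + 1L, 0L)
    docs_tbl$text[has_distractor] <- ifelse(
      dlen > 0, paste(doc_text[has_distractor], distractor), distractor)
    sents_tbl <- bind_rows(sents_tbl, tibble(
      doc_id = doc_ids[has_distractor], start = as.integer(dstart),
      end = as.integer(dstart + nchar(distractor))))
  }

  corpus <- mk_corpus(
    documents = docs_tbl, sentences = sents_tbl, entities = ents_tbl,
    events = events_tbl, participants = parts_tbl, clues = clues_tbl)
  truth <- corpus$events %>%
    select("doc_id", "event_id", "kt", "cl", "polarity", "manner", "source")
  structure(list(corpus = corpus, truth = truth), class = "mk_simulation")
}

#' @export
print.mk_simulation <- function(x, ...) {
  cat("<mk_simulation> with ground truth for", nrow(x$truth), "event(s)\n")
  print(x$corpus)
  invisible(x)
}

# insert `text` at 0-based position `pos` of one document, shifting all
# span coordinates (starts at or after pos; ends after pos)
insert_text_at <- function(corpus, doc_id, pos, text) {
  n <- nchar(text)
  di <- which(corpus$documents$doc_id == doc_id)
  old <- corpus$documents$text[di]
  corpus$documents$text[di] <- paste0(substr(old, 1, pos), text,
                                      substr(old, pos + 1, nchar(old)))
  shift <- function(tbl, scol, ecol) {
    sel <- tbl$doc_id == doc_id
    s <- tbl[[scol]]; e <- tbl[[ecol]]
    tbl[[scol]] <- ifelse(sel & !is.na(s) & s >= pos, s + n, s)
    tbl[[ecol]] <- ifelse(sel & !is.na(e) & e > pos, e + n, e)
    tbl
  }
  corpus$sentences <- shift(corpus$sentences, "start", "end")
  corpus$entities <- shift(corpus$entities, "start", "end")
  corpus$events <- shift(corpus$events, "trigger_start", "trigger_end")
  corpus$clues <- shift(corpus$clues, "start", "end")
  corpus
}

#' Perturb a corpus's annotations through confusion matrices
#'
#' Independently relabels each event's value on each dimension according to
#' per-dimension confusion matrices, emulating a second annotator with known
#' error rates. Clue spans are adjusted to preserve validity: when a value
#' becomes the dimension default its clues are dropped; when it becomes a
#' (different) non-default value the old clues are dropped and an
#' appropriate lexicon clue word is spliced into the trigger's sentence just
#' before the trigger, with all downstream spans shifted.
#'
#' @param x An [mk_corpus()] or `mk_simulation`.
#' @param confusion Named list of square matrices, one per dimension to
#'   perturb (`KT`, `CL`, `Polarity`, `Manner`, `Source`); rows = true
#'   value, columns = relabelled value, rows summing to 1, dimnames from the
#'   dimension's category inventory. Dimensions not listed are left alone.
#' @param seed Integer seed.
#' @return A new `mk_corpus` with perturbed annotations.
#' @examples
#' sim <- generate_corpus(mk_generation_spec(n_documents = 2,
#'                                           events_per_doc = 4), seed = 1)
#' flip <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE,
#'                dimnames = list(c("Positive", "Negative"),
#'                                c("Positive", "Negative")))
#' pert <- perturb_annotations(sim, list(Polarity = flip), seed = 2)
#' @export
perturb_annotations <- function(x, confusion, seed) {
  corpus <- if (inherits(x, "mk_simulation")) x$corpus else x
  assert_mk_corpus(corpus)
  set.seed(as.integer(seed))
  dims <- mk_dimensions()
  cols <- mk_dimension_columns()
  for (d in names(confusion)) {
    if (!d %in% names(dims)) abort(paste0("unknown dimension: ", d))
    m <- confusion[[d]]
    vals <- dims[[d]]
    if (!is.matrix(m) || !all(vals %in% rownames(m)) ||
          !all(vals %in% colnames(m))) {
      abort(paste0("confusion[['", d, "']] must be a square matrix with ",
                   "dimnames covering: ", paste(vals, collapse = ", ")))
    }
    m <- m[vals, vals]
    if (any(abs(rowSums(m) - 1) > 1e-9) || any(m < 0)) {
      abort(paste0("rows of confusion[['", d, "']] must sum to 1"))
    }
  }

  ev <- corpus$events
  for (d in names(confusion)) {
    m <- confusion[[d]][dims[[d]], dims[[d]]]
    col <- cols[[d]]
    old_vals <- ev[[col]]
    new_vals <- vapply(old_vals, function(v) {
      sample(colnames(m), 1, prob = m[v, ])
    }, character(1))
    changed <- which(new_vals != old_vals)
    corpus$events[[col]] <- unname(new_vals)
    ev <- corpus$events
    for (i in changed) {
      docid <- ev$doc_id[i]; evid <- ev$event_id[i]
      # old clues for this dimension no longer describe the value
      drop <- corpus$clues$doc_id == docid & corpus$clues$event_id == evid &
        corpus$clues$dimension == d
      corpus$clues <- corpus$clues[!drop, , drop = FALSE]
      v <- ev[[col]][i]
      if (clue_required(d, v) && !is.na(ev$trigger_start[i])) {
        cand <- generator_clue_candidates(d, v, ev$kt[i], ev$cl[i])
        w <- if (length(cand) == 1) cand else sample(cand, 1)
        pos <- ev$trigger_start[i]
        corpus <- insert_text_at(corpus, docid, pos, paste0(w, " "))
        corpus$clues <- bind_rows(corpus$clues, tibble(
          doc_id = docid, event_id = evid, dimension = d,
          start = pos, end = pos + nchar(w)))
        ev <- corpus$events
      }
    }
  }
  corpus$clues <- coerce_mk_table(arrange(corpus$clues, .data$doc_id,
                                          .data$event_id, .data$dimension,
                                          .data$start), "clues")
  corpus
}
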