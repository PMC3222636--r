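# Inter-annotator agreement: unweighted Cohen's kappa per dimension, plus a
# discrepancy report. Events are paired by id, with a (trigger span, event
# type) fallback; events present in only one annotation are excluded from
# kappa but listed, since both annotators are expected to label a fixed
# event set.

#' Align the events of two annotations of the same documents
#'
#' Pairs events document by document, first by event id, then — for the
#' leftovers — by (trigger span, event type). Both corpora must cover the
#' same document ids.
#'
#' @param corpus_a,corpus_b [mk_corpus()] objects over the same documents.
#' @return A list with `pairs` (tibble: `doc_id`, `event_id_a`,
#'   `event_id_b`, `method` = `"id"`/`"span"`), `unmatched_a` and
#'   `unmatched_b` (tibbles of `doc_id`, `event_id`).
#' @export
align_events <- function(corpus_a, corpus_b) {
  assert_mk_corpus(corpus_a, "corpus_a")
  assert_mk_corpus(corpus_b, "corpus_b")
  ids_a <- sort(unique(corpus_a$documents$doc_id))
  ids_b <- sort(unique(corpus_b$documents$doc_id))
  if (!identical(ids_a, ids_b)) {
    diff <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    abort(paste0("document sets differ; symmetric difference: ",
                 paste(diff, collapse = ", ")))
  }
  eva <- corpus_a$events
  evb <- corpus_b$events
  key_a <- paste(eva$doc_id, eva$event_id)
  key_b <- paste(evb$doc_id, evb$event_id)
  by_id <- intersect(key_a, key_b)
  idx <- match(by_id, key_a)
  pairs <- tibble(
    doc_id = eva$doc_id[idx],
    event_id_a = eva$event_id[idx],
    event_id_b = eva$event_id[idx],
    method = rep("id", length(by_id))
  )
  rest_a <- eva[!key_a %in% by_id, , drop = FALSE]
  rest_b <- evb[!key_b %in% by_id, , drop = FALSE]
  if (nrow(rest_a) > 0 && nrow(rest_b) > 0) {
    span_key <- function(ev) paste(ev$doc_id, ev$trigger_start,
                                   ev$trigger_end, ev$event_type)
    sk_a <- span_key(rest_a); sk_b <- span_key(rest_b)
    # one-to-one span matches only; duplicated spans stay unmatched
    usable <- intersect(sk_a[!duplicated(sk_a) & !sk_a %in% sk_a[duplicated(sk_a)]],
                        sk_b[!duplicated(sk_b) & !sk_b %in% sk_b[duplicated(sk_b)]])
    usable <- usable[!grepl(" NA NA ", usable, fixed = TRUE)]
    if (length(usable) > 0) {
      ia <- match(usable, sk_a); ib <- match(usable, sk_b)
      pairs <- bind_rows(pairs, tibble(
        doc_id = rest_a$doc_id[ia],
        event_id_a = rest_a$event_id[ia],
        event_id_b = rest_b$event_id[ib],
        method = "span"))
      rest_a <- rest_a[-ia, , drop = FALSE]
      rest_b <- rest_b[-ib, , drop = FALSE]
    }
  }
  list(
    pairs = arrange(pairs, .data$doc_id, .data$event_id_a),
    unmatched_a = rest_a %>% select("doc_id", "event_id") %>%
      arrange(.data$doc_id, .data$event_id),
    unmatched_b = rest_b %>% select("doc_id", "event_id") %>%
      arrange(.data$doc_id, .data$event_id)
  )
}

#' Cohen's kappa for two label sequences
#'
#' Chance-corrected agreement between two annotators over the same items:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` the
#' fraction of equal labels and expected agreement
#' `p_e = sum_c m_a(c) * m_b(c)` over the annotators' marginal label
#' distributions. Unweighted: all disagreements count equally. When both
#' `p_o` and `p_e` are 1 kappa is defined as 1; when `p_e = 1` with
#' `p_o < 1` kappa is undefined and returned as `NA` with `undefined =
#' TRUE`.
#'
#' @param labels_a,labels_b Equal-length character vectors of labels.
#' @param categories Label inventory (default: the labels observed).
#' @return A list with `kappa`, `p_o`, `p_e`, `n`, `undefined`.
#' @examples
#' cohens_kappa(c("x", "x", "y", "y"), c("y", "y", "x", "x"))  # kappa -1
#' @export
cohens_kappa <- function(labels_a, labels_b, categories = NULL) {
  if (length(labels_a) != length(labels_b)) {
    abort("labels_a and labels_b must have the same length")
  }
  n <- length(labels_a)
  if (n < 1) abort("at least one label pair is required")
  if (is.null(categories)) categories <- sort(unique(c(labels_a, labels_b)))
  unknown <- setdiff(unique(c(labels_a, labels_b)), categories)
  if (length(unknown) > 0) {
    abort(paste0("label(s) outside the category set: ",
                 paste(unknown, collapse = ", ")))
  }
  p_o <- mean(labels_a == labels_b)
  m_a <- table(factor(labels_a, levels = categories)) / n
  m_b <- table(factor(labels_b, levels = categories)) / n
  p_e <- sum(as.numeric(m_a) * as.numeric(m_b))
  if (p_e >= 1) {
    if (p_o == 1) {
      return(list(kappa = 1, p_o = 1, p_e = 1, n = n, undefined = FALSE))
    }
    return(list(kappa = NA_real_, p_o = p_o, p_e = 1, n = n,
                undefined = TRUE))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = n,
       undefined = FALSE)
}

#' Per-dimension agreement between two annotations
#'
#' Aligns the two corpora (see [align_events()]) and computes Cohen's kappa
#' for each of the five dimensions over the aligned event pairs, together
#' with a discrepancy list recording every disagreeing (event, dimension)
#' cell and the clue surface each annotator used.
#'
#' @param corpus_a,corpus_b [mk_corpus()] objects over the same documents.
#' @return An object of class `mk_agreement`: a list with `summary` (tibble:
#'   `dimension`, `kappa`, `p_o`, `p_e`, `n`, `undefined`), `discrepancies`
#'   (tibble: `doc_id`, `event_id`, `dimension`, `value_a`, `value_b`,
#'   `clue_a`, `clue_b`, sorted by document, event, dimension), `unmatched_a`
#'   and `unmatched_b`. Supports [tidy()], [glance()], [autoplot()].
#' @export
per_dimension_agreement <- function(corpus_a, corpus_b) {
  al <- align_events(corpus_a, corpus_b)
  pairs <- al$pairs
  eva <- corpus_a$events; evb <- corpus_b$events
  ia <- match(paste(pairs$doc_id, pairs$event_id_a),
              paste(eva$doc_id, eva$event_id))
  ib <- match(paste(pairs$doc_id, pairs$event_id_b),
              paste(evb$doc_id, evb$event_id))
  cols <- mk_dimension_columns()
  dims <- mk_dimensions()

  clue_surface <- function(corpus, idx_doc, idx_event, d) {
    cl <- corpus$clues[corpus$clues$dimension == d, , drop = FALSE]
    key <- paste(cl$doc_id, cl$event_id)
    text <- setNames(corpus$documents$text, corpus$documents$doc_id)
    hit <- match(paste(idx_doc, idx_event), key)
    ifelse(is.na(hit), NA_character_,
           substr(text[cl$doc_id[hit]], cl$start[hit] + 1L, cl$end[hit]))
  }

  summaries <- list(); disc <- list()
  for (d in names(dims)) {
    va <- eva[[cols[[d]]]][ia]
    vb <- evb[[cols[[d]]]][ib]
    if (nrow(pairs) == 0) {
      summaries <- c(summaries, list(tibble(
        dimension = d, kappa = NA_real_, p_o = NA_real_, p_e = NA_real_,
        n = 0L, undefined = TRUE)))
      next
    }
    k <- cohens_kappa(va, vb, categories = dims[[d]])
    summaries <- c(summaries, list(tibble(
      dimension = d, kappa = k$kappa, p_o = k$p_o, p_e = k$p_e,
      n = as.integer(k$n), undefined = k$undefined)))
    bad <- which(va != vb)
    if (length(bad) > 0) {
      disc <- c(disc, list(tibble(
        doc_id = pairs$doc_id[bad],
        event_id = pairs$event_id_a[bad],
        dimension = d,
        value_a = va[bad], value_b = vb[bad],
        clue_a = clue_surface(corpus_a, pairs$doc_id[bad],
                              pairs$event_id_a[bad], d),
        clue_b = clue_surface(corpus_b, pairs$doc_id[bad],
                              pairs$event_id_b[bad], d))))
    }
  }
  disc <- if (length(disc) > 0) {
    bind_rows(disc) %>% arrange(.data$doc_id, .data$event_id, .data$dimension)
  } else {
    tibble(doc_id = character(), event_id = character(),
           dimension = character(), value_a = character(),
           value_b = character(), clue_a = character(), clue_b = character())
  }
  structure(list(summary = bind_rows(summaries), discrepancies = disc,
                 unmatched_a = al$unmatched_a, unmatched_b = al$unmatched_b),
            class = "mk_agreement")
}

#' @export
print.mk_agreement <- function(x, ...) {
  cat("<mk_agreement> per-dimension Cohen's kappa over",
      if (nrow(x$summary) > 0) x$summary$n[1] else 0, "aligned event pairs\n")
  print(x$summary)
  cat(nrow(x$discrepancies), "discrepanc(ies);",
      nrow(x$unmatched_a), "unmatched in a,",
      nrow(x$unmatched_b), "in b\n")
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `mk_agreement` object.
#' @param ... Unused.
#' @return The per-dimension summary tibble (`dimension`, `kappa`, `p_o`,
#'   `p_e`, `n`, `undefined`).
#' @exportS3Method generics::tidy
tidy.mk_agreement <- function(x, ...) x$summary

#' One-row overview of an agreement report
#'
#' @param x An `mk_agreement` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_dimensions`, `min_kappa`,
#'   `max_kappa`, `mean_kappa`, `n_discrepancies`, `n_unmatched`.
#' @exportS3Method generics::glance
glance.mk_agreement <- function(x, ...) {
  k <- x$summary$kappa
  tibble(
    n_pairs = if (nrow(x$summary) > 0) x$summary$n[1] else 0L,
    n_dimensions = nrow(x$summary),
    min_kappa = suppressWarnings(min(k, na.rm = TRUE)),
    max_kappa = suppressWarnings(max(k, na.rm = TRUE)),
    mean_kappa = mean(k, na.rm = TRUE),
    n_discrepancies = nrow(x$discrepancies),
    n_unmatched = nrow(x$unmatched_a) + nrow(x$unmatched_b)
  )
}

#' Plot per-dimension agreement
#'
#' @param object An `mk_agreement` object.
#' @param ... Unused.
#' @return A ggplot bar chart of kappa by dimension.
#' @exportS3Method ggplot2::autoplot
autoplot.mk_agreement <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = stats::reorder(.data$dimension,
                                                  -.data$kappa),
                               y = .data$kappa)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Cohen's kappa") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
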