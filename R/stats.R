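# Distribution tables. All percentages flow through mk_round_pct() so the
# rounding convention is a single point of change.

#' Distribution of annotated categories for one dimension
#'
#' Counts events per category of a dimension, including zero-count
#' categories (no category is redundant), sorted by count descending with
#' the canonical category order breaking ties. Percentages are of total
#' events, rounded half-up to one decimal.
#'
#' @param x An [mk_corpus()] or events data frame (see [as_mk_events()]).
#' @param dimension One of `"KT"`, `"CL"`, `"Polarity"`, `"Manner"`,
#'   `"Source"`.
#' @return A tibble of class `mk_distribution` with columns `dimension`,
#'   `category`, `n`, `pct_total`.
#' @examples
#' ev <- tibble::tibble(polarity = rep(c("Positive", "Negative"), c(9, 1)))
#' dimension_distribution(ev, "Polarity")
#' @export
dimension_distribution <- function(x, dimension) {
  ev <- as_mk_events(x)
  values <- mk_dimension_values(dimension)
  col <- mk_dimension_columns()[[dimension]]
  total <- nrow(ev)
  counts <- table(factor(ev[[col]], levels = values))
  out <- tibble(
    dimension = dimension,
    category = values,
    n = as.integer(counts),
    pct_total = if (total == 0) rep(0, length(values)) else
      mk_round_pct(100 * as.integer(counts) / total)
  )
  out <- out[order(-out$n, match(out$category, values)), ]
  class(out) <- c("mk_distribution", class(out))
  out
}

#' Cross-tabulate a dimension's marked values against Knowledge Type
#'
#' For each KT category, counts the events whose value on another dimension
#' falls in a chosen category set (for example `Polarity = Negative`, or
#' `Manner` in `{High, Low}`), and reports the share within that KT
#' category, rounded half-up to one decimal.
#'
#' @param x An [mk_corpus()] or events data frame.
#' @param dimension A dimension other than `"KT"`.
#' @param categories Character vector of values of `dimension` to count
#'   (default: all non-default values).
#' @return A tibble with columns `kt_category`, `n`, `kt_total`,
#'   `pct_within`, `empty_category` (flags KT categories with zero events,
#'   whose `pct_within` is reported as 0), sorted by `n` descending.
#' @examples
#' ev <- tibble::tibble(kt = c("Observation", "Observation", "Analysis"),
#'                      polarity = c("Negative", "Positive", "Positive"))
#' kt_cross_tab(ev, "Polarity", "Negative")
#' @export
kt_cross_tab <- function(x, dimension, categories = NULL) {
  if (dimension == "KT") abort("cross-tabulation dimension must not be KT")
  ev <- as_mk_events(x)
  values <- mk_dimension_values(dimension)
  if (is.null(categories)) {
    categories <- values[!vapply(values, function(v)
      is_default_value(dimension, v), logical(1))]
  }
  bad <- setdiff(categories, values)
  if (length(bad) > 0) {
    abort(paste0("unknown ", dimension, " categor(ies): ",
                 paste(bad, collapse = ", ")))
  }
  col <- mk_dimension_columns()[[dimension]]
  kt_values <- mk_dimension_values("KT")
  kt_f <- factor(ev$kt, levels = kt_values)
  totals <- as.integer(table(kt_f))
  marked <- as.integer(table(kt_f[ev[[col]] %in% categories]))
  out <- tibble(
    kt_category = kt_values,
    n = marked,
    kt_total = totals,
    pct_within = ifelse(totals == 0, 0,
                        mk_round_pct(100 * marked / pmax(totals, 1L))),
    empty_category = totals == 0
  )
  out[order(-out$n, match(out$kt_category, kt_values)), ]
}

#' Frequency of clue surface forms for one dimension value
#'
#' Extracts the surface text of every clue span annotated on events holding
#' a given value of a dimension, lower-cases it, and ranks forms by count
#' (ties alphabetically).
#'
#' @param corpus An [mk_corpus()] (document text is required to recover
#'   surface forms).
#' @param dimension The clue dimension.
#' @param value Count only clues on events annotated with this value of the
#'   dimension (default: any value).
#' @return A tibble with columns `surface`, `n`; the number of distinct
#'   forms is attached as attribute `n_distinct` and equals `nrow()`.
#' @export
clue_frequency <- function(corpus, dimension, value = NULL) {
  assert_mk_corpus(corpus)
  cl <- corpus$clues[corpus$clues$dimension == dimension, , drop = FALSE]
  if (!is.null(value)) {
    col <- mk_dimension_columns()[[dimension]]
    ev <- corpus$events[corpus$events[[col]] == value, , drop = FALSE]
    cl <- cl[paste(cl$doc_id, cl$event_id) %in%
               paste(ev$doc_id, ev$event_id), , drop = FALSE]
  }
  if (nrow(cl) == 0) {
    out <- tibble(surface = character(), n = integer())
    attr(out, "n_distinct") <- 0L
    return(out)
  }
  text <- setNames(corpus$documents$text, corpus$documents$doc_id)
  cl$surface <- unname(tolower(substr(text[cl$doc_id], cl$start + 1L,
                                      cl$end)))
  out <- cl %>% count(.data$surface, name = "n") %>%
    arrange(desc(.data$n), .data$surface)
  attr(out, "n_distinct") <- nrow(out)
  out
}

#' Distribution of the two derived hyper-dimensions
#'
#' Applies the New Knowledge and Hypothesis inference tables to every event
#' and reports Yes/No counts with percentages of total events.
#'
#' @param x An [mk_corpus()] or events data frame.
#' @return A tibble of class `mk_distribution` with columns `dimension`
#'   (`"NewKnowledge"`/`"Hypothesis"`), `category` (`"Yes"`/`"No"`), `n`,
#'   `pct_total`, plus an `empty_corpus` attribute flag when there are no
#'   events.
#' @examples
#' ev <- tibble::tibble(kt = "Observation", cl = "L3", source = "Current")
#' hyperdim_distribution(ev)
#' @export
hyperdim_distribution <- function(x) {
  ev <- infer_hyperdimensions(x)
  total <- nrow(ev)
  one <- function(flags, label) {
    yes <- sum(flags)
    tibble(dimension = label, category = c("Yes", "No"),
           n = as.integer(c(yes, total - yes)),
           pct_total = if (total == 0) c(0, 0) else
             mk_round_pct(100 * c(yes, total - yes) / total))
  }
  out <- bind_rows(one(ev$new_knowledge, "NewKnowledge"),
                   one(ev$hypothesis, "Hypothesis"))
  attr(out, "empty_corpus") <- total == 0
  class(out) <- c("mk_distribution", class(out))
  out
}

#' Plot a distribution table
#'
#' Bar chart of category percentages, faceted by dimension when the table
#' covers more than one.
#'
#' @param object An `mk_distribution` tibble from
#'   [dimension_distribution()] or [hyperdim_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mk_distribution <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = stats::reorder(.data$category,
                                                       -.data$n),
                                    y = .data$pct_total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of total events") +
    ggplot2::theme_minimal()
  if (length(unique(object$dimension)) > 1) {
    p <- p + ggplot2::facet_wrap(~dimension, scales = "free_x")
  }
  p
}
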