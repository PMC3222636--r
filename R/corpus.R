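# Stand-off corpus container: six tibbles keyed by document id. Offsets are
# 0-based, half-open character offsets into the document text (start
# inclusive, end exclusive), so substr(text, start + 1, end) recovers a span.

mk_table_schemas <- function() {
  list(
    documents = c(doc_id = "character", text = "character"),
    sentences = c(doc_id = "character", start = "integer", end = "integer"),
    entities = c(doc_id = "character", entity_id = "character",
                 start = "integer", end = "integer", type = "character"),
    events = c(doc_id = "character", event_id = "character",
               event_type = "character",
               trigger_start = "integer", trigger_end = "integer",
               kt = "character", cl = "character", polarity = "character",
               manner = "character", source = "character"),
    participants = c(doc_id = "character", event_id = "character",
                     role = "character", ref = "character"),
    clues = c(doc_id = "character", event_id = "character",
              dimension = "character", start = "integer", end = "integer")
  )
}

empty_mk_table <- function(name) {
  schema <- mk_table_schemas()[[name]]
  cols <- lapply(schema, function(ty) vector(ty, 0L))
  as_tibble(cols)
}

coerce_mk_table <- function(df, name) {
  schema <- mk_table_schemas()[[name]]
  if (is.null(df)) return(empty_mk_table(name))
  df <- as_tibble(df)
  if (nrow(df) == 0 && ncol(df) == 0) return(empty_mk_table(name))
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    # meta-knowledge columns may be omitted; they take scheme defaults
    defaults <- default_metaknowledge()
    fillable <- intersect(missing, names(defaults))
    for (col in fillable) df[[col]] <- defaults[[col]][rep(1L, nrow(df))]
    missing <- setdiff(missing, fillable)
  }
  if (length(missing) > 0) {
    abort(paste0("Corpus table '", name, "' is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
                        character = as.character(df[[col]]),
                        integer = as.integer(df[[col]]))
  }
  df[, names(schema)]
}

#' Construct a stand-off annotated event corpus
#'
#' An `mk_corpus` bundles six tibbles describing documents, their sentence
#' segmentation, entity mentions, events, event participants, and the clue
#' expressions justifying non-default meta-knowledge values. All character
#' offsets are 0-based, half-open, relative to the owning document's text.
#'
#' @param documents Tibble with columns `doc_id`, `text`.
#' @param sentences Tibble with columns `doc_id`, `start`, `end`; spans must
#'   be ordered and non-overlapping within a document.
#' @param entities Tibble with columns `doc_id`, `entity_id`, `start`, `end`,
#'   `type`.
#' @param events Tibble with columns `doc_id`, `event_id`, `event_type`,
#'   `trigger_start`, `trigger_end` (both `NA` for triggerless events), and
#'   the five dimension columns `kt`, `cl`, `polarity`, `manner`, `source`
#'   (omitted columns are filled with scheme defaults).
#' @param participants Tibble with columns `doc_id`, `event_id`, `role`,
#'   `ref`; `ref` names an entity id or another event id in the same
#'   document.
#' @param clues Tibble with columns `doc_id`, `event_id`, `dimension`
#'   (`KT`/`CL`/`Polarity`/`Manner`/`Source`), `start`, `end`.
#' @return An object of class `mk_corpus`.
#' @seealso [validate_corpus()], [read_corpus()], [write_corpus()]
#' @examples
#' corp <- mk_corpus(
#'   documents = tibble::tibble(doc_id = "d1", text = "IkBa inhibits NFkB."),
#'   sentences = tibble::tibble(doc_id = "d1", start = 0L, end = 19L),
#'   events = tibble::tibble(doc_id = "d1", event_id = "E1",
#'                           event_type = "Negative_Regulation",
#'                           trigger_start = 5L, trigger_end = 13L)
#' )
#' corp
#' @export
mk_corpus <- function(documents = NULL, sentences = NULL, entities = NULL,
                      events = NULL, participants = NULL, clues = NULL) {
  x <- list(
    documents = coerce_mk_table(documents, "documents"),
    sentences = coerce_mk_table(sentences, "sentences"),
    entities = coerce_mk_table(entities, "entities"),
    events = coerce_mk_table(events, "events"),
    participants = coerce_mk_table(participants, "participants"),
    clues = coerce_mk_table(clues, "clues")
  )
  structure(x, class = "mk_corpus")
}

#' @export
print.mk_corpus <- function(x, ...) {
  cat("<mk_corpus> ", nrow(x$documents), " document(s), ",
      nrow(x$events), " event(s), ", nrow(x$clues), " clue span(s)\n", sep = "")
  invisible(x)
}

#' Test or assert that an object is an `mk_corpus`
#' @param x Object to test.
#' @return `is_mk_corpus()` returns a logical scalar.
#' @export
is_mk_corpus <- function(x) inherits(x, "mk_corpus")

assert_mk_corpus <- function(x, arg = "corpus") {
  if (!is_mk_corpus(x)) abort(paste0("`", arg, "` must be an mk_corpus object"))
  invisible(x)
}

#' Extract the events table from a corpus or pass a data frame through
#'
#' Statistics functions accept either a full [mk_corpus()] or a bare events
#' data frame (useful for reconstructing published distribution tables from
#' printed counts without inventing document text).
#'
#' @param x An `mk_corpus` or a data frame with the event dimension columns.
#' @return A tibble of events with the five dimension columns present.
#' @export
as_mk_events <- function(x) {
  if (is_mk_corpus(x)) return(x$events)
  if (is.data.frame(x)) {
    df <- as_tibble(x)
    defaults <- default_metaknowledge()
    for (col in names(defaults)) {
      if (!col %in% names(df)) df[[col]] <- defaults[[col]][rep(1L, nrow(df))]
    }
    return(df)
  }
  abort("`x` must be an mk_corpus or a data frame of events")
}

# stable row order used by writers and equality checks
normalise_corpus <- function(corpus) {
  corpus$documents <- arrange(corpus$documents, .data$doc_id)
  corpus$sentences <- arrange(corpus$sentences, .data$doc_id, .data$start)
  corpus$entities <- arrange(corpus$entities, .data$doc_id, .data$entity_id)
  corpus$events <- arrange(corpus$events, .data$doc_id, .data$event_id)
  corpus$participants <- arrange(corpus$participants, .data$doc_id,
                                 .data$event_id, .data$role, .data$ref)
  corpus$clues <- arrange(corpus$clues, .data$doc_id, .data$event_id,
                          .data$dimension, .data$start)
  corpus
}

#' Field-wise equality of two corpora
#'
#' Compares all six tables after sorting into canonical row order, so two
#' corpora that differ only in row order compare equal.
#'
#' @param a,b `mk_corpus` objects.
#' @return Logical scalar.
#' @export
corpus_equal <- function(a, b) {
  assert_mk_corpus(a, "a"); assert_mk_corpus(b, "b")
  a <- normalise_corpus(a); b <- normalise_corpus(b)
  all(vapply(names(a), function(nm) identical(as.data.frame(a[[nm]]),
                                              as.data.frame(b[[nm]])),
             logical(1)))
}
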