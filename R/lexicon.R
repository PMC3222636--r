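# Clue lexicon: surface patterns licensing non-default dimension values.
# The packaged lexicon compiles the most common annotated clue expressions
# for each dimension (hedging, negation, manner and attribution cues) plus
# numeral patterns such as "{NUM}-fold". It ships as an editable TSV so
# users can extend it, mirroring how annotation clue lists grow in practice.

the <- new.env(parent = emptyenv())

#' Read a clue lexicon from a TSV file
#'
#' The file format is tab-separated with a header line
#' `pattern dimension value event_types priority` and `#` comment lines.
#' `pattern` holds space-separated literal tokens; the placeholders `{NUM}`
#' (a numeral) and `{PCT}` (a percentage) may be embedded and never stand
#' alone. `event_types` is `"*"` or a comma-separated set of event types the
#' clue is restricted to; e.g. *independent* only signals negation on
#' correlation/regulation events. Matching is case-insensitive on whole
#' words.
#'
#' @param path Path to a lexicon TSV.
#' @return A tibble of class `mk_lexicon` with columns `pattern`,
#'   `dimension`, `value`, `event_types` (list column of character vectors,
#'   `NULL` meaning unconditional), `priority`, `n_tokens`, and a compiled
#'   `regex` column.
#' @seealso [default_clue_lexicon()], [match_clues()]
#' @export
read_clue_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 1) abort("lexicon file has no header line")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("pattern", "dimension", "value", "event_types", "priority")
  if (!identical(header, expected)) {
    abort(paste0("lexicon header must be: ", paste(expected, collapse = ", ")))
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- lengths(rows) != 5
  if (any(bad)) abort(paste0("malformed lexicon line(s): ",
                             paste(which(bad) + 1, collapse = ", ")))
  lex <- tibble(
    pattern = vapply(rows, `[[`, character(1), 1),
    dimension = vapply(rows, `[[`, character(1), 2),
    value = vapply(rows, `[[`, character(1), 3),
    event_types = lapply(rows, function(r) {
      if (r[[4]] == "*") NULL else strsplit(r[[4]], ",", fixed = TRUE)[[1]]
    }),
    priority = as.integer(vapply(rows, `[[`, character(1), 5))
  )
  validate_lexicon(lex)
  lex$n_tokens <- lengths(strsplit(lex$pattern, " ", fixed = TRUE))
  lex$regex <- vapply(lex$pattern, compile_clue_pattern, character(1))
  class(lex) <- c("mk_lexicon", class(lex))
  lex
}

validate_lexicon <- function(lex) {
  dims <- mk_dimensions()
  bad_dim <- !lex$dimension %in% names(dims)
  if (any(bad_dim)) {
    abort(paste0("unknown dimension in lexicon: ",
                 paste(unique(lex$dimension[bad_dim]), collapse = ", ")))
  }
  bad_val <- !purrr::map2_lgl(lex$dimension, lex$value,
                              function(d, v) v %in% dims[[d]])
  if (any(bad_val)) {
    abort(paste0("illegal value for dimension in lexicon: ",
                 paste(unique(paste0(lex$dimension[bad_val], "=",
                                     lex$value[bad_val])), collapse = ", ")))
  }
  dup <- duplicated(paste(tolower(lex$pattern), lex$dimension))
  if (any(dup)) {
    abort(paste0("duplicate (pattern, dimension) pair(s): ",
                 paste(unique(lex$pattern[dup]), collapse = ", ")))
  }
  # defaults never need licensing, so a clue must assign a non-default value
  is_def <- purrr::map2_lgl(lex$dimension, lex$value, is_default_value)
  if (any(is_def)) {
    abort("lexicon entries must assign non-default values")
  }
  stripped <- gsub("\\{(NUM|PCT)\\}", "", lex$pattern)
  if (any(!grepl("[[:alpha:]]", stripped))) {
    abort("every pattern needs at least one literal token")
  }
  invisible(lex)
}

# pattern string -> ICU regex with word boundaries; {NUM} = numeral,
# {PCT} = numeral followed by %
compile_clue_pattern <- function(pattern) {
  x <- gsub("{NUM}", "QQNUMQQ", pattern, fixed = TRUE)
  x <- gsub("{PCT}", "QQPCTQQ", x, fixed = TRUE)
  x <- gsub("([^[:alnum:][:space:]])", "\\\\\\1", x, perl = TRUE)
  x <- gsub(" ", "\\s+", x, fixed = TRUE)
  x <- gsub("QQNUMQQ", "\\d+(?:\\.\\d+)?", x, fixed = TRUE)
  x <- gsub("QQPCTQQ", "\\d+(?:\\.\\d+)?%", x, fixed = TRUE)
  paste0("(?<![[:alnum:]])", x, "(?![[:alnum:]])")
}

#' The packaged clue lexicon
#'
#' Loads (and caches) the lexicon shipped with the package. It contains the
#' most common clue expressions for each dimension value: *Analysis* /
#' *Investigation* / *Observation* / *Fact* markers for KT; hedges such as
#' *suggest*, *likely* (L2) and *may*, *might* (L1) for CL; negation cues
#' (*not*, *no*, *without*, ...) for Polarity, including event-type
#' conditioned cues (*independent*, *normal*, *silent*); degree expressions
#' and `{NUM}-fold` patterns for Manner; and attribution cues (*previously*,
#' *has been*, ...) for Source. Dual-role cues such as *suggest* appear once
#' per dimension they can license (KT = Analysis and CL = L2).
#'
#' @return An `mk_lexicon` tibble (see [read_clue_lexicon()]).
#' @examples
#' lex <- default_clue_lexicon()
#' dplyr::filter(lex, pattern == "suggest")[, 1:3]
#' @export
default_clue_lexicon <- function() {
  if (is.null(the$default_lexicon)) {
    path <- system.file("extdata", "clue_lexicon.tsv", package = "metamk")
    if (path == "") abort("packaged lexicon resource is missing")
    the$default_lexicon <- read_clue_lexicon(path)
  }
  the$default_lexicon
}

#' Match clue expressions in one sentence
#'
#' Finds all lexicon patterns in a sentence, case-insensitively and on whole
#' words, left to right. A match whose span is strictly contained in a
#' longer match is suppressed whatever its dimension, so *no significant*
#' (Manner = Low) silences both the *no* negation cue and the *significant*
#' high-manner cue inside it. Identical spans licensing two dimensions (for
#' example *suggest* as KT = Analysis and CL = L2) are both kept.
#'
#' @param sentence_text The sentence substring.
#' @param sentence_start 0-based offset of the sentence within its document
#'   (default 0), used to express match spans in document coordinates.
#' @param lexicon An `mk_lexicon` (default: the packaged lexicon).
#' @return A tibble with columns `start`, `end` (document coordinates),
#'   `surface`, `pattern`, `dimension`, `value`, `event_types`, `priority`,
#'   `n_tokens`.
#' @examples
#' match_clues("had no significant influence on binding")[, 1:6]
#' @export
match_clues <- function(sentence_text, sentence_start = 0L,
                        lexicon = default_clue_lexicon()) {
  hits <- purrr::map(seq_len(nrow(lexicon)), function(i) {
    loc <- stringr::str_locate_all(
      sentence_text,
      stringr::regex(lexicon$regex[i], ignore_case = TRUE))[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble(
      start = as.integer(sentence_start + loc[, 1] - 1L),
      end = as.integer(sentence_start + loc[, 2]),
      surface = stringr::str_sub(sentence_text, loc[, 1], loc[, 2]),
      pattern = lexicon$pattern[i],
      dimension = lexicon$dimension[i],
      value = lexicon$value[i],
      event_types = lexicon$event_types[i],
      priority = lexicon$priority[i],
      n_tokens = lexicon$n_tokens[i]
    )
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(start = integer(), end = integer(), surface = character(),
                  pattern = character(), dimension = character(),
                  value = character(), event_types = list(),
                  priority = integer(), n_tokens = integer()))
  }
  # suppress matches strictly contained in a longer match (any dimension)
  len <- hits$end - hits$start
  contained <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$start <= hits$start[i] & hits$end >= hits$end[i] &
          len > len[i])
  }, logical(1))
  hits <- hits[!contained, , drop = FALSE]
  arrange(hits, .data$start, .data$dimension)
}
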