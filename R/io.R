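# Corpus serialization in two dialects.
#
# genia_mk_xml: a compact GENIA-style XML dialect,
#   <corpus><document id><text/><sentence from to/><term id from to type/>
#   <event id type trigger_from trigger_to kt cl polarity manner source>
#   <participant role ref/><clue dim from to/></event></document></corpus>
# All five dimension attributes are optional on read (scheme defaults fill
# in); the writer always emits them. Writing is deterministic: canonical row
# order and fixed attribute order make repeated writes byte-identical.
#
# event_jsonl: one document per line as a JSON object mirroring the model,
#   UTF-8, LF newlines, numeric offsets.
#
# Derived hyper-dimension values are never serialized in either dialect.

mk_dialects <- function() c("genia_mk_xml", "event_jsonl")

#' Read an annotated event corpus
#'
#' @param path File to read.
#' @param dialect `"genia_mk_xml"` (default) or `"event_jsonl"`.
#' @return An [mk_corpus()]. Missing meta-knowledge attributes are filled
#'   with scheme defaults; unknown elements or attributes are skipped with a
#'   warning, but unknown category labels and out-of-range spans are errors
#'   naming the offending document and attribute.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, dialect = c("genia_mk_xml", "event_jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  corpus <- switch(dialect,
                   genia_mk_xml = read_genia_mk_xml(path),
                   event_jsonl = read_event_jsonl(path))
  check_categories(corpus)
  check_spans_on_read(corpus)
  corpus
}

#' Write an annotated event corpus
#'
#' Refuses to write a corpus whose [validate_corpus()] report contains
#' errors. Output is deterministic: the same corpus always produces the same
#' bytes.
#'
#' @param corpus An [mk_corpus()].
#' @param path Output file.
#' @param dialect `"genia_mk_xml"` (default) or `"event_jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path,
                         dialect = c("genia_mk_xml", "event_jsonl")) {
  dialect <- match.arg(dialect)
  assert_mk_corpus(corpus)
  viol <- validate_corpus(corpus)
  errs <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    abort(paste0("refusing to write invalid corpus; first error: ",
                 errs$code[1], " (document ", errs$doc_id[1], "): ",
                 errs$message[1]))
  }
  corpus <- normalise_corpus(corpus)
  switch(dialect,
         genia_mk_xml = write_genia_mk_xml(corpus, path),
         event_jsonl = write_event_jsonl(corpus, path))
  invisible(path)
}

# category / span checks shared by both readers -------------------------------

check_categories <- function(corpus) {
  dims <- mk_dimensions()
  cols <- mk_dimension_columns()
  ev <- corpus$events
  for (d in names(dims)) {
    v <- ev[[cols[[d]]]]
    bad <- which(is.na(v) | !v %in% dims[[d]])
    if (length(bad) > 0) {
      abort(paste0("document ", ev$doc_id[bad[1]], ", event ",
                   ev$event_id[bad[1]], ": illegal ", cols[[d]],
                   " value \"", v[bad[1]], "\""))
    }
  }
  bad_dim <- which(!corpus$clues$dimension %in% names(dims))
  if (length(bad_dim) > 0) {
    abort(paste0("document ", corpus$clues$doc_id[bad_dim[1]],
                 ": illegal clue dimension \"",
                 corpus$clues$dimension[bad_dim[1]], "\""))
  }
  invisible(corpus)
}

check_spans_on_read <- function(corpus) {
  len <- setNames(nchar(corpus$documents$text), corpus$documents$doc_id)
  check <- function(tbl, s, e, what) {
    if (nrow(tbl) == 0) return()
    start <- tbl[[s]]; end <- tbl[[e]]
    keep <- !(is.na(start) & is.na(end))
    bad <- which(keep & (is.na(start) | is.na(end) | start < 0 |
                           start >= end | end > len[tbl$doc_id]))
    if (length(bad) > 0) {
      abort(paste0("document ", tbl$doc_id[bad[1]], ": ", what,
                   " span [", start[bad[1]], ",", end[bad[1]],
                   ") out of range"))
    }
  }
  check(corpus$sentences, "start", "end", "sentence")
  check(corpus$entities, "start", "end", "term")
  check(corpus$events, "trigger_start", "trigger_end", "event trigger")
  check(corpus$clues, "start", "end", "clue")
  invisible(corpus)
}

# genia_mk_xml ----------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

write_genia_mk_xml <- function(corpus, path) {
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<corpus>")
  for (i in seq_len(nrow(corpus$documents))) {
    docid <- corpus$documents$doc_id[i]
    out <- c(out, paste0("  <document id=\"", xml_escape(docid), "\">"),
             paste0("    <text>", xml_escape(corpus$documents$text[i]),
                    "</text>"))
    sen <- corpus$sentences[corpus$sentences$doc_id == docid, , drop = FALSE]
    out <- c(out, sprintf("    <sentence from=\"%d\" to=\"%d\"/>",
                          sen$start, sen$end))
    ent <- corpus$entities[corpus$entities$doc_id == docid, , drop = FALSE]
    out <- c(out, sprintf(
      "    <term id=\"%s\" from=\"%d\" to=\"%d\" type=\"%s\"/>",
      xml_escape(ent$entity_id), ent$start, ent$end, xml_escape(ent$type)))
    ev <- corpus$events[corpus$events$doc_id == docid, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      trig <- if (is.na(ev$trigger_start[j])) "" else
        sprintf(" trigger_from=\"%d\" trigger_to=\"%d\"",
                ev$trigger_start[j], ev$trigger_end[j])
      out <- c(out, sprintf(
        paste0("    <event id=\"%s\" type=\"%s\"%s kt=\"%s\" cl=\"%s\"",
               " polarity=\"%s\" manner=\"%s\" source=\"%s\">"),
        xml_escape(ev$event_id[j]), xml_escape(ev$event_type[j]), trig,
        ev$kt[j], ev$cl[j], ev$polarity[j], ev$manner[j], ev$source[j]))
      pa <- corpus$participants[
        corpus$participants$doc_id == docid &
          corpus$participants$event_id == ev$event_id[j], , drop = FALSE]
      out <- c(out, sprintf("      <participant role=\"%s\" ref=\"%s\"/>",
                            xml_escape(pa$role), xml_escape(pa$ref)))
      cl <- corpus$clues[corpus$clues$doc_id == docid &
                           corpus$clues$event_id == ev$event_id[j], ,
                         drop = FALSE]
      out <- c(out, sprintf("      <clue dim=\"%s\" from=\"%d\" to=\"%d\"/>",
                            cl$dimension, cl$start, cl$end))
      out <- c(out, "    </event>")
    }
    out <- c(out, "  </document>")
  }
  out <- c(out, "</corpus>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
}

int_attrs <- function(nodes, name) {
  v <- xml2::xml_attr(nodes, name)
  iv <- suppressWarnings(as.integer(v))
  if (any(!is.na(v) & is.na(iv))) {
    abort(paste0("non-integer offset attribute '", name, "'"))
  }
  iv
}

attr_def <- function(nodes, name, default) {
  v <- xml2::xml_attr(nodes, name)
  ifelse(is.na(v), default, v)
}

read_genia_mk_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed XML in ", path, ": ", conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "corpus") {
    abort(paste0("root element must be <corpus>, found <",
                 xml2::xml_name(doc), ">"))
  }
  defaults <- default_metaknowledge()
  dnodes <- xml2::xml_find_all(doc, "./document")
  docid <- xml2::xml_attr(dnodes, "id")
  if (any(is.na(docid))) abort("document element without id attribute")
  documents <- tibble(
    doc_id = docid,
    text = vapply(dnodes, function(d) {
      tn <- xml2::xml_find_first(d, "./text")
      if (inherits(tn, "xml_missing")) "" else xml2::xml_text(tn)
    }, character(1)))

  # tolerant reader: unknown elements are skipped with a warning
  kids <- xml2::xml_find_all(doc, "./document/*")
  kid_names <- xml2::xml_name(kids)
  unknown <- setdiff(unique(kid_names),
                     c("text", "sentence", "term", "event"))
  for (nm in unknown) {
    warn(paste0("skipping unknown element <", nm, ">"))
  }
  # xml_parent() on a nodeset deduplicates; resolve parents per node
  doc_of <- function(nodes) {
    xml2::xml_attr(xml2::xml_find_first(nodes, "ancestor::document"), "id")
  }

  sen_nodes <- xml2::xml_find_all(doc, "./document/sentence")
  sentences <- tibble(doc_id = doc_of(sen_nodes),
                      start = int_attrs(sen_nodes, "from"),
                      end = int_attrs(sen_nodes, "to"))
  term_nodes <- xml2::xml_find_all(doc, "./document/term")
  entities <- tibble(doc_id = doc_of(term_nodes),
                     entity_id = xml2::xml_attr(term_nodes, "id"),
                     start = int_attrs(term_nodes, "from"),
                     end = int_attrs(term_nodes, "to"),
                     type = attr_def(term_nodes, "type", ""))
  ev_nodes <- xml2::xml_find_all(doc, "./document/event")
  events <- tibble(
    doc_id = doc_of(ev_nodes),
    event_id = xml2::xml_attr(ev_nodes, "id"),
    event_type = attr_def(ev_nodes, "type", ""),
    trigger_start = int_attrs(ev_nodes, "trigger_from"),
    trigger_end = int_attrs(ev_nodes, "trigger_to"),
    kt = attr_def(ev_nodes, "kt", defaults$kt),
    cl = attr_def(ev_nodes, "cl", defaults$cl),
    polarity = attr_def(ev_nodes, "polarity", defaults$polarity),
    manner = attr_def(ev_nodes, "manner", defaults$manner),
    source = attr_def(ev_nodes, "source", defaults$source))

  ev_kids <- xml2::xml_find_all(doc, "./document/event/*")
  ev_kid_names <- xml2::xml_name(ev_kids)
  for (nm in setdiff(unique(ev_kid_names), c("participant", "clue"))) {
    warn(paste0("skipping unknown element <", nm, "> inside <event>"))
  }
  ev_of <- function(nodes) {
    xml2::xml_attr(xml2::xml_find_first(nodes, "parent::event"), "id")
  }
  doc_of2 <- doc_of
  pa_nodes <- xml2::xml_find_all(doc, "./document/event/participant")
  participants <- tibble(doc_id = doc_of2(pa_nodes),
                         event_id = ev_of(pa_nodes),
                         role = attr_def(pa_nodes, "role", ""),
                         ref = xml2::xml_attr(pa_nodes, "ref"))
  cl_nodes <- xml2::xml_find_all(doc, "./document/event/clue")
  clues <- tibble(doc_id = doc_of2(cl_nodes),
                  event_id = ev_of(cl_nodes),
                  dimension = xml2::xml_attr(cl_nodes, "dim"),
                  start = int_attrs(cl_nodes, "from"),
                  end = int_attrs(cl_nodes, "to"))
  mk_corpus(documents = documents, sentences = sentences,
            entities = entities, events = events,
            participants = participants, clues = clues)
}

# event_jsonl -----------------------------------------------------------------

write_event_jsonl <- function(corpus, path) {
  ev_key <- function(tbl) paste(tbl$doc_id, tbl$event_id, sep = "\r")
  pa_idx <- split(seq_len(nrow(corpus$participants)),
                  ev_key(corpus$participants))
  cl_idx <- split(seq_len(nrow(corpus$clues)), ev_key(corpus$clues))
  lines <- purrr::map_chr(seq_len(nrow(corpus$documents)), function(i) {
    docid <- corpus$documents$doc_id[i]
    sen <- corpus$sentences[corpus$sentences$doc_id == docid, , drop = FALSE]
    ent <- corpus$entities[corpus$entities$doc_id == docid, , drop = FALSE]
    ev <- corpus$events[corpus$events$doc_id == docid, , drop = FALSE]
    evs <- purrr::map(seq_len(nrow(ev)), function(j) {
      rec <- list(event_id = ev$event_id[j], event_type = ev$event_type[j])
      if (!is.na(ev$trigger_start[j])) {
        rec$trigger <- list(start = ev$trigger_start[j],
                            end = ev$trigger_end[j])
      }
      rec$kt <- ev$kt[j]; rec$cl <- ev$cl[j]
      rec$polarity <- ev$polarity[j]; rec$manner <- ev$manner[j]
      rec$source <- ev$source[j]
      key <- paste(docid, ev$event_id[j], sep = "\r")
      pa <- corpus$participants[pa_idx[[key]] %||% integer(0), ,
                                drop = FALSE]
      rec$participants <- purrr::map(seq_len(nrow(pa)), function(k) {
        list(role = pa$role[k], ref = pa$ref[k])
      })
      cl <- corpus$clues[cl_idx[[key]] %||% integer(0), , drop = FALSE]
      rec$clues <- purrr::map(seq_len(nrow(cl)), function(k) {
        list(dimension = cl$dimension[k], start = cl$start[k],
             end = cl$end[k])
      })
      rec
    })
    obj <- list(
      doc_id = docid,
      text = corpus$documents$text[i],
      sentences = purrr::map(seq_len(nrow(sen)), function(k) {
        list(start = sen$start[k], end = sen$end[k])
      }),
      entities = purrr::map(seq_len(nrow(ent)), function(k) {
        list(entity_id = ent$entity_id[k], start = ent$start[k],
             end = ent$end[k], type = ent$type[k])
      }),
      events = evs
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

read_event_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  defaults <- default_metaknowledge()
  objs <- lapply(seq_along(lines), function(ln) {
    tryCatch(
      jsonlite::fromJSON(lines[[ln]], simplifyVector = FALSE),
      error = function(e) abort(paste0("malformed JSON on line ", ln, ": ",
                                       conditionMessage(e))))
  })
  docid_of <- vapply(seq_along(objs), function(i) {
    id <- objs[[i]]$doc_id
    if (is.null(id)) abort(paste0("line ", i, ": missing doc_id"))
    id
  }, character(1))
  documents <- tibble(
    doc_id = docid_of,
    text = vapply(objs, function(o) o$text %||% "", character(1)))

  # flatten one record type across documents into column vectors
  gather <- function(get_records, fields) {
    recs <- list(); owner_doc <- list()
    for (i in seq_along(objs)) {
      r <- get_records(objs[[i]])
      if (length(r) > 0) {
        recs <- c(recs, r)
        owner_doc[[length(owner_doc) + 1L]] <- rep(docid_of[i], length(r))
      }
    }
    cols <- lapply(fields, function(f) {
      vals <- lapply(recs, f$get)
      if (f$type == "integer") {
        vapply(vals, function(v) as.integer(v %||% NA_integer_), integer(1))
      } else {
        vapply(vals, function(v) as.character(v %||% f$default), character(1))
      }
    })
    names(cols) <- names(fields)
    c(list(doc_id = unlist(owner_doc) %||% character(0)), cols)
  }
  chr <- function(get, default = "") list(get = get, type = "character",
                                          default = default)
  int <- function(get) list(get = get, type = "integer")

  sentences <- as_tibble(gather(
    function(o) o$sentences %||% list(),
    list(start = int(function(s) s$start), end = int(function(s) s$end))))
  entities <- as_tibble(gather(
    function(o) o$entities %||% list(),
    list(entity_id = chr(function(e) e$entity_id, NA_character_),
         start = int(function(e) e$start), end = int(function(e) e$end),
         type = chr(function(e) e$type))))
  events <- as_tibble(gather(
    function(o) o$events %||% list(),
    list(event_id = chr(function(e) e$event_id, NA_character_),
         event_type = chr(function(e) e$event_type),
         trigger_start = int(function(e) e$trigger$start),
         trigger_end = int(function(e) e$trigger$end),
         kt = chr(function(e) e$kt, defaults$kt),
         cl = chr(function(e) e$cl, defaults$cl),
         polarity = chr(function(e) e$polarity, defaults$polarity),
         manner = chr(function(e) e$manner, defaults$manner),
         source = chr(function(e) e$source, defaults$source))))

  sub_records <- function(field) {
    function(o) {
      out <- list()
      for (e in o$events %||% list()) {
        for (r in e[[field]] %||% list()) {
          r$event_id <- e$event_id
          out[[length(out) + 1L]] <- r
        }
      }
      out
    }
  }
  participants <- as_tibble(gather(
    sub_records("participants"),
    list(event_id = chr(function(p) p$event_id, NA_character_),
         role = chr(function(p) p$role),
         ref = chr(function(p) p$ref, NA_character_))))
  clues <- as_tibble(gather(
    sub_records("clues"),
    list(event_id = chr(function(cl) cl$event_id, NA_character_),
         dimension = chr(function(cl) cl$dimension, NA_character_),
         start = int(function(cl) cl$start),
         end = int(function(cl) cl$end))))

  mk_corpus(documents = documents, sentences = sentences,
            entities = entities, events = events,
            participants = participants, clues = clues)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
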