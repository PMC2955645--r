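#' Standoff corpus input/output
#'
#' Readers and writers for BioNLP-style standoff annotation: a plain-text
#' document `.txt`, entity annotations `.a1` ("T" lines) and event
#' annotations `.a2` (trigger "T" lines plus "E" lines). All character
#' offsets are 0-based, half-open `[start, end)`.
#'
#' @name corpus_io
NULL

#' Event-type registry
#'
#' Maps standoff event-type labels to the POS-lane tag substituted at
#' trigger positions when patterns are built (e.g. gene expression
#' triggers are tagged `GEE`).
#'
#' @return named character vector, names are event types.
#' @export
event_type_registry <- function() {
  c(Gene_expression = "GEE",
    Transcription = "TRN",
    Protein_catabolism = "CAT",
    Phosphorylation = "PHO")
}

#' Placeholder symbol used when masking entity mentions
#' @export
PLACEHOLDER <- "PTN"

parse_t_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3L) {
    stop(sprintf("malformed T line %d in %s: %s", lineno, file, line),
         call. = FALSE)
  }
  mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  if (length(mid) < 3L) {
    stop(sprintf("malformed T line %d in %s: %s", lineno, file, line),
         call. = FALSE)
  }
  # discontinuous spans ("start end;start end") are not modeled: first
  # fragment wins, with a warning
  if (grepl(";", parts[2], fixed = TRUE)) {
    warning(sprintf("discontinuous span on line %d in %s; using first fragment",
                    lineno, file), call. = FALSE)
    mid <- mid[1:3]
  }
  list(id = parts[1], etype = mid[1],
       start = as.integer(mid[2]), end = as.integer(mid[3]),
       surface = parts[3])
}

#' Read one standoff document
#'
#' @param txt document text (a single string).
#' @param a1 contents of the `.a1` file (entity "T" lines), possibly `""`.
#' @param a2 contents of the `.a2` file (trigger "T" lines and event "E"
#'   lines); may be `""` in test mode.
#' @param doc_id document identifier.
#' @param registry event-type registry; events with a type not present are
#'   skipped with a warning.
#' @return an object of class `standoff_document`: a list with `doc_id`,
#'   `text`, `entities` (data.frame `id`, `etype`, `start`, `end`,
#'   `surface`) and `events` (data.frame `id`, `etype`, `trigger_id`,
#'   `trigger_start`, `trigger_end`, `trigger_surface`, `theme_id`,
#'   `site_id`).
#' @examples
#' d <- read_standoff("CD19 protein is expressed",
#'                    "T1\tProtein 0 4\tCD19", "", "doc1")
#' d$entities
#' @export
read_standoff <- function(txt, a1, a2, doc_id,
                          registry = event_type_registry()) {
  stopifnot(is.character(txt), length(txt) == 1L)
  split_lines <- function(x) {
    if (is.null(x) || !length(x)) return(character())
    x <- paste(x, collapse = "\n")
    if (!nzchar(x)) return(character())
    ln <- strsplit(x, "\n", fixed = TRUE)[[1]]
    ln[nzchar(ln)]
  }
  check_span <- function(tl, file) {
    if (is.na(tl$start) || is.na(tl$end) || tl$start < 0L ||
        tl$start >= tl$end || tl$end > nchar(txt)) {
      stop(sprintf("span [%s,%s) of %s out of bounds in %s",
                   tl$start, tl$end, tl$id, file), call. = FALSE)
    }
    got <- substr(txt, tl$start + 1L, tl$end)
    if (got != tl$surface) {
      stop(sprintf(
        "integrity error: %s in %s spans \"%s\" but annotation says \"%s\"",
        tl$id, file, got, tl$surface), call. = FALSE)
    }
  }

  ents <- list()
  for (i in seq_along(a1_lines <- split_lines(a1))) {
    line <- a1_lines[i]
    if (!startsWith(line, "T")) {
      stop(sprintf("unexpected line %d in %s.a1: %s", i, doc_id, line),
           call. = FALSE)
    }
    tl <- parse_t_line(line, i, paste0(doc_id, ".a1"))
    check_span(tl, paste0(doc_id, ".a1"))
    ents[[length(ents) + 1L]] <- tl
  }
  entities <- if (length(ents)) {
    data.frame(id = vapply(ents, `[[`, "", "id"),
               etype = vapply(ents, `[[`, "", "etype"),
               start = vapply(ents, `[[`, 0L, "start"),
               end = vapply(ents, `[[`, 0L, "end"),
               surface = vapply(ents, `[[`, "", "surface"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), etype = character(), start = integer(),
               end = integer(), surface = character(),
               stringsAsFactors = FALSE)
  }
  if (anyDuplicated(entities$id)) {
    stop(sprintf("duplicate entity ids in %s.a1", doc_id), call. = FALSE)
  }

  triggers <- list()
  evs <- list()
  for (i in seq_along(a2_lines <- split_lines(a2))) {
    line <- a2_lines[i]
    if (startsWith(line, "T")) {
      tl <- parse_t_line(line, i, paste0(doc_id, ".a2"))
      check_span(tl, paste0(doc_id, ".a2"))
      triggers[[tl$id]] <- tl
    } else if (startsWith(line, "E")) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) {
        stop(sprintf("malformed E line %d in %s.a2: %s", i, doc_id, line),
             call. = FALSE)
      }
      args <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      head_kv <- strsplit(args[1], ":", fixed = TRUE)[[1]]
      if (length(head_kv) != 2L) {
        stop(sprintf("malformed E line %d in %s.a2: %s", i, doc_id, line),
             call. = FALSE)
      }
      etype <- head_kv[1]
      trig_ref <- head_kv[2]
      if (!etype %in% names(registry)) {
        warning(sprintf("skipping event %s of unregistered type %s in %s",
                        parts[1], etype, doc_id), call. = FALSE)
        next
      }
      kv <- strsplit(args[-1], ":", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, `[`, "", 2L)
      theme <- vals[match("Theme", keys)]
      site <- vals[match("Site", keys)]
      if (is.na(theme)) {
        stop(sprintf("event %s in %s.a2 has no Theme", parts[1], doc_id),
             call. = FALSE)
      }
      evs[[length(evs) + 1L]] <- list(id = parts[1], etype = etype,
                                      trigger = trig_ref, theme = theme,
                                      site = site)
    } else {
      stop(sprintf("unexpected line %d in %s.a2: %s", i, doc_id, line),
           call. = FALSE)
    }
  }

  events <- data.frame(id = character(), etype = character(),
                       trigger_id = character(), trigger_start = integer(),
                       trigger_end = integer(), trigger_surface = character(),
                       theme_id = character(), site_id = character(),
                       stringsAsFactors = FALSE)
  for (ev in evs) {
    tr <- triggers[[ev$trigger]]
    if (is.null(tr)) {
      stop(sprintf("event %s in %s.a2 references missing trigger %s",
                   ev$id, doc_id, ev$trigger), call. = FALSE)
    }
    if (!ev$theme %in% entities$id) {
      stop(sprintf("event %s in %s.a2 references missing theme %s",
                   ev$id, doc_id, ev$theme), call. = FALSE)
    }
    events[nrow(events) + 1L, ] <- list(ev$id, ev$etype, tr$id, tr$start,
                                        tr$end, tr$surface, ev$theme,
                                        if (is.na(ev$site)) NA_character_
                                        else ev$site)
  }

  structure(list(doc_id = doc_id, text = txt, entities = entities,
                 events = events),
            class = "standoff_document")
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff document %s: %d chars, %d entities, %d events>\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$events)))
  invisible(x)
}

#' Serialize predicted events as an `.a2` file
#'
#' Trigger T lines are emitted first, with numeric ids continuing after
#' the id space used by the document's entities, then one E line per
#' event. The output round-trips through [read_standoff()].
#'
#' @param doc a `standoff_document` (provides text, entities and the id
#'   space).
#' @param predictions data.frame with columns `etype`, `trigger_start`,
#'   `trigger_end`, `theme_id`, optionally `site_id`.
#' @return a single string (possibly `""`).
#' @export
write_a2 <- function(doc, predictions) {
  if (is.null(predictions) || !nrow(predictions)) return("")
  if (!all(predictions$theme_id %in% doc$entities$id)) {
    stop("integrity error: prediction references an unknown theme entity",
         call. = FALSE)
  }
  if (any(predictions$trigger_start < 0L |
          predictions$trigger_end > nchar(doc$text))) {
    stop("prediction trigger span outside the document", call. = FALSE)
  }
  next_t <- max(c(0L, as.integer(sub("^T", "", doc$entities$id)))) + 1L
  # one T line per distinct (etype, span)
  key <- paste(predictions$etype, predictions$trigger_start,
               predictions$trigger_end)
  uniq <- !duplicated(key)
  tid <- stats::setNames(paste0("T", seq_len(sum(uniq)) + next_t - 1L),
                         key[uniq])
  t_lines <- vapply(which(uniq), function(i) {
    sprintf("%s\t%s %d %d\t%s", tid[[key[i]]], predictions$etype[i],
            predictions$trigger_start[i], predictions$trigger_end[i],
            substr(doc$text, predictions$trigger_start[i] + 1L,
                   predictions$trigger_end[i]))
  }, character(1))
  e_lines <- vapply(seq_len(nrow(predictions)), function(i) {
    site <- if ("site_id" %in% names(predictions) &&
                !is.na(predictions$site_id[i])) {
      sprintf(" Site:%s", predictions$site_id[i])
    } else ""
    sprintf("E%d\t%s:%s Theme:%s%s", i, predictions$etype[i],
            tid[[key[i]]], predictions$theme_id[i], site)
  }, character(1))
  paste(c(t_lines, e_lines), collapse = "\n")
}

#' Read a directory of standoff triples
#'
#' Reads every `<base>.txt` with its sibling `<base>.a1` and (when
#' present) `<base>.a2`.
#'
#' @param dir directory path.
#' @param registry event-type registry passed to [read_standoff()].
#' @return list of `standoff_document`, ordered by basename.
#' @export
read_corpus_dir <- function(dir, registry = event_type_registry()) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(f) {
    base <- sub("\\.txt$", "", f)
    read_file <- function(p) {
      if (file.exists(p)) readChar(p, file.size(p), useBytes = FALSE) else ""
    }
    read_standoff(trimws(read_file(f), which = "right"),
                  read_file(paste0(base, ".a1")),
                  read_file(paste0(base, ".a2")),
                  doc_id = basename(base), registry = registry)
  })
}

#' Write a corpus as standoff triples
#'
#' @param corpus list of `standoff_document`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_corpus_dir <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus) {
    base <- file.path(dir, doc$doc_id)
    writeLines(doc$text, paste0(base, ".txt"))
    a1 <- vapply(seq_len(nrow(doc$entities)), function(i) {
      with(doc$entities[i, ], sprintf("%s\t%s %d %d\t%s", id, etype,
                                      start, end, surface))
    }, character(1))
    writeLines(a1, paste0(base, ".a1"))
    a2_lines <- character()
    if (nrow(doc$events)) {
      tr <- doc$events[!duplicated(doc$events$trigger_id),
                       c("trigger_id", "etype", "trigger_start",
                         "trigger_end", "trigger_surface")]
      a2_lines <- c(
        sprintf("%s\t%s %d %d\t%s", tr$trigger_id, tr$etype,
                tr$trigger_start, tr$trigger_end, tr$trigger_surface),
        vapply(seq_len(nrow(doc$events)), function(i) {
          site <- if (!is.na(doc$events$site_id[i])) {
            sprintf(" Site:%s", doc$events$site_id[i])
          } else ""
          sprintf("%s\t%s:%s Theme:%s%s", doc$events$id[i],
                  doc$events$etype[i], doc$events$trigger_id[i],
                  doc$events$theme_id[i], site)
        }, character(1)))
    }
    writeLines(a2_lines, paste0(base, ".a2"))
  }
  invisible(dir)
}

# ---- sentence annotation ---------------------------------------------------

#' Split a document into linguistically annotated sentences
#'
#' Each sentence carries per-token surface, stem and POS lanes with
#' character spans, the entity covering each token (if any), and the gold
#' events whose trigger and theme both fall inside the sentence. Events
#' whose trigger and theme land in different sentences, or whose
#' annotations straddle a sentence boundary, are dropped with a message
#' reporting the count (the large majority of events in this kind of
#' corpus are sentence-internal).
#'
#' @param doc a `standoff_document`.
#' @param annotator an [annotators] object.
#' @return list of objects of class `annotated_sentence`, each a list with
#'   `doc_id`, `sent_start`, `sent_end`, `tokens` (data.frame `surface`,
#'   `stem`, `pos`, `start`, `end` with document-absolute offsets),
#'   `entity_id` (character vector, one per token, `NA` off entities) and
#'   `events` (data.frame `id`, `etype`, `trigger_first`, `trigger_last`,
#'   `theme_first`, `theme_last`, `theme_id`, `site_id`, token indices).
#' @export
annotate_sentences <- function(doc, annotator = default_annotator()) {
  segs <- annotator$segment(doc$text)
  if (!nrow(segs)) return(list())
  sentences <- vector("list", nrow(segs))
  sent_of_span <- function(s, e) {
    hit <- which(segs$start <= s & e <= segs$end)
    if (length(hit) == 1L) hit else NA_integer_
  }
  dropped <- 0L
  for (k in seq_len(nrow(segs))) {
    seg_text <- substr(doc$text, segs$start[k] + 1L, segs$end[k])
    toks <- annotator$tokenize(seg_text)
    toks$start <- toks$start + segs$start[k]
    toks$end <- toks$end + segs$start[k]
    toks$stem <- annotator$stem(toks$surface)
    toks$pos <- annotator$pos(toks$surface, toks$stem)
    toks <- toks[, c("surface", "stem", "pos", "start", "end")]

    entity_id <- rep(NA_character_, nrow(toks))
    if (nrow(doc$entities)) {
      for (i in seq_len(nrow(doc$entities))) {
        es <- doc$entities$start[i]; ee <- doc$entities$end[i]
        if (ee <= segs$start[k] || es >= segs$end[k]) next
        cover <- which(toks$start < ee & toks$end > es)
        entity_id[cover] <- doc$entities$id[i]
      }
    }
    sentences[[k]] <- structure(
      list(doc_id = doc$doc_id, sent_start = segs$start[k],
           sent_end = segs$end[k], tokens = toks, entity_id = entity_id,
           events = data.frame(id = character(), etype = character(),
                               trigger_first = integer(),
                               trigger_last = integer(),
                               theme_first = integer(),
                               theme_last = integer(),
                               theme_id = character(),
                               site_id = character(),
                               stringsAsFactors = FALSE),
           masked = FALSE),
      class = "annotated_sentence")
  }

  if (nrow(doc$events)) {
    ent_span <- function(id) {
      i <- match(id, doc$entities$id)
      c(doc$entities$start[i], doc$entities$end[i])
    }
    for (i in seq_len(nrow(doc$events))) {
      ev <- doc$events[i, ]
      ts <- sent_of_span(ev$trigger_start, ev$trigger_end)
      th <- ent_span(ev$theme_id)
      hs <- sent_of_span(th[1], th[2])
      if (is.na(ts) || is.na(hs) || ts != hs) {
        dropped <- dropped + 1L
        next
      }
      toks <- sentences[[ts]]$tokens
      trig_idx <- which(toks$start < ev$trigger_end & toks$end > ev$trigger_start)
      theme_idx <- which(sentences[[ts]]$entity_id == ev$theme_id)
      if (!length(trig_idx) || !length(theme_idx)) {
        dropped <- dropped + 1L
        next
      }
      sentences[[ts]]$events[nrow(sentences[[ts]]$events) + 1L, ] <-
        list(ev$id, ev$etype, min(trig_idx), max(trig_idx),
             min(theme_idx), max(theme_idx), ev$theme_id, ev$site_id)
    }
  }
  if (dropped > 0L) {
    message(sprintf("%s: dropped %d cross-sentence or unresolvable event(s)",
                    doc$doc_id, dropped))
  }
  sentences
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<sentence %s [%d,%d): %d tokens, %d entities, %d events%s>\n",
              x$doc_id, x$sent_start, x$sent_end, nrow(x$tokens),
              length(unique(stats::na.omit(x$entity_id))), nrow(x$events),
              if (isTRUE(x$masked)) ", masked" else ""))
  invisible(x)
}

#' Replace entity mentions with a placeholder token
#'
#' Every maximal run of tokens covered by one entity mention collapses to
#' a single token whose surface, stem and POS are all the placeholder
#' symbol; the entity id is retained as a back-map. Applying the mask
#' twice equals applying it once.
#'
#' @param sent an `annotated_sentence`.
#' @param placeholder placeholder symbol (default `"PTN"`).
#' @return masked `annotated_sentence` with an `index_map` attribute-like
#'   element mapping original token indices to masked ones.
#' @export
mask_entities <- function(sent, placeholder = PLACEHOLDER) {
  n <- nrow(sent$tokens)
  if (!n) return(sent)
  # group id per token: runs of one entity collapse together
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && !is.na(sent$entity_id[i]) &&
        identical(sent$entity_id[i], sent$entity_id[i - 1L])) {
      grp[i] <- g
    } else {
      g <- g + 1L
      grp[i] <- g
    }
  }
  keep <- !duplicated(grp)
  index_map <- grp  # original index -> new index
  toks <- sent$tokens[keep, , drop = FALSE]
  ent <- sent$entity_id[keep]
  rownames(toks) <- NULL
  for (j in which(!is.na(ent))) {
    members <- which(grp == j)
    toks$surface[j] <- placeholder
    toks$stem[j] <- placeholder
    toks$pos[j] <- placeholder
    toks$start[j] <- min(sent$tokens$start[members])
    toks$end[j] <- max(sent$tokens$end[members])
  }
  out <- sent
  out$tokens <- toks
  out$entity_id <- ent
  out$index_map <- index_map
  out$masked <- TRUE
  if (nrow(out$events)) {
    for (col in c("trigger_first", "trigger_last", "theme_first",
                  "theme_last")) {
      out$events[[col]] <- index_map[sent$events[[col]]]
    }
  }
  out
}

#' Annotate and mask a whole corpus once
#'
#' Convenience wrapper producing, per document, the raw and masked
#' sentence lists the matcher and learner consume.
#'
#' @param corpus list of `standoff_document`.
#' @param annotator an [annotators] object.
#' @return list (one element per document) of lists with `doc`,
#'   `sentences`, `masked`.
#' @export
prepare_corpus <- function(corpus, annotator = default_annotator()) {
  lapply(corpus, function(doc) {
    sents <- annotate_sentences(doc, annotator)
    list(doc = doc, sentences = sents, masked = lapply(sents, mask_entities))
  })
}
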