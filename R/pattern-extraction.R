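#' Pattern learning
#'
#' A pattern is the three-layer representation of the "core phrase" of a
#' gold event sentence: the minimal token span containing the trigger
#' word and the Theme entity, widened by a configurable neighbourhood.
#' The three lanes are the tokens themselves, their word stems, and their
#' POS tags; entity mentions appear as the placeholder symbol on all
#' three lanes, and trigger tokens carry the event-type tag (e.g. `GEE`)
#' on the POS lane.
#'
#' @name pattern_extraction
NULL

#' Collect gold event sentences
#'
#' @param corpus list of `standoff_document` or the output of
#'   [prepare_corpus()].
#' @param etype event type (registry label, e.g. `"Gene_expression"`).
#' @param annotator annotator used if `corpus` is raw documents.
#' @return list of records, one per (sentence, event) pair of the
#'   requested type: `doc_id`, `sent_index`, `sentence` (unmasked),
#'   `masked`, `event` (one-row data.frame with token indices valid in
#'   the masked sentence).
#' @export
collect_event_sentences <- function(corpus, etype,
                                    annotator = default_annotator()) {
  prep <- as_prepared(corpus, annotator)
  out <- list()
  for (d in prep) {
    for (k in seq_along(d$masked)) {
      ms <- d$masked[[k]]
      if (!nrow(ms$events)) next
      hits <- which(ms$events$etype == etype)
      for (i in hits) {
        out[[length(out) + 1L]] <- list(
          doc_id = d$doc$doc_id, sent_index = k,
          sentence = d$sentences[[k]], masked = ms,
          event = ms$events[i, , drop = FALSE])
      }
    }
  }
  out
}

as_prepared <- function(corpus, annotator) {
  if (!length(corpus)) return(corpus)
  if (inherits(corpus[[1]], "standoff_document")) {
    return(prepare_corpus(corpus, annotator))
  }
  corpus
}

#' Core phrase of an event
#'
#' The minimal token interval containing the trigger and theme tokens,
#' widened by `neighbourhood` tokens on each side and clipped to the
#' sentence.
#'
#' @param n_tokens number of tokens in the sentence.
#' @param trigger_idx,theme_idx token index ranges, each `c(first, last)`
#'   or a single index.
#' @param neighbourhood non-negative integer widening.
#' @return integer vector `c(first, last)` (1-based, inclusive).
#' @examples
#' extract_core_phrase(10, 5, 3, neighbourhood = 0)  # c(3, 5)
#' @export
extract_core_phrase <- function(n_tokens, trigger_idx, theme_idx,
                                neighbourhood = 1L) {
  stopifnot(neighbourhood >= 0L)
  idx <- c(trigger_idx, theme_idx)
  if (any(idx < 1L | idx > n_tokens)) {
    stop("trigger/theme token index out of range", call. = FALSE)
  }
  c(max(1L, min(idx) - neighbourhood),
    min(n_tokens, max(idx) + neighbourhood))
}

#' Build a three-layer pattern from a masked sentence
#'
#' @param masked masked `annotated_sentence`.
#' @param core integer `c(first, last)` token interval.
#' @param trigger_idx token index range of the trigger (all trigger
#'   tokens keep their surface/stem; their POS becomes the event tag).
#' @param theme_idx token index of the Theme placeholder.
#' @param etype event type.
#' @param registry event-type registry supplying the POS-lane tag.
#' @return an object of class `event_pattern`.
#' @export
build_pattern <- function(masked, core, trigger_idx, theme_idx, etype,
                          registry = event_type_registry()) {
  stopifnot(isTRUE(masked$masked))
  rng <- core[1]:core[2]
  t_first <- min(trigger_idx); t_last <- max(trigger_idx)
  if (t_first < core[1] || t_last > core[2] ||
      theme_idx < core[1] || theme_idx > core[2]) {
    stop("core must contain trigger and theme", call. = FALSE)
  }
  toks <- masked$tokens[rng, , drop = FALSE]
  pos <- toks$pos
  tag <- unname(registry[etype])
  if (is.na(tag)) stop(sprintf("no POS tag registered for %s", etype),
                       call. = FALSE)
  trig_rel <- (t_first:t_last) - core[1] + 1L
  pos[trig_rel] <- tag
  structure(list(
    pattern_id = NA_character_,
    etype = etype,
    length = length(rng),
    token_lane = toks$surface,
    stem_lane = toks$stem,
    pos_lane = pos,
    trigger_pos = trig_rel[1],
    trigger_positions = trig_rel,
    theme_pos = theme_idx - core[1] + 1L,
    provenance = list(doc_id = masked$doc_id, sent_index = NA_integer_)
  ), class = "event_pattern")
}

pattern_key <- function(p) {
  paste(p$etype, p$trigger_pos, p$theme_pos,
        paste(p$token_lane, collapse = ""), sep = "")
}

#' @export
print.event_pattern <- function(x, ...) {
  cat(sprintf("<pattern %s (%s), length %d>\n",
              ifelse(is.na(x$pattern_id), "?", x$pattern_id), x$etype,
              x$length))
  cat("  token:", paste(x$token_lane, collapse = " "), "\n")
  cat("  stem: ", paste(x$stem_lane, collapse = " "), "\n")
  cat("  pos:  ", paste(x$pos_lane, collapse = " "), "\n")
  invisible(x)
}

#' Construct a pattern set
#'
#' @param patterns list of `event_pattern`.
#' @param etype event type.
#' @param metadata list of learning configuration to carry along.
#' @return object of class `pattern_set`.
#' @export
pattern_set <- function(patterns, etype, metadata = list()) {
  structure(list(etype = etype, patterns = patterns, metadata = metadata),
            class = "pattern_set")
}

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' @export
print.pattern_set <- function(x, ...) {
  lens <- vapply(x$patterns, `[[`, 0L, "length")
  cat(sprintf("<pattern set: %d %s patterns, mean length %.2f>\n",
              length(x$patterns), x$etype,
              if (length(lens)) mean(lens) else NA_real_))
  invisible(x)
}

#' Average pattern length of a set
#' @param ps a `pattern_set`.
#' @return mean token count (NA for an empty set).
#' @export
mean_pattern_length <- function(ps) {
  lens <- vapply(ps$patterns, `[[`, 0L, "length")
  if (!length(lens)) return(NA_real_)
  mean(lens)
}

#' Learn the initial pattern set from a gold corpus
#'
#' Composition of [collect_event_sentences()], [mask_entities()],
#' [extract_core_phrase()] and [build_pattern()], followed by
#' deduplication on (event type, token lane, trigger position, theme
#' position). The result is sorted by that key, so the learned set does
#' not depend on document order; each kept pattern records the
#' lexicographically smallest provenance among its duplicates.
#'
#' @param corpus list of `standoff_document` or [prepare_corpus()] output.
#' @param etype event type.
#' @param neighbourhood tokens added on each side of the minimal span
#'   (default 1).
#' @param annotator annotator for raw corpora.
#' @param registry event-type registry.
#' @return a `pattern_set`; empty (with a warning) on a corpus without
#'   events of `etype`.
#' @export
learn_patterns <- function(corpus, etype, neighbourhood = 1L,
                           annotator = default_annotator(),
                           registry = event_type_registry()) {
  recs <- collect_event_sentences(corpus, etype, annotator)
  if (!length(recs)) {
    warning(sprintf("no %s events found; returning empty pattern set",
                    etype), call. = FALSE)
    return(pattern_set(list(), etype,
                       metadata = list(neighbourhood = neighbourhood)))
  }
  pats <- lapply(recs, function(r) {
    ev <- r$event
    core <- extract_core_phrase(
      nrow(r$masked$tokens),
      c(ev$trigger_first, ev$trigger_last),
      c(ev$theme_first, ev$theme_last),
      neighbourhood)
    p <- build_pattern(r$masked, core,
                       trigger_idx = ev$trigger_first:ev$trigger_last,
                       theme_idx = ev$theme_first, etype = ev$etype,
                       registry = registry)
    p$provenance <- list(doc_id = r$doc_id, sent_index = r$sent_index)
    p
  })
  keys <- vapply(pats, pattern_key, character(1))
  prov <- vapply(pats, function(p) {
    sprintf("%s#%05d", p$provenance$doc_id, p$provenance$sent_index)
  }, character(1))
  # smallest provenance per key, then sort by key for order independence
  ord <- order(keys, prov)
  pats <- pats[ord]; keys <- keys[ord]
  pats <- pats[!duplicated(keys)]
  for (i in seq_along(pats)) {
    pats[[i]]$pattern_id <- sprintf("P%04d", i)
  }
  pattern_set(pats, etype,
              metadata = list(neighbourhood = neighbourhood,
                              n_source_events = length(recs)))
}

#' Tag phosphorylation site mentions
#'
#' Site mentions (residue + position, e.g. "Ser-473", "Y705",
#' "serine 133") are located by regular expressions; matched
#' phosphorylation events can then attach the nearest tagged site as
#' their Site argument.
#'
#' @param sent an `annotated_sentence` (or any object with `tokens` and
#'   `sent_start`), or a plain string.
#' @param site_regexes character vector of PCRE patterns; the defaults
#'   cover common residue-position notations.
#' @return data.frame `start`, `end`, `surface` (document-absolute,
#'   0-based half-open), ordered by `start`.
#' @export
tag_phospho_sites <- function(sent, site_regexes = default_site_regexes()) {
  if (is.character(sent)) {
    text <- sent
    offset <- 0L
  } else {
    text <- substr_span(sent)
    offset <- sent$sent_start
  }
  hits <- data.frame(start = integer(), end = integer(),
                     surface = character(), stringsAsFactors = FALSE)
  for (rx in site_regexes) {
    g <- gregexpr(rx, text, perl = TRUE)
    m <- g[[1]]
    if (m[1] == -1L) next
    s <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    hits <- rbind(hits, data.frame(start = s + offset, end = s + len + offset,
                                   surface = regmatches(text, g)[[1]],
                                   stringsAsFactors = FALSE))
  }
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$start, -hits$end), , drop = FALSE]
  # drop spans nested in an earlier, longer match
  keep <- rep(TRUE, nrow(hits))
  max_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$end[i] <= max_end) keep[i] <- FALSE
    max_end <- max(max_end, hits$end[i])
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @rdname tag_phospho_sites
#' @export
default_site_regexes <- function() {
  c("\\b(?:Ser|Thr|Tyr|His|Asp|Lys|Arg)[- ]?\\d+\\b",
    "\\b(?:serine|threonine|tyrosine|histidine)\\s+(?:residue\\s+)?\\d+\\b",
    "\\b[STY]\\d+\\b")
}

substr_span <- function(sent) {
  # reconstruct sentence text from token spans is lossy; sentences carry
  # their document text implicitly only via tokens, so join on spans
  toks <- sent$tokens
  if (!nrow(toks)) return("")
  text <- rep(" ", sent$sent_end - sent$sent_start)
  for (i in seq_len(nrow(toks))) {
    rel <- (toks$start[i] - sent$sent_start + 1L):(toks$end[i] - sent$sent_start)
    text[rel] <- strsplit(toks$surface[i], "")[[1]][seq_along(rel)]
  }
  paste(text, collapse = "")
}

# ---- serialization ---------------------------------------------------------

#' Write a pattern set as TSV (+ JSON metadata sidecar)
#'
#' One pattern per line: id, event type, trigger position, theme
#' position, and the three lanes pipe-joined. A `<path>.meta.json`
#' sidecar stores the learning configuration.
#'
#' @param ps a `pattern_set`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_patterns <- function(ps, path) {
  df <- as.data.frame(ps)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(etype = ps$etype, n_patterns = length(ps)), ps$metadata),
    paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @export
as.data.frame.pattern_set <- function(x, ...) {
  if (!length(x$patterns)) {
    return(data.frame(pattern_id = character(), etype = character(),
                      trigger_pos = integer(), theme_pos = integer(),
                      token_lane = character(), stem_lane = character(),
                      pos_lane = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    pattern_id = vapply(x$patterns, `[[`, "", "pattern_id"),
    etype = vapply(x$patterns, `[[`, "", "etype"),
    trigger_pos = vapply(x$patterns, `[[`, 0L, "trigger_pos"),
    theme_pos = vapply(x$patterns, `[[`, 0L, "theme_pos"),
    token_lane = vapply(x$patterns, function(p)
      paste(p$token_lane, collapse = "|"), ""),
    stem_lane = vapply(x$patterns, function(p)
      paste(p$stem_lane, collapse = "|"), ""),
    pos_lane = vapply(x$patterns, function(p)
      paste(p$pos_lane, collapse = "|"), ""),
    stringsAsFactors = FALSE)
}

#' Read a pattern set written by [write_patterns()]
#'
#' @param path TSV path.
#' @return a `pattern_set`.
#' @export
read_patterns <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  pats <- lapply(seq_len(nrow(df)), function(i) {
    token_lane <- strsplit(df$token_lane[i], "|", fixed = TRUE)[[1]]
    pos_lane <- strsplit(df$pos_lane[i], "|", fixed = TRUE)[[1]]
    trig <- which(pos_lane %in% event_type_registry())
    if (!length(trig)) trig <- df$trigger_pos[i]
    structure(list(
      pattern_id = df$pattern_id[i], etype = df$etype[i],
      length = length(token_lane),
      token_lane = token_lane,
      stem_lane = strsplit(df$stem_lane[i], "|", fixed = TRUE)[[1]],
      pos_lane = pos_lane,
      trigger_pos = df$trigger_pos[i],
      trigger_positions = trig,
      theme_pos = df$theme_pos[i],
      provenance = list(doc_id = NA_character_, sent_index = NA_integer_)
    ), class = "event_pattern")
  })
  etype <- if (nrow(df)) df$etype[1] else meta$etype
  pattern_set(pats, etype = etype,
              metadata = meta[setdiff(names(meta), c("etype", "n_patterns"))])
}
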