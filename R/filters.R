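#' Pattern and trigger filters
#'
#' Simple precision-oriented filters over an automatically learned
#' pattern set: keep only patterns whose trigger word has a high hit
#' rate, only short patterns, or only the individually best-performing
#' patterns on a development corpus. Every filter is a contraction
#' (output is a subset of its input), so filtering can only remove
#' predictions downstream — false positives can be avoided but no new
#' true positives appear.
#'
#' @name filters
NULL

#' Per-trigger statistics
#'
#' @param word trigger surface, case-normalized.
#' @param event_occurrences occurrences annotated as a trigger of the
#'   target event type.
#' @param other_event_occurrences occurrences annotated as triggers of
#'   other event types (stored for inspection; not part of the hit
#'   rate).
#' @param total_occurrences all corpus occurrences of the word.
#' @return one-row data.frame with `hit_rate =
#'   event_occurrences / total_occurrences`.
#' @export
trigger_stats <- function(word, event_occurrences,
                          other_event_occurrences, total_occurrences) {
  stopifnot(event_occurrences <= total_occurrences, total_occurrences > 0)
  data.frame(word = word,
             event_occurrences = event_occurrences,
             other_event_occurrences = other_event_occurrences,
             total_occurrences = total_occurrences,
             hit_rate = event_occurrences / total_occurrences,
             stringsAsFactors = FALSE)
}

#' Trigger-word hit rates over a gold corpus
#'
#' For every distinct (case-normalized) trigger surface of the target
#' event type, counts its total token occurrences in the corpus and the
#' fraction of those annotated as triggers of the type (the hit rate).
#' Occurrence counting is case-insensitive exact token matching over the
#' tokenized corpus; multi-word trigger surfaces are counted as token
#' subsequences.
#'
#' @param prep gold corpus ([prepare_corpus()] output or raw documents).
#' @param etype target event type.
#' @param annotator used if `prep` is a raw corpus.
#' @return data.frame of [trigger_stats()] rows, sorted by hit rate
#'   descending, ties by total occurrences descending then word.
#' @export
trigger_hit_rates <- function(prep, etype,
                              annotator = default_annotator()) {
  prep <- as_prepared(prep, annotator)
  # distinct trigger spans per surface, for the target and other types
  trig_of <- function(doc, types_in) {
    ev <- doc$events[doc$events$etype %in% types_in, , drop = FALSE]
    if (!nrow(ev)) return(character())
    key <- paste(ev$trigger_start, ev$trigger_end)
    tolower(ev$trigger_surface[!duplicated(key)])
  }
  target <- unlist(lapply(prep, function(d) trig_of(d$doc, etype)))
  all_types <- unique(unlist(lapply(prep, function(d) d$doc$events$etype)))
  other <- unlist(lapply(prep, function(d)
    trig_of(d$doc, setdiff(all_types, etype))))
  words <- sort(unique(target))
  if (!length(words)) {
    return(data.frame(word = character(), event_occurrences = integer(),
                      other_event_occurrences = integer(),
                      total_occurrences = integer(), hit_rate = numeric(),
                      stringsAsFactors = FALSE))
  }
  # corpus token stream (lower-cased), per sentence
  token_seqs <- unlist(lapply(prep, function(d)
    lapply(d$sentences, function(s) tolower(s$tokens$surface))),
    recursive = FALSE)
  count_occurrences <- function(word) {
    parts <- strsplit(word, "[[:space:]]+")[[1]]
    sum(vapply(token_seqs, function(toks) {
      if (length(parts) == 1L) return(sum(toks == parts[1]))
      n <- length(toks) - length(parts) + 1L
      if (n < 1L) return(0L)
      sum(vapply(seq_len(n), function(i) {
        all(toks[i:(i + length(parts) - 1L)] == parts)
      }, logical(1)))
    }, integer(1)))
  }
  stats <- do.call(rbind, lapply(words, function(w) {
    ev <- sum(target == w)
    tot <- count_occurrences(w)
    trigger_stats(w, ev, sum(other == w), max(tot, ev))
  }))
  stats <- stats[order(-stats$hit_rate, -stats$total_occurrences,
                       stats$word), , drop = FALSE]
  rownames(stats) <- NULL
  stats
}

pattern_trigger_words <- function(ps) {
  vapply(ps$patterns, function(p) {
    tolower(paste(p$token_lane[p$trigger_positions], collapse = " "))
  }, character(1))
}

#' Keep patterns whose trigger is among the k best-hit-rate words
#'
#' Multi-word triggers never pass this filter: the retained trigger
#' vocabulary consists of single-word triggers ranked by hit rate.
#'
#' @param ps a `pattern_set`.
#' @param stats [trigger_hit_rates()] output computed on training data.
#' @param k number of top-ranked trigger words to keep; `k >= nrow(stats)`
#'   keeps every single-word trigger.
#' @return filtered `pattern_set`.
#' @export
trigger_word_filter <- function(ps, stats, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  single <- stats[!grepl("[[:space:]]", stats$word), , drop = FALSE]
  kept_words <- single$word[seq_len(min(k, nrow(single)))]
  trig <- pattern_trigger_words(ps)
  pattern_set(ps$patterns[trig %in% kept_words], ps$etype,
              metadata = c(ps$metadata, list(trigger_k = k)))
}

#' Keep patterns up to (or exactly of) a given token length
#'
#' @param ps a `pattern_set`.
#' @param max_len maximum pattern length to keep.
#' @param exact when TRUE, keep only patterns of exactly `max_len`
#'   tokens (the per-length sweep variant).
#' @return filtered `pattern_set`.
#' @export
length_filter <- function(ps, max_len, exact = FALSE) {
  stopifnot(max_len >= 1L)
  lens <- vapply(ps$patterns, `[[`, 0L, "length")
  keep <- if (exact) lens == max_len else lens <= max_len
  pattern_set(ps$patterns[keep], ps$etype,
              metadata = c(ps$metadata,
                           list(length_cap = max_len, exact = exact)))
}

#' Individual precision of every pattern on a development corpus
#'
#' Runs the matcher once per pattern (via a shared match table) and
#' scores each pattern's own predictions at event level. Patterns with
#' no accepted match get an undefined (NA) precision.
#'
#' @param ps a `pattern_set`.
#' @param prep development corpus with gold annotations.
#' @param model a `substitution_model` (its threshold is used).
#' @param annotator used if `prep` is a raw corpus.
#' @param matches optional precomputed [corpus_matches()] table.
#' @return data.frame `pattern_id`, `matches`, `tp`, `fp`, `precision`
#'   (NA when `matches == 0`), one row per pattern, input order.
#' @export
pattern_precisions <- function(ps, prep, model,
                               annotator = default_annotator(),
                               matches = NULL) {
  prep <- as_prepared(prep, annotator)
  if (is.null(matches)) matches <- corpus_matches(ps, prep, model, annotator)
  out <- data.frame(
    pattern_id = vapply(ps$patterns, `[[`, "", "pattern_id"),
    matches = 0L, tp = 0L, fp = 0L, precision = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    pid <- out$pattern_id[i]
    sub <- matches[matches$pattern_id == pid, , drop = FALSE]
    preds <- predictions_from_matches(sub, model$threshold)
    n <- sum(vapply(preds, nrow, 0L))
    out$matches[i] <- n
    if (n == 0L) next
    rpt <- evaluate(preds, prep, etype = ps$etype)
    out$tp[i] <- rpt$tp
    out$fp[i] <- rpt$fp
    out$precision[i] <- if (rpt$tp + rpt$fp > 0) {
      rpt$tp / (rpt$tp + rpt$fp)
    } else NA_real_
  }
  out
}

#' Single-pattern precision
#'
#' @param p an `event_pattern`.
#' @inheritParams pattern_precisions
#' @return one-row data.frame as in [pattern_precisions()].
#' @export
pattern_precision <- function(p, prep, model,
                              annotator = default_annotator()) {
  pattern_precisions(pattern_set(list(p), p$etype), prep, model, annotator)
}

rank_by_precision <- function(stats) {
  # undefined precision ranks last; ties by matches desc, then id
  order(-ifelse(is.na(stats$precision), -1, stats$precision),
        -stats$matches, stats$pattern_id)
}

#' Keep the k individually best-performing patterns
#'
#' Patterns are ranked by development precision (undefined-precision
#' patterns last, then by match count descending, then by id) and the
#' top k kept.
#'
#' @param ps a `pattern_set`.
#' @param prep development corpus.
#' @param model a `substitution_model`.
#' @param k number of patterns to keep.
#' @param annotator used if `prep` is a raw corpus.
#' @param stats optional precomputed [pattern_precisions()] table.
#' @param drop_unmatched when TRUE, patterns with undefined precision
#'   are dropped before ranking.
#' @return filtered `pattern_set` in ranked order.
#' @export
performance_filter <- function(ps, prep, model, k,
                               annotator = default_annotator(),
                               stats = NULL, drop_unmatched = FALSE) {
  stopifnot(k >= 1L)
  if (is.null(stats)) stats <- pattern_precisions(ps, prep, model, annotator)
  stopifnot(identical(stats$pattern_id,
                      vapply(ps$patterns, `[[`, "", "pattern_id")))
  ord <- rank_by_precision(stats)
  if (drop_unmatched) ord <- ord[!is.na(stats$precision[ord])]
  keep <- ord[seq_len(min(k, length(ord)))]
  pattern_set(ps$patterns[keep], ps$etype,
              metadata = c(ps$metadata, list(performance_k = k)))
}

#' Partition sentences by protein-mention count
#'
#' Diagnostic partition: sentences keyed by their exact number of entity
#' mentions; counts above `k_max` pool into an overflow bucket. The
#' partitions are disjoint and jointly cover every sentence with at
#' least one protein.
#'
#' @param prep corpus ([prepare_corpus()] output or raw documents).
#' @param k_max largest exact count to key separately.
#' @param annotator used if `prep` is a raw corpus.
#' @return named list `"1"`, ..., `"k_max"`, `">k_max"` of lists of
#'   `annotated_sentence`.
#' @export
partition_by_protein_count <- function(prep, k_max = 8L,
                                       annotator = default_annotator()) {
  prep <- as_prepared(prep, annotator)
  buckets <- stats::setNames(
    vector("list", k_max + 1L),
    c(as.character(seq_len(k_max)), paste0(">", k_max)))
  for (d in prep) {
    for (s in d$sentences) {
      n <- length(unique(stats::na.omit(s$entity_id)))
      if (n == 0L) next
      key <- if (n <= k_max) as.character(n) else paste0(">", k_max)
      buckets[[key]] <- c(buckets[[key]], list(s))
    }
  }
  buckets
}

#' Write trigger statistics as TSV
#'
#' Columns mirror the word / false-positive / true-positive /
#' occurrence / hit-rate layout used in trigger-word error analyses.
#'
#' @param stats [trigger_hit_rates()] output.
#' @param path output path.
#' @export
write_trigger_stats <- function(stats, path) {
  out <- data.frame(word = stats$word,
                    FP = stats$other_event_occurrences,
                    TP = stats$event_occurrences,
                    Occurrence = stats$total_occurrences,
                    `Hit rate` = round(stats$hit_rate, 1),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
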