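#' Event-level evaluation
#'
#' Predictions are scored against gold events with approximate trigger
#' span matching: a prediction is credited when its event type and Theme
#' entity agree with a gold event and its trigger span lies within the
#' gold trigger span extended by a slack of one token on each side.
#' Matching is greedy 1-1 in score order, so each gold event is credited
#' at most once.
#'
#' @name evaluation
NULL

#' F1 from precision and recall (percent scale)
#'
#' @param precision,recall percentages in `[0, 100]`.
#' @return harmonic mean `2pr/(p+r)`; defined as 0 when both are 0.
#' @examples
#' f1(24.7, 49.2)
#' @export
f1 <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Does a predicted event approximately match a gold event?
#'
#' @param pred one-row data.frame (or list) with `etype`,
#'   `trigger_start`, `trigger_end`, `theme_id`.
#' @param gold one-row data.frame of a gold event (columns as in
#'   `standoff_document$events`).
#' @param token_spans data.frame `start`, `end` of the document's
#'   tokens, used to widen the gold span by whole tokens.
#' @param slack tokens of extension on each side (default 1).
#' @return logical.
#' @export
approx_span_match <- function(pred, gold, token_spans, slack = 1L) {
  if (pred$etype != gold$etype || pred$theme_id != gold$theme_id) {
    return(FALSE)
  }
  ext <- extend_span(gold$trigger_start, gold$trigger_end, token_spans, slack)
  pred$trigger_start >= ext[1] && pred$trigger_end <= ext[2]
}

extend_span <- function(start, end, token_spans, slack) {
  if (slack <= 0L || !nrow(token_spans)) return(c(start, end))
  cover <- which(token_spans$start < end & token_spans$end > start)
  if (!length(cover)) return(c(start, end))
  lo <- max(1L, min(cover) - slack)
  hi <- min(nrow(token_spans), max(cover) + slack)
  c(min(start, token_spans$start[lo]), max(end, token_spans$end[hi]))
}

#' Evaluation report constructor
#'
#' @param tp,fp,fn non-negative counts.
#' @param by_type optional per-event-type data.frame of counts.
#' @return object of class `eval_report` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (proportions in `[0,1]`) and
#'   `undefined_precision` flagging the zero-prediction case, where
#'   precision is reported as 0 by convention.
#' @export
eval_report <- function(tp, fp, fn, by_type = NULL) {
  undef <- (tp + fp) == 0
  precision <- if (undef) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 f1 = f1(precision * 100, recall * 100) / 100,
                 undefined_precision = undef,
                 by_type = by_type),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval: TP %d FP %d FN %d | P %.1f%% R %.1f%% F1 %.1f%%>\n",
              x$tp, x$fp, x$fn, 100 * x$precision, 100 * x$recall,
              100 * x$f1))
  invisible(x)
}

#' Score predictions against a gold corpus
#'
#' @param predictions named list (doc_id) of prediction data.frames as
#'   returned by [predict_corpus()].
#' @param prep gold corpus: [prepare_corpus()] output or a list of
#'   `standoff_document`.
#' @param slack token slack for [approx_span_match()].
#' @param etype restrict scoring to one event type (default: all types
#'   present in gold or predictions).
#' @param annotator used if `prep` is a raw corpus.
#' @return an `eval_report`.
#' @export
evaluate <- function(predictions, prep, slack = 1L, etype = NULL,
                     annotator = default_annotator()) {
  prep <- as_prepared(prep, annotator)
  tp <- 0L; fp <- 0L; fn <- 0L
  type_counts <- list()
  bump <- function(ty, what) {
    if (is.null(type_counts[[ty]])) {
      type_counts[[ty]] <<- c(tp = 0L, fp = 0L, fn = 0L)
    }
    type_counts[[ty]][what] <<- type_counts[[ty]][what] + 1L
  }
  for (d in prep) {
    doc_id <- d$doc$doc_id
    gold <- d$doc$events
    if (!is.null(etype)) gold <- gold[gold$etype == etype, , drop = FALSE]
    preds <- predictions[[doc_id]]
    if (!is.null(preds) && !is.null(etype)) {
      preds <- preds[preds$etype == etype, , drop = FALSE]
    }
    token_spans <- if (length(d$sentences)) {
      do.call(rbind, lapply(d$sentences, function(s)
        s$tokens[, c("start", "end")]))
    } else data.frame(start = integer(), end = integer())

    matched_gold <- rep(FALSE, nrow(gold))
    if (!is.null(preds) && nrow(preds)) {
      ord <- if ("score" %in% names(preds)) {
        order(-preds$score, preds$trigger_start)
      } else seq_len(nrow(preds))
      for (i in ord) {
        hit <- NA_integer_
        for (g in seq_len(nrow(gold))) {
          if (matched_gold[g]) next
          if (approx_span_match(preds[i, ], gold[g, ], token_spans, slack)) {
            hit <- g
            break
          }
        }
        if (!is.na(hit)) {
          matched_gold[hit] <- TRUE
          tp <- tp + 1L
          bump(preds$etype[i], "tp")
        } else {
          fp <- fp + 1L
          bump(preds$etype[i], "fp")
        }
      }
    }
    fn <- fn + sum(!matched_gold)
    for (g in which(!matched_gold)) bump(gold$etype[g], "fn")
  }
  by_type <- if (length(type_counts)) {
    data.frame(etype = names(type_counts),
               tp = vapply(type_counts, `[[`, 0L, "tp"),
               fp = vapply(type_counts, `[[`, 0L, "fp"),
               fn = vapply(type_counts, `[[`, 0L, "fn"),
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  eval_report(tp, fp, fn, by_type = by_type)
}

#' Tune the match-score threshold on a development corpus
#'
#' Aligns once at threshold 0 and re-thresholds the cached match table
#' for every grid value, so recall is guaranteed non-increasing along an
#' ascending grid. Returns the threshold maximizing F1; ties favor the
#' higher threshold (higher precision).
#'
#' @param ps a `pattern_set`.
#' @param prep development corpus with gold annotations.
#' @param model a `substitution_model`.
#' @param grid numeric vector of candidate thresholds.
#' @param slack token slack for evaluation.
#' @param annotator used if `prep` is a raw corpus.
#' @return list: `threshold`, `report` (the winning `eval_report`) and
#'   `curve` (data.frame `threshold`, `precision`, `recall`, `f1`, in
#'   percent, for precision/recall trade-off plots).
#' @export
tune_threshold <- function(ps, prep, model, grid = seq(0.5, 1, by = 0.05),
                           slack = 1L, annotator = default_annotator()) {
  stopifnot(length(grid) >= 1L)
  prep <- as_prepared(prep, annotator)
  matches <- corpus_matches(ps, prep, model, annotator)
  grid <- sort(grid)
  reports <- lapply(grid, function(t) {
    evaluate(predictions_from_matches(matches, t), prep, slack = slack,
             etype = ps$etype)
  })
  f1s <- vapply(reports, `[[`, 0, "f1")
  best <- max(which(f1s >= max(f1s) - SCORE_EPS))  # tie -> higher threshold
  list(threshold = grid[best], report = reports[[best]],
       curve = data.frame(
         threshold = grid,
         precision = 100 * vapply(reports, `[[`, 0, "precision"),
         recall = 100 * vapply(reports, `[[`, 0, "recall"),
         f1 = 100 * f1s))
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    tp = report$tp, fp = report$fp, fn = report$fn,
    precision = 100 * report$precision, recall = 100 * report$recall,
    f1 = 100 * report$f1), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
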