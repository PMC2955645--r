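#' Multi-layer alignment matching
#'
#' Patterns are matched against masked sentences by semi-global sequence
#' alignment over three lanes at once. Each (pattern position, sentence
#' token) pair scores a linear combination of per-lane substitution
#' scores; gaps (a skipped pattern position, or a sentence token inserted
#' inside the matched region) pay a constant penalty; sentence tokens
#' outside the matched region are free. The optimum is found by dynamic
#' programming over all monotone alignments of the full pattern into a
#' contiguous region of the sentence. Scores are normalized by the
#' pattern's self-score, so a verbatim re-occurrence of the pattern core
#' scores exactly 1.
#'
#' @name alignment_matcher
NULL

#' Substitution model
#'
#' @param weights named numeric `(token, stem, pos)` layer weights;
#'   non-negative, normalized to sum 1.
#' @param match,mismatch per-layer substitution scores for identical and
#'   differing symbols; `match` must exceed `mismatch` (diagonal
#'   dominance).
#' @param gap_penalty negative score per gap position.
#' @param threshold minimum normalized score for a match to be accepted.
#' @param placeholder entity placeholder symbol; a placeholder pattern
#'   position matches any entity-masked sentence token with the full
#'   match score and anything else with the mismatch score.
#' @param event_tags POS-lane tags marking trigger positions; these occur
#'   only in patterns, never in unlabeled sentences, so on the POS lane
#'   they match any sentence tag with the full match score.
#' @param overrides optional per-layer score overrides: a list with
#'   elements named `token`, `stem` and/or `pos`, each a named numeric
#'   vector whose names are `"<pattern symbol> <sentence symbol>"` pairs.
#' @return object of class `substitution_model`.
#' @export
substitution_model <- function(weights = c(token = 0.5, stem = 0.3, pos = 0.2),
                               match = 1, mismatch = -1,
                               gap_penalty = -0.4, threshold = 0.8,
                               placeholder = PLACEHOLDER,
                               event_tags = unname(event_type_registry()),
                               overrides = list()) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0,
            match > mismatch, gap_penalty < 0)
  weights <- weights / sum(weights)
  names(weights) <- c("token", "stem", "pos")
  structure(list(weights = weights, match = match, mismatch = mismatch,
                 gap_penalty = gap_penalty, threshold = threshold,
                 placeholder = placeholder, event_tags = event_tags,
                 overrides = overrides),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf(paste0("<substitution model: weights (%.2f, %.2f, %.2f), ",
                     "match %+g / mismatch %+g, gap %+g, threshold %g>\n"),
              x$weights[1], x$weights[2], x$weights[3], x$match,
              x$mismatch, x$gap_penalty, x$threshold))
  invisible(x)
}

#' Read / write a substitution model as YAML
#' @param path YAML file path.
#' @rdname substitution_model_io
#' @export
read_substitution_model <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$weights)) args$weights <- unlist(y$weights)
  for (f in c("match", "mismatch", "gap_penalty", "threshold",
              "placeholder")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$event_tags)) args$event_tags <- unlist(y$event_tags)
  if (!is.null(y$overrides)) {
    args$overrides <- lapply(y$overrides, function(l) unlist(l))
  }
  do.call(substitution_model, args)
}

#' @param model a `substitution_model`.
#' @rdname substitution_model_io
#' @export
write_substitution_model <- function(model, path) {
  yaml::write_yaml(list(
    weights = as.list(model$weights), match = model$match,
    mismatch = model$mismatch, gap_penalty = model$gap_penalty,
    threshold = model$threshold, placeholder = model$placeholder,
    event_tags = as.list(model$event_tags),
    overrides = lapply(model$overrides, as.list)), path)
  invisible(path)
}

layer_scores <- function(pat_syms, sent_syms, layer, model,
                         wildcard_rows = logical(length(pat_syms))) {
  S <- matrix(model$mismatch, length(pat_syms), length(sent_syms))
  S[outer(pat_syms, sent_syms, "==")] <- model$match
  S[wildcard_rows, ] <- model$match
  ov <- model$overrides[[layer]]
  if (length(ov)) {
    keys <- outer(pat_syms, sent_syms, paste)
    hit <- keys %in% names(ov)
    S[hit] <- unname(ov[keys[hit]])
  }
  S
}

#' Combined pair-score matrix for one pattern against one sentence
#'
#' @param p an `event_pattern`.
#' @param sent a masked `annotated_sentence`.
#' @param model a `substitution_model`.
#' @param anchor optional sentence token index; when given, the pattern's
#'   Theme placeholder scores a full match only against that token
#'   (mismatch elsewhere), implementing per-entity re-anchoring.
#' @return numeric matrix, pattern positions x sentence tokens.
#' @export
pair_score_matrix <- function(p, sent, model, anchor = NA_integer_) {
  toks <- sent$tokens
  n <- nrow(toks)
  w <- model$weights
  S <- w[["token"]] * layer_scores(p$token_lane, toks$surface, "token", model) +
    w[["stem"]] * layer_scores(p$stem_lane, toks$stem, "stem", model) +
    w[["pos"]] * layer_scores(p$pos_lane, toks$pos, "pos", model,
                              wildcard_rows = p$pos_lane %in% model$event_tags)
  ph_rows <- which(p$token_lane == model$placeholder)
  if (length(ph_rows)) {
    masked_tok <- !is.na(sent$entity_id)
    S[ph_rows, ] <- matrix(ifelse(masked_tok, model$match, model$mismatch),
                           nrow = length(ph_rows), ncol = n, byrow = TRUE)
  }
  if (!is.na(anchor)) {
    S[p$theme_pos, ] <- model$mismatch
    S[p$theme_pos, anchor] <- model$match
  }
  S
}

#' Score of one pattern-position / sentence-token pair
#'
#' @inheritParams pair_score_matrix
#' @param p_pos pattern position.
#' @param s_tok sentence token index.
#' @return numeric score.
#' @export
pair_score <- function(p, p_pos, sent, s_tok, model, anchor = NA_integer_) {
  pair_score_matrix(p, sent, model, anchor)[p_pos, s_tok]
}

#' Self-score of a pattern
#'
#' The alignment score of the pattern against its own core; used to
#' normalize raw alignment scores.
#'
#' @inheritParams pair_score_matrix
#' @return positive numeric.
#' @export
pattern_self_score <- function(p, model) {
  w <- model$weights
  per_pos <- numeric(p$length)
  for (i in seq_len(p$length)) {
    if (p$token_lane[i] == model$placeholder) {
      per_pos[i] <- model$match
    } else {
      lu <- function(layer, sym) {
        ov <- model$overrides[[layer]]
        key <- paste(sym, sym)
        if (length(ov) && key %in% names(ov)) unname(ov[key]) else model$match
      }
      per_pos[i] <- w[["token"]] * lu("token", p$token_lane[i]) +
        w[["stem"]] * lu("stem", p$stem_lane[i]) +
        w[["pos"]] * lu("pos", p$pos_lane[i])
    }
  }
  sum(per_pos)
}

SCORE_EPS <- 1e-9

#' Align a pattern to a sentence
#'
#' Semi-global dynamic programming: the whole pattern is aligned into a
#' contiguous region of the sentence; sentence overhangs on either side
#' are free, every other gap costs `gap_penalty`. Ties are broken by
#' fewer gaps, then by leftmost start.
#'
#' @inheritParams pair_score_matrix
#' @return a list of class `match_result`: `pattern_id`, `doc_id`,
#'   `sent_index` (NA here, filled by [match_sentence()]), `alignment`
#'   (integer vector, one sentence token index per pattern position, NA
#'   for pattern gaps), `raw_score`, `norm_score`, `n_gaps`, `start`.
#' @export
align <- function(p, sent, model, anchor = NA_integer_) {
  S <- pair_score_matrix(p, sent, model, anchor)
  m <- nrow(S); n <- ncol(S)
  stopifnot(m >= 1L, n >= 1L)
  gap <- model$gap_penalty

  SC <- matrix(-Inf, m + 1L, n + 1L)
  G <- matrix(0L, m + 1L, n + 1L)
  ST <- matrix(0L, m + 1L, n + 1L)
  D <- matrix(0L, m + 1L, n + 1L)  # 1 diag, 2 up, 3 left, 0 init
  SC[1L, ] <- 0
  ST[1L, ] <- 0L:n
  for (i in 1L:m) {
    SC[i + 1L, 1L] <- i * gap
    G[i + 1L, 1L] <- i
    D[i + 1L, 1L] <- 2L
  }
  for (i in 1L:m) {
    for (j in 1L:n) {
      s_d <- SC[i, j] + S[i, j]
      s_u <- SC[i, j + 1L] + gap
      s_l <- SC[i + 1L, j] + gap
      # lexicographic best: score desc, gaps asc, start asc
      best_s <- s_d; best_g <- G[i, j]; best_st <- ST[i, j]; best_d <- 1L
      if (s_u > best_s + SCORE_EPS ||
          (s_u > best_s - SCORE_EPS &&
           (G[i, j + 1L] + 1L < best_g ||
            (G[i, j + 1L] + 1L == best_g && ST[i, j + 1L] < best_st)))) {
        best_s <- s_u; best_g <- G[i, j + 1L] + 1L
        best_st <- ST[i, j + 1L]; best_d <- 2L
      }
      if (s_l > best_s + SCORE_EPS ||
          (s_l > best_s - SCORE_EPS &&
           (G[i + 1L, j] + 1L < best_g ||
            (G[i + 1L, j] + 1L == best_g && ST[i + 1L, j] < best_st)))) {
        best_s <- s_l; best_g <- G[i + 1L, j] + 1L
        best_st <- ST[i + 1L, j]; best_d <- 3L
      }
      SC[i + 1L, j + 1L] <- best_s
      G[i + 1L, j + 1L] <- best_g
      ST[i + 1L, j + 1L] <- best_st
      D[i + 1L, j + 1L] <- best_d
    }
  }
  # free trailing overhang: best cell in the last row
  last <- SC[m + 1L, ]
  jbest <- 1L
  for (j in seq_len(n + 1L)) {
    better <- last[j] > last[jbest] + SCORE_EPS ||
      (last[j] > last[jbest] - SCORE_EPS &&
       (G[m + 1L, j] < G[m + 1L, jbest] ||
        (G[m + 1L, j] == G[m + 1L, jbest] &&
         ST[m + 1L, j] < ST[m + 1L, jbest])))
    if (j > 1L && better) jbest <- j
  }
  raw <- last[jbest]

  # traceback
  aln <- rep(NA_integer_, m)
  i <- m + 1L; j <- jbest
  while (i > 1L) {
    d <- D[i, j]
    if (d == 1L) {
      aln[i - 1L] <- j - 1L
      i <- i - 1L; j <- j - 1L
    } else if (d == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }

  self <- pattern_self_score(p, model)
  structure(list(pattern_id = p$pattern_id, doc_id = sent$doc_id,
                 sent_index = NA_integer_, alignment = aln,
                 raw_score = raw, norm_score = raw / self,
                 n_gaps = G[m + 1L, jbest], start = ST[m + 1L, jbest]),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match %s on %s: raw %.3f, norm %.3f, %d gap(s)>\n",
              x$pattern_id, x$doc_id, x$raw_score, x$norm_score, x$n_gaps))
  invisible(x)
}

match_event_from <- function(p, sent, res, anchor) {
  trig <- res$alignment[p$trigger_positions]
  theme <- res$alignment[p$theme_pos]
  if (any(is.na(trig)) || is.na(theme)) return(NULL)
  if (!is.na(anchor) && theme != anchor) return(NULL)
  theme_id <- sent$entity_id[theme]
  if (is.na(theme_id)) return(NULL)
  list(etype = p$etype,
       trigger_start = min(sent$tokens$start[trig]),
       trigger_end = max(sent$tokens$end[trig]),
       theme_id = theme_id)
}

#' Match a pattern set against one sentence
#'
#' Each pattern is aligned once per candidate anchoring of its Theme
#' placeholder (one per entity token in the sentence); matches with
#' normalized score at or above the model threshold are kept, and
#' duplicate predicted events keep the best score.
#'
#' @param ps a `pattern_set`.
#' @param sent a masked `annotated_sentence`.
#' @param model a `substitution_model`.
#' @param threshold overrides `model$threshold` when given.
#' @return list of accepted `match_result`s, each with an `event` element
#'   (`NULL` when trigger or theme aligned to a gap).
#' @export
match_sentence <- function(ps, sent, model, threshold = model$threshold) {
  if (!nrow(sent$tokens)) return(list())
  anchors <- which(!is.na(sent$entity_id))
  if (!length(anchors)) anchors <- NA_integer_
  out <- list()
  for (p in ps$patterns) {
    for (a in anchors) {
      res <- align(p, sent, model, anchor = a)
      if (res$norm_score < threshold - SCORE_EPS) next
      res$event <- match_event_from(p, sent, res, a)
      out[[length(out) + 1L]] <- res
    }
  }
  # collapse duplicate predicted events, keeping the best score
  has_ev <- vapply(out, function(r) !is.null(r$event), logical(1))
  ev_key <- vapply(out, function(r) {
    if (is.null(r$event)) NA_character_
    else paste(r$event$etype, r$event$trigger_start, r$event$trigger_end,
               r$event$theme_id)
  }, character(1))
  keep <- rep(TRUE, length(out))
  if (any(has_ev)) {
    for (key in unique(ev_key[has_ev])) {
      grp <- which(!is.na(ev_key) & ev_key == key)
      if (length(grp) > 1L) {
        scores <- vapply(out[grp], `[[`, 0, "norm_score")
        keep[grp[-which.max(scores)]] <- FALSE
      }
    }
  }
  out[keep]
}

#' All candidate matches of a pattern set over a corpus
#'
#' Computes, for every pattern x sentence x anchoring, the best
#' alignment, and returns those that yield a predicted event, ignoring
#' the threshold. Downstream consumers ([predict_corpus()],
#' [tune_threshold()], [pattern_precisions()]) filter this table, which
#' avoids re-aligning for every threshold or pattern subset.
#'
#' @param ps a `pattern_set`.
#' @param prep output of [prepare_corpus()] (or raw corpus).
#' @param model a `substitution_model`.
#' @param annotator used if `prep` is a raw corpus.
#' @return data.frame: `doc_id`, `sent_index`, `pattern_id`,
#'   `norm_score`, `etype`, `trigger_start`, `trigger_end`, `theme_id`.
#' @export
corpus_matches <- function(ps, prep, model,
                           annotator = default_annotator()) {
  prep <- as_prepared(prep, annotator)
  rows <- list()
  for (d in prep) {
    for (k in seq_along(d$masked)) {
      sent <- d$masked[[k]]
      if (!nrow(sent$tokens)) next
      anchors <- which(!is.na(sent$entity_id))
      if (!length(anchors)) next
      for (p in ps$patterns) {
        for (a in anchors) {
          res <- align(p, sent, model, anchor = a)
          ev <- match_event_from(p, sent, res, a)
          if (is.null(ev)) next
          rows[[length(rows) + 1L]] <- data.frame(
            doc_id = d$doc$doc_id, sent_index = k,
            pattern_id = p$pattern_id, norm_score = res$norm_score,
            etype = ev$etype, trigger_start = ev$trigger_start,
            trigger_end = ev$trigger_end, theme_id = ev$theme_id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(), sent_index = integer(),
                      pattern_id = character(), norm_score = numeric(),
                      etype = character(), trigger_start = integer(),
                      trigger_end = integer(), theme_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Threshold and deduplicate a match table into per-document predictions
#'
#' @param matches output of [corpus_matches()].
#' @param threshold minimum normalized score.
#' @return named list (doc_id) of prediction data.frames (`etype`,
#'   `trigger_start`, `trigger_end`, `theme_id`, `score`, `pattern_id`),
#'   best score per distinct event, ordered by score descending.
#' @export
predictions_from_matches <- function(matches, threshold) {
  acc <- matches[matches$norm_score >= threshold - SCORE_EPS, , drop = FALSE]
  out <- list()
  for (doc in unique(acc$doc_id)) {
    sub <- acc[acc$doc_id == doc, , drop = FALSE]
    key <- paste(sub$etype, sub$trigger_start, sub$trigger_end, sub$theme_id)
    ord <- order(-sub$norm_score, sub$pattern_id)
    sub <- sub[ord, , drop = FALSE]
    sub <- sub[!duplicated(key[ord]), , drop = FALSE]
    out[[doc]] <- data.frame(etype = sub$etype,
                             trigger_start = sub$trigger_start,
                             trigger_end = sub$trigger_end,
                             theme_id = sub$theme_id,
                             score = sub$norm_score,
                             pattern_id = sub$pattern_id,
                             stringsAsFactors = FALSE)
  }
  out
}

#' Predict events over a corpus
#'
#' @inheritParams corpus_matches
#' @param threshold overrides `model$threshold` when given.
#' @param site_regexes when non-NULL, phosphorylation predictions attach
#'   the nearest site mention tagged by [tag_phospho_sites()]
#'   (`site_start`/`site_end` columns).
#' @return named list (doc_id) of prediction data.frames; documents with
#'   no predictions are absent.
#' @export
predict_corpus <- function(ps, prep, model, threshold = model$threshold,
                           annotator = default_annotator(),
                           site_regexes = NULL) {
  prep <- as_prepared(prep, annotator)
  preds <- predictions_from_matches(corpus_matches(ps, prep, model,
                                                   annotator),
                                    threshold)
  if (!is.null(site_regexes) && length(preds)) {
    docs <- stats::setNames(lapply(prep, `[[`, "doc"),
                            vapply(prep, function(d) d$doc$doc_id, ""))
    for (doc_id in names(preds)) {
      pr <- preds[[doc_id]]
      pr$site_start <- NA_integer_
      pr$site_end <- NA_integer_
      phos <- which(pr$etype == "Phosphorylation")
      if (length(phos)) {
        sites <- tag_phospho_sites(docs[[doc_id]]$text, site_regexes)
        if (nrow(sites)) {
          for (i in phos) {
            d <- pmax(sites$start - pr$trigger_end[i],
                      pr$trigger_start[i] - sites$end, 0L)
            j <- which.min(d)
            pr$site_start[i] <- sites$start[j]
            pr$site_end[i] <- sites$end[j]
          }
        }
      }
      preds[[doc_id]] <- pr
    }
  }
  preds
}
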