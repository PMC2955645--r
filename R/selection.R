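#' Pattern selection by repeated resampling
#'
#' The held-out-evaluation protocol: resample the combined training
#' corpus into several random train/development splits, optimize the
#' filters on each split independently, pool the distinct surviving
#' patterns ranked by their development precision, and evaluate best-k
#' prefixes of the pooled set on unseen text.
#'
#' @name selection
NULL

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Random train/development splits
#'
#' @param ids document identifiers (or any vector of corpus keys).
#' @param n_splits number of independent splits (default 5).
#' @param train_size documents per training part; the remainder forms
#'   the development part.
#' @param seed integer seed; the plan is reproducible for a fixed seed
#'   and leaves the global RNG state untouched.
#' @return object of class `split_plan`: list with `seed`, `n_splits`,
#'   `train_size`, `dev_size` and `splits`, a list of
#'   `list(train =, dev =)` id vectors.
#' @export
make_splits <- function(ids, n_splits = 5L, train_size, seed) {
  stopifnot(length(ids) >= 2L, !anyDuplicated(ids))
  if (train_size >= length(ids)) {
    stop("train_size must be smaller than the corpus", call. = FALSE)
  }
  splits <- with_local_seed(seed, {
    lapply(seq_len(n_splits), function(i) {
      train <- sort(sample(ids, train_size))
      list(train = train, dev = sort(setdiff(ids, train)))
    })
  })
  structure(list(seed = seed, n_splits = n_splits,
                 train_size = train_size,
                 dev_size = length(ids) - train_size, splits = splits),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split plan: %d splits of %d train / %d dev (seed %d)>\n",
              x$n_splits, x$train_size, x$dev_size, x$seed))
  invisible(x)
}

#' Write / read a split plan as JSON
#' @param plan a `split_plan`.
#' @param path file path.
#' @rdname split_plan_io
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname split_plan_io
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$splits <- lapply(seq_len(nrow(x$splits)), function(i) {
    list(train = unlist(x$splits[i, "train"][[1]]),
         dev = unlist(x$splits[i, "dev"][[1]]))
  })
  class(x) <- "split_plan"
  x
}

#' Optimize filters on one train/development split
#'
#' Learns patterns on the training documents, ranks them by individual
#' development precision, sweeps the performance-filter size k over a
#' grid picking the development-F1 optimum, then (optionally) sweeps a
#' maximum-length cap the same way. Performance and length filters are
#' applied sequentially in that order.
#'
#' @param prep full prepared corpus (all documents of the plan).
#' @param split one element of `split_plan$splits`.
#' @param etype event type.
#' @param model a `substitution_model`.
#' @param k_grid candidate performance-filter sizes (clipped to the
#'   pattern-set size).
#' @param sweep_length also sweep the length cap after the k sweep.
#' @param neighbourhood pattern-learning neighbourhood.
#' @param annotator annotator (must match the one used for `prep`).
#' @return list: `patterns` (optimized `pattern_set`, ranked),
#'   `report` (dev `eval_report`), `k`, `length_cap`, `precisions`
#'   (per-pattern dev stats for the surviving patterns).
#' @export
optimize_on_split <- function(prep, split, etype, model,
                              k_grid = seq(10L, 200L, by = 10L),
                              sweep_length = TRUE, neighbourhood = 1L,
                              annotator = default_annotator()) {
  doc_ids <- vapply(prep, function(d) d$doc$doc_id, "")
  train <- prep[doc_ids %in% split$train]
  dev <- prep[doc_ids %in% split$dev]
  ps <- learn_patterns(train, etype, neighbourhood = neighbourhood,
                       annotator = annotator)
  if (!length(ps)) {
    return(list(patterns = ps, report = eval_report(0L, 0L, 0L),
                k = 0L, length_cap = NA_integer_,
                precisions = pattern_precisions(ps, dev, model, annotator)))
  }
  matches <- corpus_matches(ps, dev, model, annotator)
  stats <- pattern_precisions(ps, dev, model, annotator, matches = matches)
  ord <- rank_by_precision(stats)

  eval_subset <- function(pids) {
    sub <- matches[matches$pattern_id %in% pids, , drop = FALSE]
    evaluate(predictions_from_matches(sub, model$threshold), dev,
             etype = etype)
  }
  ks <- unique(pmin(k_grid[k_grid >= 1L], length(ps)))
  best <- NULL
  for (k in sort(ks)) {
    ids_k <- stats$pattern_id[ord[seq_len(k)]]
    rpt <- eval_subset(ids_k)
    if (is.null(best) || rpt$f1 > best$report$f1 + SCORE_EPS) {
      best <- list(k = k, ids = ids_k, report = rpt)
    }
  }
  kept <- ps$patterns[match(best$ids, vapply(ps$patterns, `[[`, "",
                                             "pattern_id"))]
  length_cap <- NA_integer_
  if (sweep_length && length(kept)) {
    lens <- vapply(kept, `[[`, 0L, "length")
    best_len <- NULL
    for (cap in sort(unique(lens))) {
      ids_c <- vapply(kept[lens <= cap], `[[`, "", "pattern_id")
      rpt <- eval_subset(ids_c)
      if (is.null(best_len) || rpt$f1 > best_len$report$f1 + SCORE_EPS) {
        best_len <- list(cap = cap, ids = ids_c, report = rpt)
      }
    }
    if (best_len$report$f1 > best$report$f1 + SCORE_EPS) {
      kept <- kept[lens <= best_len$cap]
      best$report <- best_len$report
      length_cap <- best_len$cap
    }
  }
  kept_ids <- vapply(kept, `[[`, "", "pattern_id")
  list(patterns = pattern_set(kept, etype,
                              metadata = list(k = best$k,
                                              length_cap = length_cap)),
       report = best$report, k = best$k, length_cap = length_cap,
       precisions = stats[match(kept_ids, stats$pattern_id), ,
                          drop = FALSE])
}

#' Pool optimized pattern sets from several splits
#'
#' Deduplicates by pattern identity (event type, lanes, trigger/theme
#' positions), keeping for each pattern the maximum development
#' precision achieved on any split, and ranks by that precision
#' (undefined last; ties by development match count descending, then
#' pattern key).
#'
#' @param results list of [optimize_on_split()] results.
#' @return object of class `ranked_pattern_set`: a `pattern_set` whose
#'   `metadata$ranking` data.frame records `dev_precision`, `matches`
#'   and `source_split` per pattern, in rank order.
#' @export
union_patterns <- function(results) {
  stopifnot(length(results) >= 1L)
  pool <- list()
  for (s in seq_along(results)) {
    res <- results[[s]]
    for (i in seq_along(res$patterns$patterns)) {
      p <- res$patterns$patterns[[i]]
      key <- pattern_key(p)
      prec <- res$precisions$precision[i]
      nmatch <- res$precisions$matches[i]
      cur <- pool[[key]]
      if (is.null(cur) ||
          (is.na(cur$precision) && !is.na(prec)) ||
          (!is.na(prec) && !is.na(cur$precision) && prec > cur$precision)) {
        pool[[key]] <- list(pattern = p, precision = prec,
                            matches = nmatch, split = s)
      }
    }
  }
  keys <- names(pool)
  prec <- vapply(pool, function(x) {
    if (is.na(x$precision)) -1 else x$precision
  }, 0)
  nmatch <- vapply(pool, `[[`, 0L, "matches")
  ord <- order(-prec, -nmatch, keys)
  pats <- lapply(pool[ord], `[[`, "pattern")
  for (i in seq_along(pats)) pats[[i]]$pattern_id <- sprintf("U%04d", i)
  ranking <- data.frame(
    pattern_id = vapply(pats, `[[`, "", "pattern_id"),
    dev_precision = vapply(pool[ord], function(x) x$precision, 0),
    matches = nmatch[ord],
    source_split = vapply(pool[ord], `[[`, 0L, "split"),
    stringsAsFactors = FALSE)
  etype <- if (length(pats)) pats[[1]]$etype else results[[1]]$patterns$etype
  out <- pattern_set(pats, etype, metadata = list(ranking = ranking))
  class(out) <- c("ranked_pattern_set", class(out))
  out
}

#' Top-k prefix of a ranked pattern set
#'
#' @param rps a `ranked_pattern_set`.
#' @param k prefix size, `1 <= k <= length(rps)`.
#' @return a `pattern_set` of the k best-ranked patterns.
#' @export
take_best <- function(rps, k) {
  if (k < 1L || k > length(rps)) {
    stop(sprintf("k must be in [1, %d]", length(rps)), call. = FALSE)
  }
  pattern_set(rps$patterns[seq_len(k)], rps$etype,
              metadata = list(taken = k))
}
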