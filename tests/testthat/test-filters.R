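model_strict <- substitution_model(threshold = 1)

ambig_world <- local({
  gen <- generate_corpus(ambig_config(seed = 11L, n_docs = 40L))
  prep <- prepare_corpus(gen$corpus, lex_ann)
  ps <- learn_patterns(prep, "Gene_expression", annotator = lex_ann)
  list(gen = gen, prep = prep, ps = ps,
       matches = corpus_matches(ps, prep, model_strict, lex_ann))
})

test_that("hit rate is event occurrences over total occurrences", {
  s <- trigger_stats("expressed", 136, 25, 232)
  expect_equal(s$hit_rate, 136 / 232)
  expect_equal(round(s$hit_rate, 1), 0.6)
  expect_equal(trigger_stats("co-transfections", 1, 1, 2)$hit_rate, 0.5)
  # a word never annotated as a trigger has hit rate 0
  expect_equal(trigger_stats("cells", 0, 0, 50)$hit_rate, 0)
  expect_error(trigger_stats("x", 5, 0, 4))
})

test_that("trigger hit rates are counted over the tokenized corpus", {
  stats <- trigger_hit_rates(ambig_world$prep, "Gene_expression", lex_ann)
  expect_true(all(stats$hit_rate >= 0 & stats$hit_rate <= 1))
  expect_true(all(stats$event_occurrences <= stats$total_occurrences))
  # sorted by hit rate desc, then total occurrences desc, then word
  expect_true(all(diff(stats$hit_rate) <= 1e-12))
  # planted rates recovered: always-event triggers at 1, ambiguous low
  hr <- function(w) stats$hit_rate[stats$word == w]
  expect_equal(hr("expressed"), 1)
  expect_equal(hr("expression"), 1)
  expect_lt(hr("induced"), 0.35)
  expect_true(abs(hr("overexpression") - 0.5) < 0.3)
})

test_that("trigger word filter keeps only top-hit-rate triggers", {
  stats <- trigger_hit_rates(ambig_world$prep, "Gene_expression", lex_ann)
  ps <- ambig_world$ps
  expect_equal(length(trigger_word_filter(ps, stats, nrow(stats))),
               length(ps))
  top1 <- trigger_word_filter(ps, stats, 1L)
  trig_words <- unique(vapply(top1$patterns, function(p)
    tolower(p$token_lane[p$trigger_pos]), ""))
  expect_equal(trig_words, stats$word[1])
  expect_error(trigger_word_filter(ps, stats, 0L), "positive")
})

test_that("length filter selects by maximum or exact token count", {
  ps <- ambig_world$ps
  lens <- vapply(ps$patterns, `[[`, 0L, "length")
  expect_equal(length(length_filter(ps, max(lens))), length(ps))
  f4 <- length_filter(ps, 4L)
  expect_true(all(vapply(f4$patterns, `[[`, 0L, "length") <= 4L))
  e5 <- length_filter(ps, 5L, exact = TRUE)
  expect_true(all(vapply(e5$patterns, `[[`, 0L, "length") == 5L))
  expect_equal(length(f4) + sum(lens > 4), length(ps))
})

test_that("per-pattern precision separates clean from dirty patterns", {
  w <- ambig_world
  stats <- pattern_precisions(w$ps, w$prep, model_strict, lex_ann,
                              matches = w$matches)
  expect_equal(nrow(stats), length(w$ps))
  trig <- vapply(w$ps$patterns, function(p)
    tolower(p$token_lane[p$trigger_pos]), "")
  clean <- trig %in% c("expressed", "expression", "produced")
  matched <- stats$matches > 0
  expect_true(all(stats$precision[clean & matched] == 1))
  dirty <- trig == "induced" & matched
  expect_true(all(stats$precision[dirty] < 0.6))
  # the 1:1 ambiguous trigger sits near one half
  amb <- trig == "overexpression" & matched
  if (any(amb)) {
    expect_true(all(abs(stats$precision[amb] - 0.5) < 0.35))
  }
})

test_that("patterns matching nothing get undefined precision, ranked last", {
  w <- ambig_world
  # a pattern whose token lane occurs nowhere
  alien <- random_pattern(3, c("zzz", "yyy", "xxx"))
  alien$pattern_id <- "P9999"
  alien$token_lane[1] <- "PTN"
  alien$stem_lane[1] <- "PTN"
  alien$pos_lane[1] <- "PTN"
  alien$theme_pos <- 1L
  alien$trigger_pos <- 2L
  alien$trigger_positions <- 2L
  ps <- pattern_set(c(w$ps$patterns, list(alien)), "Gene_expression")
  stats <- pattern_precisions(ps, w$prep, model_strict, lex_ann)
  expect_equal(stats$matches[nrow(stats)], 0L)
  expect_true(is.na(stats$precision[nrow(stats)]))
  ranked <- performance_filter(ps, w$prep, model_strict, k = length(ps),
                               annotator = lex_ann, stats = stats)
  ids <- vapply(ranked$patterns, `[[`, "", "pattern_id")
  expect_equal(ids[length(ids)], "P9999")
  # drop_unmatched removes it entirely
  dropped <- performance_filter(ps, w$prep, model_strict, k = length(ps),
                                annotator = lex_ann, stats = stats,
                                drop_unmatched = TRUE)
  expect_false("P9999" %in% vapply(dropped$patterns, `[[`, "", "pattern_id"))
})

test_that("performance filter keeps the k individually best patterns", {
  w <- ambig_world
  stats <- pattern_precisions(w$ps, w$prep, model_strict, lex_ann,
                              matches = w$matches)
  k <- sum(stats$precision == 1, na.rm = TRUE)
  top <- performance_filter(w$ps, w$prep, model_strict, k = k,
                            annotator = lex_ann, stats = stats)
  expect_equal(length(top), k)
  base_rpt <- evaluate(predictions_from_matches(w$matches, 1), w$prep,
                       etype = "Gene_expression")
  top_ids <- vapply(top$patterns, `[[`, "", "pattern_id")
  top_rpt <- evaluate(
    predictions_from_matches(
      w$matches[w$matches$pattern_id %in% top_ids, ], 1),
    w$prep, etype = "Gene_expression")
  expect_gte(top_rpt$precision, base_rpt$precision)
})

test_that("filters are contractions and trigger x length commutes", {
  w <- ambig_world
  stats <- trigger_hit_rates(w$prep, "Gene_expression", lex_ann)
  ids <- function(ps) sort(vapply(ps$patterns, `[[`, "", "pattern_id"))
  a <- trigger_word_filter(w$ps, stats, 2L)
  b <- length_filter(w$ps, 5L)
  expect_true(all(ids(a) %in% ids(w$ps)))
  expect_true(all(ids(b) %in% ids(w$ps)))
  expect_equal(ids(length_filter(a, 5L)),
               ids(trigger_word_filter(b, stats, 2L)))
})

test_that("filtering never adds predictions downstream", {
  w <- ambig_world
  full_keys <- pred_keys(predictions_from_matches(w$matches, 1))
  stats <- trigger_hit_rates(w$prep, "Gene_expression", lex_ann)
  for (filtered in list(
    trigger_word_filter(w$ps, stats, 2L),
    length_filter(w$ps, 5L),
    performance_filter(w$ps, w$prep, model_strict, k = 5L,
                       annotator = lex_ann))) {
    pids <- vapply(filtered$patterns, `[[`, "", "pattern_id")
    sub_keys <- pred_keys(predictions_from_matches(
      w$matches[w$matches$pattern_id %in% pids, ], 1))
    expect_true(all(sub_keys %in% full_keys))
  }
})

test_that("protein-count partition is disjoint and exhaustive", {
  w <- ambig_world
  parts <- partition_by_protein_count(w$prep, k_max = 4L)
  n_prot_sent <- sum(vapply(w$prep, function(d) {
    sum(vapply(d$sentences, function(s)
      length(unique(stats::na.omit(s$entity_id))) >= 1L, logical(1)))
  }, 0L))
  expect_equal(sum(lengths(parts)), n_prot_sent)
  for (k in 1:4) {
    for (s in parts[[as.character(k)]]) {
      expect_equal(length(unique(stats::na.omit(s$entity_id))), k)
    }
  }
})

test_that("trigger statistics export mirrors the error-analysis layout", {
  stats <- trigger_hit_rates(ambig_world$prep, "Gene_expression", lex_ann)
  path <- file.path(withr::local_tempdir(), "triggers.tsv")
  write_trigger_stats(stats, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(names(back), c("word", "FP", "TP", "Occurrence", "Hit rate"))
  expect_equal(back$TP, stats$event_occurrences)
  expect_equal(back$Occurrence, stats$total_occurrences)
})
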