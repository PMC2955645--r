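test_that("splits partition the corpus reproducibly", {
  ids <- sprintf("a%03d", 1:950)
  plan <- make_splits(ids, n_splits = 5L, train_size = 800L, seed = 4L)
  expect_equal(plan$dev_size, 150L)
  for (s in plan$splits) {
    expect_length(s$train, 800L)
    expect_length(s$dev, 150L)
    expect_length(intersect(s$train, s$dev), 0L)
    expect_setequal(c(s$train, s$dev), ids)
  }
  # splits differ from each other (w.h.p.) but reproduce under the seed
  expect_false(identical(plan$splits[[1]]$train, plan$splits[[2]]$train))
  plan2 <- make_splits(ids, n_splits = 5L, train_size = 800L, seed = 4L)
  expect_identical(plan, plan2)
  expect_error(make_splits(ids, 2L, 950L, seed = 1L), "smaller")
})

test_that("split plans survive a JSON round trip", {
  plan <- make_splits(letters, n_splits = 2L, train_size = 20L, seed = 9L)
  path <- file.path(withr::local_tempdir(), "plan.json")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  expect_equal(back$seed, plan$seed)
  expect_equal(back$splits[[1]]$train, plan$splits[[1]]$train)
  expect_equal(back$splits[[2]]$dev, plan$splits[[2]]$dev)
})

test_that("per-split optimization recovers the clean pattern subset", {
  gen <- generate_corpus(ambig_config(seed = 41L, n_docs = 30L))
  prep <- prepare_corpus(gen$corpus, lex_ann)
  ids <- vapply(prep, function(d) d$doc$doc_id, "")
  plan <- make_splits(ids, n_splits = 1L, train_size = 22L, seed = 5L)
  model <- substitution_model(threshold = 1)
  res <- optimize_on_split(prep, plan$splits[[1]], "Gene_expression",
                           model, k_grid = seq(2L, 30L, by = 2L),
                           annotator = lex_ann)
  expect_gt(length(res$patterns), 0L)
  expect_gt(res$report$f1, 0.8)
  # surviving patterns carry clean triggers predominantly
  trig <- vapply(res$patterns$patterns, function(p)
    tolower(p$token_lane[p$trigger_pos]), "")
  expect_gt(mean(trig %in% c("expressed", "expression", "produced")), 0.7)
  expect_equal(nrow(res$precisions), length(res$patterns))
})

test_that("a single-template corpus optimizes to a single pattern", {
  cfg <- synthetic_config(
    seed = 3L, n_docs = 12L,
    templates = synthetic_templates()[c(1, 5), ],
    trigger_vocab = data.frame(word = "expressed", hit_rate = 1,
                               weight = 1, stringsAsFactors = FALSE),
    distractor_rate = 0.3, noise_rate = 0)
  gen <- generate_corpus(cfg)
  prep <- prepare_corpus(gen$corpus, lex_ann)
  ids <- vapply(prep, function(d) d$doc$doc_id, "")
  plan <- make_splits(ids, 1L, train_size = 9L, seed = 2L)
  res <- optimize_on_split(prep, plan$splits[[1]], "Gene_expression",
                           substitution_model(threshold = 1),
                           k_grid = 1:5, annotator = lex_ann)
  expect_equal(res$k, 1L)
  expect_equal(length(res$patterns), 1L)
})

test_that("union merges duplicates keeping the best dev precision", {
  gen <- generate_corpus(clean_config(seed = 6L, n_docs = 10L))
  ps <- learn_patterns(gen$corpus, "Gene_expression", annotator = lex_ann)
  mk_res <- function(ps, precs, matches) {
    list(patterns = ps,
         precisions = data.frame(
           pattern_id = vapply(ps$patterns, `[[`, "", "pattern_id"),
           matches = matches, tp = 0L, fp = 0L, precision = precs,
           stringsAsFactors = FALSE))
  }
  n <- length(ps)
  # five identical sets: union size is n
  same <- replicate(5, mk_res(ps, rep(0.8, n), rep(3L, n)),
                    simplify = FALSE)
  expect_equal(length(union_patterns(same)), n)
  # disjoint sets of sizes 2 and 3: union size 5
  s1 <- pattern_set(ps$patterns[1:2], "Gene_expression")
  s2 <- pattern_set(ps$patterns[3:5], "Gene_expression")
  expect_equal(length(union_patterns(list(
    mk_res(s1, c(1, 1), c(2L, 2L)), mk_res(s2, c(1, 1, 1), rep(2L, 3))))),
    5L)
  # a pattern in two splits keeps its maximum precision
  both <- union_patterns(list(mk_res(s1, c(0.8, 0.4), c(2L, 2L)),
                              mk_res(s1, c(0.6, 0.9), c(2L, 2L))))
  expect_equal(length(both), 2L)
  expect_equal(sort(both$metadata$ranking$dev_precision,
                    decreasing = TRUE), c(0.9, 0.8))
  # ranking is precision-descending
  expect_true(all(diff(both$metadata$ranking$dev_precision) <= 0))
})

test_that("take_best returns nested prefixes of the ranking", {
  gen <- generate_corpus(clean_config(seed = 6L, n_docs = 10L))
  ps <- learn_patterns(gen$corpus, "Gene_expression", annotator = lex_ann)
  res <- list(patterns = ps,
              precisions = data.frame(
                pattern_id = vapply(ps$patterns, `[[`, "", "pattern_id"),
                matches = seq_along(ps$patterns), tp = 0L, fp = 0L,
                precision = seq(1, 0.5, length.out = length(ps)),
                stringsAsFactors = FALSE))
  rps <- union_patterns(list(res))
  expect_equal(length(take_best(rps, length(rps))), length(rps))
  ids <- function(ps) vapply(ps$patterns, `[[`, "", "pattern_id")
  for (k in seq_len(length(rps) - 1L)) {
    expect_true(all(ids(take_best(rps, k)) %in% ids(take_best(rps, k + 1L))))
  }
  expect_error(take_best(rps, 0L))
  expect_error(take_best(rps, length(rps) + 1L))
})
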