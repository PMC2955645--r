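model_default <- substitution_model()
model_strict <- substitution_model(threshold = 1)

learned_tiny <- function() {
  learn_patterns(list(tiny_doc()), "Gene_expression", neighbourhood = 1,
                 annotator = lex_ann)$patterns[[1]]
}

test_that("pair scores combine the three lanes linearly", {
  p <- learned_tiny()
  ms <- mask_entities(annotate_sentences(tiny_doc(), lex_ann)[[1]])
  S <- pair_score_matrix(p, ms, model_default)
  # identical symbols on all lanes: maximal combined score
  expect_equal(S[2, 2], 1)          # protein vs protein
  expect_equal(S[3, 3], 1)          # is vs is
  # trigger position: token+stem match, POS lane wildcarded by GEE tag
  expect_equal(S[4, 4], 1)
  # placeholder vs entity-masked token: full match
  expect_equal(S[1, 1], 1)
  # placeholder vs ordinary token: mismatch
  expect_equal(S[1, 2], -1)
  # all-lane mismatch
  expect_equal(S[2, 3], -1)
  expect_equal(pair_score(p, 2, ms, 2, model_default), 1)
})

test_that("token mismatch with stem/POS agreement scores in between", {
  # "expressed" vs "expressing": stems agree, POS differs (VBN/VBG)
  doc <- read_standoff("CD19 protein is expressing",
                       "T1\tProtein 0 4\tCD19", "", "alt")
  ms <- mask_entities(annotate_sentences(doc, lex_ann)[[1]])
  p <- learned_tiny()
  S <- pair_score_matrix(p, ms, model_default)
  # token -1, stem +1, POS wildcard (GEE) +1 -> -0.5 + 0.3 + 0.2 = 0
  expect_equal(S[4, 4], 0)
  expect_true(S[4, 4] > -1 && S[4, 4] < 1)
})

test_that("self-alignment is exact with normalized score 1", {
  p <- learned_tiny()
  ms <- mask_entities(annotate_sentences(tiny_doc(), lex_ann)[[1]])
  res <- align(p, ms, model_default, anchor = 1L)
  expect_equal(res$norm_score, 1.0)
  expect_equal(res$raw_score, pattern_self_score(p, model_default))
  expect_equal(res$alignment, 1:4)
  expect_equal(res$n_gaps, 0L)
})

test_that("a deleted pattern token costs one match plus one gap", {
  p <- learned_tiny()  # PTN protein is expressed
  doc <- read_standoff("CD19 is expressed", "T1\tProtein 0 4\tCD19",
                       "", "short")
  ms <- mask_entities(annotate_sentences(doc, lex_ann)[[1]])
  res <- align(p, ms, model_default, anchor = 1L)
  # self-score 4; drop match(protein)=1, add gap -0.4
  expect_equal(res$raw_score, 4 - 1 - 0.4)
  expect_equal(res$norm_score, 2.6 / 4)
  expect_equal(res$alignment, c(1L, NA, 2L, 3L))
  expect_equal(res$n_gaps, 1L)
})

test_that("the DP optimum equals exhaustive enumeration", {
  set.seed(421)
  alphabet <- letters[1:5]
  for (rep in 1:300) {
    p <- random_pattern(sample(1:4, 1), alphabet)
    sent <- random_sentence(sample(1:6, 1), alphabet)
    S <- pair_score_matrix(p, sent, model_default)
    expect_equal(align(p, sent, model_default)$raw_score,
                 brute_align_score(S, model_default$gap_penalty),
                 tolerance = 1e-9)
  }
})

test_that("alignment is deterministic across repeated runs", {
  set.seed(77)
  p <- random_pattern(4, letters[1:4])
  sent <- random_sentence(6, letters[1:4])
  r1 <- align(p, sent, model_default)
  r2 <- align(p, sent, model_default)
  expect_identical(r1$raw_score, r2$raw_score)
  expect_identical(r1$alignment, r2$alignment)
  expect_identical(r1$n_gaps, r2$n_gaps)
  expect_identical(r1$start, r2$start)
})

test_that("match_sentence enforces the threshold and re-anchors entities", {
  # sentence with two proteins and one trigger (theme-ambiguous)
  txt <- "TNF is strongly expressed by STAT3 ."
  a1 <- "T1\tProtein 0 3\tTNF\nT2\tProtein 29 34\tSTAT3"
  doc <- read_standoff(txt, a1, "", "two")
  ms <- mask_entities(annotate_sentences(doc, lex_ann)[[1]])
  tpl_doc <- read_standoff(
    "FOXP3 is strongly expressed by MYC .",
    "T1\tProtein 0 5\tFOXP3\nT2\tProtein 31 34\tMYC",
    paste("T3\tGene_expression 18 27\texpressed",
          "E1\tGene_expression:T3 Theme:T1", sep = "\n"), "tpl")
  ps <- learn_patterns(list(tpl_doc), "Gene_expression", neighbourhood = 1,
                       annotator = lex_ann)
  # threshold 0: the aligner runs once per anchoring; up to two
  # candidate events, and only anchorings where the theme stays aligned
  # yield an event
  res0 <- match_sentence(ps, ms, model_default, threshold = 0)
  expect_equal(length(res0), 2L)
  evs <- Filter(Negate(is.null), lapply(res0, `[[`, "event"))
  expect_true(length(evs) >= 1L && length(evs) <= 2L)
  themes <- vapply(evs, `[[`, "", "theme_id")
  expect_true("T1" %in% themes)
  scores <- vapply(res0, `[[`, 0, "norm_score")
  # the correct anchoring scores strictly higher than the alternative
  expect_gt(max(scores), min(scores))
  expect_equal(max(scores), 1.0)
  # threshold 1: only the verbatim anchoring survives
  res1 <- match_sentence(ps, ms, model_default, threshold = 1)
  expect_length(res1, 1L)
  expect_equal(res1[[1]]$event$theme_id, "T1")
})

test_that("accepted matches are nested along ascending thresholds", {
  gen <- generate_corpus(ambig_config(seed = 31L, n_docs = 15L,
                                      noise_rate = 0.2))
  prep <- prepare_corpus(gen$corpus, lex_ann)
  ps <- learn_patterns(prep, "Gene_expression", annotator = lex_ann)
  matches <- corpus_matches(ps, prep, model_default, lex_ann)
  grid <- c(0.4, 0.6, 0.8, 0.9, 1.0)
  keysets <- lapply(grid, function(t)
    pred_keys(predictions_from_matches(matches, t)))
  recalls <- vapply(grid, function(t) {
    evaluate(predictions_from_matches(matches, t), prep,
             etype = "Gene_expression")$recall
  }, 0)
  for (i in seq_along(grid)[-1]) {
    expect_true(all(keysets[[i]] %in% keysets[[i - 1]]))
    expect_lte(recalls[i], recalls[i - 1])
  }
})

test_that("predictions on the training corpus contain every verbatim core", {
  gen <- generate_corpus(clean_config(seed = 13L, n_docs = 15L))
  prep <- prepare_corpus(gen$corpus, lex_ann)
  ps <- learn_patterns(prep, "Gene_expression", annotator = lex_ann)
  preds <- predict_corpus(ps, prep, model_strict, annotator = lex_ann)
  rpt <- evaluate(preds, prep, etype = "Gene_expression")
  expect_equal(rpt$fn, 0L)
  # empty pattern set: no predictions
  empty <- suppressWarnings(learn_patterns(list(), "Gene_expression",
                                           annotator = lex_ann))
  expect_length(predict_corpus(empty, prep, model_strict,
                               annotator = lex_ann), 0L)
})

test_that("substitution models round-trip through YAML", {
  m <- substitution_model(weights = c(token = 2, stem = 1, pos = 1),
                          gap_penalty = -0.7, threshold = 0.9,
                          overrides = list(token = c("a b" = 0.25)))
  path <- file.path(withr::local_tempdir(), "model.yaml")
  write_substitution_model(m, path)
  back <- read_substitution_model(path)
  expect_equal(back$weights, c(token = 0.5, stem = 0.25, pos = 0.25))
  expect_equal(back$gap_penalty, -0.7)
  expect_equal(back$threshold, 0.9)
  expect_equal(back$overrides$token, c("a b" = 0.25))
  expect_error(substitution_model(gap_penalty = 0.1))
})
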