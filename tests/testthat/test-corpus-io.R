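test_that("read_standoff parses entity and event lines", {
  doc <- read_standoff("CD19 protein is expressed",
                       "T1\tProtein 0 4\tCD19", "", "d1")
  expect_s3_class(doc, "standoff_document")
  expect_equal(nrow(doc$entities), 1L)
  expect_equal(nrow(doc$events), 0L)

  doc2 <- tiny_doc()
  expect_equal(nrow(doc2$events), 1L)
  expect_equal(doc2$events$trigger_start, 16L)
  expect_equal(doc2$events$trigger_end, 25L)
  expect_equal(doc2$events$theme_id, "T1")
})

test_that("read_standoff enforces span/surface integrity and line grammar", {
  expect_error(
    read_standoff("CD19 protein is expressed", "T1\tProtein 0 4\tCD20",
                  "", "d1"),
    "integrity")
  expect_error(
    read_standoff("CD19", "T1\tProtein 0", "", "d1"),
    "line 1")
  expect_warning(
    read_standoff("CD19 protein is expressed", "T1\tProtein 0 4\tCD19",
                  paste("T2\tBinding 16 25\texpressed",
                        "E1\tBinding:T2 Theme:T1", sep = "\n"), "d1"),
    "unregistered")
})

test_that("write_a2 round-trips through read_standoff", {
  doc <- tiny_doc()
  preds <- data.frame(etype = "Gene_expression", trigger_start = 16L,
                      trigger_end = 25L, theme_id = "T1",
                      stringsAsFactors = FALSE)
  a2 <- write_a2(doc, preds)
  expect_equal(length(strsplit(a2, "\n")[[1]]), 2L)
  back <- read_standoff(doc$text,
                        "T1\tProtein 0 4\tCD19", a2, "d1")
  expect_equal(back$events$etype, doc$events$etype)
  expect_equal(back$events$trigger_start, doc$events$trigger_start)
  expect_equal(back$events$trigger_end, doc$events$trigger_end)
  expect_equal(back$events$theme_id, doc$events$theme_id)
  expect_equal(write_a2(doc, preds[0, ]), "")
  expect_error(write_a2(doc, transform(preds, theme_id = "T9")),
               "integrity")
})

test_that("annotated sentences carry aligned token/stem/POS lanes", {
  sents <- annotate_sentences(tiny_doc(), lex_ann)
  expect_length(sents, 1L)
  toks <- sents[[1]]$tokens
  expect_equal(toks$surface, c("CD19", "protein", "is", "expressed"))
  expect_equal(toks$stem, c("cd19", "protein", "be", "express"))
  expect_equal(toks$pos, c("NN", "NN", "VBZ", "VBN"))
  expect_equal(sents[[1]]$entity_id, c("T1", NA, NA, NA))
  expect_equal(sents[[1]]$events$trigger_first, 4L)
  # token spans slice the document text exactly
  expect_equal(substring(tiny_doc()$text, toks$start + 1, toks$end),
               toks$surface)
})

test_that("events attach only to their own sentence; empty text is empty", {
  txt <- "TNF is expressed. CD19 was degraded."
  a1 <- "T1\tProtein 0 3\tTNF\nT2\tProtein 18 22\tCD19"
  a2 <- paste("T3\tGene_expression 7 16\texpressed",
              "E1\tGene_expression:T3 Theme:T1", sep = "\n")
  sents <- annotate_sentences(read_standoff(txt, a1, a2, "d2"), lex_ann)
  expect_length(sents, 2L)
  expect_equal(nrow(sents[[1]]$events), 1L)
  expect_equal(nrow(sents[[2]]$events), 0L)
  expect_length(
    annotate_sentences(read_standoff("", "", "", "empty"), lex_ann), 0L)
})

test_that("cross-sentence events are dropped with a message, not an error", {
  txt <- "TNF is expressed. CD19 was degraded."
  a1 <- "T1\tProtein 0 3\tTNF\nT2\tProtein 18 22\tCD19"
  # trigger in sentence 1, theme in sentence 2
  a2 <- paste("T3\tGene_expression 7 16\texpressed",
              "E1\tGene_expression:T3 Theme:T2", sep = "\n")
  expect_message(
    sents <- annotate_sentences(read_standoff(txt, a1, a2, "d3"), lex_ann),
    "dropped 1")
  expect_equal(sum(vapply(sents, function(s) nrow(s$events), 0L)), 0L)
})

test_that("mask_entities collapses mentions and is idempotent", {
  # multi-token mention: entity covering "CD19 protein"
  txt <- "CD19 protein is expressed"
  doc <- read_standoff(txt, "T1\tProtein 0 12\tCD19 protein", "", "d4")
  ms <- mask_entities(annotate_sentences(doc, lex_ann)[[1]])
  expect_equal(ms$tokens$surface, c("PTN", "is", "expressed"))
  expect_equal(ms$tokens$stem[1], "PTN")
  expect_equal(ms$tokens$pos[1], "PTN")
  expect_equal(ms$tokens$start[1], 0L)
  expect_equal(ms$tokens$end[1], 12L)
  expect_equal(ms$entity_id[1], "T1")
  expect_equal(ms$index_map, c(1L, 1L, 2L, 3L))
  # idempotence
  ms2 <- mask_entities(ms)
  expect_equal(ms2$tokens, ms$tokens)
  expect_equal(ms2$entity_id, ms$entity_id)
  # no entities: identity on tokens
  doc2 <- read_standoff("is expressed", "", "", "d5")
  s2 <- annotate_sentences(doc2, lex_ann)[[1]]
  expect_equal(mask_entities(s2)$tokens, s2$tokens)
})

test_that("corpus directories round-trip", {
  gen <- generate_corpus(clean_config(seed = 3L, n_docs = 4L))
  dir <- withr::local_tempdir()
  write_corpus_dir(gen$corpus, dir)
  back <- read_corpus_dir(dir)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$text, gen$corpus[[i]]$text)
    expect_equal(back[[i]]$entities, gen$corpus[[i]]$entities)
    expect_equal(back[[i]]$events, gen$corpus[[i]]$events)
  }
})
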