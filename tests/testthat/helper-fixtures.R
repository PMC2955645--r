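# Shared fixtures: all corpora are generated in code; nothing is read
# from disk.

tiny_doc <- function() {
  read_standoff(
    "CD19 protein is expressed",
    "T1\tProtein 0 4\tCD19",
    paste("T2\tGene_expression 16 25\texpressed",
          "E1\tGene_expression:T2 Theme:T1", sep = "\n"),
    doc_id = "d1")
}

lex_ann <- lexicon_annotator()

# All trigger occurrences are true events: learning at threshold 1
# must reconstruct the gold annotation exactly.
clean_config <- function(seed, n_docs = 50L) {
  synthetic_config(
    seed = seed, n_docs = n_docs,
    trigger_vocab = data.frame(
      word = c("expressed", "expression", "produced"),
      hit_rate = c(1, 1, 1), weight = c(5, 5, 3),
      stringsAsFactors = FALSE),
    distractor_rate = 0.3, noise_rate = 0)
}

# Planted ambiguity: three always-event triggers, one 1:1 ambiguous
# trigger ("overexpression", hit rate 0.5) and one mostly-distractor
# trigger ("induced", hit rate 0.1) that floods the corpus with
# non-event contexts matching its patterns verbatim.
ambig_config <- function(seed, n_docs = 50L, noise_rate = 0) {
  synthetic_config(
    seed = seed, n_docs = n_docs,
    trigger_vocab = data.frame(
      word = c("expressed", "expression", "produced", "overexpression",
               "induced"),
      hit_rate = c(1, 1, 1, 0.5, 0.1), weight = c(6, 6, 3, 1, 7),
      stringsAsFactors = FALSE),
    distractor_rate = 0.35, noise_rate = noise_rate)
}

# Exhaustive enumeration over all monotone alignments of the pattern
# into the sentence: each pattern position either aligns to a sentence
# token (strictly increasing) or to a gap; sentence tokens skipped
# between the first and last aligned token pay the gap penalty, tokens
# outside the aligned region are free. Independent of the DP.
brute_align_score <- function(S, gap) {
  m <- nrow(S)
  n <- ncol(S)
  best <- -Inf
  rec <- function(i, lastcol, score, nmatched) {
    if (i > m) {
      best <<- max(best, score)
      return(invisible())
    }
    rec(i + 1L, lastcol, score + gap, nmatched)
    if (lastcol < n) {
      for (j in (lastcol + 1L):n) {
        skipped <- if (nmatched == 0L) 0L else j - lastcol - 1L
        rec(i + 1L, j, score + S[i, j] + skipped * gap, nmatched + 1L)
      }
    }
  }
  rec(1L, 0L, 0, 0L)
  best
}

random_pattern <- function(len, alphabet, etype = "Gene_expression") {
  structure(list(
    pattern_id = "RND", etype = etype, length = len,
    token_lane = sample(alphabet, len, replace = TRUE),
    stem_lane = sample(alphabet, len, replace = TRUE),
    pos_lane = sample(alphabet, len, replace = TRUE),
    trigger_pos = 1L, trigger_positions = 1L, theme_pos = 1L,
    provenance = list(doc_id = NA, sent_index = NA)),
    class = "event_pattern")
}

random_sentence <- function(len, alphabet) {
  structure(list(
    doc_id = "rnd", sent_start = 0L, sent_end = 2L * len,
    tokens = data.frame(
      surface = sample(alphabet, len, replace = TRUE),
      stem = sample(alphabet, len, replace = TRUE),
      pos = sample(alphabet, len, replace = TRUE),
      start = 2L * seq_len(len) - 2L, end = 2L * seq_len(len) - 1L,
      stringsAsFactors = FALSE),
    entity_id = rep(NA_character_, len),
    events = data.frame(), masked = TRUE),
    class = "annotated_sentence")
}

# flatten per-document prediction lists into one comparable data.frame
flatten_preds <- function(preds) {
  if (!length(preds)) {
    return(data.frame(doc_id = character(), etype = character(),
                      trigger_start = integer(), trigger_end = integer(),
                      theme_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(names(preds), function(d) {
    cbind(doc_id = d,
          preds[[d]][, c("etype", "trigger_start", "trigger_end",
                         "theme_id")])
  }))
  out[order(out$doc_id, out$trigger_start, out$theme_id), , drop = FALSE]
}

pred_keys <- function(preds) {
  df <- flatten_preds(preds)
  paste(df$doc_id, df$etype, df$trigger_start, df$trigger_end, df$theme_id)
}
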