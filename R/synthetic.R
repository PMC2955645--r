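#' Synthetic standoff corpora with known ground truth
#'
#' Generates abstracts in the standoff format (.txt/.a1/.a2 semantics)
#' from sentence templates with PROTEIN and TRIGGER slots, a closed
#' vocabulary with fixed stems and POS tags, per-trigger planted hit
#' rates, and distractor sentences. Every planted event is recorded in a
#' manifest, so learning, matching, filtering and evaluation can all be
#' checked against exact ground truth without any external corpus.
#'
#' @name synthetic_fixtures
NULL

#' Closed lexicon for synthetic vocabulary
#'
#' @return data.frame `word`, `stem`, `pos`. Words sharing a stem (e.g.
#'   "expressed"/"expressing") form the inflection groups used by the
#'   lexical-noise option.
#' @export
synthetic_lexicon <- function() {
  d <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(word = m[, 1], stem = m[, 2], pos = m[, 3],
               stringsAsFactors = FALSE)
  }
  d(
    "the", "the", "DT",        "a", "a", "DT",
    "of", "of", "IN",          "in", "in", "IN",
    "by", "by", "IN",          "after", "after", "IN",
    "is", "be", "VBZ",         "was", "be", "VBD",
    "were", "be", "VBD",       "and", "and", "CC",
    "not", "not", "RB",        "strongly", "strong", "RB",
    "protein", "protein", "NN", "cells", "cell", "NNS",
    "human", "human", "JJ",    "levels", "level", "NNS",
    "high", "high", "JJ",      "treatment", "treatment", "NN",
    ".", ".", ".",
    # gene-expression trigger family
    "expressed", "express", "VBN",   "expressing", "express", "VBG",
    "expresses", "express", "VBZ",   "express", "express", "VB",
    "expression", "express", "NN",
    "produced", "produc", "VBN",     "production", "produc", "NN",
    "synthesized", "synthes", "VBN", "overexpression", "overexpress", "NN",
    "induces", "induc", "VBZ",       "induced", "induc", "VBN",
    "modulates", "modul", "VBZ",     "modulated", "modul", "VBN",
    # other event families
    "transcribed", "transcrib", "VBN", "transcription", "transcrib", "NN",
    "degraded", "degrad", "VBN",       "degradation", "degrad", "NN",
    "phosphorylated", "phosphoryl", "VBN",
    "phosphorylation", "phosphoryl", "NN",
    # distractor content words
    "cultured", "cultur", "VBN",   "overnight", "overnight", "RB",
    "samples", "sampl", "NNS",     "measured", "measur", "VBN",
    "detected", "detect", "VBN",   "results", "result", "NNS",
    "analysis", "analys", "NN",    "patients", "patient", "NNS",
    "clinical", "clinic", "JJ",    "study", "study", "NN",
    "significant", "signific", "JJ", "data", "data", "NNS",
    "observed", "observ", "VBN")
}

#' Default synthetic protein vocabulary
#' @export
synthetic_proteins <- function() {
  c("CD19", "STAT3", "IL2", "TNF", "FOXP3", "GATA1", "NFKB1", "TP53",
    "MYC", "JAK2")
}

#' Default sentence templates
#'
#' Skeletons are space-separated token strings with `PROTEIN` and
#' `TRIGGER` slots. `etype = NA` marks distractor templates (no event;
#' their sentences may still contain proteins). For event templates the
#' first `PROTEIN` slot is the Theme.
#'
#' @return data.frame `template_id`, `etype`, `skeleton`.
#' @export
synthetic_templates <- function() {
  data.frame(
    template_id = c("ev1", "ev2", "ev3", "ev4", "dis1", "dis2", "dis3"),
    etype = c(rep("Gene_expression", 4), NA, NA, NA),
    skeleton = c(
      "PROTEIN protein is TRIGGER in human cells .",
      "the TRIGGER of PROTEIN was detected .",
      "high levels of PROTEIN TRIGGER were observed after treatment .",
      "PROTEIN is strongly TRIGGER by PROTEIN .",
      "the samples were cultured overnight .",
      "clinical data of patients were measured .",
      "the study of PROTEIN samples was significant ."),
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' The defaults emulate the published training-corpus shape: 800
#' abstracts of roughly 9 sentences, one dominant event type, trigger
#' words whose hit rates span the 0.3-0.7 range observed in real
#' trigger-word error analyses, and a share of distractor sentences.
#'
#' @param seed integer RNG seed; generation is byte-identical for a
#'   fixed seed.
#' @param n_docs number of abstracts.
#' @param sentences_per_doc integer range `c(min, max)`.
#' @param templates template table (see [synthetic_templates()]).
#' @param trigger_vocab data.frame `word`, `hit_rate`, `weight`: each
#'   trigger occurrence is annotated as a true event with probability
#'   `hit_rate`; `weight` sets the relative frequency of the trigger.
#' @param protein_vocab character vector of protein names.
#' @param distractor_rate probability that a sentence is a distractor
#'   (drawn from the `etype = NA` templates, never annotated).
#' @param noise_rate per-token probability of swapping a word for an
#'   inflection variant sharing its stem (surface noise that preserves
#'   the stem lane).
#' @return object of class `generator_config`.
#' @export
synthetic_config <- function(seed = 1L, n_docs = 800L,
                             sentences_per_doc = c(6L, 12L),
                             templates = synthetic_templates(),
                             trigger_vocab = data.frame(
                               word = c("expressed", "expression",
                                        "expressing", "produced",
                                        "production", "overexpression"),
                               hit_rate = c(0.6, 0.5, 0.6, 0.5, 0.5, 0.3),
                               weight = c(5, 8, 2, 3, 3, 2),
                               stringsAsFactors = FALSE),
                             protein_vocab = synthetic_proteins(),
                             distractor_rate = 0.4,
                             noise_rate = 0) {
  stopifnot(all(trigger_vocab$hit_rate >= 0 & trigger_vocab$hit_rate <= 1),
            all(trigger_vocab$weight > 0),
            distractor_rate >= 0, distractor_rate < 1,
            noise_rate >= 0, noise_rate <= 1,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1L,
            sentences_per_doc[1] <= sentences_per_doc[2])
  ev <- templates[!is.na(templates$etype), , drop = FALSE]
  stopifnot(nrow(ev) >= 1L)
  n_slots <- function(sk, slot) {
    lengths(regmatches(sk, gregexpr(paste0("\\b", slot, "\\b"), sk)))
  }
  stopifnot(all(n_slots(ev$skeleton, "PROTEIN") >= 1L),
            all(n_slots(ev$skeleton, "TRIGGER") == 1L))
  structure(list(seed = seed, n_docs = n_docs,
                 sentences_per_doc = sentences_per_doc,
                 templates = templates, trigger_vocab = trigger_vocab,
                 protein_vocab = protein_vocab,
                 distractor_rate = distractor_rate,
                 noise_rate = noise_rate),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator config: %d docs, %d-%d sentences/doc, ",
                     "%d templates, %d triggers, distractor rate %.2f, ",
                     "noise %.2f, seed %d>\n"),
              x$n_docs, x$sentences_per_doc[1], x$sentences_per_doc[2],
              nrow(x$templates), nrow(x$trigger_vocab),
              x$distractor_rate, x$noise_rate, x$seed))
  invisible(x)
}

noise_variants <- function(lexicon) {
  split(lexicon$word, lexicon$stem)
}

#' Generate a synthetic standoff corpus
#'
#' @param cfg a [synthetic_config()].
#' @return list with `corpus` (list of `standoff_document`, validated by
#'   round-tripping through [read_standoff()]) and `manifest`
#'   (data.frame, one row per sentence: `doc_id`, `sent_no`,
#'   `template_id`, `etype`, `trigger`, `is_event`, `theme`).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  lexicon <- synthetic_lexicon()
  variants <- noise_variants(lexicon)
  stem_of <- stats::setNames(lexicon$stem, lexicon$word)
  ev_templates <- cfg$templates[!is.na(cfg$templates$etype), , drop = FALSE]
  dis_templates <- cfg$templates[is.na(cfg$templates$etype), , drop = FALSE]

  with_local_seed(cfg$seed, {
    corpus <- vector("list", cfg$n_docs)
    manifest <- list()
    for (dn in seq_len(cfg$n_docs)) {
      doc_id <- sprintf("synth%04d", dn)
      n_sent <- sample(cfg$sentences_per_doc[1]:cfg$sentences_per_doc[2], 1L)
      text_parts <- character(n_sent)
      offset <- 0L
      ents <- list()
      evs <- list()
      for (sn in seq_len(n_sent)) {
        is_distractor <- nrow(dis_templates) > 0L &&
          stats::runif(1) < cfg$distractor_rate
        if (is_distractor) {
          tpl <- dis_templates[sample.int(nrow(dis_templates), 1L), ]
          trigger <- NA_character_
          is_event <- FALSE
        } else {
          tpl <- ev_templates[sample.int(nrow(ev_templates), 1L), ]
          ti <- sample.int(nrow(cfg$trigger_vocab), 1L,
                           prob = cfg$trigger_vocab$weight)
          trigger <- cfg$trigger_vocab$word[ti]
          is_event <- stats::runif(1) < cfg$trigger_vocab$hit_rate[ti]
        }
        toks <- strsplit(tpl$skeleton, " ", fixed = TRUE)[[1]]
        # lexical noise: swap non-slot words for same-stem variants
        if (cfg$noise_rate > 0) {
          for (i in seq_along(toks)) {
            w <- toks[i]
            if (w %in% c("PROTEIN", "TRIGGER")) next
            st <- unname(stem_of[w])
            if (is.na(st)) next
            alts <- setdiff(variants[[st]], w)
            if (length(alts) && stats::runif(1) < cfg$noise_rate) {
              toks[i] <- sample(alts, 1L)
            }
          }
        }
        prot_slots <- which(toks == "PROTEIN")
        prots <- sample(cfg$protein_vocab,
                        length(prot_slots),
                        replace = length(prot_slots) >
                          length(cfg$protein_vocab))
        toks[prot_slots] <- prots
        trig_slot <- which(toks == "TRIGGER")
        if (length(trig_slot)) toks[trig_slot] <- trigger
        # sentence-initial capitalization so segmentation is unambiguous
        substr(toks[1], 1, 1) <- toupper(substr(toks[1], 1, 1))

        starts <- offset + cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
        ends <- starts + nchar(toks)
        text_parts[sn] <- paste(toks, collapse = " ")
        for (j in seq_along(prot_slots)) {
          ents[[length(ents) + 1L]] <- list(
            etype = "Protein", start = starts[prot_slots[j]],
            end = ends[prot_slots[j]], surface = toks[prot_slots[j]])
        }
        theme_word <- NA_character_
        if (is_event && length(trig_slot) && length(prot_slots)) {
          theme_word <- toks[prot_slots[1]]
          evs[[length(evs) + 1L]] <- list(
            etype = tpl$etype, trig_start = starts[trig_slot],
            trig_end = ends[trig_slot], trig_surface = toks[trig_slot],
            theme_ent = length(ents) - length(prot_slots) + 1L)
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          doc_id = doc_id, sent_no = sn, template_id = tpl$template_id,
          etype = if (is_event) tpl$etype else NA_character_,
          trigger = trigger, is_event = is_event, theme = theme_word,
          stringsAsFactors = FALSE)
        offset <- ends[length(ends)] + 1L  # joining space
      }
      txt <- paste(text_parts, collapse = " ")
      a1 <- vapply(seq_along(ents), function(i) {
        e <- ents[[i]]
        sprintf("T%d\t%s %d %d\t%s", i, e$etype, e$start, e$end, e$surface)
      }, character(1))
      n_t <- length(ents)
      a2 <- character()
      if (length(evs)) {
        a2 <- c(
          vapply(seq_along(evs), function(i) {
            e <- evs[[i]]
            sprintf("T%d\t%s %d %d\t%s", n_t + i, e$etype, e$trig_start,
                    e$trig_end, e$trig_surface)
          }, character(1)),
          vapply(seq_along(evs), function(i) {
            e <- evs[[i]]
            sprintf("E%d\t%s:T%d Theme:T%d", i, e$etype, n_t + i,
                    e$theme_ent)
          }, character(1)))
      }
      corpus[[dn]] <- read_standoff(txt, paste(a1, collapse = "\n"),
                                    paste(a2, collapse = "\n"), doc_id)
    }
    list(corpus = corpus,
         manifest = if (length(manifest)) do.call(rbind, manifest)
         else data.frame())
  })
}

#' Summary statistics of a corpus
#'
#' @param corpus list of `standoff_document`.
#' @param annotator annotator used for sentence/token counting.
#' @return data.frame with one row: `docs`, `sentences`, `tokens`, and
#'   one `events_<type>` column per event type present.
#' @export
corpus_stats <- function(corpus, annotator = lexicon_annotator()) {
  n_sent <- 0L
  n_tok <- 0L
  for (doc in corpus) {
    segs <- annotator$segment(doc$text)
    n_sent <- n_sent + nrow(segs)
    n_tok <- n_tok + nrow(annotator$tokenize(doc$text))
  }
  out <- data.frame(docs = length(corpus), sentences = n_sent,
                    tokens = n_tok)
  types <- sort(unique(unlist(lapply(corpus, function(d) d$events$etype))))
  for (ty in types) {
    out[[paste0("events_", ty)]] <- sum(vapply(corpus, function(d) {
      sum(d$events$etype == ty)
    }, 0L))
  }
  out
}
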