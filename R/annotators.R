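#' Linguistic annotators
#'
#' An annotator bundles the four deterministic NLP steps the corpus reader
#' needs: sentence segmentation, tokenization, word stemming and
#' part-of-speech tagging. Two implementations ship with the package:
#' [default_annotator()] (regex tokenizer, Porter stemmer, lexicon+suffix
#' POS rules) for real text, and [lexicon_annotator()] which draws stems
#' and tags from a closed lexicon so that test expectations do not depend
#' on any particular tagger.
#'
#' @details
#' The contract is a list with class `"eventex_annotator"` and elements:
#' \describe{
#'   \item{`segment(text)`}{returns a data.frame with 0-based, half-open
#'     character intervals `start`, `end`, one row per sentence.}
#'   \item{`tokenize(text)`}{returns a data.frame `surface`, `start`,
#'     `end` (offsets relative to `text`), rows in reading order.}
#'   \item{`stem(words)`}{character vector of stems, one per word.}
#'   \item{`pos(words, stems)`}{character vector of Penn-Treebank-style
#'     tags, one per word.}
#' }
#' All four must be pure functions of their inputs.
#'
#' @name annotators
NULL

token_regex <- "[[:alnum:]]+(?:[-'/.][[:alnum:]]+)*|[^[:space:]]"

tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  g <- gregexpr(token_regex, text, perl = TRUE)
  m <- g[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = regmatches(text, g)[[1]],
             start = start, end = start + len, stringsAsFactors = FALSE)
}

segment_text <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer()))
  }
  # break after ., ! or ? followed by whitespace and an upper-case or
  # digit sentence opener; abbreviation handling is deliberately minimal
  breaks <- gregexpr("(?<=[.!?])[[:space:]]+(?=[A-Z0-9\"(])", text,
                     perl = TRUE)[[1]]
  if (breaks[1] == -1L) {
    starts <- 0L
    ends <- nchar(text)
  } else {
    gap_start <- as.integer(breaks) - 1L
    gap_end <- gap_start + attr(breaks, "match.length")
    starts <- c(0L, gap_end)
    ends <- c(gap_start, nchar(text))
  }
  # trim surrounding whitespace inside each sentence interval
  out <- mapply(function(s, e) {
    seg <- substr(text, s + 1L, e)
    lead <- regmatches(seg, regexpr("^[[:space:]]*", seg))
    trail <- regmatches(seg, regexpr("[[:space:]]*$", seg))
    c(s + nchar(lead), e - nchar(trail))
  }, starts, ends)
  keep <- out[2, ] > out[1, ]
  data.frame(start = as.integer(out[1, keep]), end = as.integer(out[2, keep]))
}

# ---- Porter stemmer --------------------------------------------------------

# Measure-based suffix stripping; operates on a single lower-case word.
porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

porter_measure <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!length(chars)) return(0L)
  types <- vapply(seq_along(chars), function(i) porter_is_cons(chars, i),
                  logical(1))
  # count VC sequences
  m <- 0L
  prev <- types[1]
  for (t in types[-1]) {
    if (prev && !t) {
      # vowel after consonant: nothing yet
    } else if (!prev && t) {
      m <- m + 1L
    }
    prev <- t
  }
  m
}

porter_has_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  any(!vapply(seq_along(chars), function(i) porter_is_cons(chars, i),
              logical(1)))
}

porter_ends_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  chars[n] == chars[n - 1L] && porter_is_cons(chars, n)
}

porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!porter_is_cons(chars, n) || porter_is_cons(chars, n - 1L) ||
      !porter_is_cons(chars, n - 2L)) {
    return(FALSE)
  }
  !(chars[n] %in% c("w", "x", "y"))
}

porter_stem_word <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)

  ends <- function(s) {
    nchar(w) > nchar(s) &&
      substring(w, nchar(w) - nchar(s) + 1L) == s
  }
  trunc_to <- function(s) substring(w, 1L, nchar(w) - nchar(s))

  # step 1a
  if (ends("sses")) w <- paste0(trunc_to("sses"), "ss")
  else if (ends("ies")) w <- paste0(trunc_to("ies"), "i")
  else if (ends("ss")) w <- w
  else if (ends("s")) w <- trunc_to("s")

  # step 1b
  step1b2 <- FALSE
  if (ends("eed")) {
    if (porter_measure(trunc_to("eed")) > 0L) w <- paste0(trunc_to("eed"), "ee")
  } else if (ends("ed")) {
    if (porter_has_vowel(trunc_to("ed"))) { w <- trunc_to("ed"); step1b2 <- TRUE }
  } else if (ends("ing")) {
    if (porter_has_vowel(trunc_to("ing"))) { w <- trunc_to("ing"); step1b2 <- TRUE }
  }
  if (step1b2) {
    if (ends("at") || ends("bl") || ends("iz")) {
      w <- paste0(w, "e")
    } else if (porter_ends_double_cons(w) &&
               !(substring(w, nchar(w)) %in% c("l", "s", "z"))) {
      w <- substring(w, 1L, nchar(w) - 1L)
    } else if (porter_measure(w) == 1L && porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (ends("y") && porter_has_vowel(trunc_to("y"))) {
    w <- paste0(trunc_to("y"), "i")
  }

  replace_if <- function(pairs, min_m) {
    for (k in seq_along(pairs)) {
      suf <- names(pairs)[k]
      if (ends(suf)) {
        stem <- trunc_to(suf)
        if (porter_measure(stem) > min_m) w <<- paste0(stem, pairs[[k]])
        return(TRUE)
      }
    }
    FALSE
  }

  # step 2 (m > 0)
  replace_if(c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
               izer = "ize", abli = "able", alli = "al", entli = "ent",
               eli = "e", ousli = "ous", ization = "ize", ation = "ate",
               ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
               ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble"),
             0L)
  # step 3 (m > 0)
  replace_if(c(icate = "ic", ative = "", alize = "al", iciti = "ic",
               ical = "ic", ful = "", ness = ""), 0L)
  # step 4 (m > 1)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ou", "ism", "ate", "iti", "ous",
             "ive", "ize")
  for (suf in step4) {
    if (ends(suf)) {
      stem <- trunc_to(suf)
      if (porter_measure(stem) > 1L) w <- stem
      break
    }
  }
  if (ends("ion")) {
    stem <- trunc_to("ion")
    if (porter_measure(stem) > 1L &&
        substring(stem, nchar(stem)) %in% c("s", "t")) {
      w <- stem
    }
  }

  # step 5a
  if (ends("e")) {
    stem <- trunc_to("e")
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }
  # step 5b
  if (porter_measure(w) > 1L && porter_ends_double_cons(w) &&
      substring(w, nchar(w)) == "l") {
    w <- substring(w, 1L, nchar(w) - 1L)
  }
  w
}

#' Porter word stems
#'
#' @param words character vector of words.
#' @return character vector of stems (lower-cased); tokens containing
#'   non-alphabetic characters are returned lower-cased but unstemmed.
#' @examples
#' porter_stem(c("expressed", "expression", "relational"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}

# ---- default POS tagger ----------------------------------------------------

default_pos_lexicon <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", these = "DT", that = "DT",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
  been = "VBN", being = "VBG", has = "VBZ", have = "VBP", had = "VBD",
  of = "IN", "in" = "IN", by = "IN", at = "IN", on = "IN", with = "IN",
  from = "IN", into = "IN", after = "IN", during = "IN",
  and = "CC", or = "CC", but = "CC", not = "RB", no = "DT",
  to = "TO", we = "PRP", it = "PRP", its = "PRP$", which = "WDT",
  cells = "NNS", cell = "NN", protein = "NN", proteins = "NNS",
  gene = "NN", genes = "NNS", levels = "NNS", level = "NN",
  "." = ".", "," = ",", ";" = ":", ":" = ":", "(" = "-LRB-", ")" = "-RRB-"
)

rule_pos_tag <- function(words, stems) {
  lower <- tolower(words)
  tags <- unname(default_pos_lexicon[lower])
  guess <- function(word) {
    if (grepl("^[^[:alnum:]]$", word)) return(word)
    if (grepl("^[0-9.,]+$", word)) return("CD")
    if (grepl("(ed|en)$", word)) return("VBN")
    if (grepl("ing$", word)) return("VBG")
    if (grepl("(ly)$", word)) return("RB")
    if (grepl("(able|ible|ous|ive|al|ic)$", word)) return("JJ")
    if (grepl("(ates|izes|esses|es)$", word)) return("VBZ")
    if (grepl("(tion|sion|ment|ness|ity|ism)s$", word)) return("NNS")
    if (grepl("(tion|sion|ment|ness|ity|ism|ase|or|er)$", word)) return("NN")
    if (grepl("s$", word) && !grepl("ss$", word)) return("NNS")
    if (grepl("^[A-Z0-9-]{2,}$", word)) return("NN")  # gene-symbol-like
    "NN"
  }
  miss <- is.na(tags)
  tags[miss] <- vapply(words[miss], guess, character(1), USE.NAMES = FALSE)
  tags
}

#' Default annotator: regex tokenizer, Porter stems, rule-based POS tags
#'
#' Suitable for real biomedical abstracts when no external tagger is
#' available; fully deterministic. See [annotators] for the contract.
#'
#' @return an object of class `eventex_annotator`.
#' @export
default_annotator <- function() {
  structure(list(
    name = "default",
    segment = segment_text,
    tokenize = tokenize_text,
    stem = porter_stem,
    pos = rule_pos_tag
  ), class = "eventex_annotator")
}

#' Closed-lexicon annotator
#'
#' Stems and POS tags are looked up in a fixed lexicon, so annotation is
#' independent of any stemming or tagging algorithm. Words missing from
#' the lexicon fall back to the lower-cased surface as stem and tag `"NN"`
#' (punctuation tags as itself). This is the annotator used with synthetic
#' corpora, whose vocabulary is closed by construction.
#'
#' @param lexicon data.frame with columns `word`, `stem`, `pos`.
#' @return an object of class `eventex_annotator`.
#' @seealso [synthetic_lexicon()]
#' @export
lexicon_annotator <- function(lexicon = synthetic_lexicon()) {
  stopifnot(is.data.frame(lexicon),
            all(c("word", "stem", "pos") %in% names(lexicon)))
  stems <- stats::setNames(lexicon$stem, tolower(lexicon$word))
  tags <- stats::setNames(lexicon$pos, tolower(lexicon$word))
  structure(list(
    name = "lexicon",
    segment = segment_text,
    tokenize = tokenize_text,
    stem = function(words) {
      out <- unname(stems[tolower(words)])
      out[is.na(out)] <- tolower(words[is.na(out)])
      out
    },
    pos = function(words, stems_in) {
      out <- unname(tags[tolower(words)])
      miss <- is.na(out)
      punct <- miss & grepl("^[^[:alnum:]]$", words)
      out[punct] <- words[punct]
      out[miss & !punct] <- "NN"
      out
    }
  ), class = "eventex_annotator")
}

#' @export
print.eventex_annotator <- function(x, ...) {
  cat(sprintf("<eventex annotator: %s>\n", x$name))
  invisible(x)
}
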