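# Domain-specific sentiment lexicons for intracranial hemorrhage narratives
# and the Estimated Association (EA) text statistic.

#' Default intracranial-hemorrhage sentiment lexicon
#'
#' Fixed positive / negative / neutral phrase sets used both by the note
#' generator (to plant sentiment-consistent language) and by
#' [lexicon_sentiment()]. Users may extend via [lexicon()] or JSON.
#'
#' @return A `lexicon` object (list of three disjoint lowercase phrase sets).
#' @export
default_lexicon <- function() {
  lexicon(
    positive = c("good outcome", "favorable outcome", "improved survival",
                 "recovery", "stable"),
    negative = c("coma", "large hematoma", "intraventricular hemorrhage",
                 "posterior fossa hemorrhage", "old age"),
    neutral = c("glasgow coma scale", "gcs", "ich score", "hematoma volume",
                "infratentorial", "supratentorial", "midline shift",
                "mass effect", "perihematomal edema"))
}

#' Construct a sentiment lexicon
#'
#' @param positive,negative,neutral Character vectors of lowercase phrases;
#'   the three sets must be pairwise disjoint.
#' @return A `lexicon` object.
#' @export
lexicon <- function(positive, negative, neutral) {
  positive <- tolower(positive); negative <- tolower(negative)
  neutral <- tolower(neutral)
  all <- c(positive, negative, neutral)
  if (any(all == "")) stop("lexicon phrases must be non-empty")
  if (anyDuplicated(all))
    stop("lexicon phrase sets must be pairwise disjoint")
  structure(list(positive = positive, negative = negative,
                 neutral = neutral), class = "lexicon")
}

#' Read a lexicon from JSON
#'
#' Expects keys `positive`, `negative`, `neutral`.
#' @param path Path to a JSON file.
#' @return A `lexicon`.
#' @export
read_lexicon <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lexicon(x$positive, x$negative, x$neutral)
}

#' Count lexicon phrase hits and derive a polarity
#'
#' Case-insensitive, longest-phrase-first, non-overlapping matching (so
#' "glasgow coma scale" consumes its span before "coma" can fire inside
#' it). Polarity: positive if positive hits outnumber negative ones,
#' negative for the converse, neutral on a tie with at least one neutral
#' hit, uncertain otherwise.
#'
#' @param text Character scalar.
#' @param lex A `lexicon` (default [default_lexicon()]).
#' @return List `pos_count`, `neg_count`, `neutral_count`, `polarity`.
#' @export
lexicon_sentiment <- function(text, lex = default_lexicon()) {
  stopifnot(inherits(lex, "lexicon"))
  low <- tolower(paste(text, collapse = " "))
  taken <- rep(FALSE, nchar(low))
  phrases <- data.frame(
    phrase = c(lex$positive, lex$negative, lex$neutral),
    class = rep(c("pos", "neg", "neu"),
                c(length(lex$positive), length(lex$negative),
                  length(lex$neutral))),
    stringsAsFactors = FALSE)
  phrases <- phrases[order(-nchar(phrases$phrase)), ]
  counts <- c(pos = 0L, neg = 0L, neu = 0L)
  for (i in seq_len(nrow(phrases))) {
    p <- phrases$phrase[i]
    m <- gregexpr(p, low, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (j in seq_along(m)) {
      span <- m[j]:(m[j] + nchar(p) - 1L)
      if (!any(taken[span])) {
        taken[span] <- TRUE
        counts[phrases$class[i]] <- counts[phrases$class[i]] + 1L
      }
    }
  }
  polarity <- if (counts["pos"] > counts["neg"]) "positive"
    else if (counts["neg"] > counts["pos"]) "negative"
    else if (counts["neu"] > 0L) "neutral"
    else "uncertain"
  list(pos_count = unname(counts["pos"]), neg_count = unname(counts["neg"]),
       neutral_count = unname(counts["neu"]), polarity = polarity)
}

#' Estimated Association (EA) of a narrative
#'
#' `EA = 100 * (number of complex words) / (total number of words)` under
#' whitespace tokenization, case-insensitive. By convention the default
#' complex-word set is the union of the constituent words of the negative
#' and neutral lexicon phrases.
#'
#' @param text Character scalar (non-empty).
#' @param complex_word_set Character vector of lowercase words counted as
#'   complex.
#' @return Percentage in `[0, 100]`.
#' @export
estimated_association <- function(text,
                                  complex_word_set = default_complex_words()) {
  words <- strsplit(tolower(paste(text, collapse = " ")), "\\s+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("estimated_association: empty text")
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
  100 * sum(words %in% tolower(complex_word_set)) / length(words)
}

#' Default complex-word set for the EA statistic
#' @return Character vector of words.
#' @export
default_complex_words <- function() {
  lex <- default_lexicon()
  unique(unlist(strsplit(c(lex$negative, lex$neutral), "\\s+")))
}
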