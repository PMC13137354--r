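# WordPiece tokenization and token+segment+position embedding: a weightless,
# seeded stand-in for a biomedical BERT front end. The embedding tables are
# random but deterministic, so downstream classifiers see a fixed feature
# map.

#' Construct a WordPiece vocabulary
#'
#' Continuation pieces carry the `##` prefix; the special tokens `[CLS]`,
#' `[SEP]` and `[UNK]` are always present.
#'
#' @param pieces Character vector of word pieces.
#' @return A `wp_vocab` object.
#' @export
wp_vocab <- function(pieces) {
  pieces <- unique(as.character(pieces))
  if (any(!nzchar(pieces))) stop("vocabulary pieces must be non-empty")
  specials <- c("[CLS]", "[SEP]", "[UNK]")
  structure(list(pieces = union(specials, pieces),
                 starts = setdiff(pieces[!startsWith(pieces, "##")],
                                  specials),
                 conts = sub("^##", "", pieces[startsWith(pieces, "##")])),
            class = "wp_vocab")
}

#' Read a vocabulary from a newline-delimited text file
#' @param path One piece per line, UTF-8.
#' @return A `wp_vocab`.
#' @export
read_wp_vocab <- function(path) wp_vocab(readLines(path, encoding = "UTF-8"))

#' Write a vocabulary to a newline-delimited text file
#' @param vocab A `wp_vocab`.
#' @param path Output path.
#' @export
write_wp_vocab <- function(vocab, path)
  writeLines(vocab$pieces, path, useBytes = TRUE)

# Greedy longest-prefix segmentation of one lowercase word. Returns
# character(0) when the word cannot be segmented.
.wp_word <- function(word, vocab) {
  out <- character(0)
  pos <- 1L; n <- nchar(word)
  while (pos <= n) {
    found <- ""
    for (len in seq(n - pos + 1L, 1L)) {
      cand <- substr(word, pos, pos + len - 1L)
      pool <- if (pos == 1L) vocab$starts else vocab$conts
      if (cand %in% pool) { found <- cand; break }
    }
    if (!nzchar(found)) return(character(0))
    out <- c(out, if (pos == 1L) found else paste0("##", found))
    pos <- pos + nchar(found)
  }
  out
}

#' WordPiece tokenization
#'
#' Lowercases, splits on whitespace, strips surrounding punctuation, and
#' segments each word greedily by longest prefix with `##` continuation
#' pieces; a word that cannot be fully segmented emits a single `[UNK]`.
#'
#' @param text Character scalar.
#' @param vocab A [wp_vocab()].
#' @return Character vector of tokens.
#' @export
wordpiece_tokenize <- function(text, vocab) {
  stopifnot(inherits(vocab, "wp_vocab"))
  words <- strsplit(tolower(paste(text, collapse = " ")), "\\s+")[[1]]
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
  words <- words[nzchar(words)]
  if (length(words) == 0L) return(character(0))
  unlist(lapply(words, function(w) {
    seg <- .wp_word(w, vocab)
    if (length(seg) == 0L) "[UNK]" else seg
  }), use.names = FALSE)
}

#' Seeded token/segment/position embedding tables
#'
#' @param vocab A [wp_vocab()].
#' @param embed_dim Embedding dimension D.
#' @param max_len Maximum sequence length (default 512).
#' @param seed Integer seed; tables are Gaussian (sd 0.02), deterministic.
#' @return A `text_tables` object with `token_table` (|V| x D, rownames are
#'   pieces), `segment_table` (2 x D) and `position_table` (max_len x D).
#' @export
make_text_tables <- function(vocab, embed_dim = 32L, max_len = 512L,
                             seed = 0L) {
  V <- length(vocab$pieces)
  tabs <- with_seed(substream_seed(seed, "text-tables"), {
    list(token = matrix(stats::rnorm(V * embed_dim, 0, 0.02), V, embed_dim,
                        dimnames = list(vocab$pieces, NULL)),
         segment = matrix(stats::rnorm(2 * embed_dim, 0, 0.02), 2, embed_dim),
         position = matrix(stats::rnorm(max_len * embed_dim, 0, 0.02),
                           max_len, embed_dim))
  })
  structure(list(token_table = tabs$token, segment_table = tabs$segment,
                 position_table = tabs$position, max_len = as.integer(max_len),
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
            class = "text_tables")
}

#' Embed a token sequence
#'
#' Vector *i* is `token_table[tok_i] + segment_table[seg_i] +
#' position_table[i]`. Sequences longer than `max_len` are truncated with a
#' warning; single-segment inputs use segment id 0 throughout.
#'
#' @param tokens Character vector of pieces present in the tables.
#' @param segment_ids Integer vector in `{0, 1}` (recycled).
#' @param tables A [make_text_tables()] object.
#' @return Numeric matrix, one row per token.
#' @export
embed_tokens <- function(tokens, segment_ids = 0L, tables) {
  stopifnot(inherits(tables, "text_tables"))
  if (length(tokens) > tables$max_len) {
    warning(sprintf("sequence truncated from %d to max_len=%d tokens",
                    length(tokens), tables$max_len), call. = FALSE)
    tokens <- tokens[seq_len(tables$max_len)]
  }
  segment_ids <- rep_len(as.integer(segment_ids), length(tokens))
  if (any(!segment_ids %in% c(0L, 1L)))
    stop("segment ids must be 0 or 1")
  miss <- setdiff(tokens, rownames(tables$token_table))
  if (length(miss))
    stop("token(s) absent from table: ", paste(miss, collapse = ", "))
  tables$token_table[tokens, , drop = FALSE] +
    tables$segment_table[segment_ids + 1L, , drop = FALSE] +
    tables$position_table[seq_along(tokens), , drop = FALSE]
}

#' Default WordPiece vocabulary
#'
#' Built programmatically from the note templates, the sentiment lexicons
#' and generic fallback pieces (single letters and digits plus common
#' suffixes), so synthetic narratives tokenize with almost no `[UNK]`.
#'
#' @return A `wp_vocab`.
#' @export
default_wp_vocab <- function() {
  words <- unique(c(.note_template_words(),
                    unlist(strsplit(unlist(default_lexicon()), "\\s+"))))
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tolower(words))
  words <- unique(words[nzchar(words)])
  fallback <- c(letters, 0:9, paste0("##", c(letters, 0:9)),
                paste0("##", c("s", "ing", "ed", "toma", "al", "ion")))
  wp_vocab(c(words, fallback))
}
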