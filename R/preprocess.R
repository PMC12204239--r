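# Text -> token stream. Tokens are lowercase, split on anything that is
# not a letter, digit or apostrophe; URLs, emojis and digit-only tokens
# cannot match any lexicon pattern and are dropped.

.tokenize_one <- function(text) {
  text <- tolower(text)
  text <- gsub("(https?://|www\\.)[^[:space:]]+", " ", text)
  toks <- strsplit(text, "[^a-z0-9']+")[[1L]]
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nzchar(toks)]
  toks[grepl("[a-z]", toks)]
}

#' Tokenize one message text
#'
#' Lowercases the text and splits it into word tokens on any character
#' that is not a letter, digit or apostrophe, so contractions ("don't")
#' survive as single tokens. URLs, tokens without any letter (digit
#' strings) and non-alphabetic symbols (emojis, punctuation) are dropped.
#'
#' @param text a single character string; may be empty.
#' @return character vector of lowercase raw (unstemmed) tokens.
#' @examples
#' tokenize("I feel SO bad.")
#' tokenize("can't stop—hurting")
#' @export
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop("`text` must be a single character string")
  }
  if (is.na(text) || !nzchar(text)) return(character(0L))
  .tokenize_one(text)
}

#' Build the token stream for a conversation segment
#'
#' Tokenizes and Porter-stems each message, then concatenates the stemmed
#' unigrams. Bigrams (adjacent stemmed pairs joined by a single space) are
#' formed strictly within a message, never across message boundaries: a
#' phrase split over two chat messages is not adjacent in the speaker's
#' utterance.
#'
#' @param texts character vector of message texts, in conversation order.
#' @return an object of class `token_stream`: a list with `unigrams`
#'   (stemmed tokens), `bigrams` (space-joined stemmed pairs),
#'   `bigram_pos` (index of the first unigram of each bigram) and
#'   `n_unigrams`.
#' @examples
#' build_stream(c("I want to harm myself", "please help"))
#' @export
build_stream <- function(texts) {
  if (!is.character(texts)) stop("`texts` must be a character vector")
  toks <- lapply(texts, .tokenize_one)
  lens <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (is.null(flat)) flat <- character(0L)
  stems <- porter_stem(flat)
  big <- character(0L)
  pos <- integer(0L)
  off <- 0L
  for (i in seq_along(lens)) {
    L <- lens[i]
    if (L >= 2L) {
      s <- stems[(off + 1L):(off + L)]
      big <- c(big, paste(s[-L], s[-1L]))
      pos <- c(pos, off + seq_len(L - 1L))
    }
    off <- off + L
  }
  structure(list(unigrams = stems, bigrams = big, bigram_pos = pos,
                 n_unigrams = length(stems)),
            class = "token_stream")
}

#' @export
print.token_stream <- function(x, ...) {
  cat("<token_stream> ", x$n_unigrams, " unigrams, ",
      length(x$bigrams), " bigrams\n", sep = "")
  invisible(x)
}
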