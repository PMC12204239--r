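# Shared fixtures and independent oracles, all built in code.

# small message data frame -> chat_corpus
mini_corpus <- function(...) {
  convs <- list(...)
  rows <- lapply(seq_along(convs), function(i) {
    cv <- convs[[i]]
    data.frame(conversation_id = names(convs)[i],
               index = seq_along(cv$role) - 1L,
               role = cv$role,
               timestamp = NA_character_,
               text = cv$text,
               stringsAsFactors = FALSE)
  })
  chat_corpus(do.call(rbind, rows), provenance = "test fixture")
}

# a conversation of n help-seeker messages with given texts (recycled),
# optionally interleaved with supporter filler
hs_conv <- function(texts, supporter_every = 0L) {
  n <- length(texts)
  role <- rep("help_seeker", n)
  if (supporter_every > 0L) {
    out_role <- character(0L)
    out_text <- character(0L)
    for (i in seq_len(n)) {
      out_role <- c(out_role, "help_seeker")
      out_text <- c(out_text, texts[i])
      if (i %% supporter_every == 0L) {
        out_role <- c(out_role, "supporter")
        out_text <- c(out_text, "acknowledged")
      }
    }
    role <- out_role
    texts <- out_text
  }
  list(role = role, text = texts)
}

# naive brute-force occurrence count: scans every (pattern, token/bigram)
# pair with explicit loops; bigram matches consume their two tokens first
brute_count <- function(stream, category) {
  pat <- category$patterns
  consumed <- rep(FALSE, stream$n_unigrams)
  total <- 0L
  for (j in seq_along(stream$bigrams)) {
    is_big <- FALSE
    for (k in seq_len(nrow(pat))) {
      if (pat$kind[k] == "bigram" && pat$key[k] == stream$bigrams[j]) {
        is_big <- TRUE
      }
    }
    if (is_big) {
      p <- stream$bigram_pos[j]
      if (!consumed[p] && !consumed[p + 1L]) {
        consumed[p] <- consumed[p + 1L] <- TRUE
        total <- total + 1L
      }
    }
  }
  for (i in seq_len(stream$n_unigrams)) {
    if (consumed[i]) next
    for (k in seq_len(nrow(pat))) {
      if (pat$kind[k] == "exact_stem" &&
          stream$unigrams[i] == pat$key[k]) {
        total <- total + 1L
      } else if (pat$kind[k] == "prefix_wildcard" &&
                 startsWith(stream$unigrams[i], pat$key[k])) {
        total <- total + 1L
      }
    }
  }
  total
}

# random token stream over a vocabulary that overlaps the test lexicon
rand_stream <- function(n_msgs, vocab, rng_max = 8L) {
  texts <- vapply(seq_len(n_msgs), function(i) {
    paste(sample(vocab, sample.int(rng_max, 1L), replace = TRUE),
          collapse = " ")
  }, character(1L))
  build_stream(texts)
}

test_category <- function() {
  lex_category("suicidality_mini",
               c("suicid*", "harm*", "harm myself", "hurt", "die"),
               kind = "contextual")
}

test_vocab <- c("i", "want", "to", "harm", "myself", "hurt", "hurting",
                "die", "died", "suicide", "suicidal", "stop", "feel",
                "ok", "tomorrow", "harms", "harmed", "self")

# construct a score_table directly (for stats-level tests)
fake_score_table <- function(counts_by_cat, phase_values = NULL,
                             kinds = NULL) {
  cats <- names(counts_by_cat)
  n <- length(counts_by_cat[[1L]])
  ids <- sprintf("c%03d", seq_len(n))
  rows <- list()
  for (cc in cats) {
    rows[[length(rows) + 1L]] <- data.frame(
      conversation_id = ids, segment_kind = "whole",
      segment_label = "whole", category = cc,
      count = counts_by_cat[[cc]], n_unigrams = 100L,
      degree = counts_by_cat[[cc]] / 100,
      stringsAsFactors = FALSE)
    if (!is.null(phase_values)) {
      pv <- phase_values[[cc]]   # n x 3 matrix
      for (j in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          conversation_id = ids, segment_kind = "phase",
          segment_label = c("beginning", "middle", "end")[j],
          category = cc, count = round(pv[, j]), n_unigrams = 100L,
          degree = pv[, j] / 100, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(kinds)) kinds <- stats::setNames(rep("contextual",
                                                   length(cats)), cats)
  structure(tab, categories = cats, category_kinds = kinds,
            n_conversations = n,
            term_counts = data.frame(category = character(0L),
                                     key = character(0L),
                                     count = integer(0L)),
            class = c("score_table", "data.frame"))
}

# single-category lexicons with invented vocabulary disjoint from the
# generator's filler pseudo-words, for null / recovery simulations
disjoint_lexicon <- function(flat = TRUE, declining = TRUE) {
  out <- list()
  if (flat) {
    out$steady <- lex_category("steady",
                               c("zorple", "mirtak", "veldin"),
                               kind = "contextual")
  }
  if (declining) {
    out$fading <- lex_category("fading",
                               c("quobar", "lestrik*", "fandor"),
                               kind = "contextual")
  }
  out
}
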