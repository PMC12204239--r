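# Apply a lexicon to every conversation x segment of a corpus, producing
# the long-format score table that all downstream statistics consume.
#
# Matching here is vectorized over the whole corpus (flattened token
# vector, per-message tallies, prefix sums over message spans); it is
# equivalent to running count_occurrences() on each segment's stream,
# which the test suite verifies, because bigrams never cross message
# boundaries and all segments are message-aligned.

.score_grid_labels <- function(kind) {
  switch(kind,
         whole = "whole",
         phase = c("beginning", "middle", "end"),
         window = as.character(1:9))
}

#' Score a corpus against a lexicon
#'
#' For each conversation, builds the help-seeker token stream and computes,
#' per requested segment kind and category, the occurrence count, the
#' unigram total and the lexical degree score. Segment kinds are `whole`
#' (the full conversation), `phase` (equal thirds) and `window` (nine
#' overlapping 20%-width windows).
#'
#' @param corpus a `chat_corpus`, already filtered with
#'   [filter_eligible()] (phases need at least 3 and windows at least 10
#'   help-seeker messages per conversation).
#' @param lexicon named list of [lex_category()] objects.
#' @param segment_kinds subset of `c("whole", "phase", "window")`.
#' @return a `score_table` data frame with one row per (conversation,
#'   segment, category): columns `conversation_id`, `segment_kind`,
#'   `segment_label`, `category`, `count`, `n_unigrams`, `degree`
#'   (`NA` when the segment has no tokens). Attributes: `categories`,
#'   `category_kinds`, `n_conversations`, and `term_counts` (corpus-wide
#'   per-pattern-key totals feeding [top_terms()]).
#' @export
score_corpus <- function(corpus, lexicon,
                         segment_kinds = c("whole", "phase", "window")) {
  stopifnot(inherits(corpus, "chat_corpus"))
  segment_kinds <- match.arg(segment_kinds, several.ok = TRUE)
  if (!length(lexicon)) stop("empty lexicon")
  if (is.null(names(lexicon))) {
    names(lexicon) <- vapply(lexicon, `[[`, "", "name")
  }

  hs <- corpus[corpus$role == "help_seeker", , drop = FALSE]
  conv_ids <- unique(corpus$conversation_id)
  conv <- match(hs$conversation_id, conv_ids)
  n_conv <- length(conv_ids)
  if (!nrow(hs)) stop("corpus contains no help-seeker messages")

  # message ordinal within conversation (0-based, help-seeker only)
  ord <- order(conv, hs$index)
  hs <- hs[ord, , drop = FALSE]
  conv <- conv[ord]
  gmsg <- seq_along(conv)                      # global message id
  msgs_per_conv <- tabulate(conv, nbins = n_conv)

  # flatten tokens
  tok_lists <- lapply(hs$text, .tokenize_one)
  tok_lens <- lengths(tok_lists)
  tok <- porter_stem(unlist(tok_lists, use.names = FALSE))
  tok_msg <- rep.int(gmsg, tok_lens)
  ntok <- length(tok)

  # within-message adjacency for bigrams
  if (ntok >= 2L) {
    adj <- which(tok_msg[-ntok] == tok_msg[-1L])
    bigrams <- paste(tok[adj], tok[adj + 1L])
  } else {
    adj <- integer(0L)
    bigrams <- character(0L)
  }

  n_uni_msg <- tabulate(tok_msg, nbins = length(gmsg))
  utok <- unique(tok)

  per_cat_msg <- list()    # per-message counts, one vector per category
  term_rows <- list()
  for (nm in names(lexicon)) {
    cat_ <- lexicon[[nm]]
    pat <- cat_$patterns
    consumed <- logical(ntok)
    key_tally <- integer(0L)
    msg_counts <- integer(length(gmsg))

    bkeys <- pat$key[pat$kind == "bigram"]
    if (length(bkeys) && length(bigrams)) {
      for (j in which(bigrams %in% bkeys)) {
        p <- adj[j]
        if (!consumed[p] && !consumed[p + 1L]) {
          consumed[c(p, p + 1L)] <- TRUE
          key <- bigrams[j]
          key_tally[key] <- (if (key %in% names(key_tally))
            key_tally[[key]] else 0L) + 1L
          m <- tok_msg[p]
          msg_counts[m] <- msg_counts[m] + 1L
        }
      }
    }

    avail <- !consumed
    ekeys <- pat$key[pat$kind == "exact_stem"]
    if (length(ekeys)) {
      hit <- tok %in% ekeys & avail
      if (any(hit)) {
        add <- tabulate(tok_msg[hit], nbins = length(gmsg))
        msg_counts <- msg_counts + add
        tt <- table(tok[hit])
        key_tally[names(tt)] <- as.integer(
          ifelse(names(tt) %in% names(key_tally),
                 key_tally[names(tt)], 0L)) + as.integer(tt)
      }
    }
    for (key in pat$key[pat$kind == "prefix_wildcard"]) {
      uhit <- utok[startsWith(utok, key)]
      if (!length(uhit)) next
      hit <- tok %in% uhit & avail
      if (any(hit)) {
        msg_counts <- msg_counts + tabulate(tok_msg[hit],
                                            nbins = length(gmsg))
        key_tally[key] <- (if (key %in% names(key_tally))
          key_tally[[key]] else 0L) + sum(hit)
      }
    }

    per_cat_msg[[nm]] <- msg_counts
    if (length(key_tally)) {
      term_rows[[nm]] <- data.frame(category = nm,
                                    key = names(key_tally),
                                    count = as.integer(key_tally),
                                    stringsAsFactors = FALSE)
    }
  }

  cats <- names(lexicon)
  n_cat <- length(cats)
  M <- do.call(cbind, per_cat_msg)             # messages x categories

  # assemble per-conversation segment spans and prefix sums
  out <- vector("list", n_conv)
  msg_off <- c(0L, cumsum(msgs_per_conv))
  for (ci in seq_len(n_conv)) {
    m <- msgs_per_conv[ci]
    rows_m <- (msg_off[ci] + 1L):(msg_off[ci + 1L])
    spans <- list()
    for (kind in segment_kinds) {
      sp <- switch(kind,
                   whole = data.frame(label = "whole", start = 0L, end = m),
                   phase = {
                     p <- split_phases(m)
                     data.frame(label = p$label, start = p$start,
                                end = p$end)
                   },
                   window = {
                     w <- make_windows(m)
                     data.frame(label = as.character(w$ordinal),
                                start = w$start, end = w$end)
                   })
      sp$kind <- kind
      spans[[kind]] <- sp
    }
    spans <- do.call(rbind, spans)
    mm <- M[rows_m, , drop = FALSE]
    cs_cnt <- matrix(0L, m + 1L, n_cat)
    for (j in seq_len(n_cat)) cs_cnt[-1L, j] <- cumsum(mm[, j])
    cs_uni <- c(0L, cumsum(n_uni_msg[rows_m]))
    counts <- cs_cnt[spans$end + 1L, , drop = FALSE] -
      cs_cnt[spans$start + 1L, , drop = FALSE]
    unis <- cs_uni[spans$end + 1L] - cs_uni[spans$start + 1L]
    out[[ci]] <- data.frame(
      conversation_id = conv_ids[ci],
      segment_kind = rep(spans$kind, n_cat),
      segment_label = rep(spans$label, n_cat),
      category = rep(cats, each = nrow(spans)),
      count = as.integer(counts),
      n_unigrams = rep(as.integer(unis), n_cat),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$degree <- ifelse(tab$n_unigrams > 0L,
                       pmin(1, tab$count / tab$n_unigrams), NA_real_)
  rownames(tab) <- NULL

  term_counts <- if (length(term_rows)) {
    tc <- do.call(rbind, term_rows)
    rownames(tc) <- NULL
    tc
  } else {
    data.frame(category = character(0L), key = character(0L),
               count = integer(0L))
  }

  structure(tab,
            categories = cats,
            category_kinds = stats::setNames(
              vapply(lexicon, `[[`, "", "kind"), cats),
            n_conversations = n_conv,
            term_counts = term_counts,
            class = c("score_table", "data.frame"))
}

#' Per-category occurrence totals and per-conversation mean/SD
#'
#' Summarizes whole-conversation occurrence counts: the corpus total, the
#' per-conversation mean (total / number of conversations) and the sample
#' (n-1 denominator) standard deviation across conversations. With a
#' single conversation the SD is undefined and reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param table a `score_table` containing `whole` rows.
#' @param categories categories to summarize; default all.
#' @return data frame with columns `category`, `total`, `mean`, `sd`,
#'   `n_conversations`, `sd_defined`.
#' @export
category_summary <- function(table, categories = attr(table, "categories")) {
  stopifnot(inherits(table, "score_table"))
  w <- table[table$segment_kind == "whole", , drop = FALSE]
  if (!nrow(w)) stop("score table has no whole-conversation rows")
  out <- lapply(categories, function(cat_) {
    x <- w$count[w$category == cat_]
    if (!length(x)) stop("category ", sQuote(cat_), " not in score table")
    sd_ok <- length(x) > 1L
    data.frame(category = cat_, total = sum(x), mean = mean(x),
               sd = if (sd_ok) stats::sd(x) else 0,
               n_conversations = length(x), sd_defined = sd_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Most frequent member terms of a category
#'
#' Ranks pattern keys by corpus-wide occurrence count (ties broken
#' lexicographically by key) and reports the share of the category total
#' accounted for by the top `k`.
#'
#' @param table a `score_table` produced by [score_corpus()] (which
#'   retains match-level detail).
#' @param category category name.
#' @param k number of terms to report (default 10). If `k` exceeds the
#'   number of distinct matched keys, all are returned with a warning.
#' @return data frame with columns `key`, `count` and `frac` (of the
#'   category total), with attributes `share` (summed top-`k` fraction)
#'   and `total`.
#' @export
top_terms <- function(table, category, k = 10L) {
  stopifnot(inherits(table, "score_table"))
  tc <- attr(table, "term_counts")
  tc <- tc[tc$category == category, , drop = FALSE]
  if (!nrow(tc)) {
    stop("no matched terms recorded for category ", sQuote(category))
  }
  tc <- tc[order(-tc$count, tc$key), , drop = FALSE]
  total <- sum(tc$count)
  if (k > nrow(tc)) {
    warning("k = ", k, " exceeds the ", nrow(tc),
            " distinct matched terms; returning all")
    k <- nrow(tc)
  }
  top <- tc[seq_len(k), c("key", "count"), drop = FALSE]
  top$frac <- top$count / total
  rownames(top) <- NULL
  structure(top, share = sum(top$count) / total, total = total)
}
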