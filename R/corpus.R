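# Transcript ingestion, validation and eligibility filtering. A corpus is
# a data frame of messages (conversation_id, index, role, timestamp, text)
# with class "chat_corpus"; the unit of analysis is the conversation.

.chatlex_roles <- c("help_seeker", "supporter", "bot")

#' Construct and validate a chat corpus
#'
#' Checks the message-level invariants (known roles, unique and contiguous
#' 0-based indices within each conversation, non-empty text except for bot
#' messages), sorts messages by conversation and index, and attaches the
#' `chat_corpus` class.
#'
#' @param messages data frame with columns `conversation_id`, `index`,
#'   `role`, `text` and optionally `timestamp`.
#' @param provenance free-text label recording where the transcripts came
#'   from.
#' @return a `chat_corpus` data frame sorted by conversation (order of
#'   first appearance) and message index.
#' @export
chat_corpus <- function(messages, provenance = "unspecified") {
  required <- c("conversation_id", "index", "role", "text")
  missing_cols <- setdiff(required, names(messages))
  if (length(missing_cols)) {
    stop("corpus is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"timestamp" %in% names(messages)) messages$timestamp <- NA_character_
  messages$conversation_id <- as.character(messages$conversation_id)
  messages$index <- as.integer(messages$index)
  messages$role <- as.character(messages$role)
  messages$text <- as.character(messages$text)
  messages$timestamp <- as.character(messages$timestamp)

  bad_role <- !messages$role %in% .chatlex_roles
  if (any(bad_role)) {
    stop("unknown role(s) ",
         paste(sQuote(unique(messages$role[bad_role])), collapse = ", "),
         "; allowed roles are: ", paste(.chatlex_roles, collapse = ", "))
  }
  if (anyNA(messages$index)) stop("message `index` must be an integer")

  key <- paste(messages$conversation_id, messages$index)
  if (anyDuplicated(key)) {
    stop("duplicate (conversation_id, index) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }

  conv_order <- unique(messages$conversation_id)
  messages <- messages[order(match(messages$conversation_id, conv_order),
                             messages$index), , drop = FALSE]
  rownames(messages) <- NULL

  expected <- as.integer(stats::ave(seq_len(nrow(messages)),
                                    messages$conversation_id,
                                    FUN = seq_along) - 1L)
  bad <- messages$index != expected
  if (any(bad)) {
    stop("conversation ",
         sQuote(messages$conversation_id[which(bad)[1L]]),
         ": message indices must be contiguous starting at 0")
  }
  empty <- !nzchar(messages$text) & messages$role != "bot"
  if (any(empty)) {
    stop("empty text is only allowed for role=bot (conversation ",
         sQuote(messages$conversation_id[which(empty)[1L]]), ")")
  }

  messages <- messages[, c("conversation_id", "index", "role",
                           "timestamp", "text")]
  structure(messages, provenance = provenance,
            class = c("chat_corpus", "data.frame"))
}

#' Read chat transcripts from JSON Lines or CSV
#'
#' The JSONL schema is one message object per line:
#' `{"conversation_id": str, "index": int, "role":
#' "help_seeker"|"supporter"|"bot", "timestamp": str|null, "text": str}`.
#' The CSV fallback has the same columns with a header row. Records are
#' grouped by conversation and sorted by index; malformed records are
#' rejected with the offending line number.
#'
#' @param path path to the transcript file.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return a [chat_corpus()] data frame.
#' @export
read_transcripts <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lineno <- which(nzchar(trimws(lines)))
    n <- length(lineno)
    if (!n) stop("no records found in ", path)
    cid <- idx <- role <- ts <- txt <- character(n)
    for (i in seq_len(n)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[lineno[i]]),
                      error = function(e) {
                        stop("malformed JSON record at line ", lineno[i],
                             ": ", conditionMessage(e), call. = FALSE)
                      })
      for (f in c("conversation_id", "role", "text")) {
        if (is.null(rec[[f]])) {
          stop("record at line ", lineno[i], " is missing field ",
               sQuote(f))
        }
      }
      if (is.null(rec$index)) {
        stop("record at line ", lineno[i],
             " is missing field 'index' (or a sortable order field)")
      }
      cid[i] <- as.character(rec$conversation_id)
      idx[i] <- as.character(rec$index)
      role[i] <- as.character(rec$role)
      ts[i] <- if (is.null(rec$timestamp)) NA_character_ else
        as.character(rec$timestamp)
      txt[i] <- as.character(rec$text)
    }
    messages <- data.frame(conversation_id = cid,
                           index = as.integer(idx), role = role,
                           timestamp = ts, text = txt,
                           stringsAsFactors = FALSE)
  } else {
    messages <- utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character",
                                encoding = "UTF-8")
    if (!"index" %in% names(messages)) {
      stop("CSV transcript file must have an 'index' column")
    }
    messages$index <- as.integer(messages$index)
    if ("timestamp" %in% names(messages)) {
      messages$timestamp[!nzchar(messages$timestamp) |
                           is.na(messages$timestamp)] <- NA_character_
    }
  }
  chat_corpus(messages, provenance = path)
}

#' Write a corpus back to JSON Lines or CSV
#'
#' Inverse of [read_transcripts()]: `read_transcripts(write_transcripts(x))`
#' reproduces the corpus.
#'
#' @param corpus a `chat_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "chat_corpus"))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(conversation_id = corpus$conversation_id[i],
                  index = corpus$index[i],
                  role = corpus$role[i],
                  timestamp = if (is.na(corpus$timestamp[i])) NULL else
                    corpus$timestamp[i],
                  text = corpus$text[i])
      jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
    }, character(1L))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(as.data.frame(corpus), path, row.names = FALSE,
                     na = "")
  }
  invisible(path)
}

#' Help-seeker message counts per conversation
#'
#' @param corpus a `chat_corpus`.
#' @return named integer vector, one entry per conversation in corpus
#'   order.
#' @export
n_helpseeker <- function(corpus) {
  stopifnot(inherits(corpus, "chat_corpus"))
  ids <- unique(corpus$conversation_id)
  counts <- table(factor(
    corpus$conversation_id[corpus$role == "help_seeker"], levels = ids))
  stats::setNames(as.integer(counts), ids)
}

#' Filter a corpus to eligible conversations
#'
#' Drops bot/automated messages (identified by `role = "bot"`, never by
#' content heuristics) and removes conversations with fewer than
#' `min_helpseeker` help-seeker messages. Message order is preserved and
#' indices are renumbered to keep them contiguous. The operation is
#' idempotent.
#'
#' @param corpus a `chat_corpus`.
#' @param min_helpseeker minimum number of help-seeker messages a
#'   conversation must contain to be retained (default 10).
#' @param drop_bot drop `role = "bot"` messages first (default `TRUE`).
#' @return the filtered `chat_corpus`; may contain zero conversations.
#' @export
filter_eligible <- function(corpus, min_helpseeker = 10L, drop_bot = TRUE) {
  stopifnot(inherits(corpus, "chat_corpus"))
  if (min_helpseeker < 1L) stop("`min_helpseeker` must be at least 1")
  out <- as.data.frame(corpus)
  if (drop_bot) out <- out[out$role != "bot", , drop = FALSE]
  hs <- n_helpseeker(structure(out, provenance = attr(corpus, "provenance"),
                               class = c("chat_corpus", "data.frame")))
  keep_ids <- names(hs)[hs >= min_helpseeker]
  out <- out[out$conversation_id %in% keep_ids, , drop = FALSE]
  # renumber indices so they stay contiguous after bot removal
  if (nrow(out)) {
    out$index <- as.integer(stats::ave(seq_len(nrow(out)),
                                       out$conversation_id,
                                       FUN = seq_along) - 1L)
  }
  rownames(out) <- NULL
  structure(out, provenance = attr(corpus, "provenance"),
            class = c("chat_corpus", "data.frame"))
}

#' Help-seeker messages of one conversation, in order
#'
#' Only help-seeker text is ever analyzed; supporter messages are carried
#' through the corpus but never scored.
#'
#' @param corpus a `chat_corpus`.
#' @param conversation_id which conversation; may be omitted when the
#'   corpus holds a single conversation.
#' @return data frame of the conversation's help-seeker messages in
#'   original order (possibly zero rows).
#' @export
helpseeker_stream <- function(corpus, conversation_id = NULL) {
  stopifnot(inherits(corpus, "chat_corpus"))
  ids <- unique(corpus$conversation_id)
  if (is.null(conversation_id)) {
    if (length(ids) != 1L) {
      stop("corpus has ", length(ids),
           " conversations; supply `conversation_id`")
    }
    conversation_id <- ids
  }
  if (!conversation_id %in% ids) {
    stop("no conversation with id ", sQuote(conversation_id))
  }
  out <- corpus[corpus$conversation_id == conversation_id &
                  corpus$role == "help_seeker", , drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' @export
print.chat_corpus <- function(x, ...) {
  ids <- unique(x$conversation_id)
  cat("<chat_corpus> ", length(ids), " conversation(s), ", nrow(x),
      " messages (provenance: ", attr(x, "provenance"), ")\n", sep = "")
  invisible(x)
}
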