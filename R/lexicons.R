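# Lexical categories: named sets of matchable term patterns. A raw term
# is classified by syntax: a trailing "*" makes a prefix wildcard, internal
# whitespace makes a bigram phrase, anything else matches a stem exactly.
# All keys are Porter-stemmed so that surface inflections collapse onto
# the authored pattern ("suicid*" captures suicide/suicidal/suicidality).

.normalize_term <- function(raw) {
  raw <- trimws(tolower(raw))
  if (!nzchar(raw)) stop("empty lexicon term")
  if (grepl("\\s", raw)) {
    words <- strsplit(raw, "\\s+")[[1L]]
    if (length(words) != 2L) {
      stop("multi-word term ", sQuote(raw),
           " must be a bigram (exactly two words)")
    }
    key <- paste(porter_stem(words), collapse = " ")
    kind <- "bigram"
  } else if (endsWith(raw, "*")) {
    stripped <- sub("\\*+$", "", raw)
    key <- porter_stem(stripped)
    kind <- "prefix_wildcard"
  } else {
    key <- porter_stem(raw)
    kind <- "exact_stem"
  }
  if (!nzchar(gsub(" ", "", key))) {
    stop("term ", sQuote(raw), " stems to an empty string")
  }
  list(raw = raw, kind = kind, key = key)
}

#' Build a lexical category from raw term strings
#'
#' Terms are normalized into match patterns: Porter-stemmed exact terms,
#' star-stripped stemmed prefix wildcards, and stemmed two-word bigram
#' phrases. Duplicate raw terms are collapsed with a warning; an exact
#' pattern whose key coincides with a wildcard key in the same category is
#' redundant (the wildcard subsumes it) and is dropped.
#'
#' @param name category name.
#' @param terms character vector of raw member terms (e.g. `"hurt"`,
#'   `"scar*"`, `"harm myself"`).
#' @param kind `"empath"` for general-purpose categories scored by lexical
#'   degree, `"contextual"` for domain-specific categories scored by raw
#'   occurrence counts.
#' @return an object of class `lex_category` with elements `name`, `kind`,
#'   `patterns` (data frame raw/kind/key) and `n_terms`.
#' @export
lex_category <- function(name, terms, kind = c("contextual", "empath")) {
  kind <- match.arg(kind)
  if (!length(terms)) stop("category ", sQuote(name), " has no terms")
  terms <- as.character(terms)
  if (anyDuplicated(tolower(trimws(terms)))) {
    dup <- unique(terms[duplicated(tolower(trimws(terms)))])
    warning("category ", sQuote(name), ": duplicate term(s) collapsed: ",
            paste(sQuote(dup), collapse = ", "))
    terms <- terms[!duplicated(tolower(trimws(terms)))]
  }
  pats <- lapply(terms, .normalize_term)
  pat <- data.frame(
    raw = vapply(pats, `[[`, "", "raw"),
    kind = vapply(pats, `[[`, "", "kind"),
    key = vapply(pats, `[[`, "", "key"),
    stringsAsFactors = FALSE)
  # wildcard subsumes an exact pattern with the same key
  wkeys <- pat$key[pat$kind == "prefix_wildcard"]
  pat <- pat[!(pat$kind == "exact_stem" & pat$key %in% wkeys), ,
             drop = FALSE]
  pat <- pat[!duplicated(paste(pat$kind, pat$key)), , drop = FALSE]
  rownames(pat) <- NULL
  structure(list(name = name, kind = kind, patterns = pat,
                 n_terms = nrow(pat)),
            class = "lex_category")
}

#' @export
print.lex_category <- function(x, ...) {
  cat("<lex_category> ", x$name, " (", x$kind, "), ", x$n_terms,
      " patterns\n", sep = "")
  invisible(x)
}

#' Load lexical categories from a YAML file
#'
#' The file maps category names to either a list of raw term strings or a
#' mapping `{kind: empath|contextual, terms: [...]}`.
#'
#' @param path path to a UTF-8 YAML (or JSON) lexicon file.
#' @return named list of [lex_category()] objects.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  spec <- yaml::read_yaml(path)
  if (!length(spec)) stop("lexicon file ", path, " defines no categories")
  if (is.null(names(spec)) || any(!nzchar(names(spec)))) {
    stop("lexicon file must map category names to term lists")
  }
  out <- lapply(names(spec), function(nm) {
    entry <- spec[[nm]]
    if (is.list(entry) && !is.null(entry$terms)) {
      kind <- if (is.null(entry$kind)) "contextual" else entry$kind
      lex_category(nm, unlist(entry$terms), kind = kind)
    } else {
      lex_category(nm, unlist(entry), kind = "contextual")
    }
  })
  stats::setNames(out, names(spec))
}

#' Import bundled general-purpose category word lists
#'
#' Reads plain word-list files (one term per line, `#` comments allowed)
#' for general-emotion categories and normalizes them through the same
#' pattern machinery as any other lexicon. The lists bundled with the
#' package are deliberately partial synthetic stand-ins seeded from the
#' most frequent member terms of each category; see
#' `inst/extdata/empath_synthetic/README.txt`.
#'
#' A member term that happens to be the name of another category
#' contributes only itself, never that category's members.
#'
#' @param names character vector of category names to import.
#' @param dir directory holding `<name>.txt` word lists; defaults to the
#'   lists bundled with the package.
#' @return named list of [lex_category()] objects with `kind = "empath"`.
#' @export
import_empath_categories <- function(names,
                                     dir = system.file(
                                       "extdata", "empath_synthetic",
                                       package = "chatlex")) {
  available <- sort(sub("\\.txt$", "",
                        list.files(dir, pattern = "\\.txt$")))
  available <- setdiff(available, "README")
  if (!length(names)) return(stats::setNames(list(), character(0L)))
  unknown <- setdiff(names, available)
  if (length(unknown)) {
    stop("unknown category name(s): ",
         paste(sQuote(unknown), collapse = ", "),
         "; available categories: ", paste(available, collapse = ", "))
  }
  out <- lapply(names, function(nm) {
    lines <- readLines(file.path(dir, paste0(nm, ".txt")),
                       warn = FALSE, encoding = "UTF-8")
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lex_category(nm, lines, kind = "empath")
  })
  stats::setNames(out, names)
}

#' The lexicon bundled with the package
#'
#' Combines the four general-emotion categories (negative_emotion,
#' positive_emotion, suffering, optimism; partial synthetic word lists)
#' with the two contextual crisis categories (distress, suicidality,
#' seeded from their ten most frequent published member terms plus the
#' "harm myself" bigram).
#'
#' @return named list of six [lex_category()] objects.
#' @export
fixture_lexicon <- function() {
  empath <- import_empath_categories(
    c("negative_emotion", "positive_emotion", "suffering", "optimism"))
  contextual <- load_lexicon(system.file(
    "extdata", "lexicon_contextual_top10.yaml", package = "chatlex"))
  c(empath, contextual)
}

# ---- matching ----

#' Count category-term occurrences in a token stream
#'
#' Bigram patterns are matched first against within-message bigrams; each
#' unigram consumed by a bigram match is excluded from unigram matching
#' within the same category, so "harm myself" counts once even when
#' "harm*" is also a member pattern. Exact patterns match by equality on
#' the stemmed unigram; wildcards match when the stemmed unigram starts
#' with the key. Every match is counted with multiplicity, and a token may
#' match several distinct patterns of the category. Categories are matched
#' independently: shared member terms count in each category that lists
#' them.
#'
#' @param stream a `token_stream` from [build_stream()].
#' @param category a [lex_category()].
#' @return an object of class `match_result`: list with `category`,
#'   `count` and `matched` (named integer vector of per-pattern-key
#'   counts).
#' @export
count_occurrences <- function(stream, category) {
  stopifnot(inherits(stream, "token_stream"),
            inherits(category, "lex_category"))
  pat <- category$patterns
  consumed <- logical(stream$n_unigrams)
  matched <- integer(0L)

  bkeys <- pat$key[pat$kind == "bigram"]
  if (length(bkeys) && length(stream$bigrams)) {
    hits <- which(stream$bigrams %in% bkeys)
    for (j in hits) {
      p <- stream$bigram_pos[j]
      if (!consumed[p] && !consumed[p + 1L]) {
        consumed[c(p, p + 1L)] <- TRUE
        key <- stream$bigrams[j]
        matched[key] <- (if (key %in% names(matched)) matched[[key]] else 0L) + 1L
      }
    }
  }

  toks <- stream$unigrams
  avail <- !consumed
  for (key in pat$key[pat$kind == "exact_stem"]) {
    n <- sum(toks == key & avail)
    if (n) matched[key] <- (if (key %in% names(matched)) matched[[key]] else 0L) + n
  }
  for (key in pat$key[pat$kind == "prefix_wildcard"]) {
    n <- sum(startsWith(toks, key) & avail)
    if (n) matched[key] <- (if (key %in% names(matched)) matched[[key]] else 0L) + n
  }

  structure(list(category = category$name,
                 count = sum(matched),
                 matched = matched),
            class = "match_result")
}

#' Lexical degree score of a stream for one category
#'
#' The proportion of the segment's word tokens matching the category:
#' occurrence count divided by the unigram total, clamped to \[0, 1\]
#' (bigrams are views over the same tokens, not extra tokens). For an
#' empty stream the score is undefined and `NA` is returned, never 0.
#'
#' @inheritParams count_occurrences
#' @return a number in \[0, 1\], or `NA_real_` for an empty stream.
#' @export
degree_score <- function(stream, category) {
  stopifnot(inherits(stream, "token_stream"))
  if (stream$n_unigrams == 0L) return(NA_real_)
  min(1, count_occurrences(stream, category)$count / stream$n_unigrams)
}
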