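# Original Porter (1980) suffix-stripping stemmer. Implemented from the
# algorithm's published definition because no stemming package ships with
# this stack. A word is modelled as [C](VC)^m[V]; all conditions below are
# stated on the measure m of the candidate stem.

.pt_vowels <- c("a", "e", "i", "o", "u")

# consonant/vowel profile: TRUE = consonant; "y" is a vowel only when it
# follows a consonant (so "cry" is CCY = all consonants up to the y).
.pt_cv <- function(chars) {
  n <- length(chars)
  cv <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    cv[i] <- if (ch %in% .pt_vowels) {
      FALSE
    } else if (ch == "y") {
      if (i == 1L) TRUE else !cv[i - 1L]
    } else {
      TRUE
    }
  }
  cv
}

.pt_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.pt_m <- function(s) {
  ch <- .pt_chars(s)
  if (!length(ch)) return(0L)
  runs <- rle(.pt_cv(ch))$values
  if (runs[1L]) runs <- runs[-1L]   # optional leading consonant run
  sum(runs)                          # number of VC blocks
}

.pt_has_vowel <- function(s) {
  ch <- .pt_chars(s)
  length(ch) > 0L && any(!.pt_cv(ch))
}

# *d: ends with a double consonant
.pt_double_c <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(FALSE)
  if (substr(s, n, n) != substr(s, n - 1L, n - 1L)) return(FALSE)
  .pt_cv(.pt_chars(s))[n]
}

# *o: ends cvc where the final c is not w, x or y
.pt_cvc <- function(s) {
  ch <- .pt_chars(s)
  n <- length(ch)
  if (n < 3L) return(FALSE)
  cv <- .pt_cv(ch)
  cv[n] && !cv[n - 1L] && cv[n - 2L] && !(ch[n] %in% c("w", "x", "y"))
}

.pt_chop <- function(s, k) substr(s, 1L, nchar(s) - k)

# longest-suffix match within one step; `cond(stem, suffix)` gates the
# rewrite, and per Porter a failed condition ends the step (no fallback
# to shorter suffixes).
.pt_rules <- function(b, suffixes, replacements, cond) {
  hit <- which(vapply(suffixes, function(s) endsWith(b, s), logical(1L)))
  if (!length(hit)) return(b)
  hit <- hit[which.max(nchar(suffixes[hit]))]
  stem <- .pt_chop(b, nchar(suffixes[hit]))
  if (cond(stem, suffixes[hit])) paste0(stem, replacements[hit]) else b
}

.pt_step2_suf <- c("ational", "ization", "iveness", "fulness", "ousness",
                   "tional", "biliti", "ation", "alism", "aliti", "ousli",
                   "entli", "iviti", "enci", "anci", "izer", "abli", "alli",
                   "ator", "eli")
.pt_step2_rep <- c("ate", "ize", "ive", "ful", "ous",
                   "tion", "ble", "ate", "al", "al", "ous",
                   "ent", "ive", "ence", "ance", "ize", "able", "al",
                   "ate", "e")

.pt_step3_suf <- c("icate", "ative", "alize", "iciti", "ical", "ness", "ful")
.pt_step3_rep <- c("ic", "", "al", "ic", "ic", "", "")

.pt_step4_suf <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                   "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
                   "al", "er", "ic", "ou")

.porter_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  b <- word

  # step 1a: plurals
  if (endsWith(b, "sses")) {
    b <- .pt_chop(b, 2L)
  } else if (endsWith(b, "ies")) {
    b <- .pt_chop(b, 2L)
  } else if (!endsWith(b, "ss") && endsWith(b, "s")) {
    b <- .pt_chop(b, 1L)
  }

  # step 1b: -eed / -ed / -ing
  if (endsWith(b, "eed")) {
    if (.pt_m(.pt_chop(b, 3L)) > 0L) b <- .pt_chop(b, 1L)
  } else {
    stripped <- FALSE
    if (endsWith(b, "ed") && .pt_has_vowel(.pt_chop(b, 2L))) {
      b <- .pt_chop(b, 2L); stripped <- TRUE
    } else if (endsWith(b, "ing") && .pt_has_vowel(.pt_chop(b, 3L))) {
      b <- .pt_chop(b, 3L); stripped <- TRUE
    }
    if (stripped) {
      if (endsWith(b, "at") || endsWith(b, "bl") || endsWith(b, "iz")) {
        b <- paste0(b, "e")
      } else if (.pt_double_c(b) &&
                 !(substr(b, nchar(b), nchar(b)) %in% c("l", "s", "z"))) {
        b <- .pt_chop(b, 1L)
      } else if (.pt_m(b) == 1L && .pt_cvc(b)) {
        b <- paste0(b, "e")
      }
    }
  }

  # step 1c: y -> i when the stem contains a vowel
  if (endsWith(b, "y") && .pt_has_vowel(.pt_chop(b, 1L))) {
    b <- paste0(.pt_chop(b, 1L), "i")
  }

  # steps 2 and 3: m(stem) > 0
  cond_m0 <- function(stem, suf) .pt_m(stem) > 0L
  b <- .pt_rules(b, .pt_step2_suf, .pt_step2_rep, cond_m0)
  b <- .pt_rules(b, .pt_step3_suf, .pt_step3_rep, cond_m0)

  # step 4: m(stem) > 1; -ion additionally needs the stem to end s or t
  b <- .pt_rules(b, .pt_step4_suf, rep("", length(.pt_step4_suf)),
                 function(stem, suf) {
                   .pt_m(stem) > 1L &&
                     (suf != "ion" || endsWith(stem, "s") || endsWith(stem, "t"))
                 })

  # step 5a: drop final e
  if (endsWith(b, "e")) {
    stem <- .pt_chop(b, 1L)
    m <- .pt_m(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) b <- stem
  }

  # step 5b: -ll -> -l when m > 1
  if (.pt_m(b) > 1L && .pt_double_c(b) && endsWith(b, "l")) {
    b <- .pt_chop(b, 1L)
  }

  b
}

.porter_cache <- new.env(parent = emptyenv())

#' Porter stems of a token vector
#'
#' Applies the original Porter (1980) suffix-stripping algorithm to each
#' token. Tokens are expected lowercase; tokens of one or two characters are
#' returned unchanged, as are tokens already in stem form (the algorithm is
#' idempotent on its own output for ordinary vocabulary). Stems of unique
#' tokens are memoised across calls.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length and order as `tokens`.
#' @examples
#' porter_stem(c("hurting", "suicidal", "feelings", "happy"))
#' @export
porter_stem <- function(tokens) {
  if (!is.character(tokens)) stop("`tokens` must be a character vector")
  if (!length(tokens)) return(character(0L))
  u <- unique(tokens)
  out <- vapply(u, function(w) {
    if (!nzchar(w)) return(w)
    hit <- get0(w, envir = .porter_cache, inherits = FALSE)
    if (is.null(hit)) {
      hit <- .porter_one(w)
      assign(w, hit, envir = .porter_cache)
    }
    hit
  }, character(1L))
  unname(out[match(tokens, u)])
}
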