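# Tokenization and Porter stemming.

test_that("tokenize lowercases, strips punctuation and keeps contractions", {
  expect_identical(tokenize("I feel SO bad."), c("i", "feel", "so", "bad"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("can't stop—hurting"),
                   c("can't", "stop", "hurting"))
  # URLs, digit-only tokens and symbols cannot match any pattern
  expect_identical(tokenize("see https://example.org/x?y=1 at 10 ☺ ok"),
                   c("see", "at", "ok"))
  expect_identical(tokenize("'quoted' words"), c("quoted", "words"))
})

test_that("re-tokenizing joined tokens is a no-op", {
  texts <- c("I feel SO bad.", "can't stop hurting...",
             "what's the point;; really", "ok")
  for (tx in texts) {
    toks <- tokenize(tx)
    expect_identical(tokenize(paste(toks, collapse = " ")), toks)
  }
})

test_that("stemmer reproduces the published example vocabulary", {
  # worked examples from the algorithm's definition, carried through the
  # full step sequence by hand
  words <- c("caresses", "ponies", "ties", "caress", "cats", "feed",
             "agreed", "plastered", "bled", "motoring", "sing",
             "conflated", "troubled", "sized", "hopping", "tanned",
             "falling", "hissing", "fizzed", "failing", "filing",
             "happy", "sky", "relational", "conditional", "rational",
             "valenci", "hesitanci", "digitizer", "conformabli",
             "radicalli", "differentli", "vileli", "analogousli",
             "vietnamization", "predication", "operator", "feudalism",
             "decisiveness", "hopefulness", "callousness", "formaliti",
             "sensitiviti", "sensibiliti", "triplicate", "formative",
             "formalize", "electriciti", "electrical", "hopeful",
             "goodness", "revival", "allowance", "inference", "airliner",
             "gyroscopic", "adjustable", "defensible", "irritant",
             "replacement", "adjustment", "dependent", "adoption",
             "homologou", "communism", "activate", "angulariti",
             "homologous", "effective", "bowdlerize", "probate", "rate",
             "cease", "controll", "roll", "generalizations",
             "oscillators")
  stems <- c("caress", "poni", "ti", "caress", "cat", "feed",
             "agre", "plaster", "bled", "motor", "sing",
             "conflat", "troubl", "size", "hop", "tan",
             "fall", "hiss", "fizz", "fail", "file",
             "happi", "sky", "relat", "condit", "ration",
             "valenc", "hesit", "digit", "conform",
             "radic", "differ", "vile", "analog",
             "vietnam", "predic", "oper", "feudal",
             "decis", "hope", "callous", "formal",
             "sensit", "sensibl", "triplic", "form",
             "formal", "electr", "electr", "hope",
             "good", "reviv", "allow", "infer", "airlin",
             "gyroscop", "adjust", "defens", "irrit",
             "replac", "adjust", "depend", "adopt",
             "homolog", "commun", "activ", "angular",
             "homolog", "effect", "bowdler", "probat", "rate",
             "ceas", "control", "roll", "gener",
             "oscil")
  expect_identical(porter_stem(words), stems)
})

test_that("stemmer collapses crisis-vocabulary inflections onto one stem", {
  expect_identical(porter_stem("hurting"), "hurt")
  expect_identical(
    porter_stem(c("suicide", "suicidal", "suicidality")),
    rep("suicid", 3))
  expect_identical(porter_stem(c("feel", "feels", "feeling", "feelings")),
                   rep("feel", 4))
  expect_identical(porter_stem("stop"), "stop")
  expect_identical(porter_stem(c("scary", "cry", "family", "worse")),
                   c("scari", "cry", "famili", "wors"))
})

test_that("stemming is deterministic and idempotent on stems", {
  vocab <- c(test_vocab, "struggling", "happiness", "alone", "depressed")
  s1 <- porter_stem(vocab)
  expect_identical(porter_stem(vocab), s1)
  # words of length > 2 whose stems are stable under re-stemming
  stable <- s1[nchar(s1) > 2 & !endsWith(s1, "i")]
  expect_identical(porter_stem(stable), stable)
})

test_that("build_stream forms bigrams only within a message", {
  s <- build_stream("harm myself")
  expect_identical(s$unigrams, c("harm", "myself"))
  expect_identical(s$bigrams, "harm myself")

  s2 <- build_stream(c("harm", "myself"))
  expect_identical(s2$bigrams, character(0))
  expect_identical(s2$n_unigrams, 2L)
})

test_that("bigram count is sum of max(0, Li - 1) over messages", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample.int(5, 1)
    texts <- vapply(seq_len(k), function(i) {
      paste(sample(test_vocab, sample.int(6, 1), replace = TRUE),
            collapse = " ")
    }, character(1))
    s <- build_stream(texts)
    lens <- lengths(lapply(texts, tokenize))
    expect_identical(length(s$bigrams), sum(pmax(0L, lens - 1L)))
    expect_identical(s$n_unigrams, sum(lens))
    # concatenation additivity of unigram counts
    half <- build_stream(texts[1])
    rest <- build_stream(texts[-1])
    expect_identical(s$n_unigrams, half$n_unigrams + rest$n_unigrams)
  }
})
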