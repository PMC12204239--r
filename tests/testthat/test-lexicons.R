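# Pattern normalization, lexicon loading and the matching engine.

test_that("raw terms are classified by syntax and keys are stemmed", {
  cat_ <- lex_category("x", c("suicid*", "harm myself", "hurt"))
  expect_setequal(cat_$patterns$kind,
                  c("prefix_wildcard", "bigram", "exact_stem"))
  expect_identical(cat_$patterns$key[cat_$patterns$raw == "suicid*"],
                   "suicid")
  expect_identical(cat_$patterns$key[cat_$patterns$raw == "harm myself"],
                   "harm myself")
  expect_identical(cat_$n_terms, 3L)
})

test_that("scar* and scary survive as two patterns (keys differ)", {
  # Porter("scary") = "scari" != star-stripped "scar"
  cat_ <- lex_category("x", c("scar*", "scary"))
  expect_identical(nrow(cat_$patterns), 2L)
  expect_setequal(cat_$patterns$key, c("scar", "scari"))
  # but an exact term whose stem equals a wildcard key is subsumed
  cat2 <- lex_category("y", c("stop*", "stop"))
  expect_identical(nrow(cat2$patterns), 1L)
  expect_identical(cat2$patterns$kind, "prefix_wildcard")
})

test_that("lexicon files are validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("{}", path)
  expect_error(load_lexicon(path), "no categories")

  writeLines(c("bad:", "  - '*'"), path)
  expect_error(load_lexicon(path), "empty")

  writeLines(c("dup:", "  - hurt", "  - hurt"), path)
  expect_warning(lx <- load_lexicon(path), "duplicate")
  expect_identical(lx$dup$n_terms, 1L)

  writeLines(c("ok:", "  kind: empath", "  terms: [hope, better]"), path)
  lx <- load_lexicon(path)
  expect_identical(lx$ok$kind, "empath")
})

test_that("bundled general-emotion lists import through normalization", {
  opt <- import_empath_categories("optimism")$optimism
  expect_identical(opt$kind, "empath")
  # patterns derived from terms such as hopeful, perseverance, progress
  expect_true(all(c("hope", "persever", "progress") %in%
                    opt$patterns$key))
  expect_error(import_empath_categories("despair"), "available")
  expect_length(import_empath_categories(character(0)), 0)
  # a member term naming another category contributes one pattern only
  dir <- withr::local_tempdir()
  writeLines(c("death", "hurt"), file.path(dir, "suffering_mini.txt"))
  cat_ <- import_empath_categories("suffering_mini", dir = dir)[[1L]]
  expect_identical(cat_$n_terms, 2L)
})

test_that("bigram precedence prevents double counting within a category", {
  fix <- lex_category("suicidality_fix", c("harm*", "harm myself"))
  s <- build_stream("i want to harm myself")
  res <- count_occurrences(s, fix)
  expect_identical(res$count, 1L)
  expect_identical(names(res$matched), "harm myself")

  # without the bigram, the wildcard matches the unigram
  fix2 <- lex_category("w", "harm*")
  expect_identical(count_occurrences(s, fix2)$count, 1L)
})

test_that("occurrences count multiplicity and empty streams count zero", {
  cat_ <- lex_category("h", "hurt")
  expect_identical(count_occurrences(build_stream("hurt hurt hurt"),
                                     cat_)$count, 3L)
  expect_identical(count_occurrences(build_stream(character(0)),
                                     cat_)$count, 0L)
})

test_that("matching engine agrees with a brute-force oracle", {
  set.seed(101)
  cat_ <- test_category()
  for (rep in 1:200) {
    s <- rand_stream(sample.int(4, 1), test_vocab)
    expect_identical(count_occurrences(s, cat_)$count,
                     as.integer(brute_count(s, cat_)))
  }
})

test_that("degree score is count over unigrams, clamped, NA when empty", {
  cat_ <- lex_category("h", "hurt")
  ten <- build_stream(paste(c(rep("hurt", 2), rep("ok", 8)),
                            collapse = " "))
  expect_equal(degree_score(ten, cat_), 0.2)
  none <- build_stream(paste(rep("ok", 10), collapse = " "))
  expect_equal(degree_score(none, cat_), 0)
  all10 <- build_stream(paste(rep("hurt", 10), collapse = " "))
  expect_equal(degree_score(all10, cat_), 1)
  expect_true(is.na(degree_score(build_stream(character(0)), cat_)))
})

test_that("degree score is invariant to token order", {
  set.seed(7)
  cat_ <- test_category()
  words <- sample(test_vocab, 30, replace = TRUE)
  s1 <- build_stream(paste(words, collapse = " "))
  s2 <- build_stream(paste(rev(words), collapse = " "))
  # single messages of the same multiset (bigram-free category order
  # effects are excluded by using unigram patterns only)
  uni <- lex_category("u", c("hurt", "suicid*", "die"))
  expect_equal(degree_score(s1, uni), degree_score(s2, uni))
})

test_that("categories match independently and share terms freely", {
  a <- lex_category("a", c("hurt", "die"))
  b <- lex_category("b", c("hurt", "stop"))
  s <- build_stream("hurt and stop and die")
  ra <- count_occurrences(s, a)
  rb <- count_occurrences(s, b)
  expect_identical(ra$count, 2L)
  expect_identical(rb$count, 2L)
})

test_that("adding a pattern never decreases count or degree", {
  set.seed(23)
  for (rep in 1:20) {
    s <- rand_stream(2, test_vocab)
    base_terms <- c("hurt", "die")
    bigger <- lex_category("g", c(base_terms, "suicid*"))
    smaller <- lex_category("s", base_terms)
    expect_gte(count_occurrences(s, bigger)$count,
               count_occurrences(s, smaller)$count)
    if (s$n_unigrams > 0) {
      expect_gte(degree_score(s, bigger), degree_score(s, smaller))
    }
  }
})

test_that("the bundled lexicon has the six analysis categories", {
  lex <- fixture_lexicon()
  expect_setequal(names(lex),
                  c("negative_emotion", "positive_emotion", "suffering",
                    "optimism", "distress", "suicidality"))
  kinds <- vapply(lex, `[[`, "", "kind")
  expect_identical(unname(kinds[c("distress", "suicidality")]),
                   rep("contextual", 2))
  expect_identical(unname(kinds[["optimism"]]), "empath")
  # wildcard semantics: suicid* captures all inflections after stemming
  s <- build_stream("suicide suicidal suicidality")
  expect_identical(count_occurrences(s, lex$suicidality)$count, 3L)
})
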