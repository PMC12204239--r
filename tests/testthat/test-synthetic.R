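# Generator contracts: determinism, validity, calibration of emission
# rates against binomial sampling theory, and parameter recovery.

test_that("generation is a pure function of the config", {
  cfg <- synth_config(n_conversations = 8, seed = 99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth$per_category, b$truth$per_category)
  # and the seed matters
  c2 <- generate_corpus(synth_config(n_conversations = 8, seed = 100))
  expect_false(identical(a$corpus, c2$corpus))
})

test_that("seed is mandatory and rate sanity checks fire", {
  expect_error(synth_config(n_conversations = 5), "seed")
  spec <- default_category_specs()
  spec$base_rate[1] <- 0.9
  expect_error(synth_config(n_conversations = 5, seed = 1,
                            category_specs = spec), "0.5")
  spec <- default_category_specs()
  spec$base_rate[] <- 0.2
  expect_error(synth_config(n_conversations = 5, seed = 1,
                            category_specs = spec), "sum")
})

test_that("generated corpora pass validation and the eligibility filter", {
  cfg <- synth_config(n_conversations = 20, seed = 4)
  sim <- generate_corpus(cfg)
  kept <- filter_eligible(sim$corpus)
  expect_identical(length(unique(kept$conversation_id)), 20L)
  hs <- n_helpseeker(kept)
  expect_true(all(hs >= 10))
  expect_identical(unname(hs), as.integer(sim$truth$lengths))
  # supporter messages are interleaved but never empty
  expect_true(any(kept$role == "supporter"))
  expect_true(all(nzchar(kept$text)))
})

test_that("zero emission rates yield an all-zero score table", {
  spec <- data.frame(category = "steady", base_rate = 0, end_rate = 0,
                     shape = "flat")
  cfg <- synth_config(n_conversations = 5, seed = 12,
                      category_specs = spec)
  sim <- generate_corpus(cfg, lexicon = disjoint_lexicon(declining = FALSE))
  tab <- score_corpus(sim$corpus, disjoint_lexicon(declining = FALSE))
  expect_true(all(tab$count == 0L))
})

test_that("empirical phase match rates track the emission model", {
  # linear decline 0.10 -> 0.02 on a single disjoint category: observed
  # per-token match rates in the first and last phase must sit within 3
  # binomial standard errors of the analytic expectation
  spec <- data.frame(category = "fading", base_rate = 0.10,
                     end_rate = 0.02, shape = "linear")
  cfg <- synth_config(n_conversations = 200, seed = 2024,
                      category_specs = spec)
  lex <- disjoint_lexicon(flat = FALSE)
  sim <- generate_corpus(cfg, lexicon = lex)
  tab <- score_corpus(sim$corpus, lex, segment_kinds = "phase")

  for (phase in c("beginning", "end")) {
    rows <- tab[tab$segment_label == phase, ]
    observed <- sum(rows$count) / sum(rows$n_unigrams)
    # expectation: mean emission rate over the messages in this phase
    exp_rate <- mean(unlist(lapply(sim$truth$lengths, function(m) {
      u <- (seq_len(m) - 1) / (m - 1)
      ph <- split_phases(m)
      j <- match(phase, ph$label)
      span <- (ph$start[j] + 1):ph$end[j]
      0.10 + (0.02 - 0.10) * u[span]
    })))
    se <- sqrt(exp_rate * (1 - exp_rate) / sum(rows$n_unigrams))
    expect_lt(abs(observed - exp_rate), 3 * se + 0.002)
  }
})

test_that("conversation lengths match the calibrated distribution", {
  cfg <- synth_config(n_conversations = 800, seed = 6)
  sim <- generate_corpus(cfg)
  lens <- sim$truth$lengths
  expect_true(all(lens >= 10 & lens <= 382))
  # mean 30.5, sd 20.6 within sampling tolerance (3 SEs)
  expect_lt(abs(mean(lens) - 30.5), 3 * 20.6 / sqrt(800))
  expect_lt(abs(sd(lens) - 20.6), 4)
})

test_that("declining categories are recovered with the right sign", {
  lex <- disjoint_lexicon()
  spec <- data.frame(category = c("steady", "fading"),
                     base_rate = c(0.04, 0.10),
                     end_rate = c(0.04, 0.02),
                     shape = c("flat", "linear"))
  negatives <- 0L
  runs <- 5L
  for (s in seq_len(runs)) {
    cfg <- synth_config(n_conversations = 60, seed = 300 + s,
                        category_specs = spec)
    sim <- generate_corpus(cfg, lexicon = lex)
    fit <- lexical_trajectory(sim$corpus, lexicon = lex)
    rr <- recovery_report(sim$corpus, sim$truth, fit)
    fading <- rr[rr$category == "fading", ]
    if (fading$fitted_slope < 0) negatives <- negatives + 1L
    expect_true(fading$sign_match)
    expect_gt(fading$d_beginning_end, 0)
    # the flat category's expected slope is essentially zero
    expect_lt(abs(rr$true_slope[rr$category == "steady"]), 0.02)
  }
  expect_identical(negatives, runs)
})

test_that("stronger declines yield monotonically larger effect sizes", {
  lex <- disjoint_lexicon(flat = FALSE)
  drops <- c(0.02, 0.05, 0.09)
  d_be <- vapply(seq_along(drops), function(i) {
    spec <- data.frame(category = "fading", base_rate = 0.10,
                       end_rate = 0.10 - drops[i], shape = "linear")
    cfg <- synth_config(n_conversations = 80, seed = 700,
                        category_specs = spec)
    sim <- generate_corpus(cfg, lexicon = lex)
    fit <- lexical_trajectory(sim$corpus, lexicon = lex)
    fit$phases$fading$pairwise$d[3L]
  }, numeric(1))
  expect_true(all(diff(d_be) > 0))
})

test_that("recovery_report demands results for every generated category", {
  lex <- disjoint_lexicon()
  spec <- data.frame(category = c("steady", "fading"),
                     base_rate = c(0.04, 0.08), end_rate = c(0.04, 0.02),
                     shape = c("flat", "linear"))
  cfg <- synth_config(n_conversations = 12, seed = 55,
                      category_specs = spec)
  sim <- generate_corpus(cfg, lexicon = lex)
  fit <- lexical_trajectory(sim$corpus,
                            lexicon = disjoint_lexicon(flat = FALSE))
  expect_error(recovery_report(sim$corpus, sim$truth, fit), "steady")
})
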