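# Synthetic two-party chat corpora with known emotional-trajectory ground
# truth. Help-seeker message counts follow a truncated negative binomial
# (overdispersed, emulating real conversation-length distributions);
# each help-seeker token is a category-term emission with a probability
# that interpolates linearly between a start rate and an end rate over
# normalized conversation position, or a filler pseudo-word otherwise.
# Supporter messages are interleaved but built entirely from filler
# vocabulary, so the help-seeker-only analysis contract is exercised end
# to end.

#' Default per-category emission-rate specifications
#'
#' Start/end emission rates per help-seeker token chosen to echo the
#' phase-level magnitudes observed in crisis-chat conversations: all
#' negatively framed categories decline over the conversation, optimism
#' stays flat.
#'
#' @return data frame with columns `category`, `base_rate` (expected
#'   category-term emissions per token at conversation start), `end_rate`
#'   and `shape` (`"linear"` or `"flat"`).
#' @export
default_category_specs <- function() {
  data.frame(
    category = c("negative_emotion", "positive_emotion", "suffering",
                 "optimism", "distress", "suicidality"),
    base_rate = c(0.027, 0.0135, 0.015, 0.007, 0.034, 0.018),
    end_rate = c(0.015, 0.0100, 0.005, 0.007, 0.010, 0.007),
    shape = c("linear", "linear", "linear", "flat", "linear", "linear"),
    stringsAsFactors = FALSE)
}

# solve for untruncated NB (mu, sd) whose [min,max]-truncated moments hit
# the requested mean/sd
.calibrate_lengths <- function(mean, sd, min, max) {
  trunc_moments <- function(mu, s) {
    if (s^2 <= mu) return(c(NA_real_, NA_real_))
    x <- min:max
    p <- stats::dnbinom(x, size = mu^2 / (s^2 - mu), mu = mu)
    p <- p / sum(p)
    m <- sum(x * p)
    c(m, sqrt(sum(x^2 * p) - m^2))
  }
  obj <- function(par) {
    v <- trunc_moments(par[1L], par[2L])
    if (anyNA(v)) return(1e6)
    sum((v - c(mean, sd))^2)
  }
  fit <- stats::optim(c(mean, sd * 1.05), obj)
  list(mu = fit$par[1L], size = fit$par[1L]^2 /
         (fit$par[2L]^2 - fit$par[1L]))
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_conversations number of conversations to generate.
#' @param seed integer seed; mandatory, every generated corpus is a pure
#'   function of its configuration.
#' @param length_mean,length_sd target mean and SD of help-seeker message
#'   counts after truncation to `[length_min, length_max]` (defaults
#'   30.5, 20.6, 10, 382). The underlying negative-binomial parameters
#'   are calibrated numerically so the truncated moments match.
#' @param length_min,length_max truncation bounds on help-seeker message
#'   counts.
#' @param tokens_per_message Poisson mean for tokens per help-seeker
#'   message (default 12; a floor of one token per message applies).
#' @param category_specs data frame as in [default_category_specs()];
#'   rates must lie in \[0, 0.5\] and sum to at most 1 at every
#'   conversation position.
#' @param filler_vocab_size number of distinct filler pseudo-words.
#' @param supporter_reply_prob probability that a supporter message is
#'   interleaved after each help-seeker message.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_conversations = 500L, seed,
                         length_mean = 30.5, length_sd = 20.6,
                         length_min = 10L, length_max = 382L,
                         tokens_per_message = 12,
                         category_specs = default_category_specs(),
                         filler_vocab_size = 500L,
                         supporter_reply_prob = 0.8) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_conversations >= 1L, length_min >= 3L,
            length_max > length_min, tokens_per_message > 0)
  req <- c("category", "base_rate", "end_rate", "shape")
  if (!all(req %in% names(category_specs))) {
    stop("category_specs needs columns: ", paste(req, collapse = ", "))
  }
  rates <- c(category_specs$base_rate, category_specs$end_rate)
  if (any(rates < 0 | rates > 0.5)) {
    stop("emission rates must lie in [0, 0.5]")
  }
  # linear interpolation: the rate sum is maximal at an endpoint
  if (sum(category_specs$base_rate) > 1 || sum(category_specs$end_rate) > 1) {
    stop("category emission rates sum to more than 1")
  }
  category_specs$end_rate[category_specs$shape == "flat"] <-
    category_specs$base_rate[category_specs$shape == "flat"]
  nb <- .calibrate_lengths(length_mean, length_sd, length_min, length_max)
  structure(list(n_conversations = as.integer(n_conversations),
                 seed = as.integer(seed),
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 nb_mu = nb$mu, nb_size = nb$size,
                 tokens_per_message = tokens_per_message,
                 category_specs = category_specs,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 supporter_reply_prob = supporter_reply_prob),
            class = "synth_config")
}

# pronounceable pseudo-words that cannot match any lexicon pattern; any
# accidental match is filtered out against the supplied lexicon
.filler_vocab <- function(n, lexicon) {
  syll <- c("ba", "co", "du", "ga", "ji", "ku", "lo", "mi", "nu", "po",
            "qua", "ri", "sa", "tu", "vo", "wi", "xo", "yu", "zem", "blo")
  words <- character(0L)
  reps <- 2L
  while (length(words) < n) {
    grid <- expand.grid(a = syll, b = syll,
                        c = if (reps > 2L) syll else "",
                        stringsAsFactors = FALSE)
    cand <- unique(paste0(grid$a, grid$b, grid$c))
    stems <- porter_stem(cand)
    ok <- rep(TRUE, length(cand))
    for (cat_ in lexicon) {
      pat <- cat_$patterns
      ek <- pat$key[pat$kind == "exact_stem"]
      ok <- ok & !(stems %in% ek)
      for (wk in pat$key[pat$kind == "prefix_wildcard"]) {
        ok <- ok & !startsWith(stems, wk)
      }
    }
    words <- cand[ok]
    reps <- reps + 1L
  }
  words[seq_len(n)]
}

# surface forms whose processed stream actually matches the pattern;
# inflected variants exercise stemming and wildcard matching
.surface_pool <- function(category) {
  pat <- category$patterns
  out <- character(0L)
  for (i in seq_len(nrow(pat))) {
    if (pat$kind[i] == "bigram") {
      out <- c(out, pat$raw[i])
      next
    }
    base <- sub("\\*+$", "", pat$raw[i])
    cand <- unique(c(base, paste0(base, c("s", "ed", "ing"))))
    keep <- vapply(cand, function(w) {
      count_occurrences(build_stream(w), category)$count > 0L
    }, logical(1L))
    out <- c(out, cand[keep])
  }
  unique(out)
}

#' Generate a synthetic chat corpus with known ground truth
#'
#' See [synth_config()] for the generative model. Supporter messages are
#' interleaved between help-seeker messages but contain only filler
#' vocabulary; conversation lengths refer to help-seeker messages, so
#' every generated corpus passes the eligibility filter untouched.
#'
#' @param config a [synth_config()].
#' @param lexicon lexicon supplying the category term surfaces; defaults
#'   to [fixture_lexicon()]. Every category in
#'   `config$category_specs` must be present.
#' @return list with elements `corpus` (a `chat_corpus`) and `truth`
#'   (class `synth_truth`: the config, per-category expected window mean
#'   counts and the slope of those expected means). Expected counts are
#'   emission-based; observed category scores can exceed them where
#'   categories share member terms.
#' @export
generate_corpus <- function(config, lexicon = fixture_lexicon()) {
  stopifnot(inherits(config, "synth_config"))
  spec <- config$category_specs
  missing_cat <- setdiff(spec$category, names(lexicon))
  if (length(missing_cat)) {
    stop("lexicon lacks categories: ", paste(missing_cat, collapse = ", "))
  }

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  filler <- .filler_vocab(config$filler_vocab_size, lexicon)
  pools <- lapply(spec$category, function(nm) .surface_pool(lexicon[[nm]]))
  names(pools) <- spec$category
  n_cat <- nrow(spec)

  # truncated negative-binomial help-seeker message counts
  n <- config$n_conversations
  lens <- stats::rnbinom(n, size = config$nb_size, mu = config$nb_mu)
  bad <- lens < config$length_min | lens > config$length_max
  while (any(bad)) {
    lens[bad] <- stats::rnbinom(sum(bad), size = config$nb_size,
                                mu = config$nb_mu)
    bad <- lens < config$length_min | lens > config$length_max
  }

  conv_cols <- vector("list", n)
  t0 <- as.POSIXct("2023-05-01 09:00:00", tz = "UTC")
  for (ci in seq_len(n)) {
    m <- lens[ci]
    u <- (seq_len(m) - 1L) / (m - 1L)
    rate <- vapply(seq_len(n_cat), function(j) {
      spec$base_rate[j] + (spec$end_rate[j] - spec$base_rate[j]) * u
    }, numeric(m))                        # m x n_cat
    cum <- t(apply(rate, 1L, cumsum))     # m x n_cat cumulative rates
    if (n_cat == 1L) cum <- matrix(cum, ncol = 1L)

    ntok <- pmax(1L, stats::rpois(m, config$tokens_per_message))
    N <- sum(ntok)
    tok_msg <- rep.int(seq_len(m), ntok)
    r <- stats::runif(N)
    emit <- r < cum[cbind(tok_msg, rep.int(n_cat, N))]
    words <- character(N)
    if (any(emit)) {
      sub <- cum[tok_msg[emit], , drop = FALSE]   # n_emit x n_cat
      cat_idx <- rowSums(sub < r[emit]) + 1L
      for (j in seq_len(n_cat)) {
        sel <- which(cat_idx == j)
        if (length(sel)) {
          pool <- pools[[j]]
          words[which(emit)[sel]] <-
            pool[sample.int(length(pool), length(sel), replace = TRUE)]
        }
      }
    }
    nf <- sum(!emit)
    if (nf) {
      words[!emit] <- filler[sample.int(length(filler), nf,
                                        replace = TRUE)]
    }
    hs_text <- vapply(split(words, factor(tok_msg, levels = seq_len(m))),
                      paste, character(1L), collapse = " ")

    reply <- stats::runif(m) < config$supporter_reply_prob
    n_sup <- sum(reply)
    sup_text <- if (n_sup) {
      apply(matrix(filler[sample.int(length(filler), 3L * n_sup,
                                     replace = TRUE)], nrow = n_sup),
            1L, paste, collapse = " ")
    } else {
      character(0L)
    }
    # interleave: supporter replies follow their help-seeker message
    slot <- rep.int(seq_len(m), 1L + reply)
    is_sup <- unlist(lapply(seq_len(m), function(mi)
      c(FALSE, if (reply[mi]) TRUE)), use.names = FALSE)
    n_msgs <- length(slot)
    text <- character(n_msgs)
    text[!is_sup] <- hs_text
    text[is_sup] <- sup_text
    ts <- format(t0 + (ci - 1L) * 3600 + (seq_len(n_msgs) - 1L) * 20,
                 "%Y-%m-%dT%H:%M:%SZ")
    conv_cols[[ci]] <- list(
      conversation_id = rep.int(sprintf("synth-%05d", ci), n_msgs),
      index = seq_len(n_msgs) - 1L,
      role = ifelse(is_sup, "supporter", "help_seeker"),
      timestamp = ts, text = text)
  }
  messages <- data.frame(
    conversation_id = unlist(lapply(conv_cols, `[[`, "conversation_id"),
                             use.names = FALSE),
    index = unlist(lapply(conv_cols, `[[`, "index"), use.names = FALSE),
    role = unlist(lapply(conv_cols, `[[`, "role"), use.names = FALSE),
    timestamp = unlist(lapply(conv_cols, `[[`, "timestamp"),
                       use.names = FALSE),
    text = unlist(lapply(conv_cols, `[[`, "text"), use.names = FALSE),
    stringsAsFactors = FALSE)
  corpus <- chat_corpus(messages,
                        provenance = sprintf(
                          "synthetic (seed %d, %d conversations)",
                          config$seed, n))

  # expected window mean counts from the emission model (analytic, given
  # the realized lengths and the Poisson token mean)
  exp_means <- matrix(0, n_cat, 9L,
                      dimnames = list(spec$category, NULL))
  for (ci in seq_len(n)) {
    m <- lens[ci]
    u <- if (m > 1L) (seq_len(m) - 1L) / (m - 1L) else 0
    w <- make_windows(m)
    for (k in 1:9) {
      span <- (w$start[k] + 1L):w$end[k]
      for (j in seq_len(n_cat)) {
        rate_u <- spec$base_rate[j] +
          (spec$end_rate[j] - spec$base_rate[j]) * u[span]
        exp_means[j, k] <- exp_means[j, k] +
          config$tokens_per_message * sum(rate_u)
      }
    }
  }
  exp_means <- exp_means / n
  x <- 1:9
  true_slope <- apply(exp_means, 1L, function(y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  })
  truth <- structure(list(config = config,
                          per_category = data.frame(
                            spec,
                            true_slope = unname(true_slope),
                            stringsAsFactors = FALSE),
                          expected_window_means = exp_means,
                          lengths = lens),
                     class = "synth_truth")
  list(corpus = corpus, truth = truth)
}

#' Compare pipeline results against generator ground truth
#'
#' For each generated category, reports the fitted window-trend slope
#' against the slope of the expected (emission-model) window means, and
#' the beginning-vs-end effect size, flagging whether the recovered
#' direction of change matches the truth. For flat categories the sign
#' check is replaced by a near-zero check on the expected slope.
#'
#' @param corpus the generated `chat_corpus` (unused except for a sanity
#'   check on conversation counts; results are read from `fit`).
#' @param truth the `synth_truth` object from [generate_corpus()].
#' @param fit a [lexical_trajectory()] fit of the corpus.
#' @return data frame with one row per generated category: `category`,
#'   `shape`, `true_slope`, `fitted_slope`, `slope_bias`,
#'   `sign_match`, `d_beginning_end`.
#' @export
recovery_report <- function(corpus, truth, fit) {
  stopifnot(inherits(truth, "synth_truth"),
            inherits(fit, "lexical_trajectory"))
  spec <- truth$per_category
  missing_cat <- setdiff(spec$category, names(fit$trends))
  if (length(missing_cat)) {
    stop("pipeline results lack categories: ",
         paste(missing_cat, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(spec)), function(j) {
    nm <- spec$category[j]
    fitted <- fit$trends[[nm]]$slope
    truth_slope <- spec$true_slope[j]
    d_be <- fit$phases[[nm]]$pairwise$d[3L]
    data.frame(category = nm, shape = spec$shape[j],
               true_slope = truth_slope, fitted_slope = fitted,
               slope_bias = fitted - truth_slope,
               sign_match = if (spec$shape[j] == "flat") NA else
                 sign(fitted) == sign(truth_slope),
               d_beginning_end = d_be,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("recovery_report", "data.frame"))
}
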