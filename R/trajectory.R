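# The fitting interface: one call that runs the whole analysis on a
# corpus and returns a classed result with the usual methods.

#' Fit lexical trajectories to a chat corpus
#'
#' Runs the full analysis: eligibility filtering, scoring of every
#' conversation against the lexicon over whole conversations, three
#' phases and nine overlapping windows, then the statistical battery —
#' pairwise category correlations, per-category one-way phase ANOVA with
#' post hoc t tests and Cohen's d, and OLS trend fits to the nine window
#' mean counts.
#'
#' @param corpus a `chat_corpus` (see [read_transcripts()] or
#'   [generate_corpus()]).
#' @param lexicon named list of [lex_category()] objects; defaults to the
#'   bundled [fixture_lexicon()].
#' @param min_helpseeker eligibility threshold passed to
#'   [filter_eligible()] (default 10).
#' @param drop_bot drop `role = "bot"` messages (default `TRUE`).
#' @param phase_metric metric convention for the phase ANOVA: `"auto"`
#'   compares empath categories on degree scores and contextual
#'   categories on counts.
#' @param trend_metric metric averaged within windows for the trend
#'   regression (default `"count"`).
#' @return an object of class `lexical_trajectory` with components
#'   `scores` (the long score table), `summary` (per-category totals),
#'   `correlations` (`lex_cor` or `NULL` if fewer than 3 conversations),
#'   `phases` (named list of `phase_comparison`), `trends` (named list of
#'   `trend_result`), `window_table` (9 x category matrix of window
#'   means), `n_conversations` and `call`. Methods: `print`, `summary`,
#'   `coef` (slope/intercept/R-squared per category), `plot`.
#' @examples
#' cfg <- synth_config(n_conversations = 30, seed = 42)
#' sim <- generate_corpus(cfg)
#' fit <- lexical_trajectory(sim$corpus)
#' coef(fit)
#' @export
lexical_trajectory <- function(corpus, lexicon = fixture_lexicon(),
                               min_helpseeker = 10L, drop_bot = TRUE,
                               phase_metric = c("auto", "degree", "count"),
                               trend_metric = c("count", "degree")) {
  phase_metric <- match.arg(phase_metric)
  trend_metric <- match.arg(trend_metric)
  corpus <- filter_eligible(corpus, min_helpseeker = min_helpseeker,
                            drop_bot = drop_bot)
  n_conv <- length(unique(corpus$conversation_id))
  if (!n_conv) stop("no conversations remain after eligibility filtering")

  scores <- score_corpus(corpus, lexicon)
  cats <- attr(scores, "categories")

  correlations <- if (n_conv >= 3L) correlate_categories(scores) else NULL
  phases <- lapply(cats, function(cc)
    phase_anova(scores, cc, metric = phase_metric))
  names(phases) <- cats
  wm <- vapply(cats, function(cc)
    window_means(scores, cc, metric = trend_metric), numeric(9L))
  trends <- lapply(cats, function(cc) fit_trend(wm[, cc]))
  names(trends) <- cats

  structure(list(call = match.call(),
                 n_conversations = n_conv,
                 categories = cats,
                 scores = scores,
                 summary = category_summary(scores),
                 correlations = correlations,
                 phases = phases,
                 trends = trends,
                 window_table = wm,
                 phase_metric = phase_metric,
                 trend_metric = trend_metric),
            class = "lexical_trajectory")
}

#' @export
print.lexical_trajectory <- function(x, ...) {
  cat("Lexical trajectory fit: ", x$n_conversations,
      " conversations, ", length(x$categories), " categories\n",
      sep = "")
  d_be <- vapply(x$phases, function(p) p$pairwise$d[3L], numeric(1L))
  slope <- vapply(x$trends, `[[`, numeric(1L), "slope")
  r2 <- vapply(x$trends, `[[`, numeric(1L), "r_squared")
  print(data.frame(category = x$categories,
                   d_beginning_end = round(d_be, 2),
                   trend_slope = round(slope, 4),
                   r_squared = round(r2, 3),
                   row.names = NULL))
  invisible(x)
}

#' @export
summary.lexical_trajectory <- function(object, ...) {
  ph <- do.call(rbind, lapply(object$categories, function(cc) {
    p <- object$phases[[cc]]
    data.frame(category = cc, metric = p$metric, F = p$F,
               df_between = p$df_between, df_within = p$df_within,
               p = p$p,
               mean_beginning = p$phase_means[["beginning"]],
               mean_middle = p$phase_means[["middle"]],
               mean_end = p$phase_means[["end"]],
               sd_beginning = p$phase_sds[["beginning"]],
               sd_middle = p$phase_sds[["middle"]],
               sd_end = p$phase_sds[["end"]],
               d_beginning_middle = p$pairwise$d[1L],
               d_middle_end = p$pairwise$d[2L],
               d_beginning_end = p$pairwise$d[3L],
               stringsAsFactors = FALSE)
  }))
  tr <- do.call(rbind, lapply(object$categories, function(cc) {
    t <- object$trends[[cc]]
    data.frame(category = cc, slope = t$slope, intercept = t$intercept,
               r_squared = t$r_squared, stringsAsFactors = FALSE)
  }))
  structure(list(n_conversations = object$n_conversations,
                 descriptives = object$summary,
                 correlations = object$correlations,
                 phase_table = ph, trend_table = tr,
                 window_table = object$window_table),
            class = "summary.lexical_trajectory")
}

#' @export
print.summary.lexical_trajectory <- function(x, ...) {
  cat("Lexical trajectory analysis of", x$n_conversations,
      "conversations\n\nPer-category occurrences:\n")
  print(transform(x$descriptives, mean = round(mean, 2),
                  sd = round(sd, 2)), row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("\n")
    print(x$correlations)
  }
  cat("\nPhase comparisons:\n")
  ph <- x$phase_table
  ph[-(1:2)] <- lapply(ph[-(1:2)], function(v) round(v, 4))
  print(ph, row.names = FALSE)
  cat("\nWindow trends:\n")
  print(transform(x$trend_table, slope = round(slope, 4),
                  intercept = round(intercept, 3),
                  r_squared = round(r_squared, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.lexical_trajectory <- function(object, ...) {
  t(vapply(object$trends, function(t)
    c(slope = t$slope, intercept = t$intercept,
      r_squared = t$r_squared), numeric(3L)))
}

#' Plot fitted lexical trajectories
#'
#' Plots the mean occurrence count per window ordinal for each category,
#' with the fitted OLS trend lines.
#'
#' @param x a `lexical_trajectory` fit.
#' @param categories which categories to draw (default all).
#' @param ... further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.lexical_trajectory <- function(x, categories = x$categories, ...) {
  wm <- x$window_table[, categories, drop = FALSE]
  k <- ncol(wm)
  cols <- grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
  graphics::matplot(1:9, wm, type = "b", pch = 16, lty = 1, col = cols,
                    xlab = "conversation window (1-9)",
                    ylab = paste("mean", x$trend_metric, "per window"),
                    ...)
  for (j in seq_len(k)) {
    t <- x$trends[[categories[j]]]
    graphics::abline(t$intercept, t$slope, col = cols[j], lty = 3)
  }
  graphics::legend("topright", legend = categories, col = cols,
                   pch = 16, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
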