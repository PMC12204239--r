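# The statistical battery: pairwise category correlations on
# whole-conversation counts, one-way ANOVA across the three conversation
# phases with post hoc t tests and Cohen's d, and OLS trend regression on
# the nine window means.

#' Pearson correlations between category occurrence counts
#'
#' Pairwise Pearson correlations of per-conversation whole-conversation
#' occurrence counts, with two-sided p-values from the t distribution on
#' `n - 2` degrees of freedom. A zero-variance category yields `NA` for
#' its pairs and is flagged, never coerced to 0.
#'
#' @param table a `score_table` with `whole` rows for at least 3
#'   conversations.
#' @return an object of class `lex_cor`: list with `categories`, `r`
#'   (symmetric correlation matrix, unit diagonal), `p`, `n` and
#'   `degenerate` (names of zero-variance categories).
#' @export
correlate_categories <- function(table) {
  stopifnot(inherits(table, "score_table"))
  cats <- attr(table, "categories")
  w <- table[table$segment_kind == "whole", , drop = FALSE]
  X <- sapply(cats, function(cc) w$count[w$category == cc])
  if (is.null(dim(X)) || nrow(X) < 3L) {
    stop("need whole-conversation counts for at least 3 conversations")
  }
  n <- nrow(X)
  degen <- cats[apply(X, 2L, stats::var) == 0]
  k <- length(cats)
  r <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  p <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { r[i, j] <- 1; next }
      if (cats[i] %in% degen || cats[j] %in% degen) next
      rij <- stats::cor(X[, i], X[, j])
      r[i, j] <- rij
      tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  structure(list(categories = cats, r = r, p = p, n = n,
                 degenerate = degen),
            class = "lex_cor")
}

#' @export
print.lex_cor <- function(x, digits = 2, ...) {
  cat("Pearson correlations of per-conversation occurrence counts (n = ",
      x$n, ")\n", sep = "")
  print(round(x$r, digits))
  if (length(x$degenerate)) {
    cat("zero-variance (r undefined):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference using the pooled standard deviation for
#' equal group sizes: `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`.
#' Positive when the first (earlier) group mean exceeds the second.
#'
#' @param mean1,sd1 mean and standard deviation of the first group.
#' @param mean2,sd2 mean and standard deviation of the second group.
#' @return the effect size d. With both SDs zero: 0 for equal means, an
#'   error otherwise.
#' @examples
#' cohens_d(3.64, 2.89, 1.70, 1.93)  # ~0.79
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) < 0)) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (isTRUE(all.equal(mean1, mean2))) return(0)
    stop("Cohen's d undefined: zero variance in both groups with ",
         "unequal means")
  }
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' One-way ANOVA of a category across conversation phases
#'
#' Each conversation contributes one value per phase; the `3 n` values
#' are treated as three independent groups (matching degrees of freedom
#' `(2, 3n - 3)`), not as repeated measures. General-emotion (empath)
#' categories are compared on lexical degree scores and contextual
#' categories on occurrence counts by default; either metric can be
#' forced. Post hoc Student two-sample t tests (pooled variance) compare
#' the three phase pairs, with uncorrected and Bonferroni-adjusted
#' p-values and Cohen's d signed so that a decline over the conversation
#' is positive.
#'
#' @param table a `score_table` with `phase` rows.
#' @param category category name.
#' @param metric `"auto"` (degree for empath categories, count for
#'   contextual), `"degree"` or `"count"`.
#' @return an object of class `phase_comparison`: list with `category`,
#'   `metric`, `F`, `df_between`, `df_within`, `p`, `phase_means`,
#'   `phase_sds`, `n` (conversations) and `pairwise` (data frame with
#'   `pair`, `t`, `p`, `p_bonferroni`, `d`).
#' @export
phase_anova <- function(table, category,
                        metric = c("auto", "degree", "count")) {
  stopifnot(inherits(table, "score_table"))
  metric <- match.arg(metric)
  if (metric == "auto") {
    kinds <- attr(table, "category_kinds")
    metric <- if (identical(unname(kinds[category]), "empath"))
      "degree" else "count"
  }
  ph <- table[table$segment_kind == "phase" &
                table$category == category, , drop = FALSE]
  if (!nrow(ph)) stop("no phase rows for category ", sQuote(category))
  labs <- c("beginning", "middle", "end")
  vals <- lapply(labs, function(l) {
    v <- ph[[metric]][ph$segment_label == l]
    v[!is.na(v)]
  })
  n_conv <- length(unique(ph$conversation_id))
  if (n_conv < 2L) stop("phase ANOVA needs at least 2 conversations")

  g <- factor(rep(labs, lengths(vals)), levels = labs)
  y <- unlist(vals)
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  means <- vapply(vals, mean, numeric(1L))
  sds <- vapply(vals, stats::sd, numeric(1L))

  pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  pw <- lapply(pairs, function(ij) {
    a <- vals[[ij[1L]]]; b <- vals[[ij[2L]]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(pair = paste(labs[ij[1L]], labs[ij[2L]], sep = "-"),
               t = unname(tt$statistic), p = tt$p.value,
               d = cohens_d(mean(a), stats::sd(a), mean(b), stats::sd(b)),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_bonferroni <- pmin(1, pw$p * 3)
  pw <- pw[, c("pair", "t", "p", "p_bonferroni", "d")]

  structure(list(category = category, metric = metric,
                 F = unname(ow$statistic),
                 df_between = unname(ow$parameter["num df"]),
                 df_within = unname(ow$parameter["denom df"]),
                 p = ow$p.value,
                 phase_means = stats::setNames(means, labs),
                 phase_sds = stats::setNames(sds, labs),
                 n = n_conv, pairwise = pw),
            class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, digits = 3, ...) {
  cat("One-way ANOVA across conversation phases: ", x$category,
      " (", x$metric, ")\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.2f, p %s\n", x$df_between, x$df_within,
              x$F, format.pval(x$p, digits = digits)))
  m <- rbind(mean = x$phase_means, sd = x$phase_sds)
  print(round(m, 4))
  print(transform(x$pairwise, t = round(t, 2), d = round(d, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Mean segment value per window ordinal
#'
#' For each of the nine window ordinals, the mean across conversations of
#' the per-conversation window value (occurrence count by default,
#' matching trend analysis on mean token counts).
#'
#' @param table a `score_table` with `window` rows.
#' @param category category name.
#' @param metric `"count"` (default) or `"degree"`.
#' @return numeric vector of length 9 named by window ordinal.
#' @export
window_means <- function(table, category, metric = c("count", "degree")) {
  stopifnot(inherits(table, "score_table"))
  metric <- match.arg(metric)
  w <- table[table$segment_kind == "window" &
               table$category == category, , drop = FALSE]
  if (!nrow(w)) stop("no window rows for category ", sQuote(category))
  out <- vapply(as.character(1:9), function(l) {
    v <- w[[metric]][w$segment_label == l]
    mean(v, na.rm = TRUE)
  }, numeric(1L))
  out
}

#' Fit a linear trend to the nine window means
#'
#' Ordinary least squares of the window means on the window ordinal 1-9.
#' The slope is change per window step; R-squared equals the squared
#' Pearson correlation between ordinal and mean. Constant means give
#' slope 0 and R-squared 0.
#'
#' @param window_means numeric vector of 9 finite means (e.g. from
#'   [window_means()]).
#' @return an object of class `trend_result`: list with `window_means`,
#'   `slope`, `intercept` and `r_squared`.
#' @examples
#' fit_trend(9:1)  # slope -1, R^2 = 1
#' @export
fit_trend <- function(window_means) {
  y <- as.numeric(window_means)
  if (length(y) != 9L) stop("expected 9 window means, got ", length(y))
  if (any(!is.finite(y))) stop("window means must all be finite")
  x <- 1:9
  if (stats::var(y) == 0) {
    res <- list(window_means = y, slope = 0, intercept = y[1L],
                r_squared = 0)
  } else {
    fit <- stats::lm(y ~ x)
    res <- list(window_means = y,
                slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                r_squared = stats::cor(x, y)^2)
  }
  structure(res, class = "trend_result")
}

#' @export
print.trend_result <- function(x, digits = 4, ...) {
  cat(sprintf("Window trend: slope = %.*f per window, R^2 = %.*f\n",
              digits, x$slope, digits, x$r_squared))
  invisible(x)
}
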