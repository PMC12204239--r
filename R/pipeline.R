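# End-to-end orchestration: ingest -> filter -> score -> stats -> report,
# writing plain CSV artifacts plus a JSON manifest sufficient to re-run
# the identical analysis. No message text is written to any artifact or
# log: privacy by default.

.write_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage ", sQuote(stage), " failed: ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline and write report artifacts
#'
#' Reads (or accepts) a corpus, fits [lexical_trajectory()], and writes
#' tidy CSV artifacts to `out_dir`: the long score table, per-category
#' descriptives, per-conversation length descriptives, the correlation
#' matrix, the phase-comparison table, the window means and the trend
#' fits, plus `manifest.json` recording input hashes, package version and
#' all parameters. Outputs are byte-identical across reruns on the same
#' inputs.
#'
#' @param input path to a transcript file, or a `chat_corpus`.
#' @param out_dir output directory (created if needed).
#' @param lexicon_path optional YAML lexicon file; by default the bundled
#'   [fixture_lexicon()] is used.
#' @param format transcript format when `input` is a path.
#' @param min_helpseeker eligibility threshold (default 10).
#' @param phase_metric,trend_metric metric conventions, see
#'   [lexical_trajectory()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(input, out_dir, lexicon_path = NULL,
                         format = c("jsonl", "csv"),
                         min_helpseeker = 10L,
                         phase_metric = "auto", trend_metric = "count") {
  format <- match.arg(format)
  corpus <- .write_stage("ingest", {
    if (inherits(input, "chat_corpus")) input
    else read_transcripts(input, format = format)
  })
  lexicon <- .write_stage("lexicon", {
    if (is.null(lexicon_path)) fixture_lexicon()
    else load_lexicon(lexicon_path)
  })
  fit <- .write_stage("fit", lexical_trajectory(
    corpus, lexicon, min_helpseeker = min_helpseeker,
    phase_metric = phase_metric, trend_metric = trend_metric))
  s <- summary(fit)

  .write_stage("report", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    wcsv(as.data.frame(fit$scores), "scores.csv")
    wcsv(s$descriptives, "category_summary.csv")

    # per-conversation length descriptives (messages and tokens), whole
    # and per third
    whole <- fit$scores[fit$scores$segment_kind == "whole" &
                          fit$scores$category == fit$categories[1L], ]
    ph <- fit$scores[fit$scores$segment_kind == "phase" &
                       fit$scores$category == fit$categories[1L], ]
    occ_conv <- tapply(
      fit$scores$count[fit$scores$segment_kind == "whole"],
      fit$scores$conversation_id[fit$scores$segment_kind == "whole"],
      sum)
    hs_counts <- n_helpseeker(
      filter_eligible(corpus, min_helpseeker = min_helpseeker))
    desc <- data.frame(
      quantity = c("helpseeker_messages", "tokens",
                   "lexical_term_occurrences"),
      total = c(sum(hs_counts), sum(whole$n_unigrams), sum(occ_conv)),
      mean_per_conversation = c(mean(hs_counts), mean(whole$n_unigrams),
                                mean(occ_conv)),
      sd_per_conversation = c(stats::sd(hs_counts),
                              stats::sd(whole$n_unigrams),
                              stats::sd(occ_conv)),
      mean_per_third = c(mean(hs_counts) / 3,
                         mean(ph$n_unigrams), NA),
      stringsAsFactors = FALSE)
    wcsv(desc, "descriptives.csv")

    if (!is.null(s$correlations)) {
      rmat <- as.data.frame(s$correlations$r)
      rmat <- cbind(category = rownames(rmat), rmat)
      wcsv(rmat, "correlations.csv")
    }
    wcsv(s$phase_table, "phase_comparisons.csv")
    wm <- as.data.frame(s$window_table)
    wm <- cbind(window = 1:9, wm)
    wcsv(wm, "window_means.csv")
    wcsv(s$trend_table, "trends.csv")
  })

  manifest <- list(
    package = "chatlex",
    version = as.character(utils::packageVersion("chatlex")),
    input = if (is.character(input)) list(
      path = input, md5 = unname(tools::md5sum(input))) else
        list(path = NA, md5 = NA,
             provenance = attr(corpus, "provenance")),
    lexicon_path = if (is.null(lexicon_path)) "bundled" else lexicon_path,
    parameters = list(min_helpseeker = min_helpseeker,
                      phase_metric = phase_metric,
                      trend_metric = trend_metric,
                      format = format),
    n_conversations = fit$n_conversations,
    categories = fit$categories,
    artifacts = c("scores.csv", "category_summary.csv",
                  "descriptives.csv", "correlations.csv",
                  "phase_comparisons.csv", "window_means.csv",
                  "trends.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
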