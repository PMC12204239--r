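Package: chatlex
Title: Lexicon-Based Trajectory Analysis of Crisis Chat Conversations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Scores two-party online chat transcripts against
    psycholinguistic lexical categories and tracks changes in help-seeker
    language over the course of a conversation. Provides transcript
    ingestion, validation and filtering; lowercasing, tokenization, Porter
    (1980) stemming and within-message bigram phrase matching; lexical
    degree scores and occurrence counts per conversation phase (equal
    thirds) and per nine overlapping 20%-width windows; a statistical
    battery of category correlations, one-way ANOVA with post hoc t tests
    and Cohen's d, and linear trend regression over window means; and a
    synthetic dialogue corpus generator with known ground-truth emission
    rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, yaml, stats, utils, tools, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
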