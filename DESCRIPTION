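Package: sentidrift
Title: Dynamic Lexicon-Based Sentiment Tracking for Social-Media Streams
Version: 0.1.0
Authors@R: person("Sentidrift", "Developers", email = "sentidrift@example.org",
                  role = c("aut", "cre"))
Description: A pipeline for tracking how the sentiment polarity of individual
    words drifts over time in a stream of short social-media texts. Tweets are
    filtered by keyword rules (pandemic context, topics of interest, country),
    cleaned and lemmatised, scored against a seed polarity lexicon, and the
    per-word polarities are updated day by day with an exponential-smoothing
    rule that also learns new words from the stream. Includes a per-word
    sentiment archive with trend extraction, similarity-laid-out sentiment
    word clouds (co-occurrence, PPMI, cosine, classical MDS), and a synthetic
    tweet-stream generator with planted sentiment trajectories for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
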