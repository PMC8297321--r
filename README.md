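# sentidrift

Dynamic lexicon-based sentiment tracking for social-media streams.

## The problem

During a fast-moving crisis, the sentiment a population attaches to
individual words — *vaccine*, *lockdown*, *unemployment* — is not constant:
it drifts day by day with events. Static lexicon approaches assign each word
one polarity forever and so cannot see this drift. `sentidrift` implements a
tweet-stream pipeline for tracking it, built for the kind of infodemiology
study that follows Spanish-language Twitter across several countries over
months of a pandemic:

1. **Filter** a raw tweet stream by keyword rules in three stages: a context
   rule (e.g. `covid`, `covid19`, `coronavirus`), a set of topic rules
   (government, health, economy, employment, vaccines), and a country
   filter — with a country-by-topic count report.
2. **Preprocess** retained tweets: strip URLs, mentions, hashtags, emoji and
   special characters; tokenize; lemmatize (injectable lemmatizer, bundled
   rule-based default); remove Spanish stopwords plus configured domain
   stopwords.
3. **Score and update.** Each tweet's score is the mean lexicon polarity of
   its matched lemma occurrences. For every lexicon word `w` seen on day
   `d`, the stored polarity is updated by exponential smoothing

   ```
   s_w(d) = (1 − α) · s_w(d−1) + α · m_w(d),      α ∈ (0, 1]
   ```

   where `m_w(d)` is the mean score of day-`d` tweets containing `w`.
   Words absent from the lexicon that recur in scored tweets are *learned*
   (inserted at the mean of their tweets' scores). All history goes to an
   append-only per-word, per-day **archive**.
4. **Visualise**: per-word sentiment trend series, and word-cloud snapshots
   where position encodes relatedness (tweet co-occurrence → PPMI → cosine
   → classical MDS), colour encodes polarity (red −1 → green +1) and size
   encodes frequency; snapshots at different dates add the time dimension.

Because the original study's tweets are not redistributable, the package
ships a **synthetic stream generator** that plants per-word sentiment
trajectories (constant / linear drift / step change) with Gaussian noise,
plus recovery metrics, so the whole pipeline is testable offline.

## Worked example

```r
library(sentidrift)

lex <- lexicon(c("buena", "mala", "esperanza", "miedo"),
               c(0.8, -0.7, 0.6, -0.8))

tweets <- data.frame(
  id = sprintf("t%02d", 1:6),
  created_at = paste0(rep(c("2021-03-01", "2021-03-02", "2021-03-03"),
                          each = 2), "T10:00:00Z"),
  text = c("La vacuna covid es buena noticia",
           "covid y pfizer: mala gestion, mucho miedo",
           "@amigo la vacuna pfizer da esperanza contra el covid",
           "covid sin vacuna, mala epoca y miedo",
           "buena vacuna, buena esperanza, covid retrocede",
           "el miedo al covid sigue, vacuna ya por favor"),
  country_code = "ES"
)

topics <- list(rule_set("vaccines", c("vacuna", "pfizer")))
fl <- filter_stream(tweets, default_context_rules(), topics,
                    countries = "ES",
                    stopwords = c(spanish_stopwords(), "covid"))
fl$counts
#>       vaccines Total
#> ES           6     6
#> Total        6     6

res <- run_stream(fl$tweets, lex,
                  engine_config(alpha = 0.5, min_learn_occurrences = 2))
get_series(res$archive, "vacuna")
#>           day polarity_after
#> 1: 2021-03-03      -0.009375
res$lexicon[res$lexicon$lemma %in% c("vacuna", "miedo")]
#>     lemma  polarity  origin created_on total_frequency
#> 1:  miedo -0.590625    seed       <NA>               3
#> 2: vacuna -0.009375 learned 2021-03-02               4
```

Reading the output: all six tweets mention the pandemic context, a topic
keyword and carry a country code, so all six are retained under the
`vaccines` topic. The word `vacuna` is not in the seed lexicon; on
2021-03-02 it appears in two scored tweets (one hopeful, one fearful) and is
learned at their mean score −0.075; on 2021-03-03 its polarity is pulled up
by a positive day to −0.009. The seed word `miedo` ("fear", −0.8) is
dragged towards the milder scores of the tweets that contain it, ending at
−0.59. `cloud_snapshot()` and `plot_trends()` turn the archive into the
package's two visual products.

For a full run — synthetic stream, filter, engine per country, trends,
snapshots, counts, manifest — see `run_all()` or the CLI wrapper
(`inst/cli/sentidrift`): subcommands `synth`, `filter`, `run`, `trends`,
`cloud`, `freqcloud`, `report`, `all`.

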