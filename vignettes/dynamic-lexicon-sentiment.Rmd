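---
title: "Tracking word-sentiment drift in tweet streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking word-sentiment drift in tweet streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentidrift)
```

## The model

`sentidrift` treats sentiment as a property of *words* that evolves in
time. The state is a lexicon: a map from lemma to polarity
$s_w \in [-1, 1]$. A tweet's sentiment score is the arithmetic mean of the
polarities of its matched lemma occurrences; tweets matching no lexicon
word have an undefined score and contribute nothing anywhere.

For each word $w$ observed on calendar day $d$ (UTC), let $m_w(d)$ be the
mean score of the day's defined-score tweets containing $w$ (a tweet counts
once per word, however often it repeats it), and $n_w(d)$ the number of
those tweets. The daily update is exponential smoothing:

$$ s_w(d) = (1 - \alpha)\, s_w(d-1) + \alpha\, m_w(d), \qquad \alpha \in (0, 1]. $$

Three consequences shape everything downstream and are asserted as
properties in the test suite:

* **Boundedness.** The update is a convex combination, so polarities never
  leave $[-1, 1]$.
* **Strengthening/weakening.** $s_w$ moves strictly towards the day's
  evidence: $\operatorname{sign}(s_w(d) - s_w(d-1)) =
  \operatorname{sign}(m_w(d) - s_w(d-1))$.
* **Closed form.** Under constant evidence $m$,
  $s_w(D) = m + (1-\alpha)^D (s_w(0) - m)$ — the engine's iteration matches
  this to $10^{-12}$ over random draws.

Scoring always uses the *start-of-day* lexicon, and words learned on day
$d$ participate in scoring only from day $d+1$. Both choices exist for one
reason: within a day, tweet order must not matter (permuting a day's tweets
leaves every output byte-identical). Words unobserved on a day keep their
polarity — there is no decay, matching the flat segments seen in real
word-trend plots between mentions.

**New-word learning.** A lemma absent from the lexicon that appears in at
least `min_learn_occurrences` defined-score tweets on one day is inserted
at the mean of those tweets' scores, tagged `origin = "learned"` with its
creation date. The threshold trades vocabulary growth against noise; the
default is 5 tweets in one day, which ignores one-off co-occurrences while
catching genuinely recurring terms within a single active day.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `alpha` | 0.3 | update weight, (0, 1] | a word mentioned daily forgets half its past in ~2 days — fast enough to follow weekly news cycles, slow enough to ignore single-day spikes |
| `min_learn_occurrences` | 5 | tweets/day | see above |
| `learn_enabled` | TRUE | switch | learning off freezes the vocabulary |
| stopword extras | context + topic keywords | — | filter keywords occur in *every* retained tweet; left in, they become high-frequency pseudo-words whose polarity couples all topics |

The source gives the *inputs* of the daily update (the stored value and the
day's tweet scores, with "strengthening or weakening" behaviour) but not a
formula; exponential smoothing is the minimal rule consistent with both,
and `alpha` is exposed rather than hidden. The mean-of-occurrences tweet
score is likewise the simplest statistic consistent with per-word evidence;
negation and intensifier handling are out of scope.

## Filtering semantics

Rules are sets of normalized keyword phrases matched as contiguous token
subsequences — `covid` does not match `covidiota`. Matching operates on raw
normalized tokens (pre-lemmatization), so inflections behave exactly as the
analyst wrote them in the rule file; a switch enables lemma-level matching.
The three stages run in order: context, topics (a tweet may carry several),
country. The count report tallies a tweet once per matched topic, so row
totals equal per-topic dataset sizes and can exceed distinct-tweet counts;
the published reference grid this package carries
(`covid_corpus_counts()`) is presented per topic in the same way.

Normalization lowercases and folds Spanish diacritics (á é í ó ú ü) to
base letters so unaccented user spellings match; **ñ is preserved**, since
folding it merges distinct words ("año"/"ano"). The bundled lemmatizer is
a deliberately shallow suffix-stripper (plural `-es`/`-s`, stems ≥ 3
letters, small exception table) requiring no model download; it serves as
both the "stemming" and "lemmatisation" role and is injectable, as is an
optional PoS tagger (when provided, only content words survive; none is
bundled because the package must run offline).

## The visual products

The archive feeds two visualisations. Trend plots are direct reads of
`polarity_after` over time. Word-cloud snapshots encode five dimensions:
word identity (label), relatedness (2-D position), polarity (colour, red at
−1 through grey to green at +1), frequency (size, affine in
`log(1+frequency)`), and time (snapshots at successive windows). The
source defines only these visual semantics, not the statistics behind
"distance"; this package declares its substitute openly:
tweet-level co-occurrence (whole tweet as context — tweets are short), PPMI
weighting, cosine similarity, and classical (Torgerson) MDS on
$D = 1 - S$ keeping the top two eigendimensions. Every step is
deterministic and oracle-checkable: the layout is compared against
`stats::cmdscale` to $10^{-9}$, with axis signs fixed so the
largest-magnitude coordinate on each axis is positive. Degenerate inputs
(rank < 2) are padded with zero coordinates. When the top-2 eigenspace is
nearly degenerate (e.g. two words with identical association profiles),
coordinates are only defined up to mixing within that eigenspace; pairwise
distances on well-separated spectra are what the oracle test pins.

## The synthetic world

No tweet data ships with the package, so validation rests on a generator
whose defaults are a fixed, stated world (seed 42): 60 days, one country,
200 tweets per day per word, per-tweet Gaussian noise with $\sigma = 0.05$,
$\alpha = 0.3$, and three planted trajectories covering the three shapes —
linear $-0.6 \to 0.6$ ("vacuna"), constant $0.5$ ("reunion"), and a step
$0.4 \to -0.4$ at day 30 ("mascarilla"). Background tweets without context
keywords verify the filter rejects them (100% retention for planted tweets,
0% for background).

Each planted tweet contains a context keyword, a topic keyword, the
trajectory word, four filler lexicon words and one *adjuster* lexicon word
chosen from the polarity grid so the tweet's matched-lemma mean equals the
planted value (clipped to $[-1,1]$; fillers are drawn from within 0.1 of
the target so the adjuster stays in range). Two design points deserve
emphasis:

* **Fresh evidence blocks.** Filler and adjuster words are drawn from a
  partition of the lexicon specific to each (trajectory word, day)
  (`scenario_lexicon()`). This is what makes the planted value actually
  reach the engine: evidence words are themselves lexicon words, and the
  engine updates them too. With a single shared filler vocabulary, words
  near a drifting trajectory's path are dragged towards that word's
  *lagged* polarity and carry the contamination into other words' tweets —
  measured on the default scenario, the linear word's recovery RMSE
  degrades from 0.059 to 0.33 and the engine's genuine smoothing behaviour
  is no longer what the benchmark measures. Fresh per-day blocks hold every
  evidence word at its seed grid value at the moment of use, so each
  tweet's score equals the planted target up to grid resolution
  ($2/(n-1)$, 0.025 at the default $n = 81$) plus noise.
* **Noise enters per tweet**, not per day, matching the engine's evidence
  model (the daily mean is taken over tweet scores).

What a green recovery test establishes: scored evidence reaches the
archive through the full filter → preprocess → score → update → learn
chain, with the lag structure of exponential smoothing (the recovered
linear trajectory crosses zero ~3 days after the planted one; the step
heals at rate $1 - 5\alpha/6$ per day, the $5/6$ because the learned word's
own polarity joins its tweets' scores from day 2). What it does **not**
establish: robustness to real Spanish morphology, negation, sarcasm, bot
traffic, topic imbalance, or lexicon coverage gaps — the generator's
vocabulary is synthetic and its grammar is a bag of words. The constant
trajectory has zero planted variance, so its Pearson correlation is
undefined (flagged by `recovery_metrics()`); its RMSE bound still applies.

## Numerical and degenerate-input choices

* Duplicate lemmas after normalization when loading a seed lexicon: keep
  the first, warn (deterministic; the alternative orderings have no
  principled winner).
* Lexicon TSV round-trips polarities at 6 decimals; the archive CSV
  round-trips at full `fwrite` precision.
* A tweet whose text cleans to nothing is kept with empty lemmas: its
  score is undefined and it contributes nothing.
* Unparseable timestamps skip the record and count it (`skipped`
  attribute) rather than aborting a stream run.
* Frequency-cloud ties break alphabetically; archive records within a day
  are emitted in lemma order — both so artifacts are byte-stable.
* Exact-duplicate texts within a day are kept by default (retweets are
  real signal); `dedupe = TRUE` drops them.
* Day boundaries are UTC calendar dates: reproducible, timezone-free.
* Per-country analyses run one engine per country partition plus a pooled
  `"all"` run, with country as part of the archive key. Whether the
  original system shared one lexicon across countries is not stated in the
  source; per-country engines reproduce the per-country trend curves and
  keep countries independent.

## Known limitations

The lemmatizer is a heuristic stemmer and will over- or under-strip rare
forms ("clases" → "clase" but "tres" → "tre" if it escapes the exception
list and the stopword filter). Learning is per-day: a word that never
reaches the threshold within a single day is never learned, however often
it appears across days. The similarity statistic operates on a chosen
vocabulary of plotted words only; it does not embed the whole lexicon. The
update rule is a declared stand-in for the original system's unpublished
formula — conclusions about *that* system should be limited to the
behaviours the two provably share: bounded polarities pulled monotonically
towards daily evidence, with persistence in the absence of mentions.
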