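---
title: "Methods: trend detection, involvement and sentiment dynamics in microblog streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend detection, involvement and sentiment dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendsent)
```

`trendsent` analyses a timestamped microblog stream in sliding time windows:
it infers one topic per tweet, ranks topics by a trending score, scores each
user's topical involvement, scores tweet sentiment with a lexicon-and-rule
engine, and partitions users into sentiment clusters whose quality is
measured by entropy and semantic cohesion. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
bundled synthetic-data generator does and does not establish about real
data.

## Time windows

The stream span is partitioned into half-open windows `[start, start + len)`
anchored at the span start and shifted by `delta_t <= len`; overlap is
allowed, gaps are not. Half-openness means a boundary tweet belongs to
exactly the windows whose interval contains it — no double counting at
shared endpoints, while overlapping windows deliberately share interior
tweets. A span covering nine calendar days with `len = 3d`, `delta_t = 1d`
yields seven windows; "three days starting 23 March" is read as
3 × 24 h from 00:00 UTC of the first date (timestamps are normalized to UTC
on ingest so that window membership is timezone-stable). If the retained
fully-fitting windows do not reach the span end, one final overrunning
window is appended so the union always covers the span; with
`delta_t = len` the windows form a disjoint partition.

## Preprocessing

Tweets are noisy: markup, URLs, mentions, hashtags, elongations
("goooood"), informal variants ("tmrw"). The cleaning order is fixed: HTML
strip → URL/mention removal → lowercase → hashtag mark strip (the word is
kept, since hashtag words are often topical) → punctuation removal →
whitespace tokenization → elongation squeeze (3+ repeats collapse to 2,
then dictionary lookup) → lexical-variant substitution (two-column TSV,
multi-word canonical forms expand) → stopword removal → optional light
stemming. Stemming defaults to off because unstemmed topic-word lists are
easier to read. The pipeline is idempotent: re-processing processed text is
a no-op.

The bundled stopword list is the standard 179-entry English list used
throughout NLP tooling. Note one consequence: stopword removal deletes
negators ("not", "don't"), so the sentiment engine's negation rules only
fire when scoring raw text.

## Topic model

The topic layer is a Twitter-style LDA with two departures from vanilla
LDA, both motivated by tweet shortness:

* **one topic per tweet** — a tweet-length document rarely mixes topics, so
  the tweet's topic `z` is drawn once from its author's topic-interest
  distribution `Phi_u` (symmetric Dirichlet prior `alpha`);
* **a background switch** — each word position carries a Bernoulli switch
  `y` (Beta prior `gamma`) choosing between a corpus-wide background
  distribution `theta_B` (prior `lambda`) and the tweet's topic
  distribution `theta_z` (prior `beta`). The background absorbs ubiquitous
  words that would otherwise blur every topic. The switch prior is a
  two-outcome Dirichlet, i.e. a Beta.

Inference is collapsed Gibbs sampling, implemented in C++: per sweep, every
tweet's topic is resampled from its exact full conditional (the
Dirichlet-multinomial closed form, with within-document repeated words
advancing the smoothed counts incrementally), then every word's switch from
its two-point conditional. The sampler uses R's RNG, so `set.seed()` makes
fits exactly reproducible. Point estimates are posterior means averaged
over post-burn-in sweeps; each tweet's reported topic is its modal sampled
topic, ties resolving to the lowest topic index. The collapsed joint
log-density is recorded every sweep as a convergence monitor (it should
trend upward through burn-in; the package monitors rather than asserts
per-step monotonicity, since individual Gibbs steps may decrease it).

Defaults follow common practice for collapsed Gibbs topic models:
`alpha = 50/K`, `beta = 0.01`, `lambda = 0.01`, `gamma = 20`, 500 sweeps
with 200 burn-in; all configurable. Words below `min_count` (default 1 =
keep all) can be pruned. Topic labels are not inferred — topics are
anonymous indices, and any human-readable labelling is supplied externally.
The per-tweet conditional is also exposed to the test suite, where it is
checked against brute-force enumeration of the collapsed posterior on a
two-document corpus, and parameter recovery is verified on generated
corpora with well-separated planted topics (matched topic-word cosine
at least 0.9).

## Trending score and the query

Within a window, topic `i` has `N_i` tweets and `U_i` distinct posting
users. The trending score mixes the two on a common scale:

$$\Lambda_i = \alpha \frac{N_i}{\max_j N_j} + (1 - \alpha)\frac{U_i}{\max_j U_j},
\qquad \alpha \in [0, 1].$$

Both components are max-normalized within the window before mixing. This
normalization is a deliberate design choice: raw tweet counts and raw user
counts live on different scales, and without normalization the volume term
dominates and the mixing weight is meaningless. At the limits, `alpha = 1`
reproduces the pure volume ranking and `alpha = 0` the pure reach ranking
(both are tested). The default `alpha = 0.5` weighs the two equally.

The window's query Q is the top-k topics by `Lambda`, selected through a
bounded priority queue of size k (equivalent to, and tested against, the
full-sort prefix); ties break by higher tweet count, then lower topic
index. If fewer than k topics exist, all are returned with a short-query
flag.

## Involvement

For user `u` and query Q in window m, `kappa_l` is the number of the user's
tweets on the l-th ranked query topic, and

$$\psi(u) = \sum_{l=1}^{k}(k + 1 - l)\,\kappa_l, \qquad
\sigma(u) = \frac{\psi(u)}{\max_z \psi(z)},$$

so rank-1 activity weighs k times a rank-k tweet, and `sigma` expresses
involvement relative to the window's most active eligible user (who scores
exactly 1; ties allowed). Eligibility requires at least `min_tweets`
query-topic tweets in the window (default 1 — the threshold is a free
parameter and the most inclusive choice is the least arbitrary); the same
eligible set supplies the `sigma` denominator and, later, the cluster
universe, keeping all per-window populations consistent. The default
report length is `r = 20` users per window. Users sort by `sigma`
descending with ties by total query-tweet count, then user id, making the
ranking deterministic.

## Sentiment

Sentiment is scored by a valence-aware lexicon-and-rule engine of the VADER
family, implemented in the package: word valences on [-4, 4] are adjusted
by degree boosters/dampeners (±0.293, damped by 0.95 / 0.9 with distance),
negation (×(−0.74), including "n't" forms, "no" as a negator of a following
lexicon word, the "never so/this" intensifier and the "at least"/"without
doubt" exceptions), ALL-CAPS emphasis (±0.733) in mixed-case text,
exclamation/question-mark emphasis, contrastive "but" reweighting (0.5
before, 1.5 after), and a small idiom table. The adjusted sum `s`
normalizes to the compound score

$$\varrho = \frac{s}{\sqrt{s^2 + 15}} \in [-1, 1],$$

and `pos`/`neg`/`neu` are the token-mass proportions of each category
(summing to 1 within rounding; proportions are reported to 3 decimals and
the compound to 4, matching the reference implementation's rounding).
Classification is boundary-inclusive: positive iff `compound >= 0.05`,
negative iff `compound <= -0.05`, neutral between. Empty input scores
`pos = neg = 0, neu = 1, compound = 0` by convention.

Two design decisions deserve emphasis:

* **The pipeline scores the processed token stream.** The package's
  window-level pipeline feeds the cleaned, stopword-free token stream to
  the scorer — the same representation the topic model consumes — which
  makes the tweet-level proportions a function of the content-bearing
  tokens only. `score_stream(text = "raw")` and `vader_scores()` on raw
  text remain available, and are the right choice when capitalization,
  punctuation, emoticons or negation scope matter; the rule engine is
  fully exercised on raw text in the unit tests.
* **The bundled lexicon is a curated subset** (~350 entries) of the
  published MIT-licensed VADER ratings, shipped as a plain TSV. It covers
  the words used anywhere in the package's examples, tests and generator
  pools, but arbitrary real-world text will contain valenced words outside
  the subset and will therefore score closer to neutral than under the
  full ~7,500-entry lexicon. Swap in a complete lexicon file via
  `vader_lexicon(path)` for production scoring.

Per-user aggregates are **unweighted sums** (not means) of compound scores
over the user's query-topic tweets in the window — aggregate magnitudes
above 1 are meaningful and indicate sustained signed activity. Off-query
tweets never enter an aggregate. Window-level dynamics are the label
percentages among a topic's tweets; reports round half-up to integers.

## Sentiment clusters and their evaluation

Eligible users partition into `C_Pos` / `C_Neg` / `C_Neu` by thresholding
the aggregate at ±0.05 — the same boundary as tweet-level classification.
Reusing the tweet-level threshold (rather than splitting on sign alone) is
deliberate: a pure sign rule would empty the neutral cluster, because any
user with a single weakly-valenced tweet would leave it. Clustering is done
both overall (query-sum) and topic-wise (per-topic sums).

Cluster quality uses each user's *main topic* — the query topic with the
user's maximal tweet count in the window, ties to the higher-ranked topic:

* **Entropy**: `entropy(C_j) = -sum_i p_ij log2 p_ij` with `0·log2 0 := 0`,
  where `p_ij` is the fraction of cluster j's users whose main topic is
  topic i, over the n = k query topics — so each entropy lies in
  `[0, log2 k]` and the size-weighted total is 0 exactly when every
  cluster is topic-pure. `p` uses one main topic per user rather than
  tweet-level topic fractions, matching the "share of active users"
  reading. Empty clusters contribute zero and are excluded from the
  weighting.
* **Semantic cohesion**: `rho(C_j)` is the fraction of the cluster sharing
  its modal main topic, in `[1/|C_j|, 1]`; undefined (reported `NA`) for
  empty clusters.

Both are verified against brute-force recomputation from raw user-by-topic
tables, and the two move oppositely as the planted specialist fraction in
synthetic data rises.

## The synthetic-data generator

`generate_stream()` draws a stream from the topic model's own generative
story plus controlled trend and sentiment structure, with full ground truth
(per-tweet topic, per-word switch, planted polarity, user activity rates).
The defaults are the package's reference study conditions, chosen once:

* 200 users × 20 expected tweets over nine days from 2020-03-23 — enough
  volume that seven 3-day windows each hold on the order of a thousand
  tweets, while a full fit stays in seconds;
* three 50-word topics with zero vocabulary overlap (overlap is the
  difficulty knob for recovery experiments), a 40-word background
  vocabulary, background probability 0.2, Zipf-shaped word masses;
* a two-phase trend schedule: topic 1 at 70% prevalence in days 1–4, topic
  2 at 70% in days 5–9 — so the rank-1 trending topic switches after the
  third 3-day window;
* log-normal user activity (sdlog 1) with one 10× hyper-active user, who
  should attain involvement `sigma = 1` in every window;
* a sentiment plan ramping the positive-tweet probability linearly from
  0.2 to 0.6 across the span with a constant 0.2 negative probability.
  Sentiment is planted by appending genuine valence-lexicon words (1–2 per
  non-neutral tweet) from fixed pools, not by labelling, so the rule-based
  scorer is exercised for real.

The generator emulates the statistical structure the pipeline consumes —
bag-of-words topical text, heavy-tailed activity, drifting prevalence and
mood. It does **not** emulate English syntax, emoticons, capitalization,
sarcasm, code-switching, retweet cascades or the follow graph; passing
recovery tests on synthetic data therefore demonstrates correctness of the
computations under the model's assumptions, not robustness of those
assumptions on real streams.

## Numerical choices and degenerate inputs

* Topic resampling works in log space with a max-shift before
  exponentiation, so long tweets cannot underflow the conditional.
* All tie-breaks are specified and deterministic (topics: count then
  index; users: activity then id; words: lexicographic; topic assignment:
  lowest index).
* An empty window yields empty statistics, not an error; an all-zero
  involvement window warns that the `sigma` denominator is undefined and
  returns no users; tweets that lose every token in preprocessing are
  excluded from sampling and reported `NA`-topic with a warning.
* Malformed JSONL lines and unparseable timestamps are skipped and
  counted, never silently dropped.
* Distribution estimates are posterior means (smoothed by their priors),
  so they are strictly positive and sum to one to machine precision.
* Problem sizes in the test suite: formula oracles run on 1,000 random
  instances; recovery runs use the generator defaults (4,000 tweets, 500
  sweeps) and the end-to-end run 300 sweeps — each a few seconds in the
  compiled sampler.

## Known limitations

* The one-topic-per-tweet assumption is inherited, not validated; long or
  multi-threaded posts violate it.
* The reduced valence lexicon biases absolute sentiment levels toward
  neutral on out-of-vocabulary words; comparative statements (drift,
  cluster composition) are less affected.
* Scoring stopword-free tokens disables negation scope; raw-text scoring
  is available where that matters.
* `K` is fixed by the user; the package offers no automatic topic-number
  selection or coherence-based labelling.
* The social follow graph, if present in the data, is carried but unused —
  no computation in this pipeline consumes edges.
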