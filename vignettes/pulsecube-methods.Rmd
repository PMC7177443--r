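---
title: "Methods: multidimensional analysis of health-related post streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multidimensional analysis of health-related post streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecube)
```

pulsecube analyses keyword-collected micro-blog streams for public-health
surveillance (infoveillance). A stream is modelled as two fact tables —
posts and users — analysed along dynamic dimensions: *quality* (is the
author a bot, a spammer, or off-domain?), *temporality* (is a term a short
burst or a sustained theme?), *topic* (which co-occurring term group does a
post belong to?) and *profile* (who is talking: professionals, journalists,
concerned people, alternative-therapy accounts, ...). This vignette
documents the statistical choices behind each stage, the tunable parameters,
and what the synthetic-data generator does and does not emulate.

## Stream model and pipeline order

Posts carry day-resolution timestamps: a day is the canonical time grain, so
all temporal statistics operate on zero-padded daily count series over the
analysis window. The reference pipeline (`surveil_stream()`) is:

1. build user facts on the raw originals (quality metrics must see every
   authored post, including spam copies);
2. drop posts of *filtered* users;
3. split retweets from originals — retweets carry no authored text and are
   used only to measure audience;
4. collapse verbatim duplicate texts (keyword streams are dominated by
   copies; duplicates would otherwise multiply term counts and stretch
   event spans);
5. detect event and topic term groups on the unique originals;
6. aggregate per-group report rows and author/audience profiles.

## User quality metrics

**Vocabulary diversity** is Yule's I, the inverse of Yule's characteristic
K, computed on the user's pooled tokens:

$$I = \frac{M_1^2}{M_2 - M_1}, \qquad M_1 = \text{number of word types},
\quad M_2 = \sum_i i^2 V_i,$$

with $V_i$ the number of types occurring exactly $i$ times. I is largely
insensitive to text length, which matters because account activity spans
four orders of magnitude. Automated accounts cycle over a tiny vocabulary
and score well below 30; engaged human accounts typically land in the
60–115 range. When every type occurs once ($M_2 = M_1$) diversity is
unbounded; the statistic is reported as a configurable cap (default 10,000)
in fact tables. Pooling is per user over all their original posts — one
diversity value per account, not an average of per-post values, since
per-post estimates of a length-robust statistic would be dominated by
small-sample noise.

**Domain coherence** is the inner product of the user's unigram
distribution $P_u$ with a domain term distribution $P_d$:
$\sum_w P_u(w) P_d(w)$ — the probability that one word drawn from each
coincides. It is zero iff the vocabularies are disjoint, needs no
smoothing, and against a broad medical lexicon takes values of order
$10^{-4}$, which sets the scale of the thresholds. Unigram (not bigram)
models are used: bigram overlap is far sparser and would make the metric
brittle for low-volume users. The lexicon is pluggable (two-column TSV,
term + weight); multiword terms contribute their weight to each constituent
word. The packaged lexicon is a small synthetic stand-in for a real
terminology export and is adequate for tests and examples only.

**Bands.** A user is `filtered` when prolific and repetitive
(n ≥ 100 posts and I < 30: the bot/spammer signature) or prolific and
off-domain (n ≥ 100 and coherence < 0.5×10⁻⁴). Users within a ±20%
multiplicative margin of either boundary are `inspect` — kept, but queued
for manual review; everyone else is `good`. All five numbers are
parameters of `quality_thresholds()`. The boundaries are deliberately
conservative: a low-volume account is never filtered regardless of its
metrics, because diversity estimates on a handful of posts are
uninformative.

## Event and topic detection

Terms are adjacent word bigrams after tokenization (URLs stripped, hashtag
symbols removed, `@mentions` excluded from pairs, stopwords per language
excluded), plus a configurable whitelist of standalone unigrams for
conditions whose single word is unambiguous. For every term the package
computes total occurrences, peak daily count, span (first to last
occurrence, inclusive) and the population excess kurtosis of the
zero-padded daily series:

$$g_2 = m_4 / m_2^2 - 3.$$

Kurtosis is computed over the *full* window including zero days — this is
what makes an isolated burst high-kurtosis (a single spike in a 100-day
window scores ≈ 95, the Bernoulli closed form $(1-6pq)/(pq)$ at $p = 1/n$)
while a sustained daily theme scores near 0. Zero-variance series return 0
by convention. A term is an **event** when kurtosis ≥ 10, peak ≥ 20 and
span ≤ 10 days; a **topic** when total ≥ 20 and *not* event-shaped. The
peak rule is a minimum: events of interest are large bursts, and the rule
suppresses the long tail of rare bigrams that spike once by chance. Terms
rarer than `min_total` (default 5) are not scored at all — they carry no
temporal signal.

Selected terms co-occur across posts, so each selection (events and topics
separately, mirroring their separate reporting) is clustered on a weighted
co-occurrence graph: nodes are terms, edge weights count posts containing
both endpoints. Groups are found by greedy modularity maximization
(Louvain), with

$$Q = \sum_c \left( \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right)$$

implemented independently in `modularity_q()` for verification. Vertices
are sorted by name and the RNG seed is fixed, so partitions are
bit-reproducible. Isolated terms become singleton groups. A post belongs to
every group owning a term it contains (one-term membership; requiring a
quorum of a group's terms would drop most relevant posts for large groups).

## Profile dimension

Account descriptions are classified into 11 profiles (professional,
ex-professional, student, sports, religion, public services, health
services, concerned, pseudo/alternative-therapy, journalist, others) by a
single-hidden-layer feed-forward network with softmax output over
unigram+bigram count features of the description. Descriptions are short
(a dozen words), so the signal lives in a few hundred highly indicative
words; the feature vocabulary is capped at the 300 most frequent features
(ties broken alphabetically for determinism) and the hidden layer defaults
to 16 units — the optimizer's cost grows quadratically with the weight
count, and larger networks buy nothing on inputs this small while taking
orders of magnitude longer to fit. Both are arguments. A
multinomial-logistic fallback (`method = "multinom"`, a skip-layer network
of size 0) is available. Training requires ≥ 2 classes and ≥ 5 examples per
class, and is reproducible under a seed. Empty or entirely out-of-vocabulary
descriptions are deterministically assigned `others`. One multilingual
vocabulary is used rather than per-language models: descriptions mix
languages freely and the label set is language-independent.

## Report tables

Per term group the package reports: tweet count; average Yule's I,
percentage verified, and mean stream activity (*OnDom*) over **distinct
authors** (per-post weighting would let one prolific account dominate every
author-side statistic); distinct authors and distinct retweeting users;
and the percentage of group posts that are replies or use a first-person
marker (small per-language lexicons; first-person share approximates the
fraction of directly affected posters). Reply percentages are computed over
original posts only — a retweet's reply status describes the retweeted
content, not new discussion. The screening step flags groups matching three
monitoring signatures: spam-like (author diversity < 30 with mean activity
> 100), active discussion (replies ≥ 40%), and unverified-viral (retweeted
audience, zero verified authors). All thresholds are arguments.

## Synthetic-data generator

No public stream ships with the package, so every stage is exercised
against `generate_stream()`, which emits a ground-truthed stream. The
default configuration — a 90-day window, 50 users across eight archetypes,
10 planted events, 20 topic groups of three bigrams, 100 rare noise
bigrams, 60% duplicate texts, a 70/30 English/Spanish mix — is the
package's reference study condition and is what the test suite and the
acceptance script analyse.

Design of the plantings:

* **Events** are near-Gaussian day bursts truncated to a width ≤ 10 days,
  with volumes (80–140 posts) chosen so the peak-day count clears the
  detection threshold with several standard deviations of multinomial
  slack. Every event post contains all of the event's bigrams, separated by
  filler words so no spurious "bridging" bigram is created.
* **Topics** are uniform daily rates; each post carries two terms of its
  group (giving within-group co-occurrence), and with probability 0.05
  borrows a term from another group (weak inter-group ties, so clustering
  is tested against non-trivial graphs).
* **Bots** draw six words per post from an eight-word vocabulary
  (Yule's I ≪ 30); **spammers** repeat three promotional texts; both post
  above the 100-post filtering floor. **Off-domain** users draw from a
  1,500-word background vocabulary disjoint from the medical lexicon
  (coherence exactly 0). Engaged users' filler mixes lexicon words
  (fraction 0.35) with background words.
* Descriptions are sampled from per-profile seed vocabularies; retweets
  and replies are wired to existing post ids; duplicates are verbatim
  copies emitted on the same or a later day.

What the generator does **not** emulate — and therefore what green tests do
not establish about real data: token frequencies are uniform within
vocabularies rather than Zipfian, so absolute diversity values for
synthetic "good" users are higher than the 60–115 of natural accounts (the
band logic is exercised; the magnitudes are not calibrated); there is no
natural-language structure, irony, or keyword ambiguity; no follower
topology; and events are clean bursts with no background usage of the same
bigram. Threshold behaviour on real streams should be audited with
`plot_user_quality()` and the `inspect` band.

`small_fixture()` is a deterministic ≤ 200-post instance (one single-day
event of volume 35 — by construction past every event threshold in a
60-day window — two single-bigram topics of exactly 20 posts, a 100-post
bot, an off-domain user, both languages) used throughout the unit tests.
With only 200 posts the off-domain account stays below the 100-post
filtering floor by design; off-domain filtering is exercised at full
generator scale.

## Numerical and degenerate-input conventions

* Population (not sample-corrected) moments for kurtosis; windows shorter
  than 2 days are an error; zero variance returns 0.
* `yules_i` errors on empty input; the all-singletons case returns the cap.
* Empty user language models yield coherence 0 with a warning.
* Modularity is undefined (error) on edgeless graphs; `cluster_terms`
  returns singletons with `NA` modularity instead, since an edgeless term
  set is a legitimate detection outcome.
* Duplicate-text canonicalisation breaks ties by day, then stream order.
* Users with no original post get `NA` metrics and no quality band; they
  are never filtered.

## Problem sizes

Tests and the acceptance script run the reference configuration
(~18,000 posts incl. retweets and copies, 50 users), ten 5-group
clustering streams, twenty quality-band replicates at reduced size
(10 users, 2 topics), and a 1,100-description profiling corpus
(100 per class, 80/20 split). These sizes were chosen so the full
verification cycle completes in a few minutes while keeping every
statistical margin (multinomial slack on event peaks, class separation in
profiling) comfortably wide.
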