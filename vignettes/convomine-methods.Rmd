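---
title: "Mining burn first aid conversations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining burn first aid conversations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convomine)
```

## The problem

Parents seeking first-aid advice for a child's burn or scald often turn to
social media before (or instead of) health services. Conversations about
burn first aid (BFA) are scattered across parenting forums, microblogs and
video-comment sections, and they cannot be located with a single hashtag:
the obvious keywords ("burn", "treat", "cure") are wildly ambiguous — people
burn calories, suffer burnout, burn bridges and get heartburn far more often
than they scald a hand on a kettle. `convomine` implements a pipeline for
this setting:

1. a **search-term taxonomy** rendered into platform-constrained boolean
   queries, with whole-thread extraction;
2. **text normalisation** (emoji/symbol stripping, stopword removal,
   lemmatisation);
3. a **dual-lexicon relevance filter**: seed lexicons expanded with their
   nearest neighbours in a word-embedding space, each analysis unit scored
   by its mean pairwise similarity to the positive (injury-sense) and
   negative (figurative-sense) lexicons, and classified by two per-platform
   thresholds;
4. **fixed-K topic modeling** with overlapping document membership;
5. **descriptive characterization** — conversation purpose, burn-type
   crosstabs, yearly trends, term prevalence, parent-voice detection.

Because raw platform data cannot be redistributed, the package ships a
seeded **synthetic corpus generator** with gold labels; every stage is
exercised end-to-end against it.

## Search taxonomy and query composition

The packaged taxonomy (`default_taxonomy()`) groups lowercase terms into six
categories: 9 burn-injury terms, 10 general first-aid terms, 25 specific
remedies, 11 food remedies, 16 child-reference terms and 9 exclusion terms.
The source list repeated "lotion" among the specific remedies; categories
are sets, so it is stored once.

Search backends limit query length, so `compose_queries()` always emits
**three** queries per platform — burn terms conjoined with each first-aid
flavour in turn. Child-reference and exclusion groups are attached only on
profiles that need them: parent-specific forums are assumed to host parent
voices already, whereas a general-audience microblog both needs a child
reference and benefits from exclusion terms. A rendered query that exceeds
the platform budget (1024 characters for the microblog profile) is a hard
error, never a silent truncation.

Matching (`match_text()`) mirrors search-engine semantics on the raw text:
case-insensitive, word-boundary only ("yo" is a standalone token and never
matches inside "you" or "yoghurt"), multiword terms as contiguous phrases.
A text matches when every required group contributes at least one term and
no exclusion term occurs. `select_threads()` retains **whole** threads when
any post matches any query, merging duplicates across queries. Whether
forum search engines index whole threads or only titles is platform lore we
cannot observe; the whole-thread rule is the stated extraction behaviour
and the generator plants matches accordingly.

## Preprocessing

`strip_symbols()` deletes the emoji blocks (Emoticons; Miscellaneous
Symbols and Pictographs; Transport and Map Symbols; Supplemental Symbols
and Pictographs; plus the legacy Miscellaneous Symbols, Dingbats, variation
selectors and the zero-width joiner) and all Unicode punctuation and
symbols. Letters, digits and whitespace survive; removals are deletions, so
output never grows.

Tokenisation lowercases first (informal casing is noise), splits on
whitespace, removes stopwords, lemmatizes, and re-applies the stopword
filter (a lemma can land on a stopword: "was" → "be"). The stopword list is
a standard English list **frozen** in `inst/extdata/stopwords_en.txt` —
reproducibility beats list pedigree here. No lemmatizer is available in the
package's dependency footprint, so a deliberately small rule-based one is
included: an irregular-form table plus suffix rules for plurals, past forms
and gerunds, iterated to a **fixed point** so that lemmatizing a lemma is
always the identity (this is what makes preprocessing idempotent, e.g.
"meetings" → "meeting" → "meet"). It over-stems occasional nouns
("meeting" → "meet"); for relevance scoring and topic modeling this
conflation is harmless and consistent. Numerals are kept by default — "20
minutes" under cool running water is topically meaningful.

## Embeddings

`train_embeddings()` fits skip-gram-with-negative-sampling vectors (the
word2vec family) via a small single-threaded C++ core: dynamic context
window, unigram^0.75 noise distribution sampled by inverse CDF, linear
learning-rate decay. Determinism was a design requirement — one RNG, one
thread — so identical seeds give bit-identical vectors. Defaults follow the
pipeline's study conditions: `d = 50`, `window = 5`, `epochs = 5`,
`min_count = 2`, 5 negative samples.

Out-of-vocabulary handling follows the character n-gram idea of subword
models, applied at lookup time: every 3–5-character n-gram (with `<`/`>`
boundary markers) is assigned the mean vector of the vocabulary words
containing it, and an unseen token receives the mean of its known n-gram
vectors. A swapped-letter misspelling ("scadl") therefore lands near its
source word, which is exactly the failure mode social-media text produces.
This is an inference-time approximation — n-gram vectors are not trained
parameters — and it is documented as such.

## The dual-lexicon relevance filter

The positive lexicon seeds with the burn-injury and all first-aid terms;
the negative lexicon's default seeds are the exclusion terms. Seeds are
lemmatized before lookup, since scoring happens in lemma space. Each
lexicon is expanded with its `k = 50` nearest vocabulary neighbours, where
a candidate's similarity to the seed set is its **maximum** cosine over
individual seeds (a centroid mode exists but the maximum matches "most
similar to the search terms" without inventing an average). Ties at the
cut break lexicographically, and seeds never re-enter as neighbours.

The phrase "similar to the negated search terms" admits two readings, and
the package ships both, clearly labelled: `strategy = "exclusion"` (default)
expands the exclusion-term seeds; `strategy = "negated"` takes the
vocabulary terms closest to the *negated positive-seed centroid*. Neither
is claimed to be canonical.

For a unit with scorable tokens $t_1 \dots t_n$ and a lexicon with vectors
$l_1 \dots l_m$, the score is the mean over all $n \times m$ pairs of
cosine similarity. The vectorised implementation uses the identity
$\frac{1}{nm}\sum_{i,j}\hat t_i \cdot \hat l_j
 = \frac{1}{n}\sum_i \hat t_i \cdot \bar l$
with $\bar l$ the mean of the unit-normalised lexicon vectors; the naive
double loop is kept in the test suite as an independent oracle and agrees
to $10^{-9}$. Tokens without vectors are skipped and excluded from the
token count; a unit with no scorable token is *undefined* and the pipeline
classifies it irrelevant (conservative: only positively scoring content is
retained). Classification is `pos_mean >= theta_pos && neg_mean <=
theta_neg`, both boundaries inclusive.

Thresholds are empirical per-platform artifacts. `calibrate_thresholds()`
grid-searches (resolution 0.01 by default over the observed score range)
for the pair maximising F1 on the relevant class, with a deterministic
tie-break: smallest `theta_pos`, then largest `theta_neg` (prefer recall at
equal F1). Calibration requires both label classes and the result records
its provenance (objective value, grid, sample size).

The analysis unit is per platform: thread title plus main post on forums,
the tweet on microblogs, the comment on video platforms. Filtering reports
carry before/after counts and the percentage reduction recomputed from
them.

## Topic modeling

`fit_topics()` is latent Dirichlet allocation with symmetric priors
($\alpha = 1/K$, $\beta = 0.01$), fitted by collapsed Gibbs sampling in
C++ — single chain, single thread, deterministic under seed. Posterior
means come from the final sweep's counts; both distribution matrices are
checked to row-sum to $1 \pm 10^{-6}$. `K` is configuration, not a derived
quantity — the pipeline default is 11 topics per platform corpus, fixed up
front; the package deliberately offers no coherence-based K selection.

Documents may belong to several topics: `assign_topics()` includes every
topic whose weight reaches the membership threshold $\tau$ (default 0.25 —
the membership rule behind published overlap counts is not stated anywhere,
so the rule and its threshold are surfaced in every report), falling back
to the argmax topic (all of them, on ties) when none reaches $\tau$.
Overlap between two topics is a document count plus a percentage at one
decimal; the multi-topic rate uses two decimals. The qualitative
interpretation of topics is human work; the pipeline emits top-word sheets
(probability-descending, lexicographic ties) to support it.

200 Gibbs sweeps are used by default; on the package's corpus sizes
(hundreds of documents, vocabularies in the hundreds) the sampler is
insensitive to more sweeps, and topic recovery on planted
disjoint-vocabulary corpora is complete.

## Characterization

All tables share one rounding convention, `pct()`: half-up, at the decimal
places each table style prints (1 for purpose tables and prevalence, 2 for
yearly breakdowns and the multi-topic rate, 0 for crosstab row percentages
and parent-voice counts). Every percentage cell in an emitted table is
reproducible from its count cells — the test suite asserts this on
randomized fixtures, and crosstab margins always equal their sums. Purpose
and burn-type labels are *inputs* (gold labels from the generator, or human
coding files for real data); automatic purpose classification is a
deliberate non-goal. Posts with no author id are counted as distinct
singleton users and their number is reported, mirroring forum scrapes where
a few posts lack usernames.

## The synthetic corpus generator

`generate_corpus()` emulates the features the pipeline's statistics
depend on, with gold labels for all of them:

* threads with shifted negative-binomial lengths (mean ≈ 13.5, capped at
  318 posts — heavy-tailed like real forum threads);
* per-post planted senses: relevant posts template-compose a burn term
  with first-aid vocabulary (plus a child term on non-forum platforms);
  distractor posts use the calories / burnout / bridges / heartburn senses
  with their context vocabulary; neutral posts carry no burn vocabulary;
* defaults matching the study conditions the pipeline is assessed under:
  ~2000 posts, 30% relevant, distractors on 40% of irrelevant posts;
* timestamps over 2004–2020 with a forum-like yearly intensity profile
  rising toward the present;
* user descriptions carrying parent terms at a 6% rate, matching the rate
  observed among microblog users;
* emoji/punctuation noise on 20% of posts and one character-swap
  misspelling on 10% of relevant posts — confined to filler words so that
  planted relevance labels remain matcher-consistent.

`generate_training_text()` emits sentences from the same templates, so
embedding training vocabulary and scoring vocabulary coincide;
`generate_topic_corpus()` performs standard generative topic-model
sampling and records the gold mixtures. All generators are byte-identical
under a fixed seed and leave the caller's RNG stream untouched.

**What passing tests do and do not show.** The generator's language is
template-based: small vocabulary, clean word senses, no sarcasm, no code
switching, no drift over time, and distractor senses that are lexically
well separated once embeddings are trained on matching text. Near-perfect
filter F1 on this corpus demonstrates that the machinery — expansion,
scoring, calibration, thresholds — is implemented correctly and that the
planted signal is recoverable; it does not certify comparable accuracy on
real platform text, where the reported reductions (70–98% of units
filtered away) still left substantial manual verification work.

## Numerical choices and degenerate inputs

* Zero-norm vectors are guarded in normalisation (treated as norm 1, so
  cosine contributions are 0 rather than NaN).
* Score grids for calibration are built at a fixed resolution from the
  observed range; comparisons are inclusive on both thresholds.
* Empty text, all-stopword text, and units with no scorable tokens are
  well-defined everywhere: empty token lists, undefined scores classified
  irrelevant, empty tables with zero counts.
* Ties break lexicographically (lexicon expansion, top words,
  top-frequent words) or by the documented threshold rule (calibration),
  never by platform hash order.
* An empty ingested corpus produces a zero-count manifest, not an error;
  a failing stage aborts with the stage name and the partial manifest
  attached to the condition.

## Problem sizes

The shipped tests and the acceptance script use: ~2000-post corpora with
3000 training sentences for filter fidelity; 100 random units for the
scoring oracle; 600 documents × 60 tokens for topic recovery; 200
randomized fixtures for table conservation; and 30–60-thread corpora for
pipeline determinism. These sizes were chosen as the smallest at which the
binomial error on recovered rates is comfortably inside the tested bands.

## Limitations

* The lemmatizer is rule-based and English-only; it over-stems some nouns
  and does not attempt part-of-speech disambiguation.
* Subword vectors are inferred, not trained, so out-of-vocabulary handling
  is weaker than a true subword-trained model.
* The LDA point estimate comes from a single chain's final sweep; for
  corpora far larger than the tested sizes, averaging over sweeps would be
  preferable.
* No live platform access, scraping, or API client is included — ingest is
  NDJSON only — and video/audio content is out of scope by design.
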