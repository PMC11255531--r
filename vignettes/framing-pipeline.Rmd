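---
title: "Measuring gendered framing in news reports of suicide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gendered framing in news reports of suicide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framescore)
```

## The problem and the model

News reports of suicide deaths can frame the decedent with stigmatizing
language (ascribing negative attributes to people who die by suicide),
glorifying language (normalising or valorising the act), or language of
isolation and depression. These attitudes are captured by a validated scale
of one-word descriptors, grouped into three dimensions; `framescore`
operationalises each dimension as a *frame lexicon* and measures a text's
alignment with a frame as an embedding similarity rather than a keyword
count, so that paraphrase and context still register.

The pipeline has four stages.

1. **Corpus screening.** Articles are retained when they contain at least
   one suicide keyword (case-insensitive, word-boundary matching) and match
   no exclusion pattern (homicide-suicide, bombings, attempts, euphemisms
   such as "political suicide", and fictional portrayals are screened out,
   because those report types are studied separately in suicidology). An
   excluded article is attributed to the *first* matching rule, so
   exclusion counts partition the corpus — included plus excluded always
   equals the input size.
2. **Decedent resolution.** The unit of analysis is the decedent, not the
   article. Articles whose annotations share one gender are treated as
   reporting a single death and keep the full text with the union of
   annotated circumstances; articles mentioning decedents of different
   genders require a character span per decedent (0-based, half-open
   offsets) and contribute one record per span.
3. **Embedding and scoring.** A frame's centroid is the unweighted mean of
   its expanded terms' embeddings; an article vector is the unweighted mean
   of its sentence embeddings (sentences are split on terminal punctuation
   with abbreviation guards). The framing score is the cosine similarity
   between the two, clamped to $[-1, 1]$ against floating-point drift. No
   normalisation is applied before averaging: cosine similarity is
   scale-invariant, so normalising term vectors would only reweight terms.
4. **Statistics.** Per frame, the two gender groups' scores are compared
   with a two-sided Mann–Whitney U test. Per (circumstance, frame) cell,
   the between-gender divergence is the plug-in mutual information
   $I(G;S)$ between the binary group label $G$ and the binned score $S$.
   Cohen's $\kappa$ summarises coder agreement on the annotation layers,
   and the circumstance table reports per-gender attribution counts with
   percentages.

### Mutual information: estimator and direction

$I(G;S) = \sum_{g,s} p(g,s)\log_2 \frac{p(g,s)}{p(g)p(s)}$, with empirical
cell frequencies over shared equal-width bins of the pooled scores and the
$0\log 0 = 0$ convention. For a binary grouping $I(G;S)\le H(G)\le 1$ bit,
attained exactly when the binned distributions are disjoint and the groups
have equal size, and $I(G;S)=0$ exactly when the binned distributions
coincide. We deliberately report the standard orientation — **larger MI
means more divergent gender-conditional distributions** — and label it so
in every output. Prose descriptions of MI in parts of the applied
literature sometimes invert this reading while still interpreting small
values as dissimilarity; because the estimator behind published matrices
of this kind (binning, base, pairing) is typically unspecified, we make no
attempt to reverse-engineer any particular published matrix and instead
document our estimator completely: 10 shared equal-width bins over the
pooled range by default, configurable per call. Values are in bits.

The plug-in estimator is biased upward in small strata (roughly
$(|G|-1)(|S|-1)/(2N\ln 2)$ bits); cells are reported with their group
sizes so readers can judge, and a cell with an empty gender group is
reported as `NA` rather than silently dropped.

### Mann–Whitney implementation

The U statistic for the first group is the rank-sum with midranks. The
p-value is exact — the full permutation distribution — when
$n_a n_b \le 400$ and the pooled sample is tie-free, and otherwise uses
the normal approximation with tie correction and continuity correction.
The switch point is a documented implementation choice: exact enumeration
at $n_a n_b = 400$ costs nothing perceptible, while cosine scores from a
contextual backend are effectively tie-free only in small samples. When
every pooled observation is identical the samples are indistinguishable
and the comparison reports $U = n_an_b/2$, $p = 1$. No multiple-testing
correction is applied; raw p-values are reported, and users testing many
frames or strata should adjust downstream (`p.adjust`).

### Cohen's kappa

$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the product of the two
coders' marginal label frequencies; $\kappa = 1$ is returned in the
degenerate case $p_e = 1$ (both coders constant and identical), which is
perfect agreement.

### Percentages

Circumstance-table percentages are rounded **half-up** to one decimal
(3.25 → 3.3), matching the convention of published summary tables, rather
than R's banker's rounding.

## Lexicons and synonym expansion

The package ships the nine published example descriptors as default seeds
— three per frame — and accepts complete user-supplied lexicons via CSV
(`frame,term,role`). We deliberately ship no larger invented lexicon: the
full 80-descriptor inventory belongs to the original scale publication.
Seed expansion works through a pluggable `synonym_source` abstraction that
answers synset-style lookups (word and part-of-speech in, lemmas out)
across noun, verb, adjective and adverb classes; a CSV-backed source and
an in-memory list source are provided, and a small hand-authored table
covering the default seeds is bundled for examples. Underscore-joined
multiword lemmas are normalised to space-joined phrases, and the candidate
order is deterministic (seeds first in given order, then lexicographic) so
expansion is reproducible for a fixed synonym-database version.

Pruning is dual-coder: every non-seed candidate needs a keep/remove
decision from every coder, and the default policy `unanimous_remove`
excludes a term only when all coders agree — the conservative choice when
the adjudication rule used by a given annotation team is unknown;
`any_remove` is available. Seeds are never excluded.

## The hash embedding backend

The built-in backend is a feature-hashing embedder: a token maps to a unit
vector with a single nonzero coordinate, with slot and sign drawn from a
seeded 31-bit polynomial hash passed through three Lehmer mixing rounds
(the mixing matters: without it, structured token inventories cover only
part of the slot space). A string embeds as the mean of its token vectors,
so identical strings embed bitwise-identically in any process, and tokens
with disjoint vocabulary are exactly orthogonal up to hash collisions
(probability about $1/D$ per pair). The default $D = 2048$ is chosen to
sit well above the working vocabulary (the synthetic generator's 500
background tokens plus lexicon terms): when $D$ is comparable to the
vocabulary size, each frame-term slot is shared by one or two background
tokens, those collisions give every frame score a small fixed per-seed
offset, and differential injection on *another* frame rescales that
offset between groups — a spurious, rank-detectable contrast on frames
that received no injection at all. Keeping the hash space sparse restores
the property the generator relies on: background text orthogonal to every
frame centroid.

This backend is a test double with useful guarantees, not a semantic
model: it makes injected frame language identifiable by construction,
which is exactly what controlled recovery experiments need. Passing tests
with the hash backend therefore demonstrates that the *pipeline* — the
filtering, resolution, averaging, scoring, ranking and information
estimators — behaves correctly; it says nothing about the semantic
adequacy of any particular pretrained checkpoint. A contextual backend
(e.g. a BERT-family sentence-transformer with mean pooling) plugs in by
providing one `embed_text()` method and a `dimension` field; an analysis
using a real model should document its checkpoint, layer and pooling
choices, since results depend on all three.

## The synthetic corpus generator

`generate_corpus()` emulates the structure of an annotated news corpus
about suicide deaths: decedents with genders at the observed study mix
(153 male to 64 female by default), circumstances drawn per gender from
the observed attribution frequencies of the top seven circumstances,
article text of roughly eight sentences of twelve tokens (about 100 tokens,
enough for binomial injection rates to concentrate), and frame-lexicon
terms injected i.i.d. per token at a configurable (gender, circumstance,
frame) rate. The background vocabulary is synthetic token strings
(`tok0001`, …, disjointness from the real-word lexicons is enforced), so
under the hash backend the background is uncorrelated with every frame
centroid. One circumstance is drawn per decedent — the observed data show
roughly 1.04 attributions per decedent — and multi-circumstance decedents
are constructed explicitly where the stratification logic needs them.
`generate_mixed_gender_articles()` produces two-decedent articles with
valid spans to exercise the span-resolution path.

What the generator does **not** emulate: real news prose (discourse
structure, named entities, reporting verbs), publisher or date effects,
correlated circumstances, or semantic relatedness between background and
frame vocabulary. Recovery results on synthetic corpora therefore validate
the statistical machinery, not the construct validity of embedding-based
framing measurement on real journalism.

## Problem sizes and reproducibility

The recovery experiments use 100 decedents per gender with stigma
injection at 0.15 versus 0.05 (gender contrast) and a 0.2-rate injection
targeted at one circumstance (stratified MI), 20 replicates each with both
the corpus seed and the backend seed varied — sizes chosen to match the
scale of the annotated study sample while keeping a full run in about a
minute. Every random quantity in the package flows from explicit seeds:
the corpus from `synthetic_spec(seed=)`, token vectors from
`hash_backend(seed=)`, and a pipeline run with a fixed configuration is
bitwise-reproducible, which the test suite asserts on the emitted files.

## Known limitations

- Cosine scores from averaged embeddings compress long articles; a single
  stigmatizing paragraph in a long neutral article is diluted. Span-level
  annotation mitigates this for mixed-gender articles but is optional
  elsewhere.
- The plug-in MI has positive small-sample bias and no variance estimate;
  comparisons *between* cells of very different size should be made
  cautiously.
- The default keyword list and bundled synonym table are deliberately
  small placeholders for operational inventories (curated keyword lists,
  WordNet); analyses of real corpora should supply their own via the
  documented CSV/YAML interfaces.
- Non-cisgender decedents are scored but excluded from the default
  two-group comparisons, mirroring the underrepresentation that motivates
  the default gender pair; the pair is configurable.
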