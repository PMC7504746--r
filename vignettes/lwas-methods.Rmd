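---
title: "Literature-wide association for drug repurposing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-wide association for drug repurposing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lwas)
library(dplyr)
```

## The idea

A literature-wide association study (LWAS) treats the biomedical literature
itself as the measurement. The linguistic context of a biological term — the
words that co-occur with it across millions of abstracts — carries
information about what the term *is*: a drug's contexts reflect its targets,
pathways and indications; a disease's contexts reflect its biology and its
therapies. If two diseases are written about in similar ways, drugs known to
treat one become plausible candidates for the other. This is particularly
attractive for rare diseases, where no validated molecular target may exist
to anchor structure-based methods: the only requirement is that people have
written about the disease.

`lwas` implements this inference end to end:

1. **Corpus preparation** — abstracts are cleaned, sentence-split and
   tokenized, with multiword drug and disease names collapsed into single
   hyphenated tokens so each entity is one vocabulary item.
2. **Embedding** — a shallow neural network (CBOW or skip-gram with negative
   sampling) learns a vector for every token from its sentence-level
   contexts.
3. **Similarity** — diseases near a target disease in the embedding space
   (cosine similarity) form its neighborhood; 2D t-SNE maps visualize the
   same geometry.
4. **Repurposing** — the known drugs of the neighborhood diseases, taken
   from a curated drug–disease reference set, are pooled, deduplicated and
   ranked as candidates, then tabulated against a literature annotation
   table.

## Corpus preparation

Cleaning uppercases the text and replaces every ASCII punctuation character
with a space. Two refinements make the later stages well defined:

* **Sentence-terminal marks** (`.`, `?`, `!` followed by whitespace or end
  of text) are kept as standalone tokens until sentence splitting, then
  dropped. A period after a known abbreviation (any single letter, `FIG`,
  `VS`, `ET`, `AL`, … — see `sentence_abbreviations()`) does not end a
  sentence, so "E. coli" survives intact. No published splitting rule
  exists for this pipeline's inputs; this simple, auditable rule is the
  package's own choice, and `split_sentences()` guarantees that
  concatenating its output reproduces the token stream.
* **Raw hyphens are punctuation.** "anti-HER2" becomes `ANTI HER2` *before*
  entity hyphenation, so that a hyphen inside a token unambiguously marks a
  multiword entity joined by the pipeline, never an accident of the source
  text.

Digits are retained (`HER2`, `G01B` and friends carry signal). Multiword
entity matching is greedy leftmost-longest over token sequences,
case-insensitive, driven by a lexicon of surface forms: at each position the
longest lexicon entry starting there wins, the match is joined with `-`, and
scanning resumes after it. This is the standard deterministic behavior of
gazetteer matchers; the overlapping-entity tie (`X Y` vs `Y Z` on
`X Y Z`) resolves to the leftmost match.

## The embedding model

For a center word $w$ with context window $C_w$ (the tokens within $\pm$
`window` positions in the same sentence), the model learns input vectors
$v$ and context vectors $v'$ by minimizing, per training example, the
negative-sampling objective

$$
L = -\log \sigma(h^\top v'_o) \;-\; \sum_{i=1}^{m} \log \sigma(-h^\top v'_{n_i}),
$$

where $h$ is the mean of the context input vectors and $o = w$ (CBOW), or
$h = v_w$ and $o$ ranges over the context words (skip-gram), and the $m$
noise words $n_i$ are drawn from the unigram distribution raised to the
$3/4$ power. The trainer is plain SGD in Rcpp, single-threaded, with its
own multiplicative-congruential RNG, so a given `(corpus, config)` is
bit-reproducible. The exported `ns_loss_grad()` evaluates this loss and its
exact gradient for explicit negative samples; the test suite checks it
against central finite differences for both architectures (relative error
below $10^{-4}$) and checks that training lowers the mean corpus loss under
seeded evaluation draws.

Parameters, defaults, and their status:

| parameter | default | status |
|---|---|---|
| `dim` | 150 | study setting |
| `window` | 5 | study setting (effective window uniform on 1..5 per word) |
| `min_count` | 1 | study setting (every token embedded) |
| `architecture` | `cbow` | study setting; skip-gram selectable |
| `negative` | 5 | package choice (ecosystem convention) |
| `epochs` | 5 | package choice |
| `initial_lr`, `final_lr` | 0.025, 1e-4 | package choice, linear annealing over all words |
| `subsample` | 1e-3 | package choice (frequent-word subsampling) |

The last four are not fixed by the study protocol; they are set to the
conventional defaults of the Word2Vec ecosystem and are all overridable
through `train_config()`. Parallel training is intentionally absent: a
single deterministic worker is the reference mode, and reproducibility is
treated as part of the method's contract.

## Similarity maps and their diagnostics

`project_2d()` is an exact $O(n^2)$ t-SNE: per-point bandwidths calibrated
to the target perplexity by bisection, symmetrized joint affinities, early
exaggeration (factor 12 for the first quarter of iterations, capped at
250), momentum 0.5 → 0.8, adaptive per-coordinate gains, and deterministic
PCA initialization (scaled to $10^{-4}$, with a seeded $10^{-6}$ jitter to
break exact ties). Defaults are perplexity 30 and 1000 iterations. At the
scales this package addresses (tens to a few hundred terms) the exact
method is fast and avoids approximation error as a confounder.

Because t-SNE distances are not metrically meaningful, the package treats
the 2D map strictly as a display: **candidate selection in the default
pipeline happens by cosine k-NN in the original embedding space**, never on
map coordinates. Two tools keep the map honest:

* `trustworthiness(high, low, k)` — the rank-based score in $[0,1]$
  penalizing 2D neighbors that are not true high-dimensional neighbors;
  1 means no intrusions. The suite verifies it is exactly 1 under rigid
  transforms, matches a direct formula evaluation, and sits well below
  faithful layouts for random ones.
* `map_neighbors(map, target, radius)` — an explicit "map mode" that reads
  a Euclidean-radius vicinity off the 2D plot, provided for comparison with
  the k-NN neighborhood, not as a default.

How the original study drew its visual vicinity boundary (fixed k, a
similarity threshold, or a drawn cluster outline) is not stated; all three
are therefore exposed — `k`, `min_similarity` in `similar_diseases()`, and
the map-radius mode — with cosine k-NN as the reproducible default.

## Reference set and vocabulary filtering

The reference set pairs DrugBank-style drug accessions (`DBnnnnn`) with
KEGG-style disease accessions (`Hnnnnn`). Names are resolved to corpus
tokens with exactly the hyphenation used in corpus preparation
(`entity_token()`), so the reference set and the vocabulary can never drift
apart. An entity known under several surface forms (an acronym and its
spelled-out name share one canonical id in the lexicon) passes vocabulary
filtering if *any* form is embedded; the most frequent embedded form is the
one used for similarity. Synonyms of the target are excluded from its own
neighborhood by canonical id — returning "inflammatory breast cancer" as a
disease similar to "IBC" would be vacuous.

Candidate ranking uses `rank_score = max` supporting similarity by default:
one strongly similar indication is sufficient reason to propose a drug, and
a mean would dilute a strong single link with weak ones. `score = "mean"`
is available for sensitivity analysis. Ties break alphabetically.

## The planted-world generator

`generate_world()` / `generate_abstracts()` produce the validation corpus:
disease groups with shared per-group theme vocabularies, per-disease drugs,
and abstracts sampled as mixtures — each sentence position draws a theme
word (p = 0.5), a disease mention (0.2), a drug mention (0.1) or a
background token, for the abstract's assigned group. The default world is
10 groups × 3 diseases × 2 drugs over 2,000 abstracts against a 500-token
background. Disease names cycle 1-, 2- and 3-word patterns so hyphenation
is always exercised, and one drug is shared between two groups so candidate
deduplication is always exercised. `shuffle_groups = TRUE` permutes the
disease-to-group assignment before sampling, which preserves all marginal
frequencies while destroying the planted association — the null control.

The generator is a mixture-of-pools sampler, not a language model. What
passing recovery tests show is that the pipeline recovers distributional
structure *when it exists at the sentence level*; they do not show
robustness to the things real abstracts add — polysemy, negation, section
boilerplate, very skewed term frequencies, entity-name ambiguity — nor how
much corpus a real, subtle association needs. Validation problem sizes
(2,000 abstracts, `dim = 50`, 10 epochs, 5 seeds, k = 2 retrieval against
each target's 2 true group-mates, with chance level 2/29) were chosen as
the smallest world in which the planted signal is unambiguous; at these
sizes retrieval precision and drug recall are expected at or near 1 and the
shuffled null near 0.

## Numerical notes and degenerate inputs

* Empty documents yield zero sentences; an all-`NA` text row is skipped
  with a count. An empty corpus is an error at vocabulary building.
* A sentence of one token generates no CBOW update (no context); training
  on it is a no-op, not an error.
* Cosine similarity with a zero vector is an explicit error
  (`lwas_zero_vector`), not `NaN`; zero-vector candidates are dropped from
  neighbor rankings.
* Exact similarity ties in retrieval break lexicographically, making ranked
  outputs order-stable across platforms.
* Vocabulary order is count-descending with lexicographic tie-break; the
  negative-sampling table is built over that order, so vocabulary identity,
  not construction order, determines training.
* t-SNE bisection runs at most 64 steps per point with entropy tolerance
  $10^{-5}$; affinities are floored at $10^{-12}$.

## Known limitations

* The embedding quality on a real PubMed-scale corpus is not evaluated
  here; packaged fixtures cover the published worked example
  (18 neighborhood diseases → 24 candidate drugs → 19 PubMed / 11
  ClinicalTrials / 4 novel) and synthetic worlds cover the machinery.
* Entity recognition is exact gazetteer matching: misspellings and unseen
  synonyms are missed; there is no disambiguation of a surface form used
  for two different concepts.
* Negative evidence ("drug X failed in disease Y") is indistinguishable
  from positive co-occurrence; the annotation step tabulates literature
  presence, not efficacy.
* Drug-side similarity (proposing by drug-drug neighborhoods) and chemical
  structure descriptors are out of scope.
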