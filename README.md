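# lwas

Literature-wide association studies (LWAS) for drug repurposing.

`lwas` is for computational drug-discovery researchers who want to mine a
literature corpus for repurposing candidates, especially for rare diseases
where no validated molecular target exists to anchor docking or QSAR. The
premise: the textual context of a biomedical term encodes what the term is.
If a target disease is *written about* like certain other diseases, the
drugs known to treat those diseases are candidates for the target.

## Method

1. **Corpus preparation.** Abstracts are uppercased, punctuation-stripped
   and sentence-split; multiword drug/disease names from an entity lexicon
   are collapsed into single hyphenated tokens (`EWING-SARCOMA`), so every
   entity is one vocabulary item.
2. **Word embedding.** A shallow neural network (CBOW by default,
   skip-gram selectable) with negative sampling learns a vector
   $v_w \in \mathbb{R}^d$ for every token $w$ from its context windows
   $C_w$, minimizing per example
   $-\log\sigma(h^\top v'_o) - \sum_i \log\sigma(-h^\top v'_{n_i})$ with
   noise words drawn from the unigram distribution to the 3/4 power.
   Defaults: $d = 150$, window 5, every token embedded. Training is an
   Rcpp single-threaded SGD, bit-reproducible for a given seed.
3. **Disease similarity.** Diseases are ranked by cosine similarity to the
   target in the full embedding space (k-NN default; similarity-threshold
   and 2D-map-radius modes available). Exact t-SNE maps with a
   trustworthiness diagnostic visualize the geometry but never drive
   selection.
4. **Candidates.** The known drugs of the neighborhood diseases, from a
   curated drug–disease reference set (DrugBank-style `DBnnnnn` ×
   KEGG-style `Hnnnnn` pairs), are pooled and deduplicated; each candidate
   is scored by its best supporting similarity, then tabulated against a
   PubMed / ClinicalTrials.gov annotation table.

A planted-world generator (disease groups sharing theme vocabularies, with
known drugs) makes the whole pipeline testable without external data.

## Worked example

The packaged fixtures carry the published worked example: the 18 diseases
found in the embedding-space vicinity of inflammatory breast cancer (IBC)
with their known drugs, and the literature annotation of the resulting
candidates.

```r
library(lwas)
library(dplyr)

refset <- read_reference_pairs(lwas_example("table1_pairs.tsv"))
similar <- tibble::tibble(disease_id = unique(refset$disease_id),
                          similarity = seq(0.99, 0.80, length.out = 18))
candidates <- propose_drugs(similar, refset)
print(candidates, n = 5)
#> # A tibble: 24 × 5
#>   drug_id drug_name   rank_score n_support supporting_diseases
#>   <chr>   <chr>            <dbl>     <int> <list>
#> 1 DB00958 carboplatin      0.99          6 <tibble [6 × 2]>
#> 2 DB00773 etoposide        0.99          3 <tibble [3 × 2]>
#> 3 DB00541 vincristine      0.99          6 <tibble [6 × 2]>
#> 4 DB00997 doxorubicin      0.979         9 <tibble [9 × 2]>
#> 5 DB01030 topotecan        0.968         1 <tibble [1 × 2]>
#> # ℹ 19 more rows
```

The 18 diseases contribute 67 drug mentions that deduplicate to 24 unique
candidates; `rank_score` is each drug's best supporting similarity and
`supporting_diseases` records the provenance. Evaluating against the
annotation table:

```r
annotated <- annotate_candidates(candidates,
  read_annotations(lwas_example("table3_annotations.tsv")))
glance(annotated)
#> # A tibble: 1 × 4
#>   n_candidates n_pubmed_supported n_clinicaltrials n_novel
#>          <int>              <int>            <int>   <int>
#> 1           24                 19               11       4

annotated |> filter(novel) |> pull(drug_name)
#> [1] "topotecan"   "hydroxyurea" "dacarbazine" "cytarabine"
```

19 of 24 candidates have PubMed support in IBC models, 11 reached IBC
clinical trials, and 4 (cytarabine, dacarbazine, hydroxyurea, topotecan)
are supported by neither source — the novel predictions.

An end-to-end run on a synthetic planted world, from raw text to
candidates:

```r
cfg <- generator_config(n_groups = 4, n_abstracts = 400, seed = 42)
world <- generate_world(cfg)
docs <- generate_abstracts(world, cfg)
result <- run_pipeline(list(
  docs = docs, lexicon = world$lexicon, pairs = world$pairs,
  target = world$diseases$disease_name[1], k = 2,
  train = train_config(dim = 50, epochs = 10, seed = 42)))
result
#> <lwas_result> target G01A-SYNDROME, k = 2: 2 similar diseases -> 4 candidate drugs
result$similar
#> # A tibble: 2 × 3
#>   disease_token          similarity disease_id
#>   <chr>                       <dbl> <chr>
#> 1 G01B-STORIFORM-DISEASE      1.000 H90102
#> 2 CHRONIC-G01C-LESION         0.999 H90103

evaluate_recovery(result$similar$disease_token,
                  true_group_mates(world, result$config$target))
#> # A tibble: 1 × 2
#>   precision recall
#>       <dbl>  <dbl>
#> 1         1      1
```

Both retrieved diseases are the target's true planted group-mates.

A thin command-line wrapper over the same functions ships at
`inst/scripts/lwas` (subcommands `synth`, `prepare`, `train`, `map`,
`refset`, `repurpose`).

## Package documentation

See the methods vignette (`vignettes/lwas-methods.Rmd`) for the model,
its assumptions and parameters, the design decisions behind the sentence
splitter, entity matcher, t-SNE and neighborhood modes, and what the
synthetic validation does and does not demonstrate about real corpora.
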