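# litmine

Literature-mining pipelines for systematic review automation, in R.

Evidence synthesis teams screen thousands of citations per review, and a
growing class of tools uses large language models to automate the three
stages of that work: generating the boolean search strategy, screening
candidate citations against eligibility criteria, and extracting
structured data from the selected trial publications. litmine implements
those three stages as a backend-agnostic framework, together with
everything needed to develop and verify such a system **offline, without
a trained model**: a seeded synthetic linked corpus with planted ground
truth, an in-memory boolean search engine, deterministic oracle and
noisy-oracle backends, a six-task instruction-dataset builder, and the
evaluation protocol (recall at K, exact numeric matching, cosine soft
text matching, difficulty-binned breakdowns).

It is aimed at researchers building or benchmarking review-automation
systems, and at methodologists who need a controlled testbed where every
pipeline stage has known truth.

## The models at the core

**Search.** For a review with N ground-truth studies, per-study keyword
sets P·n (population) and I·n (intervention), each at most M = 10 terms,
aggregate as

    S_P = S_P1 OR … OR S_PN,   S_Pn = p1_n AND … AND pM_n
    S_I = S_I1 OR … OR S_IN,   S_In = i1_n AND … AND iM_n
    S   = S_P AND S_I

Queries with recall below 0.2 on the review's truth set are discarded as
poorly generated. Ensembled generation samples several queries under
run-indexed seeds and returns the deduplicated union of their rankings,
so ensemble recall never decreases with more runs.

**Screening.** Each candidate is assessed per criterion with labels
YES / PARTIAL / UNCERTAIN / NO mapping to scores 1 / 0.5 / 0 / −1; the
final eligibility score is the mean of the criterion scores, and
candidates rank by descending score (ascending-id ties). Pools hold up
to 2,000 candidates published strictly before the review, topped up from
single-element queries when the primary search runs short.

**Extraction.** Four tasks — study characteristics, arm design,
participant statistics, trial results — with typed schemas, fenced-JSON
backend answers, and validation (unique arm labels, referenced group
ids, numeric normalisation). Numeric fields score by exact match after
stripping separators/percents/units; text fields by embedding cosine at
an inclusive 0.75 threshold (deterministic hashed 3-gram embedder by
default).

## A worked example

```r
library(litmine)

corpus <- generate_corpus(synthetic_config(
  n_reviews = 3, included_per_review = 5, distractors_per_review = 45,
  seed = 42
))
backend <- oracle_backend(corpus)   # answers from planted truth

run_search_pipeline(corpus, "R001", backend, n_runs = 1)
#> # A tibble: 1 × 5
#>   review_id n_runs n_hits recall n_truth
#>   <chr>      <int>  <int>  <dbl>   <int>
#> 1 R001           1      5      1       5

ranked <- run_screening_pipeline(corpus, "R001", backend, pool_size = 100)
attr(ranked, "recall")
#> [1] 1
head(ranked, 3)
#> # A tibble: 3 × 8
#>    rank study_id final_score label_P1 label_I2 label_C3 label_O4 rationales
#>   <int> <chr>          <dbl> <chr>    <chr>    <chr>    <chr>    <chr>
#> 1     1 34460693           1 YES      YES      YES      YES      "[\"study meet…
#> 2     2 35505922           1 YES      YES      YES      YES      "[\"study meet…
#> 3     3 43841185           1 YES      YES      YES      YES      "[\"study meet…

sid <- corpus$inclusion_truth[["R001"]][1]
extract_structured("arm_design", NULL, corpus$studies[[sid]], backend)[[1]]
#> $label              "Arm A1"
#> $arm_type           "EXPERIMENTAL"
#> $description        "participants receiving sumatriptan"
#> $intervention_names "sumatriptan"
```

The search recall of 1 says the assembled query retrieved all five
ground-truth studies; the screening recall of 1 says all five occupy the
top five ranks of the scored pool; the arm record reproduces the
registry truth embedded in the study's pseudo full text. Swapping
`oracle_backend()` for `noisy_oracle_backend(corpus, error_rate = 0.1)`
or an API adapter changes no pipeline code.

A thin command-line dispatcher ships in `inst/cli/litmine.R`:

```sh
Rscript inst/cli/litmine.R screen --corpus corpus.json --review R001 \
  --pool 2000 --backend oracle --out ranked.csv
```

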