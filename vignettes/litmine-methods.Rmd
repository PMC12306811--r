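---
title: "Mining the medical literature offline: models, oracles, and design choices in litmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the medical literature offline: models, oracles, and design choices in litmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmine)
```

litmine implements the three pipeline stages that systematic-review
automation systems built on large language models perform — search-query
generation, citation screening, and structured data extraction — together
with the machinery needed to develop and test such a system without a
trained model: a synthetic linked corpus with planted ground truth, an
offline boolean search engine, deterministic oracle backends, an
instruction-dataset builder, and the evaluation protocol. This vignette
explains the underlying models and the design decisions a maintainer
would want to know about.

## The search model

A review question is framed by its PICO elements (Population,
Intervention, Comparator, Outcome). For a review with $N$ ground-truth
included studies, per-study keyword sets are extracted by a generative
backend: population terms $P_n = p_1^n, \dots, p_M^n$ and intervention
terms $I_n = i_1^n, \dots, i_M^n$ with at most $M = 10$ terms per list.
They aggregate into a single boolean strategy

$$
S_P = S_{P_1} \,\mathrm{OR}\, \dots \,\mathrm{OR}\, S_{P_N}, \qquad
S_{P_n} = p_1^n \,\mathrm{AND}\, \dots \,\mathrm{AND}\, p_M^n,
$$

likewise $S_I$, and the final query $S = S_P \,\mathrm{AND}\, S_I$
(`assemble_query()`). A synthesized query is kept only if its recall
against the review's truth set reaches 0.2; queries with recall below
that threshold are discarded as poorly generated (`filter_by_recall()`).
The threshold boundary is *inclusive-keep*: "recall below 0.2" drops, so
exactly 0.2 survives. Conjoining up to ten terms per study is a very
restrictive predicate against real abstracts, so the inner connective is
configurable (`inner_connective = "or"`); the default follows the
AND-inner form above.

Ensembled generation (`ensemble_generate()`) samples `n_runs` queries
under run-indexed seeds (`seed + run`), executes each, and concatenates
the per-run rankings with first-occurrence deduplication. Because the
result is a union, ensemble recall is non-decreasing in the number of
runs; the tests verify both the union identity and the monotone mean
recall under a noisy generator. Runs that fail to parse are skipped, not
fatal — aggregation is best-effort — and only an ensemble whose every run
fails raises.

## The offline search engine

Real pipelines execute strategies against PubMed; litmine evaluates them
against the in-memory corpus so everything is testable without a network.
A term matches a document iff the term's tokens occur as a contiguous,
case-insensitive token subsequence of title + abstract — phrase matching,
not substring matching, so "art" never matches "heart". Stemming is off
by default, with a light suffix stripper behind `stem = TRUE`. Retrieval
order is publication date descending with ties broken by ascending study
id: a deterministic stand-in for a search engine's undocumented relevance
ranking. This is an explicit limitation — when more results exist than the
retrieval limit, a live engine's ordering (and hence recall at 3000)
cannot be replicated offline, and litmine does not claim to approximate
it; it substitutes a documented, reproducible order instead.

## The screening model

Each candidate is assessed criterion-by-criterion. Criteria are
categorised into P, I, C, or O; when a review carries no explicit list,
one criterion per non-empty PICO element is derived. Labels map to scores
YES $\to 1$, PARTIAL $\to 0.5$, UNCERTAIN $\to 0$, NO $\to -1$
("Partially Yes" is the same label as PARTIAL), and the final eligibility
score is their arithmetic mean, so it lies in $[-1, 1]$ with the extremes
exactly at all-NO and all-YES. Exclusion-role criteria are phrased so a
YES still means "the study satisfies this requirement" — the negation
lives in the assessor prompt — which keeps the aggregation formula
sign-free for both roles; the formula is applied identically to inclusion
and exclusion criteria. A criterion answer that fails to parse degrades
to UNCERTAIN (score 0) with rationale `"unparsed"` and a warning rather
than failing the study: the ranking must stay total. Ranking is by
descending final score with ascending-id tie-breaks, making recall at K
deterministic.

Candidate pools mirror practice: query-derived hits first, restricted to
studies published strictly before the review (same-day excluded; records
with no date are skipped with a warning, since real bibliographic data
loses dates), then topped up from single-element queries over the other
PICO elements — population, then intervention, then outcome — up to the
pool cap of 2,000. Score stratification into the bands $[-1, -0.5]$,
$(-0.5, 0.75)$, $[0.75, 1]$ supports comparing model assessments with
expert decisions.

## The extraction model

Four tasks: study characteristics (default schema: conditions,
interventions, enrollment, study type — extensible via `field_spec()`
lists), arm design (label, type, description, interventions; labels
unique), participant statistics (measure definition, parameter type,
unit, groups with ids; results reference known group ids only), and trial
results (outcome/group definitions, parameter type, unit, timeframe,
denominator; results are value–title pairs). Backends answer with fenced
JSON; parsing is lenient about missing optional fields (absent markers)
but never coerces across value kinds, and derived numerics (e.g. a mean
age that requires computation) are the backend's job — the framework
validates, it does not recompute. Documents are truncated to a
whitespace-token budget (default 30,000 tokens, matching the long-context
budget such pipelines assume) with title + abstract always retained
first; a model tokenizer can replace the whitespace count via a hook.

## Evaluation

Recall at $K$ is the fraction of truth studies in the top $K$; the strict
search variant sets $K$ to the truth-set size. Numeric fields score by
exact decimal equality after normalisation (thousands separators, percent
signs, and unit words stripped); an unparseable prediction scores
incorrect rather than raising. Text fields score by embedding cosine at a
0.75 threshold, inclusive at the boundary (the source descriptions of the
rule are ambiguous between "threshold of" and "exceeding"; litmine fixes
$\ge$ and documents it). The default embedder is a hashed character
3-gram count vector (FNV-1a folded into a fixed dimension, default 512) —
fully deterministic and network-free, so scores are reproducible; which
embedding model a production system uses is left backend-pluggable.
List-valued fields are scored element-wise, aligned by key where one
exists (arm label, group id) and by position otherwise. Difficulty
breakdowns bin reviews by truth-set size (width 5) and report mean recall
with a normal-approximation 95% interval, omitted for bins under ten
reviews.

## The synthetic corpus and what it does (not) show

The generator (`generate_corpus()`) emulates the linked structure such
pipelines are trained on: reviews with PICO frames and criteria; included
publications whose titles/abstracts contain the review's planted
population and intervention terms plus one study-specific term of each
kind; distractors sharing a Binomial(`overlap_rate`)-thinned subset of
the review-level terms; and registry-derived structured truth (arms,
enrollment, participant measures, outcome results) embedded verbatim in
each included publication's pseudo full text and tables, so extraction is
verifiable round-trip. Defaults — 10 reviews, 10 included plus 90
distractors each, vocabulary 400, overlap 0.3 — are sized so that a
desk-scale corpus still contains genuine confusers; overlap 0.3 makes the
expected distractor share several review terms without satisfying the
full conjunctive query. Roughly one distractor in ten postdates its
review so the time constraint has real work. Identifiers are PMID-like
8-digit strings (ascending lexical order equals numeric order, which the
tie-break relies on) and `NCT` + 8 digits for registry links; identical
configurations, including the seed, reproduce byte-identical corpora.

What passing tests on this corpus show: the algebra (query assembly,
score aggregation, ranking, union ensembling), the contracts (schema
closure between backends and parsers, round-trip serialization), and the
calibration of the ranking rule under controlled noise. What they do not
show: term-extraction quality on real abstracts, PubMed's matching and
ranking behaviour, OCR/PDF noise in real full text, or the ambiguity of
real eligibility criteria. The oracle backends answer from planted truth
and exist to make every stage verifiable, not to emulate a model's error
profile; the noisy oracle corrupts the oracle at a configurable rate
(eligibility YES labels flip to NO per criterion; query terms are
replaced by junk) as a pure function of prompt and seeds, which is what
makes the analytic recall expectation checkable: distractors score
exactly $-1$ under the oracle's all-NO analyses, a truth study joins them
only when all $C$ of its YES labels flip (probability $\varepsilon^C$),
and $-1$ ties resolve by ascending id, giving a closed-form top-rank
probability per truth study.

## Numerical and scale choices

Test and acceptance runs use deliberately small problem sizes — corpora of
5–10 reviews with 14–200 candidates per review, pools of 40–200, 20–200
noisy replicates — chosen as the smallest sizes at which the checked
properties are non-trivial (multiple truth-set size bins, pools larger
than truth sets, enough replicates for a meaningful binomial interval).
Instruction building balances eligibility records 1:1 per review by
uniform negative sampling under the dataset seed (the balancing ratio is
a design choice; sources describing such datasets say "balanced" without
a number), drops ground-truth-included records whose generated analysis
aggregates below zero, and assigns train/dev/test 6:2:2 at the *review*
level so no review leaks across splits. All derived seeds stay below
$2^{31}$.

## Known limitations

The offline engine's deterministic ordering cannot reproduce a live
search engine's relevance ranking; adapters for PubMed E-utilities and
ClinicalTrials.gov v2 are provided as parsers plus a thin HTTP layer but
are deliberately outside the test surface. The generator's language is a
pseudo-term vocabulary: it exercises tokenisation, phrase matching, and
determinism, not linguistic variation. Prompt templates are original
compositions describing each task's inputs and output contract; systems
trained with other prompts will behave differently, which is why every
template is versioned and recorded in the instruction datasets it
produces.
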