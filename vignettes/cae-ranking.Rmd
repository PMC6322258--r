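---
title: "Identifying conclusive association entities: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying conclusive association entities: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(caerank)
```

## The problem

A biomedical article's title and abstract mention many genes, diseases and
chemicals, but database curators record only the few entities that the
article's *conclusions* are actually about — its conclusive association
entities (CAEs). Given a controlled vocabulary (IDs with official names,
symbols and synonyms for the three entity types), `caerank` detects the
candidate entities of each article and ranks them so that the CAEs surface
at the top. Ranking, rather than classification, matches the curation
workflow: a curator inspects a short prioritized list per article.

## Candidate detection

Abstracts are segmented by a rule-based splitter (a run of `.?!` followed
by whitespace and an uppercase letter or digit ends a sentence, guarded
against decimals, single-letter initials and common abbreviations such as
"e.g." or "et al."). Tokens are maximal alphanumeric runs with internal
hyphens, so "2-bromolisuride" is one token. The title is deliberately *not*
a member of the abstract sentence list: sentence-level statistics (CoOcc,
AbstractX) operate on abstract sentences only, while title occurrences
feed TF and the TITLE flag.

Dictionary matching is three-pass and gold-first. When curated CAEs are
supplied for an article, their surface forms (official names *and*
synonyms) are matched first — their presence is already confirmed, so the
matcher must never lose them. Then official names of all entities are
tried, and finally synonyms of entities whose official names did not
appear. Matching is longest-match-first, left to right; a token span feeds
at most one mention, so TF is never double-counted. Matching is
case-insensitive except for short all-uppercase symbols (≤ 4 characters),
which match case-sensitively — the standard compromise that keeps gene
symbols like *WAS* or *CAT* from firing on common words. A surface form
owned by several entities yields a mention for every owner unless a
priority id resolves the ambiguity.

Authors introduce their own short forms in parentheses ("dopamine (DA)").
When the tokens before a parenthesised short form match a lexicon surface,
the short form maps to that entity for the rest of the article; the first
definition wins, and short forms that are themselves lexicon surfaces are
left to ordinary matching. The defining parenthesised token is consumed
without emitting a mention — the definition itself is not an occurrence,
so an article defining an abbreviation it never reuses gains no TF from it.

## Indicators

Per (entity, article) pair, six indicators are assembled
(`build_features()`):

* **TF** — mentions of *e* anywhere in *a* (title included);
* **IDF** — `log2((|A|+1) / (DF(e)+1))`, the +1 smoothing keeping unseen
  entities finite;
* **CoOcc** — over abstract sentences, the sum across co-candidates *x* of
  `|S_e ∩ S_x| / |S_e|`; a title-only entity has an empty sentence set and
  scores 0 (the division is guarded, never NaN);
* **AvgTF** — `c(e,C) / DF(e)`, the micro-average frequency; ≥ 1 for any
  observed entity, undefined (error) for DF = 0;
* **TITLE** and **AbstractX** (X ∈ {1,2,3}) — binary locality flags; an
  abstract with ≤ 2X sentences makes every abstract-located entity
  boundary-eligible, which is the honest reading of "first X or last X".

Collection statistics come from the *training* articles under
cross-validation, so no test-fold information leaks into IDF or AvgTF. At
prediction time an entity unseen in the reference collection takes the
smoothed IDF and an AvgTF floor of 1 — the least-informative value an
observed entity could have.

## Fusion

Two families combine the indicators. The parametric scorers are TFIDF,
BM25e (k1 = 1.2, b = 0.75 by default — the standard BM25 settings, since
nothing in the problem fixes them; both configurable), ESe (its constants
are part of the formula), positional CCSEe, and the rule-counting eGRABe.
CCSEe's weight profiles are configuration: by default the title
contributes 1, and both the leading and trailing three sentences carry
linearly decaying weights (1, 2/3, 1/3 counted outward from the boundary).
Profiles are indexed from their boundary — element 1 of the conclusion
profile applies to the *last* sentence — which keeps "linearly increasing
toward the end" and "highest weight at the end" the same statement. Every
mention contributes, so an entity spread across title, opening and closing
sentences is amplified.

The learned fusion trains a linear model by pairwise ranking: within each
training article, every (CAE, non-CAE) candidate pair contributes the
difference of their z-scored feature vectors labelled +1, and its negation
labelled −1; a soft-margin linear SVM (cost C = 1 by default) fits the
separator, and candidates are scored by the learned linear combination.
The symmetric ±pair construction centres the problem so the intercept is
irrelevant; z-scoring puts binary flags and unbounded counts on one scale;
a feature constant in training is scaled to zero contribution rather than
NaN. Articles lacking either a CAE or a non-CAE candidate yield no pairs
and are skipped (counted in the model metadata). The default feature set
is {TF, IDF, CoOcc, AvgTF, TITLE, Abstract2}; ablations drop one member
(`feature_set_all_minus()`).

Every ranking — from any scorer — breaks score ties by entity id
ascending, making all downstream metrics deterministic. The tie rule also
resolves the ambiguity in "entities ranked higher than or equal to" that
otherwise afflicts average precision under tied scores.

## Evaluation

Per article, average precision is the mean over its k CAEs of `j /
rank(j-th best CAE)`; MAP averages over articles. Precision at X keeps X
in the denominator even when fewer candidates exist. %P@X>0 is the share
of articles with any CAE in the top X; since P@1 is 0/1 per article,
%P@1>0 always equals 100 × Average P@1 — a useful internal consistency
check that the tests exercise. Gold CAEs absent from an article's
candidates are dropped from k with a reported count; articles whose gold
CAEs are all absent are excluded and counted. Cross-validation shuffles
articles by seed into five near-equal folds; a fold plan reused across
scorers keeps test memberships identical, which is what makes paired
t-tests on per-article AP valid. The t-test is two-sided at α = 0.01;
numerically constant differences short-circuit to certainty (or to the
null when the constant is zero) rather than erroring.

## Distribution analysis and the frequency–recency map

For any indicator, the value spectrum is split into 20 equal-width
intervals over [0, max] (one bin per integer for TF; a percent-of-maximum
reading of the bins falls out of this anchoring), and per interval
the CAE prevalence, non-CAE prevalence and the probability gain — the
interval's CAE rate minus the overall CAE rate — are computed. The
entity-count-weighted mean of the gain is zero by construction, which the
acceptance tests assert exactly. Positional profiles assign each *mention*
to one of 20 relative-position parts (words or sentences), with title
mentions as a separate leading category.

For curation support, the top-k (default 2) ranked entities of each
article are treated as its predicted CAEs; each entity is then placed by
frequency (articles predicting it) and recency (mean publication year).
Thresholds partition the plane into zones I (frequent/older), II
(frequent/recent), III (infrequent/older) and IV (infrequent/recent) —
zone IV is where newly emerging entities live. A focused view rebuilds the
map over the articles where one entity of interest is predicted, excluding
the entity itself. Articles without a publication year are skipped from
recency computations only, with a count.

## The synthetic generator

Real curated corpora are large and behind downloads, so the generator
emulates the contrasts the indicators exploit, with every knob explicit:
CAE mentions are drawn at a higher Poisson rate (counts are 1 + Poisson,
so every candidate appears), land in the title and in boundary sentences
with higher probability, and a "focal" quarter of the vocabulary — the
entities articles tend to conclude about — has its mention counts
multiplied by a concentration boost, raising AvgTF corpus-wide; CAE slots
prefer focal candidates. Entity popularity is Zipf-distributed, spreading
document frequency and hence IDF. Some articles introduce a parenthesised
author abbreviation on an entity's first abstract mention and use the
short form afterwards, exercising abbreviation resolution end to end.
Entity names are collision-free synthetic strings so matching behaviour
stays analyzable; an ambiguity knob optionally shares synonyms between
entity pairs to exercise the multi-owner path.

Defaults (300 articles, 200 entities, 4–10 candidates and 1–3 CAEs per
article, rates 1.0/0.5, title 0.35/0.15, boundary 0.45/0.30, boost 3,
Zipf 1, 5–10 sentences, years 2005–2016) were chosen once as moderate
contrasts: strong enough that informative indicators separate classes,
weak enough that no single indicator is perfect and fusion has something
to learn. What passing tests on such corpora shows is that the machinery
is correct and directionally faithful; what they cannot show is
performance on real prose — the generator has no linguistic structure, no
curation noise, no species ambiguity, and its lexicon is tiny next to a
2.5-million-term vocabulary.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; library code saves and
  restores the caller's RNG state.
* Ranking ties: entity id ascending, everywhere.
* CoOcc with an empty sentence set, sole candidates, empty candidate sets
  (flagged, excluded from metrics with a count), and abstracts shorter
  than 2X sentences are all defined, not errors.
* ESe is undefined at DF = 0 and errors on direct calls; during ranking
  (where held-out articles may contain entities unseen in training folds)
  it scores such entities as if seen exactly once — the weakest
  concentration signal consistent with the formula.
* Test and acceptance problem sizes — corpora of 15–300 articles,
  vocabularies up to 200 entities, 5 seeds for directional claims, 1000
  replicates for the t-test level, 40 shuffles against the analytic random
  baseline — were picked so the full suite completes in under two minutes
  while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

Statistical NER, species disambiguation and ontology mapping beyond the
provided lexicon are out of scope; the dictionary matcher is only as good
as the vocabulary. The positional CCSEe weights are a parameterization,
not a fitted scheme. MEDLINE parsing is a best-effort convenience for
PMID/TI/AB/DP records. The frequency–recency views are emitted as static
plots and tables; interactive navigation is not attempted.
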