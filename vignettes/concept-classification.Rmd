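---
title: "Concept-based classification of radiology reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-based classification of radiology reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the model

`radconcept` classifies free-text radiology reports by the lung-carcinoma
concept they mention: 1 = lung carcinoma (UMLS CUI C0684249), 2 =
non-small cell lung carcinoma (C0007131), 3 = small cell lung carcinoma
(C0149925), or 0 = none. The primary model is a dictionary-driven
rule-based recognizer; tf-idf + gradient-boosted trees and two Bi-LSTM
networks serve as statistical baselines trained on the *binary* task
(any concept vs none), because per-concept classes in a realistic corpus
are far too small for supervised training.

### Rule-based recognition

Every lexicon synonym is compiled to a literal pattern anchored at token
boundaries. A phrase matches when it is preceded by start-of-text or
whitespace and followed by end-of-text, whitespace, or one of `.` `,`
`;` `)`. This boundary set is reconstructed from the punctuation-attached
dictionary variants (`"nsclc,"`, `"nsclc."`, `"nsclc)"` …): treating
trailing punctuation as a boundary is exactly what lets those mentions
match, while the preceding-boundary requirement guarantees that the
concept-3 pattern `"sclc"` can never fire inside `"nsclc"`.

A report is labeled by the match with the **minimal character offset**
across all concepts — "whichever phrase comes first" — and only that one
match is extracted. Absence of a match is the explicit value `"NA"`
(label 0), not an error. Assumptions worth stating:

* matching runs on the cleaned, whitespace-squashed unified text
  (findings ⧺ " " ⧺ impression), all lowercase; offsets are 0-based into
  that text;
* negation is *not* modeled (a deliberate scope decision; the corpora
  this emulates carry essentially no negated concept mentions);
* laterality/lobe-interrupted phrasings ("ca left lung") are known
  misses of the boundary-anchored design, and the synthetic generator
  emits them as labeled hard negatives so the behavior is tested rather
  than hidden.

**Generative templates** (on by default, `enable_generative = FALSE` for
strict-dictionary behavior) add two concept-1 morphological patterns:
`(adeno | <squamous-variant> cell)? (ca|ca.|carcinoma) lung` and
`lung (adeno)?carcinoma`. They reproduce the observed ability of the
rule set to catch histology+site collocations that were never listed
explicitly ("adenoca lung", "adenocarcinoma lung"). Both spellings
"squamous" and the recurrent report misspelling "sqaumous" are accepted.

**Tie-breaking.** Two patterns can match at the same offset (e.g.
`"nsclc"` and `"nsclc,"`). Ties are resolved by the longest surface
form, then the lowest concept index. This rule is an implementation
choice — the phrase inventory produces no semantically ambiguous ties —
and is documented precisely because it is the one place where behavior
is not forced by the earliest-match principle.

### The lexicon

A mapping file is CSV with columns `preferred_label`, `cui`,
`concept_index` and pipe-separated `synonyms`. Synonyms are lowercased
on load (the cleaning stage lowercases all report text, so case carries
no information), must be unique across entries, and CUIs must match
`C\d{7}`. The bundled default carries the three-concept phrase
inventory, including the misspelling `sqaumous cell ca lung` verbatim.

Customization mirrors the expert workflow: `propose_aberrant_terms()`
enumerates corpus 1–3-grams containing an anchor token (`lung`, `ca`,
`carcinoma`, `nsclc`, `sclc`), drops known synonyms, and ranks by
frequency (ties lexicographic). Candidates are *never* auto-added —
acceptance is a human decision applied with `add_synonyms()`, which is
idempotent and rejects phrases owned by another entry.

## Corpus handling

* **Anonymization** removes `case_number`, `gender`, `name`; a pseudo-id
  permutation (deterministic given the seed) breaks the link between
  record order and identity, and the lookup table is the only place the
  mapping survives.
* **Cleaning** lowercases and excises configured reporting-doctor
  signatures as literal strings — list-driven rather than
  pattern-guessing, because deterministic and auditable beats clever
  here.
* **Selection** filters by modality (default CT, PET/CT), calendar year
  (the year-range reading; full dates are parsed only for logging) and
  disease-management-group tag; a record is *blank* (and dropped) when
  findings and impression are both empty after cleaning. Exclusion
  counts per filter are recorded so record-count conservation can be
  asserted.
* **Preprocessing** applies exactly three steps in order: whitespace
  tokenization, stop-word removal, special-character removal. The
  stop-word list is a compact English function-word list; the
  protected-token list `{non, no, not, small, cell}` is excluded from
  removal so that `"non small cell lung carcinoma"` can never be
  destroyed by preprocessing. Because the rule matcher needs
  punctuation-attached variants, NER runs on the *cleaned* unified text;
  the stop-word-stripped normalized text feeds the ML/DL vectorizers.
  `preprocess()` rejects uppercase input to enforce pipeline order, and
  `strip_punct = FALSE` exposes the punctuation-retaining token stream
  for experiments on that choice.

## Baselines

### tf-idf + boosted trees

The vectorizer uses smoothed idf (`ln((1+n)/(1+df)) + 1`), raw counts as
tf, L2-normalized rows, unigrams+bigrams, minimum document frequency 2 —
a standard variant chosen once and kept configurable; a single-document
corpus degenerates to equal idf without error, and unseen terms
contribute nothing at transform time.

The learner is in-package second-order gradient boosting (logistic
loss, exact greedy splits, L2 leaf regularization λ = 1). The default
search grid is depth {3, 6} × learning rate {0.1, 0.3} × rounds
{50, 200}, overridable by any data.frame.

**Nested CV protocol.** Per trial: a fresh stratified 5-fold outer
shuffle; per outer fold, grid search by stratified inner CV (default 3
folds) fit **only on the outer-training partition** — including the
tf-idf vectorizer, so outer-test vocabulary cannot leak into model
selection (the leak is asserted away in the tests by planting a
fold-unique token). "20 trials" is read as 20 repetitions of the whole
nested procedure under different shuffle seeds, reported as mean (SD)
across trials in the `0.748(0.006)` style. The final model refits the
most frequently selected configuration on the full corpus. A `"global"`
vectorizer mode exists purely for comparison with the leaky variant.

### Bi-LSTM classifiers

No deep-learning framework is assumed: the networks are implemented in
R (forward and backward passes written out, Adam, global-norm gradient
clipping at 5), and the backward pass is verified against central finite
differences in the test suite — that check is the ground truth for
correctness of the implementation.

Two fixed architectures follow the stated layer counts, under the
documented counting convention (a bidirectional LSTM is one layer;
dropout layers count):

* `simple` (5): embedding → Bi-LSTM → Bi-LSTM → dense → sigmoid output;
* `dropout` (13): the same recurrent trunk with a dropout layer after
  the embedding, after each Bi-LSTM, and after each of three dense
  layers (inverted dropout, default rate 0.3).

Defaults (embedding 32, hidden 16 per direction, sequence length 200,
sigmoid head) are desk-scale: 5-fold CV on ~1,500 short synthetic reports
finishes in minutes on one CPU. The classifier reads the concatenated
final hidden states (forward at the last step, backward at the first).
Padding uses reserved index 0 with a frozen zero embedding; there is no
masking, which is acceptable at these sequence lengths and is stated
here so a green test is not over-read. Training is a stratified 70:30
split (`train_bilstm()`) or stratified k-fold CV (`crossval_bilstm()`),
with vocabulary built from training texts only. Because the backend is
plain R, training is *exactly* reproducible from the seed — there is no
nondeterministic kernel to log around.

## Evaluation machinery

Sensitivity, PPV, NPV, accuracy and F1 are computed from confusion
counts; a metric whose denominator is zero is reported as an explicit
undefined marker (`NA`), never silently 0 — the zero-false-positive
regime makes this distinction observable (PPV = 1 exactly vs PPV
undefined). F1 is the harmonic mean of PPV and sensitivity wherever both
are defined. Report tables round half-away-from-zero to 2 decimals
(matching printed precision conventions); full-precision values are
always retained. "Overall" metrics are computed on the binary task;
per-concept metrics one-vs-rest, with both micro- and macro-style views
derivable from the persisted per-concept counts.

Bootstrap evaluation resamples indices with replacement to the original
set size (default 20 trials), recomputes all metrics per trial, and
reports mean (SD) formatted `0.77(0.02)`. A trial whose resample lacks a
class leaves the affected metrics undefined for that trial; undefined
trials are excluded from the aggregate with a logged count. AUC is the
midrank Mann–Whitney statistic; curve points are exportable.

## The synthetic world

The generator emulates the corpus the pipeline assumes — it is a stated
world, not a tuning dial:

* class mix defaults to 896/571/29/4 per 1,500 (the internal-corpus
  composition); counts are exact by largest-remainder apportionment;
* `variant_rate = 0.4`: probability a positive uses an abbreviated /
  punctuation-attached / misspelled surface form instead of the
  canonical phrase — corpora of this kind are described as rich in
  colloquial and abbreviated forms, so a substantial minority rate is
  realistic;
* `hard_negative_rate = 94/604 ≈ 0.156`: the fraction of concept-1
  positives emitted with interrupted phrasing (gold label 1,
  `rule_expected` 0), matching the documented false-negative share;
* modality 60:40 CT:PET/CT, years 2014–2016, short (3–8 sentence)
  reports with identifiers and doctor signatures — realism is secondary
  to controlled statistical structure;
* the external-style generator shifts the dialect: sectioned headers,
  expanded phrase preference, and out-of-dialect disease phrasings
  ("bronchogenic carcinoma", "oat cell carcinoma") for a fixed 40% of
  positives — the level implied by a 0.84 → 0.60 sensitivity drop — so
  the generalization-drop phenomenon can be exercised without any
  external data.

What a green test does and does not establish: gold labels are correct
by construction and verified by an independent brute-force scanner, so
clean-injection recovery and zero false positives are statements about
the *rule engine's* correctness on its stated inputs. They are not
evidence about real reports, which carry negations, templates, OCR
noise and dialects the generator does not model.

## Numerical and degenerate-input choices

* Half-away-from-zero rounding at 2 decimals for report tables (base R
  `round()` half-to-even would print 0.905 as 0.90).
* Empty text → no match (`"NA"`); empty corpus proposals → empty list;
  empty selection → warning, not error; all-zero confusion → error.
* Boosted-tree hessians are floored at 1e-12; the base score clamps the
  class rate to (1e-6, 1−1e-6).
* Bi-LSTM losses use a 1e-9 probability floor; the forget-gate bias
  starts at 1; Glorot-uniform initialization throughout.
* All stochastic operations run under a locally seeded RNG that is
  restored afterwards, so package calls never perturb a caller's RNG
  stream, and trial *t* of a repeated procedure uses `seed + t`.

## Known limitations

* No negation, laterality, lobe, staging or multi-mention extraction —
  the first match decides the label, by design.
* The bundled stop-word list and the ML grid are package choices; the
  originals for the emulated setting are not public. Both are
  configurable and documented rather than guessed at silently.
* The Bi-LSTM is CPU-scale with no pretrained embeddings or masking;
  it exists to make the comparison harness complete and testable, not
  to chase state of the art.
* Dataset-level headline scores from any particular hospital corpus are
  not reproducible here; the package reproduces *procedures* and
  verifies them on the synthetic world plus worked-example arithmetic.
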