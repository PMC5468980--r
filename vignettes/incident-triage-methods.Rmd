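---
title: "Methods: binary-classifier ensembles for incident-report triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binary-classifier ensembles for incident-report triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incidenttriage)
```

## The problem and the model

Patient safety incident reports are short free-text narratives that must
be routed by *incident type* (11 categories: 10 priority types plus
"others") and by *severity assessment code* (SAC1 extreme risk … SAC4 low
risk). Both are multiclass single-label problems. `incidenttriage`
solves them by problem transformation: the `l`-class task is decomposed
into binary sub-problems, each handled by a discriminative binary
classifier, and the binary outputs are combined by a group decision
scheme.

**Decompositions.** One-versus-one trains `l(l-1)/2` classifiers, one per
unordered label pair, each on the reports of its two classes only.
One-versus-all trains `l` classifiers; each contrasts `per_class_n`
positives of the target class against `per_class_n` negatives subsampled
as evenly as possible from the other `l-1` classes (floor division,
remainder round-robin in scheme order, seeded) so the binary task stays
balanced.

**Decision schemes.**

* *Voting* (OvsO): each pairwise classifier votes by the sign of its
  decision score (an exact 0 votes for the pair's first label — a
  documented edge case); the label with the most votes wins. Ties break
  by the largest summed calibrated probability over the tied labels'
  contests, then by scheme order. Both tie-break stages are deterministic.
* *Decision DAG* (OvsO only): the ordered candidate list starts as the
  full scheme; each node evaluates the classifier of the (first, last)
  candidate pair and rejects the loser from that end. A leaf is reached
  after exactly `l-1` evaluations. The node layout of the original
  description is not fully specified, so this package fixes the classic
  tail-rejection convention over the scheme order (type order as listed
  in `incident_type_labels()`; SAC1→SAC4), and tests enumerate all
  pairwise-outcome assignments at `l = 4` to prove soundness: whenever
  every classifier involving the gold label is correct, both voting and
  the DAG return the gold label.
* *Argmax* (OvsA): the label whose one-vs-rest classifier emits the
  highest calibrated probability; ties break by scheme order.

**Base classifiers.** Logistic regression with L2 regularization (the
regularizer family is a package choice; the source method says only
"regularized") and support vector machines with linear and RBF kernels.
No SVM implementation is available in the supported dependency set, so
the package ships its own SMO dual solver (maximal-violating-pair working
set selection, solver tolerance `1e-4`, iteration cap with a warning on
non-convergence). Logistic regression is backed by glmnet with the ridge
mapping `lambda = 1/(n * C)`, so a larger trade-off `C` means weaker
regularization for all three algorithms.

**Probabilities.** Logistic regression emits its native sigmoid. SVM
margins are mapped through a Platt-style sigmoid
`p = plogis(a * s + c)` fitted on validation-fold scores with the usual
smoothed targets; the slope is clamped nonnegative so probabilities stay
order-isomorphic to scores. Whether the original method calibrated SVM
outputs for the OvsA argmax is unstated; calibration is this package's
choice and is flagged here.

## Features

Narratives are normalized to lowercase alphanumerics (digits retained —
only non-alphanumeric characters are removed), whitespace-tokenized,
stop-word-filtered against a vendored, versioned 127-word English list,
stripped of tokens shorter than two characters, lemmatized, and stemmed.
The lemmatize-then-stem order is a package decision (the source lists the
stages without an order); running the dictionary step first lets the
stemmer see base forms of irregular inflections. The stemmer is a
from-scratch implementation of the original Porter algorithm, pinned by
fixtures frozen from a reference implementation; the lemmatizer is a
small rule-plus-exception-table engine (no dictionary lemmatizer exists
in the supported offline dependency set) — both are deterministic and
swappable via `preprocess_corpus()` switches.

Documents become bag-of-words vectors over a vocabulary built **from
training-partition documents only**; prediction-time out-of-vocabulary
tokens are dropped. Three weightings: binary occurrence, raw term
frequency, and tf-idf with unsmoothed `idf(t) = ln(N / df(t))` (a term in
every training document gets weight 0). No vector normalization is
applied and no frequency pruning is done, matching the source's silence
on both. Matrices are sparse (`Matrix::dgCMatrix`) throughout.

## Validation protocol

`make_split_plan()` implements repeated random sub-sampling with a frozen
test partition: per class, `floor(n/10)` reports are drawn once as the
test set; each of the (default 10) repetitions re-draws `floor(n/10)`
validation reports from the remaining pool, with the remainder (including
the rounding remainder) used for training. Freezing the test draw per
class — rather than per binary subset — guarantees that a report in one
classifier's test set is never in another classifier's training set.

Hyperparameters (`C` over `2^(-5), 2^(-3), …, 2^15`; RBF `gamma` over
`2^(-15), …, 2^3`; standard log-grid practice, the source states no grid)
are selected by the mean validation F-score of the task's positive class
across repetitions, ties toward smaller `C` then smaller `gamma`. The
final base model is refit on train+validation of the frozen split
(whether the source refit is unstated; this is a flagged assumption), and
SVM calibration reuses the validation-fold scores collected at the
winning grid point.

Two deliberate simplifications, both flagged: (1) during tuning, the
vocabulary is built once per binary task from its train+validation pool
rather than per repetition — document frequencies over 80% vs 90% of a
subset differ negligibly, and the frozen test partition never informs any
vocabulary; (2) for batch prediction the DAG path precomputes scores per
base model over the whole batch for speed, while single-document
`predict_dag()` evaluates lazily and proves the `l-1` bound.

`run_grid()` crosses OvsO × {voting, dag} and OvsA × {argmax} with the
three algorithms and three weightings — 27 configurations per task, with
base models shared between the two OvsO decisions — and evaluates each on
the frozen test partition plus any external corpora, using the
training-time vocabularies unchanged. The best configuration is chosen by
micro-averaged F (ties: macro-F, then configuration order).

## Evaluation

Confusion matrices have gold rows and predicted columns; per-class
`tp`/`fp`/`fn` derive from the diagonal, column sums and row sums.
`F = 2PR/(P+R)`; cells of the form 0/0 are defined as 0 with a warning (a
conservative convention for never-predicted classes; the source is
silent). Micro averages pool `tp`/`fp`/`fn` before computing P/R/F —
which forces micro P = R = F for single-label prediction over the full
scheme, an identity the tests assert to `1e-12` — and macro averages are
unweighted means over classes. Percentages are surfaced with one decimal
place; internal values keep full precision.

## The synthetic world

The real corpora are confidential, so the generator emulates the
structure the analysis depends on, with defaults fixed once:

* **Compositions**: the four presets encode the published designs —
  balanced 260/type (total 2860) and 290/SAC (total 1160); stratified
  real-world ratios (type 444 / severity 4837 state-wide; type 6000 /
  severity 5950 independent).
* **Lengths**: truncated normal rounded to integer words (only
  mean/SD/range are published, not a family): mean 78.5, SD 35.5, range
  5–308 for state-wide presets; mean 63.4, SD 31.6, range 5–404 for the
  independent preset. Left truncation at 5 words shifts realized means
  up by 1–3 words; the acceptance report emits the realized values
  honestly.
* **Vocabulary**: each class has a versioned pool of ~22 discriminative
  clinical terms, pairwise disjoint at the raw-token level, plus a shared
  pool of ~60 general ward terms. Non-overlap tokens are drawn 50/50
  from the own and shared pools. The `overlap` knob (default 0.2, a
  package choice — within-class lexical heterogeneity is not published)
  draws that fraction of tokens from other classes' pools.
* **Severity keywords**: each severity report receives 1–3 indicator
  phrases; the extreme-risk pool follows the published keyword structure
  (death, suicide, high risk, police notified, incorrect patient,
  infection, blood transfusion reaction, aggression). Multi-token
  phrases are emitted as consecutive tokens — bag-of-words later discards
  order, matching the model. `sac23_blend` (default 0.3) cross-mixes the
  SAC2/SAC3 pools, emulating the published confusion between high- and
  medium-risk reports.
* **Co-occurrence**: documentation-type reports receive
  patient-identification or medications vocabulary at rate
  `cooccurrence_rate` (default 0.6; the published co-occurrence rates are
  47–77%). The gold label stays single — co-occurrence only perturbs
  text.
* **Seeding**: one master seed; per-class substreams are derived
  deterministically (`(seed mod 1e6) * 1009 + class_index * 101`), so
  corpora are pure functions of their configuration.

One resolved tension: a strictly separable world requires `overlap = 0`
**and** `cooccurrence_rate = 0`, since co-occurrence injection crosses
pools by design. The separable fixtures used by the recovery tests fix
both to zero a priori.

**What a green test establishes — and what it does not.** The synthetic
world has exchangeable token positions, exact class-conditional mixtures,
and no discourse, negation, misspelling, or reporter-style variation. A
green recovery test shows the pipeline's machinery is correct (it
recovers a known separable structure, and degrades monotonically as
confusability rises); it does *not* establish the published real-data
F-scores, which are explicitly out of scope. The qualitative rare-class
finding is reproduced directionally: training balanced and evaluating on
a stratified corpus with realistic priors and higher confusability
(overlap 0.5, standing in for distribution shift) collapses rare-class
precision while recall stays high.

## Numerical choices and degenerate inputs

* Solver: SMO tolerance `1e-4`, cap 200 000 iterations; glmnet threshold
  `1e-8` with a short descending lambda path ending at the target.
* Exact-zero decision scores vote for the pair's first label.
* Empty narratives preprocess to empty token documents and vectorize to
  all-zero rows (classified by the intercept); an all-empty training
  partition is an error (no features).
* A calibration slope that fits negative is clamped to `1e-6` with a
  warning rather than allowed to invert the score order.
* 0/0 metric cells are 0 with a warning.
* Single-class training input, unknown labels, dimension mismatches,
  invalid strategy/decision pairs, and classes smaller than 10 reports
  all raise early, named errors.

## Runtime scaling in the shipped tests

The acceptance suite runs the full 11 × 260 separable recovery with a
reduced grid (logistic regression, binary weighting, both strategies, 2
repetitions — documented reduced-grid mode); the overlap-monotonicity and
rare-class checks average over 5 seeds at reduced corpus sizes (40
reports/class; stratified ratios scaled by 1/4 with the rare class kept
at ~0.5% prevalence). Scaling affects runtime only; the stated-world
parameters (compositions, length moments, keyword structure, default
rates) are never adjusted to the outcome of a test.

## Known limitations

No realistic clinical language (see above); no de-identification; no
multi-label outputs (real reports are frequently multi-type — the
single-label gold standard is a stated simplification); no N-grams,
semantic types, feature selection, oversampling or cost-sensitive
training; no significance testing between configurations. The stemmer
and lemmatizer are implementation-pinned, not source-pinned: the source
does not name its tools, so token-level fixtures assert *this package's*
documented behavior.
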