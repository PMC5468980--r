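# incidenttriage

Automated triage of free-text patient safety incident reports by **incident
type** (falls, medications, pressure injury, aggression, documentation,
blood products, patient identification, infection, clinical handover,
deteriorating patient, others) and **severity assessment code** (SAC1
*extreme* … SAC4 *low*).

Hospitals collect far more incident reports than safety teams can read.
`incidenttriage` implements the classic text-classification pipeline for
this problem: the multiclass task over `l` classes is reduced to binary
sub-problems and solved by an ensemble of binary classifiers —

* **one-versus-one (OvsO)**: `l(l−1)/2` pairwise classifiers, combined
  either by **voting** (each classifier votes; most votes wins) or by a
  **decision DAG** (starting from the (first, last) label pair, each node
  rejects one candidate; a leaf is reached after exactly `l−1`
  comparisons);
* **one-versus-all (OvsA)**: `l` one-vs-rest classifiers with balanced
  negative subsampling; the label with the highest calibrated probability
  wins.

Base classifiers are L2-regularized logistic regression and support vector
machines (linear and RBF kernel, solved by a built-in SMO optimizer;
Platt-style sigmoid calibration). Narratives are normalized (lowercase
alphanumerics), stop-word- and short-word-filtered, lemmatized and Porter-
stemmed, then represented as bag-of-words vectors under three weightings:
binary occurrence, term frequency *tf*, and *tf-idf* with
`idf(t) = ln(N / df(t))`.

Evaluation uses per-class precision/recall/F (`F = 2PR/(P+R)`), confusion
matrices, and micro/macro averaging; model selection is by micro-averaged
F. Validation follows a repeated random sub-sampling protocol: per class,
10% of reports are frozen once as a test partition (so no base
classifier's training data ever touches a test report), and the remaining
pool is repeatedly re-split 80/10 for training/validation during
hyperparameter tuning.

The real corpora behind this problem are confidential, so the package
ships a **synthetic incident-report generator** that emulates their
published structure: class compositions of the balanced designs (260
reports per type, total 2860; 290 per SAC level, total 1160) and the
real-world stratified ratios (444 and 4837 for the state-wide system;
6000 and 5950 for the independent hospital system), report-length moments
(truncated normal; mean 78.5, SD 35.5, range 5–308 words state-wide, mean
63.4, SD 31.6, range 5–404 independent), severity-indicative keyword
phrases, an `overlap` confusability knob, and documentation-type
co-occurrence with patient-identification/medications vocabulary.

## Worked example

Train on a balanced synthetic severity corpus, evaluate on a stratified
corpus with real-world class ratios and higher lexical confusability:

```r
library(incidenttriage)

corpus     <- generate_corpus(default_config("balanced_severity", seed = 42))
stratified <- generate_corpus(default_config("stratified_original", seed = 43,
                                             task = "severity", overlap = 0.5))
cfg <- experiment_config(corpus, task = "severity",
                         algorithms = c("logreg", "svm_linear"),
                         weightings = c("binary", "tf"), n_repetitions = 3,
                         external = list(stratified = stratified), seed = 7)
res <- run_grid(cfg)
res$results[, c(1:4, 5, 7)]
```

```
   strategy    decision  algorithm weighting test_micro_f stratified_micro_f
1      ovso      voting     logreg    binary        1.000              0.787
2      ovso      voting     logreg        tf        1.000              0.817
3      ovso      voting svm_linear    binary        1.000              0.775
...
```

Per-class metrics of the selected configuration on the stratified corpus
(`print(res$reports[[as.integer(res$best)]]$stratified$report)`):

```
metrics over 4837 reports
      precision recall    f
SAC1        8.8   80.0 15.9
SAC2       11.0   64.2 18.8
SAC3       90.3   73.7 81.2
SAC4       93.0   83.5 88.0
micro      78.7   78.7 78.7
macro      50.8   75.4 51.0
```

Two hallmarks of this problem are visible: micro precision = recall = F
(every report gets exactly one predicted label), and the rare-class
pattern — extreme-risk SAC1 reports (25 of 4837) are found with high
recall but very low precision once class priors are realistic, because a
small false-positive rate among thousands of lower-severity reports
swamps the few true positives. Such false positives are cheap to screen;
missed SAC1 events are not.

## Command line

```sh
Rscript exec/incidenttriage generate --preset balanced_type --seed 7 \
    --overlap 0.2 --out corpus.jsonl
Rscript exec/incidenttriage train --in corpus.jsonl --task type \
    --strategy ovso --decision dag --algorithm svm_rbf \
    --weighting binary --out model/
Rscript exec/incidenttriage predict --model model/ --in corpus.jsonl \
    --out predictions.csv
Rscript exec/incidenttriage evaluate --model model/ --in corpus.jsonl \
    --out metrics.csv
Rscript exec/incidenttriage experiment --preset balanced_severity \
    --task severity --seed 1 --out experiment-out/
```

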