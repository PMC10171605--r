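---
title: "Coding clinical free text with a human-in-the-loop labelling loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding clinical free text with a human-in-the-loop labelling loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health-services researchers routinely need to turn free-text fields from
historical databases — hand-transcribed cause-of-death strings on death
certificates, the few words of triage shorthand recorded when an aeromedical
retrieval is tasked — into a small set of researcher-defined categories.
The texts are short, idiosyncratic, full of abbreviations and typographical
errors, and no labelled training corpus exists for the bespoke categories a
given project needs.  Fully automated coding pipelines struggle here; paying
experts to label tens of thousands of records up front is not an option.

`hitloop` implements an interactive alternative: a *label–train–evaluate*
loop in which a clinical expert (or, in simulation, a seeded oracle) labels
small batches of records, a classifier is retrained after every batch, and
the model's own predictions steer which records are worth the expert's next
few minutes.  The package provides every part of that workflow — corpus and
split management, featurization, two classifier families, sampling policies,
test/validation-set construction, confusion-matrix diagnostics and learning
curves — plus a synthetic-corpus generator so the whole method can be
studied end to end without access to restricted clinical data.

## Data model and splits

A corpus holds one record per clinical note: a unique id, the free-text
field, optional categorical and continuous supplementary features (age, sex,
triage priority, ...; missing values are retained) and an optional *gold*
label that is hidden from the learner and consumed only by the simulated
oracle and final scoring.  Records whose text is empty are excluded at load
time and counted.

Three disjoint id sets partition every corpus for the life of a session:

* a **frozen test set**, built once, never retrained on, used for interim
  accuracy after every round;
* the **training set**, which only ever grows;
* the **prediction pool** — everything else, the records the model predicts
  and the expert picks from.

`init_splits()` and `move_to_training()` are pure transitions; the partition
invariant (pairwise disjoint, union = all eligible ids) is re-checked after
every move, and moving a test id is a hard error.

## Featurization

Text is tokenised on whitespace after optional lowering and punctuation
stripping (intra-word hyphens and apostrophes survive); purely numeric
tokens and stop-list tokens can be removed.  Death-certificate corpora are
featurized with stop words, punctuation and numbers removed; triage
shorthand keeps all three, because `#NOF` and `?ACS` are informative there.
Word n-grams (default max 2) and character n-grams (default max 3, computed
over the token-joined text so that spaces mark word edges) are counted,
L2-normalised per record (tf-idf is available but off by default, term
weighting being a free choice), and concatenated with one-hot supplementary
categories (always including an explicit `missing` level) and min-max
normalised continuous features (missing values imputed at the training
mean; a zero-spread feature maps to 0.5).  The vocabulary is built from
training records only — a property test asserts that editing pool texts
cannot change the feature space.

## Classifiers

Two families sit behind one train/predict interface, mirroring the two
model shapes that win on each text style:

* **tree-ensemble** — gradient-boosted decision trees (via `xgboost`,
  histogram method, leaf-wise growth).  Defaults: 100 boosting rounds,
  31 leaves, learning rate 0.1.
* **maxent-linear** — L2-regularised multinomial maximum-entropy model
  (via `glmnet`).  Defaults: penalty `l2 = 0.01` with per-observation
  lambda `l2/N`, convergence tolerance `1e-6`.

Two numerical choices deserve a note.  First, the maxent penalty: with
L2-normalised sparse text blocks, each informative gram carries a small
weight, and a conventional unit penalty visibly shrinks the model toward
the majority class; the default was calibrated down to 0.01 on the
package's own easy mortality benchmark, where the loop is expected to
reach perfect accuracy.  Second, the solver is run down a short
warm-started lambda path ending at the target penalty rather than cold at a
single small lambda, which is dramatically more reliable; and a category
with a single labelled example (routine in early rounds) is kept
predictable by duplicating its row for the fit.  Categories never seen in
training remain valid score keys with probability zero; prediction scores
always form a simplex, arg-max ties breaking by codebook order.

`select_algorithm()` re-creates the semi-automated model-selection
experiment: every family × featurizer-variant is trained on a
class-stratified 80–20 split (one split, fixed by the seed, shared by all
variants) and ranked by macro-accuracy (mean per-class recall) then
micro-accuracy (overall proportion correct).  `ablate_features()` runs
greedy backward elimination over the supplementary features, dropping the
least-damaging feature until any further removal would cost more than a
tolerance (default 0.5 percentage points) of held-out macro-accuracy —
yielding the minimal feature set that does not compromise accuracy.

## The label–train–evaluate loop

Each round:

1. **Sample** a batch from the pool under the round's strategy.  Round 1 is
   50 random cases; later rounds alternate confidence-descending and
   confidence-ascending batches of 25 — scan what the model is most sure of
   for high-confidence errors, then feed it the cases it finds hardest.
   Any keyword expansions queued by the previous round run first.
2. **Label** each sampled case through the two-expert consensus oracle.
3. **Triage**: a correct prediction at confidence ≥ 0.9 is *ignored* (stays
   in the pool, costs no label); a correct low-confidence prediction is
   *confirmed*; an incorrect one is *relabelled*.  Confirmed and relabelled
   cases move to training and count against the label budget.
4. **Retrain** and re-predict the frozen test set and the pool, recording a
   learning-curve point keyed by the cumulative number of labels.
5. **Expand**: a (truth, predicted) error pair appearing at least 3 times
   on the test set this round is a *consistent misclassification*; the most
   frequent non-stop-word token among those error texts becomes a keyword
   search for the next round.  Only the two most frequent pairs are pursued
   per round, keeping effort focused on the major confusions (and keeping
   any single round from swallowing the whole budget).

The loop halts at the target accuracy (default 0.90), on budget exhaustion
(default 600 labels; test-set labels are budgeted separately), on an empty
pool, or at a round cap.  If a full round moves nothing to training — every
review was an "ignore" — the next round falls back to a random batch so the
session cannot stall.  `use_triage = FALSE` and `use_expansion = FALSE`
together with a random schedule give a pure passive-learning baseline for
comparison studies.

### The simulated experts

Two medical experts plus an adjudicator are emulated by a seeded oracle:
expert 1 reports gold perturbed with probability `expert1_error_rate`
(uniform over the other categories); expert 2 perturbs expert 1's label
with probability `disagreement_rate`; agreement stands, disagreement goes
to a third expert who returns gold.  Adjudications therefore occur at
exactly the disagreement rate, and the consensus label is wrong only when
expert 1 errs *and* expert 2 happens to agree.  The oracle draws from a
private RNG stream, so labelling is reproducible from the oracle seed
regardless of surrounding computation.

### Test and validation sets

Balanced test sets are built by labelling `K × target` random cases, then
topping up rare categories via case-insensitive keyword search until each
category holds `target` cases (warning, never silently, when a category
cannot be filled), and finally subsampling overfull categories back to the
target.  After a session concludes, `build_validation_set()` draws equal
numbers of pool cases *per model-predicted category* and has the oracle
label them blind to the prediction — the prediction-balanced, blinded
geometry used for final validation reporting (50 per class gives the
standard 150-case three-class and 250-case five-class tables).

## Metrics

Confusion matrices are oriented rows = predicted, columns = truth, ordered
by the codebook.  For class *c* with TP the diagonal entry, FP the rest of
its row, FN the rest of its column: recall = TP/(TP+FN), precision (PPV) =
TP/(TP+FP), specificity = TN/(TN+FP), NPV = TN/(TN+FN); division by zero
yields an `NA` marked undefined, never an error.  The headline number is
**overall accuracy** (trace/total); on a prediction-balanced validation set
(equal row totals) it coincides exactly with the mean per-row precision,
which is why a balanced validation table's "macro" figure equals
trace/total.  Macro recall (the unweighted mean of defined per-class
recalls) is always computed and logged alongside.  Presentation rounding is
half-up at two decimals; all arithmetic is done unrounded.

## The synthetic-corpus generator

Because the real registries are access-restricted, the generator emulates
the two text styles so every claim in this package is testable from code:

* **mortality style** — 1–4 cause clauses separated by semicolons, each
  optionally suffixed by a duration in parentheses ("(3 Years)"); a
  configurable fraction of records carries an all-caps coroner-style legal
  preamble; character-level typos (swap/drop/duplicate, uniform — the error
  kinds seen in hand-transcribed text) at a per-character rate.  Gold
  labels follow the clinical precedence rules for the stroke task: any
  ischaemic cue wins over a haemorrhagic one; subdural, subarachnoid and
  unspecified intracranial bleeds are *Not* stroke; only intracerebral-type
  haemorrhage cues label *Haemorrhagic*.  The `Not` vocabulary deliberately
  contains near-miss causes ("ischaemic heart disease", "gastrointestinal
  haemorrhage") so that unigrams alone cannot solve the task.
* **retrieval style** — 1–3 shorthand terms (mean length ≈ 20 characters)
  drawn from per-class vocabularies of ~20 terms, with a shared pool for
  the confusable Medical/Surgical/Trauma group (a term is drawn from the
  shared pool with probability `overlap`, default 0.25), abbreviation
  substitution ("shortness of breath" → "SOB") and typos.  Supplementary
  age, sex and triage priority are loosely class-dependent with ~5%
  missingness.

Three shipped presets define the study conditions: `mortality-easy`
(cue-disjoint vocabularies, no typos or traps — exactness tests can demand
accuracy 1.0), `mortality-hard` (6% ischaemic / 3% haemorrhagic / 91%
other, traps, typos, coroner records) and `retrieval-hard` (45/20/15/12/8%
class mix with the overlapping M/S/T vocabulary).  Class prevalences are
plausible imbalance choices — real prevalences are not published — and are
exposed as configuration.

**What the generator does not emulate:** four decades of era drift in
medical language, genuinely out-of-vocabulary pathology descriptions,
correlated expert biases, and the long tail of real free text.  Passing
loop benchmarks on these corpora therefore demonstrates that the *method*
behaves as described under controlled difficulty — rare classes, confusable
pairs, noise — not that any particular accuracy will transfer to a given
real registry.

## Benchmark problem sizes

The package's own simulation checks run the hard presets at full size
(10,000 records, balanced 50-per-class test sets, 600-label budget, 5
seeds) for the headline ≥90%-accuracy behaviour, and at a reduced scale
chosen for multi-seed property studies (2,500 records, 40-per-class test
sets, 250-label budget, 10 seeds) for the learning-curve-pattern and
active-versus-passive comparisons.  The reduced scale keeps 40-session
experiments cheap while preserving the class structure that drives both
effects.

## Known limitations

* The two classifier families cover the decision-tree and linear shapes
  used in practice, not a full AutoML menu; probability calibration is not
  attempted, so confidence thresholds are policy knobs, not probabilities.
* Keyword search is case-insensitive substring matching, as in a labelling
  UI's text box — no stemming or fuzzy match, so typo-bearing records can
  escape expansion batches.
* The oracle's errors are independent across cases and categories;
  systematic expert bias (which consensus cannot fix) is out of scope.
* Session state is in-memory; the CLI persists artifacts per run directory
  but there is no database backend or concurrent multi-user labelling.
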