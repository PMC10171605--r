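# The label-train-evaluate loop: simulated two-expert consensus oracle,
# balanced test-set construction, pool sampling strategies, prediction
# triage, consistent-misclassification expansion, the session driver and
# blinded validation-set construction.

#' Configure the simulated expert oracle
#'
#' The oracle stands in for the two medical experts plus adjudicator:
#' expert 1 reports the gold label perturbed with probability
#' `expert1_error_rate` (to a uniformly drawn different category); expert 2
#' reports expert 1's label perturbed with probability `disagreement_rate`.
#' Agreement yields that label; disagreement is adjudicated by a third
#' expert who returns gold.  All draws come from a private stream seeded by
#' `seed`, so labelling is reproducible regardless of surrounding code.
#'
#' @param expert1_error_rate probability in [0, 1].
#' @param disagreement_rate probability in [0, 1].
#' @param seed integer oracle seed.
#' @return an object of class `oracle_config`.
#' @export
oracle_config <- function(expert1_error_rate = 0, disagreement_rate = 0,
                          seed = 1L) {
  if (expert1_error_rate < 0 || expert1_error_rate > 1 ||
      disagreement_rate < 0 || disagreement_rate > 1) {
    stop("oracle rates must lie in [0, 1]")
  }
  structure(list(expert1_error_rate = expert1_error_rate,
                 disagreement_rate = disagreement_rate,
                 seed = as.integer(seed)),
            class = "oracle_config")
}

#' Instantiate an oracle for a codebook
#'
#' @param codebook a [codebook()].
#' @param config an [oracle_config()].
#' @return an object of class `hitl_oracle` holding a private RNG stream.
#' @export
make_oracle <- function(codebook, config = oracle_config()) {
  structure(list(codebook = codebook, config = config,
                 stream = rng_stream(config$seed)),
            class = "hitl_oracle")
}

perturb_label <- function(label, cats, rate) {
  if (rate > 0 && stats::runif(1) < rate) sample(setdiff(cats, label), 1) else label
}

#' Two-expert consensus label for one record
#'
#' @param gold the record's hidden gold category.
#' @param oracle an oracle from [make_oracle()].
#' @return list with `label` (the consensus category) and `adjudicated`
#'   (whether the third expert was needed).
#' @export
consensus_label <- function(gold, oracle) {
  stopifnot(inherits(oracle, "hitl_oracle"))
  cats <- oracle$codebook$categories
  cfg <- oracle$config
  stream_eval(oracle$stream, function() {
    e1 <- perturb_label(gold, cats, cfg$expert1_error_rate)
    e2 <- perturb_label(e1, cats, cfg$disagreement_rate)
    if (identical(e1, e2)) list(label = e1, adjudicated = FALSE)
    else list(label = gold, adjudicated = TRUE)
  })
}

# Vectorised consensus labelling; returns labels with adjudication count.
oracle_label <- function(golds, oracle) {
  out <- character(length(golds))
  adj <- 0L
  for (i in seq_along(golds)) {
    r <- consensus_label(golds[i], oracle)
    out[i] <- r$label
    adj <- adj + r$adjudicated
  }
  structure(out, n_adjudicated = adj)
}

#' Define a pool sampling strategy
#'
#' @param kind one of `"random"`, `"keyword"`, `"confidence-desc"`,
#'   `"confidence-asc"`.
#' @param batch_size maximum number of cases to return.
#' @param keyword search string (required iff `kind = "keyword"`;
#'   case-insensitive substring match, no stemming).
#' @param category_filter optional predicted category to filter on first.
#' @return an object of class `sampling_strategy`.
#' @export
sampling_strategy <- function(kind = c("random", "keyword",
                                       "confidence-desc", "confidence-asc"),
                              batch_size = 25L, keyword = NULL,
                              category_filter = NULL) {
  kind <- match.arg(kind)
  if (kind == "keyword" && (is.null(keyword) || !nzchar(keyword))) {
    stop("keyword strategies require a non-empty keyword")
  }
  if (kind != "keyword" && !is.null(keyword)) {
    stop("keyword is only meaningful for kind = 'keyword'")
  }
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(kind = kind, batch_size = as.integer(batch_size),
                 keyword = keyword, category_filter = category_filter),
            class = "sampling_strategy")
}

#' Select pool cases for expert review
#'
#' After the optional predicted-category filter: `random` draws uniformly
#' without replacement; `keyword` takes all case-insensitive substring
#' matches (uniformly subsampled down to the batch size); the confidence
#' kinds take the top/bottom of the confidence ordering, ties broken by id.
#'
#' @param predictions an `hitl_predictions` frame over the current pool.
#' @param strategy a [sampling_strategy()].
#' @param texts named character vector of record texts (needed for keyword
#'   search).
#' @return character vector of at most `batch_size` record ids (possibly
#'   empty — the caller decides what to try next).
#' @export
sample_cases <- function(predictions, strategy, texts = NULL) {
  df <- as.data.frame(predictions)
  if (!nrow(df)) stop("pool predictions are empty")
  if (!is.null(strategy$category_filter)) {
    df <- df[df$predicted == strategy$category_filter, , drop = FALSE]
  }
  if (!nrow(df)) return(character(0))
  b <- strategy$batch_size
  switch(strategy$kind,
    random = sample(df$id, min(b, nrow(df))),
    keyword = {
      if (is.null(texts)) stop("keyword sampling needs record texts")
      hit <- grepl(tolower(strategy$keyword), tolower(texts[df$id]), fixed = TRUE)
      ids <- df$id[hit]
      if (length(ids) > b) sample(ids, b) else ids
    },
    `confidence-desc` = df$id[order(-df$confidence, df$id)][seq_len(min(b, nrow(df)))],
    `confidence-asc` = df$id[order(df$confidence, df$id)][seq_len(min(b, nrow(df)))])
}

#' Triage reviewed predictions
#'
#' Encodes the expert review policy: a correct prediction with confidence at
#' or above `high_threshold` is ignored (the case stays in the pool); a
#' correct prediction below it is confirmed (moved to training with the
#' predicted label); an incorrect prediction is relabelled (moved to
#' training with the expert label).
#'
#' @param predictions `hitl_predictions` rows for the reviewed cases.
#' @param expert_labels character vector of expert (consensus) labels,
#'   parallel to `predictions`.
#' @param high_threshold confidence above which correct cases are ignored.
#' @return data frame with columns `id`, `action`
#'   (`ignore`/`confirm`/`relabel`) and `label`.
#' @export
triage_predictions <- function(predictions, expert_labels, high_threshold = 0.9) {
  df <- as.data.frame(predictions)
  stopifnot(nrow(df) == length(expert_labels))
  correct <- df$predicted == expert_labels
  action <- ifelse(!correct, "relabel",
                   ifelse(df$confidence >= high_threshold, "ignore", "confirm"))
  data.frame(id = df$id, action = action,
             label = ifelse(action == "relabel", expert_labels, df$predicted),
             stringsAsFactors = FALSE)
}

#' Turn consistent misclassifications into keyword searches
#'
#' A (truth, predicted) error pair seen at least `m` times in the current
#' evaluation round is "consistent".  For each such pair, the most frequent
#' non-stop-word token among the error texts (ties: lexicographically
#' first) becomes a keyword search strategy for the next round, so that
#' similar cases can be found and labelled.
#'
#' @param predictions `hitl_predictions` for the evaluated cases.
#' @param truth character vector of known labels, parallel to `predictions`.
#' @param texts named character vector of record texts.
#' @param m consistency trigger (default 3 occurrences per round).
#' @param stop_words tokens never used as keywords.
#' @param batch_size batch size of the emitted strategies.
#' @param max_pairs cap on strategies emitted per round; only the most
#'   frequent error pairs are pursued, keeping the labelling effort focused
#'   on the major misclassifications.
#' @return list of [sampling_strategy()] objects (empty if no pair is
#'   consistent), with a `pairs` attribute describing the pairs found.
#' @export
expand_misclassification <- function(predictions, truth, texts, m = 3L,
                                     stop_words = default_stop_words(),
                                     batch_size = 25L, max_pairs = 2L) {
  df <- as.data.frame(predictions)
  stopifnot(nrow(df) == length(truth))
  err <- df$predicted != truth
  if (!any(err)) return(structure(list(), pairs = NULL))
  key <- paste(truth[err], df$predicted[err], sep = " -> ")
  tab <- sort(table(key), decreasing = TRUE)
  tab <- tab[tab >= m]
  if (!length(tab)) return(structure(list(), pairs = NULL))
  tab <- utils::head(tab, max_pairs)
  cfg <- featurizer_config(remove_stop_words = TRUE, remove_punctuation = TRUE,
                           remove_numbers = TRUE, lowercase = TRUE,
                           stop_words = stop_words)
  strategies <- list()
  pairs <- data.frame(pair = names(tab), n = as.integer(tab), keyword = "",
                      stringsAsFactors = FALSE)
  for (i in seq_along(tab)) {
    ids <- df$id[err][key == names(tab)[i]]
    toks <- unlist(lapply(unname(texts[ids]), preprocess_text, config = cfg))
    if (!length(toks)) next
    tt <- table(toks)
    best <- sort(names(tt)[tt == max(tt)])[1]
    pairs$keyword[i] <- best
    strategies[[length(strategies) + 1L]] <-
      sampling_strategy("keyword", batch_size = batch_size, keyword = best)
  }
  structure(strategies, pairs = pairs)
}

#' Build a balanced labelled test set
#'
#' Phase 1 labels `per_class_target * K` uniformly random cases through the
#' two-expert consensus oracle; phase 2 tops up each category still below
#' target by labelling random cases whose text matches one of that
#' category's keywords (case-insensitive substring) until the target is met
#' or candidates are exhausted (with a warning, never silently).  Classes
#' over target are subsampled back down, so on a sufficiently rich corpus
#' every class contributes exactly `per_class_target` cases.
#'
#' @param x an `hitl_corpus` with gold labels.
#' @param oracle an oracle from [make_oracle()].
#' @param rare_keywords named list: category -> character vector of search
#'   keywords for categories expected to be rare.
#' @param per_class_target cases per category (>= 1).
#' @param seed selection seed.
#' @return list of class `hitl_test_set` with `ids` and named `labels`.
#' @export
build_balanced_test_set <- function(x, oracle, rare_keywords = list(),
                                    per_class_target = 50L, seed = 1L) {
  stopifnot(per_class_target >= 1)
  cats <- x$codebook$categories
  gold <- corpus_gold(x)
  if (anyNA(gold)) stop("balanced test construction requires gold labels on every record")
  texts <- corpus_texts(x)
  withr::with_seed(as.integer(seed), {
    labelled <- character(0) # named: id -> consensus label
    n1 <- min(per_class_target * length(cats), length(gold))
    phase1 <- sample(names(gold), n1)
    lab1 <- oracle_label(gold[phase1], oracle)
    labelled[phase1] <- lab1
    for (cl in cats) {
      short <- function() sum(labelled == cl) < per_class_target
      if (!short()) next
      kws <- rare_keywords[[cl]]
      if (is.null(kws) || !length(kws)) {
        warning(sprintf("category '%s' below target (%d/%d) and no keywords supplied",
                        cl, sum(labelled == cl), per_class_target))
        next
      }
      pat <- tolower(kws)
      unlab <- setdiff(names(texts), names(labelled))
      hit <- unlab[Reduce(`|`, lapply(pat, function(p)
        grepl(p, tolower(texts[unlab]), fixed = TRUE)))]
      hit <- sample(hit, length(hit))
      for (id in hit) {
        if (!short()) break
        labelled[id] <- oracle_label(gold[id], oracle)
      }
      if (short()) {
        warning(sprintf("category '%s' reached only %d of %d test cases after keyword search",
                        cl, sum(labelled == cl), per_class_target))
      }
    }
    keep <- unlist(lapply(cats, function(cl) {
      ids <- names(labelled)[labelled == cl]
      if (length(ids) > per_class_target) sample(ids, per_class_target) else ids
    }))
    structure(list(ids = keep, labels = labelled[keep]), class = "hitl_test_set")
  })
}

# ---- loop configuration ----------------------------------------------------

#' Configure the label-train-evaluate loop
#'
#' @param target_accuracy stop once frozen-test overall accuracy reaches
#'   this fraction (default 0.90).
#' @param max_labels training-label budget (test-set labels not counted).
#' @param batch_schedule optional function `round -> sampling_strategy`.
#'   The default reviews 50 random cases in round 1, then alternates
#'   confidence-descending and confidence-ascending batches of 25 (scan the
#'   model's confident predictions for high-confidence errors; then feed it
#'   the cases it finds hardest).
#' @param misclassification_m consistency trigger for
#'   [expand_misclassification()] (default 3).
#' @param high_threshold triage confidence threshold (default 0.9).
#' @param per_class_test balanced-test-set size per category.
#' @param rare_keywords named list of keywords for rare categories, used
#'   when the session has to build its own test set.
#' @param max_rounds hard cap on loop rounds.
#' @param use_triage apply the ignore/confirm/relabel review policy; with
#'   `FALSE` every sampled case is labelled and moved to training.
#' @param use_expansion queue keyword searches for consistent
#'   misclassifications.  Setting both switches `FALSE` together with a
#'   random schedule gives a pure passive-learning baseline.
#' @param seed session seed; drives sampling, training and test selection.
#' @return an object of class `loop_config`.
#' @export
loop_config <- function(target_accuracy = 0.90, max_labels = 600L,
                        batch_schedule = NULL, misclassification_m = 3L,
                        high_threshold = 0.9, per_class_test = 50L,
                        rare_keywords = list(), max_rounds = 100L,
                        use_triage = TRUE, use_expansion = TRUE, seed = 1L) {
  structure(list(target_accuracy = target_accuracy,
                 max_labels = as.integer(max_labels),
                 batch_schedule = batch_schedule,
                 misclassification_m = as.integer(misclassification_m),
                 high_threshold = high_threshold,
                 per_class_test = as.integer(per_class_test),
                 rare_keywords = rare_keywords,
                 max_rounds = as.integer(max_rounds),
                 use_triage = isTRUE(use_triage),
                 use_expansion = isTRUE(use_expansion),
                 seed = as.integer(seed)),
            class = "loop_config")
}

default_schedule <- function(round) {
  if (round == 1L) sampling_strategy("random", batch_size = 50L)
  else if (round %% 2 == 0L) sampling_strategy("confidence-desc", batch_size = 25L)
  else sampling_strategy("confidence-asc", batch_size = 25L)
}

random_schedule <- function(round) {
  if (round == 1L) sampling_strategy("random", batch_size = 50L)
  else sampling_strategy("random", batch_size = 25L)
}

#' Run a label-train-evaluate session
#'
#' Drives the full loop: each round samples pool cases under the scheduled
#' strategy (plus any keyword expansions queued by consistent
#' misclassifications), labels them through the consensus oracle, triages
#' them against the current predictions (ignore / confirm / relabel), moves
#' the non-ignored cases to training, retrains, re-predicts the frozen test
#' set and the pool, and records a learning-curve point.  The loop halts on
#' reaching the target accuracy, exhausting the label budget or the pool,
#' or hitting the round cap.  The trained model only ever sees training-set
#' labels; the test set is never touched after creation.
#'
#' @param x an `hitl_corpus` with gold labels (consumed only by the oracle).
#' @param cfg a [loop_config()].
#' @param oracle_cfg an [oracle_config()].
#' @param family a [model_family()].
#' @param feat_config a [featurizer_config()].
#' @param test_set optional pre-built [build_balanced_test_set()] result;
#'   built from `cfg` if missing.
#' @return an object of class `hitl_session`: `trajectory` and `per_class`
#'   data frames, `status`, `labels_used`, final `model`, final `state`,
#'   `test_set`, `training_labels`, and per-round `test_fingerprints`.
#' @export
run_session <- function(x, cfg, oracle_cfg, family, feat_config,
                        test_set = NULL) {
  stopifnot(inherits(cfg, "loop_config"))
  oracle <- make_oracle(x$codebook, oracle_cfg)
  withr::with_seed(cfg$seed,
                   run_session_impl(x, cfg, oracle, family, feat_config, test_set))
}

run_session_impl <- function(x, cfg, oracle, family, feat_config, test_set) {
  schedule <- cfg$batch_schedule %||% default_schedule
  if (is.null(test_set)) {
    test_set <- build_balanced_test_set(x, oracle, cfg$rare_keywords,
                                        cfg$per_class_test, seed = cfg$seed)
  }
  state <- init_splits(x, test_set$ids)
  cache <- build_gram_cache(x, feat_config)
  gold <- corpus_gold(x)
  texts <- corpus_texts(x)

  training_labels <- character(0)
  labels_used <- 0L
  model <- NULL
  pool_pred <- NULL
  expansions <- list()
  force_random <- FALSE
  idle_rounds <- 0L
  traj <- list(); per_class <- list(); fingerprints <- character(0)
  actions_log <- list()
  status <- "max-rounds"

  for (r in seq_len(cfg$max_rounds)) {
    if (labels_used >= cfg$max_labels) { status <- "budget-exhausted"; break }
    if (!length(state$pool_ids)) { status <- "pool-exhausted"; break }

    sched <- if (force_random) sampling_strategy("random", batch_size = 25L)
             else schedule(r)
    force_random <- FALSE
    strategies <- c(expansions, list(sched))
    expansions <- list()
    moved_any <- FALSE

    for (st in strategies) {
      remaining <- cfg$max_labels - labels_used
      if (remaining <= 0L || !length(state$pool_ids)) break
      st$batch_size <- min(st$batch_size, remaining)
      ids <- if (is.null(model)) {
        sample(state$pool_ids, min(st$batch_size, length(state$pool_ids)))
      } else {
        pp <- pool_pred[pool_pred$id %in% state$pool_ids, , drop = FALSE]
        if (!nrow(pp)) character(0) else sample_cases(pp, st, texts)
      }
      if (!length(ids)) next
      olab <- oracle_label(gold[ids], oracle)
      acts <- if (is.null(model) || !cfg$use_triage) {
        data.frame(id = ids, action = "relabel", label = as.character(olab),
                   stringsAsFactors = FALSE)
      } else {
        triage_predictions(pool_pred[match(ids, pool_pred$id), , drop = FALSE],
                           as.character(olab), cfg$high_threshold)
      }
      mv <- acts$id[acts$action != "ignore"]
      if (length(mv)) {
        state <- move_to_training(state, mv)
        training_labels[mv] <- acts$label[match(mv, acts$id)]
        labels_used <- labels_used + length(mv)
        moved_any <- TRUE
      }
      actions_log[[length(actions_log) + 1L]] <-
        cbind(round = r, strategy = st$kind, acts)
    }

    if (!moved_any) {
      # a whole round of reviews produced no new labels (e.g. every
      # high-confidence prediction was correct): fall back to random next
      # round so the session cannot stall
      idle_rounds <- idle_rounds + 1L
      if (idle_rounds >= 2L) force_random <- TRUE
      if (idle_rounds >= 10L) { status <- "stalled"; break }
      next
    }
    idle_rounds <- 0L

    if (length(unique(training_labels)) < 2L) next # need >= 2 classes to train

    model <- train_model(x, names(training_labels), unname(training_labels),
                         family, feat_config, seed = cfg$seed, cache = cache)
    test_pred <- predict_model(model, x, test_set$ids, cache = cache)
    pool_pred <- if (length(state$pool_ids)) {
      predict_model(model, x, state$pool_ids, cache = cache)
    } else NULL

    cm <- confusion(test_pred$predicted, unname(test_set$labels[test_pred$id]),
                    x$codebook)
    rep <- per_class_metrics(cm)
    traj[[length(traj) + 1L]] <- data.frame(
      round = r, n_labelled = labels_used,
      overall_accuracy = rep$overall_accuracy,
      macro_recall = rep$macro_recall)
    per_class[[length(per_class) + 1L]] <-
      cbind(round = r, n_labelled = labels_used, rep$per_class)
    fingerprints <- c(fingerprints, id_fingerprint(state$test_ids))

    if (rep$overall_accuracy >= cfg$target_accuracy) { status <- "target-reached"; break }
    if (labels_used >= cfg$max_labels) { status <- "budget-exhausted"; break }

    if (cfg$use_expansion) {
      expansions <- expand_misclassification(
        test_pred, unname(test_set$labels[test_pred$id]), texts,
        m = cfg$misclassification_m,
        stop_words = feat_config$stop_words %||% default_stop_words())
      attributes(expansions) <- NULL
      expansions <- as.list(expansions)
    }
  }

  structure(list(
    trajectory = if (length(traj)) do.call(rbind, traj) else
      data.frame(round = integer(0), n_labelled = integer(0),
                 overall_accuracy = numeric(0), macro_recall = numeric(0)),
    per_class = if (length(per_class)) do.call(rbind, per_class) else NULL,
    status = status, labels_used = labels_used,
    model = model, state = state, test_set = test_set,
    training_labels = training_labels,
    test_fingerprints = fingerprints,
    actions = if (length(actions_log)) do.call(rbind, actions_log) else NULL),
    class = "hitl_session")
}

#' @export
print.hitl_session <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat("<session>", x$status, "|", x$labels_used, "labels |", n, "evaluated rounds")
  if (n) cat(sprintf(" | final test accuracy %.3f",
                     x$trajectory$overall_accuracy[n]))
  cat("\n")
  invisible(x)
}

#' Build a blinded, prediction-balanced validation set
#'
#' After the loop concludes, samples `per_class_n` pool cases per
#' model-predicted category (never from the test or training sets) and
#' labels them through the consensus oracle without reference to the
#' prediction (labels derive solely from gold plus oracle noise).  Predicted
#' categories with too few pool cases contribute what they have, with a
#' warning.
#'
#' @param model the trained `hitl_model`.
#' @param x the corpus.
#' @param state the session's final `split_state`.
#' @param oracle an oracle from [make_oracle()].
#' @param per_class_n cases per predicted category (50 gives the standard
#'   150-case 3-class / 250-case 5-class validation geometry).
#' @param seed selection seed.
#' @param cache optional gram cache for `x`.
#' @return data frame with columns `id`, `predicted`, `truth`.
#' @export
build_validation_set <- function(model, x, state, oracle, per_class_n = 50L,
                                 seed = 1L, cache = NULL) {
  gold <- corpus_gold(x)
  if (!length(state$pool_ids)) stop("prediction pool is empty")
  pp <- predict_model(model, x, state$pool_ids, cache = cache)
  withr::with_seed(as.integer(seed), {
    sel <- unlist(lapply(x$codebook$categories, function(cl) {
      cand <- pp$id[pp$predicted == cl]
      if (length(cand) < per_class_n) {
        warning(sprintf("predicted category '%s' has only %d pool case(s) (target %d)",
                        cl, length(cand), per_class_n))
      }
      if (length(cand) > per_class_n) sample(cand, per_class_n) else
        if (length(cand)) sample(cand, length(cand)) else character(0)
    }))
    truth <- as.character(oracle_label(gold[sel], oracle))
    data.frame(id = sel, predicted = pp$predicted[match(sel, pp$id)],
               truth = truth, stringsAsFactors = FALSE)
  })
}
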