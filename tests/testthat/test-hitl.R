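test_that("noise-free oracles always return gold; forced disagreement adjudicates to gold", {
  cb <- stroke_cb()
  o <- make_oracle(cb, oracle_config(0, 0, seed = 1))
  expect_equal(vapply(1:20, function(i) consensus_label("Haem", o)$label, ""),
               rep("Haem", 20))
  # expert 2 always contradicts expert 1: every case goes to the adjudicator,
  # who restores gold
  o2 <- make_oracle(cb, oracle_config(expert1_error_rate = 0,
                                      disagreement_rate = 1, seed = 1))
  res <- lapply(1:20, function(i) consensus_label("Isch", o2))
  expect_true(all(vapply(res, `[[`, TRUE, "adjudicated")))
  expect_equal(unique(vapply(res, `[[`, "", "label")), "Isch")
})

test_that("adjudication frequency matches the disagreement probability", {
  # expert 2 perturbs expert 1 with p = 0.1, so adjudications are
  # Binomial(n, 0.1); check the observed fraction against the 99% CI
  cb <- stroke_cb()
  o <- make_oracle(cb, oracle_config(expert1_error_rate = 0.1,
                                     disagreement_rate = 0.1, seed = 33))
  n <- 10000
  golds <- sample(cb$categories, n, replace = TRUE)
  labs <- hitloop:::oracle_label(golds, o)
  p_hat <- attr(labs, "n_adjudicated") / n
  half <- stats::qnorm(0.995) * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(p_hat - 0.1), half)
})

test_that("oracle draws are seed-deterministic and isolated from the global RNG", {
  cb <- stroke_cb()
  draw <- function() {
    o <- make_oracle(cb, oracle_config(0.3, 0.3, seed = 5))
    vapply(1:30, function(i) consensus_label("Not", o)$label, "")
  }
  a <- draw()
  set.seed(999); runif(3)  # disturb the global stream
  expect_identical(a, draw())
})

test_that("sampling strategies order, filter and bound batches as specified", {
  p <- structure(data.frame(id = c("a", "b", "c"),
                            predicted = c("Isch", "Not", "Not"),
                            confidence = c(0.9, 0.5, 0.1),
                            stringsAsFactors = FALSE),
                 class = c("hitl_predictions", "data.frame"))
  texts <- c(a = "stroke of the brain", b = "renal failure", c = "fall")
  expect_equal(sample_cases(p, sampling_strategy("confidence-asc", 1)), "c")
  expect_equal(sample_cases(p, sampling_strategy("confidence-desc", 2)), c("a", "b"))
  expect_equal(sample_cases(p, sampling_strategy("keyword", 5, keyword = "stroke"),
                            texts), "a")
  expect_equal(sample_cases(p, sampling_strategy("keyword", 5, keyword = "zebra"),
                            texts), character(0))
  expect_equal(sample_cases(p, sampling_strategy("confidence-asc", 5,
                                                 category_filter = "Not")),
               c("c", "b"))
  expect_equal(sample_cases(p, sampling_strategy("confidence-asc", 5,
                                                 category_filter = "Haem")),
               character(0))
  withr::with_seed(1, expect_length(sample_cases(p, sampling_strategy("random", 2)), 2))
  # confidence ties break by id
  p$confidence <- c(0.5, 0.5, 0.5)
  expect_equal(sample_cases(p, sampling_strategy("confidence-desc", 2)), c("a", "b"))
  expect_error(sampling_strategy("keyword", 5), "keyword")
})

test_that("triage ignores confident correct cases and relabels errors", {
  p <- structure(data.frame(id = c("a", "b", "c"),
                            predicted = c("Isch", "Isch", "Haem"),
                            confidence = c(0.99, 0.60, 0.97),
                            stringsAsFactors = FALSE),
                 class = c("hitl_predictions", "data.frame"))
  acts <- triage_predictions(p, c("Isch", "Isch", "Not"), high_threshold = 0.95)
  expect_equal(acts$action, c("ignore", "confirm", "relabel"))
  expect_equal(acts$label, c("Isch", "Isch", "Not"))
})

test_that("consistent misclassifications become keyword strategies", {
  ids <- paste0("e", 1:7)
  p <- structure(data.frame(id = ids,
                            predicted = c(rep("Not", 5), "Isch", "Isch"),
                            confidence = 0.8, stringsAsFactors = FALSE),
                 class = c("hitl_predictions", "data.frame"))
  truth <- c(rep("Haem", 5), "Isch", "Isch")
  texts <- stats::setNames(
    c(paste("subdural", c("haematoma", "bleed", "fall", "elderly", "found")),
      "other", "other"), ids)
  out <- expand_misclassification(p, truth, texts, m = 3)
  expect_length(out, 1)
  expect_equal(out[[1]]$kind, "keyword")
  expect_equal(out[[1]]$keyword, "subdural")
  expect_equal(attr(out, "pairs")$pair, "Haem -> Not")
  # below the trigger: nothing
  expect_length(expand_misclassification(p, truth, texts, m = 6), 0)
  # token frequency ties resolve lexicographically
  texts2 <- stats::setNames(c(rep("beta alpha", 5), "x", "x"), ids)
  out2 <- expand_misclassification(p, truth, texts2, m = 3)
  expect_equal(out2[[1]]$keyword, "alpha")
})

test_that("balanced test sets hit the per-class target on rich corpora", {
  x <- generate_corpus(benchmark_spec("mortality-easy", n = 800, seed = 2))
  o <- make_oracle(x$codebook, oracle_config(seed = 2))
  ts <- build_balanced_test_set(x, o, benchmark_keywords("mortality-3class"),
                                per_class_target = 20, seed = 3)
  expect_equal(unname(table(ts$labels)[x$codebook$categories]),
               rep(20L, 3), ignore_attr = TRUE)
  expect_setequal(ts$ids, names(ts$labels))
  # reruns with the same seed select identically
  o2 <- make_oracle(x$codebook, oracle_config(seed = 2))
  ts2 <- build_balanced_test_set(x, o2, benchmark_keywords("mortality-3class"),
                                 per_class_target = 20, seed = 3)
  expect_identical(ts$labels, ts2$labels)
})

test_that("unfillable categories warn instead of failing silently", {
  # a corpus with no Haem cases at all and no keywords for it
  spec <- corpus_spec("mortality-3class", n_records = 120,
                      class_proportions = c(Isch = 0.5, Haem = 0, Not = 0.5),
                      typo_rate = 0, seed = 4)
  x <- generate_corpus(spec)
  o <- make_oracle(x$codebook, oracle_config(seed = 1))
  expect_warning(
    ts <- build_balanced_test_set(x, o, list(), per_class_target = 10, seed = 1),
    "below target")
  expect_equal(sum(ts$labels == "Haem"), 0)
})

test_that("a zero budget yields an empty trajectory with budget-exhausted status", {
  x <- generate_corpus(benchmark_spec("mortality-easy", n = 200, seed = 3))
  lc <- loop_config(max_labels = 0, per_class_test = 10,
                    rare_keywords = benchmark_keywords("mortality-3class"),
                    seed = 1)
  s <- run_session(x, lc, oracle_config(seed = 1),
                   model_family("maxent-linear"), featurizer_config())
  expect_equal(s$status, "budget-exhausted")
  expect_equal(nrow(s$trajectory), 0)
  expect_equal(s$labels_used, 0)
})

test_that("the loop reaches perfect accuracy on an easy corpus and is reproducible", {
  x <- generate_corpus(benchmark_spec("mortality-easy", n = 500, seed = 9))
  lc <- loop_config(target_accuracy = 1.0, max_labels = 250, per_class_test = 15,
                    rare_keywords = benchmark_keywords("mortality-3class"),
                    seed = 17)
  run_once <- function() {
    run_session(x, lc, oracle_config(seed = 17),
                model_family("tree-ensemble"), featurizer_config())
  }
  s1 <- run_once()
  expect_equal(tail(s1$trajectory$overall_accuracy, 1), 1.0)
  expect_equal(s1$status, "target-reached")
  s2 <- run_once()
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$training_labels, s2$training_labels)
})

test_that("sessions never mutate the test set nor leak ids across splits", {
  x <- generate_corpus(benchmark_spec("retrieval-hard", n = 600, seed = 12))
  lc <- loop_config(target_accuracy = 0.95, max_labels = 120, per_class_test = 10,
                    rare_keywords = benchmark_keywords("retrieval-5class"),
                    seed = 5)
  s <- run_session(x, lc, oracle_config(seed = 5),
                   model_family("maxent-linear"), retrieval_feat_config())
  # frozen test set: identical fingerprint at every evaluated round
  expect_gt(length(s$test_fingerprints), 1)
  expect_equal(unique(s$test_fingerprints),
               hitloop:::id_fingerprint(s$test_set$ids))
  # split partition at the end of the session
  expect_silent(validate_splits(s$state))
  expect_length(intersect(names(s$training_labels), s$test_set$ids), 0)
  # the learner saw only training-set labels
  expect_setequal(names(s$training_labels), s$state$training_ids)
  # labels-used matches the training set and the trajectory is keyed by it
  expect_equal(s$labels_used, length(s$training_labels))
  expect_true(all(diff(s$trajectory$n_labelled) >= 0))
})

test_that("validation sets are prediction-balanced, blind and warn when short", {
  x <- generate_corpus(benchmark_spec("mortality-easy", n = 900, seed = 21))
  lc <- loop_config(target_accuracy = 0.97, max_labels = 200, per_class_test = 15,
                    rare_keywords = benchmark_keywords("mortality-3class"),
                    seed = 2)
  s <- run_session(x, lc, oracle_config(seed = 2),
                   model_family("maxent-linear"), featurizer_config())
  o <- make_oracle(x$codebook, oracle_config(seed = 99))
  val <- build_validation_set(s$model, x, s$state, o, per_class_n = 20, seed = 7)
  expect_equal(nrow(val), 60)  # 3 predicted categories x 20
  expect_equal(unname(table(val$predicted)[x$codebook$categories]),
               rep(20L, 3), ignore_attr = TRUE)
  # blind labelling: truth comes from gold (noise-free oracle here)
  expect_equal(val$truth, unname(corpus_gold(x)[val$id]))
  # never draws from test or training
  expect_length(intersect(val$id, c(s$test_set$ids, s$state$training_ids)), 0)
  # identical selection on rerun
  o2 <- make_oracle(x$codebook, oracle_config(seed = 99))
  val2 <- build_validation_set(s$model, x, s$state, o2, per_class_n = 20, seed = 7)
  expect_identical(val, val2)
  # scarce predicted categories: warns and returns what exists
  w <- testthat::capture_warnings(
    build_validation_set(s$model, x, s$state, o, per_class_n = 5000, seed = 1))
  expect_true(any(grepl("only", w)))
})
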