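test_that("both families fit a separable corpus to training accuracy 1", {
  x <- separable_corpus(n_per_class = 10)
  cfg <- featurizer_config()
  ids <- corpus_ids(x)
  gold <- unname(corpus_gold(x))
  for (fam in list(model_family("tree-ensemble"), model_family("maxent-linear"))) {
    m <- train_model(x, ids, gold, fam, cfg, seed = 1)
    p <- predict_model(m, x, ids)
    expect_equal(mean(p$predicted == gold), 1, info = fam$name)
    # probes written in each class's private vocabulary land in that class
    probe <- as_corpus(data.frame(id = c("pa", "pb"),
                                  text = c("apple apricot avocado",
                                           "beet barley bean"),
                                  stringsAsFactors = FALSE), x$codebook)
    pp <- predict_model(m, probe)
    expect_equal(pp$predicted, c("A", "B"), info = fam$name)
  }
})

test_that("training is deterministic given data and seed", {
  x <- separable_corpus(n_per_class = 8)
  cfg <- featurizer_config()
  ids <- corpus_ids(x)
  gold <- unname(corpus_gold(x))
  for (fam in list(model_family("tree-ensemble"), model_family("maxent-linear"))) {
    m1 <- train_model(x, ids, gold, fam, cfg, seed = 7)
    m2 <- train_model(x, ids, gold, fam, cfg, seed = 7)
    p1 <- predict_model(m1, x, ids)
    p2 <- predict_model(m2, x, ids)
    expect_identical(attr(p1, "scores"), attr(p2, "scores"), info = fam$name)
  }
})

test_that("single-class training data is rejected with labelling advice", {
  x <- separable_corpus(n_per_class = 5)
  ids <- corpus_ids(x)[1:5]
  expect_error(train_model(x, ids, rep("A", 5), model_family("maxent-linear"),
                           featurizer_config()),
               "single category")
})

test_that("prediction scores form a simplex with codebook-order tie-breaks", {
  spec <- benchmark_spec("retrieval-hard", n = 150, seed = 4)
  x <- generate_corpus(spec)
  cfg <- retrieval_feat_config()
  ids <- corpus_ids(x)
  m <- train_model(x, ids[1:100], unname(corpus_gold(x))[1:100],
                   model_family("maxent-linear"), cfg, seed = 2)
  p <- predict_model(m, x, ids[101:150])
  S <- attr(p, "scores")
  expect_equal(unname(rowSums(S)), rep(1, 50), tolerance = 1e-6)
  expect_true(all(S >= 0))
  imax <- apply(S, 1, which.max)
  expect_equal(p$predicted, m$categories[imax])
  expect_equal(p$confidence, unname(S[cbind(1:50, imax)]))
})

test_that("categories absent from training keep zero scores but stay valid keys", {
  spec <- benchmark_spec("mortality-easy", n = 80, seed = 6)
  x <- generate_corpus(spec)
  lab <- unname(corpus_gold(x))
  keep <- lab != "Haem"
  ids <- corpus_ids(x)[keep][1:30]
  m <- train_model(x, ids, unname(corpus_gold(x)[ids]),
                   model_family("maxent-linear"), featurizer_config(), seed = 1)
  p <- predict_model(m, x, corpus_ids(x)[1:20])
  S <- attr(p, "scores")
  expect_equal(colnames(S), c("Isch", "Haem", "Not"))
  expect_equal(unname(S[, "Haem"]), rep(0, 20))
  expect_equal(unname(rowSums(S)), rep(1, 20), tolerance = 1e-6)
})

test_that("maxent on an all-zero vector returns the softmax of the intercepts", {
  x <- separable_corpus(n_per_class = 10)
  cfg <- featurizer_config()
  m <- train_model(x, corpus_ids(x), unname(corpus_gold(x)),
                   model_family("maxent-linear"), cfg, seed = 1)
  # no shared word, char or boundary gram with the fruit vocabulary
  probe <- as_corpus(data.frame(id = "z", text = "zzz",
                                stringsAsFactors = FALSE), x$codebook)
  p <- predict_model(m, probe)
  expect_true("z" %in% attr(p, "zero_text"))
  cf <- stats::coef(m$fit, s = min(m$fit$lambda))
  b <- vapply(m$present, function(k) cf[[k]][1, 1], numeric(1))
  expect_equal(unname(attr(p, "scores")[1, m$present]),
               unname(exp(b) / sum(exp(b))), tolerance = 1e-6)
})

test_that("maxent decision boundary matches direct likelihood optimisation", {
  # 2 classes, 3 features (one informative, two inert); the independent
  # oracle optimises the same ridge-penalised multinomial objective with
  # a generic quasi-Newton routine instead of coordinate descent
  set.seed(3)
  x1 <- seq(-2, 2, length.out = 24)
  X <- cbind(x1, 0, 0)
  y <- factor(ifelse(x1 > 0.3, "pos", "neg"), levels = c("neg", "pos"))
  l2 <- 0.5
  fit <- hitloop:::fit_maxent(Matrix::Matrix(X, sparse = TRUE), y,
                              list(l2 = l2, tol = 1e-12))
  cf <- stats::coef(fit, s = min(fit$lambda))
  dw <- cf$pos[2, 1] - cf$neg[2, 1]
  db <- cf$pos[1, 1] - cf$neg[1, 1]
  boundary_fit <- -db / dw

  lam <- l2 / length(y)
  nll <- function(par) {
    b <- par[1:2]; W <- matrix(par[3:8], nrow = 3)
    eta <- sweep(X %*% W, 2, b, `+`)
    ll <- sum(eta[cbind(seq_along(y), as.integer(y))] -
                log(rowSums(exp(eta))))
    -ll / length(y) + lam / 2 * sum(W^2)
  }
  opt <- stats::optim(rep(0, 8), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  Wo <- matrix(opt$par[3:8], nrow = 3)
  boundary_opt <- -(opt$par[2] - opt$par[1]) / (Wo[1, 2] - Wo[1, 1])
  expect_equal(boundary_fit, boundary_opt, tolerance = 1e-3)
})

test_that("algorithm selection ranks family x variant grids reproducibly", {
  x <- separable_corpus(n_per_class = 12)
  cfg <- featurizer_config()
  fams <- list(model_family("tree-ensemble"), model_family("maxent-linear"))
  grid <- data.frame(remove_stop_words = c(TRUE, FALSE))
  r1 <- select_algorithm(x, corpus_ids(x), unname(corpus_gold(x)), fams, cfg,
                         grid = grid, seed = 5)
  expect_s3_class(r1, "selection_report")
  expect_equal(nrow(r1), 4)
  expect_true(all(c("micro", "macro", "status") %in% names(r1)))
  # separable corpus: the top variant is perfect on the held-out split
  expect_equal(r1$micro[1], 1)
  expect_equal(r1$macro[1], 1)
  r2 <- select_algorithm(x, corpus_ids(x), unname(corpus_gold(x)), fams, cfg,
                         grid = grid, seed = 5)
  expect_identical(r1, r2)
  expect_error(select_algorithm(x, corpus_ids(x)[1:5], unname(corpus_gold(x))[1:5],
                                fams, cfg, seed = 1), "at least 10")
})

test_that("feature ablation drops label-independent features and keeps informative ones", {
  # labels depend only on text; sex and age are noise
  withr::with_seed(8, {
    n <- 60
    cl <- rep(c("A", "B"), each = n / 2)
    df <- data.frame(
      id = sprintf("r%02d", 1:n),
      text = ifelse(cl == "A", "apple apricot", "beet barley"),
      gold = cl,
      sex = sample(c("M", "F"), n, replace = TRUE),
      age = runif(n, 1, 90), stringsAsFactors = FALSE)
  })
  x <- as_corpus(df, codebook("toy", c("A", "B")),
                 cat_features = "sex", num_features = "age")
  cfg <- featurizer_config()
  res <- ablate_features(x, corpus_ids(x), unname(corpus_gold(x)),
                         model_family("maxent-linear"), cfg, seed = 2)
  expect_length(res$retained, 0)
  expect_equal(res$trace$macro[1], res$baseline)

  # now the label IS a categorical feature and the text is uninformative
  df2 <- df
  df2$text <- "same text everywhere"
  df2$grp <- cl
  x2 <- as_corpus(df2, codebook("toy", c("A", "B")),
                  cat_features = c("sex", "grp"), num_features = "age")
  res2 <- ablate_features(x2, corpus_ids(x2), unname(corpus_gold(x2)),
                          model_family("maxent-linear"), cfg, seed = 2)
  expect_true("grp" %in% res2$retained)
  expect_false("sex" %in% res2$retained)

  # a tolerance of a full accuracy point removes everything
  res3 <- ablate_features(x, corpus_ids(x), unname(corpus_gold(x)),
                          model_family("maxent-linear"), cfg, seed = 2,
                          tolerance = 1.0)
  expect_length(res3$retained, 0)
})
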