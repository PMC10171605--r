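# Two classifier families behind one train/predict interface, plus the
# semi-automated algorithm-selection (80-20 experiments over featurizer
# variants) and greedy backward feature-ablation procedures.

#' Define a classifier family
#'
#' Two families are provided: `"tree-ensemble"` (gradient-boosted decision
#' trees; default 100 boosting rounds, 31 leaves, learning rate 0.1) and
#' `"maxent-linear"` (L2-regularised multinomial maximum-entropy / logistic
#' model; default penalty 0.01, convergence tolerance 1e-6).  Hyperparameters
#' can be overridden through `...`.
#'
#' @param name `"tree-ensemble"` or `"maxent-linear"`.
#' @param ... hyperparameter overrides (`nrounds`, `max_leaves`,
#'   `learning_rate` for trees; `l2`, `tol` for maxent).
#' @return an object of class `model_family`.
#' @export
model_family <- function(name = c("tree-ensemble", "maxent-linear"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    "tree-ensemble" = list(nrounds = 100L, max_leaves = 31L, learning_rate = 0.1),
    "maxent-linear" = list(l2 = 0.01, tol = 1e-6))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyperparameters = hp), class = "model_family")
}

#' Train a classifier on labelled records
#'
#' Builds the feature space from the training records only, fits the chosen
#' family, and returns a self-contained model.  Training is deterministic
#' given (data, family, hyperparameters, seed).  Codebook categories never
#' seen in training remain valid score keys with probability zero.
#'
#' @param x an `hitl_corpus`.
#' @param ids training record ids.
#' @param labels character vector of category labels parallel to `ids`.
#' @param family a [model_family()].
#' @param config a [featurizer_config()].
#' @param seed integer training seed.
#' @param cache internal gram cache covering all of `x`; computed if `NULL`.
#' @return an object of class `hitl_model`.
#' @export
train_model <- function(x, ids, labels, family, config, seed = 1L,
                        cache = NULL) {
  stopifnot(inherits(x, "hitl_corpus"), inherits(family, "model_family"),
            length(ids) == length(labels))
  cats <- x$codebook$categories
  bad <- setdiff(unique(labels), cats)
  if (length(bad)) stop("label(s) outside the codebook: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  present <- cats[cats %in% labels]
  if (length(present) < 2) {
    stop("training data covers a single category ('", present,
         "'); label cases from at least one more category before training")
  }
  if (is.null(cache)) cache <- build_gram_cache(x, config)
  rows <- match(ids, cache$ids)
  if (anyNA(rows)) stop("unknown training record id(s)")
  space <- space_from_cache(cache, rows, config)
  X <- featurize_from_cache(cache, rows, space, config)
  y <- factor(labels, levels = present)
  hp <- family$hyperparameters
  fit <- withr::with_seed(as.integer(seed), switch(family$name,
    "tree-ensemble" = fit_tree_ensemble(X, y, hp, seed),
    "maxent-linear" = fit_maxent(X, y, hp)))
  structure(list(family = family, space = space, config = config, fit = fit,
                 categories = cats, present = present,
                 training_seed = as.integer(seed), n_train = length(ids)),
            class = "hitl_model")
}

#' @export
print.hitl_model <- function(x, ...) {
  cat("<model>", x$family$name, "|", x$n_train, "training records |",
      length(x$present), "of", length(x$categories), "categories seen\n")
  invisible(x)
}

fit_maxent <- function(X, y, hp) {
  if (ncol(X) < 2) X <- cbind(X, Matrix::Matrix(0, nrow(X), 2 - ncol(X), sparse = TRUE))
  # the solver requires >= 2 observations per class; a category labelled only
  # once (common in early rounds) is kept predictable by duplicating its row
  singleton <- names(which(table(y) == 1L))
  if (length(singleton)) {
    dup <- which(y %in% singleton)
    X <- rbind(X, X[dup, , drop = FALSE])
    y <- factor(c(as.character(y), as.character(y)[dup]), levels = levels(y))
  }
  # warm-started descent along a short lambda path: far more robust than
  # asking the coordinate solver for one small lambda cold
  lam <- hp$l2 / length(y)
  path <- exp(seq(log(lam * 100), log(lam), length.out = 8))
  withCallingHandlers(
    glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                   lambda = path, standardize = FALSE,
                   thresh = hp$tol, maxit = 1e5),
    # rare categories routinely have < 8 training examples early in a
    # session; glmnet's advisory warning about that is expected here
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
    })
}

fit_tree_ensemble <- function(X, y, hp, seed) {
  d <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  params <- list(objective = "multi:softprob", num_class = nlevels(y),
                 eta = hp$learning_rate, max_leaves = hp$max_leaves,
                 max_depth = 6L, grow_policy = "lossguide",
                 tree_method = "hist", nthread = 1L, seed = as.integer(seed))
  xgboost::xgb.train(params = params, data = d, nrounds = hp$nrounds,
                     verbose = 0)
}

#' Predict categories with per-class confidence scores
#'
#' Returns one prediction per input record: a probability distribution over
#' the full codebook (summing to 1; categories absent from training score 0),
#' the arg-max category (ties broken by codebook order) and its confidence.
#' Records that vectorise to an all-zero text block are still predicted
#' (prior/bias driven) and listed in the `zero_text` attribute.
#'
#' @param model an `hitl_model`.
#' @param x the corpus the records come from.
#' @param ids record ids to predict; defaults to all.
#' @param cache internal gram cache covering all of `x`; computed if `NULL`.
#' @return a data frame of class `hitl_predictions` with columns `id`,
#'   `predicted`, `confidence`; the full score matrix is in the `scores`
#'   attribute (rows in input order, columns in codebook order).
#' @export
predict_model <- function(model, x, ids = NULL, cache = NULL) {
  stopifnot(inherits(model, "hitl_model"))
  ids <- ids %||% corpus_ids(x)
  if (!length(ids)) stop("no records to predict")
  if (is.null(cache)) cache <- build_gram_cache(x, model$config)
  rows <- match(ids, cache$ids)
  if (anyNA(rows)) stop("unknown record id(s)")
  X <- featurize_from_cache(cache, rows, model$space, model$config)
  P <- switch(model$family$name,
    "maxent-linear" = {
      Xp <- X
      if (ncol(Xp) < 2) Xp <- cbind(Xp, Matrix::Matrix(0, nrow(Xp), 2 - ncol(Xp), sparse = TRUE))
      s <- min(model$fit$lambda)
      stats::predict(model$fit, newx = Xp, type = "response", s = s)[, , 1, drop = TRUE]
    },
    "tree-ensemble" = stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(ids), byrow = TRUE)
  colnames(P) <- model$present
  S <- matrix(0, nrow = length(ids), ncol = length(model$categories),
              dimnames = list(ids, model$categories))
  S[, model$present] <- P
  imax <- max.col(S, ties.method = "first")
  out <- data.frame(id = ids,
                    predicted = model$categories[imax],
                    confidence = S[cbind(seq_along(ids), imax)],
                    stringsAsFactors = FALSE)
  # rows whose text contributed nothing (no known term)
  ntext <- model$space$n_text
  zero_text <- if (ntext) ids[Matrix::rowSums(X[, seq_len(ntext), drop = FALSE] != 0) == 0] else ids
  structure(out, scores = S, zero_text = zero_text,
            class = c("hitl_predictions", "data.frame"))
}

prediction_scores <- function(p) attr(p, "scores")

# ---- 80-20 experiments -----------------------------------------------------

# Class-stratified 80-20 split, reproducible from the seed.  Every class
# with >= 2 members keeps at least one record on each side.
stratified_split <- function(labels, p = 0.8, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(p * length(idx))))
      if (length(idx) == 1L) n_tr <- 1L
      train[sample(idx, n_tr)] <- TRUE
    }
    list(train = which(train), test = which(!train))
  })
}

eval_variant <- function(x, ids, labels, split, family, config, seed, cache = NULL) {
  m <- train_model(x, ids[split$train], labels[split$train], family, config,
                   seed = seed, cache = cache)
  pr <- predict_model(m, x, ids[split$test], cache = cache)
  cm <- confusion(pr$predicted, labels[split$test], x$codebook)
  list(micro = overall_accuracy(cm), macro = as.numeric(macro_recall(cm)))
}

#' Rank classifier families over a featurizer-variant grid
#'
#' Re-creates the semi-automated algorithm selection experiment: for every
#' family x featurizer variant, train on a class-stratified 80% split and
#' evaluate micro-accuracy (overall proportion correct) and macro-accuracy
#' (unweighted mean per-class recall) on the held-out 20%.  The same
#' seed-derived split is used for every variant; the report is sorted by
#' (macro, micro) descending.  Variants whose training fails are reported
#' with status `"failed"`, never fatally.
#'
#' @param x an `hitl_corpus`.
#' @param ids,labels labelled records (>= 10, spanning >= 2 classes).
#' @param families list of [model_family()] objects.
#' @param config base [featurizer_config()].
#' @param grid data frame of featurizer overrides, one variant per row;
#'   defaults to the 8 on/off combinations of stop words, punctuation and
#'   numbers.
#' @param seed split/training seed.
#' @return data frame report of class `selection_report`.
#' @export
select_algorithm <- function(x, ids, labels, families, config,
                             grid = NULL, seed = 1L) {
  if (length(ids) < 10) stop("need at least 10 labelled records for selection")
  if (length(unique(labels)) < 2) stop("labelled data must span >= 2 classes")
  if (is.null(grid)) {
    grid <- expand.grid(remove_stop_words = c(TRUE, FALSE),
                        remove_punctuation = c(TRUE, FALSE),
                        remove_numbers = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  }
  if (!nrow(grid)) stop("empty variant grid")
  if (inherits(families, "model_family")) families <- list(families)
  split <- stratified_split(labels, 0.8, seed)
  rows <- list()
  for (fam in families) {
    for (v in seq_len(nrow(grid))) {
      cfg <- do.call(featurizer_config,
                     utils::modifyList(unclass(config)[setdiff(names(config), "stop_words")],
                                       as.list(grid[v, , drop = FALSE])))
      cfg$stop_words <- config$stop_words
      res <- tryCatch(eval_variant(x, ids, labels, split, fam, cfg, seed),
                      error = function(e) e)
      failed <- inherits(res, "error")
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(family = fam$name, variant = v, stringsAsFactors = FALSE),
        grid[v, , drop = FALSE],
        data.frame(micro = if (failed) NA_real_ else res$micro,
                   macro = if (failed) NA_real_ else res$macro,
                   status = if (failed) "failed" else "ok",
                   stringsAsFactors = FALSE))
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  ord <- order(-replace(rep$macro, is.na(rep$macro), -1),
               -replace(rep$micro, is.na(rep$micro), -1),
               rep$family, rep$variant)
  rep <- rep[ord, , drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("selection_report", "data.frame")
  rep
}

#' Greedy backward feature ablation
#'
#' Starting from all configured supplementary features, repeatedly drops the
#' feature whose removal degrades held-out (80-20) macro-accuracy least, and
#' stops when any further removal would fall more than `tolerance` below the
#' all-features baseline.  Returns the minimal retained feature set and the
#' accuracy trace.
#'
#' @param x an `hitl_corpus`.
#' @param ids,labels labelled records.
#' @param family a [model_family()].
#' @param config a [featurizer_config()]; its `included_supplementary`
#'   (default: all corpus features) is the starting set.
#' @param seed split/training seed.
#' @param tolerance acceptable macro-accuracy loss (fraction; default 0.005,
#'   i.e. half a percentage point).
#' @return list with `retained`, `baseline`, and a `trace` data frame.
#' @export
ablate_features <- function(x, ids, labels, family, config, seed = 1L,
                            tolerance = 0.005) {
  feats <- config$included_supplementary %||% c(x$cat_features, x$num_features)
  if (!length(feats)) stop("no supplementary features configured to ablate")
  split <- stratified_split(labels, 0.8, seed)
  eval_set <- function(fs) {
    cfg <- config
    cfg$included_supplementary <- fs
    eval_variant(x, ids, labels, split, family, cfg, seed)$macro
  }
  baseline <- eval_set(feats)
  current <- feats
  trace <- data.frame(step = 0L, removed = NA_character_, macro = baseline,
                      n_features = length(current), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current)) {
    cand <- vapply(current, function(f) eval_set(setdiff(current, f)), numeric(1))
    best <- which.max(cand) # ties: first in current order (stable)
    if (cand[best] < baseline - tolerance) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = current[best],
                                     macro = unname(cand[best]),
                                     n_features = length(current) - 1L,
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, current[best])
  }
  list(retained = current, baseline = baseline, trace = trace)
}
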