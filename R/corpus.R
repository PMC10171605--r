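# Corpus data model: records, codebooks and the three-way split state
# (frozen test set / training set / prediction pool) used by the
# label-train-evaluate loop.

#' Create a codebook
#'
#' A codebook is the fixed, ordered list of categories a coding task uses.
#' The order defines the row/column order of every confusion matrix and the
#' tie-break order for predicted categories.
#'
#' @param task_name short name for the coding task.
#' @param categories character vector of at least two distinct category names.
#' @return an object of class `hitl_codebook`.
#' @export
#' @examples
#' codebook("stroke", c("Isch", "Haem", "Not"))
codebook <- function(task_name, categories) {
  categories <- as.character(categories)
  if (length(categories) < 2) stop("a codebook needs at least two categories")
  if (anyDuplicated(categories)) stop("codebook categories must be distinct")
  structure(list(task_name = as.character(task_name)[1], categories = categories),
            class = "hitl_codebook")
}

#' @export
print.hitl_codebook <- function(x, ...) {
  cat("<codebook>", x$task_name, ":", paste(x$categories, collapse = " | "), "\n")
  invisible(x)
}

#' Build a corpus from a data frame of records
#'
#' A corpus holds one row per clinical note: a unique `id`, the free-text
#' field, an optional hidden gold label (used only by the simulated oracle
#' and final scoring, never shown to the learner), and any number of
#' categorical / continuous supplementary feature columns (age, sex, triage
#' priority, ...).  Records whose text is empty after whitespace stripping
#' are dropped; the number dropped is kept in the `n_excluded` attribute.
#' Missing supplementary values are retained as `NA`.
#'
#' @param records data frame with at least columns `id` and `text`; a `gold`
#'   column may be present (NA allowed).
#' @param codebook a [codebook()].
#' @param cat_features names of categorical supplementary columns.
#' @param num_features names of continuous supplementary columns.
#' @return an object of class `hitl_corpus`.
#' @export
as_corpus <- function(records, codebook, cat_features = character(),
                      num_features = character()) {
  stopifnot(is.data.frame(records), inherits(codebook, "hitl_codebook"))
  need <- c("id", "text")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing required column(s): ",
                         paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$id <- as.character(records$id)
  records$text <- as.character(records$text)
  if (!"gold" %in% names(records)) records$gold <- NA_character_
  records$gold <- as.character(records$gold)
  records$gold[!is.na(records$gold) & records$gold == ""] <- NA_character_

  if (anyDuplicated(records$id)) {
    stop("duplicate record id(s): ",
         paste(utils::head(unique(records$id[duplicated(records$id)]), 3), collapse = ", "))
  }
  bad_gold <- !is.na(records$gold) & !(records$gold %in% codebook$categories)
  if (any(bad_gold)) {
    i <- which(bad_gold)[1]
    stop(sprintf("gold label '%s' (row id '%s') is not in the codebook",
                 records$gold[i], records$id[i]))
  }
  feat <- c(cat_features, num_features)
  miss <- setdiff(feat, names(records))
  if (length(miss)) stop("supplementary feature column(s) not found: ",
                         paste(miss, collapse = ", "))
  for (f in num_features) records[[f]] <- as.numeric(records[[f]])
  for (f in cat_features) {
    records[[f]] <- as.character(records[[f]])
    records[[f]][!is.na(records[[f]]) & records[[f]] == ""] <- NA_character_
  }

  keep <- nzchar(trimws(records$text)) & !is.na(records$text)
  n_excluded <- sum(!keep)
  records <- records[keep, c("id", "text", "gold", feat), drop = FALSE]
  rownames(records) <- NULL

  structure(list(records = records, codebook = codebook,
                 cat_features = cat_features, num_features = num_features),
            class = "hitl_corpus", n_excluded = n_excluded)
}

#' Load a corpus from a delimited text file
#'
#' Reads a UTF-8, comma-delimited file with a header row (fields may be
#' quoted; death-certificate texts embed semicolons and commas).  Rows whose
#' text field is empty or whitespace are excluded and counted.
#'
#' @param path file path.
#' @param codebook a [codebook()].
#' @param schema column mapping: a list with elements `id`, `text`, optional
#'   `gold`, and optional character vectors `cat_features`, `num_features`
#'   naming file columns.
#' @return an `hitl_corpus`; attribute `n_excluded` reports dropped rows.
#' @export
load_corpus <- function(path, codebook,
                        schema = list(id = "id", text = "text", gold = "gold")) {
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (is.null(schema$text) || !(schema$text %in% names(df))) {
    stop("schema error: text column '", schema$text %||% "<unset>",
         "' not present in ", path)
  }
  if (is.null(schema$id) || !(schema$id %in% names(df))) {
    stop("schema error: id column '", schema$id %||% "<unset>",
         "' not present in ", path)
  }
  out <- data.frame(id = df[[schema$id]], text = df[[schema$text]],
                    stringsAsFactors = FALSE)
  if (!is.null(schema$gold) && schema$gold %in% names(df)) {
    out$gold <- df[[schema$gold]]
  }
  cat_features <- intersect(schema$cat_features %||% character(), names(df))
  num_features <- intersect(schema$num_features %||% character(), names(df))
  for (f in c(cat_features, num_features)) out[[f]] <- df[[f]]
  corp <- as_corpus(out, codebook, cat_features = cat_features,
                    num_features = num_features)
  if (attr(corp, "n_excluded") > 0) {
    message(attr(corp, "n_excluded"), " record(s) with missing free text excluded")
  }
  corp
}

#' Write a corpus to CSV
#'
#' Inverse of [load_corpus()] under the default schema: ids, texts, gold
#' labels and supplementary columns round-trip exactly.
#'
#' @param x an `hitl_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "hitl_corpus"))
  utils::write.csv(x$records, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' @export
print.hitl_corpus <- function(x, ...) {
  cat("<corpus>", nrow(x$records), "records |", length(x$cat_features),
      "categorical +", length(x$num_features), "continuous features | task:",
      x$codebook$task_name, "\n")
  invisible(x)
}

corpus_ids <- function(x) x$records$id

corpus_texts <- function(x) stats::setNames(x$records$text, x$records$id)

corpus_gold <- function(x) stats::setNames(x$records$gold, x$records$id)

# ---- split state -----------------------------------------------------------

#' Initialise the three-way split
#'
#' Partitions record ids into a frozen test set, an (initially empty)
#' training set and the prediction pool.  The test set never changes for the
#' life of a session; every id later moved out of the pool goes to training.
#'
#' @param x an `hitl_corpus`.
#' @param test_ids ids of the frozen test set (duplicates are collapsed).
#' @return an object of class `split_state`.
#' @export
init_splits <- function(x, test_ids) {
  all_ids <- corpus_ids(x)
  test_ids <- unique(as.character(test_ids))
  unknown <- setdiff(test_ids, all_ids)
  if (length(unknown)) stop("unknown id(s) in test set: ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  if (!length(test_ids)) warning("empty test set: interim accuracy cannot be tracked")
  state <- structure(list(test_ids = test_ids,
                          training_ids = character(0),
                          pool_ids = setdiff(all_ids, test_ids),
                          all_ids = all_ids),
                     class = "split_state")
  validate_splits(state)
  state
}

#' Move pool records into the training set
#'
#' Pure transition: returns a new state, never mutates the input.  Moving an
#' id that sits in the test set is test contamination and errors; so does
#' re-moving an id already in training.
#'
#' @param state a `split_state`.
#' @param ids ids currently in the pool.
#' @return the new `split_state`.
#' @export
move_to_training <- function(state, ids) {
  stopifnot(inherits(state, "split_state"))
  ids <- unique(as.character(ids))
  if (any(ids %in% state$test_ids)) {
    stop("test contamination: id(s) ",
         paste(utils::head(intersect(ids, state$test_ids), 3), collapse = ", "),
         " belong to the frozen test set")
  }
  if (any(ids %in% state$training_ids)) {
    stop("id(s) already in training: ",
         paste(utils::head(intersect(ids, state$training_ids), 3), collapse = ", "))
  }
  outside <- setdiff(ids, state$pool_ids)
  if (length(outside)) stop("id(s) not in the prediction pool: ",
                            paste(utils::head(outside, 3), collapse = ", "))
  new_state <- state
  new_state$pool_ids <- setdiff(state$pool_ids, ids)
  new_state$training_ids <- c(state$training_ids, ids)
  validate_splits(new_state)
  new_state
}

#' Check the split partition invariant
#'
#' The three sets must be pairwise disjoint and their union must equal the
#' full eligible id set.  Called after every transition.
#'
#' @param state a `split_state`.
#' @return `state`, invisibly; errors if the invariant is violated.
#' @export
validate_splits <- function(state) {
  sets <- state[c("test_ids", "training_ids", "pool_ids")]
  n <- sum(lengths(sets))
  u <- unique(unlist(sets, use.names = FALSE))
  if (n != length(u) || n != length(state$all_ids) ||
      !setequal(u, state$all_ids)) {
    stop("split partition invariant violated")
  }
  invisible(state)
}

#' @export
print.split_state <- function(x, ...) {
  cat("<splits> test:", length(x$test_ids), "| training:",
      length(x$training_ids), "| pool:", length(x$pool_ids), "\n")
  invisible(x)
}
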