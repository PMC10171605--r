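# Featurization: word n-grams, character n-grams, one-hot supplementary
# categories and min-max-normalised continuous features, assembled into
# sparse vectors.  The vocabulary (feature space) is always built from
# training records only.

#' Load the shipped English stop-word list
#'
#' About 150 common function words, one per line.  Any plain-text file with
#' the same layout can be substituted via the `path` argument.
#'
#' @param path optional path to an alternative list.
#' @return character vector of lower-case stop words.
#' @export
default_stop_words <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "hitloop")
  }
  tolower(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
}

#' Featurizer configuration
#'
#' Controls text preprocessing and feature assembly.  Death-certificate
#' style corpora are typically featurized with stop words, punctuation and
#' numbers removed; very short triage shorthand keeps all three (punctuation
#' such as `#` and `?` carries meaning there).  Word n-grams default to a
#' maximum of 2 and character n-grams to a maximum of 3.
#'
#' @param remove_stop_words drop tokens on the stop list.
#' @param remove_punctuation strip non-alphanumeric characters (intra-word
#'   hyphens/apostrophes are kept).
#' @param remove_numbers drop purely numeric tokens.
#' @param lowercase unify case before tokenising (coroner-style records are
#'   all-caps; lowercasing is on by default even when punctuation is kept).
#' @param word_ngram_max maximum word n-gram length (>= 1).
#' @param char_gram_max maximum character n-gram length (>= 1).
#' @param included_supplementary names of supplementary features to include;
#'   `NULL` means every feature declared by the corpus.
#' @param weighting `"l2"` for L2-normalised term counts (default) or
#'   `"tfidf"` for smoothed tf-idf, L2-normalised.
#' @param stop_words character vector; defaults to the shipped list.
#' @return an object of class `featurizer_config`.
#' @export
featurizer_config <- function(remove_stop_words = TRUE,
                              remove_punctuation = TRUE,
                              remove_numbers = TRUE,
                              lowercase = TRUE,
                              word_ngram_max = 2L,
                              char_gram_max = 3L,
                              included_supplementary = NULL,
                              weighting = c("l2", "tfidf"),
                              stop_words = NULL) {
  weighting <- match.arg(weighting)
  word_ngram_max <- as.integer(word_ngram_max)
  char_gram_max <- as.integer(char_gram_max)
  if (word_ngram_max < 1L || char_gram_max < 1L) {
    stop("word_ngram_max and char_gram_max must be >= 1")
  }
  if (is.null(stop_words) && remove_stop_words) stop_words <- default_stop_words()
  structure(list(remove_stop_words = isTRUE(remove_stop_words),
                 remove_punctuation = isTRUE(remove_punctuation),
                 remove_numbers = isTRUE(remove_numbers),
                 lowercase = isTRUE(lowercase),
                 word_ngram_max = word_ngram_max,
                 char_gram_max = char_gram_max,
                 included_supplementary = included_supplementary,
                 weighting = weighting,
                 stop_words = stop_words %||% character(0)),
            class = "featurizer_config")
}

#' Preprocess free text into tokens
#'
#' Lowercases (if configured), optionally strips punctuation (every
#' non-alphanumeric character except intra-word hyphens and apostrophes
#' becomes a space), splits on whitespace, then optionally removes purely
#' numeric tokens and stop-list tokens (matched case-insensitively).  When
#' punctuation is retained, marks stay attached to their tokens as written.
#'
#' @param text a single string.
#' @param config a [featurizer_config()].
#' @return character vector of tokens (possibly empty).
#' @export
#' @examples
#' cfg <- featurizer_config()
#' preprocess_text("MVA #femur", cfg)   # "mva" "femur"
preprocess_text <- function(text, config) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- if (config$lowercase) tolower(text) else text
  if (config$remove_punctuation) {
    s <- gsub("[^[:alnum:]'[:space:]-]", " ", s)
    # strip hyphens/apostrophes that are not flanked by alphanumerics
    s <- gsub("(?<![[:alnum:]])['-]|['-](?![[:alnum:]])", " ", s, perl = TRUE)
  }
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (config$remove_numbers) toks <- toks[!grepl("^[0-9]+$", toks)]
  if (config$remove_stop_words && length(config$stop_words)) {
    toks <- toks[!(tolower(toks) %in% config$stop_words)]
  }
  toks
}

#' Extract word n-grams
#'
#' All contiguous n-grams for n = 1..`n_max`, joined with single spaces.
#' Repeats are preserved (the result is a multiset).
#'
#' @param tokens character vector of tokens.
#' @param n_max maximum n-gram length.
#' @return character vector of n-grams.
#' @export
extract_word_ngrams <- function(tokens, n_max) {
  nt <- length(tokens)
  if (!nt) return(character(0))
  out <- vector("list", min(n_max, nt))
  for (n in seq_len(min(n_max, nt))) {
    g <- tokens[seq_len(nt - n + 1L)]
    if (n > 1L) for (k in 2:n) g <- paste(g, tokens[k:(nt - n + k)])
    out[[n]] <- g
  }
  unlist(out, use.names = FALSE)
}

#' Extract character n-grams
#'
#' Sliding window of widths 1..`len_max` over the string.  Callers pass the
#' preprocessed text with token boundaries marked by single spaces, so that
#' space characters carry word-edge information (useful for misspellings).
#'
#' @param text a single string.
#' @param len_max maximum gram length.
#' @return character vector of character n-grams (multiset).
#' @export
extract_char_grams <- function(text, len_max) {
  stopifnot(is.character(text), length(text) == 1L)
  L <- nchar(text)
  if (!L) return(character(0))
  out <- vector("list", min(len_max, L))
  for (n in seq_len(min(len_max, L))) {
    st <- seq_len(L - n + 1L)
    out[[n]] <- substring(text, st, st + n - 1L)
  }
  unlist(out, use.names = FALSE)
}

# ---- gram cache ------------------------------------------------------------
# Gram extraction is by far the most expensive step of a session round, and
# the grams of a record never change, so they are computed once per corpus
# and config.  The cache holds, per record, the namespaced gram strings
# ("w:" word grams, "c:" char grams) with their counts, plus supplementary
# one-hot keys and numeric values.  It carries no label information.
build_gram_cache <- function(x, config) {
  recs <- x$records
  n <- nrow(recs)
  grams <- vector("list", n)
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- preprocess_text(recs$text[i], config)
    g <- character(0)
    if (length(toks)) {
      g <- paste0("w:", extract_word_ngrams(toks, config$word_ngram_max))
      joined <- paste(toks, collapse = " ")
      g <- c(g, paste0("c:", extract_char_grams(joined, config$char_gram_max)))
    }
    if (length(g)) {
      tab <- sort(g, method = "radix")
      r <- rle(tab)
      grams[[i]] <- r$values
      counts[[i]] <- r$lengths
    } else {
      grams[[i]] <- character(0)
      counts[[i]] <- integer(0)
    }
  }
  cat_feats <- included_cat(x, config)
  num_feats <- included_num(x, config)
  cat_keys <- lapply(cat_feats, function(f) {
    v <- recs[[f]]
    v[is.na(v)] <- "missing"
    paste0("oh:", f, "=", v)
  })
  names(cat_keys) <- cat_feats
  num_vals <- if (length(num_feats)) {
    m <- as.matrix(recs[, num_feats, drop = FALSE])
    colnames(m) <- num_feats
    m
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  list(ids = recs$id, grams = grams, counts = counts,
       cat_keys = cat_keys, num_vals = num_vals,
       cat_feats = cat_feats, num_feats = num_feats)
}

included_cat <- function(x, config) {
  if (is.null(config$included_supplementary)) return(x$cat_features)
  intersect(x$cat_features, config$included_supplementary)
}

included_num <- function(x, config) {
  if (is.null(config$included_supplementary)) return(x$num_features)
  intersect(x$num_features, config$included_supplementary)
}

# Build the feature space from the cache rows of the training records only.
space_from_cache <- function(cache, train_rows, config) {
  if (!length(train_rows)) stop("cannot build a feature space with no training records")
  terms <- unique(unlist(cache$grams[train_rows], use.names = FALSE))
  terms <- sort(terms, method = "radix")
  idf <- NULL
  if (config$weighting == "tfidf") {
    df <- table(factor(unlist(cache$grams[train_rows], use.names = FALSE),
                       levels = terms))
    nd <- length(train_rows)
    idf <- log((1 + nd) / (1 + as.numeric(df))) + 1
    names(idf) <- terms
  }
  oh_keys <- character(0)
  for (f in cache$cat_feats) {
    lev <- unique(cache$cat_keys[[f]][train_rows])
    mk <- paste0("oh:", f, "=missing")
    if (!(mk %in% lev)) lev <- c(lev, mk)
    oh_keys <- c(oh_keys, sort(lev, method = "radix"))
  }
  num_stats <- NULL
  if (length(cache$num_feats)) {
    v <- cache$num_vals[train_rows, , drop = FALSE]
    num_stats <- data.frame(
      feature = cache$num_feats,
      min = apply(v, 2, function(z) suppressWarnings(min(z, na.rm = TRUE))),
      max = apply(v, 2, function(z) suppressWarnings(max(z, na.rm = TRUE))),
      mean = colMeans(v, na.rm = TRUE),
      row.names = NULL)
    # feature entirely missing in training: fall back to neutral constants
    bad <- !is.finite(num_stats$min)
    num_stats$min[bad] <- 0; num_stats$max[bad] <- 0
    num_stats$mean[!is.finite(num_stats$mean)] <- 0
  }
  all_keys <- c(terms, oh_keys,
                if (length(cache$num_feats)) paste0("num:", cache$num_feats))
  structure(list(terms = terms, oh_keys = oh_keys, num_stats = num_stats,
                 idf = idf, config_weighting = config$weighting,
                 term_index = stats::setNames(seq_along(all_keys), all_keys),
                 n_text = length(terms), n_oh = length(oh_keys),
                 n_train = length(train_rows)),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("<feature space>", x$n_text, "text terms +", x$n_oh, "one-hot keys +",
      length(x$term_index) - x$n_text - x$n_oh, "continuous features (built on",
      x$n_train, "training records)\n")
  invisible(x)
}

# Sparse design matrix for the cache rows `rows` under `space`.
featurize_from_cache <- function(cache, rows, space, config) {
  n <- length(rows)
  D <- length(space$term_index)
  # text block
  gs <- cache$grams[rows]
  cs <- cache$counts[rows]
  ri <- rep.int(seq_len(n), lengths(gs))
  cj <- match(unlist(gs, use.names = FALSE), space$terms)
  xv <- as.numeric(unlist(cs, use.names = FALSE))
  keep <- !is.na(cj)
  ri <- ri[keep]; cj <- cj[keep]; xv <- xv[keep]
  if (identical(space$config_weighting, "tfidf") && length(xv)) {
    xv <- xv * space$idf[cj]
  }
  if (length(xv)) { # L2-normalise the text block per record
    ss <- rowsum(xv^2, ri)
    nrm <- sqrt(ss[, 1])
    xv <- xv / nrm[match(ri, as.integer(rownames(ss)))]
  }
  # one-hot block
  for (f in cache$cat_feats) {
    col <- unname(space$term_index[cache$cat_keys[[f]][rows]])
    ok <- !is.na(col) # categories unseen in training are ignored
    ri <- c(ri, seq_len(n)[ok]); cj <- c(cj, col[ok]); xv <- c(xv, rep(1, sum(ok)))
  }
  # continuous block
  if (length(cache$num_feats)) {
    for (k in seq_along(cache$num_feats)) {
      f <- cache$num_feats[k]
      st <- space$num_stats[space$num_stats$feature == f, ]
      v <- cache$num_vals[rows, k]
      rng <- st$max - st$min
      z <- if (rng > 0) (v - st$min) / rng else rep(0.5, n)
      z[is.na(v)] <- if (rng > 0) (st$mean - st$min) / rng else 0.5
      z <- pmin(pmax(z, 0), 1)
      col <- unname(space$term_index[paste0("num:", f)])
      nz <- z != 0
      ri <- c(ri, seq_len(n)[nz]); cj <- c(cj, rep(col, sum(nz))); xv <- c(xv, z[nz])
    }
  }
  Matrix::sparseMatrix(i = ri, j = cj, x = xv, dims = c(n, D),
                       dimnames = list(cache$ids[rows], names(space$term_index)))
}

#' Build a feature space from training records
#'
#' The vocabulary is the union of word n-grams, character n-grams and
#' one-hot keys (`feature=category`, always including `feature=missing`)
#' observed in the given training records; continuous features store
#' training-set min/max (for min-max normalisation) and mean (imputation of
#' missing values).  Pool and test records contribute nothing.
#'
#' @param x an `hitl_corpus`.
#' @param config a [featurizer_config()].
#' @param ids training record ids; defaults to all records in `x`.
#' @return an object of class `feature_space`.
#' @export
build_feature_space <- function(x, config, ids = NULL) {
  ids <- ids %||% corpus_ids(x)
  rows <- match(ids, x$records$id)
  if (anyNA(rows)) stop("unknown record id(s) in training set")
  if (!length(rows)) stop("cannot build a feature space with no training records")
  cache <- build_gram_cache(x, config)
  space_from_cache(cache, rows, config)
}

#' Vectorise records into the feature space
#'
#' Terms unseen in training are ignored.  The text block (word + char grams)
#' is L2-normalised per record (or tf-idf weighted then normalised); one-hot
#' weights are 0/1; continuous values are min-max normalised and clipped to
#' [0, 1], with missing values imputed at the training mean.
#'
#' @param x an `hitl_corpus`.
#' @param space a `feature_space` built with [build_feature_space()].
#' @param config the same [featurizer_config()] used to build `space`.
#' @param ids record ids to vectorise; defaults to all.
#' @return a sparse `dgCMatrix`, one row per record, columns in
#'   `space$term_index` order.
#' @export
vectorize <- function(x, space, config, ids = NULL) {
  ids <- ids %||% corpus_ids(x)
  rows <- match(ids, x$records$id)
  if (anyNA(rows)) stop("unknown record id(s)")
  cache <- build_gram_cache(x, config)
  featurize_from_cache(cache, rows, space, config)
}
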