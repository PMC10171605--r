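# Fixtures built in code: tiny corpora, independent brute-force oracles.

stroke_cb <- function() codebook("stroke", c("Isch", "Haem", "Not"))

retrieval_cb <- function() {
  codebook("retrieval", c("Medical", "Psychiatric", "Obstetric", "Trauma",
                          "Surgical"))
}

# A linearly separable two-class corpus: each class writes from a private
# vocabulary, so any reasonable classifier can reach training accuracy 1.
separable_corpus <- function(n_per_class = 10, seed = 42) {
  vocab <- list(A = c("apple", "apricot", "avocado", "almond"),
                B = c("beet", "barley", "bean", "broccoli"))
  withr::with_seed(seed, {
    rows <- lapply(c("A", "B"), function(cl) {
      data.frame(
        id = paste0(cl, seq_len(n_per_class)),
        text = replicate(n_per_class,
                         paste(sample(vocab[[cl]], 3, replace = TRUE),
                               collapse = " ")),
        gold = cl, stringsAsFactors = FALSE)
    })
    as_corpus(do.call(rbind, rows), codebook("toy", c("A", "B")))
  })
}

# Brute-force gram enumerators, independent of the featurizer's
# vectorised implementation.
brute_word_ngrams <- function(tokens, n_max) {
  out <- character(0)
  for (n in seq_len(n_max)) {
    if (n > length(tokens)) next
    for (i in seq_len(length(tokens) - n + 1)) {
      out <- c(out, paste(tokens[i:(i + n - 1)], collapse = " "))
    }
  }
  out
}

brute_char_grams <- function(text, len_max) {
  out <- character(0)
  L <- nchar(text)
  for (n in seq_len(len_max)) {
    if (n > L) next
    for (i in seq_len(L - n + 1)) out <- c(out, substr(text, i, i + n - 1))
  }
  out
}

# Naive pair-by-pair confusion counter (rows = predicted, cols = truth).
brute_confusion <- function(predicted, truth, cats) {
  m <- matrix(0L, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_along(predicted)) {
    m[predicted[i], truth[i]] <- m[predicted[i], truth[i]] + 1L
  }
  m
}

# Published 3-class validation counts (rows = predicted Isch/Haem/Not).
validation_counts_3class <- function() {
  confusion_from_counts(c(49, 0, 1,
                          2, 43, 5,
                          0, 0, 50), stroke_cb())
}

# Published 5-class validation counts
# (rows = predicted Medical/Psychiatric/Obstetric/Trauma/Surgical).
validation_counts_5class <- function() {
  confusion_from_counts(c(46, 0, 0, 2, 2,
                          0, 50, 0, 0, 0,
                          2, 0, 48, 0, 0,
                          4, 0, 1, 43, 2,
                          6, 0, 0, 0, 44), retrieval_cb())
}

retrieval_feat_config <- function() {
  featurizer_config(remove_stop_words = FALSE, remove_punctuation = FALSE,
                    remove_numbers = FALSE)
}
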