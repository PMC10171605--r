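# Seeded generator of gold-labelled synthetic clinical corpora.  Two text
# styles are emulated: (a) death-certificate cause-of-death strings --
# multi-cause clauses with durations in parentheses, semicolon separators,
# all-caps coroner-style legal preambles and spelling errors; (b) very short
# aeromedical-retrieval triage shorthand with abbreviations and typos (mean
# length around 20 characters), rare classes and confusable category pairs.
# No real record text is reproduced; vocabularies are generic clinical terms.

# ---- vocabularies ----------------------------------------------------------

stroke_vocab <- function() {
  list(
    isch = c("ischaemic stroke", "cerebral infarction", "cerebrovascular accident",
             "CVA", "middle cerebral artery infarct", "embolic stroke",
             "cerebral thrombosis", "lacunar infarct", "brain stem infarction",
             "thrombotic stroke", "acute ischaemic stroke", "right MCA infarct",
             "left hemisphere infarct", "cerebral embolism"),
    haem = c("intracerebral haemorrhage", "spontaneous intracerebral haemorrhage",
             "haemorrhagic stroke", "intraparenchymal haemorrhage",
             "cerebral haemorrhage", "haemorrhagic CVA", "brain haemorrhage",
             "massive intracerebral haemorrhage", "pontine haemorrhage",
             "basal ganglia haemorrhage"),
    # haemorrhage-adjacent events that are coded 'Not': subdural and
    # subarachnoid bleeds (often traumatic), unspecified intracranial
    # haemorrhage, septic emboli
    trap = c("subdural haematoma", "subdural haemorrhage",
             "subarachnoid haemorrhage", "acute subdural haematoma",
             "intracranial haemorrhage", "septic emboli to the brain",
             "traumatic subarachnoid haemorrhage"),
    not_ = c("ischaemic heart disease", "myocardial infarction",
             "coronary atherosclerosis", "congestive cardiac failure",
             "atrial fibrillation", "hypertension", "aortic stenosis",
             "cardiac arrest", "septicaemia", "pneumonia", "aspiration pneumonia",
             "chronic obstructive pulmonary disease", "respiratory arrest",
             "respiratory failure", "pulmonary embolism", "lung cancer",
             "metastatic colorectal cancer", "hepatic malignancy",
             "breast cancer", "prostate cancer", "end stage renal failure",
             "acute renal failure", "type 2 diabetes", "alcoholic liver disease",
             "cirrhosis of the liver", "gastrointestinal haemorrhage",
             "peritonitis", "dementia", "parkinsons disease", "old age",
             "multiple injuries", "motor vehicle accident", "drowning",
             "septic shock", "urosepsis"))
}

retrieval_vocab <- function() {
  list(
    Medical = c("chest pain", "shortness of breath", "acute kidney injury",
                "sepsis", "?ACS", "pneumonia", "urinary tract infection",
                "hyperkalaemia", "diabetic ketoacidosis", "seizure",
                "GI bleed", "anaemia", "dehydration", "cellulitis", "fever",
                "gastroenteritis", "pyelonephritis", "heart failure", "CCF",
                "meningitis ?", "rheumatic fever", "endocarditis",
                "renal failure HD pt", "hypoglycaemia", "AF rapid rate"),
    Surgical = c("abdo pain ?appendicitis", "bowel obstruction",
                 "I and D abscess", "cholecystitis", "acute abdomen",
                 "incarcerated hernia", "?perforation", "ischaemic limb",
                 "testicular torsion", "haematuria", "perianal abscess",
                 "appendicitis", "gallstones", "obstructed hernia",
                 "wound dehiscence", "empyema for drainage", "PR bleeding",
                 "acute urinary retention", "osteomyelitis", "renal colic"),
    Trauma = c("MVA", "#femur", "head injury", "stab wound", "fall from height",
               "burns", "assault", "#NOF", "crush injury",
               "motorcycle accident", "dislocated shoulder", "facial fractures",
               "# ribs", "gunshot wound", "pedestrian vs car", "quad bike rollover",
               "spear wound leg", "#tib fib", "traumatic head injury", "hit by cow"),
    Obstetric = c("PPROM", "labour", "APH", "pre-eclampsia", "PV bleeding",
                  "contractions 29/40", "PPH", "G2P1 in labour", "eclampsia",
                  "miscarriage", "threatened preterm labour", "SROM term",
                  "twin pregnancy 34/40", "breech in labour", "hyperemesis",
                  "cord prolapse", "placenta praevia", "post dates induction"),
    Psychiatric = c("suicidal ideation", "psychosis", "schizophrenia",
                    "acute behavioural disturbance", "intentional overdose",
                    "mental health assessment", "deteriorating mental state",
                    "self harm", "mania", "paranoid ideation",
                    "auditory hallucinations", "MHA assessment",
                    "acute psychotic episode", "severe depression",
                    "aggressive behaviour psych", "drug induced psychosis"),
    # shorthand common to the three confusable specialties
    shared = c("abdo pain", "vomiting", "unwell ?cause", "generalised pain",
               "collapse", "bleeding", "back pain", "headache", "weakness",
               "for assessment", "transfer for review", "deteriorating",
               "hypotensive", "febrile", "not eating", "pain ++",
               "review needed", "unstable", "drowsy", "sore leg"))
}

retrieval_abbreviations <- function() {
  c("shortness of breath" = "SOB", "acute kidney injury" = "AKI",
    "motor vehicle accident" = "MVA", "schizophrenia" = "schitz",
    "urinary tract infection" = "UTI", "diabetic ketoacidosis" = "DKA",
    "deteriorating mental state" = "detiorating mental state",
    "pre-eclampsia" = "PET", "heart failure" = "CCF",
    "suicidal ideation" = "SI", "head injury" = "HI",
    "acute behavioural disturbance" = "ABD", "intentional overdose" = "OD")
}

#' Gold stroke category from cue-term presence
#'
#' Encodes the clinical labelling precedence used for the stroke coding
#' task: any ischaemic cue labels the record Ischaemic even if a
#' haemorrhagic cue is also present; otherwise a haemorrhagic
#' (intracerebral) cue labels it Haemorrhagic; subdural/subarachnoid/
#' unspecified-intracranial cues alone are labelled Not.
#'
#' @param has_isch,has_haem,has_trap logical cue-presence flags.
#' @param categories the three category names, in (ischaemic,
#'   haemorrhagic, not) order.
#' @return one category string.
#' @export
stroke_category <- function(has_isch, has_haem, has_trap = FALSE,
                            categories = c("Isch", "Haem", "Not")) {
  if (has_isch) categories[1]
  else if (has_haem) categories[2]
  else categories[3]
}

#' Specify a synthetic corpus
#'
#' @param task `"mortality-3class"`, `"retrieval-5class"` or `"custom"`.
#' @param n_records number of records to generate.
#' @param class_proportions named numeric vector over the task's categories
#'   (must sum to 1).
#' @param style_mix fraction of coroner-style all-caps legal records
#'   (mortality task only).
#' @param typo_rate per-character perturbation probability.
#' @param abbreviation_rate probability a term with a known shorthand form
#'   is abbreviated (retrieval task).
#' @param overlap probability a confusable-class term is drawn from the
#'   shared vocabulary instead of the class's own list.
#' @param trap_rate probability a mortality 'Not' record carries a
#'   haemorrhage-adjacent non-stroke clause (subdural/subarachnoid).
#' @param vocab per-class keyword lists; defaults to the shipped lists for
#'   the task.
#' @param seed generation seed.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(task = c("mortality-3class", "retrieval-5class", "custom"),
                        n_records = 1000L,
                        class_proportions = NULL,
                        style_mix = 0.2, typo_rate = 0.01,
                        abbreviation_rate = 0.4, overlap = 0.25,
                        trap_rate = 0.12, vocab = NULL, seed = 1L) {
  task <- match.arg(task)
  if (is.null(class_proportions)) {
    class_proportions <- switch(task,
      "mortality-3class" = c(Isch = 0.06, Haem = 0.03, Not = 0.91),
      "retrieval-5class" = c(Medical = 0.45, Surgical = 0.20, Trauma = 0.15,
                             Obstetric = 0.12, Psychiatric = 0.08),
      stop("custom tasks must supply class_proportions"))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1")
  }
  rates <- c(style_mix, typo_rate, abbreviation_rate, overlap, trap_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (is.null(vocab)) {
    vocab <- switch(task, "mortality-3class" = stroke_vocab(),
                    "retrieval-5class" = retrieval_vocab(), NULL)
  }
  structure(list(task = task, n_records = as.integer(n_records),
                 class_proportions = class_proportions,
                 style_mix = style_mix, typo_rate = typo_rate,
                 abbreviation_rate = abbreviation_rate, overlap = overlap,
                 trap_rate = trap_rate, vocab = vocab,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Inject typographical errors
#'
#' Each character is independently perturbed with probability `rate` by an
#' operator drawn uniformly from: swap with the following character, drop,
#' or duplicate -- the error kinds seen in hand-transcribed clinical text.
#' Uses the current RNG state.
#'
#' @param text a single string.
#' @param rate per-character perturbation probability.
#' @return the perturbed string; attribute `n_ops` counts perturbations.
#' @export
inject_typos <- function(text, rate) {
  if (rate <= 0 || !nchar(text)) return(structure(text, n_ops = 0L))
  ch <- strsplit(text, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ops <- sample(c("swap", "drop", "dup"), sum(hit), replace = TRUE)
  j <- 1L
  for (i in which(hit)) {
    op <- ops[j]; j <- j + 1L
    if (op == "swap") {
      k <- if (i < length(ch)) i + 1L else i - 1L
      if (k >= 1L) { tmp <- ch[i]; ch[i] <- ch[k]; ch[k] <- tmp }
    } else if (op == "drop") {
      ch[i] <- ""
    } else {
      ch[i] <- paste0(ch[i], ch[i])
    }
  }
  structure(paste(ch, collapse = ""), n_ops = sum(hit))
}

duration_suffix <- function() {
  unit <- sample(c("Years", "Months", "Weeks", "Days", "Hours", "Minutes"),
                 1, prob = c(0.4, 0.2, 0.1, 0.15, 0.1, 0.05))
  n <- sample(1:20, 1)
  sprintf(" (%d %s)", n, unit)
}

gen_mortality_record <- function(label, spec) {
  v <- spec$vocab
  k <- sample(1:4, 1, prob = c(0.35, 0.3, 0.2, 0.15))
  clauses <- sample(v$not_, k, replace = FALSE)
  has_isch <- FALSE; has_haem <- FALSE; has_trap <- FALSE
  slot <- sample(seq_len(k), 1)
  if (label == "Isch") {
    clauses[slot] <- sample(v$isch, 1)
    has_isch <- TRUE
    if (k >= 2 && stats::runif(1) < 0.1) { # old bleed recorded too; still Isch
      free <- setdiff(seq_len(k), slot)
      other <- if (length(free) == 1L) free else sample(free, 1)
      clauses[other] <- sample(v$haem, 1)
      has_haem <- TRUE
    }
  } else if (label == "Haem") {
    clauses[slot] <- sample(v$haem, 1)
    has_haem <- TRUE
  } else if (stats::runif(1) < spec$trap_rate) {
    clauses[slot] <- sample(v$trap, 1)
    has_trap <- TRUE
  }
  dur <- stats::runif(k) < 0.6
  clauses[dur] <- paste0(clauses[dur], vapply(seq_len(sum(dur)),
                                              function(i) duration_suffix(), ""))
  text <- paste(clauses, collapse = ";")
  if (stats::runif(1) < spec$style_mix) {
    text <- toupper(paste0("INQUEST DISPENSED WITH - DIED FROM NATURAL CAUSES BEING ",
                           text))
  }
  text <- as.character(inject_typos(text, spec$typo_rate))
  gold <- stroke_category(has_isch, has_haem, has_trap,
                          names(spec$class_proportions))
  list(text = text, gold = gold)
}

gen_retrieval_record <- function(label, spec) {
  v <- spec$vocab
  confusable <- c("Medical", "Surgical", "Trauma")
  k <- sample(1:3, 1, prob = c(0.45, 0.4, 0.15))
  shared_p <- if (label %in% confusable) spec$overlap else 0.05
  terms <- vapply(seq_len(k), function(i) {
    pool <- if (stats::runif(1) < shared_p) v$shared else v[[label]]
    sample(pool, 1)
  }, "")
  abbr <- retrieval_abbreviations()
  swap <- terms %in% names(abbr) & stats::runif(k) < spec$abbreviation_rate
  terms[swap] <- abbr[terms[swap]]
  text <- paste(terms, collapse = sample(c(", ", " ", "; "), 1,
                                         prob = c(0.5, 0.35, 0.15)))
  text <- as.character(inject_typos(text, spec$typo_rate))
  list(text = text, gold = label)
}

#' Generate a synthetic gold-labelled corpus
#'
#' Fully deterministic given the spec's seed.  Mortality records are 1-4
#' semicolon-separated cause clauses, optionally suffixed with a duration in
#' parentheses, with a `style_mix` fraction prefixed by an all-caps
#' coroner-style preamble; gold labels respect the stroke precedence rules
#' (see [stroke_category()]).  Retrieval records are 1-3 shorthand terms
#' with abbreviations, drawn from per-class vocabularies that overlap for
#' the confusable Medical/Surgical/Trauma group.  Supplementary features:
#' age and sex (both tasks, with some missingness), indigenous status
#' (mortality), triage priority 1-6 (retrieval).
#'
#' @param spec a [corpus_spec()].
#' @return an `hitl_corpus` with gold labels.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  cats <- names(spec$class_proportions)
  cb <- codebook(spec$task, cats)
  withr::with_seed(spec$seed, {
    n <- spec$n_records
    labels <- sample(cats, n, replace = TRUE, prob = spec$class_proportions)
    gen <- if (spec$task == "retrieval-5class") gen_retrieval_record
           else gen_mortality_record
    recs <- lapply(labels, gen, spec = spec)
    df <- data.frame(id = sprintf("s%06d", seq_len(n)),
                     text = vapply(recs, `[[`, "", "text"),
                     gold = vapply(recs, `[[`, "", "gold"),
                     stringsAsFactors = FALSE)
    # supplementary features, loosely class-dependent, with missingness
    if (spec$task == "retrieval-5class") {
      df$age <- round(ifelse(df$gold == "Obstetric", stats::runif(n, 16, 42),
                      ifelse(df$gold == "Trauma", stats::runif(n, 5, 60),
                             stats::runif(n, 1, 90))))
      df$sex <- ifelse(df$gold == "Obstetric", "F",
                       sample(c("M", "F"), n, replace = TRUE))
      df$priority <- as.character(pmin(6, pmax(1,
        round(stats::rnorm(n, ifelse(df$gold %in% c("Trauma", "Obstetric"), 2.2, 3.2), 1.1)))))
      cat_feats <- c("sex", "priority"); num_feats <- "age"
    } else {
      df$age <- round(ifelse(df$gold == "Not", stats::runif(n, 20, 95),
                             stats::runif(n, 45, 95)))
      df$sex <- sample(c("M", "F"), n, replace = TRUE)
      df$indigenous <- sample(c("Y", "N"), n, replace = TRUE, prob = c(0.3, 0.7))
      cat_feats <- c("sex", "indigenous"); num_feats <- "age"
    }
    for (f in cat_feats) df[[f]][stats::runif(n) < 0.05] <- NA
    df$age[stats::runif(n) < 0.05] <- NA
    as_corpus(df, cb, cat_features = cat_feats, num_features = num_feats)
  })
}

#' Shipped benchmark corpus specifications
#'
#' Three named presets exercise the loop under different difficulty
#' regimes:
#' * `mortality-easy` -- disjoint vocabularies (no haemorrhage-adjacent
#'   traps, no typos, no coroner preambles), balanced-ish classes; exactness
#'   tests can reach accuracy 1.0.
#' * `mortality-hard` -- realistic imbalance (6% ischaemic, 3% haemorrhagic),
#'   subdural/subarachnoid trap clauses, typos, coroner-style records.
#' * `retrieval-hard` -- five classes with rare Psychiatric/Obstetric and an
#'   overlapping Medical/Surgical/Trauma shorthand vocabulary.
#'
#' @param name preset name.
#' @param n corpus size override (defaults: 2,000 easy / 10,000 hard).
#' @param seed generation seed.
#' @return a [corpus_spec()].
#' @export
benchmark_spec <- function(name = c("mortality-easy", "mortality-hard",
                                    "retrieval-hard"),
                           n = NULL, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "mortality-easy" = {
      v <- stroke_vocab()
      # drop every 'Not' cause sharing a stroke cue word, and the
      # stroke-worded haemorrhage terms, so the class cues are disjoint
      v$not_ <- v$not_[!grepl("ischaemic|infarct|haemorrhag|stroke|cva|cerebr",
                              v$not_, ignore.case = TRUE)]
      v$haem <- v$haem[!grepl("stroke|cva", v$haem, ignore.case = TRUE)]
      corpus_spec("mortality-3class", n_records = n %||% 2000L,
                  class_proportions = c(Isch = 0.25, Haem = 0.15, Not = 0.60),
                  style_mix = 0, typo_rate = 0, trap_rate = 0,
                  vocab = v, seed = seed)
    },
    "mortality-hard" = corpus_spec("mortality-3class", n_records = n %||% 10000L,
                                   seed = seed),
    "retrieval-hard" = corpus_spec("retrieval-5class", n_records = n %||% 10000L,
                                   seed = seed))
}

#' All benchmark presets
#'
#' @param seed generation seed passed to every preset.
#' @return named list of [corpus_spec()] objects.
#' @export
standard_benchmarks <- function(seed = 1L) {
  names <- c("mortality-easy", "mortality-hard", "retrieval-hard")
  stats::setNames(lapply(names, benchmark_spec, seed = seed), names)
}

#' Keyword lists for rare-category test enrichment
#'
#' Default text-search keywords per category used when building balanced
#' test sets on the benchmark tasks (rare categories cannot be filled by
#' random sampling alone).
#'
#' @param task `"mortality-3class"` or `"retrieval-5class"`.
#' @return named list: category -> character vector of keywords.
#' @export
benchmark_keywords <- function(task = c("mortality-3class", "retrieval-5class")) {
  task <- match.arg(task)
  switch(task,
    "mortality-3class" = list(
      Isch = c("stroke", "infarct", "cva", "cerebrovascular", "thrombosis"),
      Haem = c("intracerebral", "haemorrhagic", "pontine", "basal ganglia"),
      Not = c("failure", "cancer", "pneumonia")),
    "retrieval-5class" = list(
      Medical = c("pain", "sepsis", "pneumonia", "sob"),
      Surgical = c("abdo", "abscess", "hernia", "appendic"),
      Trauma = c("#", "mva", "injury", "fall", "wound"),
      Obstetric = c("labour", "prom", "40", "eclampsia", "pv"),
      Psychiatric = c("mental", "psych", "suicid", "overdose", "schitz",
                      "self harm")))
}
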