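# Psycholinguistic norm handling (age of acquisition, concreteness, valence,
# arousal, frequency), word-preservation coding across transitions, and the
# preservation / story-mean AOA analyses.

RC_NORM_NAMES <- c("aoa", "concreteness", "valence", "arousal", "frequency")

rc_read_norm <- function(path, preset = c("plain", "kuperman")) {
  preset <- match.arg(preset)
  if (!file.exists(path)) stop("norm file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df))
    return(data.frame(word = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  if (preset == "kuperman") {
    # Kuperman et al. column layout: Word, Rating.Mean
    need <- c("Word", "Rating.Mean")
    if (!all(need %in% names(df)))
      stop("kuperman preset expects columns Word, Rating.Mean in ", path)
    df <- data.frame(word = df$Word, value = df$Rating.Mean,
                     stringsAsFactors = FALSE)
  }
  if (!all(c("word", "value") %in% names(df)))
    stop("norm file ", path, " must have columns word, value")
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1]
    stop("norm parse error in ", path, ": non-numeric value at data line ",
         bad)
  }
  data.frame(word = tolower(trimws(df$word)), value = val,
             stringsAsFactors = FALSE)
}

#' Load psycholinguistic norm tables
#'
#' Each file is a CSV with columns `word`, `value` (the `"kuperman"` preset
#' accepts the `Word`/`Rating.Mean` layout). Duplicate words are resolved by
#' the mean. Word length in characters is derived, not read.
#'
#' @param paths named character vector or list mapping a norm name (subset of
#'   `aoa`, `concreteness`, `valence`, `arousal`, `frequency`) to a file path.
#' @param preset column-layout preset applied to every file.
#' @return An object of class `norm_table`: data.frame keyed by `word` with
#'   one column per loaded norm plus `length`.
#' @export
load_norms <- function(paths, preset = c("plain", "kuperman")) {
  preset <- match.arg(preset)
  stopifnot(length(paths) > 0, !is.null(names(paths)))
  unknown <- setdiff(names(paths), RC_NORM_NAMES)
  if (length(unknown))
    stop("unknown norm name(s): ", paste(unknown, collapse = ", "))
  tabs <- lapply(names(paths), function(nm) {
    df <- rc_read_norm(paths[[nm]], preset)
    if (!nrow(df)) {
      out <- data.frame(word = character(), stringsAsFactors = FALSE)
      out[[nm]] <- numeric()
      return(out)
    }
    agg <- stats::aggregate(list(value = df$value), list(word = df$word),
                            mean)
    names(agg)[2] <- nm
    agg
  })
  out <- Reduce(function(a, b) merge(a, b, by = "word", all = TRUE), tabs)
  out$length <- nchar(out$word)
  out <- out[order(out$word), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("norm_table", "data.frame")
  out
}

#' Fraction of a lexicon covered by a norm table
#'
#' @param norms a `norm_table`.
#' @param words character vector of words to check.
#' @param norm which norm column must be non-missing (default `"aoa"`).
#' @return proportion of `words` with a value.
#' @export
norm_coverage <- function(norms, words, norm = "aoa") {
  words <- tolower(words)
  i <- match(words, norms$word)
  mean(!is.na(i) & !is.na(norms[[norm]][i]))
}

#' Code lemma-type preservation between a parent and a child story
#'
#' One record per distinct lemma type of the parent story; `preserved` is
#' TRUE iff the lemma occurs in the child story (so inflectional variants
#' match through lemmatization). Norms are attached where available.
#'
#' @param parent,child `story_annotation`s (non-empty).
#' @param norms optional `norm_table`.
#' @param chain_id,transition,producer metadata carried into the records.
#' @param unit `"type"` (default) or `"token"`: token mode emits one record
#'   per parent token instead of per type.
#' @return data.frame of preservation records.
#' @export
code_preservation <- function(parent, child, norms = NULL,
                              chain_id = NA_character_, transition = NA,
                              producer = NA_character_,
                              unit = c("type", "token")) {
  unit <- match.arg(unit)
  if (parent$word_count == 0L || child$word_count == 0L)
    stop("code_preservation requires non-empty parent and child annotations")
  lemmas <- parent$tokens$lemma
  if (unit == "type") lemmas <- unique(lemmas)
  child_lemmas <- unique(child$tokens$lemma)
  rec <- data.frame(chain_id = chain_id, transition = transition,
                    producer = producer, word = lemmas,
                    preserved = lemmas %in% child_lemmas,
                    stringsAsFactors = FALSE)
  if (!is.null(norms)) {
    i <- match(rec$word, norms$word)
    for (col in setdiff(names(norms), "word"))
      rec[[col]] <- norms[[col]][i]
  }
  rec
}

#' Preservation records for a whole corpus
#'
#' Applies [code_preservation()] to every transition (0->1, 1->2, 2->3) of
#' every chain.
#'
#' @param chains list of chains.
#' @param norms a `norm_table`.
#' @param annotations optional list (per chain) of 4 `story_annotation`s.
#' @param ... passed to [code_preservation()].
#' @return row-bound preservation records.
#' @export
preservation_records <- function(chains, norms = NULL, annotations = NULL,
                                 ...) {
  rows <- lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    anns <- if (is.null(annotations))
      lapply(ch$versions, function(v) annotate_story(v$text))
    else annotations[[ci]]
    do.call(rbind, lapply(1:3, function(r) {
      code_preservation(anns[[r]], anns[[r + 1L]], norms,
                        chain_id = ch$chain_id, transition = r,
                        producer = ch$producer, ...)
    }))
  })
  do.call(rbind, rows)
}

#' Logistic model of word preservation
#'
#' Fits `preserved ~ producer * aoa + frequency + length + concreteness +
#' valence` by maximum likelihood with all predictors standardized (z-scored
#' over complete cases) and the producer effect-coded (human = +1/2,
#' llm = -1/2), so the `producer:aoa` coefficient is the human-minus-llm
#' difference in AOA slopes. Records lacking any norm are dropped with a
#' logged count.
#'
#' @param records preservation records (see [preservation_records()]) with
#'   columns `preserved`, `producer`, and the five norm columns.
#' @param predictors covariates beside `aoa` (default the conventional four).
#' @return list with `coefficients` (estimate, se, z, p), per-producer AOA
#'   slopes, `n_used`, `n_dropped`, and the fitted `glm` object.
#' @export
fit_preservation_model <- function(records,
                                   predictors = c("frequency", "length",
                                                  "concreteness",
                                                  "valence")) {
  need <- c("aoa", predictors)
  stopifnot(all(c("preserved", "producer", need) %in% names(records)))
  if (length(unique(records$producer)) < 2L)
    stop("records from both producers are required")
  keep <- stats::complete.cases(records[, need, drop = FALSE])
  n_dropped <- sum(!keep)
  d <- records[keep, , drop = FALSE]
  if (nrow(d) < 10 * (length(need) + 2L))
    stop("too few complete-case records (", nrow(d), ") for ",
         length(need) + 2L, " predictors")
  for (col in need) d[[col]] <- as.numeric(scale(d[[col]]))
  d$producer_ec <- ifelse(d$producer == "human", 0.5, -0.5)
  form <- stats::as.formula(paste(
    "preserved ~ producer_ec * aoa +",
    paste(predictors, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = d)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop("possible perfect separation in the preservation model; ",
         "consider a penalized (e.g. ridge/Firth) fallback")
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  # producer-specific AOA slopes: aoa +- interaction/2 under +-1/2 coding
  V <- stats::vcov(fit)
  b <- stats::coef(fit)
  int <- "producer_ec:aoa"
  slope <- function(w) {
    est <- b[["aoa"]] + w * b[[int]]
    se <- sqrt(V["aoa", "aoa"] + w^2 * V[int, int] +
                 2 * w * V["aoa", int])
    c(estimate = est, se = se, z = est / se,
      p = 2 * stats::pnorm(-abs(est / se)))
  }
  list(coefficients = coefs,
       aoa_slope_human = slope(0.5), aoa_slope_llm = slope(-0.5),
       n_used = nrow(d), n_dropped = n_dropped, fit = fit)
}

#' Story-mean age of acquisition
#'
#' Unweighted mean of AOA over tokens with a norm (tokens, not types:
#' repeated words count repeatedly), all categories included.
#'
#' @param annotation a `story_annotation`.
#' @param norms a `norm_table` with an `aoa` column.
#' @return list with `mean` (years) and `coverage` (covered tokens / tokens).
#' @export
story_mean_aoa <- function(annotation, norms) {
  if (annotation$word_count == 0L)
    stop("story_mean_aoa undefined for an empty story")
  a <- norms$aoa[match(annotation$tokens$lemma, norms$word)]
  if (all(is.na(a)))
    stop("story_mean_aoa undefined: no token has an AOA norm")
  list(mean = mean(a, na.rm = TRUE), coverage = mean(!is.na(a)))
}

#' Per-story mean AOA table for a corpus
#'
#' @param chains list of chains.
#' @param norms a `norm_table`.
#' @return data.frame with one row per story version (`NA` mean when no
#'   token is covered).
#' @export
story_aoa_table <- function(chains, norms) {
  rows <- lapply(chains, function(ch) {
    do.call(rbind, lapply(ch$versions, function(v) {
      ann <- annotate_story(v$text)
      res <- tryCatch(story_mean_aoa(ann, norms),
                      error = function(e) list(mean = NA_real_,
                                               coverage = 0))
      data.frame(chain_id = ch$chain_id,
                 retelling_index = v$retelling_index,
                 producer = v$producer, condition = ch$condition,
                 mean_aoa = res$mean, coverage = res$coverage,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
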