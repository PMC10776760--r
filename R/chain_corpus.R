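# -- constants shared across the package --------------------------------------

#' Allowed values of the experimental design factors
#'
#' `rc_conditions()` returns the four emotion conditions of the design,
#' `rc_producers()` the two producer classes, and `rc_rating_items()` the four
#' rating items collected for every retelling.
#'
#' @return Character vector of levels.
#' @export
rc_conditions <- function() c("happy", "mildly_happy", "mildly_sad", "sad")

#' @rdname rc_conditions
#' @export
rc_producers <- function() c("human", "llm")

#' @rdname rc_conditions
#' @export
rc_rating_items <- function() c("happiness", "sadness", "picture", "affected")

# Retellings per chain: index 0 is the original story, 1-3 the retellings.
RC_INDICES <- 0:3

# -- text normalization -------------------------------------------------------

#' Normalize typographic characters to ASCII
#'
#' Replaces smart quotes, dashes and common ligatures with ASCII equivalents
#' and collapses whitespace runs. Applied to every story text on load so the
#' tokenizer sees a single apostrophe convention.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  from <- c("‘", "’", "‚", "“", "”", "„",
            "–", "—", "…", "ﬁ", "ﬂ", " ")
  to <- c("'", "'", "'", "\"", "\"", "\"", "-", "-", "...", "fi", "fl", " ")
  for (i in seq_along(from)) x <- gsub(from[i], to[i], x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# -- constructors -------------------------------------------------------------

#' Construct a single story version
#'
#' @param chain_id opaque chain identifier.
#' @param retelling_index integer 0-3; 0 is the original story.
#' @param producer `"human"` or `"llm"` (who produced retellings 1-3; the
#'   original at index 0 is always human-authored).
#' @param condition one of [rc_conditions()].
#' @param text story text (UTF-8; normalized on construction).
#' @return An object of class `story_version`.
#' @export
story_version <- function(chain_id, retelling_index, producer, condition, text) {
  retelling_index <- as.integer(retelling_index)
  if (!retelling_index %in% RC_INDICES)
    stop("retelling_index must be one of 0,1,2,3, got ", retelling_index)
  producer <- match.arg(producer, rc_producers())
  condition <- match.arg(condition, rc_conditions())
  text <- normalize_text(as.character(text))
  structure(
    list(chain_id = as.character(chain_id),
         retelling_index = retelling_index,
         producer = producer, condition = condition, text = text),
    class = "story_version")
}

#' Construct a transmission chain of four story versions
#'
#' @param versions list of four [story_version()] objects with retelling
#'   indices 0..3, same chain_id and condition.
#' @return An object of class `chain`.
#' @export
chain <- function(versions) {
  stopifnot(is.list(versions))
  if (length(versions) != 4L)
    stop("a chain needs exactly 4 versions, got ", length(versions))
  idx <- vapply(versions, function(v) v$retelling_index, integer(1))
  versions <- versions[order(idx)]
  idx <- sort(idx)
  if (!identical(idx, RC_INDICES))
    stop("retelling indices must be exactly 0,1,2,3 with no gaps/duplicates")
  ids <- unique(vapply(versions, function(v) v$chain_id, character(1)))
  conds <- unique(vapply(versions, function(v) v$condition, character(1)))
  if (length(ids) != 1L) stop("versions disagree on chain_id: ",
                              paste(ids, collapse = ", "))
  if (length(conds) != 1L) stop("versions disagree on condition for chain ",
                                ids)
  structure(
    list(chain_id = ids, condition = conds,
         producer = versions[[2L]]$producer, versions = versions),
    class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain %s: %s, producer=%s, %d versions>\n",
              x$chain_id, x$condition, x$producer, length(x$versions)))
  invisible(x)
}

# -- corpus i/o ---------------------------------------------------------------

RC_CORPUS_COLS <- c("chain_id", "retelling_index", "producer", "condition",
                    "text")
RC_RATING_COLS <- c("chain_id", "retelling_index", "item", "rater_id",
                    "score", "scale_min", "scale_max")

rc_read_table <- function(path, format) {
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(data.frame())
    rows <- lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Load a transmission-chain corpus
#'
#' Reads rows of `{chain_id, retelling_index, producer, condition, text}` from
#' CSV or JSON-lines, groups them into chains and validates the chain
#' invariants. The result is deterministic: chains ordered by `chain_id`,
#' versions by `retelling_index`, independent of input row order.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"` (default guessed from the extension).
#' @return list of [chain()] objects.
#' @export
load_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("jsonl", "ndjson"))
      "jsonl" else "csv"
  if (!file.exists(path)) stop("corpus file not found: ", path)
  df <- rc_read_table(path, format)
  if (!nrow(df)) return(list())
  missing <- setdiff(RC_CORPUS_COLS, names(df))
  if (length(missing))
    stop("corpus schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  df$retelling_index <- as.integer(df$retelling_index)
  bad <- tapply(df$retelling_index, df$chain_id, function(ix) {
    length(ix) != 4L || !identical(sort(ix), RC_INDICES)
  })
  if (any(bad))
    stop("corpus validation error: chain(s) without exactly versions 0-3: ",
         paste(names(bad)[bad], collapse = ", "))
  ids <- sort(unique(df$chain_id))
  lapply(ids, function(id) {
    sub <- df[df$chain_id == id, , drop = FALSE]
    sub <- sub[order(sub$retelling_index), , drop = FALSE]
    chain(lapply(seq_len(4L), function(i) {
      story_version(sub$chain_id[i], sub$retelling_index[i],
                    sub$producer[i], sub$condition[i], sub$text[i])
    }))
  })
}

#' Serialize chains back to the canonical corpus CSV
#'
#' Writes the canonical, byte-stable form: chains ordered by `chain_id`,
#' versions by `retelling_index`, fixed column order, no quoting beyond what
#' CSV requires. `load_corpus(write_corpus(x))` round-trips.
#'
#' @param chains list of [chain()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(chains, path) {
  df <- chains_to_df(chains)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Flatten chains into the tidy corpus data frame
#' @param chains list of [chain()] objects.
#' @return data.frame with the canonical corpus columns.
#' @export
chains_to_df <- function(chains) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  chains <- chains[order(ids)]
  rows <- lapply(chains, function(ch) {
    data.frame(
      chain_id = ch$chain_id,
      retelling_index = RC_INDICES,
      producer = vapply(ch$versions, function(v) v$producer, character(1)),
      condition = ch$condition,
      text = vapply(ch$versions, function(v) v$text, character(1)),
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(stats::setNames(
      as.data.frame(matrix(character(), 0, 5)), RC_CORPUS_COLS))
  do.call(rbind, rows)
}

#' Load affect rating records
#'
#' Ratings CSV columns: `chain_id, retelling_index, item, rater_id, score,
#' scale_min, scale_max`. The slider's numeric range is carried as data
#' because designs differ; scores outside `[scale_min, scale_max]` are
#' rejected, as are unknown item labels.
#'
#' @param path ratings CSV path.
#' @return data.frame of rating records (possibly 0 rows).
#' @export
load_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    out <- stats::setNames(as.data.frame(matrix(character(), 0, 7)),
                           RC_RATING_COLS)
    return(out)
  }
  missing <- setdiff(RC_RATING_COLS, names(df))
  if (length(missing))
    stop("ratings schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(unique(df$item), rc_rating_items())
  if (length(unknown))
    stop("unknown rating item label(s): ", paste(unknown, collapse = ", "))
  df$retelling_index <- as.integer(df$retelling_index)
  for (col in c("score", "scale_min", "scale_max"))
    df[[col]] <- as.numeric(df[[col]])
  if (anyNA(df$score)) stop("non-numeric score in ratings file")
  oob <- df$score < df$scale_min | df$score > df$scale_max
  if (any(oob))
    stop("score out of declared scale range in row(s) ",
         paste(utils::head(which(oob), 5L), collapse = ", "))
  df[order(df$chain_id, df$retelling_index, df$item, df$rater_id), ,
     drop = FALSE]
}

# -- validation ---------------------------------------------------------------

#' Validate a chain against the corpus rules
#'
#' Returns a character vector of issues, empty when all invariants hold.
#' Structural violations (empty text, bad indices) are errors; a low
#' in-lexicon token fraction (gibberish heuristic) is reported as a warning
#' string prefixed `"warning:"` since the original study excluded such chains
#' by hand.
#'
#' @param ch a [chain()] object.
#' @param lexicon optional character vector of known wordforms for the
#'   gibberish check (lowercased internally).
#' @param gibberish_threshold minimum fraction of tokens that must be in the
#'   lexicon (default 0.5).
#' @param min_chars minimum text length for human retellings (default 60,
#'   the corpus rule for simulated or collected human retellings).
#' @return character vector of issue descriptions.
#' @export
validate_chain <- function(ch, lexicon = NULL, gibberish_threshold = 0.5,
                           min_chars = 60) {
  issues <- character()
  for (v in ch$versions) {
    if (!nzchar(trimws(v$text)))
      issues <- c(issues,
                  sprintf("empty text at index %d", v$retelling_index))
    else if (v$producer == "human" && v$retelling_index > 0 &&
             nchar(v$text) < min_chars)
      issues <- c(issues, sprintf(
        "text under %d characters at index %d", min_chars,
        v$retelling_index))
  }
  if (!is.null(lexicon) && length(lexicon)) {
    lex <- tolower(lexicon)
    for (v in ch$versions) {
      toks <- tolower(tokenize(v$text))
      if (!length(toks)) next
      frac <- mean(toks %in% lex)
      if (frac < gibberish_threshold)
        issues <- c(issues, sprintf(
          "warning: possible gibberish at index %d (in-lexicon fraction %.2f < %.2f)",
          v$retelling_index, frac, gibberish_threshold))
    }
  }
  issues
}

#' Validate a whole corpus plus optional ratings
#'
#' @param chains list of chains.
#' @param ratings optional ratings data frame from [load_ratings()].
#' @inheritParams validate_chain
#' @return data.frame with columns `chain_id`, `issue`.
#' @export
validate_corpus <- function(chains, ratings = NULL, lexicon = NULL,
                            gibberish_threshold = 0.5) {
  out <- list()
  for (ch in chains) {
    iss <- validate_chain(ch, lexicon, gibberish_threshold)
    if (length(iss))
      out[[length(out) + 1L]] <- data.frame(chain_id = ch$chain_id,
                                            issue = iss,
                                            stringsAsFactors = FALSE)
  }
  if (!is.null(ratings) && nrow(ratings)) {
    known <- vapply(chains, function(ch) ch$chain_id, character(1))
    orphan <- setdiff(unique(ratings$chain_id), known)
    for (id in orphan)
      out[[length(out) + 1L]] <- data.frame(
        chain_id = id, issue = "ratings reference unknown chain_id",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain_id = character(), issue = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
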