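# Tokenization, Penn-style part-of-speech tagging and negation detection.
#
# No statistical tagger ships with the package's dependency set, so tagging
# is rule + lexicon based: an exhaustive closed-class lexicon plus a primary
# tag for common open-class words (inst/extdata/tag_lexicon.tsv), suffix
# heuristics, and two context rules. Category-level counts (the unit of every
# downstream analysis) are robust to residual tag ambiguity within a bucket.

RC_CATEGORIES <- c("verb", "adverb", "noun", "adjective", "pronoun",
                   "preposition", "negation", "other")

# clitic pieces produced by contraction splitting; kept verbatim so
# tokenize() is idempotent on its own output
RC_CLITICS <- c("'s", "'re", "'ll", "'ve", "'d", "'m")

# negation lexicon: not / n't / no (as determiner) are mandatory, the rest
# are the conventional additions and can be overridden per call
RC_NEGATION_DEFAULT <- c("not", "n't", "no", "never", "neither", "nor",
                         "none", "nothing", "nobody", "nowhere")

# irregular contraction stems: token minus the n't piece -> replacement stem
RC_NT_SPECIAL <- c("ca" = "can", "wo" = "will", "sha" = "shall",
                   "ai" = "is")

#' Tokenize a story text
#'
#' Whitespace splitting with punctuation stripping and contraction handling:
#' the `n't` piece becomes the token `"not"` (with `can't` -> `can not`,
#' `won't` -> `will not`), other clitics (`'s`, `'re`, `'ll`, `'ve`, `'d`,
#' `'m`) become separate tokens, punctuation-only tokens are dropped.
#' Surfaces keep their case; lowercasing happens at lemmatization.
#'
#' @param text a single character string (empty allowed).
#' @return character vector of word tokens.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  text <- normalize_text(text)
  if (!nzchar(text)) return(character())
  raw <- strsplit(text, "[[:space:]]+")[[1]]
  out <- character(0)
  for (tok in raw) {
    if (tolower(tok) %in% RC_CLITICS || tolower(tok) == "not") {
      out <- c(out, tok)
      next
    }
    # peel external punctuation, keep internal apostrophes/hyphens
    tok <- gsub("^[^[:alnum:]']+|[^[:alnum:]']+$", "", tok)
    tok <- gsub("^'+(?=[[:alnum:]])", "", tok, perl = TRUE) # quote, not clitic
    tok <- sub("'+$", "", tok)
    if (!nzchar(tok) || !grepl("[[:alnum:]]", tok)) next
    low <- tolower(tok)
    m <- regmatches(tok, regexpr("n't$", tok, ignore.case = TRUE))
    if (length(m) && nchar(tok) > 3) {
      stem <- substr(tok, 1L, nchar(tok) - 3L)
      sl <- tolower(stem)
      if (sl %in% names(RC_NT_SPECIAL)) stem <- RC_NT_SPECIAL[[sl]]
      out <- c(out, stem, "not")
      next
    }
    cl <- regmatches(low, regexpr("'(s|re|ll|ve|d|m)$", low))
    if (length(cl)) {
      stem <- substr(tok, 1L, nchar(tok) - nchar(cl))
      if (nzchar(stem)) out <- c(out, stem, cl) else out <- c(out, cl)
      next
    }
    out <- c(out, tok)
  }
  out
}

# -- tagger resource ----------------------------------------------------------

rc_env <- new.env(parent = emptyenv())

#' Load the tagger lexicon resource
#'
#' Reads the word -> Penn tag lexicon shipped in `inst/extdata`. A missing
#' resource is a configuration error naming the file. Cached per session.
#'
#' @param path optional override of the lexicon path.
#' @return named list: for each lowercased word a character vector of tags in
#'   priority order.
#' @export
load_tag_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(rc_env$tag_lexicon)) return(rc_env$tag_lexicon)
    path <- system.file("extdata", "tag_lexicon.tsv", package = "retellchain")
    if (!nzchar(path) || !file.exists(path))
      stop("tagger configuration error: resource 'tag_lexicon.tsv' not found")
    cache <- TRUE
  } else {
    if (!file.exists(path))
      stop("tagger configuration error: resource '", path, "' not found")
    cache <- FALSE
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  lex <- split(df$tag, df$word)
  if (cache) rc_env$tag_lexicon <- lex
  lex
}

rc_suffix_tag <- function(low) {
  if (grepl("^[0-9]+([.,][0-9]+)?(st|nd|rd|th)?$", low)) return("CD")
  if (grepl("ly$", low)) return("RB")
  if (grepl("ing$", low) && nchar(low) > 4) return("VBG")
  if (grepl("ed$", low) && nchar(low) > 3) return("VBD")
  if (grepl("(tion|sion|ment|ness|ity|ship|hood|ism|ance|ence|ist)s?$", low))
    return("NN")
  if (grepl("(ous|ful|ible|able|ive|ish|less|ical)$", low)) return("JJ")
  if (grepl("(ize|ise)$", low)) return("VB")
  if (grepl("s$", low) && !grepl("(ss|us|is)$", low) && nchar(low) > 3)
    return("NNS")
  "NN"
}

# choose among a word's candidate tags using the previous tag
rc_disambiguate <- function(tags, prev_tag) {
  if (length(tags) == 1L) return(tags[[1]])
  verbish <- grepl("^(V|MD)", tags)
  nounish <- grepl("^N", tags)
  if (!is.na(prev_tag)) {
    if (prev_tag %in% c("TO", "MD", "PRP", "WP", "RB") && any(verbish))
      return(tags[verbish][1])
    if (prev_tag %in% c("DT", "JJ", "PRP$", "IN", "CD") && any(nounish))
      return(tags[nounish][1])
  }
  tags[[1]]
}

rc_tag_sentence <- function(tokens, lexicon) {
  n <- length(tokens)
  tags <- character(n)
  prev <- NA_character_
  for (i in seq_len(n)) {
    tok <- tokens[i]
    low <- tolower(tok)
    if (low %in% RC_CLITICS) {
      tags[i] <- switch(low, "'s" = "POS", "'re" = "VBP", "'m" = "VBP",
                        "'ve" = "VBP", "'ll" = "MD", "'d" = "MD")
    } else if (!is.null(lexicon[[low]])) {
      tags[i] <- rc_disambiguate(lexicon[[low]], prev)
    } else if (i > 1L && grepl("^[A-Z]", tok)) {
      tags[i] <- "NNP"
    } else {
      tags[i] <- rc_suffix_tag(low)
    }
    # base-form verbs after modals / "to"
    if (!is.na(prev) && prev %in% c("MD", "TO") && grepl("^VB", tags[i]))
      tags[i] <- "VB"
    prev <- tags[i]
  }
  tags
}

# -- lemmatizer ---------------------------------------------------------------

RC_IRREGULAR <- c(
  was = "be", were = "be", is = "be", are = "be", am = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", doing = "do", went = "go", gone = "go",
  goes = "go", going = "go", said = "say", made = "make", took = "take",
  taken = "take", came = "come", saw = "see", seen = "see", got = "get",
  gotten = "get", gave = "give", given = "give", knew = "know",
  known = "know", thought = "think", told = "tell", felt = "feel",
  left = "leave", kept = "keep", ran = "run", sat = "sit", stood = "stand",
  found = "find", held = "hold", brought = "bring", began = "begin",
  begun = "begin", wrote = "write", written = "write", spoke = "speak",
  spoken = "speak", met = "meet", paid = "pay", lost = "lose",
  meant = "mean", spent = "spend", built = "build", sent = "send",
  fell = "fall", fallen = "fall", grew = "grow", grown = "grow",
  drew = "draw", drawn = "draw", flew = "fly", flown = "fly",
  drove = "drive", driven = "drive", ate = "eat", eaten = "eat",
  broke = "break", broken = "break", chose = "choose", chosen = "choose",
  bought = "buy", caught = "catch", taught = "teach", fought = "fight",
  sought = "seek", slept = "sleep", woke = "wake", woken = "wake",
  wore = "wear", worn = "wear", threw = "throw", thrown = "throw",
  heard = "hear", led = "lead", became = "become", lay = "lie",
  lying = "lie", men = "man", women = "woman", children = "child",
  feet = "foot", teeth = "tooth", mice = "mouse", wives = "wife",
  lives = "life", leaves = "leaf", better = "good", best = "good",
  worse = "bad", worst = "bad", an = "a")

rc_known_word <- function(w, lexicon) !is.null(lexicon[[w]])

rc_strip_suffix <- function(low, suffix, lexicon) {
  stem <- substr(low, 1L, nchar(low) - nchar(suffix))
  n <- nchar(stem)
  cands <- stem
  if (n >= 2 && substr(stem, n, n) == substr(stem, n - 1L, n - 1L) &&
      !substr(stem, n, n) %in% c("l", "s"))
    cands <- c(cands, substr(stem, 1L, n - 1L))    # running -> run
  cands <- c(cands, paste0(stem, "e"))             # making -> make
  for (cand in cands) if (rc_known_word(cand, lexicon)) return(cand)
  cands[[1]]
}

#' Lemmatize a token given its Penn tag
#'
#' Irregular-form table plus POS-aware suffix stripping validated against the
#' tag lexicon (`running` -> `run`, `watches` -> `watch`, `wives` -> `wife`).
#'
#' @param surface token surface form.
#' @param tag Penn Treebank tag.
#' @param lexicon tag lexicon (for stem validation); default package resource.
#' @return lowercase lemma string.
#' @export
lemmatize <- function(surface, tag = "NN", lexicon = load_tag_lexicon()) {
  low <- tolower(surface)
  if (low %in% names(RC_IRREGULAR)) return(RC_IRREGULAR[[low]])
  if (low %in% RC_CLITICS) return(low)
  if (grepl("^V", tag)) {
    if (grepl("ies$", low) && nchar(low) > 4)
      return(paste0(substr(low, 1L, nchar(low) - 3L), "y"))
    if (grepl("ing$", low) && nchar(low) > 4)
      return(rc_strip_suffix(low, "ing", lexicon))
    if (grepl("ed$", low) && nchar(low) > 3)
      return(rc_strip_suffix(low, "ed", lexicon))
    if (grepl("(ches|shes|sses|xes|zes)$", low))
      return(substr(low, 1L, nchar(low) - 2L))
    if (grepl("s$", low) && !grepl("ss$", low) && nchar(low) > 2)
      return(substr(low, 1L, nchar(low) - 1L))
  }
  if (grepl("^N", tag) && !grepl("^NNP", tag)) {
    if (grepl("ies$", low) && nchar(low) > 4)
      return(paste0(substr(low, 1L, nchar(low) - 3L), "y"))
    if (grepl("ves$", low) && nchar(low) > 4) {
      f <- paste0(substr(low, 1L, nchar(low) - 3L), "f")
      fe <- paste0(f, "e")
      if (rc_known_word(fe, lexicon)) return(fe)
      return(f)
    }
    if (grepl("(ches|shes|sses|xes|zes)$", low))
      return(substr(low, 1L, nchar(low) - 2L))
    if (grepl("s$", low) && !grepl("(ss|us|is)$", low) && nchar(low) > 3)
      return(substr(low, 1L, nchar(low) - 1L))
  }
  low
}

# -- category mapping ---------------------------------------------------------

rc_tag_category <- function(tag) {
  if (tag %in% c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "MD")) return("verb")
  if (tag %in% c("RB", "RBR", "RBS", "WRB")) return("adverb")
  if (tag %in% c("NN", "NNS", "NNP", "NNPS")) return("noun")
  if (tag %in% c("JJ", "JJR", "JJS")) return("adjective")
  if (tag %in% c("PRP", "PRP$", "WP", "WP$")) return("pronoun")
  if (tag %in% c("IN", "TO")) return("preposition")
  "other"
}

rc_split_sentences <- function(text) {
  text <- normalize_text(text)
  if (!nzchar(text)) return(character())
  parts <- strsplit(text, "(?<=[.!?;])[[:space:]]+", perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}

#' Annotate one story text
#'
#' Tokenizes sentence by sentence, tags every token, lemmatizes it, maps
#' Penn tags to the seven coarse categories (verb, adverb, noun, adjective,
#' pronoun, preposition, negation) plus `other`, and aggregates counts.
#' Tokens in the negation lexicon are categorized `negation` regardless of
#' their Penn tag, except `"no"` which only counts when used as a determiner.
#'
#' @param text story text.
#' @param negation_lexicon negation wordforms; `not`, `n't`, `no` are always
#'   included.
#' @param tag_lexicon tagger resource from [load_tag_lexicon()].
#' @return A `story_annotation`: list with `tokens` (data.frame of `surface`,
#'   `lemma`, `pos_tag`, `category`, `is_negation`, `sentence`),
#'   `word_count`, and named integer `category_counts`.
#' @export
annotate_story <- function(text, negation_lexicon = RC_NEGATION_DEFAULT,
                           tag_lexicon = load_tag_lexicon()) {
  negation_lexicon <- union(c("not", "n't", "no"), tolower(negation_lexicon))
  sents <- rc_split_sentences(text)
  tok_l <- list(); k <- 0L
  for (si in seq_along(sents)) {
    toks <- tokenize(sents[si])
    if (!length(toks)) next
    tags <- rc_tag_sentence(toks, tag_lexicon)
    lows <- tolower(toks)
    cats <- vapply(tags, rc_tag_category, character(1), USE.NAMES = FALSE)
    is_neg <- lows %in% setdiff(negation_lexicon, "no") |
      (lows == "no" & tags == "DT")
    cats[is_neg] <- "negation"
    lemmas <- vapply(seq_along(toks), function(i)
      lemmatize(toks[i], tags[i], tag_lexicon), character(1))
    k <- k + 1L
    tok_l[[k]] <- data.frame(surface = toks, lemma = lemmas, pos_tag = tags,
                             category = cats, is_negation = is_neg,
                             sentence = si, stringsAsFactors = FALSE)
  }
  tokens <- if (k) do.call(rbind, tok_l) else
    data.frame(surface = character(), lemma = character(),
               pos_tag = character(), category = character(),
               is_negation = logical(), sentence = integer(),
               stringsAsFactors = FALSE)
  counts <- stats::setNames(integer(length(RC_CATEGORIES)), RC_CATEGORIES)
  tb <- table(tokens$category)
  counts[names(tb)] <- as.integer(tb)
  structure(list(tokens = tokens, word_count = nrow(tokens),
                 category_counts = counts),
            class = "story_annotation")
}

#' @export
print.story_annotation <- function(x, ...) {
  cat(sprintf("<story_annotation: %d tokens>\n", x$word_count))
  print(x$category_counts)
  invisible(x)
}

#' Proportion of a part-of-speech category in a story
#'
#' @param annotation a `story_annotation`.
#' @param category one of the eight categories.
#' @return `category_counts[category] / word_count`.
#' @export
pos_proportion <- function(annotation, category) {
  category <- match.arg(category, RC_CATEGORIES)
  if (annotation$word_count == 0L)
    stop("pos_proportion undefined for an empty story (word_count = 0)")
  unname(annotation$category_counts[[category]] / annotation$word_count)
}

#' Tidy per-story annotation summary for a corpus
#'
#' @param chains list of chains.
#' @param ... passed to [annotate_story()].
#' @return data.frame with one row per story version: identifiers,
#'   `word_count` and one count column per category.
#' @export
annotate_corpus <- function(chains, ...) {
  rows <- lapply(chains, function(ch) {
    do.call(rbind, lapply(ch$versions, function(v) {
      ann <- annotate_story(v$text, ...)
      cbind(data.frame(chain_id = ch$chain_id,
                       retelling_index = v$retelling_index,
                       producer = v$producer, condition = ch$condition,
                       word_count = ann$word_count,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(ann$category_counts)))
    }))
  })
  do.call(rbind, rows)
}
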