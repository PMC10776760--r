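# Concept extraction against a WordNet-style sense inventory and
# per-transition transmission metrics (survival, novelty, density).
#
# The inventory is a plain-text TSV with one synset per row:
#   synset_id  pos  lemmas (comma-separated)  hypernyms (comma-sep or "-")  gloss
# Row order encodes sense priority: the first synset listing a lemma is its
# most frequent sense, used as the gloss-overlap tie-break.

RC_LEVELS <- c("synset", "lemma", "root_hypernym")

# annotation category -> inventory POS letter
RC_CAT_POS <- c(noun = "n", verb = "v", adjective = "a", adverb = "r")

#' Load a sense inventory
#'
#' @param path TSV file with columns `synset_id`, `pos`, `lemmas`,
#'   `hypernyms`, `gloss`.
#' @return An object of class `sense_inventory`: the synset table, a lemma ->
#'   row index, and precomputed root hypernyms.
#' @export
load_inventory <- function(path) {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("synset_id", "pos", "lemmas", "hypernyms", "gloss")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("inventory schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) stop("configuration error: empty sense inventory")
  if (anyDuplicated(df$synset_id))
    stop("inventory has duplicated synset_id(s)")
  lemma_l <- strsplit(tolower(df$lemmas), ",[[:space:]]*")
  index <- split(rep(seq_len(nrow(df)), lengths(lemma_l)), unlist(lemma_l))
  hyper_l <- strsplit(df$hypernyms, ",[[:space:]]*")
  hyper_l <- lapply(hyper_l, function(h) setdiff(h, c("-", "")))
  bad <- setdiff(unlist(hyper_l), df$synset_id)
  if (length(bad))
    stop("inventory hypernym pointer(s) to unknown synset: ",
         paste(bad, collapse = ", "))
  inv <- structure(list(synsets = df, lemma_index = index,
                        hypernyms = hyper_l),
                   class = "sense_inventory")
  inv$roots <- vapply(df$synset_id, function(id) rc_root_of(inv, id),
                      character(1))
  inv
}

#' @export
print.sense_inventory <- function(x, ...) {
  cat(sprintf("<sense_inventory: %d synsets, %d lemmas>\n",
              nrow(x$synsets), length(x$lemma_index)))
  invisible(x)
}

# topmost ancestor along the first hypernym path; when a synset has several
# hypernyms the lexicographically smallest id is followed
rc_root_of <- function(inv, synset_id) {
  seen <- character()
  id <- synset_id
  repeat {
    i <- match(id, inv$synsets$synset_id)
    h <- inv$hypernyms[[i]]
    if (!length(h)) return(id)
    nxt <- sort(h)[1]
    if (nxt %in% seen) return(id)  # defensive: cycle guard
    seen <- c(seen, id)
    id <- nxt
  }
}

rc_gloss_words <- function(inv, row) {
  g <- tolower(inv$synsets$gloss[row])
  unique(strsplit(gsub("[^a-z' ]", " ", g), "[[:space:]]+")[[1]])
}

#' Disambiguate one lemma in context (simplified gloss overlap)
#'
#' Candidate synsets are those listing the lemma (restricted to the token's
#' POS when any candidate matches). Each candidate is scored by the overlap
#' between its gloss plus co-lemmas and the sentence context; ties and empty
#' overlaps go to the inventory's first-listed (most frequent) sense.
#'
#' @param lemma lowercase lemma.
#' @param pos inventory POS letter (`"n"`, `"v"`, `"a"`, `"r"`) or `NA`.
#' @param context character vector of context lemmas (the token's sentence).
#' @param inventory a `sense_inventory`.
#' @return synset_id, or `NA_character_` when the lemma is not covered.
#' @export
disambiguate <- function(lemma, pos, context, inventory) {
  rows <- inventory$lemma_index[[lemma]]
  if (is.null(rows)) return(NA_character_)
  if (!is.na(pos)) {
    m <- rows[inventory$synsets$pos[rows] == pos]
    if (length(m)) rows <- m
  }
  if (length(rows) == 1L) return(inventory$synsets$synset_id[rows])
  context <- setdiff(unique(tolower(context)), lemma)
  scores <- vapply(rows, function(r) {
    sig <- union(rc_gloss_words(inventory, r),
                 tolower(strsplit(inventory$synsets$lemmas[r],
                                  ",[[:space:]]*")[[1]]))
    length(intersect(sig, context))
  }, numeric(1))
  inventory$synsets$synset_id[rows[which.max(scores)]]  # first-listed on tie
}

#' Extract the concept set of an annotated story
#'
#' Content tokens (noun, verb, adjective, adverb categories) are
#' sense-disambiguated in their sentence context; each covered token
#' contributes one identifier at the requested granularity. Tokens absent
#' from the inventory are skipped and reflected in the coverage statistic.
#'
#' @param annotation a `story_annotation`.
#' @param level `"synset"`, `"lemma"`, or `"root_hypernym"`.
#' @param inventory a `sense_inventory`.
#' @return An object of class `concept_set`: `level`, character `ids`
#'   (deduplicated), `source_word_count`, `coverage` (covered content tokens /
#'   content tokens; `NaN` when the story has none).
#' @export
extract_concepts <- function(annotation, level = RC_LEVELS,
                             inventory = NULL) {
  level <- match.arg(level, RC_LEVELS)
  if (is.null(inventory) || !inherits(inventory, "sense_inventory"))
    stop("configuration error: a loaded sense_inventory is required")
  tk <- annotation$tokens
  content <- tk[tk$category %in% names(RC_CAT_POS), , drop = FALSE]
  ids <- character(0)
  covered <- 0L
  if (nrow(content)) {
    sent_lemmas <- split(tk$lemma, tk$sentence)
    for (i in seq_len(nrow(content))) {
      lemma <- content$lemma[i]
      ctx <- sent_lemmas[[as.character(content$sentence[i])]]
      sid <- disambiguate(lemma, RC_CAT_POS[[content$category[i]]], ctx,
                          inventory)
      if (is.na(sid)) {
        if (level == "lemma") { covered <- covered + 1L; ids <- c(ids, lemma) }
        next
      }
      covered <- covered + 1L
      ids <- c(ids, switch(level,
        synset = sid,
        lemma = lemma,
        root_hypernym = inventory$roots[[match(sid,
                                               inventory$synsets$synset_id)]]))
    }
  }
  structure(list(level = level, ids = unique(ids),
                 source_word_count = annotation$word_count,
                 coverage = if (nrow(content)) covered / nrow(content)
                            else NaN),
            class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat(sprintf("<concept_set: %d %s ids, coverage %.2f>\n",
              length(x$ids), x$level, x$coverage))
  invisible(x)
}

rc_check_pair <- function(parent, child) {
  stopifnot(inherits(parent, "concept_set"), inherits(child, "concept_set"))
  if (!identical(parent$level, child$level))
    stop("concept-set level mismatch: ", parent$level, " vs ", child$level)
}

#' Concept survival from parent to child
#'
#' Fraction of the parent version's concepts that reappear in the child:
#' `|parent intersect child| / |parent|`.
#'
#' @param parent,child `concept_set`s at the same level.
#' @return proportion in `[0, 1]`.
#' @export
survival_rate <- function(parent, child) {
  rc_check_pair(parent, child)
  if (!length(parent$ids))
    stop("survival_rate undefined for an empty parent concept set")
  length(intersect(parent$ids, child$ids)) / length(parent$ids)
}

#' Concept novelty (creation) from parent to child
#'
#' Fraction of the child version's concepts absent from the parent:
#' `|child \ parent| / |child|`.
#'
#' @inheritParams survival_rate
#' @return proportion in `[0, 1]`.
#' @export
novelty_rate <- function(parent, child) {
  rc_check_pair(parent, child)
  if (!length(child$ids))
    stop("novelty_rate undefined for an empty child concept set")
  length(setdiff(child$ids, parent$ids)) / length(child$ids)
}

#' Per-transition transmission metrics for one chain
#'
#' Annotates (or reuses annotations of) the four versions, extracts concept
#' sets, and reports survival, novelty, child concept count and child density
#' (concepts per word) for the transitions 0->1, 1->2, 2->3.
#'
#' @param ch a [chain()].
#' @param level concept granularity.
#' @param inventory a `sense_inventory`.
#' @param annotations optional list of 4 precomputed `story_annotation`s.
#' @return data.frame with one row per transition.
#' @export
chain_metrics <- function(ch, level = RC_LEVELS, inventory = NULL,
                          annotations = NULL) {
  level <- match.arg(level, RC_LEVELS)
  if (is.null(annotations))
    annotations <- lapply(ch$versions, function(v) annotate_story(v$text))
  sets <- lapply(annotations, extract_concepts, level = level,
                 inventory = inventory)
  out <- lapply(1:3, function(r) {
    parent <- sets[[r]]; child <- sets[[r + 1L]]
    data.frame(
      chain_id = ch$chain_id, producer = ch$producer,
      condition = ch$condition, parent_index = r - 1L, child_index = r,
      level = level,
      survival = if (length(parent$ids)) survival_rate(parent, child)
                 else NA_real_,
      novelty = if (length(child$ids)) novelty_rate(parent, child)
                else NA_real_,
      child_count = length(child$ids),
      child_density = if (child$source_word_count > 0)
        length(child$ids) / child$source_word_count else NA_real_,
      child_coverage = child$coverage,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Transmission metrics for a whole corpus
#'
#' @param chains list of chains.
#' @inheritParams chain_metrics
#' @return row-bound [chain_metrics()] tables.
#' @export
corpus_metrics <- function(chains, level = RC_LEVELS, inventory = NULL) {
  level <- match.arg(level, RC_LEVELS)
  do.call(rbind, lapply(chains, chain_metrics, level = level,
                        inventory = inventory))
}
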