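# shared fixtures, all built in code or read from inst/extdata

rc_fixture <- function(name) {
  p <- system.file("extdata", name, package = "retellchain")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

toy_inventory <- function() load_inventory(rc_fixture("toy_inventory.tsv"))

# wordforms of the toy inventory (gibberish-check lexicon)
toy_lexicon_words <- function() {
  inv <- toy_inventory()
  unique(unlist(strsplit(tolower(inv$synsets$lemmas), ",")))
}

# a minimal well-formed 4-version chain
make_chain <- function(id = "c1", producer = "human",
                       condition = "happy",
                       texts = c(
                         "The old man watched the dog near the river in the morning sun.",
                         "The man saw a dog by the river and smiled at it for a while.",
                         "A man watched his dog run near the water on a quiet morning.",
                         "The man and the dog sat together by the river for the whole day.")) {
  chain(lapply(0:3, function(r)
    story_version(id, r, producer, condition, texts[r + 1L])))
}

# corpus CSV on disk from a data.frame of rows
write_corpus_rows <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

corpus_row <- function(chain_id, idx, producer = "human",
                       condition = "happy", text = strrep("word ", 20)) {
  data.frame(chain_id = chain_id, retelling_index = idx,
             producer = producer, condition = condition, text = text,
             stringsAsFactors = FALSE)
}

ratings_file <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

rating_row <- function(chain_id = "c1", idx = 0, item = "happiness",
                       rater = "r1", score = 50, lo = 0, hi = 100) {
  data.frame(chain_id = chain_id, retelling_index = idx, item = item,
             rater_id = rater, score = score, scale_min = lo,
             scale_max = hi, stringsAsFactors = FALSE)
}

# small concept_set literal
cs <- function(ids, level = "synset") {
  structure(list(level = level, ids = unique(ids),
                 source_word_count = length(ids), coverage = 1),
            class = "concept_set")
}
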