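# Seeded generators for chains, lexicons and ratings with recorded ground
# truth, so every analysis stage runs and is testable without downloads.
#
# The generators state a world mirroring the study's design: 4-version
# chains whose length decays geometrically, per-transition concept survival
# around 0.42 for the human profile vs 0.9 for the LLM profile, novelty
# filling the length budget, condition-dependent negation rates matching
# the reported cell proportions, and affect ratings drawn from the
# spine/compression likelihood. Presets live as data in
# inst/extdata/sim_presets.json.

#' Simulation parameter presets
#'
#' Loads the `"human"` or `"llm"` profile from the packaged preset file,
#' optionally overriding individual fields.
#'
#' @param preset `"human"` or `"llm"`.
#' @param ... named overrides of preset fields.
#' @return named list of simulation parameters.
#' @export
sim_params <- function(preset = c("human", "llm"), ...) {
  preset <- match.arg(preset)
  path <- system.file("extdata", "sim_presets.json", package = "retellchain")
  if (!nzchar(path)) stop("preset file not found")
  p <- jsonlite::fromJSON(path)[[preset]]
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

# pseudoword generator: unique CV-syllable forms. Forms colliding with the
# tagger lexicon, the irregular-lemma table or the negation lexicon are
# rejected so every simulated content word is tagged as an (unknown) noun
# and survives annotation unchanged.
rc_pseudowords <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  known <- tryCatch(names(load_tag_lexicon()), error = function(e)
    character())
  known <- c(known, names(RC_IRREGULAR), RC_NEGATION_DEFAULT)
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:3, n, replace = TRUE)
    w <- vapply(k, function(kk)
      paste0(paste0(sample(cons, kk, TRUE), sample(vow, kk, TRUE)),
             collapse = ""), character(1))
    out <- unique(c(out, setdiff(w, known)))
  }
  out[seq_len(n)]
}

#' Build a toy simulation lexicon
#'
#' Generates `n_synsets` synonym groups of pseudowords with categories,
#' hypernym roots and psycholinguistic norms drawn from documented
#' distributions: AOA ~ Normal(6, 2.5) truncated below at 1.5 years;
#' concreteness ~ Normal(3.5, 0.8) clamped to [1, 5]; valence ~
#' Normal(5, 1.5) clamped to [1, 9]; arousal ~ Normal(4, 1) clamped to
#' [1, 9]; frequency weights Zipf (1/rank). Deterministic given `seed`.
#'
#' @param n_synsets number of synonym groups (>= 10).
#' @param seed integer seed.
#' @param mean_aoa,sd_aoa AOA generating distribution (years).
#' @return An object of class `sim_lexicon`: `entries` (one row per
#'   wordform), `synsets` (one row per group, inventory layout), and the
#'   generating parameters.
#' @export
build_toy_lexicon <- function(n_synsets, seed = 1, mean_aoa = 6,
                              sd_aoa = 2.5) {
  if (n_synsets < 10) stop("n_synsets must be >= 10, got ", n_synsets)
  set.seed(as.integer(seed))
  n_roots <- max(2L, round(n_synsets * 0.05))
  cat_pool <- c("noun", "verb", "adjective", "adverb")
  cats <- c(rep("noun", n_roots),
            sample(cat_pool, n_synsets - n_roots, replace = TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.10)))
  pos <- c(noun = "n", verb = "v", adjective = "a", adverb = "r")[cats]
  sizes <- pmin(1L + stats::rpois(n_synsets, 0.6), 3L)
  forms <- rc_pseudowords(sum(sizes))
  grp <- rep(seq_len(n_synsets), sizes)
  ids <- sprintf("sim%04d.%s.01", seq_len(n_synsets), pos)
  hyper <- rep("-", n_synsets)
  assignable <- which(seq_len(n_synsets) > n_roots &
                        cats %in% c("noun", "verb"))
  hyper[assignable] <- ids[sample.int(n_roots, length(assignable),
                                      replace = TRUE)]
  # truncated-normal AOA per wordform, shared group norms otherwise
  rtnorm <- function(n, mu, sd, lower) {
    x <- stats::rnorm(n, mu, sd)
    while (any(x < lower)) x[x < lower] <- stats::rnorm(sum(x < lower),
                                                        mu, sd)
    x
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  aoa <- rtnorm(sum(sizes), mean_aoa, sd_aoa, 1.5)
  conc_g <- clamp(stats::rnorm(n_synsets, 3.5, 0.8), 1, 5)
  val_g <- clamp(stats::rnorm(n_synsets, 5, 1.5), 1, 9)
  aro_g <- clamp(stats::rnorm(n_synsets, 4, 1), 1, 9)
  w_g <- 1 / rank(sample.int(n_synsets))  # Zipf over a random rank order
  entries <- data.frame(
    wordform = forms, lemma = forms, category = cats[grp],
    synset_id = ids[grp], root_id = NA_character_,
    aoa = aoa, concreteness = conc_g[grp], valence = val_g[grp],
    arousal = aro_g[grp],
    frequency = log10(w_g[grp] / sum(w_g) * 1e6),
    weight = w_g[grp], stringsAsFactors = FALSE)
  gloss_src <- split(forms, grp)
  synsets <- data.frame(
    synset_id = ids, pos = unname(pos),
    lemmas = vapply(gloss_src, paste, character(1), collapse = ","),
    hypernyms = hyper,
    gloss = vapply(seq_len(n_synsets), function(i)
      paste(sample(forms, 4L), collapse = " "), character(1)),
    stringsAsFactors = FALSE)
  lex <- structure(list(entries = entries, synsets = synsets,
                        params = list(n_synsets = n_synsets, seed = seed,
                                      mean_aoa = mean_aoa, sd_aoa = sd_aoa)),
                   class = "sim_lexicon")
  inv <- rc_lexicon_inventory(lex)
  lex$entries$root_id <- inv$roots[match(lex$entries$synset_id,
                                         inv$synsets$synset_id)]
  lex$inventory <- inv
  lex
}

#' @export
print.sim_lexicon <- function(x, ...) {
  cat(sprintf("<sim_lexicon: %d synsets, %d wordforms>\n",
              nrow(x$synsets), nrow(x$entries)))
  invisible(x)
}

# in-memory inventory matching load_inventory() output
rc_lexicon_inventory <- function(lex) {
  df <- lex$synsets
  lemma_l <- strsplit(tolower(df$lemmas), ",[[:space:]]*")
  index <- split(rep(seq_len(nrow(df)), lengths(lemma_l)), unlist(lemma_l))
  hyper_l <- lapply(strsplit(df$hypernyms, ",[[:space:]]*"),
                    function(h) setdiff(h, c("-", "")))
  inv <- structure(list(synsets = df, lemma_index = index,
                        hypernyms = hyper_l),
                   class = "sense_inventory")
  inv$roots <- vapply(df$synset_id, function(id) rc_root_of(inv, id),
                      character(1))
  inv
}

#' Serialize a simulation lexicon as inventory + norm fixtures
#'
#' Writes `inventory.tsv` (the sense-inventory layout) and one
#' `<norm>.csv` per norm, mutually consistent with the lexicon.
#'
#' @param lex a `sim_lexicon`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_lexicon_fixtures <- function(lex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv_path <- file.path(dir, "inventory.tsv")
  utils::write.table(lex$synsets, inv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(inventory = inv_path)
  for (nm in RC_NORM_NAMES) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(data.frame(word = lex$entries$wordform,
                                value = lex$entries[[nm]]),
                     p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

# AOA tilt: exponent lambda such that the weighted mean AOA of sampling
# weights w * exp(lambda * aoa) equals the base weighted mean + shift
rc_aoa_tilt <- function(aoa, w, shift) {
  if (shift == 0) return(0)
  base <- sum(w * aoa) / sum(w)
  f <- function(l) sum(w * exp(l * (aoa - base)) * aoa) /
    sum(w * exp(l * (aoa - base))) - base - shift
  stats::uniroot(f, c(-5, 5), extendInt = "yes")$root
}

# render a concept-word sequence as templated sentences; negations are
# inserted as "not" before determiners at the requested per-word rate
rc_render <- function(words, negation_rate) {
  if (!length(words)) return("")
  frames <- list(c("The", 1, "of", "the", 2, "and", "the", 3),
                 c("The", 1, "with", "the", 2),
                 c("The", 1, "near", "the", 2, "and", "the", 3),
                 c("The", 1, "from", "the", 2))
  out <- character(0)
  i <- 1L
  fi <- 0L
  while (i <= length(words)) {
    fi <- fi %% length(frames) + 1L
    fr <- frames[[fi]]
    need <- sum(fr %in% c("1", "2", "3"))
    take <- min(need, length(words) - i + 1L)
    toks <- character(0)
    used <- 0L
    for (el in fr) {
      if (el %in% c("1", "2", "3")) {
        if (used < take) {
          used <- used + 1L
          toks <- c(toks, words[i + used - 1L])
        }
      } else toks <- c(toks, tolower(el))
    }
    i <- i + take
    toks[1] <- paste0(toupper(substr(toks[1], 1, 1)),
                      substr(toks[1], 2, nchar(toks[1])))
    out <- c(out, paste0(paste(toks, collapse = " "), "."))
  }
  text <- paste(out, collapse = " ")
  n_words <- length(strsplit(text, " ")[[1]])
  n_neg <- stats::rbinom(1, n_words, negation_rate)
  if (n_neg > 0) {
    toks <- strsplit(text, " ")[[1]]
    at <- which(tolower(toks) %in% c("the"))
    if (length(at)) {
      ins <- sample(at, min(n_neg, length(at)))
      for (j in sort(ins, decreasing = TRUE))
        toks <- append(toks, "not", after = j - 1L)
      text <- paste(toks, collapse = " ")
    }
  }
  text
}

#' Generate one transmission chain with ground truth
#'
#' Version 0 samples concepts by frequency with a condition-dependent
#' valence tilt. Each later version keeps every parent concept with
#' probability `p_surv` (survivors rendered as the same wordform, or a
#' synonym with probability `p_syn`), truncates/fills to the length target
#' `ceiling(parent_concepts * length_decay)`, and draws fresh concepts from
#' outside the parent set (AOA-tilted by `aoa_shift` from retelling 1 on).
#'
#' @param params from [sim_params()].
#' @param lexicon a `sim_lexicon`.
#' @param seed integer seed.
#' @param chain_id identifier for the generated chain.
#' @param condition emotion condition; default sampled uniformly.
#' @return list with `chain` (a [chain()]), `truth`: per-version character
#'   vectors of synset ids, wordforms, and summary bookkeeping
#'   (`expected_survival`, per-version concept counts, AOA means).
#' @export
generate_chain <- function(params, lexicon, seed = 1, chain_id = "sim001",
                           condition = NULL) {
  set.seed(as.integer(seed))
  if (is.null(condition))
    condition <- sample(rc_conditions(), 1)
  en <- lexicon$entries
  syn_groups <- split(seq_len(nrow(en)), en$synset_id)
  syn_ids <- names(syn_groups)
  w_syn <- vapply(syn_groups, function(ix) sum(en$weight[ix]), numeric(1))
  val_syn <- vapply(syn_groups, function(ix) en$valence[ix][1], numeric(1))
  vb <- params$valence_bias[[condition]]
  w0 <- w_syn * exp(vb * (val_syn - mean(val_syn)) / stats::sd(val_syn))
  n0 <- round(params$length0 * params$content_frac)
  if (n0 < 1) stop("target length < 1 concept; increase length0")
  n0 <- min(n0, length(syn_ids))
  neg_rate <- params$negation_rates[[condition]]
  pick_form <- function(sid, tilt_lambda = 0) {
    ix <- syn_groups[[sid]]
    if (length(ix) == 1L) return(en$wordform[ix])
    w <- en$weight[ix]
    if (tilt_lambda != 0) w <- w * exp(tilt_lambda * en$aoa[ix])
    en$wordform[ix][sample.int(length(ix), 1, prob = w)]
  }
  lambda <- rc_aoa_tilt(en$aoa, en$weight, params$aoa_shift)

  truth_sets <- vector("list", 4L)
  truth_words <- vector("list", 4L)
  ids0 <- sample(syn_ids, n0, prob = w0)
  words0 <- vapply(ids0, pick_form, character(1))
  truth_sets[[1]] <- ids0
  truth_words[[1]] <- words0
  texts <- character(4)
  texts[1] <- rc_render(words0, neg_rate)
  for (r in 1:3) {
    parent_ids <- truth_sets[[r]]
    parent_words <- truth_words[[r]]
    n_target <- max(1L, ceiling(length(parent_ids) * params$length_decay))
    keep <- stats::runif(length(parent_ids)) < params$p_surv
    surv_ids <- parent_ids[keep]
    surv_words <- parent_words[keep]
    if (length(surv_ids) > n_target) {
      sel <- sample.int(length(surv_ids), n_target)
      surv_ids <- surv_ids[sel]; surv_words <- surv_words[sel]
    }
    swap <- stats::runif(length(surv_ids)) < params$p_syn
    surv_words[swap] <- vapply(surv_ids[swap], pick_form, character(1),
                               tilt_lambda = lambda)
    n_fresh <- if (is.null(params$innovation_rate) ||
                   is.na(params$innovation_rate))
      n_target - length(surv_ids)
    else round(params$innovation_rate * n_target)
    n_fresh <- max(0L, n_fresh)
    pool <- setdiff(syn_ids, parent_ids)
    n_fresh <- min(n_fresh, length(pool))
    fresh_ids <- character(0)
    if (n_fresh > 0) {
      wp <- w_syn[pool]
      if (lambda != 0) {
        aoa_p <- vapply(syn_groups[pool], function(ix)
          mean(en$aoa[ix]), numeric(1))
        wp <- wp * exp(lambda * aoa_p)
      }
      fresh_ids <- sample(pool, n_fresh, prob = wp)
    }
    fresh_words <- vapply(fresh_ids, pick_form, character(1),
                          tilt_lambda = lambda)
    ids_r <- c(surv_ids, fresh_ids)
    words_r <- c(surv_words, fresh_words)
    ord <- sample.int(length(ids_r))
    truth_sets[[r + 1L]] <- ids_r[ord]
    truth_words[[r + 1L]] <- words_r[ord]
    texts[r + 1L] <- rc_render(words_r[ord], neg_rate)
  }
  versions <- lapply(0:3, function(r)
    story_version(chain_id, r,
                  if (r == 0) "human" else params$producer,
                  condition, texts[r + 1L]))
  list(chain = chain(versions),
       truth = list(
         synsets = truth_sets, words = truth_words,
         survival = vapply(1:3, function(r)
           length(intersect(truth_sets[[r]], truth_sets[[r + 1L]])) /
             length(truth_sets[[r]]), numeric(1)),
         novelty = vapply(1:3, function(r)
           length(setdiff(truth_sets[[r + 1L]], truth_sets[[r]])) /
             length(truth_sets[[r + 1L]]), numeric(1)),
         aoa_mean = vapply(truth_words, function(w)
           mean(en$aoa[match(w, en$wordform)]), numeric(1)),
         condition = condition))
}

#' Closed-form expected survival and novelty of the generator
#'
#' For the fill-to-target innovation mode: with `n_p` parent concepts,
#' target `n_t = ceiling(n_p * length_decay)` and survivor count
#' `B ~ Binomial(n_p, p_surv)` capped at `n_t`, expected survival is
#' `E[min(B, n_t)] / n_p` and expected novelty `E[max(n_t - B, 0)] / n_t`,
#' computed by direct summation over the binomial pmf.
#'
#' @param n_parent parent concept count.
#' @param params from [sim_params()].
#' @return list with `expected_survival`, `expected_novelty`, `n_target`.
#' @export
expected_transition_metrics <- function(n_parent, params) {
  n_t <- max(1L, ceiling(n_parent * params$length_decay))
  b <- 0:n_parent
  pb <- stats::dbinom(b, n_parent, params$p_surv)
  list(expected_survival = sum(pb * pmin(b, n_t)) / n_parent,
       expected_novelty = sum(pb * pmax(n_t - b, 0)) / n_t,
       n_target = n_t)
}

#' Generate a corpus of chains
#'
#' Conditions are balanced across the four levels; per-chain seeds are
#' derived from `seed` so the corpus is reproducible and chains are
#' independent.
#'
#' @param n_chains number of chains.
#' @param params from [sim_params()].
#' @param lexicon a `sim_lexicon`.
#' @param seed integer seed.
#' @param id_prefix chain id prefix.
#' @return list with `chains` (list of [chain()]) and `truth` (per-chain
#'   ground-truth lists).
#' @export
simulate_chains <- function(n_chains, params, lexicon, seed = 1,
                            id_prefix = "sim") {
  conds <- rep(rc_conditions(), length.out = n_chains)
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 2, n_chains)
  out <- lapply(seq_len(n_chains), function(i) {
    generate_chain(params, lexicon, seed = seeds[i],
                   chain_id = sprintf("%s%04d", id_prefix, i),
                   condition = conds[i])
  })
  list(chains = lapply(out, `[[`, "chain"),
       truth = lapply(out, `[[`, "truth"))
}

#' Simulate rating records from the spine/compression likelihood
#'
#' Story-level latent trajectories follow
#' `beta0 + beta1 * r + delta[s] * exp(-gamma * r) + Normal(0, sigma)` on
#' the standardized scale, are mapped to the slider scale as
#' `center + spread * latent`, and each rater adds Normal(0, rater_sd)
#' noise before clipping to the scale bounds.
#'
#' @param chains list of chains (only ids are used).
#' @param params from [sim_params()]; the `rating` block is used.
#' @param n_raters raters per story version.
#' @param seed integer seed.
#' @param item rating item label.
#' @return ratings data.frame in the [load_ratings()] schema.
#' @export
simulate_ratings <- function(chains, params, n_raters = 20, seed = 1,
                             item = "happiness") {
  rp <- params$rating
  set.seed(as.integer(seed))
  rows <- lapply(chains, function(ch) {
    delta <- stats::rnorm(1, 0, rp$tau)
    do.call(rbind, lapply(0:3, function(r) {
      latent <- rp$beta0 + rp$beta1 * r + delta * exp(-rp$gamma * r) +
        stats::rnorm(1, 0, rp$sigma)
      raw <- rp$center + rp$spread * latent
      score <- pmin(pmax(raw + stats::rnorm(n_raters, 0, rp$rater_sd),
                         rp$scale_min), rp$scale_max)
      data.frame(chain_id = ch$chain_id, retelling_index = r, item = item,
                 rater_id = sprintf("r%03d", seq_len(n_raters)),
                 score = score, scale_min = rp$scale_min,
                 scale_max = rp$scale_max, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
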