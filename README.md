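# retellchain

Analysis tools for **serial reproduction (transmission chain) experiments**:
studies in which an original story is retold several times, each reteller
seeing only the previous version. The package targets designs that compare
chains produced by human participants with chains produced by a large
language model, and quantifies what survives transmission — words, parts of
speech, concepts, early-acquired vocabulary, and the affective impression of
the story.

It is aimed at computational cognitive scientists and cultural-evolution
researchers who have (or simulate) a corpus of 4-version chains
(original + 3 retellings) with affect ratings, and want a tested, seeded,
end-to-end pipeline rather than a pile of notebooks.

## What it computes

For a corpus of chains `{chain_id, retelling_index 0–3, producer ∈ {human,
llm}, condition ∈ {happy, mildly_happy, mildly_sad, sad}, text}` and rating
records `{chain_id, retelling_index, item, rater_id, score}`:

* **Annotation** — rule/lexicon tokenization (contractions split so `isn't`
  → `is not`), Penn-style tags mapped to the categories verb, adverb, noun,
  adjective, pronoun, preposition, negation, other.
* **Concepts** — each content token is sense-disambiguated against a
  WordNet-style inventory (simplified gloss-overlap / Lesk) and mapped to a
  synset, lemma, or root hypernym. Per transition *r−1 → r*:

  - survival: |parent ∩ child| / |parent|
  - novelty: |child \ parent| / |child|
  - density: |child| / child word count

* **Lexical norms** — age of acquisition (AOA), concreteness, valence,
  arousal and frequency merged by lemma; preservation of each parent-story
  lemma type coded against the child and modelled as

  `logit P(preserved) = β₀ + β_p·producer + β_a·AOA + β_pa·producer×AOA + …`

  with standardized predictors and effect-coded producer; plus per-story
  mean AOA trajectories.
* **Trend models** — word counts via negative-binomial regression with a
  **separate dispersion per producer** (log link, slope over retellings
  1–3, profile-likelihood CI for the dispersion ratio); category
  proportions via beta-binomial regression with a binomial fallback when
  the overdispersion LRT is at the boundary; negation rates by
  producer × (happy-side vs sad-side) condition with an interaction test.
* **Affect stability** — a Bayesian "spine + compression" model of
  standardized story-level ratings across retellings r = 0…3:

  `y[s,r] = β₀ + β₁·r + δ_s·exp(−γ·r) + ε,  ε ~ N(0, σ), δ_s ~ N(0, τ)`

  β₁ is the spine slope, γ the compression of story deviations toward the
  spine. Posteriors are sampled exactly (marginalized likelihood + Laplace
  proposal + independence Metropolis–Hastings) and each parameter gets a
  ROPE decision: *practically zero* iff its 95% HDI lies inside ±0.1.
* **Synthetic data** — seeded generators for lexicons, chains (with
  recorded ground-truth concept sets) and ratings, so the whole pipeline is
  testable offline. Presets: `human` (p_surv = 0.42, length decay 0.75) and
  `llm` (p_surv = 0.9, decay 0.95, AOA shifted +1.5 years from retelling 1).

## Worked example

```r
library(retellchain)

lex    <- build_toy_lexicon(300, seed = 11)
params <- sim_params("human")              # p_surv = 0.42
sim    <- simulate_chains(200, params, lex, seed = 7)
m      <- corpus_metrics(sim$chains, "synset", lex$inventory)
round(c(survival = mean(m$survival), novelty = mean(m$novelty),
        density = mean(m$child_density)), 3)
#> survival  novelty  density
#>    0.415    0.450    0.373
```

The measured survival sits within two standard errors of the generating
probability 0.42: each retelling keeps ~42% of the previous version's
concepts and invents the rest, the qualitative signature of human
retelling. Fitting the affect model to simulated ratings:

```r
ratings <- simulate_ratings(sim$chains, params, n_raters = 20, seed = 8)
td  <- standardize_ratings(ratings, "happiness")
fit <- fit_trend(td, chains = 4, draws = 1000, warmup = 1000, seed = 9)
fit$summary[fit$summary$parameter %in% c("beta1", "gamma"), ]
#>  parameter  median hdi_low hdi_high             rope
#>      beta1 -0.0114 -0.0309    0.006 practically_zero
#>      gamma  0.0089 -0.0092    0.032 practically_zero
```

Both the spine slope and the compression are practically zero at ROPE
±0.1: affect ratings are stable across retellings even though most
concepts are replaced.

Command line:

```sh
retellchain simulate --preset human --n-chains 100 --seed 7 --out simdir/
retellchain validate --corpus simdir/chains.csv --ratings simdir/ratings.csv
retellchain run --config run.cfg      # validate→annotate→concepts→norms→stats→trend
retellchain report --dir out/         # regenerate summary.json from cached stages
```

## Layout

* `R/` — modules: `chain_corpus`, `annotate`, `concepts`, `lexical_norms`,
  `transmission_stats`, `affect_trend`, `synthetic_data`, `pipeline`.
* `inst/extdata/` — tag lexicon, miniature sense inventory (~80 synsets),
  matching norm tables, example chains, simulation presets.
* `vignettes/retellchain-methods.Rmd` — the model and design notes.
* `tests/testthat/` — unit, property and acceptance suites.
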