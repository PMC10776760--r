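---
title: "Models and design notes for transmission-chain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design notes for transmission-chain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retellchain)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The design being analysed

A transmission chain is one original story (retelling index 0) plus three
successive retellings (indices 1–3), each produced from the previous
version only. Chains carry a **producer** label — whether indices 1–3 were
written by human participants or by a large language model — and one of
four emotion **conditions** (happy, mildly happy, mildly sad, sad) under
which the original was written. Originals are always human-authored; human
retellings are required to be at least 60 characters (a corpus rule the
validator enforces for human producers only). Independent raters score
every version on four items (happiness, sadness, picture, affected) on a
slider whose numeric range is carried in the data, because nothing in the
design fixes it a priori.

## 2. Annotation

No statistical part-of-speech tagger is available to this package's
dependency set, so `annotate_story()` uses a rule/lexicon tagger: an
exhaustive closed-class lexicon plus primary tags for common open-class
words (`inst/extdata/tag_lexicon.tsv`, the resource whose absence is a
configuration error), suffix heuristics (`-ly` → RB, `-ing` → VBG, …), a
capitalization rule for non-initial proper nouns, and two context rules
(base verbs after modals/`to`; verb reading of `-s` forms after pronouns).
Tokenization splits contractions so that the `n't` piece becomes the token
`not`; other clitics (`'s`, `'re`, …) become their own tokens; punctuation
is stripped; typographic quotes are normalized to ASCII before anything
else because example corpora contain them.

Penn tags collapse to eight categories. The mapping is the conventional
coarse one (verb = VB\*+MD, adverb = RB\*+WRB, noun = NN\*, adjective =
JJ\*, pronoun = PRP\*+WP\*, preposition = IN+TO, all else `other`). The
**negation lexicon** is `{not, n't, no, never, neither, nor, none,
nothing, nobody, nowhere}`; `not`/`n't`/`no` are mandatory and `no` only
counts when used as a determiner. Negation takes precedence over the POS
bucket, so category proportions always sum to one.

Two levels of proportion are distinguished deliberately: corpus-level
proportions are **pooled token counts** (Σk/Σn, equal to the slope of a
1/n-weighted through-origin regression of per-story (k, n) pairs — a
property the tests check), while story-level (k, n) pairs feed the
regression models.

Because tagging is rule-based, absolute tag accuracy is below a trained
tagger's; what the downstream analyses consume are category-level counts,
and the acceptance suite freezes the annotation of a small example corpus
as golden files so any behavioural drift is caught exactly.

## 3. Concepts and transmission metrics

The sense inventory is a plain-text TSV (one synset per row: id, POS,
comma-separated lemmas, hypernym pointers, gloss); row order encodes sense
priority. A miniature hand-written inventory of ~80 synsets ships with the
package so tests need no download.

Content tokens (noun/verb/adjective/adverb categories) are disambiguated
by **simplified gloss overlap (Lesk)**: candidate synsets are those listing
the lemma (restricted to the token's POS when possible); each is scored by
the overlap between its gloss-plus-co-lemmas and the other lemmas of the
sentence; ties and zero overlaps fall back to the first-listed (most
frequent) sense. This is deliberately swappable — `disambiguate()` is one
function — because nothing stronger is justified by the data volumes here.

Granularities: `synset` (the selected sense), `lemma` (the base form,
closer to the word level; lemmas missing from the inventory still
contribute at this level), `root_hypernym` (the topmost ancestor along the
first hypernym path, following the lexicographically smallest pointer when
a synset has several — the documented tie rule). At the root level, a
retelling that replaces *apple* with *fruit* still counts as transmission.

Per transition r−1 → r: survival = |parent ∩ child| / |parent|, novelty =
|child \ parent| / |child|, density = |child| / child word count. The
**novelty baseline is the immediate parent**, not the union of ancestors
(per-retelling plots imply pairwise transitions); an ancestors baseline
would only lower novelty and is left to the caller by composing sets.
Empty parent or child sets make the respective metric undefined (an error
at the operation level, `NA` in corpus tables).

## 4. Lexical norms and preservation

Norm tables (AOA in years, concreteness, valence, arousal, log frequency)
are joined by lowercase lemma; duplicate entries average; word length is
derived. Preservation is coded at the **lemma-type level of the parent
story** — "each word" in a regression means a type, otherwise frequent
tokens dominate — with a token-level mode behind a flag. A lemma is
preserved iff it occurs (as a lemma) anywhere in the child, so
inflectional variants match.

The preservation model is a plain logistic GLM:
`preserved ~ producer × AOA + frequency + length + concreteness +
valence`, predictors z-scored over complete cases, producer effect-coded
±1/2 so the interaction coefficient equals the human-minus-llm difference
in AOA slopes and producer-specific slopes are `aoa ± interaction/2`.
Records without norms are dropped and counted. Suspected perfect
separation (non-convergence or |coef| > 15) is an error that names a
penalized fallback rather than silently reporting garbage. No
multiple-testing correction is applied across the five covariates — they
are one model's Wald tests — and an "emotionality" composite is out of
scope because no formula for it is available.

Story-mean AOA averages over **tokens** (repeats count) across all
categories whenever a norm exists, returning the coverage fraction
alongside; with function words rarely normed, coverage in real corpora is
well below 1 and should be reported with the means.

## 5. Count and proportion trend models

Word counts for retellings 1–3 follow a negative-binomial (NB2) regression
with log link, producer-specific intercepts and slopes over the numeric
retelling index, and a **separate dispersion per producer**
(Var = μ + α_p μ²). No pre-installed regression package supports per-group
dispersion, so the likelihood is maximized directly (BFGS from
deterministic log-linear starting values; observed-information standard
errors; the index is centered at 2 internally for conditioning). Reported:
per-producer slopes, the slope difference contrast, dispersions α_p, and
the log dispersion ratio with both a Wald test and a **profile-likelihood
95% CI**. The profile CI exists because the Wald interval for a weakly
identified dispersion undercovers; even the profile interval's coverage is
slightly below nominal (~90% in the acceptance replicates at these sample
sizes), which is why coverage is assessed over replicates rather than a
single draw. The Poisson limit (α → 0) reproduces a Poisson GLM on the
same data, and single-producer slopes match `MASS::glm.nb` — both checked
against those oracles in the tests.

Category proportions use a beta-binomial likelihood on per-story (k, n)
with logit-linear mean (intercept, effect-coded producer, centered
retelling index) and one overdispersion ρ. When the boundary-corrected
likelihood-ratio test for ρ = 0 (the ½χ²₀ + ½χ²₁ mixture) is not
significant at α = 0.05 the fit falls back to the plain binomial GLM. The
negation/condition analysis collapses the four conditions to happy-side
vs sad-side (the two mild levels join their poles), reports the four
pooled proportions, and Wald-tests the producer × condition interaction.
All fits are deterministic given the data: fixed starting values, no
stochastic optimization.

## 6. The affect trend model

Ratings are first reduced to story-level means per retelling and item,
then z-scored by the mean and sample SD of the retelling-0 story means, so
"original stories" define the scale: a slope of 0.1 means one tenth of the
original between-story SD per retelling. The ±0.1 region of practical
equivalence (ROPE) is applied on this standardized scale.

The model:

y[s,r] = β₀ + β₁·r + δ_s·exp(−γ·r) + ε,  ε ~ N(0, σ), δ_s ~ N(0, τ)

with priors β₀, β₁, γ ~ N(0,1) and σ, τ ~ half-N(1). β₁ is the **spine**
(the typical trend); γ the **compression**: γ = 0 leaves story deviations
stable, γ > 0 shrinks them toward the spine, γ < 0 lets stories diverge.
This parameterization is this package's concrete rendering of a verbal
model description whose original likelihood lives in an external
supplement; the likelihood sits behind one function (`rc_trend_ll`) so an
alternative can be dropped in. Rater-level noise is collapsed into σ by
averaging before fitting — a documented limitation; rater random effects
are out of scope.

**Sampling.** The story offsets are marginalized analytically: each
story's 4-vector is N(β₀+β₁r, σ²I + τ²uuᵀ) with u_r = exp(−γr), evaluated
via the rank-one (Sherman–Morrison) identities, leaving a 5-parameter
posterior. Sampling is a two-phase **independence Metropolis–Hastings**:
a Laplace (multivariate-t, df 7, scale ×1.4) proposal at the posterior
mode seeds a warmup phase; the final proposal is moment-matched to the
pooled warmup draws (t, df 10, covariance ×1.3). On this small,
near-Gaussian posterior acceptance is ~0.6–0.8 and autocorrelation is
small. Convergence is gated on split R-hat (> 1.01 is an error carrying
the full diagnostic report) and effective sample sizes are reported.
Metropolis has no divergence diagnostic, so the `divergences` field is
identically 0 — the R-hat/ESS gate is the functioning safeguard. Results
are bit-for-bit reproducible given seed and settings. A practical note:
split R-hat on very short runs (≲200 draws/chain) is noisy even for
near-iid samplers, so very small smoke-test runs should either use more
draws or a looser `rhat_max`.

Decisions: a parameter is `practically_zero` iff its 95% highest-density
interval (shortest interval, computed from pooled draws, ≥1000 required)
lies inside (−0.1, 0.1); `nonzero` iff the HDI excludes the ROPE entirely;
otherwise `undecided`. With γ fixed at 0 the model reduces to a
random-intercept linear trend and the slope posterior matches an `lmer`
fit within Monte-Carlo error (tested); simulation-based calibration on a
reduced grid checks that posterior quantile ranks of the slope are
uniform under the prior.

## 7. The synthetic generator: a stated world

The generator exists so that every stage of the pipeline can be exercised
offline with known ground truth. Its defaults are the stated conditions of
the emulated design, chosen once:

* originals of `length0 = 140` words (mid-range of the 120–160-word
  brief), content fraction 0.45;
* human profile `p_surv = 0.42`, length decay 0.75, synonym-swap 0.3;
  llm profile `p_surv = 0.9`, decay 0.95, swap 0.4, AOA sampling tilted
  +1.5 years from retelling 1 on (the tilt exponent is solved numerically
  so the tilted sampling mean exceeds the base mean by exactly the shift);
* negation insertion rates per condition matching the reported cell
  proportions (human 0.88%/1.13% happy/sad side; llm 0.36%/0.58%);
* rating block β₀ = 0, β₁ = 0, γ = 0, σ = 0.3, τ = 1 on the standardized
  scale, mapped to a 0–100 slider (center 50, spread 12, rater SD 10).

Presets are data (`inst/extdata/sim_presets.json`), not code.

Each retelling keeps every parent concept with probability `p_surv`
(rendered as the same wordform or a synonym), truncates or fills to the
target `⌈parent·decay⌉`, and draws fresh concepts from outside the parent
set. With this fill-to-target mechanic the expected novelty is
`E[max(n_t − B, 0)]/n_t` with `B ~ Bin(n_p, p_surv)` — about 0.44 under
the human preset, not the ~0.55–0.60 observed in real human chains. The
two cannot coincide at survival 0.42 unless concept counts stop shrinking
(novelty = 1 − survival/decay requires decay ≈ 1 for novelty ≈ 0.57), so
the generator honours the stated survival and decay and lets novelty
follow; the acceptance check compares measured novelty to this closed
form, not to the field value.

Rendering is separated from concept bookkeeping: concepts are dressed in
function-word sentence frames ("The X of the Y and the Z.") so the tagger
behaves sensibly, and `not` tokens are inserted at the per-condition rate.
Wordforms are CV-syllable pseudowords screened against the tagger lexicon
so every content word is tagged as an unknown noun and survives the
pipeline unchanged — which is precisely what makes pipeline-measured
metrics equal the recorded truth exactly, and is also what a green
simulator test does **not** establish: real text has polysemy, inflection,
tagging errors and incomplete norm coverage, all absent here. The golden
annotation fixtures and the hand-written inventory cover those paths
instead.

## 8. Numerical and interface choices

* Standardization, centering, and effect coding are chosen so every
  reported contrast is a difference on an interpretable scale; all are
  documented at the function level.
* Degenerate inputs fail loudly and specifically: empty stories, empty
  concept sets, zero retelling-0 variance, all-zero counts, separation,
  missing resources, non-convergence. Gibberish (in-lexicon token fraction
  below 0.5 by default) is a warning, not an error, because exclusion was
  a human judgement in the emulated workflow.
* The corpus CSV canonical form (chains by id, versions by index, fixed
  column order) makes write→load→write byte-stable, which the tests assert.
* Seeds: every generator and the sampler take explicit seeds; derived
  seeds stay below 2³¹.
* CLI exit codes: 0 ok, 1 data error, 2 configuration error,
  3 non-convergence.

## 9. Known limitations

* The tagger is rule-based; its absolute accuracy is untested against a
  treebank and unknown — only its frozen behaviour is guaranteed.
* The real corpus analyses this package mirrors (negation shares
  1.01%/0.47%, the AOA × producer interaction, universally
  practically-zero affect trends) require the study's deposited corpus;
  they are reachable through `run_all()` once that corpus is mapped to the
  canonical schema, but are not reproduced offline and are not asserted
  by the tests.
* Whether survival should be measured against the immediate parent or the
  original, and whether multi-word expressions should be chunked before
  lookup, are left as explicit options/open questions; the defaults are
  immediate parent and no chunking.
* The dispersion-ratio profile CI undercovers mildly at n = 300 chains
  (~90% empirical coverage); interpret single intervals accordingly.
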