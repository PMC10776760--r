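test_that("build_toy_lexicon is deterministic and correctly sized", {
  expect_error(build_toy_lexicon(5), ">= 10")
  l1 <- build_toy_lexicon(60, seed = 1)
  l2 <- build_toy_lexicon(60, seed = 1)
  expect_identical(l1$entries, l2$entries)
  expect_identical(nrow(build_toy_lexicon(10, seed = 2)$synsets), 10L)
  # every synset has at least one wordform; weights positive
  expect_true(all(table(l1$entries$synset_id) >= 1))
  expect_true(all(l1$entries$weight > 0))
})

test_that("lexicon AOA matches its documented generating distribution", {
  lex <- build_toy_lexicon(400, seed = 21)
  a <- lex$entries$aoa
  n <- length(a)
  # oracle: closed-form mean of Normal(6, 2.5) truncated below at 1.5
  z <- (1.5 - 6) / 2.5
  mu_trunc <- 6 + 2.5 * dnorm(z) / (1 - pnorm(z))
  expect_lt(abs(mean(a) - mu_trunc), 3 * sd(a) / sqrt(n))
  expect_gte(min(a), 1.5)
})

test_that("lexicon fixtures round-trip through the standard loaders", {
  lex <- build_toy_lexicon(60, seed = 4)
  dir <- tempfile()
  paths <- write_lexicon_fixtures(lex, dir)
  inv <- load_inventory(paths[["inventory"]])
  expect_identical(inv$synsets$synset_id, lex$synsets$synset_id)
  expect_identical(inv$roots, lex$inventory$roots)
  norms <- load_norms(paths[c("aoa", "frequency")])
  expect_identical(norm_coverage(norms, lex$entries$wordform), 1)
})

test_that("degenerate survival parameters force the stated metrics", {
  lex <- build_toy_lexicon(300, seed = 2)
  p_all <- sim_params("human", p_surv = 1, p_syn = 0, length_decay = 1,
                      innovation_rate = 0)
  g <- generate_chain(p_all, lex, seed = 3)
  m <- chain_metrics(g$chain, "synset", lex$inventory)
  expect_identical(m$survival, rep(1, 3))
  expect_identical(m$novelty, rep(0, 3))
  # all four versions concept-identical
  expect_identical(length(unique(lapply(g$truth$synsets, sort))), 1L)

  p_none <- sim_params("human", p_surv = 0)
  g0 <- generate_chain(p_none, lex, seed = 4)
  m0 <- chain_metrics(g0$chain, "synset", lex$inventory)
  expect_identical(m0$survival, rep(0, 3))
})

test_that("generators are deterministic and emit valid corpora", {
  lex <- build_toy_lexicon(200, seed = 6)
  p <- sim_params("human")
  s1 <- simulate_chains(8, p, lex, seed = 10)
  s2 <- simulate_chains(8, p, lex, seed = 10)
  expect_identical(chains_to_df(s1$chains), chains_to_df(s2$chains))
  issues <- validate_corpus(s1$chains,
                            lexicon = c(lex$entries$wordform,
                                        names(load_tag_lexicon()), "not"))
  expect_identical(nrow(issues), 0L)
  # ratings deterministic too
  r1 <- simulate_ratings(s1$chains, p, n_raters = 5, seed = 3)
  r2 <- simulate_ratings(s1$chains, p, n_raters = 5, seed = 3)
  expect_identical(r1, r2)
  # and within the declared scale
  expect_true(all(r1$score >= 0 & r1$score <= 100))
})

test_that("rating generator respects its degenerate parameters", {
  lex <- build_toy_lexicon(60, seed = 8)
  chains <- simulate_chains(12, sim_params("human"), lex, seed = 9)$chains
  flat <- sim_params("human")
  flat$rating[c("beta1", "gamma", "sigma", "tau", "rater_sd")] <-
    list(0, 0, 0, 0, 0)
  r <- simulate_ratings(chains, flat, n_raters = 3, seed = 1)
  expect_equal(unique(r$score), flat$rating$center)  # flat at beta0

  # strong compression shrinks retelling-3 spread below 10% of retelling-0
  comp <- sim_params("human")
  comp$rating[c("gamma", "sigma", "rater_sd")] <- list(5, 0.001, 0)
  rc_ <- simulate_ratings(chains, comp, n_raters = 3, seed = 2)
  m <- aggregate(list(y = rc_$score),
                 list(r = rc_$retelling_index, chain = rc_$chain_id), mean)
  sd3 <- sd(m$y[m$r == 3]); sd0 <- sd(m$y[m$r == 0])
  expect_lt(sd3, 0.1 * sd0)  # exp(-5*3) is ~0 as the numeric check says
})

test_that("measured novelty matches the closed-form expectation", {
  lex <- build_toy_lexicon(300, seed = 12)
  p <- sim_params("human", p_surv = 0.42)
  sim <- simulate_chains(80, p, lex, seed = 13)
  m <- corpus_metrics(sim$chains, "synset", lex$inventory)
  exp_nov <- unlist(lapply(sim$truth, function(t) {
    np <- lengths(t$synsets)[1:3]
    vapply(np, function(n)
      expected_transition_metrics(n, p)$expected_novelty, numeric(1))
  }))
  se <- sd(m$novelty) / sqrt(nrow(m))
  expect_lt(abs(mean(m$novelty) - mean(exp_nov)), 2 * se)
})

test_that("llm preset survives more than the human preset end to end", {
  lex <- build_toy_lexicon(300, seed = 14)
  sh <- simulate_chains(15, sim_params("human"), lex, seed = 15)
  sl <- simulate_chains(15, sim_params("llm"), lex, seed = 16)
  mh <- corpus_metrics(sh$chains, "synset", lex$inventory)
  ml <- corpus_metrics(sl$chains, "synset", lex$inventory)
  expect_gt(mean(ml$survival), mean(mh$survival) + 0.2)
  expect_lt(mean(ml$novelty), mean(mh$novelty))
})

test_that("condition-dependent negation rates show up in rendered text", {
  lex <- build_toy_lexicon(250, seed = 17)
  p <- sim_params("human")
  # exaggerate the contrast to keep the check cheap
  p$negation_rates <- list(happy = 0.002, mildly_happy = 0.002,
                           mildly_sad = 0.05, sad = 0.05)
  sim <- simulate_chains(40, p, lex, seed = 18)
  a <- annotate_corpus(sim$chains)
  side <- ifelse(a$condition %in% c("happy", "mildly_happy"), "h", "s")
  neg_h <- sum(a$negation[side == "h"]) / sum(a$word_count[side == "h"])
  neg_s <- sum(a$negation[side == "s"]) / sum(a$word_count[side == "s"])
  expect_gt(neg_s, 2 * neg_h)
})
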