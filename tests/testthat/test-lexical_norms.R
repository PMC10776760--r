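norm_names <- c("aoa", "concreteness", "valence", "arousal", "frequency")

toy_norm_paths <- function() {
  stats::setNames(
    vapply(norm_names,
           function(nm) rc_fixture(sprintf("toy_norms_%s.csv", nm)), ""),
    norm_names)
}

test_that("load_norms merges files, averages duplicates, reports coverage", {
  empty <- tempfile(fileext = ".csv")
  writeLines("word,value", empty)
  expect_identical(nrow(load_norms(c(aoa = empty))), 0L)

  dup <- tempfile(fileext = ".csv")
  writeLines(c("word,value", "cat,3.5", "cat,4.5", "dog,2.0"), dup)
  tab <- load_norms(c(aoa = dup))
  expect_equal(tab$aoa[tab$word == "cat"], 4.0)  # mean rule
  expect_identical(tab$length, nchar(tab$word))

  # fixture norms cover the fixture lexicon fully, by construction
  norms <- load_norms(toy_norm_paths())
  expect_identical(norm_coverage(norms, toy_lexicon_words()), 1)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("word,value", "cat,3.5", "dog,abc"), bad)
  expect_error(load_norms(c(aoa = bad)), "non-numeric value at data line 2")
})

test_that("code_preservation matches lemma types between stories", {
  a <- annotate_story("The dog was running to the town.")
  expect_true(all(code_preservation(a, a)$preserved))  # reflexive

  b <- annotate_story("A river and a window.")
  none <- code_preservation(a, b)
  expect_false(any(none$preserved[none$word %in% c("dog", "run", "town")]))

  # inflectional variants match through lemmas: running vs ran -> run
  p <- annotate_story("He was running home.")
  c_ <- annotate_story("She ran away.")
  rec <- code_preservation(p, c_)
  expect_true(rec$preserved[rec$word == "run"])

  # anti-monotone under child deletion
  full <- annotate_story("The dog ran to the river near the town.")
  reduced <- annotate_story("The dog ran.")
  f_rec <- code_preservation(a, full)
  r_rec <- code_preservation(a, reduced)
  m <- merge(f_rec[, c("word", "preserved")],
             r_rec[, c("word", "preserved")], by = "word")
  expect_true(all(m$preserved.y <= m$preserved.x))
})

test_that("preservation model recovers a known AOA effect", {
  gen <- function(n, slope, seed) {
    set.seed(seed)
    producer <- rep(c("human", "llm"), length.out = n)
    aoa <- rnorm(n)
    x <- data.frame(
      producer = producer, aoa = aoa, frequency = rnorm(n),
      length = rnorm(n), concreteness = rnorm(n), valence = rnorm(n))
    eta <- 0.4 + slope * aoa + 0.2 * x$frequency
    x$preserved <- runif(n) < plogis(eta)
    x
  }
  fit <- fit_preservation_model(gen(5000, -0.5, 1))
  est <- fit$coefficients$estimate[fit$coefficients$term == "aoa"]
  expect_lt(abs(est - (-0.5)), 0.1)
  # producer-specific slopes agree when no interaction was simulated
  expect_lt(abs(fit$aoa_slope_human[["estimate"]] -
                  fit$aoa_slope_llm[["estimate"]]), 0.2)

  # a simulated interaction shows up with the right sign
  set.seed(2)
  d <- gen(6000, 0, 2)
  is_h <- d$producer == "human"
  d$preserved <- runif(6000) < plogis(0.4 - 0.6 * d$aoa * is_h)
  fit2 <- fit_preservation_model(d)
  expect_lt(fit2$aoa_slope_human[["estimate"]], -0.3)
  expect_gt(fit2$aoa_slope_human[["p"]], -1)  # finite
  expect_lt(fit2$coefficients$p[fit2$coefficients$term ==
                                  "producer_ec:aoa"], 0.01)
})

test_that("preservation model errors on separation and tiny samples", {
  set.seed(3)
  n <- 200
  d <- data.frame(producer = rep(c("human", "llm"), each = n / 2),
                  aoa = c(rep(-2, n / 2), rep(2, n / 2)),
                  frequency = rnorm(n), length = rnorm(n),
                  concreteness = rnorm(n), valence = rnorm(n),
                  preserved = rep(c(TRUE, FALSE), each = n / 2))
  expect_error(suppressWarnings(fit_preservation_model(d)), "separation")
  expect_error(fit_preservation_model(d[c(1:10, 101:110), ]), "too few")
  expect_error(fit_preservation_model(d[d$producer == "human", ]),
               "both producers")
})

test_that("story_mean_aoa averages covered tokens and tracks coverage", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("word,value", "dog,4.0", "river,6.0"), f)
  norms <- load_norms(c(aoa = f))
  res <- story_mean_aoa(annotate_story("the dog saw the river"), norms)
  expect_equal(res$mean, 5.0)  # uncovered tokens excluded
  expect_equal(res$coverage, 2 / 5)

  # tokens, not types: repeats count repeatedly
  rep_res <- story_mean_aoa(annotate_story("dog dog river"), norms)
  expect_equal(rep_res$mean, (4 + 4 + 6) / 3)

  # linear in a uniform shift of all norms
  shifted <- norms; shifted$aoa <- shifted$aoa + 2
  expect_equal(story_mean_aoa(annotate_story("dog dog river"),
                              shifted)$mean, rep_res$mean + 2)
  # order invariance
  expect_equal(story_mean_aoa(annotate_story("river dog dog"),
                              norms)$mean, rep_res$mean)
  expect_error(story_mean_aoa(annotate_story("qqq zzz"), norms),
               "no token has an AOA norm")
})

test_that("llm-profile AOA shift is recovered through the pipeline", {
  lex <- build_toy_lexicon(300, seed = 5)
  params <- sim_params("llm")
  sim <- simulate_chains(30, params, lex, seed = 6)
  norms <- load_norms(write_lexicon_fixtures(lex, tempfile())[norm_names])
  # pipeline measurement vs simulator ground truth, per version means
  meas <- sapply(seq_along(sim$chains), function(i) {
    vapply(sim$chains[[i]]$versions, function(v)
      story_mean_aoa(annotate_story(v$text), norms)$mean, numeric(1))
  })
  truth <- sapply(sim$truth, function(t) t$aoa_mean)
  step_meas <- mean(meas[2, ] - meas[1, ])
  step_truth <- mean(truth[2, ] - truth[1, ])
  expect_lt(abs(step_meas - step_truth), 0.2)
  # the tilt raises AOA from retelling 1 on
  expect_gt(step_truth, 0)
})
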