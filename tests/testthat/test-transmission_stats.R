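sim_counts <- function(n_chains, a_h = 4.8, b_h = -0.25, a_l = 4.4,
                       b_l = -0.05, th_h = 8, th_l = 60, seed = 1) {
  set.seed(seed)
  half <- n_chains %/% 2
  grid <- expand.grid(chain = seq_len(n_chains), retelling_index = 1:3)
  grid$producer <- ifelse(grid$chain <= half, "human", "llm")
  r <- grid$retelling_index - 2
  mu <- ifelse(grid$producer == "human", exp(a_h + b_h * r),
               exp(a_l + b_l * r))
  th <- ifelse(grid$producer == "human", th_h, th_l)
  grid$word_count <- rnbinom(nrow(grid), size = th, mu = mu)
  grid
}

test_that("word-count model recovers slopes and dispersion structure", {
  d <- sim_counts(300, seed = 11)
  fit <- fit_wordcount_trend(d)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "slope_human"] - (-0.25)), 0.05)
  expect_lt(abs(co$estimate[co$term == "slope_llm"] - (-0.05)), 0.05)
  # dispersion alpha = 1/theta; true log ratio log(60/8) > 0
  true_ld <- log(60 / 8)
  ld <- fit$contrasts$log_dispersion_ratio
  expect_lt(abs(ld[["estimate"]] - true_ld), 2 * ld[["se"]])
  expect_lt(fit$contrasts$slope_diff[["p"]], 0.001)
  expect_gt(fit$dispersions[["human"]], fit$dispersions[["llm"]])
  # deterministic given data
  expect_identical(fit$coefficients, fit_wordcount_trend(d)$coefficients)
})

test_that("constant llm counts give a near-zero slope and a warning", {
  d <- sim_counts(120, seed = 2)
  d$word_count[d$producer == "llm"] <- 100
  expect_warning(fit <- fit_wordcount_trend(d), "degenerate variance")
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "slope_llm"]), 0.01)
})

test_that("per-producer slopes agree with a reference NB fit", {
  skip_if_not_installed("MASS")
  d <- sim_counts(200, seed = 5)
  fit <- fit_wordcount_trend(d)
  for (p in c("human", "llm")) {
    sub <- d[d$producer == p, ]
    ref <- MASS::glm.nb(word_count ~ I(retelling_index - 2), data = sub)
    got <- fit$coefficients$estimate[fit$coefficients$term ==
                                       paste0("slope_", p)]
    expect_equal(got, unname(coef(ref)[2]), tolerance = 1e-3)
  }
})

test_that("NB fit approaches the Poisson fit as dispersion vanishes", {
  set.seed(8)
  n <- 120
  d <- expand.grid(chain = 1:n, retelling_index = 1:3)
  d$producer <- ifelse(d$chain <= n / 2, "human", "llm")
  mu <- exp(4 - 0.2 * (d$retelling_index - 2))
  d$word_count <- rpois(nrow(d), mu)  # no overdispersion
  fit <- fit_wordcount_trend(d)
  ref <- glm(word_count ~ producer / I(retelling_index - 2) + producer,
             family = poisson(), data = d)
  got_h <- fit$coefficients$estimate[fit$coefficients$term ==
                                       "slope_human"]
  ref_h <- unname(coef(ref)[["producerhuman:I(retelling_index - 2)"]])
  expect_equal(got_h, ref_h, tolerance = 2e-3)
  expect_lt(fit$dispersions[["human"]], 0.02)  # alpha near the boundary
})

test_that("beta-binomial trend recovers a producer contrast", {
  set.seed(31)
  n <- 400
  d <- expand.grid(chain = seq_len(n), retelling_index = 1:3)
  d$producer <- ifelse(d$chain <= n / 2, "human", "llm")
  d$n <- 150
  mu <- ifelse(d$producer == "human", 0.15, 0.10)
  rho <- 0.02
  s <- (1 - rho) / rho
  pr <- rbeta(nrow(d), mu * s, (1 - mu) * s)
  d$k <- rbinom(nrow(d), d$n, pr)
  fit <- fit_pos_trend(d, "noun")
  true_contrast <- qlogis(0.15) - qlogis(0.10)
  pc <- fit$producer_contrast
  expect_gt(pc[["estimate"]], 0)  # sign correct
  expect_lt(abs(pc[["estimate"]] - true_contrast), 2 * pc[["se"]])
  expect_identical(fit$family, "beta-binomial")
  expect_gt(fit$rho, 0.005)

  # zero counts: degenerate boundary warning
  d0 <- d; d0$k <- 0
  expect_warning(z <- fit_pos_trend(d0, "noun"), "boundary")
  expect_true(is.na(z$producer_contrast[["estimate"]]))
  expect_error(fit_pos_trend(transform(d, k = n + 1), "x"), "k > n")
})

test_that("binomial fallback engages when there is no overdispersion", {
  set.seed(12)
  n <- 300
  d <- expand.grid(chain = seq_len(n), retelling_index = 1:3)
  d$producer <- ifelse(d$chain <= n / 2, "human", "llm")
  d$n <- 120
  d$k <- rbinom(nrow(d), d$n, 0.1)  # pure binomial
  fit <- fit_pos_trend(d, "noun")
  expect_identical(fit$family, "binomial")
  # and matches the glm oracle
  ref <- glm(cbind(k, n - k) ~ I(ifelse(producer == "human", .5, -.5)) +
               I(retelling_index - 2), family = binomial(), data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-5)
})

test_that("pooled proportions equal the weighted through-origin slope", {
  set.seed(4)
  n <- 60
  d <- data.frame(producer = rep(c("human", "llm"), each = n),
                  retelling_index = rep(1:3, length.out = 2 * n),
                  n = sample(80:160, 2 * n, TRUE))
  d$k <- rbinom(2 * n, d$n, 0.08)
  fit <- fit_pos_trend(d, "negation")
  for (p in c("human", "llm")) {
    sub <- d[d$producer == p, ]
    slope <- unname(coef(lm(k ~ 0 + n, data = sub, weights = 1 / n)))
    expect_equal(unname(fit$pooled[[p]]), slope)
  }
})

test_that("negation condition contrast detects condition, not interaction", {
  gen_neg <- function(rates, seed, n_per = 60, n_words = 130) {
    set.seed(seed)
    g <- expand.grid(chain = seq_len(n_per), retelling_index = 1:3,
                     producer = c("human", "llm"),
                     condition = c("happy", "mildly_happy", "mildly_sad",
                                   "sad"), stringsAsFactors = FALSE)
    side <- ifelse(g$condition %in% c("happy", "mildly_happy"), "h", "s")
    rate <- rates[paste(g$producer, side, sep = ".")]
    g$n <- n_words
    g$k <- rbinom(nrow(g), g$n, rate)
    g
  }
  # sad rate 2x happy in both producers: condition effect, no interaction
  rates <- c(human.h = 0.008, human.s = 0.016, llm.h = 0.004,
             llm.s = 0.008)
  d <- gen_neg(rates, 17, n_per = 150)
  res <- negation_condition_contrast(d)
  cond <- res$coefficients[res$coefficients$term == "side", ]
  expect_lt(cond$p, 0.001)
  # the doubling is shared, so the true log-odds interaction is ~0 and the
  # 95% CI should cover it
  ia <- res$interaction
  expect_lt(ia[["estimate"]] - 1.96 * ia[["se"]], 0)
  expect_gt(ia[["estimate"]] + 1.96 * ia[["se"]], 0)
  # pooled cells reflect the generating rates within 2 binomial se
  for (nm in names(res$pooled)) {
    key <- sub("(happy|sad)_side", "\\1", nm)
    key <- sub("\\.happy", ".h", sub("\\.sad", ".s", key))
    n_tot <- sum(d$n[paste(d$producer,
                           ifelse(d$condition %in% c("happy",
                                                     "mildly_happy"),
                                  "h", "s"), sep = ".") == key])
    se <- sqrt(rates[key] * (1 - rates[key]) / n_tot)
    expect_lt(abs(res$pooled[[nm]] - rates[key]), 3 * se)
  }
  expect_error(negation_condition_contrast(
    d[!(d$producer == "llm" & d$condition %in% c("sad", "mildly_sad")), ]),
    "empty cell: llm x sad_side")
})

test_that("interaction p-values are roughly uniform under the null", {
  # symmetric rates everywhere; 30 seeds, expect no systematic rejection
  ps <- vapply(1:30, function(s) {
    set.seed(100 + s)
    g <- expand.grid(chain = 1:40, retelling_index = 1:3,
                     producer = c("human", "llm"),
                     condition = rc_conditions(),
                     stringsAsFactors = FALSE)
    g$n <- 120
    g$k <- rbinom(nrow(g), g$n, 0.01)
    negation_condition_contrast(g)$interaction[["p"]]
  }, numeric(1))
  # under uniformity the rejection rate at 0.05 has sd ~ 0.04 here
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
})
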