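# Count and proportion trend models across retellings 1-3 by producer.
#
# Negative-binomial regression with a separate dispersion per producer and
# beta-binomial regression are fit by direct maximum likelihood (optim/BFGS,
# observed-information standard errors, deterministic starting values from
# moment / glm fits): no pre-packaged regression supports the per-group
# dispersion structure. The Poisson and binomial special cases of both
# likelihoods serve as oracles in the test suite.

rc_wald <- function(est, se) {
  z <- est / se
  c(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

rc_vcov_from_hessian <- function(opt_par, negll) {
  H <- stats::optimHess(opt_par, negll)
  V <- tryCatch(solve(H), error = function(e) {
    warning("observed information singular; SEs from pseudoinverse")
    ev <- eigen(H, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-10
    ev$vectors[, keep, drop = FALSE] %*%
      diag(1 / ev$values[keep], sum(keep)) %*%
      t(ev$vectors[, keep, drop = FALSE])
  })
  V
}

#' Negative-binomial word-count trend with producer-specific dispersion
#'
#' Fits `word_count ~ producer-specific intercept + slope over retelling
#' index` with a log link and a separate NB2 dispersion per producer:
#' `Var = mu + alpha_p * mu^2`. Reports per-producer slopes, the
#' human-minus-llm slope contrast, and a Wald test of the log dispersion
#' ratio.
#'
#' @param stories data.frame with columns `producer`, `retelling_index`
#'   (in 1..3) and `word_count`.
#' @return list with `coefficients`, `dispersions` (alpha per producer),
#'   `contrasts` (`slope_diff`, `log_dispersion_ratio`), `logLik`,
#'   `n_stories`, and the optimizer object.
#' @export
fit_wordcount_trend <- function(stories) {
  stopifnot(all(c("producer", "retelling_index", "word_count") %in%
                  names(stories)))
  stories <- stories[stories$retelling_index %in% 1:3, , drop = FALSE]
  prods <- rc_producers()
  if (!all(prods %in% stories$producer))
    stop("both producers must be present in the word-count data")
  y <- stories$word_count
  r <- stories$retelling_index - 2  # centered for numerical stability
  h <- stories$producer == "human"
  for (p in prods) {
    yy <- y[stories$producer == p]
    if (stats::var(yy) == 0)
      warning("degenerate variance: all counts equal for producer '", p,
              "'; dispersion at boundary")
  }
  # theta-parameterized start from per-producer log-linear lm
  start <- c(a_h = 0, b_h = 0, a_l = 0, b_l = 0, lth_h = 2, lth_l = 2)
  fit_lm <- function(sel) stats::coef(stats::lm(log(pmax(y[sel], 1)) ~
                                                  r[sel]))
  ch <- fit_lm(h); cl <- fit_lm(!h)
  start[c("a_h", "b_h", "a_l", "b_l")] <- c(ch, cl)
  negll <- function(par) {
    mu <- exp(ifelse(h, par["a_h"] + par["b_h"] * r,
                     par["a_l"] + par["b_l"] * r))
    th <- ifelse(h, exp(par["lth_h"]), exp(par["lth_l"]))
    -sum(stats::dnbinom(y, size = th, mu = mu, log = TRUE))
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  V <- rc_vcov_from_hessian(opt$par, negll)
  dimnames(V) <- list(names(start), names(start))
  se <- sqrt(pmax(diag(V), 0))
  b <- opt$par
  coefs <- data.frame(
    term = c("intercept_human", "slope_human", "intercept_llm", "slope_llm"),
    estimate = unname(b[1:4]), se = unname(se[1:4]), row.names = NULL)
  coefs$z <- coefs$estimate / coefs$se
  coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
  sd_diff <- b[["b_h"]] - b[["b_l"]]
  sd_se <- sqrt(V["b_h", "b_h"] + V["b_l", "b_l"] - 2 * V["b_h", "b_l"])
  # dispersion alpha = 1/theta; log alpha ratio = -(lth_h - lth_l)
  ld <- -(b[["lth_h"]] - b[["lth_l"]])
  ld_se <- sqrt(V["lth_h", "lth_h"] + V["lth_l", "lth_l"] -
                  2 * V["lth_h", "lth_l"])
  # profile-likelihood 95% CI for the log dispersion ratio: the Wald
  # interval undercovers when a dispersion is weakly identified
  prof_nll <- function(psi) {
    # psi = log(alpha_h / alpha_l) = lth_l - lth_h, profiled over the rest
    negll_c <- function(q)
      negll(c(q[1:4], lth_h = q[5], lth_l = q[5] + psi))
    stats::optim(c(b[1:4], b[["lth_h"]]), negll_c, method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-10))$value
  }
  ll_hat <- -opt$value
  cut <- stats::qchisq(0.95, 1) / 2
  bound <- function(side) {
    f <- function(psi) (ll_hat - (-prof_nll(psi))) - cut
    lo <- ld; hi <- ld + side * max(4 * ld_se, 0.5)
    while (f(hi) < 0 && abs(hi - ld) < 20) hi <- ld + 2 * (hi - ld)
    tryCatch(stats::uniroot(f, sort(c(lo, hi)), tol = 1e-4)$root,
             error = function(e) NA_real_)
  }
  ld_ci <- tryCatch(c(lower = bound(-1), upper = bound(1)),
                    error = function(e) c(lower = NA_real_,
                                          upper = NA_real_))
  list(coefficients = coefs,
       dispersions = c(human = exp(-b[["lth_h"]]), llm = exp(-b[["lth_l"]])),
       contrasts = list(slope_diff = rc_wald(sd_diff, sd_se),
                        log_dispersion_ratio = rc_wald(ld, ld_se),
                        log_dispersion_ratio_ci = ld_ci),
       logLik = -opt$value, n_stories = length(y), optim = opt, vcov = V)
}

# beta-binomial log-likelihood; rho in (0,1), s = (1-rho)/rho
rc_bb_ll <- function(k, n, mu, rho) {
  s <- (1 - rho) / rho
  a <- mu * s
  b <- (1 - mu) * s
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

rc_binll <- function(k, n, mu) sum(stats::dbinom(k, n, mu, log = TRUE))

# shared fitting core: design matrix X for logit(mu), optional BB dispersion
rc_fit_proportion <- function(k, n, X, term_names) {
  stopifnot(all(k >= 0), all(n >= k))
  glm0 <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ X - 1, family = stats::binomial()))
  start_beta <- unname(stats::coef(glm0))
  start_beta[is.na(start_beta)] <- 0
  negll_bb <- function(par) {
    eta <- drop(X %*% par[seq_len(ncol(X))])
    mu <- stats::plogis(eta)
    rho <- stats::plogis(par[length(par)])
    -rc_bb_ll(k, n, pmin(pmax(mu, 1e-12), 1 - 1e-12),
              pmin(pmax(rho, 1e-12), 1 - 1e-6))
  }
  negll_bin <- function(par) {
    mu <- stats::plogis(drop(X %*% par))
    -rc_binll(k, n, pmin(pmax(mu, 1e-12), 1 - 1e-12))
  }
  opt_bin <- stats::optim(start_beta, negll_bin, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
  opt_bb <- stats::optim(c(start_beta, -4), negll_bb, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
  # boundary-corrected LRT for rho = 0 (0.5 chi2_0 + 0.5 chi2_1 mixture)
  lr <- max(0, 2 * (opt_bin$value - opt_bb$value))
  p_over <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  use_bb <- p_over < 0.05
  if (use_bb) {
    opt <- opt_bb
    V <- rc_vcov_from_hessian(opt$par, negll_bb)
    rho <- stats::plogis(opt$par[length(opt$par)])
  } else {
    opt <- opt_bin
    V <- rc_vcov_from_hessian(opt$par, negll_bin)
    rho <- 0
  }
  nb <- ncol(X)
  se <- sqrt(pmax(diag(V)[seq_len(nb)], 0))
  coefs <- data.frame(term = term_names, estimate = opt$par[seq_len(nb)],
                      se = se, row.names = NULL)
  coefs$z <- coefs$estimate / coefs$se
  coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
  list(family = if (use_bb) "beta-binomial" else "binomial",
       coefficients = coefs, rho = rho,
       overdispersion_lrt = c(statistic = lr, p = p_over),
       logLik = -opt$value, vcov = V[seq_len(nb), seq_len(nb), drop = FALSE],
       optim = opt)
}

#' Beta-binomial trend in a part-of-speech proportion
#'
#' Models per-story category counts `k` of `n` with
#' `logit(mu) = b0 + b_producer * x_p + b_retelling * (r - 2)` (producer
#' effect-coded human = +1/2, llm = -1/2; retelling numeric). Falls back to
#' the plain binomial when the boundary-corrected likelihood-ratio test
#' finds no overdispersion at alpha = 0.05.
#'
#' @param stories data.frame with `producer`, `retelling_index` (1..3),
#'   `k` (category count) and `n` (word count).
#' @param category label carried through to the output.
#' @return list as in the shared proportion fitter plus `producer_contrast`
#'   (log-odds human - llm) and `pooled` proportions per producer.
#' @export
fit_pos_trend <- function(stories, category = NA_character_) {
  stopifnot(all(c("producer", "retelling_index", "k", "n") %in%
                  names(stories)))
  stories <- stories[stories$retelling_index %in% 1:3, , drop = FALSE]
  if (any(stories$k > stories$n)) stop("data error: k > n")
  if (sum(stories$k) == 0) {
    warning("all category counts are zero: producer contrast undefined ",
            "at the boundary")
    return(list(family = "degenerate", category = category,
                pooled = c(human = 0, llm = 0), coefficients = NULL,
                producer_contrast = c(estimate = NA_real_, se = NA_real_,
                                      z = NA_real_, p = NA_real_)))
  }
  xp <- ifelse(stories$producer == "human", 0.5, -0.5)
  X <- cbind(intercept = 1, producer = xp,
             retelling = stories$retelling_index - 2)
  fit <- rc_fit_proportion(stories$k, stories$n, X,
                           c("intercept", "producer", "retelling"))
  fit$category <- category
  i <- match("producer", fit$coefficients$term)
  fit$producer_contrast <- rc_wald(fit$coefficients$estimate[i],
                                   fit$coefficients$se[i])
  fit$pooled <- vapply(rc_producers(), function(p) {
    sel <- stories$producer == p
    if (!any(sel)) return(NA_real_)
    sum(stories$k[sel]) / sum(stories$n[sel])
  }, numeric(1))
  fit
}

#' Negation rates by producer and emotional side, with interaction test
#'
#' Collapses the four conditions to happy-side (`happy`, `mildly_happy`)
#' vs sad-side (`sad`, `mildly_sad`), reports the four pooled negation
#' proportions, and fits a beta-binomial (binomial fallback) model with
#' producer, side and their interaction (both factors effect-coded +-1/2);
#' the interaction Wald test is reported.
#'
#' @param stories data.frame with `producer`, `condition`,
#'   `retelling_index`, `k` (negation count), `n` (word count).
#' @return list with `pooled` (4 proportions), `coefficients`,
#'   `interaction` (Wald test), `family`.
#' @export
negation_condition_contrast <- function(stories) {
  stopifnot(all(c("producer", "condition", "k", "n") %in% names(stories)))
  stories <- stories[stories$retelling_index %in% 1:3, , drop = FALSE]
  side <- ifelse(stories$condition %in% c("happy", "mildly_happy"),
                 "happy_side", "sad_side")
  cells <- expand.grid(producer = rc_producers(),
                       side = c("happy_side", "sad_side"),
                       stringsAsFactors = FALSE)
  pooled <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- stories$producer == cells$producer[i] & side == cells$side[i]
    if (!any(sel))
      stop("empty cell: ", cells$producer[i], " x ", cells$side[i])
    pooled[i] <- sum(stories$k[sel]) / sum(stories$n[sel])
  }
  names(pooled) <- paste(cells$producer, cells$side, sep = ".")
  xp <- ifelse(stories$producer == "human", 0.5, -0.5)
  xc <- ifelse(side == "sad_side", 0.5, -0.5)
  X <- cbind(intercept = 1, producer = xp, side = xc,
             interaction = xp * xc)
  fit <- rc_fit_proportion(stories$k, stories$n, X,
                           c("intercept", "producer", "side", "interaction"))
  i <- match("interaction", fit$coefficients$term)
  list(pooled = pooled, coefficients = fit$coefficients,
       interaction = rc_wald(fit$coefficients$estimate[i],
                             fit$coefficients$se[i]),
       family = fit$family, rho = fit$rho, logLik = fit$logLik)
}

#' Per-story category-count table for the trend models
#'
#' Convenience bridge from [annotate_corpus()] output to the `(k, n)` layout
#' consumed by [fit_pos_trend()] and [negation_condition_contrast()].
#'
#' @param ann_df data.frame from [annotate_corpus()].
#' @param category one of the eight categories.
#' @return data.frame with `producer`, `condition`, `retelling_index`,
#'   `k`, `n`.
#' @export
category_counts <- function(ann_df, category) {
  stopifnot(category %in% RC_CATEGORIES)
  data.frame(chain_id = ann_df$chain_id, producer = ann_df$producer,
             condition = ann_df$condition,
             retelling_index = ann_df$retelling_index,
             k = ann_df[[category]], n = ann_df$word_count,
             stringsAsFactors = FALSE)
}
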