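# Bayesian linear-spine + compression model of rating trajectories.
#
# Model, on the standardized rating scale:
#   y[s, r] = beta0 + beta1 * r + delta[s] * exp(-gamma * r) + eps,
#   eps ~ Normal(0, sigma),  delta[s] ~ Normal(0, tau),  r = 0..3.
# beta1 is the spine slope; gamma the compression (gamma = 0: stable
# dispersion of stories around the spine; gamma > 0: stories converge to
# the spine). Priors: beta0, beta1, gamma ~ Normal(0,1); sigma, tau ~
# half-Normal(1).
#
# The story offsets delta[s] are marginalised analytically (each story's
# 4-vector is multivariate normal with rank-one covariance
# sigma^2 I + tau^2 u u', u_r = exp(-gamma r)), leaving a 5-parameter
# posterior. Sampling is independence Metropolis-Hastings from a Laplace
# (multivariate-t) approximation at the posterior mode: on this small,
# near-Gaussian posterior the proposal is close to the target, acceptance
# is high and autocorrelation negligible, which is what the split R-hat /
# ESS gate checks. Metropolis has no divergence diagnostic; the
# `divergences` field is identically 0.

RC_TREND_PARS <- c("beta0", "beta1", "gamma", "sigma", "tau")

#' Standardize rating records for the trend model
#'
#' Computes per-story per-retelling rater means for one item, then z-scores
#' every mean by the mean and (sample) SD of the retelling-0 story means, so
#' the original stories have mean 0 and SD 1 — the scale on which the
#' +-0.1 region of practical equivalence is applied.
#'
#' @param records ratings data.frame (see [load_ratings()]).
#' @param item one of [rc_rating_items()].
#' @param producer optional filter; `NULL` keeps all records.
#' @return data.frame `chain_id`, `retelling_index`, `y` (standardized
#'   story-level mean), with attributes `item`, `center`, `scale`.
#' @export
standardize_ratings <- function(records, item, producer = NULL) {
  item <- match.arg(item, rc_rating_items())
  d <- records[records$item == item, , drop = FALSE]
  if (!is.null(producer) && "producer" %in% names(d))
    d <- d[d$producer == producer | d$retelling_index == 0, , drop = FALSE]
  if (!nrow(d)) stop("no ratings for item '", item, "'")
  agg <- stats::aggregate(list(y = d$score),
                          list(chain_id = d$chain_id,
                               retelling_index = d$retelling_index),
                          mean)
  have0 <- unique(agg$chain_id[agg$retelling_index == 0])
  miss <- setdiff(unique(agg$chain_id), have0)
  if (length(miss))
    stop("stories without retelling-0 ratings: ",
         paste(miss, collapse = ", "))
  y0 <- agg$y[agg$retelling_index == 0]
  s0 <- stats::sd(y0)
  if (!is.finite(s0) || s0 == 0)
    stop("zero variance in retelling-0 ratings; cannot standardize")
  m0 <- mean(y0)
  agg$y <- (agg$y - m0) / s0
  agg <- agg[order(agg$chain_id, agg$retelling_index), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "item") <- item
  attr(agg, "center") <- m0
  attr(agg, "scale") <- s0
  agg
}

# marginal log-likelihood of the spine/compression model on an S x 4 matrix
rc_trend_ll <- function(Y, beta0, beta1, gamma, sigma, tau) {
  r <- 0:3
  u <- exp(-gamma * r)
  m <- beta0 + beta1 * r
  E <- sweep(Y, 2, m)
  c2 <- sum(u^2)
  s2 <- sigma^2
  t2 <- tau^2
  denom <- s2 + t2 * c2
  A <- rowSums(E^2)
  B <- drop(E %*% u)
  q <- A / s2 - (t2 * B^2) / (s2 * denom)
  logdet <- 4 * log(s2) + log1p(t2 * c2 / s2)
  -0.5 * sum(4 * log(2 * pi) + logdet + q)
}

rc_trend_lp <- function(par, Y, gamma_fixed = NULL) {
  beta0 <- par[1]; beta1 <- par[2]
  if (is.null(gamma_fixed)) {
    gamma <- par[3]; ls <- par[4]; lt <- par[5]
  } else {
    gamma <- gamma_fixed; ls <- par[3]; lt <- par[4]
  }
  sigma <- exp(ls); tau <- exp(lt)
  if (!is.finite(sigma) || !is.finite(tau)) return(-Inf)
  lp <- rc_trend_ll(Y, beta0, beta1, gamma, sigma, tau) +
    stats::dnorm(beta0, 0, 1, log = TRUE) +
    stats::dnorm(beta1, 0, 1, log = TRUE) +
    # half-Normal(1) on sigma, tau with log-scale Jacobian
    (log(2) + stats::dnorm(sigma, 0, 1, log = TRUE) + ls) +
    (log(2) + stats::dnorm(tau, 0, 1, log = TRUE) + lt)
  if (is.null(gamma_fixed))
    lp <- lp + stats::dnorm(gamma, 0, 1, log = TRUE)
  if (!is.finite(lp)) -Inf else lp
}

# multivariate-t log density and sampler (proposal distribution)
rc_dmvt <- function(x, mu, cholS, df) {
  k <- length(mu)
  z <- backsolve(cholS, x - mu, transpose = TRUE)
  q <- sum(z^2)
  lgamma((df + k) / 2) - lgamma(df / 2) - (k / 2) * log(df * pi) -
    sum(log(diag(cholS))) - ((df + k) / 2) * log1p(q / df)
}

rc_rmvt <- function(mu, cholS, df) {
  k <- length(mu)
  z <- stats::rnorm(k)
  w <- sqrt(df / stats::rchisq(1, df))
  mu + drop(t(cholS) %*% z) * w
}

# split R-hat (Gelman et al.) on a draws matrix [iter x chain]
rc_split_rhat <- function(x) {
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size from pooled split chains (initial positive sequence)
rc_ess <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (stats::var(as.vector(x)) == 0) return(n * m)
  acs <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = min(n - 1L, 100L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- rowMeans(acs)
  ssum <- 0
  for (k in seq(2, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair < 0) break
    ssum <- ssum + pair
  }
  max(1, (n * m) / (1 + 2 * ssum))
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing `prob` of the draws.
#'
#' @param x numeric draws.
#' @param prob interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Region-of-practical-equivalence decision for a parameter
#'
#' `practically_zero` when the 95% HDI lies entirely inside
#' `(-rope_halfwidth, +rope_halfwidth)`, `nonzero` when entirely outside,
#' `undecided` otherwise. Requires at least 1000 draws.
#'
#' @param samples posterior draws of the parameter.
#' @param rope_halfwidth half width of the ROPE (default 0.1, on the
#'   standardized rating scale).
#' @return `"practically_zero"`, `"nonzero"`, or `"undecided"`.
#' @export
rope_decision <- function(samples, rope_halfwidth = 0.1) {
  if (length(samples) < 1000)
    stop("rope_decision needs >= 1000 posterior draws, got ",
         length(samples))
  h <- hdi(samples, 0.95)
  if (h[1] > -rope_halfwidth && h[2] < rope_halfwidth)
    return("practically_zero")
  if (h[1] > rope_halfwidth || h[2] < -rope_halfwidth) return("nonzero")
  "undecided"
}

#' Fit the spine + compression trend model
#'
#' @param data output of [standardize_ratings()] (or any data.frame with
#'   `chain_id`, `retelling_index` in 0..3, `y`); every story must have all
#'   four retellings.
#' @param chains,draws,warmup sampler settings (post-warmup draws per
#'   chain).
#' @param seed integer RNG seed.
#' @param rope_halfwidth passed to [rope_decision()].
#' @param gamma_fixed fix the compression at a value (e.g. 0 reduces the
#'   model to a random-intercept linear trend); `NULL` estimates it.
#' @param rhat_max convergence gate; the fit stops with a diagnostic error
#'   when any split R-hat exceeds it.
#' @return An object of class `trend_fit`: `summary` (median and 95% HDI
#'   per parameter with ROPE decisions for `beta1` and `gamma`), `draws`
#'   (matrix of pooled post-warmup draws), `story_offsets` (posterior median
#'   `delta[s]`), `fitted_spine` (posterior-median spine per retelling),
#'   `diagnostics` (split R-hat, ESS, acceptance rate, divergences = 0).
#' @export
fit_trend <- function(data, chains = 4, draws = 1000, warmup = 1000,
                      seed = 1, rope_halfwidth = 0.1, gamma_fixed = NULL,
                      rhat_max = 1.01) {
  stopifnot(all(c("chain_id", "retelling_index", "y") %in% names(data)))
  wide <- stats::reshape(
    data[, c("chain_id", "retelling_index", "y")],
    idvar = "chain_id", timevar = "retelling_index", direction = "wide")
  need <- paste0("y.", 0:3)
  if (!all(need %in% names(wide)) || anyNA(wide[, need]))
    stop("every story needs ratings at all four retellings (0-3)")
  Y <- as.matrix(wide[, need])
  S <- nrow(Y)
  if (S < 10) stop("need >= 10 stories with 4 retellings, got ", S)

  npar <- if (is.null(gamma_fixed)) 5L else 4L
  par_names <- if (is.null(gamma_fixed)) RC_TREND_PARS else
    RC_TREND_PARS[-3]
  nlp <- function(p) -rc_trend_lp(p, Y, gamma_fixed)
  start <- if (is.null(gamma_fixed)) c(mean(Y), 0, 0, log(0.5), log(0.5))
           else c(mean(Y), 0, log(0.5), log(0.5))
  opt <- stats::optim(start, nlp, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  H <- stats::optimHess(opt$par, nlp)
  V <- tryCatch(solve(H), error = function(e)
    stop("trend model non-convergence: singular Hessian at the mode"))
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop("trend model non-convergence: Hessian not positive definite")
  cholS <- chol(V * 1.4)  # mildly inflated proposal scale
  df <- 7

  set.seed(as.integer(seed) %% .Machine$integer.max)

  # one sweep of independence MH from a fixed multivariate-t proposal
  run_im <- function(n_iter, mu, chol_prop, df_prop, count_acc = FALSE) {
    out <- matrix(NA_real_, n_iter, npar)
    n_acc <- 0L
    cur <- rc_rmvt(mu, chol_prop, df_prop)
    lp_cur <- rc_trend_lp(cur, Y, gamma_fixed)
    tries <- 0
    while (!is.finite(lp_cur) && tries < 100) {
      cur <- rc_rmvt(mu, chol_prop, df_prop)
      lp_cur <- rc_trend_lp(cur, Y, gamma_fixed)
      tries <- tries + 1
    }
    lq_cur <- rc_dmvt(cur, mu, chol_prop, df_prop)
    for (it in seq_len(n_iter)) {
      prop <- rc_rmvt(mu, chol_prop, df_prop)
      lp_prop <- rc_trend_lp(prop, Y, gamma_fixed)
      if (is.finite(lp_prop)) {
        lq_prop <- rc_dmvt(prop, mu, chol_prop, df_prop)
        if (log(stats::runif(1)) <
            (lp_prop - lq_prop) - (lp_cur - lq_cur)) {
          cur <- prop; lp_cur <- lp_prop; lq_cur <- lq_prop
          n_acc <- n_acc + 1L
        }
      }
      out[it, ] <- cur
    }
    list(draws = out, n_acc = n_acc)
  }

  # warmup phase with the curvature (Laplace) proposal, pooled across
  # chains to moment-match the final proposal to the posterior
  wu <- lapply(seq_len(chains), function(cidx)
    run_im(max(warmup, 200L), opt$par, cholS, df)$draws)
  pool <- do.call(rbind, wu)
  mu2 <- colMeans(pool)
  V2 <- stats::cov(pool)
  V2 <- (V2 + t(V2)) / 2 + diag(1e-10, npar)
  chol2 <- tryCatch(chol(V2 * 1.3), error = function(e) cholS)
  df2 <- 10

  all_draws <- array(NA_real_, c(draws, chains, npar))
  acc <- 0L; tot <- chains * draws
  for (cidx in seq_len(chains)) {
    res <- run_im(draws, mu2, chol2, df2)
    all_draws[, cidx, ] <- res$draws
    acc <- acc + res$n_acc
  }

  # back-transform scale parameters, reinsert fixed gamma
  mats <- lapply(seq_len(npar), function(j) all_draws[, , j, drop = TRUE])
  names(mats) <- par_names
  mats$sigma <- exp(mats$sigma)
  mats$tau <- exp(mats$tau)
  if (!is.null(gamma_fixed))
    mats$gamma <- matrix(gamma_fixed, draws, chains)
  mats <- mats[RC_TREND_PARS]

  rhat <- vapply(par_names, function(p) rc_split_rhat(mats[[p]]),
                 numeric(1))
  ess <- vapply(par_names, function(p) rc_ess(mats[[p]]), numeric(1))
  if (any(rhat > rhat_max))
    stop("trend model non-convergence: split R-hat ",
         paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", "),
         " exceeds ", rhat_max, " (acceptance rate ",
         sprintf("%.2f", acc / max(tot, 1)), ")")

  pooled <- vapply(RC_TREND_PARS, function(p) as.vector(mats[[p]]),
                   numeric(draws * chains))
  summ <- do.call(rbind, lapply(RC_TREND_PARS, function(p) {
    x <- pooled[, p]
    h <- hdi(x, 0.95)
    data.frame(parameter = p, median = stats::median(x),
               hdi_low = h[1], hdi_high = h[2],
               rope = if (p %in% c("beta1", "gamma") && length(x) >= 1000)
                 rope_decision(x, rope_halfwidth) else NA_character_,
               stringsAsFactors = FALSE)
  }))

  # conditional posterior medians of the story offsets
  r <- 0:3
  nd <- nrow(pooled)
  idx <- if (nd > 400) round(seq(1, nd, length.out = 400)) else seq_len(nd)
  dmat <- vapply(idx, function(i) {
    u <- exp(-pooled[i, "gamma"] * r)
    m <- pooled[i, "beta0"] + pooled[i, "beta1"] * r
    E <- sweep(Y, 2, m)
    t2 <- pooled[i, "tau"]^2; s2 <- pooled[i, "sigma"]^2
    drop(E %*% u) * t2 / (s2 + t2 * sum(u^2))
  }, numeric(S))
  offsets <- apply(dmat, 1, stats::median)

  spine <- vapply(r, function(rr)
    stats::median(pooled[, "beta0"] + pooled[, "beta1"] * rr), numeric(1))

  structure(list(
    summary = summ,
    draws = pooled,
    story_offsets = stats::setNames(offsets, wide$chain_id),
    fitted_spine = data.frame(retelling_index = r, spine_median = spine),
    diagnostics = list(rhat = rhat, ess = ess,
                       accept_rate = acc / max(tot, 1), divergences = 0L,
                       mode = stats::setNames(opt$par, par_names)),
    settings = list(chains = chains, draws = draws, warmup = warmup,
                    seed = seed, rope_halfwidth = rope_halfwidth,
                    gamma_fixed = gamma_fixed),
    n_stories = S), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: %d stories, %d draws, accept %.2f, max R-hat %.3f>\n",
              x$n_stories, nrow(x$draws), x$diagnostics$accept_rate,
              max(x$diagnostics$rhat)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
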