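## Hamiltonian Monte Carlo with warmup adaptation (dual-averaged step
## size, diagonal metric), split rank-normalized R-hat, and posterior
## summaries with support grading.

## One HMC chain. logpost_grad(theta) returns the log posterior with a
## "gradient" attribute. Adaptation: dual averaging of the step size
## toward `target_accept` throughout warmup; the diagonal metric is
## estimated from draws in (25%, 90%] of warmup and applied, with step
## size re-adaptation, for the final 10%. The number of leapfrog steps is
## drawn uniformly in 1..L_max each iteration (jittered trajectories).
hmc_chain <- function(logpost_grad, init, n_warmup, n_draws,
                      control = list()) {
  L_max <- control$L_max %||% 25L
  target_accept <- control$target_accept %||% 0.8
  d <- length(init)
  theta <- init
  lp <- logpost_grad(theta)
  if (!is.finite(lp)) stop("non-finite log posterior at the initial value")
  gr <- attr(lp, "gradient")

  inv_metric <- rep(1, d)
  eps <- 0.1 / d^0.25
  ## dual-averaging state (Hoffman & Gelman defaults)
  mu <- log(10 * eps)
  log_eps_bar <- 0
  H_bar <- 0
  da_gamma <- 0.05
  t0 <- 10
  kappa <- 0.75
  da_iter <- 0

  window_lo <- floor(0.25 * n_warmup)
  window_hi <- floor(0.90 * n_warmup)
  win_sum <- numeric(d)
  win_sumsq <- numeric(d)
  win_n <- 0

  n_iter <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, d)
  accept_sum <- 0
  divergences <- 0L

  for (it in seq_len(n_iter)) {
    adapting <- it <= n_warmup
    L <- sample.int(L_max, 1)
    r0 <- stats::rnorm(d) / sqrt(inv_metric)
    q <- theta
    r <- r0
    g <- gr
    valid <- TRUE
    lp_q <- lp
    for (s in seq_len(L)) {
      r <- r + 0.5 * eps * g
      q <- q + eps * inv_metric * r
      lp_q <- logpost_grad(q)
      if (!is.finite(lp_q)) {
        valid <- FALSE
        break
      }
      g <- attr(lp_q, "gradient")
      r <- r + 0.5 * eps * g
    }
    if (valid) {
      h0 <- -as.numeric(lp) + 0.5 * sum(inv_metric * r0^2)
      h1 <- -as.numeric(lp_q) + 0.5 * sum(inv_metric * r^2)
      a <- min(1, exp(h0 - h1))
      if (!is.finite(a)) a <- 0
      if ((h1 - h0) > 1000) divergences <- divergences + !adapting
    } else a <- 0
    if (stats::runif(1) < a) {
      theta <- q
      lp <- lp_q
      gr <- attr(lp_q, "gradient")
    }
    if (adapting) {
      da_iter <- da_iter + 1
      H_bar <- (1 - 1 / (da_iter + t0)) * H_bar +
        (target_accept - a) / (da_iter + t0)
      log_eps <- mu - sqrt(da_iter) / da_gamma * H_bar
      w <- da_iter^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it > window_lo && it <= window_hi) {
        win_sum <- win_sum + theta
        win_sumsq <- win_sumsq + theta^2
        win_n <- win_n + 1
      }
      if (it == window_hi && win_n > 10) {
        v <- (win_sumsq - win_sum^2 / win_n) / (win_n - 1)
        ## regularize toward unit scale as Stan does
        inv_metric <- win_n / (win_n + 5) * v + 5 / (win_n + 5) * 1e-3
        inv_metric[inv_metric <= 0] <- 1e-3
        ## restart step-size adaptation for the new metric
        mu <- log(10 * eps)
        H_bar <- 0
        log_eps_bar <- 0
        da_iter <- 0
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      accept_sum <- accept_sum + a
      draws[it - n_warmup, ] <- theta
    }
  }
  list(draws = draws, accept_rate = accept_sum / n_draws,
       step_size = eps, divergences = divergences)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample the posterior of the dynamic occupancy model
#'
#' Runs parallel HMC chains from random starting values on the
#' marginalized log-posterior (latent occupancy is never sampled; site
#' random intercepts are sampled as continuous parameters in a
#' non-centered parameterization). Seed-deterministic: the same
#' configuration and data yield identical draws.
#'
#' @param history A `detection_history` (or the `ndet`/`nocc` list from
#'   [history_stats()]).
#' @param designs `design_blocks` matching the history's sites/periods.
#' @param config An `occu_config`; `config$mcmc` supplies chains, warmup,
#'   draws and seed, `config$priors` the prior scales.
#' @param control Optional sampler controls (`L_max`, `target_accept`,
#'   `init_retries`).
#' @return Object of class `"occu_fit"`: post-warmup draws
#'   (iterations x chains x parameters), parameter names, seed,
#'   designs, and per-chain diagnostics.
#' @export
sample_posterior <- function(history, designs, config, control = list()) {
  stats_ <- if (inherits(history, "detection_history")) {
    history_stats(history)
  } else history
  m <- config$mcmc
  priors <- config$priors
  lay <- param_layout(designs)
  lpg <- function(theta) total_logposterior(theta, stats_, designs, priors)

  chains <- vector("list", m$chains)
  for (ch in seq_len(m$chains)) {
    set.seed(m$seed + 1000L * (ch - 1L))
    init <- NULL
    for (try in seq_len(control$init_retries %||% 20L)) {
      cand <- init_params(designs)
      if (is.finite(total_logposterior(cand, stats_, designs, priors,
                                       grad = FALSE))) {
        init <- cand
        break
      }
    }
    if (is.null(init)) stop("could not find a finite starting value")
    chains[[ch]] <- hmc_chain(lpg, init, m$warmup, m$draws, control)
  }
  draws <- array(NA_real_, dim = c(m$draws, m$chains, lay$n_par),
                 dimnames = list(iteration = NULL, chain = NULL,
                                 parameter = param_names(designs)))
  for (ch in seq_len(m$chains)) draws[, ch, ] <- chains[[ch]]$draws
  structure(list(draws = draws,
                 parameters = param_names(designs),
                 layout = lay,
                 designs = designs,
                 seed = m$seed, warmup = m$warmup,
                 diagnostics = lapply(chains, function(x)
                   x[c("accept_rate", "step_size", "divergences")])),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("occupancy model fit:", d[2], "chains x", d[1], "post-warmup draws,",
      d[3], "parameters\n")
  acc <- vapply(x$diagnostics, `[[`, numeric(1), "accept_rate")
  cat("  mean acceptance:", round(mean(acc), 2),
      " max split R-hat (coefficients):",
      round(max(rhat(x)[grep("^(psi1|p|gamma|epsilon)_", x$parameters)]), 3),
      "\n")
  invisible(x)
}

#' Split-chain rank-normalized potential scale reduction factor
#'
#' Each chain is split in half, pooled draws are rank-normalized through
#' the normal quantile function, and the classic between/within-chain
#' variance ratio is computed on the transformed draws. Values near 1
#' indicate convergence.
#'
#' @param x An `occu_fit`, or an iterations x chains matrix of draws.
#' @param parameter Parameter name or index when `x` is a fit (default:
#'   all parameters).
#' @return Named numeric vector of R-hat values (`NA` where total
#'   variance is zero, with a warning).
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "occu_fit")) {
    idx <- if (is.null(parameter)) seq_along(x$parameters) else parameter
    out <- vapply(idx, function(k) rhat_matrix(x$draws[, , k]), numeric(1))
    names(out) <- x$parameters[idx]
    return(out)
  }
  rhat_matrix(x)
}

rhat_matrix <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, nrow(mat) >= 4)
  half <- floor(nrow(mat) / 2)
  split_mat <- cbind(mat[seq_len(half), , drop = FALSE],
                     mat[(half + 1):(2 * half), , drop = FALSE])
  if (stats::var(as.vector(split_mat)) == 0) {
    warning("zero total variance; R-hat undefined")
    return(NA_real_)
  }
  z <- stats::qnorm((rank(split_mat) - 3 / 8) / (length(split_mat) + 1 / 4))
  z <- matrix(z, nrow(split_mat), ncol(split_mat))
  m <- ncol(z)
  n <- nrow(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Grade coefficient support from the posterior probability of positivity
#'
#' `p_pos` is the fraction of pooled post-warmup draws greater than zero.
#' Support is strong when `p_pos` is at or beyond the strong threshold on
#' either side (>= 0.90 or <= 0.10 by default; the strong label takes
#' precedence on the shared boundary), moderate between the moderate and
#' strong thresholds (0.70/0.30), and none otherwise.
#'
#' @param p_pos Numeric vector in `[0, 1]`.
#' @param strong,moderate Thresholds in (0.5, 1).
#' @return Character vector in
#'   `{"strong+", "moderate+", "none", "moderate-", "strong-"}`.
#' @export
support_category <- function(p_pos, strong = 0.90, moderate = 0.70) {
  out <- rep("none", length(p_pos))
  p_neg <- 1 - p_pos
  out[p_pos >= moderate] <- "moderate+"
  out[p_pos >= strong] <- "strong+"
  out[p_neg >= moderate] <- "moderate-"
  out[p_neg >= strong] <- "strong-"
  out
}

#' Summarize a fit: medians, intervals, R-hat, support
#'
#' Pools post-warmup draws across chains and reports, per parameter, the
#' posterior median, the central 95% credible interval, split
#' rank-normalized R-hat, `p_pos`, the support category, and a flag for
#' large effects (|median| > 1).
#'
#' @param fit An `occu_fit`.
#' @param thresholds List with `strong` and `moderate` (defaults 0.90 and
#'   0.70).
#' @return Data frame of class `"occu_summary"`, one row per parameter.
#' @export
summarize_fit <- function(fit, thresholds = list(strong = 0.90,
                                                 moderate = 0.70)) {
  pooled <- apply(fit$draws, 3, as.vector)
  med <- apply(pooled, 2, stats::median)
  ci <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975))
  p_pos <- colMeans(pooled > 0)
  out <- data.frame(parameter = fit$parameters,
                    median = med,
                    l95 = ci[1, ], u95 = ci[2, ],
                    rhat = rhat(fit),
                    p_pos = p_pos,
                    support = support_category(p_pos, thresholds$strong,
                                               thresholds$moderate),
                    large_effect = abs(med) > 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("occu_summary", "data.frame")
  out
}

#' Pooled post-warmup draws of a fit as a matrix
#' @param fit An `occu_fit`.
#' @return Matrix (chains * iterations) x parameters.
#' @export
pooled_draws <- function(fit) {
  m <- apply(fit$draws, 3, as.vector)
  colnames(m) <- fit$parameters
  m
}
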