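## The marginalized dynamic-occupancy likelihood.
##
## `site_loglik()` is the readable R reference (general per-occasion p);
## the sampler uses the compiled forward-backward pass, which assumes
## occasion-constant site-level detection and returns analytic gradients.
## The two agree exactly on shared ground and both are checked against
## brute-force enumeration over latent sequences in the test suite.

#' Marginalized log-likelihood of one site's detection history
#'
#' Forward recursion over the latent occupancy state `z_t` in {0, 1}:
#' initial law `(1 - psi1, psi1)`; transition rows `(1 - gamma, gamma)`
#' from `z = 0` and `(epsilon, 1 - epsilon)` from `z = 1`; period emission
#' `prod_j p^y (1-p)^(1-y)` over non-missing occasions when occupied, and
#' the indicator that no detection occurred when unoccupied (a detection
#' at an unoccupied site has probability 0). Missing occasions contribute
#' a factor 1; fully missing periods contribute emission 1 in both states.
#'
#' @param y Integer matrix T x J with values 0, 1 or `NA` (a vector is
#'   treated as a single period, T = 1).
#' @param psi1 Initial occupancy probability, in (0, 1).
#' @param gamma Colonization probabilities, length T-1.
#' @param epsilon Extirpation probabilities, length T-1.
#' @param p Detection probability: scalar, per-period vector (length T),
#'   or T x J matrix of per-occasion values.
#' @return Log-likelihood scalar; `-Inf` when the history is impossible
#'   under the parameters (never an exception).
#' @export
site_loglik <- function(y, psi1, gamma, epsilon, p) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  Tn <- nrow(y)
  J <- ncol(y)
  if (length(gamma) != Tn - 1 || length(epsilon) != Tn - 1) {
    stop("gamma and epsilon must have length T - 1 = ", Tn - 1)
  }
  if (is.matrix(p)) {
    stopifnot(nrow(p) == Tn, ncol(p) == J)
    P <- p
  } else if (length(p) == Tn) {
    P <- matrix(p, Tn, J)
  } else if (length(p) == 1) {
    P <- matrix(p, Tn, J)
  } else stop("p must be a scalar, a length-T vector, or a T x J matrix")

  emit <- function(t) {
    obs <- !is.na(y[t, ])
    if (!any(obs)) return(c(1, 1))
    yt <- y[t, obs]
    pt <- P[t, obs]
    e1 <- prod(ifelse(yt == 1, pt, 1 - pt))
    e0 <- if (any(yt == 1)) 0 else 1
    c(e0, e1)
  }

  alpha <- c(1 - psi1, psi1) * emit(1)
  ll <- 0
  if (Tn > 1) {
    for (t in 2:Tn) {
      s <- sum(alpha)
      if (s <= 0) return(-Inf)
      ll <- ll + log(s)
      alpha <- alpha / s
      g <- gamma[t - 1]
      e <- epsilon[t - 1]
      pred <- c(alpha[1] * (1 - g) + alpha[2] * e,
                alpha[1] * g + alpha[2] * (1 - e))
      alpha <- pred * emit(t)
    }
  }
  s <- sum(alpha)
  if (s <= 0) return(-Inf)
  ll + log(s)
}

#' Sufficient statistics of a detection history for site-level detection
#'
#' With occasion-constant detection per site, the likelihood depends on
#' the history only through the number of surveyed occasions and the
#' number of detections per (site, period).
#'
#' @param history A `detection_history`.
#' @return List with integer matrices `ndet` and `nocc` (site x period).
#' @export
history_stats <- function(history) {
  y <- history$y
  nocc <- apply(!is.na(y), c(1, 2), sum)
  ndet <- apply(y == 1, c(1, 2), sum)
  ndet[is.na(ndet)] <- 0
  list(ndet = ndet, nocc = nocc)
}

## ---- parameter vector layout -------------------------------------------
## theta = [beta_psi1 (4) | beta_p (3) | beta_gamma (10) | beta_epsilon (10)
##          | log_sigma_eta | eta_raw (n_sites)]
## eta_i = sigma_eta * eta_raw_i enters the detection linear predictor
## (non-centered parameterization).

param_layout <- function(designs) {
  k_psi1 <- ncol(designs$X_psi1)
  k_p <- ncol(designs$X_p)
  k_g <- ncol(designs$X_gamma)
  n <- nrow(designs$X_psi1)
  sizes <- c(beta_psi1 = k_psi1, beta_p = k_p, beta_gamma = k_g,
             beta_epsilon = k_g, log_sigma_eta = 1, eta_raw = n)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(sizes = sizes, starts = starts, ends = ends, n_par = sum(sizes))
}

param_names <- function(designs) {
  c(paste0("psi1_", colnames(designs$X_psi1)),
    paste0("p_", colnames(designs$X_p)),
    paste0("gamma_", colnames(designs$X_gamma)),
    paste0("epsilon_", colnames(designs$X_epsilon)),
    "log_sigma_eta",
    paste0("eta_raw[", seq_len(nrow(designs$X_psi1)), "]"))
}

unpack_params <- function(theta, layout) {
  s <- layout$starts
  e <- layout$ends
  list(beta_psi1 = theta[s[1]:e[1]],
       beta_p = theta[s[2]:e[2]],
       beta_gamma = theta[s[3]:e[3]],
       beta_epsilon = theta[s[4]:e[4]],
       log_sigma_eta = theta[s[5]],
       eta_raw = theta[s[6]:e[6]])
}

#' Joint log-posterior (and gradient) of the dynamic occupancy model
#'
#' Sums the marginalized site log-likelihoods (the logit-scale detection
#' predictor of site i includes the random intercept
#' `eta_i = sigma_eta * eta_raw_i`) and the log-priors: independent
#' normal(0, `beta_scale`) on all regression coefficients, half-normal(0,
#' `sigma_eta_scale`) on `sigma_eta` (sampled as `log_sigma_eta`, with the
#' Jacobian term), and standard normal on the non-centered `eta_raw`.
#'
#' @param theta Parameter vector in the package's layout (use
#'   [init_params()] for a starting point).
#' @param stats Sufficient statistics from [history_stats()].
#' @param designs `design_blocks`.
#' @param priors List with `beta_scale` and `sigma_eta_scale`.
#' @param grad Also compute the analytic gradient (attribute
#'   `"gradient"`).
#' @return Log-posterior scalar, with gradient attached when requested.
#' @export
total_logposterior <- function(theta, stats, designs,
                               priors = list(beta_scale = 2.5,
                                             sigma_eta_scale = 1),
                               grad = TRUE) {
  if (any(!is.finite(c(designs$X_psi1, designs$X_p, designs$X_gamma)))) {
    stop("non-finite covariate values in the design blocks")
  }
  layout <- param_layout(designs)
  stopifnot(length(theta) == layout$n_par)
  par <- unpack_params(theta, layout)
  n <- nrow(designs$X_psi1)
  Tn <- length(designs$periods)

  sigma <- exp(par$log_sigma_eta)
  eta <- sigma * par$eta_raw
  psi1 <- expit(drop(designs$X_psi1 %*% par$beta_psi1))
  p <- expit(drop(designs$X_p %*% par$beta_p) + eta)
  if (Tn > 1) {
    g_lin <- drop(designs$X_gamma %*% par$beta_gamma)
    e_lin <- drop(designs$X_epsilon %*% par$beta_epsilon)
    gam <- matrix(expit(g_lin), n, Tn - 1, byrow = TRUE)
    eps <- matrix(expit(e_lin), n, Tn - 1, byrow = TRUE)
  } else {
    gam <- eps <- matrix(numeric(0), n, 0)
  }

  fw <- occu_forward_grad(stats$ndet, stats$nocc, psi1, p, gam, eps)
  ll <- fw$loglik

  bs <- priors$beta_scale
  ss <- priors$sigma_eta_scale
  betas <- c(par$beta_psi1, par$beta_p, par$beta_gamma, par$beta_epsilon)
  out <- ll + log_prior_only(theta, designs, priors)
  if (!grad) return(out)

  gr <- numeric(layout$n_par)
  if (is.finite(ll)) {
    dpsi1_lin <- fw$d_psi1 * psi1 * (1 - psi1)
    dp_lin <- fw$d_p * p * (1 - p)
    gr[layout$starts[1]:layout$ends[1]] <-
      drop(crossprod(designs$X_psi1, dpsi1_lin))
    gr[layout$starts[2]:layout$ends[2]] <-
      drop(crossprod(designs$X_p, dp_lin))
    if (Tn > 1) {
      dg_lin <- as.vector(t(fw$d_gamma)) * expit(g_lin) * (1 - expit(g_lin))
      de_lin <- as.vector(t(fw$d_eps)) * expit(e_lin) * (1 - expit(e_lin))
      gr[layout$starts[3]:layout$ends[3]] <-
        drop(crossprod(designs$X_gamma, dg_lin))
      gr[layout$starts[4]:layout$ends[4]] <-
        drop(crossprod(designs$X_epsilon, de_lin))
    }
    gr[layout$starts[5]] <- sum(dp_lin * par$eta_raw) * sigma
    gr[layout$starts[6]:layout$ends[6]] <- dp_lin * sigma
  }
  ## prior gradients
  gr[1:layout$ends[4]] <- gr[1:layout$ends[4]] - betas / bs^2
  gr[layout$starts[5]] <- gr[layout$starts[5]] - sigma^2 / ss^2 + 1
  gr[layout$starts[6]:layout$ends[6]] <-
    gr[layout$starts[6]:layout$ends[6]] - par$eta_raw
  attr(out, "gradient") <- gr
  out
}

## Log-prior of a parameter vector (normal betas, half-normal sigma with
## log-scale Jacobian, standard-normal non-centered random effects).
log_prior_only <- function(theta, designs, priors) {
  layout <- param_layout(designs)
  par <- unpack_params(theta, layout)
  sigma <- exp(par$log_sigma_eta)
  betas <- c(par$beta_psi1, par$beta_p, par$beta_gamma, par$beta_epsilon)
  sum(stats::dnorm(betas, 0, priors$beta_scale, log = TRUE)) +
    stats::dnorm(sigma, 0, priors$sigma_eta_scale, log = TRUE) + log(2) +
    par$log_sigma_eta +
    sum(stats::dnorm(par$eta_raw, 0, 1, log = TRUE))
}

#' Starting parameter vector
#'
#' Random starting values: coefficients drawn from normal(0, `jitter`),
#' `log_sigma_eta` near log(0.5), `eta_raw` near 0.
#'
#' @param designs `design_blocks`.
#' @param jitter Scale of the random draw. Default 0.3.
#' @return Named numeric parameter vector.
#' @export
init_params <- function(designs, jitter = 0.3) {
  layout <- param_layout(designs)
  theta <- stats::rnorm(layout$n_par, 0, jitter)
  theta[layout$starts[5]] <- log(0.5) + stats::rnorm(1, 0, 0.1)
  i6 <- layout$starts[6]:layout$ends[6]
  theta[i6] <- stats::rnorm(length(i6), 0, 0.1)
  names(theta) <- param_names(designs)
  theta
}
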