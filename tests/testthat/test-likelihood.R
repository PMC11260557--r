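test_that("single-period closed forms match the forward recursion", {
  # T=1, J=1, y=1: psi1 * p
  expect_equal(site_loglik(matrix(1L, 1, 1), 0.5, numeric(0), numeric(0), 0.8),
               log(0.5 * 0.8))
  # T=1, J=2, y=(0,0): psi1 (1-p)^2 + (1-psi1)
  expect_equal(site_loglik(matrix(0L, 1, 2), 0.5, numeric(0), numeric(0), 0.5),
               log(0.5 * 0.25 + 0.5))
  # detection at an unoccupied-only configuration is impossible, not an error
  expect_identical(site_loglik(matrix(1L, 1, 1), 1e-300, numeric(0),
                               numeric(0), 1e-300), -Inf)
})

test_that("the forward recursion equals brute-force enumeration", {
  set.seed(2024)
  for (r in 1:200) {
    inst <- random_instance()
    got <- site_loglik(inst$y, inst$psi1, inst$gamma, inst$epsilon, inst$p)
    want <- enum_loglik(inst$y, inst$psi1, inst$gamma, inst$epsilon, inst$p)
    if (is.infinite(want)) expect_identical(got, -Inf)
    else expect_lt(abs(got - want), 1e-10)
  }
})

test_that("per-occasion detection probabilities are supported", {
  set.seed(30)
  y <- matrix(sample(c(0L, 1L, NA), 6, TRUE), 2, 3)
  P <- matrix(runif(6, 0.1, 0.9), 2, 3)
  got <- site_loglik(y, 0.6, 0.4, 0.2, P)
  want <- enum_loglik(y, 0.6, 0.4, 0.2, P)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("compiled sufficient-statistic path agrees with the R reference", {
  set.seed(77)
  for (r in 1:50) {
    inst <- random_instance()
    Tn <- nrow(inst$y)
    nocc <- matrix(rowSums(!is.na(inst$y)), 1)
    ndet <- matrix(rowSums(inst$y == 1, na.rm = TRUE), 1)
    cpp <- dynoccam:::occu_forward_grad(ndet, nocc, inst$psi1, inst$p,
                                        matrix(inst$gamma, 1),
                                        matrix(inst$epsilon, 1))$loglik
    ref <- site_loglik(inst$y, inst$psi1, inst$gamma, inst$epsilon, inst$p)
    if (is.infinite(ref)) expect_identical(cpp, -Inf)
    else expect_equal(cpp, ref, tolerance = 1e-12)
  }
})

test_that("log-posterior is site-additive and permutation invariant", {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 8)
  des <- dat$truth$designs
  st <- history_stats(dat$history)
  set.seed(4)
  theta <- init_params(des)
  lp <- total_logposterior(theta, st, des, grad = FALSE)
  expect_true(is.finite(lp))

  # permuting sites leaves the total unchanged (eta permuted alongside)
  perm <- sample(nrow(st$ndet))
  des_p <- des
  des_p$X_psi1 <- des$X_psi1[perm, , drop = FALSE]
  des_p$X_p <- des$X_p[perm, , drop = FALSE]
  Tm1 <- length(des$periods) - 1
  row_perm <- as.vector(t(matrix(seq_len(nrow(des$X_gamma)),
                                 ncol = Tm1, byrow = TRUE)[perm, ]))
  des_p$X_gamma <- des$X_gamma[row_perm, , drop = FALSE]
  des_p$X_epsilon <- des$X_epsilon[row_perm, , drop = FALSE]
  st_p <- list(ndet = st$ndet[perm, ], nocc = st$nocc[perm, ])
  lay <- dynoccam:::param_layout(des)
  theta_p <- theta
  eta_idx <- lay$starts[6]:lay$ends[6]
  theta_p[eta_idx] <- theta[eta_idx][perm]
  expect_equal(total_logposterior(theta_p, st_p, des_p, grad = FALSE), lp,
               tolerance = 1e-12)

  # doubling every site doubles the likelihood term
  priors <- list(beta_scale = 2.5, sigma_eta_scale = 1)
  ll_only <- function(st_, des_, th_) {
    total_logposterior(th_, st_, des_, priors, grad = FALSE) -
      dynoccam:::log_prior_only(th_, des_, priors)
  }
  des_d <- des
  des_d$X_psi1 <- rbind(des$X_psi1, des$X_psi1)
  des_d$X_p <- rbind(des$X_p, des$X_p)
  des_d$X_gamma <- rbind(des$X_gamma, des$X_gamma)
  des_d$X_epsilon <- rbind(des$X_epsilon, des$X_epsilon)
  st_d <- list(ndet = rbind(st$ndet, st$ndet), nocc = rbind(st$nocc, st$nocc))
  theta_d <- c(theta[1:lay$ends[5]], theta[eta_idx], theta[eta_idx])
  expect_equal(ll_only(st_d, des_d, theta_d), 2 * ll_only(st, des, theta),
               tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 15)
  des <- dat$truth$designs
  st <- history_stats(dat$history)
  set.seed(6)
  theta <- init_params(des)
  g <- attr(total_logposterior(theta, st, des), "gradient")
  h <- 1e-6
  fd <- vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (total_logposterior(tp, st, des, grad = FALSE) -
       total_logposterior(tm, st, des, grad = FALSE)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-5)
})

test_that("a dynamic model with T = 1 reduces to single-season occupancy", {
  # closed form: psi1 * prod_j p^y (1-p)^(1-y) + (1 - psi1) * 1{all y = 0}
  set.seed(12)
  for (r in 1:20) {
    J <- sample(1:5, 1)
    y <- matrix(sample(c(0L, 1L), J, TRUE, prob = c(0.7, 0.3)), 1, J)
    psi1 <- runif(1, 0.1, 0.9)
    p <- runif(1, 0.1, 0.9)
    closed <- psi1 * prod(ifelse(y == 1, p, 1 - p)) +
      (1 - psi1) * as.numeric(all(y == 0))
    expect_equal(site_loglik(y, psi1, numeric(0), numeric(0), p),
                 log(closed), tolerance = 1e-12)
  }
})

test_that("detection increases with any positively weighted detection covariate", {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 40)
  des <- dat$truth$designs
  beta_p <- c(0.2, 0.5, -0.3)
  p0 <- expit(drop(des$X_p %*% beta_p))
  for (k in 2:3) {
    bump <- beta_p
    bump[k] <- bump[k] + 0.4
    p1 <- expit(drop(des$X_p %*% bump))
    pos <- des$X_p[, k] > 0
    expect_true(all(p1[pos] > p0[pos]))
    expect_true(all(p1[!pos & des$X_p[, k] != 0] < p0[!pos &
                                                        des$X_p[, k] != 0]))
  }
})
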