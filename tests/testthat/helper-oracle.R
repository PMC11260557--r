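# Brute-force oracle: marginal likelihood by enumeration over all 2^T
# latent occupancy sequences. Deliberately independent of the package's
# forward recursion.
enum_loglik <- function(y, psi1, gamma, epsilon, p) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  Tn <- nrow(y)
  P <- if (is.matrix(p)) p else matrix(p, Tn, ncol(y))
  total <- 0
  for (code in 0:(2^Tn - 1)) {
    z <- as.integer(intToBits(code))[seq_len(Tn)]
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    if (Tn > 1) {
      for (t in 2:Tn) {
        pr <- pr * if (z[t - 1] == 0) {
          if (z[t] == 1) gamma[t - 1] else 1 - gamma[t - 1]
        } else {
          if (z[t] == 0) epsilon[t - 1] else 1 - epsilon[t - 1]
        }
      }
    }
    em <- 1
    for (t in seq_len(Tn)) {
      for (j in seq_len(ncol(y))) {
        if (is.na(y[t, j])) next
        em <- em * if (z[t] == 1) {
          if (y[t, j] == 1) P[t, j] else 1 - P[t, j]
        } else {
          if (y[t, j] == 1) 0 else 1
        }
      }
    }
    total <- total + pr * em
  }
  log(total)
}

# Random small likelihood instance under a fixed RNG state.
random_instance <- function(T_max = 4, J_max = 3) {
  Tn <- sample(seq_len(T_max), 1)
  J <- sample(seq_len(J_max), 1)
  list(y = matrix(sample(c(0L, 1L, NA), Tn * J, TRUE,
                         prob = c(0.5, 0.3, 0.2)), Tn, J),
       psi1 = stats::runif(1, 0.05, 0.95),
       gamma = stats::runif(max(Tn - 1, 0), 0.05, 0.95),
       epsilon = stats::runif(max(Tn - 1, 0), 0.05, 0.95),
       p = stats::runif(1, 0.05, 0.95))
}

# Small scenario + fast MCMC config used by several module tests.
tiny_scenario <- function(...) {
  scenario(n_sites = 15, n_periods = 3, n_occasions = 4, n_grid = 25, ...)
}

quick_config <- function(seed = 1L, chains = 2, warmup = 300, draws = 500) {
  run_config(mcmc = list(chains = chains, warmup = warmup, draws = draws,
                         seed = seed))
}

write_tmp_csv <- function(df, name = "tbl.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
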