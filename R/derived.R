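## Post-fit derived quantities: occupancy trajectories, turnover, rates
## of change, decline proportions, stable states, and grid prediction.

#' Project the occupancy trajectory from the dynamic rates
#'
#' Iterates `psi_{t+1} = psi_t (1 - epsilon_t) + (1 - psi_t) gamma_t`
#' from the initial occupancy.
#'
#' @param psi1 Initial occupancy in `[0, 1]`.
#' @param gamma Colonization probabilities, length T-1.
#' @param epsilon Extirpation probabilities, length T-1.
#' @return Numeric vector `psi` of length T.
#' @export
project_psi <- function(psi1, gamma, epsilon) {
  if (length(gamma) != length(epsilon)) {
    stop("gamma and epsilon must have equal length")
  }
  psi <- numeric(length(gamma) + 1)
  psi[1] <- psi1
  for (t in seq_along(gamma)) {
    psi[t + 1] <- psi[t] * (1 - epsilon[t]) + (1 - psi[t]) * gamma[t]
  }
  psi
}

#' Turnover probability between consecutive periods
#'
#' The probability that a site changes occupancy status from one season
#' to the next: `tau'_t = psi_t epsilon_t + (1 - psi_t) gamma_t`. Higher
#' turnover indicates lower site fidelity.
#'
#' @param psi_t Occupancy at the origin period.
#' @param gamma_t,epsilon_t Colonization and extirpation for the
#'   transition.
#' @return Turnover probability (vectorized).
#' @export
turnover <- function(psi_t, gamma_t, epsilon_t) {
  psi_t * epsilon_t + (1 - psi_t) * gamma_t
}

#' Rate of change in occupancy
#'
#' `lambda = psi_last / psi_first`; values below 1 indicate decline.
#'
#' @param psi_first Occupancy in the earlier period (> 0).
#' @param psi_last Occupancy in the later period.
#' @return `lambda` (vectorized); `NA` with a warning where
#'   `psi_first == 0`.
#' @export
rate_of_change <- function(psi_first, psi_last) {
  out <- ifelse(psi_first > 0, psi_last / psi_first, NA_real_)
  if (anyNA(out)) warning("lambda undefined where psi_first == 0")
  out
}

#' Proportion of cells in decline
#'
#' The fraction of valid cells whose rate of change is strictly below 1.
#'
#' @param lambdas Numeric vector of per-cell `lambda` (NAs are dropped).
#' @return Proportion in `[0, 1]`.
#' @export
decline_proportion <- function(lambdas) {
  ok <- !is.na(lambdas)
  if (!any(ok)) stop("no valid cells")
  mean(lambdas[ok] < 1)
}

#' Stable-state (equilibrium) occupancy
#'
#' The fixed point of the occupancy recursion under constant rates:
#' `psi_eq = gamma / (gamma + epsilon)`.
#'
#' @param gamma,epsilon Colonization and extirpation probabilities.
#' @return `psi_eq` (vectorized); `NA` with a warning where
#'   `gamma + epsilon == 0`.
#' @export
stable_state <- function(gamma, epsilon) {
  s <- gamma + epsilon
  out <- ifelse(s > 0, gamma / s, NA_real_)
  if (anyNA(out)) warning("stable state undefined where gamma + epsilon == 0")
  out
}

## Linear predictors -> per-draw dynamic rates for arbitrary covariates.
## Returns list of functions of the draw matrix.
grid_designs <- function(grid, designs) {
  site_like <- data.frame(site_id = as.character(grid$cell_id),
                          moth = grid$moth, cover = grid$cover,
                          road_dist = grid$road_dist,
                          zone_area = grid$zone_area,
                          stringsAsFactors = FALSE)
  build_design_blocks(site_like, designs$season_cov, store = designs$store)
}

#' Predict occupancy dynamics over a covariate grid
#'
#' Applies the development/water mask, transforms the grid covariates
#' through the fit-time standardization store, and, for every retained
#' cell and every posterior draw, computes the linear predictors, the
#' occupancy trajectory, per-transition turnover, rates of change per
#' season class (first vs last year of that season), and seasonal
#' stable states (colonization/extirpation averaged over the season's
#' entering transitions). Summaries are cellwise posterior medians with
#' central 95% intervals; decline proportions are computed on the
#' posterior-median lambda (a draw-wise posterior of the proportion is
#' also returned).
#'
#' @param fit An `occu_fit`.
#' @param grid Data frame with `cell_id`, the site covariate columns
#'   (`moth`, `cover`, `road_dist`, `zone_area`), and optionally
#'   `high_development_fraction` and logical `water`.
#' @param mask_rules List with `max_development` (default 0.40: cells
#'   with a larger high-development fraction are removed before any
#'   proportion is computed) and `drop_water` (default TRUE).
#' @param max_draws Cap on the number of posterior draws used (thinned
#'   deterministically). Default 1000.
#' @return Object of class `"derived_series"`: list of data frames
#'   `psi` (cell x period summaries), `tau`, `lambda` (per season class),
#'   `psi_eq` (per season class), plus `decline` (median-based `c` per
#'   season class), `decline_draws`, and `cells_retained`.
#' @export
predict_grid <- function(fit, grid, mask_rules = list(max_development = 0.40,
                                                      drop_water = TRUE),
                         max_draws = 1000) {
  designs <- fit$designs
  keep <- rep(TRUE, nrow(grid))
  if (!is.null(grid$high_development_fraction)) {
    keep <- keep & grid$high_development_fraction <=
      (mask_rules$max_development %||% 0.40)
  }
  if (isTRUE(mask_rules$drop_water %||% TRUE) && !is.null(grid$water)) {
    keep <- keep & !grid$water
  }
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) stop("no grid cells retained after masking")

  check_extrapolation(grid, designs)
  gdes <- grid_designs(grid, designs)
  n <- nrow(grid)
  Tn <- length(designs$periods)
  cls <- designs$season_classes
  tcls <- designs$transition_class

  dr <- pooled_draws(fit)
  if (nrow(dr) > max_draws) {
    dr <- dr[round(seq(1, nrow(dr), length.out = max_draws)), , drop = FALSE]
  }
  S <- nrow(dr)
  lay <- fit$layout

  first_of <- function(class) which(cls == class)[1]
  last_of <- function(class) rev(which(cls == class))[1]

  psi_draws <- array(NA_real_, c(S, n, Tn))
  tau_draws <- array(NA_real_, c(S, n, Tn - 1))
  lam_draws <- list(summer = matrix(NA_real_, S, n),
                    winter = matrix(NA_real_, S, n))
  eq_draws <- list(summer = matrix(NA_real_, S, n),
                   winter = matrix(NA_real_, S, n))

  for (s in seq_len(S)) {
    par <- unpack_params(dr[s, ], lay)
    psi1 <- expit(drop(gdes$X_psi1 %*% par$beta_psi1))
    gam <- matrix(expit(drop(gdes$X_gamma %*% par$beta_gamma)),
                  n, Tn - 1, byrow = TRUE)
    eps <- matrix(expit(drop(gdes$X_epsilon %*% par$beta_epsilon)),
                  n, Tn - 1, byrow = TRUE)
    psi <- matrix(NA_real_, n, Tn)
    psi[, 1] <- psi1
    for (t in seq_len(Tn - 1)) {
      psi[, t + 1] <- psi[, t] * (1 - eps[, t]) + (1 - psi[, t]) * gam[, t]
      tau_draws[s, , t] <- turnover(psi[, t], gam[, t], eps[, t])
    }
    psi_draws[s, , ] <- psi
    for (class in c("summer", "winter")) {
      f <- first_of(class)
      l <- last_of(class)
      lam_draws[[class]][s, ] <- psi[, l] / psi[, f]
      ## entering transitions: spring (1) precedes summers, autumn (0) winters
      enter <- if (class == "summer") which(tcls == 1L) else which(tcls == 0L)
      gbar <- rowMeans(gam[, enter, drop = FALSE])
      ebar <- rowMeans(eps[, enter, drop = FALSE])
      eq_draws[[class]][s, ] <- gbar / (gbar + ebar)
    }
  }

  qsum <- function(m) {
    m <- matrix(m, S, n)
    q <- apply(m, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
               na.rm = TRUE)
    data.frame(median = q[1, ], l95 = q[2, ], u95 = q[3, ])
  }
  psi_sum <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    cbind(data.frame(cell_id = grid$cell_id, period = designs$periods[t]),
          qsum(psi_draws[, , t]))
  }))
  tau_sum <- if (Tn > 1) {
    do.call(rbind, lapply(seq_len(Tn - 1), function(t) {
      cbind(data.frame(cell_id = grid$cell_id,
                       from = designs$periods[t],
                       to = designs$periods[t + 1]),
            qsum(tau_draws[, , t]))
    }))
  } else NULL
  lam_sum <- do.call(rbind, lapply(c("summer", "winter"), function(class) {
    cbind(data.frame(cell_id = grid$cell_id, season = class),
          qsum(lam_draws[[class]]))
  }))
  eq_sum <- do.call(rbind, lapply(c("summer", "winter"), function(class) {
    cbind(data.frame(cell_id = grid$cell_id, season = class),
          qsum(eq_draws[[class]]))
  }))

  decline <- vapply(c(summer = "summer", winter = "winter"), function(class) {
    med <- apply(lam_draws[[class]], 2, stats::median, na.rm = TRUE)
    decline_proportion(med)
  }, numeric(1))
  decline_draws <- vapply(c(summer = "summer", winter = "winter"),
                          function(class) {
    rowMeans(lam_draws[[class]] < 1, na.rm = TRUE)
  }, numeric(S))

  structure(list(psi = psi_sum, tau = tau_sum, lambda = lam_sum,
                 psi_eq = eq_sum, decline = decline,
                 decline_draws = decline_draws,
                 cells_retained = as.character(grid$cell_id)),
            class = "derived_series")
}

check_extrapolation <- function(grid, designs) {
  store <- designs$store
  for (nm in c("moth", "cover", "road_dist", "zone_area")) {
    z <- abs(std_apply(store, nm, grid[[nm]]))
    if (nm == "moth" && !isTRUE(store$standardize_moth)) next
    if (any(z > 4)) {
      warning("grid covariate '", nm,
              "' extends far beyond the fitted range (extrapolation)")
    }
  }
  invisible(TRUE)
}

#' @export
print.derived_series <- function(x, ...) {
  cat("derived occupancy dynamics over", length(x$cells_retained),
      "grid cells\n")
  cat("  decline proportions (median-based): summer",
      round(x$decline[["summer"]], 3), ", winter",
      round(x$decline[["winter"]], 3), "\n")
  invisible(x)
}
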