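## Synthetic camera-trap survey generator: landscape covariates, latent
## occupancy dynamics driven by the same linear predictors the model
## fits, occasion-level detections, and optional clustered photo bursts
## that exercise the independence filter end-to-end. Everything is
## deterministic given (scenario, seed), and the latent truth is kept.

#' Define a simulation scenario
#'
#' The default scenario emulates the shape of a state-wide seasonal
#' paired-camera survey: alternating summer/winter primary periods,
#' twelve weekly occasions per period, site covariates with realistic
#' supports (log-normal zone areas, beta-distributed percent cover,
#' exponential road distances, categorical 0-4 moth damage), seasonal
#' precipitation totals in inches (rain in summer, snow in winter), and
#' moderate standardized-scale coefficients with a site-level detection
#' random effect.
#'
#' @param label Scenario name.
#' @param n_sites Number of sites.
#' @param n_periods Number of primary periods (alternating seasons).
#' @param n_occasions Secondary occasions per period.
#' @param occasion_length Days per occasion.
#' @param first_season First period label, e.g. `"S2019"`.
#' @param site_counts Sites deployed per period (staggered designs);
#'   defaults to all sites in every period. The first `site_counts[t]`
#'   sites are active in period t.
#' @param beta_psi1,beta_p,beta_gamma,beta_epsilon True coefficient
#'   vectors on the standardized scale (lengths 4, 3, 10, 10; the
#'   gamma/epsilon order is intercept, precip, season, precip:season,
#'   zone_area, cover, zone_area:cover, moth, tsd, moth:tsd).
#' @param sigma_eta Scale of the site random intercept on logit
#'   detection.
#' @param covariate_pars List of distribution parameters (see defaults).
#' @param burst List of photo-burst parameters: `mean_extra_photos`
#'   (Poisson mean beyond the first photo), `gap_mean_min` (exponential
#'   mean inter-photo gap, minutes, well under the 20-min window),
#'   `revisit_prob` and `revisit_gap_min` (occasional > 20-min revisits).
#' @param n_grid Number of synthetic prediction-grid cells.
#' @param disturbance_origin Date the time-since-disturbance clock
#'   starts.
#' @param standardize_moth Passed through to the design stage.
#' @return Object of class `"occu_scenario"`.
#' @export
scenario <- function(label = "default",
                     n_sites = 120,
                     n_periods = 8,
                     n_occasions = 12,
                     occasion_length = 7,
                     first_season = "S2019",
                     site_counts = NULL,
                     beta_psi1 = c(0.3, -0.5, 0.7, 0.4),
                     beta_p = c(0.0, 0.4, -0.3),
                     beta_gamma = c(-0.8, 0.5, 0.8, -0.4, 0.3,
                                    -0.6, 0.25, 0.5, -0.35, 0.3),
                     beta_epsilon = c(-0.9, -0.4, 0.6, 0.3, -0.5,
                                      0.45, -0.3, 0.35, 0.5, -0.25),
                     sigma_eta = 0.5,
                     covariate_pars = list(zone_meanlog = log(1.5),
                                           zone_sdlog = 0.8,
                                           cover_shape1 = 2.5,
                                           cover_shape2 = 1.3,
                                           road_mean_km = 0.4,
                                           moth_probs = c(0.35, 0.25, 0.20,
                                                          0.12, 0.08),
                                           precip_summer_mean = 18,
                                           precip_summer_sd = 4,
                                           precip_winter_mean = 30,
                                           precip_winter_sd = 10),
                     burst = list(mean_extra_photos = 2.5,
                                  gap_mean_min = 2,
                                  revisit_prob = 0.25,
                                  revisit_gap_min = c(25, 240)),
                     n_grid = 150,
                     disturbance_origin = as.Date("2015-06-01"),
                     standardize_moth = TRUE) {
  sc <- list(label = label, n_sites = as.integer(n_sites),
             n_periods = as.integer(n_periods),
             n_occasions = as.integer(n_occasions),
             occasion_length = occasion_length,
             first_season = first_season,
             site_counts = if (is.null(site_counts))
               rep(as.integer(n_sites), n_periods) else as.integer(site_counts),
             beta_psi1 = beta_psi1, beta_p = beta_p,
             beta_gamma = beta_gamma, beta_epsilon = beta_epsilon,
             sigma_eta = sigma_eta,
             covariate_pars = covariate_pars, burst = burst,
             n_grid = as.integer(n_grid),
             disturbance_origin = as.Date(disturbance_origin),
             standardize_moth = standardize_moth)
  validate_scenario(sc)
  class(sc) <- "occu_scenario"
  sc
}

validate_scenario <- function(sc) {
  stopifnot(sc$n_sites >= 2, sc$n_periods >= 1, sc$n_occasions >= 1,
            length(sc$beta_psi1) == 4, length(sc$beta_p) == 3,
            length(sc$beta_gamma) == 10, length(sc$beta_epsilon) == 10,
            sc$sigma_eta > 0,
            length(sc$site_counts) == sc$n_periods,
            all(sc$site_counts >= 1), all(sc$site_counts <= sc$n_sites))
  ## probabilities implied at covariate means (intercepts) must not be
  ## degenerate, or the scenario carries no recoverable signal
  probs <- expit(c(sc$beta_psi1[1], sc$beta_p[1],
                   sc$beta_gamma[1], sc$beta_epsilon[1]))
  if (any(probs <= 0.01 | probs >= 0.99)) {
    stop("scenario is degenerate: an intercept-implied probability is ",
         "outside (0.01, 0.99)")
  }
  invisible(TRUE)
}

#' Scenario seeded from the published bobcat posterior medians
#'
#' True coefficients are set to the reported bobcat posterior medians
#' where printed (e.g. the colonization season effect 1.63 and the
#' extirpation zone-area effect -1.18); coefficients that were not
#' printed, and all intercepts, are synthetic defaults chosen to keep
#' baseline probabilities moderate. The survey design follows the
#' published schedule: 100 sites in 2019, expanded to 200 and then 240,
#' and back to 100 in the final winter.
#'
#' @return An `"occu_scenario"`.
#' @export
scenario_published <- function() {
  scenario(label = "bobcat-like",
           n_sites = 240, n_periods = 8, n_occasions = 12,
           first_season = "S2019",
           site_counts = c(100L, 100L, 100L, 200L, 240L, 240L, 240L, 100L),
           beta_psi1 = c(-1.4, -0.76, 0, 1.14),
           beta_p = c(-1.2, -0.06, 0),
           beta_gamma = c(-2.0, 0, 1.63, 1.27, 0, -1.07, 0, 0, 1.14, 0),
           beta_epsilon = c(-1.5, 0, 0, 0, -1.18, -0.32, -0.36, 0, 0, 0),
           sigma_eta = 1.0)
}

#' Scenario for parameter-recovery calibration
#'
#' The default survey shape (120 sites, 8 alternating periods, 12 weekly
#' occasions) with moderate standardized-scale coefficients and a
#' detection random-effect scale of 0.5, but with precipitation drawn
#' from the same distribution in both seasons. Real seasonal totals
#' differ systematically between snow and rain, which makes the
#' precipitation column nearly collinear with the season dummy over a
#' handful of transitions; a calibration experiment that wants to check
#' coefficient-level bias needs the two identified separately, so the
#' recovery design balances them (the study-emulating scenarios keep the
#' realistic confounded structure).
#'
#' @return An `"occu_scenario"`.
#' @export
scenario_recovery <- function() {
  sc <- scenario(label = "recovery")
  sc$covariate_pars$precip_summer_mean <- 24
  sc$covariate_pars$precip_summer_sd <- 6
  sc$covariate_pars$precip_winter_mean <- 24
  sc$covariate_pars$precip_winter_sd <- 6
  sc
}

#' Generate covariate tables for a scenario
#'
#' @param sc An `"occu_scenario"`.
#' @param seed Integer seed; (scenario, seed) fully determine the output.
#' @return List with `site_cov`, `season_cov` and `grid` data frames in
#'   the schemas the readers consume.
#' @export
generate_covariates <- function(sc, seed) {
  set.seed(seed)
  cp <- sc$covariate_pars
  draw_sites <- function(n, ids) {
    data.frame(site_id = ids,
               moth = sample(0:4, n, replace = TRUE, prob = cp$moth_probs),
               cover = 100 * stats::rbeta(n, cp$cover_shape1, cp$cover_shape2),
               road_dist = stats::rexp(n, rate = 1 / cp$road_mean_km),
               zone_area = stats::rlnorm(n, cp$zone_meanlog, cp$zone_sdlog),
               stringsAsFactors = FALSE)
  }
  site_cov <- draw_sites(sc$n_sites,
                         sprintf("site%03d", seq_len(sc$n_sites)))
  class(site_cov) <- c("site_covariates", "data.frame")

  periods <- season_labels(sc$first_season, sc$n_periods)
  cls <- season_class(periods)
  precip <- ifelse(cls == "summer",
                   stats::rnorm(sc$n_periods, cp$precip_summer_mean,
                                cp$precip_summer_sd),
                   stats::rnorm(sc$n_periods, cp$precip_winter_mean,
                                cp$precip_winter_sd))
  precip <- pmax(precip, 0.5)
  tsd <- as.numeric(season_start_date(periods) - sc$disturbance_origin) /
    365.25
  season_cov <- data.frame(primary_period = periods, precip = precip,
                           season_class = cls, tsd = tsd,
                           stringsAsFactors = FALSE)
  attr(season_cov, "transition_class") <- encode_transition_season(cls)
  class(season_cov) <- c("season_covariates", "data.frame")

  grid <- draw_sites(sc$n_grid, sprintf("cell%03d", seq_len(sc$n_grid)))
  names(grid)[names(grid) == "site_id"] <- "cell_id"
  grid$high_development_fraction <- stats::rbeta(sc$n_grid, 0.8, 5)
  grid$water <- stats::runif(sc$n_grid) < 0.05
  list(site_cov = site_cov, season_cov = season_cov, grid = grid)
}

#' Deployment table implied by a scenario
#'
#' The first `site_counts[t]` sites are deployed in period t from the
#' nominal season start for `n_occasions * occasion_length` days.
#'
#' @param sc An `"occu_scenario"`.
#' @return A `deployments` data frame.
#' @export
scenario_deployments <- function(sc) {
  periods <- season_labels(sc$first_season, sc$n_periods)
  starts <- season_start_date(periods)
  len <- sc$n_occasions * sc$occasion_length
  rows <- do.call(rbind, lapply(seq_len(sc$n_periods), function(t) {
    ids <- sprintf("site%03d", seq_len(sc$site_counts[t]))
    data.frame(site_id = ids, primary_period = periods[t],
               start = starts[t], end = starts[t] + len,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$site_id, match(rows$primary_period, periods)), ,
               drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("deployments", "data.frame")
  rows
}

#' Simulate the latent occupancy states
#'
#' Draws the site random effects and the latent occupancy chain
#' `z[i, 1] ~ Bernoulli(psi1_i)`, `z[i, t+1] ~ Bernoulli(1 - eps_{i,t})`
#' if occupied and `Bernoulli(gamma_{i,t})` if not, using exactly the
#' linear predictors the model fits (true coefficients live on the
#' standardized scale of these covariates).
#'
#' @param sc An `"occu_scenario"`.
#' @param covariates Output of [generate_covariates()].
#' @param seed Integer seed.
#' @return Object of class `"truth_set"`: true parameters, `z`
#'   (site x period), `eta`, the design blocks, seed and label.
#' @export
simulate_latent <- function(sc, covariates, seed) {
  set.seed(seed + 1L)
  designs <- build_design_blocks(covariates$site_cov, covariates$season_cov,
                                 standardize_moth = sc$standardize_moth)
  n <- sc$n_sites
  Tn <- sc$n_periods
  psi1 <- expit(drop(designs$X_psi1 %*% sc$beta_psi1))
  eta_raw <- stats::rnorm(n)
  eta <- sc$sigma_eta * eta_raw
  p <- expit(drop(designs$X_p %*% sc$beta_p) + eta)
  z <- matrix(0L, n, Tn)
  z[, 1] <- stats::rbinom(n, 1, psi1)
  if (Tn > 1) {
    gam <- matrix(expit(drop(designs$X_gamma %*% sc$beta_gamma)),
                  n, Tn - 1, byrow = TRUE)
    eps <- matrix(expit(drop(designs$X_epsilon %*% sc$beta_epsilon)),
                  n, Tn - 1, byrow = TRUE)
    for (t in seq_len(Tn - 1)) {
      pr <- ifelse(z[, t] == 1L, 1 - eps[, t], gam[, t])
      z[, t + 1] <- stats::rbinom(n, 1, pr)
    }
  }
  structure(list(beta_psi1 = sc$beta_psi1, beta_p = sc$beta_p,
                 beta_gamma = sc$beta_gamma,
                 beta_epsilon = sc$beta_epsilon,
                 sigma_eta = sc$sigma_eta,
                 eta = eta, eta_raw = eta_raw,
                 psi1 = psi1, p = p, z = z,
                 designs = designs, seed = seed, label = sc$label),
            class = "truth_set")
}

#' Simulate detection histories (and optionally photo streams)
#'
#' Occasion-level detections are Bernoulli(p_i) where the site is
#' occupied and 0 where it is not, over the occasions the deployment
#' schedule covers. With `photos = TRUE` every detected occasion is
#' expanded into a clustered photo burst (1 + Poisson photos with short
#' exponential gaps, plus occasional independent revisits more than 20
#' minutes later) attributed randomly to the site's two cameras, so the
#' independence filter and history builder can be exercised end-to-end.
#'
#' @param truth A `"truth_set"` from [simulate_latent()].
#' @param sc The generating `"occu_scenario"`.
#' @param seed Integer seed.
#' @param photos Also emit a photo-record stream. Default FALSE.
#' @param species Species name attached to the records.
#' @return List with `history` (a `detection_history`), `deployments`,
#'   and, when requested, `records` (a `photo_records` data frame).
#' @export
simulate_detections <- function(truth, sc, seed, photos = FALSE,
                                species = sc$label) {
  set.seed(seed + 2L)
  dep <- scenario_deployments(sc)
  periods <- season_labels(sc$first_season, sc$n_periods)
  sites <- sprintf("site%03d", seq_len(sc$n_sites))
  J <- sc$n_occasions
  y <- array(NA_integer_, dim = c(sc$n_sites, sc$n_periods, J),
             dimnames = list(site = sites, period = periods, occasion = NULL))
  cal <- do.call(rbind, lapply(seq_len(nrow(dep)), function(r) {
    occ <- occasion_calendar_one(dep$start[r], dep$end[r], sc$occasion_length)
    data.frame(site_id = dep$site_id[r], period = dep$primary_period[r],
               occasion = seq_len(nrow(occ)), start = occ$start,
               end = occ$end, stringsAsFactors = FALSE)
  }))
  i_idx <- match(cal$site_id, sites)
  t_idx <- match(cal$period, periods)
  p_occ <- truth$p[i_idx] * truth$z[cbind(i_idx, t_idx)]
  y[cbind(i_idx, t_idx, cal$occasion)] <-
    stats::rbinom(nrow(cal), 1, p_occ)
  history <- structure(list(y = y, sites = sites, periods = periods,
                            calendar = cal, species = species,
                            occasion_length = sc$occasion_length),
                       class = "detection_history")
  out <- list(history = history, deployments = dep)
  if (photos) {
    out$records <- expand_photo_bursts(history, sc, species)
  }
  out
}

## Expand detected occasions into clustered photo bursts.
expand_photo_bursts <- function(history, sc, species) {
  bp <- sc$burst
  cal <- history$calendar
  hit <- which(history$y[cbind(match(cal$site_id, history$sites),
                               match(cal$period, history$periods),
                               cal$occasion)] == 1L)
  pieces <- lapply(hit, function(r) {
    occ_start <- as.POSIXct(paste(cal$start[r], "00:00:00"), tz = "UTC")
    occ_end <- as.POSIXct(paste(cal$end[r], "00:00:00"), tz = "UTC")
    ## leave head room so bursts and revisits stay in-occasion
    occ_secs <- as.numeric(occ_end - occ_start, units = "secs")
    head_secs <- min(12 * 3600, 0.5 * occ_secs)
    t0 <- occ_start + stats::runif(1, 0, occ_secs - head_secs)
    visit_starts <- t0
    if (stats::runif(1) < (bp$revisit_prob %||% 0)) {
      gap_min <- stats::runif(1, bp$revisit_gap_min[1], bp$revisit_gap_min[2])
      visit_starts <- c(visit_starts, t0 + 60 * gap_min)
    }
    do.call(rbind, lapply(visit_starts, function(vs) {
      n_photo <- 1 + stats::rpois(1, bp$mean_extra_photos)
      gaps <- stats::rexp(n_photo - 1, rate = 1 / bp$gap_mean_min)
      ## one visit = one independent detection: cap the cluster span well
      ## below the 20-min independence window
      times <- vs + 60 * pmin(cumsum(c(0, gaps)), 18)
      data.frame(site_id = cal$site_id[r],
                 camera_id = paste0(cal$site_id[r], "_cam",
                                    sample(1:2, n_photo, replace = TRUE)),
                 species = species,
                 timestamp = times, stringsAsFactors = FALSE)
    }))
  })
  rec <- do.call(rbind, pieces)
  if (is.null(rec)) {
    rec <- data.frame(site_id = character(), camera_id = character(),
                      species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"))
  }
  rec <- rec[order(rec$site_id, rec$species, rec$timestamp), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("photo_records", "data.frame")
  rec
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: covariates, latent states, detections (and
#' optionally photos) in one call.
#'
#' @inheritParams simulate_detections
#' @param sc An `"occu_scenario"`.
#' @param seed Integer seed driving all three stages.
#' @return List with `site_cov`, `season_cov`, `grid`, `truth`,
#'   `history`, `deployments` and optionally `records`.
#' @export
simulate_dataset <- function(sc, seed, photos = FALSE, species = sc$label) {
  cov <- generate_covariates(sc, seed)
  truth <- simulate_latent(sc, cov, seed)
  det <- simulate_detections(truth, sc, seed, photos = photos,
                             species = species)
  c(cov, list(truth = truth), det)
}

#' Write the latent truth alongside simulated data
#' @param truth A `"truth_set"`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(label = truth$label, seed = truth$seed,
                            beta_psi1 = truth$beta_psi1,
                            beta_p = truth$beta_p,
                            beta_gamma = truth$beta_gamma,
                            beta_epsilon = truth$beta_epsilon,
                            sigma_eta = truth$sigma_eta,
                            eta = truth$eta, z = truth$z),
                       path, digits = NA)
  invisible(path)
}
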