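## Covariate standardization and design-matrix assembly.
##
## Column orders are frozen so coefficient indices line up with the
## ten-term colonization/extirpation linear predictor:
##   gamma/epsilon: (Intercept), precip, season, precip:season, zone_area,
##                  cover, zone_area:cover, moth, tsd, moth:tsd
##   psi1:          (Intercept), moth, cover, road_dist
##   p:             (Intercept), cover, zone_area

#' Inverse-logit and logit
#' @param x Numeric vector (for `expit`, any reals; for `logit`,
#'   probabilities in (0,1)).
#' @return Numeric vector.
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' @rdname expit
#' @export
logit <- function(x) log(x / (1 - x))

#' Mean-center and scale a covariate
#'
#' Standardizes to mean 0, sd 1 using the sample standard deviation
#' (n - 1 denominator). When a stored spec is supplied (prediction time),
#' its mean/sd are reused so prediction grids are transformed exactly as
#' the fit data were.
#'
#' @param values Numeric vector.
#' @param spec Optional list with `mean` and `sd` from a previous call.
#' @return List with `values` (transformed vector) and `spec`.
#' @export
standardize <- function(values, spec = NULL) {
  if (is.null(spec)) {
    if (length(unique(values)) < 2) {
      stop("cannot standardize a covariate with zero variance")
    }
    spec <- list(mean = mean(values), sd = stats::sd(values))
  }
  if (spec$sd <= 0) stop("standardization spec has sd <= 0")
  list(values = (values - spec$mean) / spec$sd, spec = spec)
}

#' Encode transition seasons as dummy codes
#'
#' Transitions between consecutive primary periods are summer-to-winter
#' (autumn) or winter-to-summer (spring), dummy coded 0 and 1
#' respectively: the code is 0 when the *origin* period is a summer.
#'
#' @param season_classes Character vector of per-period classes
#'   (`"summer"`/`"winter"`), or period labels accepted by
#'   [season_class()].
#' @return Integer vector of length T-1 in {0, 1} (empty for T = 1).
#' @export
encode_transition_season <- function(season_classes) {
  cls <- season_classes
  if (!all(cls %in% c("summer", "winter"))) cls <- season_class(cls)
  n <- length(cls)
  if (n <= 1) return(integer(0))
  if (any(cls[-1] == cls[-n])) {
    stop("season classes must alternate to encode transitions")
  }
  ifelse(cls[-n] == "summer", 0L, 1L)
}

#' Build (or reuse) the standardization store for all continuous covariates
#'
#' Site covariates are standardized over the modeled sites; precipitation
#' and time-since-disturbance over the period values that enter the
#' transition design (periods 1..T-1). The store is persisted with a fit
#' so prediction reuses the fit-time transform.
#'
#' @param site_cov `site_covariates`.
#' @param season_cov `season_covariates`.
#' @param standardize_moth Standardize the ordinal moth score like the
#'   other continuous covariates (default TRUE) or leave it on its raw 0-4
#'   scale.
#' @return Named list of specs (class `"std_store"`).
#' @export
standardization_store <- function(site_cov, season_cov,
                                  standardize_moth = TRUE) {
  tcur <- seq_len(max(nrow(season_cov) - 1, 1))
  ## period covariates: standardize over the origin-period values the
  ## transition design consumes; with fewer than two distinct transition
  ## values, fall back to the full period sequence
  period_spec <- function(v) {
    if (length(unique(v[tcur])) >= 2) standardize(v[tcur])$spec
    else standardize(v)$spec
  }
  store <- list(
    moth = if (standardize_moth) standardize(site_cov$moth)$spec else
      list(mean = 0, sd = 1),
    cover = standardize(site_cov$cover)$spec,
    road_dist = standardize(site_cov$road_dist)$spec,
    zone_area = standardize(site_cov$zone_area)$spec,
    precip = period_spec(season_cov$precip),
    tsd = period_spec(season_cov$tsd))
  store$standardize_moth <- standardize_moth
  class(store) <- "std_store"
  store
}

std_apply <- function(store, name, values) {
  standardize(values, store[[name]])$values
}

#' Assemble the design blocks for all four submodels
#'
#' Initial occupancy and detection designs are site-level; colonization
#' and extirpation designs have one row per (site, transition), ordered by
#' site then transition. The precipitation and time-since-disturbance
#' covariates of transition t -> t+1 are those of the origin period t, so
#' autumn transitions carry the preceding summer's rain and spring
#' transitions the preceding winter's snow. Interaction columns are
#' elementwise products of the standardized main-effect columns.
#'
#' @param site_cov `site_covariates`.
#' @param season_cov `season_covariates`.
#' @param store Standardization store from [standardization_store()];
#'   built fresh (fit time) when NULL.
#' @param standardize_moth Passed to [standardization_store()] when the
#'   store is built here.
#' @return Object of class `"design_blocks"`: list with matrices `X_psi1`
#'   (n x 4), `X_p` (n x 3), `X_gamma` and `X_epsilon` (n(T-1) x 10), the
#'   row index map `transition_index`, `store`, `periods`,
#'   `season_classes` and `transition_class`.
#' @export
build_design_blocks <- function(site_cov, season_cov, store = NULL,
                                standardize_moth = TRUE) {
  if (is.null(store)) {
    store <- standardization_store(site_cov, season_cov, standardize_moth)
  }
  n <- nrow(site_cov)
  Tn <- nrow(season_cov)
  moth <- std_apply(store, "moth", site_cov$moth)
  cover <- std_apply(store, "cover", site_cov$cover)
  road <- std_apply(store, "road_dist", site_cov$road_dist)
  zone <- std_apply(store, "zone_area", site_cov$zone_area)

  X_psi1 <- cbind("(Intercept)" = 1, moth = moth, cover = cover,
                  road_dist = road)
  X_p <- cbind("(Intercept)" = 1, cover = cover, zone_area = zone)

  if (Tn > 1) {
    trans <- seq_len(Tn - 1)
    precip <- std_apply(store, "precip", season_cov$precip[trans])
    tsd <- std_apply(store, "tsd", season_cov$tsd[trans])
    season <- encode_transition_season(season_cov$season_class)
    ## site-major row order: site 1 transitions 1..T-1, then site 2, ...
    i_idx <- rep(seq_len(n), each = Tn - 1)
    t_idx <- rep(trans, times = n)
    X_trans <- cbind("(Intercept)" = 1,
                     precip = precip[t_idx],
                     season = as.numeric(season[t_idx]),
                     "precip:season" = precip[t_idx] * season[t_idx],
                     zone_area = zone[i_idx],
                     cover = cover[i_idx],
                     "zone_area:cover" = zone[i_idx] * cover[i_idx],
                     moth = moth[i_idx],
                     tsd = tsd[t_idx],
                     "moth:tsd" = moth[i_idx] * tsd[t_idx])
    transition_index <- data.frame(site_id = site_cov$site_id[i_idx],
                                   from = season_cov$primary_period[t_idx],
                                   to = season_cov$primary_period[t_idx + 1],
                                   transition = t_idx,
                                   stringsAsFactors = FALSE)
    transition_class <- season
  } else {
    X_trans <- matrix(numeric(0), nrow = 0, ncol = 10)
    transition_index <- data.frame(site_id = character(), from = character(),
                                   to = character(), transition = integer())
    transition_class <- integer(0)
  }
  rownames(X_psi1) <- rownames(X_p) <- site_cov$site_id
  structure(list(X_psi1 = X_psi1, X_p = X_p,
                 X_gamma = X_trans, X_epsilon = X_trans,
                 transition_index = transition_index,
                 sites = site_cov$site_id,
                 periods = season_cov$primary_period,
                 season_classes = season_cov$season_class,
                 transition_class = transition_class,
                 season_cov = as.data.frame(season_cov),
                 store = store),
            class = "design_blocks")
}

#' Linear predictor
#' @param X Design matrix.
#' @param beta Coefficient vector, `length(beta) == ncol(X)`.
#' @return Numeric vector `X %*% beta`.
#' @export
linear_predictor <- function(X, beta) {
  if (ncol(X) != length(beta)) {
    stop("shape mismatch: ", ncol(X), " columns vs ", length(beta),
         " coefficients")
  }
  drop(X %*% beta)
}
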