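#' Run configuration
#'
#' Builds and validates the configuration object shared by all pipeline
#' stages. All analysis constants live here: the photo independence window,
#' the secondary-occasion length, MCMC settings, prior scales, and the
#' posterior-probability thresholds used to grade coefficient support.
#'
#' @param species Character vector of species to analyse.
#' @param independence_window Minutes that must elapse between photos of the
#'   same species at the same site for the later photo to count as an
#'   independent detection. Default 20.
#' @param occasion_length Length of one secondary occasion in days.
#'   Default 7 (weekly occasions).
#' @param mcmc List with elements `chains` (>= 2), `warmup`, `draws`
#'   (both per chain) and `seed`.
#' @param disturbance_origin Date of the disturbance event from which
#'   time-since-disturbance is measured.
#' @param priors List with `beta_scale` (normal sd on standardized-scale
#'   coefficients) and `sigma_eta_scale` (half-normal sd on the site
#'   random-effect scale).
#' @param support_thresholds List with `strong` and `moderate` posterior
#'   probabilities, both in (0.5, 1).
#' @param trap_night_basis `"camera"` (default; two paired cameras per
#'   site) or `"site"` for effort accounting.
#' @param cameras_per_site Number of cameras deployed per site. Default 2.
#' @param standardize_moth Whether the ordinal moth-damage score (0-4) is
#'   standardized like the other continuous covariates (default) or used raw.
#' @return A list of class `"occu_config"`.
#' @export
run_config <- function(species = "bobcat",
                       independence_window = 20,
                       occasion_length = 7,
                       mcmc = list(chains = 3, warmup = 2500, draws = 5000,
                                   seed = 1L),
                       disturbance_origin = as.Date("2015-06-01"),
                       priors = list(beta_scale = 2.5, sigma_eta_scale = 1),
                       support_thresholds = list(strong = 0.90, moderate = 0.70),
                       trap_night_basis = c("camera", "site"),
                       cameras_per_site = 2L,
                       standardize_moth = TRUE) {
  trap_night_basis <- match.arg(trap_night_basis)
  cfg <- list(species = as.character(species),
              independence_window = independence_window,
              occasion_length = occasion_length,
              mcmc = mcmc,
              disturbance_origin = as.Date(disturbance_origin),
              priors = priors,
              support_thresholds = support_thresholds,
              trap_night_basis = trap_night_basis,
              cameras_per_site = as.integer(cameras_per_site),
              standardize_moth = isTRUE(standardize_moth))
  validate_config(cfg)
  class(cfg) <- "occu_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$species) >= 1,
            cfg$independence_window > 0,
            cfg$occasion_length >= 1)
  m <- cfg$mcmc
  if (is.null(m$chains) || m$chains < 2) stop("mcmc$chains must be >= 2")
  if (is.null(m$warmup) || m$warmup <= 0) stop("mcmc$warmup must be > 0")
  if (is.null(m$draws) || m$draws <= 0) stop("mcmc$draws must be > 0")
  th <- cfg$support_thresholds
  if (any(c(th$strong, th$moderate) <= 0.5) ||
      any(c(th$strong, th$moderate) >= 1)) {
    stop("support thresholds must lie in (0.5, 1)")
  }
  if (th$moderate > th$strong) stop("moderate threshold cannot exceed strong")
  invisible(TRUE)
}

#' Read a run configuration from a YAML or JSON file
#'
#' Scalar fields override the defaults of [run_config()]; anything not
#' present in the file keeps its default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return An `"occu_config"` object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- formals(run_config)
  args <- list()
  for (nm in names(raw)) {
    if (!nm %in% names(defaults)) stop("unknown configuration field: ", nm)
    args[[nm]] <- raw[[nm]]
  }
  do.call(run_config, args)
}
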