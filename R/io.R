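## Validated CSV ingestion/emission for the four input tables.
## All timestamps are parsed as naive local time in a single study time
## zone (stored as UTC internally); DST is deliberately ignored.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

parse_timestamps <- function(x, what = "timestamp") {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                   origin = "1970-01-01")
  for (f in fmts) {
    idx <- which(is.na(ts))
    if (!length(idx)) break
    ts[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  bad <- which(is.na(ts) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop("malformed ", what, " in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  ts
}

#' Read photo-detection records
#'
#' Reads a CSV of timestamped species photos (one row per photo). Rows
#' whose species is not in `species_list` are dropped with a logged count.
#' The result is sorted by (site, species, timestamp), the order the
#' independence filter expects.
#'
#' @param path CSV file with header columns `site_id`, `camera_id`,
#'   `species`, `timestamp` (ISO-8601).
#' @param species_list Character vector of species to retain.
#' @return A data frame of class `"photo_records"` with columns `site_id`,
#'   `camera_id`, `species` and `timestamp` (POSIXct).
#' @export
read_photo_records <- function(path, species_list) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("site_id", "camera_id", "species", "timestamp"),
                  "photo records")
  if (nrow(df) == 0) {
    out <- data.frame(site_id = character(), camera_id = character(),
                      species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"))
    class(out) <- c("photo_records", "data.frame")
    return(out)
  }
  if (any(!nzchar(df$species))) stop("empty species field in photo records")
  ts <- parse_timestamps(df$timestamp)
  keep <- df$species %in% species_list
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("read_photo_records: dropped ", n_drop,
            " row(s) with species outside the configured list")
  }
  out <- data.frame(site_id = df$site_id[keep], camera_id = df$camera_id[keep],
                    species = df$species[keep], timestamp = ts[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_id, out$species, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("photo_records", "data.frame")
  out
}

#' Read camera deployment windows
#'
#' One row per (site, primary period) deployment window. Overlapping
#' windows for the same site and period are merged into their spanning
#' union. Periods are validated against an ordered season vocabulary when
#' one is supplied.
#'
#' @param path CSV with columns `site_id`, `primary_period`, `start`, `end`
#'   (ISO dates).
#' @param season_levels Optional ordered character vector of valid period
#'   labels (see [season_labels()]).
#' @return A data frame of class `"deployments"` sorted by site and period.
#' @export
read_deployments <- function(path, season_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("site_id", "primary_period", "start", "end"),
                  "deployments")
  start <- as.Date(df$start)
  end <- as.Date(df$end)
  if (anyNA(start) || anyNA(end)) {
    stop("malformed date in deployments row(s): ",
         paste(which(is.na(start) | is.na(end)), collapse = ", "))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("deployment end <= start in row(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(season_levels)) {
    unknown <- setdiff(unique(df$primary_period), season_levels)
    if (length(unknown)) {
      stop("unknown primary period(s): ", paste(unknown, collapse = ", "))
    }
  }
  dep <- data.frame(site_id = df$site_id, primary_period = df$primary_period,
                    start = start, end = end, stringsAsFactors = FALSE)
  dep <- merge_deployment_windows(dep)
  if (!is.null(season_levels)) {
    ord <- order(dep$site_id, match(dep$primary_period, season_levels),
                 dep$start)
  } else {
    ord <- order(dep$site_id, dep$primary_period, dep$start)
  }
  dep <- dep[ord, , drop = FALSE]
  rownames(dep) <- NULL
  class(dep) <- c("deployments", "data.frame")
  dep
}

## Union of overlapping/touching windows within each (site, period).
merge_deployment_windows <- function(dep) {
  key <- paste(dep$site_id, dep$primary_period, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(dep)), key), function(idx) {
    d <- dep[idx[order(dep$start[idx])], , drop = FALSE]
    out <- d[1, , drop = FALSE]
    if (nrow(d) > 1) {
      for (k in 2:nrow(d)) {
        last <- nrow(out)
        if (d$start[k] <= out$end[last]) {
          out$end[last] <- max(out$end[last], d$end[k])
        } else {
          out <- rbind(out, d[k, , drop = FALSE])
        }
      }
    }
    out
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Read the site covariate table
#'
#' @param path CSV with columns `site_id`, `moth` (ordinal damage severity,
#'   integer 0-4), `cover` (percent, 0-100), `road_dist` (km, >= 0),
#'   `zone_area` (km^2, > 0).
#' @return Data frame of class `"site_covariates"`.
#' @export
read_site_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("site_id", "moth", "cover", "road_dist", "zone_area"),
                  "site covariates")
  validate_site_covariates(df)
  df$site_id <- as.character(df$site_id)
  df <- df[order(df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("site_covariates", "data.frame")
  df
}

validate_site_covariates <- function(df) {
  num <- c("moth", "cover", "road_dist", "zone_area")
  if (anyNA(df[num])) stop("missing values in site covariates")
  if (any(df$moth != as.integer(df$moth)) || any(df$moth < 0 | df$moth > 4)) {
    stop("moth damage must be an integer severity score in 0..4")
  }
  if (any(df$cover < 0 | df$cover > 100)) stop("cover must be in [0, 100]")
  if (any(df$road_dist < 0)) stop("road_dist must be >= 0")
  if (any(df$zone_area <= 0)) stop("zone_area must be > 0")
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in site covariates")
  invisible(TRUE)
}

#' Read the season covariate table
#'
#' One row per primary period, in temporal order. `precip` is the seasonal
#' precipitation total in inches (rain in summer, snow in winter); `tsd` is
#' decimal years since the disturbance origin. Season classes must
#' alternate and `tsd` must be strictly increasing.
#'
#' @param path CSV with columns `primary_period`, `precip`, `season_class`
#'   (`summer`/`winter`), `tsd`.
#' @return Data frame of class `"season_covariates"` in period order, with
#'   derived transition classes attached as attribute `"transition_class"`
#'   (0 = autumn, 1 = spring; length T-1).
#' @export
read_season_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("primary_period", "precip", "season_class", "tsd"),
                  "season covariates")
  df$primary_period <- as.character(df$primary_period)
  validate_season_covariates(df)
  rownames(df) <- NULL
  attr(df, "transition_class") <- encode_transition_season(df$season_class)
  class(df) <- c("season_covariates", "data.frame")
  df
}

validate_season_covariates <- function(df) {
  if (anyNA(df[c("precip", "tsd")])) stop("missing values in season covariates")
  if (!all(df$season_class %in% c("summer", "winter"))) {
    stop("season_class must be 'summer' or 'winter'")
  }
  n <- nrow(df)
  if (n > 1) {
    if (any(df$season_class[-1] == df$season_class[-n])) {
      stop("season classes must alternate along the period sequence")
    }
    if (any(diff(df$tsd) <= 0)) stop("tsd must be strictly increasing")
  }
  if (any(df$precip < 0)) stop("precip must be >= 0")
  invisible(TRUE)
}

#' Cross-validate the four loaded inputs
#'
#' Produces a validation report rather than throwing: photos falling
#' outside every deployment window for their site are listed (non-fatal;
#' they are ignored downstream with a warning), while sites present in the
#' photo stream or deployments but absent from the covariate table, and
#' deployed periods missing season covariates, are fatal.
#'
#' @param records `photo_records`.
#' @param deployments `deployments`.
#' @param site_cov `site_covariates`.
#' @param season_cov `season_covariates`.
#' @return List of class `"validation_report"` with elements `fatal`
#'   (character), `flagged` (character) and `outside_records` (integer row
#'   indices into `records`).
#' @export
validate_inputs <- function(records, deployments, site_cov, season_cov) {
  fatal <- character()
  flagged <- character()

  dep_sites <- unique(deployments$site_id)
  miss_site_cov <- setdiff(union(unique(records$site_id), dep_sites),
                           site_cov$site_id)
  if (length(miss_site_cov)) {
    fatal <- c(fatal, paste0("site(s) lacking covariates: ",
                             paste(miss_site_cov, collapse = ", ")))
  }
  miss_period <- setdiff(unique(deployments$primary_period),
                         season_cov$primary_period)
  if (length(miss_period)) {
    fatal <- c(fatal, paste0("period(s) lacking season covariates: ",
                             paste(miss_period, collapse = ", ")))
  }

  outside <- integer()
  if (nrow(records) > 0) {
    rec_date <- as.Date(records$timestamp)
    for (k in seq_len(nrow(records))) {
      dep <- deployments[deployments$site_id == records$site_id[k], ,
                         drop = FALSE]
      if (nrow(dep) == 0 ||
          !any(rec_date[k] >= dep$start & rec_date[k] < dep$end)) {
        outside <- c(outside, k)
      }
    }
    if (length(outside)) {
      flagged <- c(flagged, paste0(length(outside),
                                   " photo record(s) outside every deployment",
                                   " window for their site"))
    }
  }

  structure(list(fatal = fatal, flagged = flagged,
                 outside_records = outside),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$fatal) == 0 && length(x$flagged) == 0) {
    cat("validation: clean\n")
  } else {
    for (f in x$fatal) cat("FATAL:", f, "\n")
    for (f in x$flagged) cat("flag:", f, "\n")
  }
  invisible(x)
}

#' Does a validation report contain fatal items?
#' @param report A `"validation_report"`.
#' @return Logical.
#' @export
has_fatal <- function(report) length(report$fatal) > 0

#' Write a table as RFC-4180 CSV (UTF-8, header row)
#'
#' Deterministic emission used by all pipeline stages: reals are written
#' with 15 significant digits so a write/read round trip preserves them to
#' at least 12 significant digits.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (inherits(df[[nm]], "POSIXct")) {
      out[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    } else if (inherits(df[[nm]], "Date")) {
      out[[nm]] <- format(df[[nm]], "%Y-%m-%d")
    } else if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
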