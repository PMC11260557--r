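## Photo stream -> independent detections -> detection-history arrays.

#' Filter photos to independent detection events
#'
#' Greedy left-to-right scan per (site, species), pooling both cameras at
#' a site: a photo is kept if and only if at least `window` minutes have
#' elapsed since the last *kept* photo of that species at that site. The
#' boundary is inclusive ("at least"), so two photos exactly `window`
#' minutes apart are both kept.
#'
#' @param records A `photo_records` data frame (sorted by site, species,
#'   timestamp; [read_photo_records()] guarantees this).
#' @param window Independence window in minutes (> 0). Default 20.
#' @return Data frame of class `"detection_events"` with columns `site_id`,
#'   `species`, `timestamp` (first photo of each independent cluster), and
#'   attribute `"species_counts"` (named integer vector).
#' @export
filter_independent <- function(records, window = 20) {
  stopifnot(window > 0)
  if (nrow(records) == 0) {
    out <- records[, c("site_id", "species", "timestamp"), drop = FALSE]
    class(out) <- c("detection_events", "data.frame")
    attr(out, "species_counts") <- integer(0)
    attr(out, "window") <- window
    return(out)
  }
  ord <- order(records$site_id, records$species, records$timestamp)
  rec <- records[ord, , drop = FALSE]
  key <- paste(rec$site_id, rec$species, sep = "\r")
  keep <- logical(nrow(rec))
  t_num <- as.numeric(rec$timestamp) / 60  # minutes
  last_kept <- -Inf
  last_key <- ""
  for (k in seq_len(nrow(rec))) {
    if (key[k] != last_key) {
      last_key <- key[k]
      last_kept <- -Inf
    }
    if (t_num[k] - last_kept >= window) {
      keep[k] <- TRUE
      last_kept <- t_num[k]
    }
  }
  out <- rec[keep, c("site_id", "species", "timestamp"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detection_events", "data.frame")
  counts <- table(out$species)
  attr(out, "species_counts") <- stats::setNames(as.integer(counts),
                                                 names(counts))
  attr(out, "window") <- window
  out
}

## Tile one deployment window [start, end) into occasions of
## `len` days; a trailing partial occasion shorter than len/2 is dropped,
## otherwise kept (truncated at the window end).
occasion_calendar_one <- function(start, end, len) {
  n_days <- as.numeric(end - start)
  n_full <- floor(n_days / len)
  rem <- n_days - n_full * len
  starts <- start + len * seq_len(n_full) - len
  ends <- starts + len
  if (rem >= len / 2) {
    starts <- c(starts, start + n_full * len)
    ends <- c(ends, end)
  }
  data.frame(start = starts, end = ends)
}

#' Build the detection-history array for one species
#'
#' Each (site, period) deployment window is tiled into consecutive
#' occasions of `occasion_length` days starting at the window start; a
#' trailing partial occasion shorter than half the occasion length is
#' dropped, otherwise kept. `y[i, t, j] = 1` if at least one independent
#' detection event of the target species falls in occasion j of period t
#' at site i, 0 if the occasion was surveyed without a detection, and `NA`
#' where no deployment covers the occasion (including entire periods in
#' which the site was not deployed).
#'
#' @param events `detection_events` (already filtered for independence).
#' @param deployments `deployments` table.
#' @param occasion_length Occasion length in days (>= 1). Default 7.
#' @param species Target species; defaults to the single species present
#'   in `events`.
#' @param season_levels Ordered period vocabulary; defaults to the sorted
#'   unique periods in `deployments`.
#' @return Object of class `"detection_history"`: list with the 3-d array
#'   `y` (site x period x occasion), `sites`, `periods`, and the occasion
#'   `calendar` (long data frame).
#' @export
build_history <- function(events, deployments, occasion_length = 7,
                          species = NULL, season_levels = NULL) {
  stopifnot(occasion_length >= 1)
  if (is.null(species)) {
    sp <- unique(events$species)
    if (length(sp) > 1) stop("events contain multiple species; pass `species`")
    species <- if (length(sp)) sp else NA_character_
  }
  ev <- events[!is.na(species) & events$species == species, , drop = FALSE]
  if (is.null(season_levels)) {
    season_levels <- sort(unique(deployments$primary_period))
  }
  sites <- sort(unique(deployments$site_id))
  periods <- season_levels

  cal <- do.call(rbind, lapply(seq_len(nrow(deployments)), function(r) {
    occ <- occasion_calendar_one(deployments$start[r], deployments$end[r],
                                 occasion_length)
    if (nrow(occ) == 0) return(NULL)
    data.frame(site_id = deployments$site_id[r],
               period = deployments$primary_period[r],
               occasion = seq_len(nrow(occ)),
               start = occ$start, end = occ$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cal)) stop("no occasions could be built from the deployments")
  ## Several disjoint windows in one (site, period) get sequential indices.
  key <- paste(cal$site_id, cal$period, sep = "\r")
  cal <- cal[order(cal$site_id, match(cal$period, periods), cal$start), ,
             drop = FALSE]
  key <- paste(cal$site_id, cal$period, sep = "\r")
  cal$occasion <- stats::ave(seq_along(key), key, FUN = seq_along)

  J <- max(cal$occasion)
  y <- array(NA_integer_, dim = c(length(sites), length(periods), J),
             dimnames = list(site = sites, period = periods, occasion = NULL))
  i_idx <- match(cal$site_id, sites)
  t_idx <- match(cal$period, periods)
  y[cbind(i_idx, t_idx, cal$occasion)] <- 0L

  if (nrow(ev) > 0) {
    ev_date <- as.Date(ev$timestamp)
    unmatched <- 0L
    for (k in seq_len(nrow(ev))) {
      rows <- which(cal$site_id == ev$site_id[k] &
                      ev_date[k] >= cal$start & ev_date[k] < cal$end)
      if (length(rows) == 0) {
        unmatched <- unmatched + 1L
        next
      }
      r <- rows[1]
      y[match(cal$site_id[r], sites), match(cal$period[r], periods),
        cal$occasion[r]] <- 1L
    }
    if (unmatched > 0) {
      warning(unmatched, " detection event(s) outside all deployment windows",
              " were ignored")
    }
  }

  structure(list(y = y, sites = sites, periods = periods, calendar = cal,
                 species = species, occasion_length = occasion_length),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat("detection history:", length(x$sites), "sites x", length(x$periods),
      "periods x", dim(x$y)[3], "occasions (", x$species, ")\n")
  cat("  detections:", sum(x$y == 1, na.rm = TRUE), " surveyed occasions:",
      sum(!is.na(x$y)), "\n")
  invisible(x)
}

#' Naive occupancy by primary period
#'
#' The raw proportion of surveyed sites (>= 1 non-missing occasion in the
#' period) with at least one detection in the period, uncorrected for
#' imperfect detection. Values are not rounded; round to 2 decimals only
#' at reporting time.
#'
#' @param history A `detection_history`.
#' @return Named numeric vector over periods; `NA` (with a warning) for
#'   periods with zero surveyed sites.
#' @export
naive_occupancy <- function(history) {
  y <- history$y
  out <- vapply(seq_along(history$periods), function(t) {
    slice <- y[, t, , drop = FALSE]
    surveyed <- apply(!is.na(slice), 1, any)
    if (!any(surveyed)) return(NA_real_)
    detected <- apply(slice == 1, 1, any, na.rm = TRUE) & surveyed
    sum(detected) / sum(surveyed)
  }, numeric(1))
  names(out) <- history$periods
  if (anyNA(out)) {
    warning("period(s) with zero surveyed sites: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Total trap nights
#'
#' Sum over deployments of whole nights between start and end, on a
#' camera-night basis by default (each site carries paired cameras) or a
#' site-night basis.
#'
#' @param deployments `deployments` table.
#' @param basis `"camera"` (default) or `"site"`.
#' @param cameras_per_site Cameras per site for the camera basis. Default 2.
#' @return Integer total.
#' @export
trap_nights <- function(deployments, basis = c("camera", "site"),
                        cameras_per_site = 2L) {
  basis <- match.arg(basis)
  nights <- sum(as.numeric(deployments$end - deployments$start))
  mult <- if (basis == "camera") cameras_per_site else 1L
  as.integer(round(nights * mult))
}

#' Serialize a detection history as long-format CSV plus calendar sidecar
#'
#' @param history A `detection_history`.
#' @param path Output CSV path (columns `site_id`, `period`, `occasion`,
#'   `y`); the occasion calendar is written as JSON next to it
#'   (`<path>.calendar.json`).
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  idx <- which(!is.na(history$y), arr.ind = TRUE)
  long <- data.frame(site_id = history$sites[idx[, 1]],
                     period = history$periods[idx[, 2]],
                     occasion = idx[, 3],
                     y = history$y[idx])
  long <- long[order(long$site_id, match(long$period, history$periods),
                     long$occasion), , drop = FALSE]
  write_table_csv(long, path)
  cal <- history$calendar
  cal$start <- as.character(cal$start)
  cal$end <- as.character(cal$end)
  jsonlite::write_json(list(species = history$species,
                            occasion_length = history$occasion_length,
                            periods = history$periods,
                            calendar = cal),
                       paste0(path, ".calendar.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a serialized detection history
#' @param path CSV path written by [write_history()].
#' @return A `detection_history`.
#' @export
read_history <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".calendar.json"),
                              simplifyVector = TRUE)
  sites <- sort(unique(side$calendar$site_id))
  periods <- side$periods
  J <- max(long$occasion)
  y <- array(NA_integer_, dim = c(length(sites), length(periods), J),
             dimnames = list(site = sites, period = periods, occasion = NULL))
  y[cbind(match(long$site_id, sites), match(long$period, periods),
          long$occasion)] <- long$y
  cal <- side$calendar
  cal$start <- as.Date(cal$start)
  cal$end <- as.Date(cal$end)
  structure(list(y = y, sites = sites, periods = periods, calendar = cal,
                 species = side$species,
                 occasion_length = side$occasion_length),
            class = "detection_history")
}
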