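#' Generate the ordered vocabulary of primary-period (season) labels
#'
#' Primary periods are alternating summer ("S") and winter ("W") field
#' seasons labelled by year, e.g. `S2019, W2020, S2020, ...`. A winter
#' season spans the year boundary and is labelled by the calendar year in
#' which it ends, so the season after `S2019` is `W2020` and the season
#' after `W2020` is `S2020`. Labels are generated from a first season and
#' a count rather than parsed from free text, so the ordering is never
#' ambiguous.
#'
#' @param first First season label, e.g. `"S2019"`.
#' @param n Number of primary periods.
#' @return Character vector of `n` ordered season labels.
#' @examples
#' season_labels("S2019", 8)
#' @export
season_labels <- function(first, n) {
  stopifnot(is.character(first), length(first) == 1, n >= 1)
  if (!grepl("^[SW][0-9]{4}$", first)) {
    stop("season label must look like 'S2019' or 'W2020', got: ", first)
  }
  cls <- substr(first, 1, 1)
  yr <- as.integer(substr(first, 2, 5))
  out <- character(n)
  for (k in seq_len(n)) {
    out[k] <- paste0(cls, yr)
    if (cls == "S") {
      cls <- "W"
      yr <- yr + 1L
    } else {
      cls <- "S"
    }
  }
  out
}

#' Season class (summer/winter) of period labels
#'
#' @param periods Character vector of season labels (see [season_labels()]).
#' @return Character vector, `"summer"` or `"winter"`.
#' @export
season_class <- function(periods) {
  cls <- substr(as.character(periods), 1, 1)
  bad <- !cls %in% c("S", "W")
  if (any(bad)) stop("unrecognized season labels: ",
                     paste(unique(periods[bad]), collapse = ", "))
  ifelse(cls == "S", "summer", "winter")
}

#' Nominal start date of a primary period
#'
#' Summer seasons start June 1 of their label year; winter seasons start
#' December 1 of the preceding calendar year (a winter labelled `W2020`
#' runs from late 2019 into 2020). Used by the synthetic-data generator;
#' real deployments carry their own dates.
#'
#' @param periods Character vector of season labels.
#' @return Vector of `Date`s.
#' @export
season_start_date <- function(periods) {
  cls <- season_class(periods)
  yr <- as.integer(substr(as.character(periods), 2, 5))
  as.Date(ifelse(cls == "summer",
                 sprintf("%d-06-01", yr),
                 sprintf("%d-12-01", yr - 1L)))
}

check_alternating <- function(periods) {
  cls <- season_class(periods)
  if (length(cls) > 1 && any(cls[-1] == cls[-length(cls)])) {
    stop("season classes must alternate summer/winter along the period sequence")
  }
  invisible(TRUE)
}
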