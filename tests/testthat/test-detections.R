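make_records <- function(minutes, site = "A", species = "coyote") {
  base <- as.POSIXct("2019-07-01 00:00:00", tz = "UTC")
  n <- length(minutes)
  df <- data.frame(site_id = rep(site, n),
                   camera_id = rep(paste0(site, "_cam1"), n),
                   species = rep(species, n), timestamp = base + 60 * minutes,
                   stringsAsFactors = FALSE)
  class(df) <- c("photo_records", "data.frame")
  df
}

test_that("independence filter keeps photos by the greedy since-last-kept rule", {
  expect_equal(nrow(filter_independent(make_records(0), 20)), 1)

  ev <- filter_independent(make_records(c(0, 10, 25, 50)), 20)
  base <- as.POSIXct("2019-07-01 00:00:00", tz = "UTC")
  expect_equal(ev$timestamp, base + 60 * c(0, 25, 50))

  # "at least 20 min": the boundary photo is kept
  expect_equal(nrow(filter_independent(make_records(c(0, 20)), 20)), 2)

  # cameras at a site are pooled before filtering
  rec <- make_records(c(0, 5))
  rec$camera_id <- c("A_cam1", "A_cam2")
  expect_equal(nrow(filter_independent(rec, 20)), 1)

  # sites and species are filtered independently
  rec2 <- rbind(make_records(c(0, 5)), make_records(c(0, 5), site = "B"),
                make_records(c(2, 7), species = "fisher"))
  expect_equal(nrow(filter_independent(rec2, 20)), 3)
})

test_that("independence filter is idempotent and monotone in the window", {
  set.seed(42)
  for (rep in 1:20) {
    mins <- sort(stats::runif(30, 0, 600))
    rec <- make_records(mins)
    ev <- filter_independent(rec, 20)
    ev_rec <- ev
    ev_rec$camera_id <- "A_cam1"
    again <- filter_independent(ev_rec, 20)
    expect_equal(again$timestamp, ev$timestamp)
    n_prev <- Inf
    for (w in c(5, 20, 60, 180)) {
      n_w <- nrow(filter_independent(rec, w))
      expect_lte(n_w, n_prev)
      n_prev <- n_w
    }
  }
})

test_that("deployment windows are tiled into weekly occasions", {
  dep <- data.frame(site_id = "A", primary_period = "S2019",
                    start = as.Date("2019-06-10"),
                    end = as.Date("2019-06-10") + 84,
                    stringsAsFactors = FALSE)
  class(dep) <- c("deployments", "data.frame")
  h <- build_history(make_records(numeric(0))[0, c(1, 3, 4)], dep,
                     occasion_length = 7, species = "coyote",
                     season_levels = "S2019")
  expect_equal(dim(h$y)[3], 12)  # 84-day deployment -> 12 weekly occasions
  expect_true(all(h$y == 0))

  # trailing partials: >= half an occasion is kept, shorter is dropped
  dep$end <- dep$start + 84 + 4
  h2 <- build_history(make_records(numeric(0))[0, c(1, 3, 4)], dep, 7,
                      species = "coyote", season_levels = "S2019")
  expect_equal(dim(h2$y)[3], 13)
  dep$end <- dep$start + 84 + 2
  h3 <- build_history(make_records(numeric(0))[0, c(1, 3, 4)], dep, 7,
                      species = "coyote", season_levels = "S2019")
  expect_equal(dim(h3$y)[3], 12)
})

test_that("histories mark detections, zeros and missingness correctly", {
  dep <- data.frame(site_id = c("A", "B"),
                    primary_period = c("S2019", "S2019"),
                    start = as.Date("2019-07-01"),
                    end = as.Date("2019-07-01") + 28,
                    stringsAsFactors = FALSE)
  class(dep) <- c("deployments", "data.frame")
  ev <- filter_independent(make_records(c(0, 60 * 24 * 10)), 20)
  h <- build_history(ev, dep, 7, species = "coyote",
                     season_levels = c("S2019", "W2020"))
  expect_equal(h$y["A", "S2019", ], c(1L, 1L, 0L, 0L))
  expect_equal(h$y["B", "S2019", ], rep(0L, 4))
  # no site deployed in W2020 -> all missing
  expect_true(all(is.na(h$y[, "W2020", ])))

  # an event outside every window is ignored with a warning
  ev_out <- filter_independent(make_records(-60 * 24 * 30), 20)
  expect_warning(build_history(ev_out, dep, 7, species = "coyote",
                               season_levels = "S2019"),
                 "outside all deployment")
})

test_that("each detection event lights at most one occasion", {
  set.seed(9)
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 11, photos = TRUE)
  ev <- filter_independent(dat$records, 20)
  h <- build_history(ev, dat$deployments, sc$occasion_length,
                     species = sc$label,
                     season_levels = dat$season_cov$primary_period)
  expect_lte(sum(h$y == 1, na.rm = TRUE), nrow(ev))
})

test_that("naive occupancy is the detected share of surveyed sites", {
  y <- array(NA_integer_, c(4, 2, 3))
  y[, 1, ] <- 0L
  y[1, 1, 2] <- 1L
  h <- structure(list(y = y, sites = paste0("s", 1:4),
                      periods = c("S2019", "W2020"), calendar = NULL,
                      species = "x", occasion_length = 7),
                 class = "detection_history")
  expect_warning(no <- naive_occupancy(h), "zero surveyed")
  expect_equal(unname(no["S2019"]), 0.25)
  expect_true(is.na(no["W2020"]))

  y[, 1, 1] <- 1L
  h$y <- y
  expect_equal(unname(suppressWarnings(naive_occupancy(h))["S2019"]), 1)
})

test_that("trap nights sum whole nights on the configured basis", {
  dep <- data.frame(site_id = c("A", "B"), primary_period = "S2019",
                    start = as.Date("2019-06-01"),
                    end = as.Date("2019-06-11"), stringsAsFactors = FALSE)
  expect_equal(trap_nights(dep, basis = "site"), 20L)
  expect_equal(trap_nights(dep[1, ], basis = "site"), 10L)
  expect_equal(trap_nights(dep, basis = "camera"), 40L)
})

test_that("history serialization round-trips", {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 21)
  path <- file.path(withr::local_tempdir(), "hist.csv")
  write_history(dat$history, path)
  back <- read_history(path)
  expect_identical(unname(back$y), unname(dat$history$y))
  expect_equal(back$periods, dat$history$periods)
})
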