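test_that("photo records are read, filtered to the species list, and sorted", {
  df <- data.frame(site_id = c("B", "A", "A"),
                   camera_id = c("B_cam1", "A_cam2", "A_cam1"),
                   species = c("coyote", "moose", "coyote"),
                   timestamp = c("2019-07-01T10:00:00", "2019-07-01T09:00:00",
                                 "2019-06-15T08:30:00"))
  path <- write_tmp_csv(df)
  expect_message(rec <- read_photo_records(path, c("coyote", "bobcat")),
                 "dropped 1")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$site_id, c("A", "B"))  # sorted by site, species, time
  expect_s3_class(rec$timestamp, "POSIXct")

  one <- write_tmp_csv(df[1, ], "one.csv")
  expect_equal(nrow(read_photo_records(one, "coyote")), 1)

  empty <- write_tmp_csv(df[0, ], "empty.csv")
  expect_equal(nrow(read_photo_records(empty, "coyote")), 0)
})

test_that("malformed timestamps and missing columns are reported", {
  bad <- data.frame(site_id = "A", camera_id = "c", species = "coyote",
                    timestamp = "not-a-time")
  expect_error(read_photo_records(write_tmp_csv(bad), "coyote"),
               "malformed timestamp.*1")
  noc <- data.frame(site_id = "A", species = "coyote",
                    timestamp = "2019-07-01T10:00:00")
  expect_error(read_photo_records(write_tmp_csv(noc), "coyote"),
               "schema error")
})

test_that("deployments validate dates and merge overlapping windows", {
  df <- data.frame(site_id = "A", primary_period = "S2019",
                   start = "2019-06-10", end = "2019-09-30")
  dep <- read_deployments(write_tmp_csv(df))
  expect_equal(nrow(dep), 1)
  expect_equal(as.numeric(dep$end - dep$start), 112)

  ovl <- data.frame(site_id = c("A", "A"), primary_period = c("S2019", "S2019"),
                    start = c("2019-06-10", "2019-07-01"),
                    end = c("2019-07-15", "2019-09-30"))
  dep2 <- read_deployments(write_tmp_csv(ovl))
  expect_equal(nrow(dep2), 1)
  expect_equal(dep2$start, as.Date("2019-06-10"))
  expect_equal(dep2$end, as.Date("2019-09-30"))

  rev <- data.frame(site_id = "A", primary_period = "S2019",
                    start = "2019-09-30", end = "2019-06-10")
  expect_error(read_deployments(write_tmp_csv(rev)), "end <= start.*1")
})

test_that("season label vocabulary is generated, ordered and validated", {
  labs <- season_labels("S2019", 8)
  expect_equal(labs, c("S2019", "W2020", "S2020", "W2021", "S2021", "W2022",
                       "S2022", "W2023"))
  expect_equal(season_class(labs[1:2]), c("summer", "winter"))
  expect_error(season_labels("X2019", 3), "look like")
  df <- data.frame(site_id = "A", primary_period = "W9999",
                   start = "2019-06-10", end = "2019-09-30")
  expect_error(read_deployments(write_tmp_csv(df), season_levels = labs),
               "unknown primary period")
})

test_that("covariate tables enforce ranges and alternation", {
  sc <- data.frame(site_id = c("A", "B"), moth = c(0, 4), cover = c(10, 95),
                   road_dist = c(0, 2.3), zone_area = c(0.5, 12))
  tab <- read_site_covariates(write_tmp_csv(sc))
  expect_equal(nrow(tab), 2)
  sc$moth[1] <- 7
  expect_error(read_site_covariates(write_tmp_csv(sc, "bad.csv")), "moth")

  se <- data.frame(primary_period = c("S2019", "W2020", "S2020"),
                   precip = c(18, 31, 20),
                   season_class = c("summer", "winter", "summer"),
                   tsd = c(4.0, 4.5, 5.0))
  tab2 <- read_season_covariates(write_tmp_csv(se, "se.csv"))
  expect_equal(attr(tab2, "transition_class"), c(0L, 1L))
  se$season_class[2] <- "summer"
  expect_error(read_season_covariates(write_tmp_csv(se, "se2.csv")),
               "alternate")
})

test_that("cross-validation report flags inconsistencies and clean inputs pass", {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 3, photos = TRUE)
  rep0 <- validate_inputs(dat$records, dat$deployments, dat$site_cov,
                          dat$season_cov)
  expect_false(has_fatal(rep0))
  expect_length(rep0$outside_records, 0)

  # a photo dated before any deployment window
  rec <- dat$records
  rec$timestamp[1] <- as.POSIXct("2000-01-01 12:00:00", tz = "UTC")
  rep1 <- validate_inputs(rec, dat$deployments, dat$site_cov, dat$season_cov)
  expect_length(rep1$outside_records, 1)
  expect_false(has_fatal(rep1))

  # a surveyed site with no covariate row is fatal
  cov_miss <- dat$site_cov[-1, ]
  rep2 <- validate_inputs(dat$records, dat$deployments, cov_miss,
                          dat$season_cov)
  expect_true(has_fatal(rep2))
})

test_that("run configuration validates and reads from YAML", {
  cfg <- run_config(species = c("bobcat", "coyote"))
  expect_s3_class(cfg, "occu_config")
  expect_equal(cfg$independence_window, 20)
  expect_equal(cfg$occasion_length, 7)
  expect_equal(cfg$mcmc$chains, 3)
  expect_error(run_config(mcmc = list(chains = 1, warmup = 10, draws = 10,
                                      seed = 1)), "chains")
  expect_error(run_config(support_thresholds = list(strong = 0.4,
                                                    moderate = 0.3)),
               "thresholds")

  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  writeLines(c("species: fisher", "independence_window: 30",
               "mcmc:", "  chains: 2", "  warmup: 50", "  draws: 100",
               "  seed: 9"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$species, "fisher")
  expect_equal(cfg2$independence_window, 30)
  expect_equal(cfg2$mcmc$seed, 9)
  writeLines("not_a_field: 1", path)
  expect_error(read_config(path), "unknown configuration field")
})

test_that("the pipeline runs from CSV inputs on disk", {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, 19, photos = TRUE, species = "marten_test")
  dir <- withr::local_tempdir()
  paths <- list(photos = file.path(dir, "photos.csv"),
                deployments = file.path(dir, "dep.csv"),
                site_covariates = file.path(dir, "site.csv"),
                season_covariates = file.path(dir, "season.csv"),
                grid = file.path(dir, "grid.csv"))
  write_table_csv(dat$records, paths$photos)
  write_table_csv(dat$deployments, paths$deployments)
  write_table_csv(dat$site_cov, paths$site_covariates)
  write_table_csv(dat$season_cov, paths$season_covariates)
  write_table_csv(dat$grid, paths$grid)
  cfg <- quick_config(seed = 19, chains = 2, warmup = 100, draws = 150)
  cfg$species <- "marten_test"
  out <- file.path(dir, "out")
  res <- suppressWarnings(run_pipeline(cfg, out, inputs = paths))
  expect_true(file.exists(file.path(out, "marten_test", "fit_summary.csv")))
  # the file-based run reproduces the in-memory detection history
  expect_identical(unname(res$marten_test$history$y), unname(dat$history$y))
})

test_that("table write/read round trip preserves reals to 12 significant digits", {
  df <- data.frame(site_id = sprintf("s%02d", 1:5),
                   moth = c(0L, 1L, 2L, 3L, 4L),
                   cover = c(12.123456789012, 99.9, 3.14159265358979, 50, 0.1),
                   road_dist = exp(seq(-3, 1, 1)),
                   zone_area = pi * (1:5))
  path <- file.path(withr::local_tempdir(), "round.csv")
  write_table_csv(df, path)
  back <- read_site_covariates(path)
  expect_identical(back$site_id, df$site_id)
  expect_identical(back$moth, df$moth)
  for (nm in c("cover", "road_dist", "zone_area")) {
    expect_equal(back[[nm]], df[[nm]], tolerance = 1e-12)
  }
  # byte-identical re-emission
  path2 <- file.path(withr::local_tempdir(), "round2.csv")
  write_table_csv(back[names(df)], path2)
  expect_identical(readLines(path), readLines(path2))
})
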