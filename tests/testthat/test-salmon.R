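test_that("travel-time distribution normalizes and handles point masses", {
  d <- travel_time_distribution(c(3, 3, 3, 3, 3))
  expect_equal(d$lags, 3L)
  expect_equal(d$weights, 1)
  d2 <- travel_time_distribution(3:7)
  expect_equal(sum(d2$weights), 1, tolerance = 1e-12)
  expect_true(all(d2$weights >= 0))
  expect_equal(d2$lags, 3:7)
  expect_error(travel_time_distribution(integer(0)), class = "buzz_input")
  expect_error(travel_time_distribution(c(3, -1)), class = "buzz_input")
})

test_that("a point-mass lag translates the weir series exactly", {
  weir <- data.frame(date = as.Date("2018-06-10") + 0:4,
                     count = c(0, 0, 100, 0, 0))
  pred <- predict_counts_at_site(weir, travel_time_distribution(rep(3, 10)))
  expect_equal(pred$predicted[pred$date == as.Date("2018-06-09")], 100)
  expect_equal(sum(pred$predicted), 100)
})

test_that("split lags divide the count by weight across earlier days", {
  weir <- data.frame(date = as.Date("2018-06-10"), count = 100)
  dist <- travel_time_distribution(c(3, 4))  # weights 0.5 / 0.5
  pred <- predict_counts_at_site(weir, dist)
  expect_equal(pred$predicted[pred$date == as.Date("2018-06-07")], 50)
  expect_equal(pred$predicted[pred$date == as.Date("2018-06-06")], 50)
})

test_that("the back-shift conserves total count for any weir series", {
  set.seed(61)
  for (rep in 1:5) {
    weir <- data.frame(date = as.Date("2018-06-01") + 0:29,
                       count = rpois(30, 40))
    lags <- sample(2:12, 40, replace = TRUE)
    pred <- predict_counts_at_site(weir, travel_time_distribution(lags))
    expect_equal(sum(pred$predicted), sum(weir$count), tolerance = 1e-9)
  }
})

test_that("percentile threshold and peak span match the hand-checked case", {
  pred <- data.frame(date = as.Date("2018-06-01") + 0:9, predicted = 1:10)
  pk <- peak_period(pred)
  expect_equal(pk$threshold, 9.1)  # linear interpolation of order statistics
  expect_equal(pk$start, as.Date("2018-06-10"))
  expect_equal(pk$end, as.Date("2018-06-10"))
  # constant series: every day qualifies
  pred2 <- data.frame(date = pred$date, predicted = 7)
  pk2 <- peak_period(pred2)
  expect_equal(pk2$start, pred$date[1])
  expect_equal(pk2$end, pred$date[10])
  expect_error(peak_period(data.frame(date = pred$date, predicted = 0)),
               class = "buzz_no_run")
})

test_that("peak period is invariant to uniform scaling of counts", {
  set.seed(62)
  pred <- data.frame(date = as.Date("2018-06-01") + 0:19,
                     predicted = rpois(20, 30))
  a <- peak_period(pred)
  pred$predicted <- pred$predicted * 17.3
  b <- peak_period(pred)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(b$threshold, a$threshold * 17.3, tolerance = 1e-9)
})

test_that("simulated season is recovered: peak date within 2 days, mass kept", {
  season <- gen_weir_season(total_fish = 10000, seed = 63)
  dist <- travel_time_distribution(season$travel_times)
  pred <- predict_counts_at_site(season$weir[, c("date", "count")], dist)
  expect_equal(sum(pred$predicted), sum(season$weir$count), tolerance = 1e-9)
  # smooth the raw daily arrivals before taking the true peak: the daily
  # multinomial noise near the crest is larger than its curvature
  true_peak <- season$site$date[which.max(running_average(season$site$count,
                                                          5))]
  est_peak <- pred$date[which.max(pred$predicted)]
  expect_lte(abs(as.numeric(est_peak - true_peak)), 2)
})

test_that("overlap summary aggregates FPM and smoothed DPH over the peak", {
  pres <- data.frame(date = as.Date("2018-06-01") + 0:9,
                     fpm = c(0, 0, 1, 2, 3, 0, 0, 0, 0, 0),
                     dph_smoothed = seq(2, 20, by = 2))
  pk <- structure(list(species = "chinook", threshold = 5,
                       start = as.Date("2018-06-03"),
                       end = as.Date("2018-06-05"),
                       dates = as.Date("2018-06-03") + 0:2,
                       interior_below = as.Date(character(0))),
                  class = "run_peak")
  out <- overlap_summary(pk, pres)
  expect_equal(out$fpm, 6)
  expect_equal(out$dph7_sum, 6 + 8 + 10)
  expect_equal(out$dph7_mean, 8)
  # peak entirely outside the monitored span: zero with a warning
  pk$start <- as.Date("2019-01-01"); pk$end <- as.Date("2019-01-03")
  pk$dates <- as.Date("2019-01-01") + 0:2
  expect_warning(out2 <- overlap_summary(pk, pres), "beyond")
  expect_equal(out2$fpm, 0)
})

test_that("feeding concentrates in the run peak in a coupled simulation", {
  set.seed(64)
  # feeding probability follows the fish pulse: feed only near the run center
  days <- seq(as.Date("2018-06-01"), by = "day", length.out = 40)
  season <- gen_weir_season(run_center = "2018-06-20", run_sd = 4,
                            total_fish = 5000, seed = 65)
  pulse <- exp(-((as.numeric(days - as.Date("2018-06-20"))) / 6)^2)
  trains <- list(); events <- list()
  p <- buzz_gen_params()
  id <- 0
  for (i in seq_along(days)) {
    n <- rpois(1, 5)
    if (n == 0) next
    secs <- sort(runif(n, 0, 86000))
    for (s in secs) {
      id <- id + 1
      t0 <- as.POSIXct(paste(days[i], "00:00:00"), tz = "UTC") + s
      tr <- if (runif(1) < 0.8 * pulse[i])
        gen_feeding_train(p, sprintf("c%04d", id), t0 = t0)
      else gen_social_buzz(p, sprintf("c%04d", id), t0 = t0)
      tr$context <- "unknown"
      trains[[length(trains) + 1]] <- tr
      events[[length(events) + 1]] <- data.frame(
        timestamp = t0, signal_type = "echolocation",
        instrument = "click_logger")
    }
  }
  verdicts <- classify_stream(trains)
  pres <- presence_series(do.call(rbind, events), verdicts, days = days)
  dist <- travel_time_distribution(season$travel_times)
  pred <- predict_counts_at_site(season$weir[, c("date", "count")], dist)
  pk <- peak_period(pred, species = "chinook")
  suppressWarnings(out <- overlap_summary(pk, pres))
  in_peak <- pres$date %in% seq(pk$start, pk$end, by = "day")
  peak_rate <- out$fpm / max(out$n_days, 1)
  off_rate <- sum(pres$fpm[!in_peak]) / sum(!in_peak)
  expect_gt(peak_rate, off_rate)
})
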