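test_that("solar altitude reproduces textbook geometry", {
  # near-overhead sun at the equator around an equinox local noon
  expect_gt(sun_altitude(utc("2024-03-20 12:07:00"), 0, 0), 88)
  # noon altitude ~ 90 - |lat - declination|: December solstice at 61 S
  noon_local <- utc("2023-12-21 15:44:00")  # ~solar noon at 56 W
  expect_lt(abs(sun_altitude(noon_local, -61, -56) - (90 - 61 + 23.44)), 1)
  # daily cycle: midnight below noon at 61 S in every month
  for (m in 1:12) {
    d <- sprintf("2014-%02d-15", m)
    noon <- sun_altitude(utc(paste(d, "15:44:00")), -61, -56)
    midnight <- sun_altitude(utc(paste(d, "03:44:00")), -61, -56)
    expect_gt(noon, midnight)
  }
  # around the December solstice at 61 S the sun stays above -12 degrees:
  # no nautical night
  hours <- utc("2023-12-21 00:00:00") + seq(0, 86400, by = 900)
  expect_gt(min(sun_altitude(hours, -61, -56)), -12)
  # mid-winter has real nights
  june <- utc("2023-06-21 00:00:00") + seq(0, 86400, by = 900)
  expect_lt(min(sun_altitude(june, -61, -56)), -12)
})

test_that("light classification partitions altitudes with twilight boundaries", {
  expect_equal(as.character(classify_light(10)), "light")
  expect_equal(as.character(classify_light(-6)), "twilight")
  expect_equal(as.character(classify_light(-20)), "dark")
  # boundary values belong to twilight
  expect_equal(as.character(classify_light(c(0, -12))),
               c("twilight", "twilight"))
  # exhaustive and mutually exclusive over a fine altitude grid
  grid <- seq(-90, 90, by = 0.25)
  cls <- classify_light(grid)
  expect_false(any(is.na(cls)))
  expect_equal(sort(unique(as.character(cls))),
               sort(c("light", "twilight", "dark")))
})

test_that("every minute of a day gets exactly one light regime", {
  mins <- utc("2014-04-10 00:00:00") + seq(0, 86399, by = 60)
  cls <- classify_light(sun_altitude(mins, -61.0147, -55.9755))
  expect_length(cls, 1440)
  expect_false(any(is.na(cls)))
  expect_true(all(c("light", "twilight", "dark") %in% cls))
})

test_that("local time is a fixed -3 h 40 min offset", {
  expect_equal(format(local_time(utc("2013-05-10 12:00:00")), "%H:%M"),
               "08:20")
  t <- utc("2013-11-03 02:15:00")
  expect_equal(local_time(t) + 13200, t)  # round trip
  # the offset approximates the hour angle of meridian 56 W (56/15 h)
  expect_lt(abs(13200 / 3600 - 56 / 15), 0.1)
})

test_that("Kruskal-Wallis wrapper matches the rank-sum formula", {
  res <- kruskal_wallis(list(1:3, 4:6, 7:9))
  # brute-force oracle: H = 12/(N(N+1)) * sum n_i (rbar_i - (N+1)/2)^2
  r <- rank(1:9)
  rb <- tapply(r, rep(1:3, each = 3), mean)
  H_oracle <- 12 / (9 * 10) * sum(3 * (rb - 5)^2)
  expect_equal(res$H, H_oracle)
  expect_equal(res$df, 2)
  expect_equal(res$critical_value, qchisq(0.95, 2))
  expect_equal(round(res$critical_value, 2), 5.99)
  expect_equal(res$group_sizes, rep(3L, 3))
  # identical constant groups carry no rank information
  res0 <- kruskal_wallis(list(rep(2, 5), rep(2, 5), rep(2, 5)))
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
  expect_error(kruskal_wallis(list(1:5)), "two groups")
  expect_error(kruskal_wallis(1:4, factor(c(1, 1, 1, 1), levels = 1:2)),
               "nonempty")
})

test_that("the test holds its nominal size and has power against a shift", {
  set.seed(31)
  rej <- 0L
  for (r in 1:600) {
    v <- rpois(90, 15)
    if (kruskal_wallis(v, rep(1:3, each = 30))$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 600 - 0.05), 0.025)
  # 2x median shift in one regime at n = 50 per group
  rej2 <- 0L
  for (r in 1:100) {
    v <- c(rpois(100, 15), rpois(50, 30))
    if (kruskal_wallis(v, rep(1:3, each = 50))$p < 0.05) rej2 <- rej2 + 1L
  }
  expect_gt(rej2 / 100, 0.8)
})

test_that("count intervals inherit the light regime of their midpoints", {
  iv <- data.frame(start_utc = utc("2013-05-10 00:00:00") + (0:23) * 3600,
                   duration_s = 600)
  iv <- assign_light_period(iv)
  expect_false(any(is.na(iv$light_period)))
  mid_alt <- sun_altitude(iv$start_utc + 300, -61.0147, -55.9755)
  expect_equal(iv$light_period, classify_light(mid_alt))
  # local noon files are lit, local midnight files dark in May at 61 S
  expect_equal(as.character(iv$light_period[iv$start_utc ==
    utc("2013-05-10 15:00:00")]), "light")
  expect_equal(as.character(iv$light_period[iv$start_utc ==
    utc("2013-05-10 04:00:00")]), "dark")
})
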