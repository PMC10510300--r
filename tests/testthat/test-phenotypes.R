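test_that("respiration rate is four times the 15-second flank count", {
  expect_equal(rr_from_counts(18), 72)
  expect_equal(rr_from_counts(3), 12)
  expect_equal(rr_from_counts(0), 0)
  expect_error(rr_from_counts(-1), "negative")
})

test_that("single-pass SD filter removes only records beyond k SD", {
  # 500 records at 39.0/40.4 (mean 39.7, SD ~0.70) plus one distant record;
  # single pass: mean and SD include the outlier itself
  base <- rep(c(39.0, 40.4), 250)
  ph <- data.frame(trait = "T_Vall", value = c(base, 42.5))
  m <- mean(ph$value); s <- sd(ph$value)
  expect_gt(abs(42.5 - m), 3.5 * s)       # the outlier exceeds the rule
  expect_lt(abs(40.4 - m), 3.5 * s)       # ordinary records do not
  fr <- filter_outliers(ph, k = 3.5, rr_trait = NULL)
  expect_equal(fr$report$reason, "sd_outlier")
  expect_equal(nrow(fr$data), 500)
  expect_false(42.5 %in% fr$data$value)
})

test_that("RR records outside [12, 172] bpm are removed, bounds retained", {
  ph <- data.frame(trait = "RR", value = c(10, 12, 80, 172, 200, 60, 70, 90))
  fr <- filter_outliers(ph, k = 100)  # disable the SD rule
  expect_setequal(fr$report$reason, "rr_bounds")
  expect_true(all(fr$data$value >= 12 & fr$data$value <= 172))
  expect_true(172 %in% fr$data$value)
  expect_true(12 %in% fr$data$value)
})

test_that("a constant series loses no records and larger k removes no more", {
  ph <- data.frame(trait = "X", value = rep(5, 10))
  expect_equal(nrow(filter_outliers(ph, k = 3.5, rr_trait = NULL)$data), 10)
  set.seed(2)
  ph2 <- data.frame(trait = "Y", value = rcauchy(300))
  removed <- sapply(c(1, 2, 3.5, 5, 10, 1e6), function(k)
    nrow(filter_outliers(ph2, k = k, rr_trait = NULL)$report))
  expect_true(all(diff(removed) <= 0))
  expect_equal(removed[length(removed)], 0)
})

# toy 10-min vaginal-temperature series: 4 days x 24 h x 6 records
make_tv <- function(ids, days = 4, seed = 1) {
  set.seed(seed)
  g <- expand.grid(minute = seq(0, 50, 10), hour = 0:23, day = seq_len(days),
                   animal_id = ids, stringsAsFactors = FALSE)
  g$time <- g$hour + g$minute / 60
  g$value <- 39.5 + 0.3 * sin(2 * pi * (g$time - 16) / 24) +
    rnorm(nrow(g), 0, 0.1)
  g$parity <- 2L
  g$location <- "R01"
  g[, c("animal_id", "day", "time", "value", "parity", "location")]
}

test_that("the T_V trait family has the documented record structure", {
  tv <- make_tv(c("A1", "A2"))
  d <- derive_tv_traits(tv)
  n <- function(tr, id) sum(d$trait == tr & d$animal_id == id)
  expect_equal(n("T_Vall", "A1"), 4 * 24 * 6)
  expect_equal(n("T_V4days", "A1"), 16)
  for (h in c(8, 12, 16, 20)) {
    expect_equal(n(sprintf("T_V%dh", h), "A1"), 4)
    expect_equal(n(sprintf("T_V%dhS", h), "A1"), 1)
  }
})

test_that("hourly T_V values are the mean of the records in that hour", {
  tv <- make_tv("A1", days = 1)
  sel <- tv$time >= 12 & tv$time < 13
  tv$value[sel] <- c(39.0, 39.2, 39.4, 39.6, 39.8, 40.0)
  d <- derive_tv_traits(tv)
  expect_equal(d$value[d$trait == "T_V12hS"], 39.5)
  # partial hour: only 3 of 6 records present
  tv2 <- tv[!(sel & tv$time > 12.4), ]
  d2 <- derive_tv_traits(tv2)
  expect_equal(d2$value[d2$trait == "T_V12hS"], mean(c(39.0, 39.2, 39.4)))
})

test_that("T_V4days is the union of the four hourly traits, S-traits day 1", {
  tv <- make_tv(c("A1", "A2", "A3"), days = 4, seed = 3)
  d <- derive_tv_traits(tv)
  v4 <- sort(d$value[d$trait == "T_V4days"])
  vh <- sort(unlist(lapply(c(8, 12, 16, 20), function(h)
    d$value[d$trait == sprintf("T_V%dh", h)])))
  expect_equal(v4, vh)
  for (h in c(8, 12, 16, 20)) {
    s <- d[d$trait == sprintf("T_V%dhS", h), ]
    hall <- d[d$trait == sprintf("T_V%dh", h), ]
    expect_true(all(s$day == 1))
    expect_true(all(s$value %in% hall$value))
  }
})

test_that("respiration efficiency is the OLS slope of T_V on RR", {
  rr <- data.frame(animal_id = "A1", day = c(1, 2), time = 8,
                   value = c(60, 100))
  tv <- data.frame(animal_id = "A1", day = c(1, 2), time = 8,
                   value = c(39.0, 39.8))
  expect_equal(respiration_efficiency(rr, tv)$value, 0.02)
  # degenerate: zero RR variance
  rr$value <- c(60, 60)
  expect_true(is.na(respiration_efficiency(rr, tv)$value))
})

test_that("respiration efficiency matches the closed-form OLS oracle", {
  set.seed(4)
  grid <- expand.grid(day = 1:4, time = c(8, 16))
  rr <- data.frame(animal_id = "A1", grid, value = round(runif(8, 40, 150)))
  tv <- data.frame(animal_id = "A1", grid, value = rnorm(8, 39.5, 0.4))
  slope <- respiration_efficiency(rr, tv)$value
  expect_equal(slope, cov(rr$value, tv$value) / var(rr$value))
  # invariances: adding a constant to T_V; scaling RR by c
  tv2 <- tv; tv2$value <- tv$value + 5
  expect_equal(respiration_efficiency(rr, tv2)$value, slope)
  rr2 <- rr; rr2$value <- rr$value * 4
  expect_equal(respiration_efficiency(rr2, tv)$value, slope / 4)
})

test_that("animals with fewer than two complete pairs get a missing slope", {
  rr <- data.frame(animal_id = c("A1", "A2"), day = 1, time = 8,
                   value = c(60, 80))
  tv <- data.frame(animal_id = c("A1", "A2"), day = 1, time = 8,
                   value = c(39, 40))
  out <- respiration_efficiency(rr, tv)
  expect_true(all(is.na(out$value)))
  expect_equal(out$n_pairs, c(1L, 1L))
})
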