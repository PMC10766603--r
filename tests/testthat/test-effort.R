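test_that("swept area from distance and from speed match hand arithmetic", {
  expect_equal(swept_area_from_distance(3, 20), 0.06)
  expect_equal(swept_area_from_distance(6, 20), 2 * swept_area_from_distance(3, 20))
  expect_equal(swept_area_from_speed(60, 3, 25), 3 * 1.852 * 0.025)
  expect_equal(swept_area_from_speed(30, 4, 20), 0.074080)
  expect_error(swept_area_from_distance(3, 0), class = "trawlr_domain_error")
  expect_error(swept_area_from_speed(0, 3, 20), class = "trawlr_domain_error")
})

test_that("speed and distance formulations agree exactly", {
  set.seed(11)
  dur <- runif(200, 10, 120); spd <- runif(200, 1, 6); op <- runif(200, 5, 40)
  expect_identical(swept_area_from_speed(dur, spd, op),
                   swept_area_from_distance(spd * 1.852 * dur / 60, op))
})

test_that("derive_swept_area prefers distance and honours a fallback opening", {
  hauls <- make_haul(haul_id = c("H1", "H2", "H3"),
                     latitude = 54, longitude = 3, year = 2010,
                     area_swept = c(0.1, NA, NA))
  hauls$distance <- c(5, 3, NA)
  hauls$speed <- c(NA, NA, 4)
  hauls$gear_opening <- c(20, 20, NA)
  d <- derive_swept_area(survey_dataset(hauls, make_catch()),
                         default_opening_m = 25)
  expect_equal(d$hauls$area_swept[1], 0.1)            # known value untouched
  expect_equal(d$hauls$area_swept[2], 3 * 0.02)       # distance x opening
  expect_equal(d$hauls$area_swept[3],
               swept_area_from_speed(30, 4, 25))      # fallback opening
})

test_that("a zero-noise linear generator is recovered exactly", {
  hauls <- make_haul(haul_id = sprintf("H%03d", 1:50),
                     latitude = 54, longitude = 3, year = 2010,
                     haul_dur = seq(15, 64, by = 1))
  hauls$area_swept <- 0.001 * hauls$haul_dur
  m <- suppressWarnings(fit_swept_area_model(hauls, predictors = "haul_dur"))
  expect_equal(unname(coef(m$fit)), c(0, 0.001), tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_equal(m$n_fit, 50)
})

test_that("too few training rows is a fitting error", {
  hauls <- make_haul(haul_id = sprintf("H%d", 1:5), latitude = 54,
                     longitude = 3, year = 2010, haul_dur = 20:24,
                     area_swept = (20:24) / 100)
  expect_error(fit_swept_area_model(hauls), class = "trawlr_fit_error")
})

test_that("an all-constant predictor leaves predictions unchanged", {
  set.seed(21)
  hauls <- make_haul(haul_id = sprintf("H%03d", 1:60), latitude = 54,
                     longitude = 3, year = 2010,
                     haul_dur = runif(60, 20, 60))
  hauls$area_swept <- 0.02 + 0.001 * hauls$haul_dur + rnorm(60, 0, 0.002)
  hauls$country <- "NL"  # constant
  m1 <- fit_swept_area_model(hauls, predictors = "haul_dur")
  m2 <- fit_swept_area_model(hauls, predictors = c("haul_dur", "country"))
  newdata <- make_haul(haul_id = "X", latitude = 54, longitude = 3,
                       year = 2010, haul_dur = 37.5, area_swept = NA_real_)
  newdata$country <- "NL"
  d <- survey_dataset(newdata, tibble::tibble(haul_id = character(),
                                              verbatim_name = character()))
  p1 <- impute_swept_area(d, m1)$hauls$area_swept
  p2 <- impute_swept_area(d, m2)$hauls$area_swept
  expect_equal(p1, p2)
})

test_that("imputation fills only absent areas and logs unpredictable hauls", {
  train <- make_haul(haul_id = sprintf("T%03d", 1:30), latitude = 54,
                     longitude = 3, year = 2010,
                     haul_dur = seq(20, 49))
  train$area_swept <- 0.001 * train$haul_dur
  m <- suppressWarnings(fit_swept_area_model(train, predictors = "haul_dur"))
  hauls <- make_haul(haul_id = c("H1", "H2", "H3"), latitude = 54,
                     longitude = 3, year = 2010,
                     haul_dur = c(40, 30, NA),
                     area_swept = c(0.123, NA, NA))
  d <- impute_swept_area(survey_dataset(hauls, make_catch()), m)
  expect_equal(d$hauls$area_swept[1], 0.123)
  expect_equal(d$hauls$area_swept[2], 0.03, tolerance = 1e-9)
  expect_true(is.na(d$hauls$area_swept[3]))
  expect_true(any(grepl("lack predictors", processing_log(d))))
})

test_that("length-weight reconstruction follows w = a * l^b", {
  expect_equal(weight_from_lengths(10, 2, lw_a = 0.01, lw_b = 3), 0.020)
  expect_equal(weight_from_lengths(numeric(0), numeric(0), 0.01, 3), 0)
  # homogeneous in counts, monotone in bins
  w1 <- weight_from_lengths(c(10, 20), c(2, 3), 0.01, 3)
  expect_equal(weight_from_lengths(c(10, 20), 5 * c(2, 3), 0.01, 3), 5 * w1)
  expect_gt(weight_from_lengths(c(10, 20, 30), c(2, 3, 1), 0.01, 3), w1)
  expect_error(weight_from_lengths(10, 2, NA, 3), class = "trawlr_domain_error")
})

test_that("catch weights are reconstructed from length tables via the backbone", {
  d <- fixture_dataset()
  d$catches$accepted_name <- d$catches$verbatim_name
  d$catches$wgt <- NA_real_
  lengths <- tibble::tibble(haul_id = "H1", taxon = "Gadus morhua",
                            length_cm = c(20, 40), count = c(3, 1))
  d2 <- add_weights_from_lengths(d, lengths, fixture_backbone())
  a <- 0.0070; b <- 3.08
  expect_equal(d2$catches$wgt[1], (3 * a * 20^b + 1 * a * 40^b) / 1000)
  expect_true(is.na(d2$catches$wgt[3]))  # no length data for H2
})

test_that("rates divide by effort and invert back to the raw values", {
  hauls <- make_haul(haul_id = c("H1", "H2"), latitude = 54, longitude = 3,
                     year = 2010, haul_dur = c(30, 60),
                     area_swept = c(0.05, 0.05))
  catches <- make_catch(haul_id = c("H1", "H2"), num = c(50, NA),
                        wgt = c(20, 10))
  d <- compute_rates(survey_dataset(hauls, catches))
  expect_equal(d$catches$num_cpue[1], 100)   # 50 per half hour
  expect_equal(d$catches$wgt_cpua[1], 400)   # 20 kg / 0.05 km2
  expect_true(is.na(d$catches$num_cpue[2]))  # absent numerator
  expect_true(is.na(d$catches$num_cpua[2]))
  expect_equal(d$catches$wgt_cpue[2], 10)

  # inversion identity on random catches
  set.seed(5)
  n <- 500
  hauls <- make_haul(haul_id = sprintf("H%04d", 1:n), latitude = 54,
                     longitude = 3, year = 2010,
                     haul_dur = runif(n, 10, 120))
  hauls$area_swept <- runif(n, 0.01, 0.2)
  catches <- make_catch(haul_id = hauls$haul_id, num = rlnorm(n, 3, 1),
                        wgt = rlnorm(n, 1, 1))
  d <- compute_rates(survey_dataset(hauls, catches))
  j <- dplyr::left_join(d$catches, d$hauls[, c("haul_id", "area_swept", "haul_dur")],
                        by = "haul_id")
  expect_equal(j$num_cpua * j$area_swept, j$num, tolerance = 1e-12)
  expect_equal(j$wgt_cpue * j$haul_dur / 60, j$wgt, tolerance = 1e-12)
})
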