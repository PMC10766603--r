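# assignment backend used to pin hauls to named cells in rule tests:
# the integer part of latitude is the cell
fake_assign <- function(latitude, longitude, resolution) {
  sprintf("cell%02d", floor(latitude))
}

worked_hauls <- function() {
  # cells A,B,C (lat 10,11,12) x years 1-3 with pattern [[1,1,1],[1,1,0],[1,0,0]]
  pattern <- list(c(2001, 2002, 2003), c(2001, 2002), 2001)
  rows <- NULL
  for (i in seq_along(pattern)) {
    for (y in pattern[[i]]) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(lat = 9.5 + i, year = y))
    }
  }
  make_haul(haul_id = sprintf("H%02d", seq_len(nrow(rows))),
            latitude = rows$lat, longitude = 3, year = rows$year)
}

test_that("hex cell areas follow the icosahedral aperture-3 series", {
  expect_equal(hex_cell_area(7), earth <- 4 * pi * 6371.0088^2 / 21872)
  expect_equal(hex_cell_area(8), 4 * pi * 6371.0088^2 / 65612)
  # aperture 3: area shrinks by ~3 per resolution step
  expect_equal(hex_cell_area(7) / hex_cell_area(8), 3, tolerance = 0.01)
  expect_error(hex_cell_area(-1), class = "trawlr_domain_error")
})

test_that("a haul at a cell centroid is assigned back to that cell", {
  set.seed(31)
  lat <- runif(50, 50, 60); lon <- runif(50, -10, 10)
  for (res in c(7, 8)) {
    cells <- assign_hex_cells(lat, lon, res)
    ctr <- attr(cells, "center")
    cent <- hex_cell_centroid(cells, ctr)
    again <- assign_hex_cells(cent$latitude, cent$longitude, res, center = ctr)
    expect_equal(as.character(again), as.character(cells))
  }
})

test_that("nearby hauls far from cell edges share a cell", {
  # two hauls ~1 km apart at a cell centroid (cell area >= 7,770 km2)
  seed_cell <- assign_hex_cells(55, 3, 8, center = c(55, 3))
  cent <- hex_cell_centroid(seed_cell, c(55, 3))
  lat <- cent$latitude + c(-0.0045, 0.0045)  # +/- 500 m
  cells <- assign_hex_cells(lat, rep(cent$longitude, 2), 8, center = c(55, 3))
  expect_equal(cells[1], cells[2])
  expect_error(assign_hex_cells(91, 0, 7), class = "trawlr_domain_error")
})

test_that("empirical cell areas match the icosahedral mean", {
  # uniform points on a spherical patch; the fraction landing in the central
  # cell and its six neighbours estimates 7 cells' surface area
  set.seed(41)
  n <- 1e6
  lat1 <- 50; lat2 <- 60; lon1 <- -6; lon2 <- 6
  u <- runif(n, sin(lat1 * pi / 180), sin(lat2 * pi / 180))
  lat <- asin(u) * 180 / pi
  lon <- runif(n, lon1, lon2)
  patch_area <- 6371.0088^2 * (lon2 - lon1) * pi / 180 *
    (sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
  center <- c(55, 0)
  cells <- assign_hex_cells(lat, lon, 7, center = center)
  central <- as.character(assign_hex_cells(55, 0, 7, center = center))
  qr <- as.integer(strsplit(central, ":")[[1]][2:3])
  neigh <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  ids <- c(central, sprintf("r7:%d:%d", qr[1] + neigh[, 1], qr[2] + neigh[, 2]))
  frac <- mean(cells %in% ids)
  est <- patch_area * frac / 7
  expect_equal(est, hex_cell_area(7), tolerance = 0.005)
})

test_that("incidence matrices reflect the sampling pattern, order-free", {
  h <- worked_hauls()
  inc <- build_incidence(h, fake_assign(h$latitude, NULL, 7))
  expect_equal(unname(inc$sampled),
               matrix(as.logical(c(1, 1, 1, 1, 1, 0, 1, 0, 0)),
                      nrow = 3, byrow = TRUE))
  perm <- sample.int(nrow(h))
  inc2 <- build_incidence(h[perm, ], fake_assign(h$latitude[perm], NULL, 7))
  expect_identical(inc2$sampled, inc$sampled)

  one <- make_haul()
  inc1 <- build_incidence(one, "c")
  expect_equal(dim(inc1$sampled), c(1, 1))
  expect_true(all(inc1$sampled))
})

test_that("core selection solves the worked example and complete matrices", {
  h <- worked_hauls()
  inc <- build_incidence(h, fake_assign(h$latitude, NULL, 7))
  core <- select_core(inc, 0)
  expect_equal(core$objective, 4)   # {A,B} x {2001,2002} beats 1x3 and 3x1
  expect_setequal(core$retained_cells, c("cell10", "cell11"))
  expect_setequal(core$retained_years, c(2001, 2002))
  expect_equal(core$missing_fraction, 0)

  full <- incidence_from_matrix(random_incidence(4, 5, p = 1.1))
  core <- select_core(full, 0)
  expect_equal(core$objective, 20)
  expect_equal(core$missing_fraction, 0)
})

test_that("core selection matches the exhaustive oracle on random matrices", {
  set.seed(53)
  for (k in 1:40) {
    m <- random_incidence(sample(2:6, 1), sample(2:6, 1),
                          p = runif(1, 0.3, 0.9))
    if (!any(m)) next
    inc <- incidence_from_matrix(m)
    for (th in c(0, 0.02)) {
      got <- select_core(inc, th)
      want <- brute_core(m, th)
      expect_equal(got$objective, want$obj)
      expect_equal(length(got$retained_cells), want$i)
      expect_equal(length(got$retained_years), want$j)
      # hard assert: at threshold 0 the retained rectangle is complete
      if (th == 0 && want$obj > 0) {
        sub <- m[got$retained_cells, as.character(got$retained_years),
                 drop = FALSE]
        expect_true(all(sub))
      }
    }
    # feasible sets nest: the budgeted optimum cannot be smaller
    expect_gte(select_core(inc, 0.02)$objective, select_core(inc, 0)$objective)
  }
})

test_that("both budget denominators are supported, rectangle by default", {
  m <- matrix(TRUE, 5, 5, dimnames = list(sprintf("c%d", 1:5),
                                          sprintf("%d", 2001:2005)))
  m[5, 2:5] <- FALSE  # one cell sampled once
  inc <- incidence_from_matrix(m)
  rect <- select_core(inc, 0.1, denominator = "rectangle")
  full <- select_core(inc, 0.1, denominator = "matrix")
  # 4 missing of 25 rectangle entries = 16% > 10%; but 4/25 of the full
  # matrix is 16% too -- use a tighter example: 0.1 * 25 = 2.5 allows 2
  expect_equal(rect$objective, 20)
  expect_equal(full$objective, 20)
  m[5, 3:5] <- TRUE   # now only cell5-year2002 missing
  inc <- incidence_from_matrix(m)
  expect_equal(select_core(inc, 0.04, denominator = "rectangle")$objective, 25)
  expect_equal(select_core(inc, 0.04, denominator = "matrix")$objective, 25)
})

test_that("hex flags mark hauls outside the retained rectangle", {
  h <- worked_hauls()
  flags <- flag_hauls_hex(survey_dataset(h, make_catch(haul_id = "H01")),
                          resolutions = 7, thresholds = 0,
                          assign_fun = fake_assign)
  j <- dplyr::left_join(flags, h[, c("haul_id", "latitude", "year")], "haul_id")
  # flagged iff cell C (lat 12) or year 2003
  expect_equal(j$flag_hex_r7_t0,
               floor(j$latitude) == 12 | j$year == 2003)
  # the (B, 2002) haul is retained; (B, 2003) would be flagged were it present
  expect_false(j$flag_hex_r7_t0[j$haul_id == "H05"])
})

test_that("a dense complete survey raises no hex flags at any setting", {
  sim <- generate_survey(sim_config(seed = 19, transient_cells = 0))
  flags <- flag_hauls_hex(sim$dataset)
  expect_equal(sum(flags$flag_hex_r7_t0), 0)
  expect_equal(sum(flags$flag_hex_r8_t0), 0)
  expect_equal(sum(flags$flag_hex_r7_t2), 0)
  expect_equal(sum(flags$flag_hex_r8_t2), 0)
})

test_that("relaxing the budget never flags more hauls", {
  set.seed(61)
  for (k in 1:10) {
    m <- random_incidence(5, 5, p = 0.7)
    if (!any(m)) next
    hauls <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j]) {
        hauls <- dplyr::bind_rows(hauls, make_haul(
          haul_id = sprintf("h%d%d", i, j), latitude = 9.5 + i,
          longitude = 3, year = 2000 + j))
      }
    }
    d <- survey_dataset(hauls, make_catch(haul_id = hauls$haul_id[1]))
    fl <- flag_hauls_hex(d, resolutions = 7, thresholds = c(0, 0.02),
                         assign_fun = fake_assign)
    expect_gte(sum(fl$flag_hex_r7_t0), sum(fl$flag_hex_r7_t2))
  }
})

test_that("BioTIME binning uses fifth-of-range half-open cells", {
  ext <- list(lat = c(50, 55), lon = c(0, 10))
  expect_equal(assign_biotime_cells(52.3, 3.7, ext), "bt:2:1")
  expect_equal(assign_biotime_cells(55, 10, ext), "bt:4:4")  # clamped
  expect_equal(assign_biotime_cells(50, 0, ext), "bt:0:0")
  # degenerate extent: a single cell
  expect_equal(unique(assign_biotime_cells(rep(54, 5), rep(3, 5))), "bt:0:0")
})

test_that("the BioTIME rule flags sparse cell-years and short cell series", {
  # one cell, 12 years with 4 hauls and one year with 3
  mk <- function(years, per_year) {
    rows <- tidyr::expand_grid(year = years, k = seq_len(per_year))
    make_haul(haul_id = sprintf("H%03d", seq_len(nrow(rows))),
              latitude = 54, longitude = 3, year = rows$year)
  }
  d <- survey_dataset(mk(2001:2012, 4), make_catch(haul_id = "H001"))
  sparse <- make_haul(haul_id = c("S1", "S2", "S3"), latitude = 54,
                      longitude = 3, year = 2013)
  d2 <- survey_dataset(dplyr::bind_rows(d$hauls, sparse),
                       make_catch(haul_id = "H001"))
  fl <- flag_hauls_biotime(d2)
  # the 3-haul year is flagged, the twelve 4-haul years are not
  expect_true(all(fl$flag_biotime[fl$haul_id %in% c("S1", "S2", "S3")]))
  expect_false(any(fl$flag_biotime[!fl$haul_id %in% c("S1", "S2", "S3")]))

  # 9 qualifying years only -> every haul in the cell flagged
  d9 <- survey_dataset(mk(2001:2009, 4), make_catch(haul_id = "H001"))
  expect_true(all(flag_hauls_biotime(d9)$flag_biotime))
})

test_that("combine_flags yields exactly five flags per haul plus a summary", {
  sim <- generate_survey(sim_config(seed = 23, n_years = 12, core_cells = 4,
                                    transient_cells = 2))
  flags <- combine_flags(sim$dataset)
  expect_equal(nrow(flags), nrow(sim$dataset$hauls))
  flag_cols <- grep("^flag_", names(flags), value = TRUE)
  expect_setequal(flag_cols, c("flag_hex_r7_t0", "flag_hex_r8_t0",
                               "flag_hex_r7_t2", "flag_hex_r8_t2",
                               "flag_biotime"))
  expect_false(anyNA(flags[, flag_cols]))
  # conservation: flagged + unflagged = all filtered hauls, per method
  for (cl in flag_cols) {
    expect_equal(sum(flags[[cl]]) + sum(!flags[[cl]]), nrow(sim$dataset$hauls))
  }
  s <- flag_summary(flags)
  expect_equal(s$n_hauls, nrow(flags))
  got <- s$flag_hex_r7_t0
  expect_equal(got, round(100 * mean(flags$flag_hex_r7_t0), 1))
})

test_that("incidence diagnostics mark retained and flagged cell-years", {
  h <- worked_hauls()
  inc <- build_incidence(h, fake_assign(h$latitude, NULL, 7))
  core <- select_core(inc, 0)
  path <- tempfile(fileext = ".csv")
  write_incidence_diagnostic(inc, core, path)
  diag <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(dim(diag), c(3, 4))
  expect_equal(diag$`2001`, c("1", "1", "x"))
  expect_equal(diag$`2003`, c("x", ".", "."))
})
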