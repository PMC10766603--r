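# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no data files ship with the package.

make_haul <- function(haul_id = "H1", latitude = 54.2, longitude = 3.1,
                      year = 2010, month = 2, day = 14, gear = "GOV",
                      gear_category = "otter", haul_dur = 30,
                      area_swept = NA_real_, quality_flag = "valid", ...) {
  tibble::tibble(haul_id = haul_id, survey = "TST", survey_unit = "TST-1",
                 latitude = latitude, longitude = longitude, year = year,
                 month = month, day = day, gear = gear,
                 gear_category = gear_category, haul_dur = haul_dur,
                 area_swept = area_swept, quality_flag = quality_flag, ...)
}

make_catch <- function(haul_id = "H1", verbatim_name = "Gadus morhua",
                       num = 10, wgt = 5, ...) {
  tibble::tibble(haul_id = haul_id, verbatim_name = verbatim_name,
                 num = num, wgt = wgt, ...)
}

# small single-unit dataset: 3 hauls over 3 years, 2 taxa
fixture_dataset <- function() {
  hauls <- make_haul(haul_id = c("H1", "H2", "H3"),
                     latitude = c(54.2, 54.3, 54.4),
                     longitude = c(3.1, 3.2, 3.3),
                     year = c(2010, 2011, 2012),
                     area_swept = c(0.05, 0.06, 0.055))
  catches <- make_catch(haul_id = c("H1", "H1", "H2", "H3"),
                        verbatim_name = c("Gadus morhua", "Argentina silus",
                                          "Gadus morhua", "Gadus morhua"),
                        num = c(10, 3, 8, 12), wgt = c(5, 0.5, 4, 6))
  survey_dataset(hauls, catches)
}

fixture_backbone <- function() {
  tibble::tribble(
    ~name, ~taxon_id, ~status, ~accepted_taxon_id, ~accepted_name, ~rank,
    ~class_name, ~spec_code, ~lw_a, ~lw_b,
    "Gadus morhua", 126436, "accepted", 126436, "Gadus morhua", "species",
    "Teleostei", 69, 0.0070, 3.08,
    "Glyptocephalus cynoglossus", 127136, "accepted", 127136,
    "Glyptocephalus cynoglossus", "species", "Teleostei", 516, 0.0042, 3.19,
    "Pleuronectes cynoglossus", 154372, "synonym", 127136,
    "Glyptocephalus cynoglossus", "species", "Teleostei", NA, NA, NA,
    "Argentina", 125885, "accepted", 125885, "Argentina", "genus",
    "Teleostei", NA, NA, NA,
    "Argentina silus", 126715, "accepted", 126715, "Argentina silus",
    "species", "Teleostei", 662, 0.0051, 3.12,
    "Squalus acanthias", 105923, "accepted", 105923, "Squalus acanthias",
    "species", "Elasmobranchii", 139, 0.0032, 3.09,
    "Crangon crangon", 107552, "accepted", 107552, "Crangon crangon",
    "species", "Malacostraca", NA, NA, NA)
}

fixture_aliases <- function() {
  tibble::tibble(survey_unit = "NS-IBTS",
                 verbatim_name = "Argentina silus",
                 accepted_name = "Argentina")
}

# write a flat survey table to a temp file and return its path
write_fixture_table <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

flat_fixture_lines <- function() {
  c("haul_id,survey,survey_unit,latitude,longitude,year,month,day,gear,gear_category,haul_dur,area_swept,quality_flag,verbatim_name,num,wgt",
    "H1,TST,TST-1,54.2,3.1,2010,2,14,GOV,otter,30,0.05,valid,Gadus morhua,10,5",
    "H1,TST,TST-1,54.2,3.1,2010,2,14,GOV,otter,30,0.05,valid,Argentina silus,3,0.5",
    "H2,TST,TST-1,54.3,3.2,2011,2,15,GOV,otter,32,0.06,valid,Gadus morhua,8,4")
}

# independent exhaustive search over sorted-marginal rectangles: direct
# recomputation of every rectangle's missing count, no cumulative sums
brute_core <- function(m, threshold, denominator = "rectangle") {
  cell_ord <- order(-rowSums(m), rownames(m))
  year_ord <- order(-colSums(m), colnames(m))
  ms <- m[cell_ord, year_ord, drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(ms))) {
    for (j in seq_len(ncol(ms))) {
      missing <- i * j - sum(ms[seq_len(i), seq_len(j)])
      denom <- if (denominator == "rectangle") i * j else length(m)
      if (missing <= threshold * denom + 1e-9) {
        better <- is.null(best) || i * j > best$obj ||
          (i * j == best$obj && j > best$j) ||
          (i * j == best$obj && j == best$j && i > best$i)
        if (better) best <- list(obj = i * j, i = i, j = j)
      }
    }
  }
  if (is.null(best)) best <- list(obj = 0, i = 0, j = 0)
  best
}

# random incidence matrix with lexicographically orderable dimnames
random_incidence <- function(nr, nc, p = 0.6) {
  m <- matrix(stats::runif(nr * nc) < p, nrow = nr,
              dimnames = list(sprintf("c%02d", seq_len(nr)),
                              sprintf("%d", 1000 + seq_len(nc))))
  m
}

incidence_from_matrix <- function(m) {
  hauls <- NULL
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j]) {
        hauls <- dplyr::bind_rows(hauls, tibble::tibble(
          haul_id = sprintf("h_%d_%d", i, j),
          cell = rownames(m)[i], year = as.integer(colnames(m)[j])))
      }
    }
  }
  build_incidence(hauls[, c("haul_id", "year")], hauls$cell)
}

# brute-force taxon-flag rule on one presence vector
brute_taxon_rule <- function(v) {
  transitions <- 0L
  for (k in seq_along(v)[-1]) {
    if (v[k] != v[k - 1]) transitions <- transitions + 1L
  }
  (mean(v) < 0.95) && (transitions < 4)
}
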