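#' Build the cell-year incidence structure of a survey unit
#'
#' A boolean matrix over observed grid cells (rows) and sampled years
#' (columns): an entry is `TRUE` when at least one haul fell in that grid
#' cell-year. Cells never sampled do not appear; years in which the survey
#' unit did not operate do not appear.
#'
#' @param hauls Haul tibble with `haul_id` and `year` (no absent years).
#' @param cells Character cell identifier per haul.
#' @param survey_unit Optional label stored on the result.
#' @return An `incidence_matrix`: list with `survey_unit`, `cells`, `years`,
#'   `sampled` (logical cells x years matrix) and `haul_index` (tibble
#'   `haul_id`, `cell`, `year`).
#' @export
build_incidence <- function(hauls, cells, survey_unit = NA_character_) {
  if (length(cells) != nrow(hauls)) {
    abort_domain("one cell id per haul is required")
  }
  if (anyNA(hauls$year)) abort_domain("hauls with absent year cannot be gridded")
  idx <- tibble(haul_id = hauls$haul_id, cell = as.character(cells),
                year = hauls$year)
  cell_ids <- sort(unique(idx$cell))
  years <- sort(unique(idx$year))
  sampled <- matrix(FALSE, nrow = length(cell_ids), ncol = length(years),
                    dimnames = list(cell_ids, as.character(years)))
  seen <- distinct(idx[, c("cell", "year")])
  sampled[cbind(match(seen$cell, cell_ids), match(seen$year, years))] <- TRUE
  structure(
    list(survey_unit = survey_unit, cells = cell_ids, years = years,
         sampled = sampled, haul_index = idx),
    class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix>\n")
  cat(sprintf("  %d cells x %d years, %.1f%% sampled\n",
              length(x$cells), length(x$years), 100 * mean(x$sampled)))
  invisible(x)
}

#' Select the largest consistently sampled cell-year core
#'
#' Orders cells by the number of years they were sampled and years by the
#' number of cells sampled (both descending, ties broken lexicographically
#' for determinism), then searches every top-i cells x top-j years rectangle
#' and returns the one maximizing the retained cell-year count i*j subject to
#' the missing budget: the fraction of unsampled entries may not exceed
#' `missing_threshold`. Ties prefer more years, then more cells. At threshold
#' 0 the retained rectangle is completely sampled.
#'
#' The unrestricted largest-complete-submatrix problem is NP-hard; the
#' sorted-rectangle family mirrors the ordered-axes construction used to
#' visualize survey coverage and is exactly solvable.
#'
#' @param incidence An `incidence_matrix`.
#' @param missing_threshold Allowed missing fraction, typically 0 or 0.02.
#' @param denominator Against what the missing budget is counted:
#'   `"rectangle"` (default; entries of the candidate rectangle) or
#'   `"matrix"` (all cell-years of the survey unit's full matrix).
#' @return A `core_selection`: `retained_cells`, `retained_years`,
#'   `missing_fraction` (of the retained rectangle), `objective` (retained
#'   cell-year count), plus the settings used.
#' @export
select_core <- function(incidence, missing_threshold = 0,
                        denominator = c("rectangle", "matrix")) {
  stopifnot(inherits(incidence, "incidence_matrix"))
  denominator <- match.arg(denominator)
  m <- incidence$sampled
  if (length(m) == 0) abort_domain("incidence matrix is empty")
  cell_cov <- rowSums(m)
  year_cov <- colSums(m)
  cell_ord <- order(-cell_cov, incidence$cells)
  year_ord <- order(-year_cov, incidence$years)
  ms <- m[cell_ord, year_ord, drop = FALSE]
  nr <- nrow(ms); nc <- ncol(ms)
  # cumulative sampled count of every top-i x top-j rectangle
  cum <- matrix(apply(ms, 2, cumsum), nrow = nr)
  cum <- matrix(t(apply(cum, 1, cumsum)), nrow = nr)
  best <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      missing <- i * j - cum[i, j]
      denom <- if (denominator == "rectangle") i * j else nr * nc
      if (missing <= missing_threshold * denom + 1e-9) {
        cand <- c(obj = i * j, i = i, j = j, missing = missing)
        if (is.null(best) ||
            cand["obj"] > best["obj"] ||
            (cand["obj"] == best["obj"] && cand["j"] > best["j"]) ||
            (cand["obj"] == best["obj"] && cand["j"] == best["j"] &&
               cand["i"] > best["i"])) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    # only possible under the matrix denominator with a tight budget
    best <- c(obj = 0, i = 0, j = 0, missing = 0)
  }
  i <- best[["i"]]; j <- best[["j"]]
  structure(
    list(
      retained_cells = incidence$cells[cell_ord][seq_len(i)],
      retained_years = incidence$years[year_ord][seq_len(j)],
      missing_fraction = if (i * j == 0) 0 else best[["missing"]] / (i * j),
      objective = best[["obj"]],
      missing_threshold = missing_threshold,
      denominator = denominator),
    class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat("<core_selection>\n")
  cat(sprintf("  retained: %d cells x %d years (objective %d cell-years)\n",
              length(x$retained_cells), length(x$retained_years), x$objective))
  cat(sprintf("  missing fraction %.4f at threshold %.2f (%s denominator)\n",
              x$missing_fraction, x$missing_threshold, x$denominator))
  invisible(x)
}

hex_flag_name <- function(resolution, threshold) {
  sprintf("flag_hex_r%d_t%d", resolution, round(100 * threshold))
}

#' Hexagonal cell-year footprint flags
#'
#' For each (resolution, threshold) setting — by default resolutions 7 and 8
#' crossed with missing thresholds 0% and 2% — hauls are gridded with
#' `assign_fun`, the cell-year core is selected with [select_core()], and a
#' haul is flagged when its cell is not retained or its year is not retained.
#' Each survey unit is gridded and flagged separately.
#'
#' @param d A filtered `survey_dataset`.
#' @param resolutions Integer grid resolutions.
#' @param thresholds Missing-fraction thresholds.
#' @param assign_fun Cell-assignment backend,
#'   `function(latitude, longitude, resolution) -> cell ids`
#'   (default [assign_hex_cells()]).
#' @param denominator Passed to [select_core()].
#' @return Tibble: `haul_id`, `survey_unit`, and one logical flag column per
#'   setting (`TRUE` = flagged for removal), e.g. `flag_hex_r7_t0`.
#' @export
flag_hauls_hex <- function(d, resolutions = c(7L, 8L), thresholds = c(0, 0.02),
                           assign_fun = assign_hex_cells,
                           denominator = "rectangle") {
  stopifnot(is_survey_dataset(d))
  hauls <- d$hauls
  if (anyNA(hauls$latitude) || anyNA(hauls$longitude) || anyNA(hauls$year)) {
    abort_domain("hauls with absent coordinates or year; apply quality filters first")
  }
  purrr::map(split(hauls, hauls$survey_unit), function(h) {
    out <- tibble(haul_id = h$haul_id, survey_unit = h$survey_unit)
    for (res in resolutions) {
      cells <- assign_fun(h$latitude, h$longitude, res)
      inc <- build_incidence(h, cells, survey_unit = h$survey_unit[1])
      for (th in thresholds) {
        core <- select_core(inc, missing_threshold = th,
                            denominator = denominator)
        out[[hex_flag_name(res, th)]] <-
          !(cells %in% core$retained_cells) | !(h$year %in% core$retained_years)
      }
    }
    out
  }) %>% bind_rows()
}

#' BioTIME-style footprint flag
#'
#' Hauls are binned on a 5x5 rectangular grid spanning the survey unit's
#' latitude/longitude extent ([assign_biotime_cells()]). A haul is flagged
#' when (stage 1) its grid cell-year holds fewer than `min_per_year` hauls —
#' sparse cell-years are sampling noise — or (stage 2) its cell has fewer
#' than `min_years` years each meeting the stage-1 rule, the shortest series
#' considered usable for temporal analysis. Haul events are counted, not
#' distinct coordinates.
#'
#' @param d A filtered `survey_dataset`.
#' @param min_per_year Minimum hauls per cell-year (default 4).
#' @param min_years Minimum qualifying years per cell (default 10).
#' @return Tibble: `haul_id`, `survey_unit`, `flag_biotime` (logical).
#' @export
flag_hauls_biotime <- function(d, min_per_year = 4, min_years = 10) {
  stopifnot(is_survey_dataset(d))
  hauls <- d$hauls
  if (anyNA(hauls$latitude) || anyNA(hauls$longitude) || anyNA(hauls$year)) {
    abort_domain("hauls with absent coordinates or year; apply quality filters first")
  }
  purrr::map(split(hauls, hauls$survey_unit), function(h) {
    cells <- assign_biotime_cells(h$latitude, h$longitude)
    idx <- tibble(haul_id = h$haul_id, survey_unit = h$survey_unit,
                  cell = cells, year = h$year)
    per_cy <- idx %>% count(cell, year, name = "n_hauls")
    per_cell <- per_cy %>%
      group_by(cell) %>%
      summarise(n_years_ok = sum(n_hauls >= min_per_year), .groups = "drop")
    idx %>%
      left_join(per_cy, by = c("cell", "year")) %>%
      left_join(per_cell, by = "cell") %>%
      mutate(flag_biotime = n_hauls < min_per_year | n_years_ok < min_years) %>%
      select(haul_id, survey_unit, flag_biotime)
  }) %>% bind_rows()
}

#' Combine the five footprint flags per haul
#'
#' Runs both flagging methods — the four hexagonal cell-year settings and the
#' BioTIME-style grid rule — and returns one row per filtered haul with
#' exactly five logical flags.
#'
#' @param d A filtered `survey_dataset`.
#' @param ... Passed on to [flag_hauls_hex()].
#' @return Tibble: `haul_id`, `survey_unit`, `flag_hex_r7_t0`,
#'   `flag_hex_r8_t0`, `flag_hex_r7_t2`, `flag_hex_r8_t2`, `flag_biotime`.
#' @export
combine_flags <- function(d, ...) {
  hex <- flag_hauls_hex(d, ...)
  bio <- flag_hauls_biotime(d)
  out <- full_join(hex, bio, by = c("haul_id", "survey_unit"))
  flag_cols <- grep("^flag_", names(out), value = TRUE)
  if (length(flag_cols) != 5 || anyNA(out[, flag_cols]) ||
      nrow(out) != nrow(d$hauls)) {
    abort_integrity("flag methods did not produce five flags for every haul")
  }
  out
}

#' Per-survey-unit flagged-haul percentages
#'
#' @param flags Flag tibble from [combine_flags()].
#' @return Tibble with `survey_unit`, `n_hauls`, and the percentage of
#'   flagged hauls per flag column, rounded to one decimal.
#' @export
flag_summary <- function(flags) {
  flag_cols <- grep("^flag_", names(flags), value = TRUE)
  flags %>%
    group_by(survey_unit) %>%
    summarise(n_hauls = n(),
              across(all_of(flag_cols), ~ round(100 * mean(.x), 1)),
              .groups = "drop")
}

#' Write an incidence-matrix diagnostic table
#'
#' A delimited cells x years view of the sampling structure with markers:
#' `1` sampled and retained, `0` unsampled but in the retained rectangle,
#' `x` sampled outside the retained rectangle, `.` unsampled outside it.
#'
#' @param incidence An `incidence_matrix`.
#' @param core A `core_selection` for the same matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_diagnostic <- function(incidence, core, path) {
  m <- incidence$sampled
  out <- matrix(".", nrow = nrow(m), ncol = ncol(m))
  in_rect <- outer(incidence$cells %in% core$retained_cells,
                   incidence$years %in% core$retained_years, `&`)
  out[m & in_rect] <- "1"
  out[!m & in_rect] <- "0"
  out[m & !in_rect] <- "x"
  df <- as_tibble(as.data.frame(out), .name_repair = "minimal")
  names(df) <- as.character(incidence$years)
  df <- bind_cols(tibble(cell = incidence$cells), df)
  readr::write_delim(df, path, delim = ",")
  invisible(path)
}
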