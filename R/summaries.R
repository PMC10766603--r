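#' Per-survey summary of sampling and catch characteristics
#'
#' The standard technical-validation view of a processed survey: hauls per
#' year, per-year distributions of the sampling and biological variables,
#' yearly trends of the most abundant taxa, and flag percentages.
#'
#' @param d A processed `survey_dataset` (rates computed).
#' @param flags Optional footprint-flag tibble from [combine_flags()].
#' @param taxon_flags Optional tibble from [flag_taxa()].
#' @param n_top Number of most-abundant taxa to track (default 6). Taxa are
#'   ranked by total abundance across years, falling back to total weight for
#'   weight-only surveys.
#' @return A `survey_summary` list: `hauls_per_year`,
#'   `variable_distributions` (long tibble of per-year quantiles),
#'   `top_taxa_trends` (yearly mean rate per top taxon), `flag_percentages`.
#' @export
summarize_survey <- function(d, flags = NULL, taxon_flags = NULL, n_top = 6) {
  stopifnot(is_survey_dataset(d))
  hauls <- d$hauls
  hauls_per_year <- hauls %>%
    count(survey_unit, year, name = "n_hauls") %>%
    arrange(survey_unit, year)

  catches <- d$catches %>%
    left_join(hauls[, c("haul_id", "survey_unit", "year")], by = "haul_id")

  haul_vars <- hauls %>%
    select(survey_unit, year, area_swept, haul_dur, depth) %>%
    tidyr::pivot_longer(c(area_swept, haul_dur, depth),
                        names_to = "variable", values_to = "value")
  catch_vars <- catches %>%
    select(survey_unit, year, num_cpue, wgt_cpue, num_cpua, wgt_cpua) %>%
    tidyr::pivot_longer(c(num_cpue, wgt_cpue, num_cpua, wgt_cpua),
                        names_to = "variable", values_to = "value")
  variable_distributions <- bind_rows(haul_vars, catch_vars) %>%
    group_by(survey_unit, year, .data$variable) %>%
    summarise(
      n = sum(!is.na(.data$value)),
      q05 = quantile(.data$value, 0.05, na.rm = TRUE, names = FALSE),
      q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q50 = quantile(.data$value, 0.50, na.rm = TRUE, names = FALSE),
      q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      q95 = quantile(.data$value, 0.95, na.rm = TRUE, names = FALSE),
      .groups = "drop")

  use_num <- any(!is.na(catches$num))
  rank_col <- if (use_num) "num" else "wgt"
  rate_col <- if (use_num) "num_cpue" else "wgt_cpue"
  totals <- catches %>%
    filter(!is.na(accepted_name)) %>%
    group_by(survey_unit, accepted_name) %>%
    summarise(total = sum_na(.data[[rank_col]]), .groups = "drop") %>%
    group_by(survey_unit) %>%
    arrange(dplyr::desc(.data$total), accepted_name, .by_group = TRUE) %>%
    slice(seq_len(n_top)) %>%
    ungroup()
  top_taxa_trends <- catches %>%
    semi_join(totals, by = c("survey_unit", "accepted_name")) %>%
    group_by(survey_unit, accepted_name, year) %>%
    summarise(mean_rate = mean(.data[[rate_col]], na.rm = TRUE),
              .groups = "drop") %>%
    mutate(rate = rate_col)

  flag_percentages <- NULL
  if (!is.null(flags)) flag_percentages <- flag_summary(flags)
  if (!is.null(taxon_flags)) {
    taxon_pct <- taxon_flags %>%
      group_by(survey_unit) %>%
      summarise(pct_taxa_flagged = round(
        100 * mean(flag_taxon, na.rm = TRUE), 1), .groups = "drop")
    flag_percentages <- if (is.null(flag_percentages)) taxon_pct else
      full_join(flag_percentages, taxon_pct, by = "survey_unit")
  }

  structure(
    list(hauls_per_year = hauls_per_year,
         variable_distributions = variable_distributions,
         top_taxa_trends = top_taxa_trends,
         flag_percentages = flag_percentages),
    class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("<survey_summary>\n")
  tot <- sum(x$hauls_per_year$n_hauls)
  yrs <- range(x$hauls_per_year$year)
  cat(sprintf("  %d hauls over %d-%d\n", tot, yrs[1], yrs[2]))
  cat(sprintf("  top taxa: %s\n",
              paste(unique(x$top_taxa_trends$accepted_name), collapse = ", ")))
  if (!is.null(x$flag_percentages)) {
    print(x$flag_percentages)
  }
  invisible(x)
}

#' Write a survey summary as delimited tables plus a plain-text report
#'
#' @param s A `survey_summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_summary <- function(s, dir) {
  stopifnot(inherits(s, "survey_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(s$hauls_per_year, file.path(dir, "hauls_per_year.csv"))
  readr::write_csv(s$variable_distributions,
                   file.path(dir, "variable_distributions.csv"))
  readr::write_csv(s$top_taxa_trends, file.path(dir, "top_taxa_trends.csv"))
  if (!is.null(s$flag_percentages)) {
    readr::write_csv(s$flag_percentages, file.path(dir, "flag_percentages.csv"))
  }
  report <- c(
    "survey summary report",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("total hauls: %d", sum(s$hauls_per_year$n_hauls)),
    sprintf("years: %d-%d", min(s$hauls_per_year$year),
            max(s$hauls_per_year$year)),
    sprintf("top taxa: %s",
            paste(unique(s$top_taxa_trends$accepted_name), collapse = ", ")))
  writeLines(report, file.path(dir, "report.txt"))
  invisible(dir)
}
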