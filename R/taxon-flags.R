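#' Build per-taxon yearly presence series for a survey unit
#'
#' For each accepted taxon, a boolean sequence over the years the survey unit
#' actually sampled (years with no hauls at all are excluded, so no
#' artificial transitions are created across gaps). A taxon is present in a
#' year when any haul of that year records a strictly positive abundance or
#' weight for it — null (zero) catches indicate absence.
#'
#' @param d A harmonized, aggregated `survey_dataset`.
#' @param survey_unit Survey-unit code; default uses the only unit present.
#' @return A `presence_series` tibble: one row per (taxon, sampled year) with
#'   columns `survey_unit`, `taxon`, `year`, `present`, ordered by year.
#' @export
build_presence_series <- function(d, survey_unit = NULL) {
  stopifnot(is_survey_dataset(d))
  if (is.null(survey_unit)) {
    units <- unique(d$hauls$survey_unit)
    if (length(units) != 1) {
      abort_domain("dataset has multiple survey units; pass survey_unit explicitly")
    }
    survey_unit <- units
  }
  hauls <- d$hauls[d$hauls$survey_unit %in% survey_unit, ]
  years <- sort(unique(hauls$year[!is.na(hauls$year)]))
  if (length(years) < 2) {
    warning(sprintf("survey unit '%s' has %d sampled year(s); flagging will be skipped",
                    survey_unit, length(years)), call. = FALSE)
  }
  catches <- d$catches[d$catches$haul_id %in% hauls$haul_id &
                         !is.na(d$catches$accepted_name), ]
  catches <- left_join(catches, hauls[, c("haul_id", "year")], by = "haul_id")
  pos <- catches[(!is.na(catches$num) & catches$num > 0) |
                   (!is.na(catches$wgt) & catches$wgt > 0), ]
  taxa <- sort(unique(catches$accepted_name))
  grid <- tidyr::expand_grid(taxon = taxa, year = years)
  seen <- distinct(tibble(taxon = pos$accepted_name, year = pos$year))
  seen$present <- TRUE
  out <- grid %>%
    left_join(seen, by = c("taxon", "year")) %>%
    mutate(present = !is.na(present),
           survey_unit = .env$survey_unit) %>%
    select(survey_unit, taxon, year, present) %>%
    arrange(taxon, year)
  class(out) <- c("presence_series", class(out))
  out
}

#' Count presence transitions in a boolean sequence
#'
#' A transition is an adjacent change between present and absent (either
#' direction).
#'
#' @param present Logical (or 0/1) vector, ordered by year; length >= 1.
#' @return Integer number of adjacent unequal pairs.
#' @export
#' @examples
#' count_transitions(c(TRUE, FALSE, TRUE, FALSE))  # 3
count_transitions <- function(present) {
  if (length(present) == 0) abort_domain("presence sequence must be non-empty")
  present <- as.logical(present)
  if (anyNA(present)) abort_domain("presence sequence must not contain NA")
  sum(present[-1] != present[-length(present)])
}

#' Flag taxa with temporally inconsistent identification
#'
#' A taxon is flagged when it was present in less than 95% of the sampled
#' years AND its presence shifted between present and absent fewer than four
#' times over the series (both inequalities strict). Few transitions with low
#' presence suggest a naming-convention change (for example a species/genus
#' protocol switch) rather than genuine ecological turnover; high-transition
#' low-presence taxa are plausibly just rare. Both statistics are reported so
#' users can re-derive other rules.
#'
#' @param series A `presence_series` from [build_presence_series()].
#' @param presence_threshold Presence fraction below which a taxon may be
#'   flagged (default 0.95).
#' @param max_transitions Transition count below which a taxon may be flagged
#'   (default 4).
#' @return A tibble: `survey_unit`, `taxon`, `presence_fraction`,
#'   `n_transitions`, `flag_taxon`. Survey units with fewer than two sampled
#'   years return `flag_taxon = NA` (flagging skipped).
#' @export
flag_taxa <- function(series, presence_threshold = 0.95, max_transitions = 4) {
  stopifnot(all(c("survey_unit", "taxon", "year", "present") %in% names(series)))
  out <- series %>%
    group_by(survey_unit, taxon) %>%
    arrange(year, .by_group = TRUE) %>%
    summarise(
      presence_fraction = mean(present),
      n_transitions = count_transitions(present),
      n_years = n(),
      .groups = "drop") %>%
    mutate(flag_taxon = ifelse(
      .data$n_years < 2, NA,
      presence_fraction < presence_threshold &
        n_transitions < max_transitions)) %>%
    select(-"n_years")
  out
}
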