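#' Validate a single haul against the mandatory-field rules
#'
#' A haul usable for standardized analysis needs precise geolocation (latitude
#' and longitude present and within bounds), a full calendar date, a gear
#' code, and at least one effort measure (haul duration or swept area).
#' Catch/taxonomy presence is a dataset-level rule checked by
#' [apply_quality_filters()].
#'
#' @param h A one-row data frame or named list with haul fields.
#' @return Character vector of violated-rule labels, empty when the haul
#'   passes: `"geolocation"`, `"date"`, `"gear"`, `"effort"`.
#' @export
#' @examples
#' validate_haul(list(latitude = 54, longitude = 3, year = 2001, month = 2,
#'                    day = 14, gear = "GOV", haul_dur = 30))
validate_haul <- function(h) {
  h <- as.list(h)
  miss <- function(x) is.null(x) || length(x) == 0 || is.na(x)
  out <- character()
  if (miss(h$latitude) || miss(h$longitude) ||
      (!miss(h$latitude) && abs(h$latitude) > 90) ||
      (!miss(h$longitude) && abs(h$longitude) > 180)) {
    out <- c(out, "geolocation")
  }
  if (miss(h$year) || miss(h$month) || miss(h$day)) out <- c(out, "date")
  if (miss(h$gear)) out <- c(out, "gear")
  if (miss(h$haul_dur) && miss(h$area_swept)) out <- c(out, "effort")
  out
}

# vectorized rule evaluation over a haul tibble; one logical column per rule
haul_rule_matrix <- function(hauls) {
  tibble(
    haul_id = hauls$haul_id,
    geolocation = is.na(hauls$latitude) | is.na(hauls$longitude) |
      abs(hauls$latitude) > 90 | abs(hauls$longitude) > 180,
    date = is.na(hauls$year) | is.na(hauls$month) | is.na(hauls$day),
    gear = is.na(hauls$gear),
    effort = is.na(hauls$haul_dur) & is.na(hauls$area_swept)
  )
}

#' Apply the haul and catch quality filters
#'
#' Removes hauls marked invalid by the source survey's own quality flag,
#' hauls not sampled with otter-trawl gear, hauls failing [validate_haul()],
#' and hauls whose catch records carry neither abundance nor weight. Catch
#' records with negative abundance or weight are integrity violations and are
#' removed (null, i.e. zero, catches are kept). Every removal is accounted
#' for in the returned report.
#'
#' @param d A `survey_dataset`.
#' @return A list with elements `dataset` (the filtered `survey_dataset`) and
#'   `report` (a `filter_report`: `n_in`, `n_out` haul counts and a `removals`
#'   tibble with columns `haul_id`, `key`, `rule`, `level`).
#' @export
apply_quality_filters <- function(d) {
  stopifnot(is_survey_dataset(d))
  hauls <- d$hauls
  catches <- d$catches
  n_in <- nrow(hauls)
  removals <- tibble(haul_id = character(), key = character(),
                     rule = character(), level = character())

  # catch-level integrity: negative values
  neg <- (!is.na(catches$num) & catches$num < 0) |
    (!is.na(catches$wgt) & catches$wgt < 0)
  if (any(neg)) {
    removals <- bind_rows(removals, tibble(
      haul_id = catches$haul_id[neg],
      key = paste(catches$haul_id[neg], catches$verbatim_name[neg], sep = ":"),
      rule = "negative_value", level = "catch"))
    catches <- catches[!neg, , drop = FALSE]
  }

  # haul-level rules
  rules <- haul_rule_matrix(hauls)
  flagged <- list(
    invalid = !is.na(hauls$quality_flag) & hauls$quality_flag == "invalid",
    gear = is.na(hauls$gear_category) | hauls$gear_category != "otter",
    geolocation = rules$geolocation,
    date = rules$date,
    effort = rules$effort
  )
  # catch presence: at least one record with num or wgt present
  with_catch <- unique(catches$haul_id[!is.na(catches$num) | !is.na(catches$wgt)])
  flagged$catch <- !(hauls$haul_id %in% with_catch)

  for (rule in names(flagged)) {
    idx <- which(flagged[[rule]])
    if (length(idx) > 0) {
      removals <- bind_rows(removals, tibble(
        haul_id = hauls$haul_id[idx], key = hauls$haul_id[idx],
        rule = rule, level = "haul"))
    }
  }
  drop_ids <- unique(removals$haul_id[removals$level == "haul"])
  hauls_out <- hauls[!(hauls$haul_id %in% drop_ids), , drop = FALSE]
  catches_out <- catches[catches$haul_id %in% hauls_out$haul_id, , drop = FALSE]

  if (nrow(hauls_out) == 0 && n_in > 0) {
    warning("no hauls remain after quality filtering", call. = FALSE)
  }
  report <- structure(
    list(n_in = n_in, n_out = nrow(hauls_out), removals = removals),
    class = "filter_report")
  out <- survey_dataset(hauls_out, catches_out, d$provenance)
  out <- sd_log(out, sprintf(
    "quality filters: %d of %d hauls retained (%d haul removals, %d catch removals)",
    report$n_out, report$n_in,
    length(drop_ids), sum(removals$level == "catch")))
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  hauls in/out: %d / %d\n", x$n_in, x$n_out))
  if (nrow(x$removals) > 0) {
    tab <- count(x$removals, .data$level, .data$rule)
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %s removals [%s]: %d\n",
                  tab$level[i], tab$rule[i], tab$n[i]))
    }
  } else {
    cat("  no removals\n")
  }
  invisible(x)
}
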