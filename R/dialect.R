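#' Canonical survey-table column dialect
#'
#' A survey table is a delimited text file with one row per taxon per haul.
#' Haul-level columns are repeated on every row of the same haul; catch-level
#' columns differ row by row. `survey_dialect()` returns the canonical
#' (snake_case) column names; a user-supplied rename map translates other
#' dialects at read time.
#'
#' @return A named list with character vectors `haul`, `catch`, `mandatory`
#'   and `numeric`: the haul-level columns, the catch-level columns, the
#'   columns that must be resolvable in an input file, and the columns parsed
#'   as numbers.
#' @export
#' @examples
#' survey_dialect()$mandatory
survey_dialect <- function() {
  haul <- c(
    "haul_id", "survey", "survey_unit", "latitude", "longitude",
    "year", "month", "day", "quarter", "season",
    "station", "stratum", "stat_rec", "country", "continent", "vessel",
    "depth", "gear", "gear_category",
    "haul_dur", "distance", "speed", "gear_opening", "sweep_length",
    "area_swept", "quality_flag"
  )
  catch <- c(
    "haul_id", "verbatim_name", "verbatim_aphia_id", "accepted_name",
    "aphia_id", "rank", "class_name", "spec_code",
    "num", "wgt", "num_cpue", "wgt_cpue", "num_cpua", "wgt_cpua"
  )
  list(
    haul = haul,
    catch = catch,
    mandatory = c("haul_id", "survey", "survey_unit", "latitude", "longitude",
                  "year", "verbatim_name"),
    numeric = c("latitude", "longitude", "year", "month", "day", "quarter",
                "depth", "haul_dur", "distance", "speed", "gear_opening",
                "sweep_length", "area_swept", "verbatim_aphia_id", "aphia_id",
                "spec_code", "num", "wgt", "num_cpue", "wgt_cpue",
                "num_cpua", "wgt_cpua")
  )
}

# condition helpers ---------------------------------------------------------

trawlr_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "trawlr_error"), ...)
}

abort_schema    <- function(msg, ...) trawlr_abort("trawlr_schema_error", msg, ...)
abort_integrity <- function(msg, ...) trawlr_abort("trawlr_integrity_error", msg, ...)
abort_domain    <- function(msg, ...) trawlr_abort("trawlr_domain_error", msg, ...)
abort_config    <- function(msg, ...) trawlr_abort("trawlr_config_error", msg, ...)
abort_fit       <- function(msg, ...) trawlr_abort("trawlr_fit_error", msg, ...)
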