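#' Construct a survey dataset
#'
#' The central container: a table of hauls (one row per sampling event), a
#' table of catches (one row per taxon per haul) and a line-oriented
#' processing log. Missing canonical columns are added filled with `NA` so
#' downstream operations can rely on the full dialect.
#'
#' @param hauls Data frame of haul-level records; must contain `haul_id`.
#' @param catches Data frame of catch records; must contain `haul_id` and
#'   `verbatim_name`.
#' @param provenance Character vector of processing-log lines.
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(hauls, catches, provenance = character()) {
  dial <- survey_dialect()
  hauls <- complete_columns(as_tibble(hauls), dial$haul, dial$numeric)
  catches <- complete_columns(as_tibble(catches), dial$catch, dial$numeric)
  if (anyDuplicated(hauls$haul_id)) {
    dup <- unique(hauls$haul_id[duplicated(hauls$haul_id)])
    abort_integrity(sprintf(
      "duplicate haul_id with conflicting haul attributes: %s",
      paste(head(dup, 5), collapse = ", ")))
  }
  orphan <- setdiff(catches$haul_id, hauls$haul_id)
  if (length(orphan) > 0) {
    abort_integrity(sprintf(
      "catch records reference unknown haul_id: %s",
      paste(head(orphan, 5), collapse = ", ")))
  }
  structure(
    list(hauls = hauls, catches = catches,
         provenance = as.character(provenance)),
    class = "survey_dataset")
}

complete_columns <- function(x, cols, numeric_cols) {
  for (cl in setdiff(cols, names(x))) {
    x[[cl]] <- if (cl %in% numeric_cols) NA_real_ else NA_character_
  }
  for (cl in intersect(cols, numeric_cols)) {
    if (!is.numeric(x[[cl]])) x[[cl]] <- as.numeric(x[[cl]])
  }
  for (cl in setdiff(cols, numeric_cols)) {
    if (!is.character(x[[cl]])) x[[cl]] <- as.character(x[[cl]])
  }
  x[, cols, drop = FALSE]
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat(sprintf("  hauls:   %d (%d survey unit%s)\n",
              nrow(x$hauls), n_distinct(x$hauls$survey_unit),
              if (n_distinct(x$hauls$survey_unit) == 1) "" else "s"))
  cat(sprintf("  catches: %d (%d verbatim name%s)\n",
              nrow(x$catches), n_distinct(x$catches$verbatim_name),
              if (n_distinct(x$catches$verbatim_name) == 1) "" else "s"))
  if (length(x$provenance)) {
    cat(sprintf("  log:     %d entr%s (last: %s)\n", length(x$provenance),
                if (length(x$provenance) == 1) "y" else "ies",
                utils::tail(x$provenance, 1)))
  }
  invisible(x)
}

#' @export
is_survey_dataset <- function(x) inherits(x, "survey_dataset")

# append a processing-log line
sd_log <- function(d, msg) {
  d$provenance <- c(d$provenance, msg)
  d
}

#' Retrieve the processing log of a survey dataset
#'
#' @param d A `survey_dataset`.
#' @return Character vector of log lines, oldest first.
#' @export
processing_log <- function(d) {
  stopifnot(is_survey_dataset(d))
  d$provenance
}
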