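#' Read a haul-level survey table
#'
#' Reads a delimited text file with one row per taxon per haul in the
#' canonical column dialect (see [survey_dialect()]) and splits it into haul
#' and catch tables. Files in other dialects are translated through `dialect`,
#' a named character vector `c(canonical_name = source_name)`. The delimiter
#' is comma by default; tab is detected from the header line.
#'
#' Unparseable numeric cells (for example `"n/a"`) become absent with a
#' warning and a processing-log entry; the row is retained. Rows whose
#' `verbatim_name` is empty contribute a haul but no catch record.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param dialect Optional named character vector renaming source columns to
#'   canonical names.
#' @param delim Field delimiter; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @return A [survey_dataset()].
#' @export
read_survey_table <- function(path, dialect = NULL, delim = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"), progress = FALSE,
    show_col_types = FALSE)
  if (!is.null(dialect)) {
    hit <- dialect[dialect %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- names(hit)
  }

  dial <- survey_dialect()
  missing_mand <- setdiff(dial$mandatory, names(raw))
  if (length(missing_mand) > 0) {
    abort_schema(sprintf("mandatory column(s) missing from %s: %s",
                         basename(path), paste(missing_mand, collapse = ", ")))
  }

  log <- sprintf("read %d rows from %s (md5 %s)", nrow(raw), basename(path),
                 unname(tools::md5sum(path)))
  for (cl in intersect(dial$numeric, names(raw))) {
    vals <- raw[[cl]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- !is.na(vals) & is.na(parsed)
    if (any(bad)) {
      warning(sprintf("column '%s': %d unparseable numeric cell(s) set to absent",
                      cl, sum(bad)), call. = FALSE)
      log <- c(log, sprintf("unparseable numeric cells in '%s': %d", cl, sum(bad)))
    }
    raw[[cl]] <- parsed
  }

  hauls <- distinct(raw[, intersect(dial$haul, names(raw)), drop = FALSE])
  catch_rows <- raw[!is.na(raw$verbatim_name),
                    intersect(dial$catch, names(raw)), drop = FALSE]
  survey_dataset(hauls, catch_rows, provenance = log)
}

#' Write a survey dataset as a flat delimited table
#'
#' Inverse of [read_survey_table()]: catch rows are joined back to their haul
#' attributes, hauls without catches are written as haul-only rows (empty
#' catch fields), and absent values are encoded as empty strings. Numbers are
#' written with shortest round-trip precision.
#'
#' @param d A `survey_dataset`.
#' @param path Output file path.
#' @param delim Field delimiter (`","` default, `"\t"` accepted).
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(d, path, delim = ",") {
  stopifnot(is_survey_dataset(d))
  dial <- survey_dialect()
  flat <- inner_join(d$hauls, d$catches, by = "haul_id")
  no_catch <- anti_join(d$hauls, d$catches, by = "haul_id")
  if (nrow(no_catch) > 0) flat <- bind_rows(flat, no_catch)
  ord <- unique(c(dial$haul, dial$catch))
  flat <- arrange(flat[, ord, drop = FALSE], haul_id, verbatim_name)
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}

#' Read a local taxonomic backbone table
#'
#' The backbone is a delimited snapshot of an external register (AphiaID-like
#' identifiers): columns `name`, `taxon_id`, `status` (accepted/synonym),
#' `accepted_taxon_id`, `accepted_name`, `rank`, `class_name`, and optional
#' `spec_code`, `lw_a`, `lw_b` (length-weight coefficients, weight in grams
#' for length in cm). The snapshot's md5 is recorded so runs can be pinned to
#' a backbone version.
#'
#' @param path Path to a delimited backbone table.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble with attribute `md5`; validated for synonym resolution
#'   (every synonym points at an accepted entry, accepted entries point at
#'   themselves).
#' @export
read_backbone <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  bb <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                          show_col_types = FALSE, progress = FALSE)
  need <- c("name", "taxon_id", "status", "accepted_taxon_id",
            "accepted_name", "rank", "class_name")
  missing <- setdiff(need, names(bb))
  if (length(missing) > 0) {
    abort_schema(sprintf("backbone is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  for (cl in c("spec_code", "lw_a", "lw_b")) {
    if (!cl %in% names(bb)) bb[[cl]] <- NA_real_
  }
  validate_backbone(bb)
  attr(bb, "md5") <- unname(tools::md5sum(path))
  bb
}

validate_backbone <- function(bb) {
  acc <- bb[bb$status == "accepted", ]
  if (any(acc$accepted_taxon_id != acc$taxon_id)) {
    abort_integrity("accepted backbone entries must have accepted_taxon_id == taxon_id")
  }
  syn <- bb[bb$status == "synonym", ]
  unresolved <- setdiff(syn$accepted_taxon_id, acc$taxon_id)
  if (length(unresolved) > 0) {
    abort_integrity(sprintf(
      "synonym accepted_taxon_id not resolvable to an accepted entry: %s",
      paste(head(unresolved, 5), collapse = ", ")))
  }
  invisible(bb)
}

#' Read a survey-specific alias table
#'
#' Aliases override backbone matching for known identification issues, for
#' example recording a species pair at genus rank when the field distinction
#' is unreliable. Columns: `survey_unit` (a survey-unit code or `"*"` for all
#' surveys), `verbatim_name`, `accepted_name` (the target name, which must
#' exist in the backbone when aliases are applied).
#'
#' @param path Path to a delimited alias table.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble of alias entries.
#' @export
read_alias_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  al <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                          show_col_types = FALSE, progress = FALSE)
  need <- c("survey_unit", "verbatim_name", "accepted_name")
  missing <- setdiff(need, names(al))
  if (length(missing) > 0) {
    abort_schema(sprintf("alias table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  al
}

#' Read a long-format length-composition table
#'
#' Abundance-at-length used for weight reconstruction: one row per
#' (haul, taxon, length bin) with columns `haul_id`, `taxon`, `length_cm`
#' (bin midpoint) and `count` (individuals, non-negative).
#'
#' @param path Path to a delimited table.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble.
#' @export
read_length_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  lc <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                          show_col_types = FALSE, progress = FALSE)
  need <- c("haul_id", "taxon", "length_cm", "count")
  missing <- setdiff(need, names(lc))
  if (length(missing) > 0) {
    abort_schema(sprintf("length table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (any(lc$length_cm <= 0, na.rm = TRUE) || any(lc$count < 0, na.rm = TRUE)) {
    abort_domain("length_cm must be positive and count non-negative")
  }
  lc
}
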