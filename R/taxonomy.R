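#' Fish taxonomic classes retained by default
#'
#' The five classes covering jawed fishes as sampled by bottom trawls:
#' sharks/rays, chimaeras, and the three actinopterygian grades.
#' Invertebrates are not consistently sampled across surveys and are dropped.
#'
#' @return Character vector of class names.
#' @export
fish_classes <- function() {
  c("Elasmobranchii", "Holocephali", "Chondrostei", "Holostei", "Teleostei")
}

norm_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# resolve a backbone row to its accepted entry (one step by invariant)
resolve_accepted <- function(entry, backbone) {
  if (entry$status == "accepted") return(entry)
  backbone[backbone$taxon_id == entry$accepted_taxon_id &
             backbone$status == "accepted", ][1, ]
}

#' Harmonize one verbatim taxon name against a local backbone
#'
#' Resolution order: (1) an alias entry for `(survey_unit, verbatim)` or
#' `("*", verbatim)`; (2) an exact identifier match on `verbatim_id`;
#' (3) an exact name match, case-insensitive and whitespace-normalized.
#' Synonyms resolve to their accepted entry. When the identifier and the name
#' resolve to different accepted taxa the identifier wins and the conflict is
#' reported. An unmatched name is signalled (`matched = FALSE`), never
#' silently kept.
#'
#' @param verbatim Taxon name as reported by the source survey.
#' @param verbatim_id Source taxon identifier (AphiaID-like), or `NA`.
#' @param backbone Backbone tibble from [read_backbone()].
#' @param aliases Optional alias tibble from [read_alias_table()].
#' @param survey_unit Survey-unit code used for alias scoping, or `NA`.
#' @return A list: `matched` (logical), `accepted_name`, `taxon_id`, `rank`,
#'   `class_name`, `spec_code`, `via` (`"alias"`, `"id"`, `"name"` or `NA`),
#'   `conflict` (logical; identifier and name disagreed).
#' @export
#' @examples
#' bb <- tibble::tibble(
#'   name = c("Gadus morhua"), taxon_id = 126436, status = "accepted",
#'   accepted_taxon_id = 126436, accepted_name = "Gadus morhua",
#'   rank = "species", class_name = "Teleostei",
#'   spec_code = 69, lw_a = 0.0070, lw_b = 3.08)
#' harmonize_name("gadus  morhua", NA, bb)$accepted_name
harmonize_name <- function(verbatim, verbatim_id = NA, backbone,
                           aliases = NULL, survey_unit = NA) {
  if (nrow(backbone) == 0) abort_domain("backbone is empty")
  unmatched <- list(matched = FALSE, accepted_name = NA_character_,
                    taxon_id = NA_real_, rank = NA_character_,
                    class_name = NA_character_, spec_code = NA_real_,
                    via = NA_character_, conflict = FALSE)
  as_result <- function(entry, via, conflict = FALSE) {
    acc <- resolve_accepted(entry, backbone)
    list(matched = TRUE, accepted_name = acc$accepted_name,
         taxon_id = acc$taxon_id, rank = acc$rank,
         class_name = acc$class_name, spec_code = acc$spec_code,
         via = via, conflict = conflict)
  }

  # (1) alias, survey-scoped then global
  if (!is.null(aliases) && nrow(aliases) > 0) {
    key <- norm_name(verbatim)
    for (scope in c(survey_unit, "*")) {
      if (is.na(scope)) next
      hit <- aliases[aliases$survey_unit == scope &
                       norm_name(aliases$verbatim_name) == key, ]
      if (nrow(hit) > 0) {
        target <- backbone[backbone$status == "accepted" &
                             backbone$accepted_name == hit$accepted_name[1], ]
        if (nrow(target) == 0) {
          abort_config(sprintf(
            "alias target '%s' is not an accepted backbone name",
            hit$accepted_name[1]))
        }
        return(as_result(target[1, ], via = "alias"))
      }
    }
  }

  # (2) identifier, (3) name
  id_entry <- NULL
  if (!is.na(verbatim_id)) {
    hit <- backbone[backbone$taxon_id == verbatim_id, ]
    if (nrow(hit) > 0) id_entry <- hit[1, ]
  }
  name_entry <- NULL
  if (!is.na(verbatim)) {
    hit <- backbone[norm_name(backbone$name) == norm_name(verbatim), ]
    if (nrow(hit) > 0) name_entry <- hit[1, ]
  }
  if (!is.null(id_entry)) {
    conflict <- !is.null(name_entry) &&
      resolve_accepted(name_entry, backbone)$taxon_id !=
        resolve_accepted(id_entry, backbone)$taxon_id
    return(as_result(id_entry, via = "id", conflict = conflict))
  }
  if (!is.null(name_entry)) return(as_result(name_entry, via = "name"))
  unmatched
}

#' Harmonize all catch records of a dataset
#'
#' Applies [harmonize_name()] to every distinct
#' (survey_unit, verbatim_name, verbatim_aphia_id) key and writes the accepted
#' taxonomy back onto the catch records. Unmatched names are retained with
#' absent accepted fields and collected into a curation report (they are
#' removed later by [filter_fish_classes()], which counts them separately).
#'
#' @param d A `survey_dataset`.
#' @param backbone Backbone tibble from [read_backbone()].
#' @param aliases Optional alias tibble.
#' @return A list: `dataset` (harmonized `survey_dataset`) and `unmatched`
#'   (tibble `survey_unit`, `verbatim_name`, `verbatim_aphia_id`, `n_records`
#'   for curation into the alias table).
#' @export
harmonize_taxa <- function(d, backbone, aliases = NULL) {
  stopifnot(is_survey_dataset(d))
  su <- d$hauls[, c("haul_id", "survey_unit")]
  catches <- left_join(d$catches, su, by = "haul_id")
  keys <- distinct(catches[, c("survey_unit", "verbatim_name", "verbatim_aphia_id")])
  res <- purrr::pmap(
    list(keys$verbatim_name, keys$verbatim_aphia_id, keys$survey_unit),
    function(vn, vid, s) {
      harmonize_name(vn, vid, backbone, aliases, s)
    })
  keys$accepted_name <- purrr::map_chr(res, "accepted_name")
  keys$aphia_id <- purrr::map_dbl(res, ~ as.numeric(.x$taxon_id))
  keys$rank <- purrr::map_chr(res, "rank")
  keys$class_name <- purrr::map_chr(res, "class_name")
  keys$spec_code <- purrr::map_dbl(res, ~ as.numeric(.x$spec_code))
  conflicts <- keys[purrr::map_lgl(res, "conflict"), , drop = FALSE]
  matched <- purrr::map_lgl(res, "matched")

  catches <- catches %>%
    select(-accepted_name, -aphia_id, -rank, -class_name, -spec_code) %>%
    left_join(keys, by = c("survey_unit", "verbatim_name", "verbatim_aphia_id")) %>%
    select(-survey_unit)
  out <- survey_dataset(d$hauls, catches[, names(d$catches)], d$provenance)
  bb_md5 <- attr(backbone, "md5")
  out <- sd_log(out, sprintf(
    "taxonomic harmonization against backbone%s: %d/%d keys matched",
    if (is.null(bb_md5)) "" else paste0(" (md5 ", bb_md5, ")"),
    sum(matched), length(matched)))
  if (nrow(conflicts) > 0) {
    out <- sd_log(out, sprintf(
      "identifier/name conflicts resolved in favour of the identifier: %s",
      paste(conflicts$verbatim_name, collapse = ", ")))
  }
  unmatched_keys <- keys[!matched, c("survey_unit", "verbatim_name",
                                     "verbatim_aphia_id")]
  unmatched <- catches |>
    left_join(su, by = "haul_id") |>
    semi_join(unmatched_keys,
              by = c("survey_unit", "verbatim_name", "verbatim_aphia_id")) |>
    count(survey_unit, verbatim_name, verbatim_aphia_id, name = "n_records")
  list(dataset = out, unmatched = unmatched)
}

#' Keep only catches of fish taxonomic classes
#'
#' Retains catch records whose harmonized class is in the allowlist (default
#' [fish_classes()]). Records with an absent class (unmatched names) are
#' removed and counted separately from the out-of-list removals.
#'
#' @param d A harmonized `survey_dataset`.
#' @param classes Character vector of class names to retain.
#' @return A list: `dataset` and `report` (a `filter_report` over catch
#'   records with rules `"class"` and `"unmatched"`).
#' @export
filter_fish_classes <- function(d, classes = fish_classes()) {
  stopifnot(is_survey_dataset(d))
  catches <- d$catches
  n_in <- nrow(catches)
  unmatched <- is.na(catches$class_name)
  off_list <- !unmatched & !(catches$class_name %in% classes)
  removals <- bind_rows(
    tibble(haul_id = catches$haul_id[off_list],
           key = paste(catches$haul_id[off_list],
                       catches$verbatim_name[off_list], sep = ":"),
           rule = "class", level = "catch"),
    tibble(haul_id = catches$haul_id[unmatched],
           key = paste(catches$haul_id[unmatched],
                       catches$verbatim_name[unmatched], sep = ":"),
           rule = "unmatched", level = "catch"))
  keep <- !unmatched & !off_list
  out <- survey_dataset(d$hauls, catches[keep, , drop = FALSE], d$provenance)
  out <- sd_log(out, sprintf(
    "fish-class filter: %d/%d catch records retained (%d off-list, %d unmatched)",
    sum(keep), n_in, sum(off_list), sum(unmatched)))
  report <- structure(list(n_in = n_in, n_out = sum(keep), removals = removals),
                      class = "filter_report")
  list(dataset = out, report = report)
}

# absent-aware sum: NA only when every value is NA
sum_na <- function(x) {
  if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA else x[1]
}

#' Aggregate catch records per accepted taxon per haul
#'
#' Records of one haul resolving to the same accepted taxon (for example two
#' verbatim species collapsed to a genus alias) are merged: abundance and
#' weight are summed treating absent as missing (the sum is absent only when
#' every contribution is absent), and the contributing verbatim names are
#' concatenated with `"|"` for provenance. Unmatched records (absent accepted
#' name) are keyed by their verbatim name so distinct unmatched names are
#' never collapsed.
#'
#' @param d A harmonized `survey_dataset`.
#' @return The aggregated `survey_dataset`, one record per
#'   (haul, accepted taxon).
#' @export
aggregate_per_taxon_haul <- function(d) {
  stopifnot(is_survey_dataset(d))
  catches <- d$catches
  key <- ifelse(is.na(catches$accepted_name),
                paste0("verbatim::", catches$verbatim_name),
                catches$accepted_name)
  agg <- catches %>%
    mutate(.key = key) %>%
    group_by(haul_id, .data$.key) %>%
    summarise(
      verbatim_name = paste(sort(unique(verbatim_name)), collapse = "|"),
      verbatim_aphia_id = first_non_na(verbatim_aphia_id),
      accepted_name = first_non_na(accepted_name),
      aphia_id = first_non_na(aphia_id),
      rank = first_non_na(rank),
      class_name = first_non_na(class_name),
      spec_code = first_non_na(spec_code),
      num = sum_na(num), wgt = sum_na(wgt),
      num_cpue = sum_na(num_cpue), wgt_cpue = sum_na(wgt_cpue),
      num_cpua = sum_na(num_cpua), wgt_cpua = sum_na(wgt_cpua),
      .groups = "drop") %>%
    select(-".key")
  out <- survey_dataset(d$hauls, agg, d$provenance)
  sd_log(out, sprintf("aggregated %d catch records into %d taxon-haul records",
                      nrow(catches), nrow(agg)))
}
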