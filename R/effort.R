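KNOTS_TO_KM_H <- 1.852  # international nautical mile, exact

#' Swept area from towed distance and gear opening
#'
#' The seafloor surface covered by the net: distance towed times the
#' horizontal gear opening (wing spread).
#'
#' @param distance_km Towed distance in km (> 0).
#' @param gear_opening_m Horizontal gear opening in metres (> 0).
#' @return Swept area in km².
#' @export
#' @examples
#' swept_area_from_distance(3, 20)  # 0.06 km2
swept_area_from_distance <- function(distance_km, gear_opening_m) {
  if (any(!is.finite(distance_km)) || any(!is.finite(gear_opening_m)) ||
      any(distance_km <= 0) || any(gear_opening_m <= 0)) {
    abort_domain("distance_km and gear_opening_m must be positive")
  }
  distance_km * (gear_opening_m / 1000)
}

#' Swept area from haul duration, vessel speed and gear opening
#'
#' Used when towed distance is not recorded: distance is reconstructed as
#' speed times duration (knots converted to km/h via 1.852 exactly) and
#' multiplied by the gear opening.
#'
#' @param haul_dur_min Haul duration in minutes (> 0).
#' @param speed_knots Vessel speed in knots (> 0).
#' @param gear_opening_m Horizontal gear opening in metres (> 0).
#' @return Swept area in km².
#' @export
#' @examples
#' swept_area_from_speed(30, 4, 20)  # 0.07408 km2
swept_area_from_speed <- function(haul_dur_min, speed_knots, gear_opening_m) {
  if (any(!is.finite(haul_dur_min)) || any(!is.finite(speed_knots)) ||
      any(haul_dur_min <= 0) || any(speed_knots <= 0)) {
    abort_domain("haul_dur_min and speed_knots must be positive")
  }
  distance_km <- speed_knots * KNOTS_TO_KM_H * haul_dur_min / 60
  swept_area_from_distance(distance_km, gear_opening_m)
}

#' Fill in swept area from distance/speed fields and a fallback opening
#'
#' For each haul lacking `area_swept`, computes it from `distance` and
#' `gear_opening` when both are present, otherwise from `haul_dur`, `speed`
#' and `gear_opening`. A survey-wide standardized gear opening
#' (`default_opening_m`, e.g. communicated by survey experts) substitutes for
#' a missing haul-level opening when given.
#'
#' @param d A `survey_dataset`.
#' @param default_opening_m Optional fallback gear opening in metres.
#' @return The `survey_dataset` with `area_swept` filled where derivable.
#' @export
derive_swept_area <- function(d, default_opening_m = NULL) {
  stopifnot(is_survey_dataset(d))
  h <- d$hauls
  opening <- h$gear_opening
  if (!is.null(default_opening_m)) {
    opening[is.na(opening)] <- default_opening_m
  }
  from_dist <- is.na(h$area_swept) & !is.na(h$distance) & h$distance > 0 &
    !is.na(opening) & opening > 0
  h$area_swept[from_dist] <-
    swept_area_from_distance(h$distance[from_dist], opening[from_dist])
  from_speed <- is.na(h$area_swept) & !is.na(h$haul_dur) & h$haul_dur > 0 &
    !is.na(h$speed) & h$speed > 0 & !is.na(opening) & opening > 0
  h$area_swept[from_speed] <- swept_area_from_speed(
    h$haul_dur[from_speed], h$speed[from_speed], opening[from_speed])
  out <- survey_dataset(h, d$catches, d$provenance)
  sd_log(out, sprintf(
    "swept area derived for %d hauls (%d from distance, %d from speed)",
    sum(from_dist) + sum(from_speed), sum(from_dist), sum(from_speed)))
}

#' Fit a linear swept-area imputation model
#'
#' Ordinary least squares with swept area as the response, fitted on hauls
#' with known area. Of the candidate predictors (haul duration, depth, sweep
#' length, country, vessel by default), those available in at least 80% of
#' the training rows form the model; categorical predictors enter as
#' indicator contrasts; fitting uses complete cases only.
#'
#' @param hauls Haul tibble (canonical columns) with some `area_swept` known.
#' @param predictors Candidate predictor columns.
#' @param min_rows Minimum complete-case training rows (default 10).
#' @param availability Minimum fraction of training rows in which a candidate
#'   must be non-absent to enter the model (default 0.8).
#' @return A `swept_area_model`: the `lm` fit plus metadata (`predictors`,
#'   `n_fit`, `r2`, `min_area` = smallest observed positive area, used as a
#'   floor for non-positive predictions).
#' @export
fit_swept_area_model <- function(hauls,
                                 predictors = c("haul_dur", "depth",
                                                "sweep_length", "country",
                                                "vessel"),
                                 min_rows = 10, availability = 0.8) {
  train <- hauls[!is.na(hauls$area_swept) & hauls$area_swept > 0, , drop = FALSE]
  if (nrow(train) < min_rows) {
    abort_fit(sprintf(
      paste("only %d hauls with known swept area (need >= %d);",
            "consider a fixed per-survey gear opening instead"),
      nrow(train), min_rows))
  }
  avail <- vapply(predictors, function(p) {
    if (!p %in% names(train)) return(0)
    mean(!is.na(train[[p]]))
  }, numeric(1))
  use <- predictors[avail >= availability]
  # drop single-valued predictors: they carry no information and a constant
  # categorical cannot even form a contrast
  use <- use[vapply(use, function(p) {
    length(unique(train[[p]][!is.na(train[[p]])])) > 1
  }, logical(1))]
  if (length(use) == 0) {
    abort_fit("no candidate predictor is available in >= 80% of training rows")
  }
  dat <- train[, c("area_swept", use), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_rows || nrow(dat) <= length(use) + 1) {
    abort_fit(sprintf(
      "insufficient complete cases (%d) for %d predictors; consider a fixed per-survey gear opening",
      nrow(dat), length(use)))
  }
  for (p in use) if (is.character(dat[[p]])) dat[[p]] <- factor(dat[[p]])
  fit <- lm(stats::reformulate(use, response = "area_swept"), data = dat)
  structure(
    list(fit = fit, predictors = use, n_fit = nrow(dat),
         r2 = summary(fit)$r.squared,
         min_area = min(train$area_swept)),
    class = "swept_area_model")
}

#' @export
print.swept_area_model <- function(x, ...) {
  cat("<swept_area_model>\n")
  cat(sprintf("  predictors: %s\n", paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n_fit: %d, r2: %.4f\n", x$n_fit, x$r2))
  invisible(x)
}

#' Impute missing swept areas from a fitted model
#'
#' Fills only absent `area_swept` values. Hauls missing any model predictor
#' (or carrying a categorical level unseen at fit time) are left absent and
#' logged. Non-positive predictions are replaced by the smallest observed
#' positive area with a warning. Imputed hauls are recorded in the processing
#' log.
#'
#' @param d A `survey_dataset`.
#' @param model A `swept_area_model` fitted on the same survey unit.
#' @return The `survey_dataset` with imputed `area_swept`.
#' @export
impute_swept_area <- function(d, model) {
  stopifnot(is_survey_dataset(d), inherits(model, "swept_area_model"))
  h <- d$hauls
  target <- which(is.na(h$area_swept))
  if (length(target) == 0) {
    return(sd_log(d, "swept-area imputation: nothing to impute"))
  }
  newdata <- h[target, model$predictors, drop = FALSE]
  usable <- stats::complete.cases(newdata)
  # unseen categorical levels cannot be predicted
  for (p in model$predictors) {
    fac <- model$fit$xlevels[[p]]
    if (!is.null(fac)) {
      usable <- usable & (newdata[[p]] %in% fac)
      newdata[[p]] <- factor(newdata[[p]], levels = fac)
    }
  }
  pred <- rep(NA_real_, length(target))
  if (any(usable)) {
    pred[usable] <- unname(predict(model$fit, newdata[usable, , drop = FALSE]))
  }
  floored <- !is.na(pred) & pred <= 0
  if (any(floored)) {
    warning(sprintf(
      "%d non-positive swept-area prediction(s) floored to the smallest observed area (%g km2)",
      sum(floored), model$min_area), call. = FALSE)
    pred[floored] <- model$min_area
  }
  h$area_swept[target] <- pred
  out <- survey_dataset(h, d$catches, d$provenance)
  out <- sd_log(out, sprintf(
    "swept-area imputation: %d of %d missing hauls imputed (model: %s, r2=%.3f)%s",
    sum(!is.na(pred)), length(target),
    paste(model$predictors, collapse = "+"), model$r2,
    if (all(usable)) "" else sprintf("; %d hauls lack predictors, left absent",
                                     sum(!usable))))
  attr(out, "imputed_haul_ids") <- h$haul_id[target][!is.na(pred)]
  out
}

#' Reconstruct taxon weight from abundance-at-length
#'
#' Applies the allometric length-weight relationship w = a * l^b per length
#' bin and sums over bins. Coefficients follow the usual convention: weight
#' in grams for length in centimetres; the result is converted to kg.
#'
#' @param length_cm Numeric vector of length-bin midpoints (cm, > 0).
#' @param count Individuals per bin (>= 0), same length as `length_cm`.
#' @param lw_a,lw_b Length-weight coefficients (both > 0).
#' @return Total weight in kg (0 for an empty composition).
#' @export
#' @examples
#' weight_from_lengths(10, 2, lw_a = 0.01, lw_b = 3)  # 0.020 kg
weight_from_lengths <- function(length_cm, count, lw_a, lw_b) {
  if (length(length_cm) == 0) return(0)
  if (is.na(lw_a) || is.na(lw_b) || lw_a <= 0 || lw_b <= 0) {
    abort_domain("lw_a and lw_b must be present and positive")
  }
  if (any(length_cm <= 0) || any(count < 0)) {
    abort_domain("lengths must be positive and counts non-negative")
  }
  sum(count * lw_a * length_cm^lw_b) / 1000
}

#' Fill missing catch weights from a length-composition table
#'
#' For catch records with absent `wgt`, reconstructs weight with
#' [weight_from_lengths()] using per-taxon coefficients from the backbone
#' (`lw_a`, `lw_b`, matched on accepted name). Records without coefficients
#' or without length data are skipped with a log entry.
#'
#' @param d A harmonized `survey_dataset`.
#' @param lengths Length-composition tibble from [read_length_table()]
#'   (`taxon` holds accepted names).
#' @param backbone Backbone tibble carrying `lw_a`/`lw_b`.
#' @return The `survey_dataset` with reconstructed weights.
#' @export
add_weights_from_lengths <- function(d, lengths, backbone) {
  stopifnot(is_survey_dataset(d))
  catches <- d$catches
  coefs <- backbone[backbone$status == "accepted",
                    c("accepted_name", "lw_a", "lw_b")]
  coefs <- distinct(coefs, accepted_name, .keep_all = TRUE)
  need <- which(is.na(catches$wgt) & !is.na(catches$accepted_name))
  n_done <- 0L; n_skipped <- 0L
  for (i in need) {
    lc <- lengths[lengths$haul_id == catches$haul_id[i] &
                    lengths$taxon == catches$accepted_name[i], ]
    if (nrow(lc) == 0) next
    cf <- coefs[coefs$accepted_name == catches$accepted_name[i], ]
    if (nrow(cf) == 0 || is.na(cf$lw_a) || is.na(cf$lw_b)) {
      n_skipped <- n_skipped + 1L
      next
    }
    catches$wgt[i] <- weight_from_lengths(lc$length_cm, lc$count,
                                          cf$lw_a, cf$lw_b)
    n_done <- n_done + 1L
  }
  if (n_skipped > 0) {
    warning(sprintf(
      "%d record(s) with length data but no length-weight coefficients; weight left absent",
      n_skipped), call. = FALSE)
  }
  out <- survey_dataset(d$hauls, catches, d$provenance)
  sd_log(out, sprintf(
    "length-weight reconstruction: %d weights filled, %d skipped (no coefficients)",
    n_done, n_skipped))
}

#' Compute standardized catch rates
#'
#' Catch per unit effort (per hour of haul duration) and catch per unit area
#' (per km² swept): `num_cpue = num / (haul_dur/60)`,
#' `num_cpua = num / area_swept`, and the weight analogues. A rate is absent
#' whenever its numerator or denominator is absent.
#'
#' @param d A `survey_dataset` with catches aggregated per taxon-haul.
#' @return The `survey_dataset` with rate columns filled.
#' @export
compute_rates <- function(d) {
  stopifnot(is_survey_dataset(d))
  eff <- d$hauls[, c("haul_id", "haul_dur", "area_swept")]
  if (any(!is.na(eff$haul_dur) & eff$haul_dur <= 0) ||
      any(!is.na(eff$area_swept) & eff$area_swept <= 0)) {
    abort_integrity("non-positive haul_dur or area_swept encountered; run quality filters first")
  }
  catches <- d$catches %>%
    left_join(eff, by = "haul_id") %>%
    mutate(
      num_cpue = num / (haul_dur / 60),
      wgt_cpue = wgt / (haul_dur / 60),
      num_cpua = num / area_swept,
      wgt_cpua = wgt / area_swept) %>%
    select(-haul_dur, -area_swept)
  out <- survey_dataset(d$hauls, catches, d$provenance)
  sd_log(out, "standardized rates computed (CPUE per hour, CPUA per km2)")
}
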