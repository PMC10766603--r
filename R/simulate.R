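#' Default synthetic species pool
#'
#' Six demersal taxa with contrasting commonness: per-haul occupancy
#' probability, lognormal density parameters (individuals per km² on the log
#' scale) and a mean individual weight used to derive catch weight.
#'
#' @return Tibble with columns `name`, `occupancy`, `meanlog_cpua`,
#'   `sdlog_cpua`, `mean_ind_wgt_kg`.
#' @export
default_species_pool <- function() {
  tibble(
    name = c("Gadus morhua", "Melanogrammus aeglefinus", "Pleuronectes platessa",
             "Argentina silus", "Merlangius merlangus", "Lophius piscatorius"),
    occupancy = c(0.95, 0.85, 0.75, 0.90, 0.60, 0.40),
    meanlog_cpua = c(6.0, 5.5, 5.0, 4.5, 4.0, 2.5),
    sdlog_cpua = c(0.8, 0.8, 0.9, 0.7, 1.0, 1.0),
    mean_ind_wgt_kg = c(1.2, 0.6, 0.3, 0.15, 0.25, 3.5))
}

#' Configuration for the synthetic survey generator
#'
#' Describes a survey world with known ground truth: a set of core grid cells
#' sampled every year, transient cells sampled only in a fraction of years
#' (footprint drift), optional identification-protocol changes that relabel a
#' species from a given year onward, and effort-field missingness. Cell
#' centres are laid out on a wide regular grid (default 3 degrees latitude by
#' 4.5 degrees longitude, roughly 330 x 290 km at 55N) so each simulated cell
#' falls in its own hexagonal grid cell at resolutions 7 and 8; hauls scatter
#' uniformly within `jitter_deg` of their centre, emulating a fixed-station
#' design in which stations are revisited within a few km every year.
#'
#' @param seed Integer random seed; the dataset is a pure function of the
#'   configuration including this seed.
#' @param n_years Number of survey years (>= 2; default 20).
#' @param core_cells Number of consistently sampled cells (default 12).
#' @param transient_cells Number of transient cells (default 8).
#' @param transient_prob Yearly sampling probability of a transient cell
#'   (default 0.3).
#' @param hauls_per_cell_year Hauls per sampled cell-year (default 4, the
#'   minimum that satisfies the BioTIME cell-year rule).
#' @param species Species pool tibble (see [default_species_pool()]).
#' @param relabel_events Tibble `species`, `year` (1-based survey year),
#'   `replacement`: from that year on the species is recorded under the
#'   replacement name. Default (`NULL`): one genus-level protocol switch
#'   halfway through the series; pass a zero-row tibble for none.
#' @param effort List: `haul_dur_mean`/`haul_dur_sd` (minutes),
#'   `speed_knots`, `gear_opening_m`, `missing_area_frac` (fraction of hauls
#'   with swept area and distance withheld, default 0).
#' @param start_year First calendar year (default 2001).
#' @param origin `c(lat, lon)` of the cell layout (default 55N, 0E).
#' @param jitter_deg Uniform within-cell scatter of haul positions, degrees.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_years = 20L,
                       core_cells = 12L,
                       transient_cells = 8L,
                       transient_prob = 0.3,
                       hauls_per_cell_year = 4L,
                       species = default_species_pool(),
                       relabel_events = NULL,
                       effort = list(),
                       start_year = 2001L,
                       origin = c(lat = 55, lon = 0),
                       jitter_deg = 0.02) {
  effort <- modifyList(
    list(haul_dur_mean = 30, haul_dur_sd = 5, speed_knots = 3.5,
         gear_opening_m = 20, missing_area_frac = 0),
    effort)
  if (is.null(relabel_events)) {
    # default protocol switch halfway through the series: a species pair too
    # hard to separate in the field gets recorded at genus rank
    relabel_events <- tibble(species = "Argentina silus",
                             year = as.integer(floor(n_years / 2) + 1),
                             replacement = "Argentina")
    if (!"Argentina silus" %in% species$name) {
      relabel_events <- relabel_events[0, ]
    }
  }
  cfg <- list(seed = as.integer(seed), n_years = as.integer(n_years),
              core_cells = as.integer(core_cells),
              transient_cells = as.integer(transient_cells),
              transient_prob = transient_prob,
              hauls_per_cell_year = as.integer(hauls_per_cell_year),
              species = as_tibble(species),
              relabel_events = as_tibble(relabel_events),
              effort = effort, start_year = as.integer(start_year),
              origin = origin, jitter_deg = jitter_deg)
  bad <- character()
  if (is.na(cfg$seed)) bad <- c(bad, "seed")
  if (cfg$n_years < 2) bad <- c(bad, "n_years")
  if (cfg$core_cells < 1) bad <- c(bad, "core_cells")
  if (cfg$transient_cells < 0) bad <- c(bad, "transient_cells")
  if (cfg$transient_prob < 0 || cfg$transient_prob > 1) {
    bad <- c(bad, "transient_prob")
  }
  if (cfg$hauls_per_cell_year < 1) bad <- c(bad, "hauls_per_cell_year")
  if (nrow(cfg$species) == 0 ||
      any(cfg$species$occupancy < 0 | cfg$species$occupancy > 1)) {
    bad <- c(bad, "species")
  }
  if (nrow(cfg$relabel_events) > 0 &&
      (any(!cfg$relabel_events$species %in% cfg$species$name) ||
         any(cfg$relabel_events$year < 1 |
               cfg$relabel_events$year > cfg$n_years))) {
    bad <- c(bad, "relabel_events")
  }
  if (effort$haul_dur_mean <= 0 || effort$speed_knots <= 0 ||
      effort$gear_opening_m <= 0 ||
      effort$missing_area_frac < 0 || effort$missing_area_frac > 1) {
    bad <- c(bad, "effort")
  }
  if (length(bad) > 0) {
    trawlr_abort("trawlr_validation_error", sprintf(
      "invalid simulation config field(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-stage sub-seeds so e.g. adding species does not perturb
# haul placement (stages: schedule/placement, effort, catches, missingness)
stage_seeds <- function(seed, n = 4) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

sim_cell_layout <- function(cfg) {
  n <- cfg$core_cells + cfg$transient_cells
  ncol_grid <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  tibble(
    sim_cell = sprintf("C%02d", seq_len(n)),
    center_lat = cfg$origin[["lat"]] + (idx %/% ncol_grid) * 3,
    center_lon = cfg$origin[["lon"]] + (idx %% ncol_grid) * 4.5,
    transient = seq_len(n) > cfg$core_cells)
}

#' Generate a synthetic survey dataset with ground truth
#'
#' Builds a complete haul-and-catch dataset from a [sim_config()]:
#' core cells yield `hauls_per_cell_year` hauls every year, transient cells
#' only in Bernoulli(`transient_prob`) years; per haul, each species occurs
#' with its occupancy probability and, when present, has a lognormal true
#' density (individuals per km²) converted to a catch count through the swept
#' area (counts may be fractional, as with raised subsampled catches); catch
#' weight is count times mean individual weight. Relabel events rewrite the
#' recorded name from the event year onward. Every haul retains at least one
#' catch record (the most common species is forced present if no species was
#' drawn), so a complete-effort configuration passes the quality filters with
#' zero removals. Deterministic given the config.
#'
#' @param cfg A `sim_config`.
#' @return A list: `dataset` (a `survey_dataset`) and `truth` (list with
#'   `cells`, `hauls` — per-haul cell and transience —, `relabel` name pairs,
#'   and the `config`).
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- stage_seeds(cfg$seed)
  layout <- sim_cell_layout(cfg)
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L

  # stage 1: sampling schedule and haul placement
  hauls <- with_seed(seeds[1], {
    sched <- tidyr::expand_grid(sim_cell = layout$sim_cell, year = years) %>%
      left_join(layout, by = "sim_cell")
    keep <- !sched$transient | runif(nrow(sched)) < cfg$transient_prob
    sched <- sched[keep, , drop = FALSE]
    sched <- sched[rep(seq_len(nrow(sched)), each = cfg$hauls_per_cell_year), ]
    n <- nrow(sched)
    sched %>%
      mutate(
        haul_id = sprintf("H%06d", row_number()),
        latitude = .data$center_lat + runif(n, -cfg$jitter_deg, cfg$jitter_deg),
        longitude = .data$center_lon + runif(n, -cfg$jitter_deg, cfg$jitter_deg),
        month = sample(1:3, n, replace = TRUE),
        day = sample(1:28, n, replace = TRUE))
  })
  n <- nrow(hauls)

  # stage 2: effort fields
  eff <- cfg$effort
  hauls <- with_seed(seeds[2], {
    hauls %>% mutate(
      haul_dur = pmax(5, rnorm(n, eff$haul_dur_mean, eff$haul_dur_sd)),
      speed = eff$speed_knots,
      gear_opening = eff$gear_opening_m,
      depth = runif(n, 50, 250))
  })
  hauls <- hauls %>% mutate(
    distance = speed * KNOTS_TO_KM_H * (haul_dur / 60),
    area_swept = distance * (gear_opening / 1000),
    survey = "SIM", survey_unit = "SIM-1", quarter = 1,
    gear = "GOV", gear_category = "otter", quality_flag = "valid",
    country = "SIM", vessel = "V1")

  # stage 3: catches
  sp <- cfg$species
  anchor <- which.max(sp$occupancy)
  catches <- with_seed(seeds[3], {
    grid <- tidyr::expand_grid(haul_row = seq_len(n), sp_row = seq_len(nrow(sp)))
    present <- runif(nrow(grid)) < sp$occupancy[grid$sp_row]
    # no empty hauls: force the most common species when nothing was drawn
    empty <- !as.logical(tapply(present, grid$haul_row, any))
    present[(which(empty) - 1L) * nrow(sp) + anchor] <- TRUE
    grid <- grid[present, , drop = FALSE]
    cpua <- rlnorm(nrow(grid), sp$meanlog_cpua[grid$sp_row],
                   sp$sdlog_cpua[grid$sp_row])
    tibble(
      haul_id = hauls$haul_id[grid$haul_row],
      year = hauls$year[grid$haul_row],
      verbatim_name = sp$name[grid$sp_row],
      verbatim_aphia_id = 100000 + grid$sp_row,
      num = cpua * hauls$area_swept[grid$haul_row],
      wgt = cpua * hauls$area_swept[grid$haul_row] *
        sp$mean_ind_wgt_kg[grid$sp_row])
  })

  # relabel events: protocol switches from the event year onward
  rel <- cfg$relabel_events
  if (nrow(rel) > 0) {
    for (k in seq_len(nrow(rel))) {
      hit <- catches$verbatim_name == rel$species[k] &
        catches$year >= cfg$start_year + rel$year[k] - 1L
      catches$verbatim_name[hit] <- rel$replacement[k]
    }
  }
  # the generated world ships already harmonized: accepted = verbatim
  catches <- catches %>%
    mutate(accepted_name = verbatim_name, aphia_id = verbatim_aphia_id,
           rank = "species", class_name = "Teleostei") %>%
    select(-year)

  # stage 4: effort missingness
  if (eff$missing_area_frac > 0) {
    hide <- with_seed(seeds[4], runif(n) < eff$missing_area_frac)
    hauls$area_swept[hide] <- NA_real_
    hauls$distance[hide] <- NA_real_
    hauls$speed[hide] <- NA_real_
  }

  dial <- survey_dialect()
  d <- survey_dataset(hauls[, intersect(dial$haul, names(hauls))], catches,
                      provenance = sprintf(
                        "synthetic survey generated (seed %d, %d hauls)",
                        cfg$seed, n))
  truth <- list(
    cells = layout,
    hauls = hauls[, c("haul_id", "sim_cell", "transient", "year")],
    relabel = if (nrow(rel) == 0) {
      tibble(old_name = character(), new_name = character(), year = integer())
    } else {
      tibble(old_name = rel$species, new_name = rel$replacement,
             year = cfg$start_year + rel$year - 1L)
    },
    config = cfg)
  list(dataset = d, truth = truth)
}

#' Score computed flags against simulation ground truth
#'
#' Footprint flags are scored as a classifier of transient-cell hauls
#' (sensitivity: flagged fraction of transient hauls; specificity: unflagged
#' fraction of core hauls). Taxon flags are scored as detection of relabel
#' events: an event is detected when both the old and the replacement name
#' are flagged.
#'
#' @param truth Ground truth from [generate_survey()].
#' @param footprint_flags Optional tibble with `haul_id` and a logical flag
#'   column; `flag_col` names the column to score.
#' @param taxon_flags Optional tibble from [flag_taxa()].
#' @param flag_col Footprint flag column to score (default
#'   `"flag_hex_r7_t0"`).
#' @return A `recovery_report` list: `footprint` (tp/fp/tn/fn, sensitivity,
#'   specificity) and/or `taxa` (per-event detection and overall hit rate).
#' @export
truth_metrics <- function(truth, footprint_flags = NULL, taxon_flags = NULL,
                          flag_col = "flag_hex_r7_t0") {
  out <- list()
  if (!is.null(footprint_flags)) {
    if (!flag_col %in% names(footprint_flags)) {
      abort_domain(sprintf("flag column '%s' not present", flag_col))
    }
    joined <- inner_join(truth$hauls, footprint_flags, by = "haul_id")
    if (nrow(joined) != nrow(truth$hauls) ||
        nrow(joined) != nrow(footprint_flags)) {
      abort_integrity("footprint flags and ground truth carry different haul ids")
    }
    fl <- joined[[flag_col]]
    tp <- sum(joined$transient & fl)
    fn <- sum(joined$transient & !fl)
    fp <- sum(!joined$transient & fl)
    tn <- sum(!joined$transient & !fl)
    out$footprint <- list(
      flag_col = flag_col, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  }
  if (!is.null(taxon_flags) && nrow(truth$relabel) > 0) {
    flagged_names <- taxon_flags$taxon[!is.na(taxon_flags$flag_taxon) &
                                         taxon_flags$flag_taxon]
    events <- truth$relabel %>%
      mutate(old_flagged = .data$old_name %in% flagged_names,
             new_flagged = .data$new_name %in% flagged_names,
             detected = .data$old_flagged & .data$new_flagged)
    out$taxa <- list(events = events, hit_rate = mean(events$detected))
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  if (!is.null(x$footprint)) {
    cat(sprintf("  footprint [%s]: sensitivity %.3f, specificity %.3f (tp %d fp %d tn %d fn %d)\n",
                x$footprint$flag_col, x$footprint$sensitivity,
                x$footprint$specificity, x$footprint$tp, x$footprint$fp,
                x$footprint$tn, x$footprint$fn))
  }
  if (!is.null(x$taxa)) {
    cat(sprintf("  taxa: %d/%d relabel events detected\n",
                sum(x$taxa$events$detected), nrow(x$taxa$events)))
  }
  invisible(x)
}
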