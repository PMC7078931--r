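#' Stochastic observer error model
#'
#' The simulated observer is the stand-in for a human listener. Three error
#' channels are modeled, matching the error categories the scoring rule must
#' classify:
#' \itemize{
#'   \item missed detections: a played clip of species `i` is detected with
#'     probability `p_detect[i]`;
#'   \item misidentification: a detected clip of species `i` is reported as
#'     species `j` with probability `confusion[i, j]` (rows sum to 1; the
#'     diagonal is the correct-identification probability);
#'   \item timing error: the recorded interval is the clip's true onset
#'     interval plus an offset drawn from `jitter` over \{-1, 0, +1\},
#'     clamped to the survey grid.
#' }
#'
#' @param label Free-text label, e.g. `"expert"` or `"naive"`.
#' @param p_detect Either a single probability recycled over all species or a
#'   named vector with one probability per species code.
#' @param confusion Square row-stochastic matrix with species codes as
#'   dimnames.
#' @param jitter Length-3 probability vector over interval offsets
#'   `c(-1, 0, +1)`; default is a point mass at 0 (perfect timing).
#' @return Object of class `observer_profile`.
#' @seealso [uniform_confusion()], [perfect_observer()]
#' @export
observer_profile <- function(label, p_detect, confusion,
                             jitter = c(0, 1, 0)) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  species <- rownames(confusion)
  if (is.null(species) || !identical(species, colnames(confusion))) {
    stop("confusion matrix needs identical species row/column names")
  }
  if (any(confusion < 0) || any(confusion > 1)) {
    stop("confusion entries must be probabilities")
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("each confusion row must sum to 1 (tolerance 1e-9)")
  }
  if (length(p_detect) == 1L && is.null(names(p_detect))) {
    p_detect <- stats::setNames(rep(as.numeric(p_detect), length(species)),
                                species)
  }
  if (!all(species %in% names(p_detect))) {
    stop("p_detect is missing species: ",
         paste(setdiff(species, names(p_detect)), collapse = ", "))
  }
  p_detect <- p_detect[species]
  if (any(p_detect < 0 | p_detect > 1)) stop("p_detect must lie in [0, 1]")
  jitter <- as.numeric(jitter)
  if (length(jitter) != 3L || any(jitter < 0) ||
      abs(sum(jitter) - 1) > 1e-9) {
    stop("jitter must be a length-3 probability vector over offsets -1,0,+1")
  }
  structure(list(label = label, species = species, p_detect = p_detect,
                 confusion = confusion, jitter = jitter),
            class = "observer_profile")
}

#' Confusion matrix with a common diagonal
#'
#' Correct-identification probability `diag` for every species, with the
#' remaining mass spread evenly over the other species. Convenient baseline
#' for calibrated campaigns; real confusion is asymmetric and concentrated in
#' similar-sounding pairs, which can be expressed by editing the result.
#'
#' @param species Character vector of species codes.
#' @param diag Probability of a correct identification.
#' @return Row-stochastic matrix.
#' @export
uniform_confusion <- function(species, diag = 1) {
  k <- length(species)
  stopifnot(k >= 1, diag >= 0, diag <= 1)
  if (k == 1L) {
    m <- matrix(1, 1, 1)
  } else {
    m <- matrix((1 - diag) / (k - 1), k, k)
    diag(m) <- diag
  }
  dimnames(m) <- list(species, species)
  m
}

#' Error-free observer
#'
#' Detects every clip, never misidentifies, never mistimes. Useful as a
#' degenerate control: scoring its log against the truth list gives a
#' false-positive rate of exactly 0.
#'
#' @param species Character vector of species codes.
#' @param label Profile label.
#' @return An [observer_profile()].
#' @export
perfect_observer <- function(species = study_roster()$code,
                             label = "perfect") {
  observer_profile(label, p_detect = 1,
                   confusion = uniform_confusion(species, 1))
}

#' Collaboration setting for dependent double-observer surveys
#'
#' In the DDO protocol the observers may confer on an identification as long
#' as the detection stays attributed to the observer who made it.
#' `collaboration` is the probability that a primary misidentification is
#' replaced by the correct identification when the secondary observer
#' independently detected and correctly identified the same clip.
#'
#' @param collaboration Probability in \[0, 1\].
#' @return Object of class `ddo_config`.
#' @export
ddo_config <- function(collaboration = 0.5) {
  collaboration <- as.numeric(collaboration)
  stopifnot(length(collaboration) == 1L, collaboration >= 0,
            collaboration <= 1)
  structure(list(collaboration = collaboration), class = "ddo_config")
}

draw_reported <- function(profile, true_species) {
  row <- profile$confusion[true_species, ]
  sample(profile$species, 1L, prob = row)
}

draw_interval <- function(profile, onset_interval, n_intervals) {
  off <- sample(c(-1L, 0L, 1L), 1L, prob = profile$jitter)
  min(max(onset_interval + off, 0L), n_intervals - 1L)
}

empty_detections <- function(survey_id = character(0)) {
  data.frame(survey_id = survey_id, detection_id = integer(0),
             interval_index = integer(0), reported_species = character(0),
             role = character(0), stringsAsFactors = FALSE)
}

check_profile_covers <- function(profile, schedule) {
  missing <- setdiff(unique(schedule$clips$species), profile$species)
  if (length(missing)) {
    stop("observer profile '", profile$label, "' does not cover species: ",
         paste(missing, collapse = ", "))
  }
}

#' Simulate an independent single-observer (ISO) survey
#'
#' One observer listens to the whole survey. For each truth clip
#' independently: detection with probability `p_detect`, reported species
#' from the confusion row, recorded interval jittered by at most one grid
#' interval. Undetected clips leave no record (nondetections).
#'
#' @param schedule A [generate_schedule()] truth list.
#' @param profile An [observer_profile()].
#' @param seed Optional integer for a private RNG stream.
#' @return Detections data.frame: `survey_id`, `detection_id`,
#'   `interval_index`, `reported_species`, `role` (all `"single"`).
#' @export
simulate_iso <- function(schedule, profile, seed = NULL) {
  stopifnot(inherits(schedule, "survey_schedule"),
            inherits(profile, "observer_profile"))
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_iso(schedule, profile)))
  }
  check_profile_covers(profile, schedule)
  clips <- schedule$clips
  n_int <- schedule$config$n_intervals
  rows <- vector("list", nrow(clips))
  for (k in seq_len(nrow(clips))) {
    sp <- clips$species[k]
    if (stats::runif(1) >= profile$p_detect[[sp]]) next
    rows[[k]] <- list(reported = draw_reported(profile, sp),
                      interval = draw_interval(profile,
                                               clips$onset_interval[k], n_int))
  }
  hit <- !vapply(rows, is.null, logical(1))
  if (!any(hit)) return(empty_detections())
  data.frame(
    survey_id = schedule$survey_id,
    detection_id = seq_len(sum(hit)),
    interval_index = vapply(rows[hit], `[[`, integer(1), "interval"),
    reported_species = vapply(rows[hit], `[[`, character(1), "reported"),
    role = "single",
    stringsAsFactors = FALSE)
}

#' Simulate a dependent double-observer (DDO) survey
#'
#' Removal design: at most one record per truth clip. The primary observer
#' reports first; whatever the primary reports is recorded (role
#' `"primary"`). If the primary's report is a misidentification and,
#' independently, the secondary observer detected and correctly identified
#' the clip, the report is corrected to the true species with probability
#' `ddo$collaboration` — attribution stays with the primary. Clips the
#' primary misses fall to the secondary (role `"secondary"`); clips both miss
#' are nondetections.
#'
#' @param schedule A [generate_schedule()] truth list.
#' @param primary,secondary [observer_profile()]s for the two roles.
#' @param ddo A [ddo_config()].
#' @param seed Optional integer for a private RNG stream.
#' @return Detections data.frame as in [simulate_iso()], `role` in
#'   `{"primary", "secondary"}`.
#' @export
simulate_ddo <- function(schedule, primary, secondary,
                         ddo = ddo_config(), seed = NULL) {
  stopifnot(inherits(schedule, "survey_schedule"),
            inherits(primary, "observer_profile"),
            inherits(secondary, "observer_profile"),
            inherits(ddo, "ddo_config"))
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_ddo(schedule, primary, secondary, ddo)))
  }
  check_profile_covers(primary, schedule)
  check_profile_covers(secondary, schedule)
  clips <- schedule$clips
  n_int <- schedule$config$n_intervals
  kappa <- ddo$collaboration
  rows <- vector("list", nrow(clips))
  for (k in seq_len(nrow(clips))) {
    sp <- clips$species[k]
    if (stats::runif(1) < primary$p_detect[[sp]]) {
      reported <- draw_reported(primary, sp)
      if (reported != sp && stats::runif(1) < secondary$p_detect[[sp]]) {
        # secondary got it right and the pair confers
        if (draw_reported(secondary, sp) == sp &&
            stats::runif(1) < kappa) {
          reported <- sp
        }
      }
      rows[[k]] <- list(reported = reported, role = "primary",
                        interval = draw_interval(primary,
                                                 clips$onset_interval[k],
                                                 n_int))
    } else if (stats::runif(1) < secondary$p_detect[[sp]]) {
      rows[[k]] <- list(reported = draw_reported(secondary, sp),
                        role = "secondary",
                        interval = draw_interval(secondary,
                                                 clips$onset_interval[k],
                                                 n_int))
    }
  }
  hit <- !vapply(rows, is.null, logical(1))
  if (!any(hit)) return(empty_detections())
  data.frame(
    survey_id = schedule$survey_id,
    detection_id = seq_len(sum(hit)),
    interval_index = vapply(rows[hit], `[[`, integer(1), "interval"),
    reported_species = vapply(rows[hit], `[[`, character(1), "reported"),
    role = vapply(rows[hit], `[[`, character(1), "role"),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-scenario survey campaign
#'
#' Runs every scenario row end to end: generates truth lists and observer
#' logs with deterministic per-survey substreams. Within a DDO scenario the
#' two observers swap primary/secondary roles on alternating surveys, as in
#' the field protocol.
#'
#' @param scenarios data.frame with columns `scenario` (unique label),
#'   `experience`, `method` (`"ISO"` or `"DDO"`), `n_surveys`, `observer_a`,
#'   `observer_b` (names into `profiles`; `observer_b` is ignored for ISO
#'   rows and may be `NA` there).
#' @param profiles Named list of [observer_profile()]s.
#' @param config A [schedule_config()] shared by all scenarios.
#' @param ddo A [ddo_config()] shared by all DDO scenarios.
#' @param seed Integer root seed.
#' @return Object of class `survey_campaign`: list with `scenarios`,
#'   `schedules` (named list keyed by survey id) and `detections` (one
#'   data.frame over all scenarios with `scenario`, `experience`, `method`
#'   prepended to the detection columns).
#' @export
simulate_campaign <- function(scenarios, profiles,
                              config = schedule_config(),
                              ddo = ddo_config(), seed = 1L) {
  stopifnot(is.data.frame(scenarios),
            all(c("scenario", "experience", "method", "n_surveys",
                  "observer_a") %in% names(scenarios)))
  if (anyDuplicated(scenarios$scenario)) {
    stop("scenario labels must be unique")
  }
  bad <- setdiff(unique(scenarios$method), c("ISO", "DDO"))
  if (length(bad)) stop("unknown method label: ", paste(bad, collapse = ", "))
  schedules <- list()
  det <- list()
  for (j in seq_len(nrow(scenarios))) {
    row <- scenarios[j, ]
    a <- profiles[[row$observer_a]]
    if (is.null(a)) stop("unknown profile: ", row$observer_a)
    b <- NULL
    if (row$method == "DDO") {
      if (is.null(scenarios$observer_b) || is.na(row$observer_b)) {
        stop("DDO scenario '", row$scenario, "' needs observer_b")
      }
      b <- profiles[[row$observer_b]]
      if (is.null(b)) stop("unknown profile: ", row$observer_b)
    }
    for (i in seq_len(row$n_surveys)) {
      sid <- sprintf("%s_%04d", row$scenario, i)
      sched <- generate_schedule(config, survey_id = sid,
                                 seed = substream_seed(seed, j * 1e6 + 2 * i))
      obs_seed <- substream_seed(seed, j * 1e6 + 2 * i + 1)
      d <- if (row$method == "ISO") {
        simulate_iso(sched, a, seed = obs_seed)
      } else if (i %% 2L == 1L) {
        simulate_ddo(sched, a, b, ddo, seed = obs_seed)
      } else {
        simulate_ddo(sched, b, a, ddo, seed = obs_seed)
      }
      if (nrow(d)) {
        d$survey_id <- sid # empty logs carry no id; stamp for safety
        d <- cbind(scenario = row$scenario, experience = row$experience,
                   method = row$method, d, stringsAsFactors = FALSE)
      }
      schedules[[sid]] <- sched
      det[[sid]] <- d
    }
  }
  det <- det[vapply(det, nrow, integer(1)) > 0L]
  detections <- if (length(det)) {
    do.call(rbind, c(det, list(make.row.names = FALSE)))
  } else {
    cbind(scenario = character(0), experience = character(0),
          method = character(0), empty_detections())
  }
  structure(list(scenarios = scenarios, schedules = schedules,
                 detections = detections, seed = seed),
            class = "survey_campaign")
}

#' @export
print.survey_campaign <- function(x, ...) {
  cat(sprintf("survey_campaign: %d scenarios, %d surveys, %d detections\n",
              nrow(x$scenarios), length(x$schedules), nrow(x$detections)))
  invisible(x)
}
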