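#' Configuration for truth-list generation
#'
#' A simulated auditory survey is a timeline of `duration_s` seconds divided
#' into recording intervals of `interval_s` seconds. Each species on the
#' roster vocalizes a random number of times (discrete-uniform on
#' `[count_low, count_high]`); every vocalization is a clip occupying
#' `clip_s` seconds, and the remaining time is white noise.
#'
#' @param duration_s Survey length in seconds. Must be divisible by
#'   `interval_s`. Default 180 (a 3-minute point count).
#' @param interval_s Width of the recording interval grid in seconds
#'   (default 3).
#' @param clip_s Length of one vocalization clip in seconds (default 4, so a
#'   clip can straddle two grid intervals).
#' @param roster Species roster data.frame (see [study_roster()]).
#' @param count_low,count_high Inclusive bounds of the per-species occurrence
#'   count (defaults 1 and 4).
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(duration_s = 180, interval_s = 3, clip_s = 4,
                            roster = study_roster(),
                            count_low = 1L, count_high = 4L) {
  validate_roster(roster)
  stopifnot(duration_s > 0, interval_s > 0, clip_s > 0)
  if (duration_s %% interval_s != 0) {
    stop("duration_s must be divisible by interval_s")
  }
  count_low <- as.integer(count_low)
  count_high <- as.integer(count_high)
  if (is.na(count_low) || is.na(count_high) ||
      count_low < 0L || count_low > count_high) {
    stop("need 0 <= count_low <= count_high")
  }
  worst <- nrow(roster) * count_high * clip_s
  if (worst > duration_s) {
    stop(sprintf(paste0(
      "worst-case clip time infeasible: %d species x %d occurrences x %gs ",
      "= %gs exceeds the %gs survey"),
      nrow(roster), count_high, clip_s, worst, duration_s))
  }
  structure(
    list(duration_s = duration_s, interval_s = interval_s, clip_s = clip_s,
         roster = roster, count_low = count_low, count_high = count_high,
         n_intervals = as.integer(duration_s / interval_s)),
    class = "schedule_config")
}

#' Draw per-species occurrence counts
#'
#' Each species' number of vocalizations in one survey is drawn
#' independently, discrete-uniform on `[count_low, count_high]`. Uses the
#' current RNG stream.
#'
#' @param config A [schedule_config()].
#' @return Named integer vector (one element per roster species).
#' @export
draw_species_counts <- function(config) {
  stopifnot(inherits(config, "schedule_config"))
  k <- config$count_high - config$count_low + 1L
  counts <- sample.int(k, nrow(config$roster), replace = TRUE) +
    config$count_low - 1L
  names(counts) <- config$roster$code
  counts
}

#' Generate one survey truth list
#'
#' Draws per-species occurrence counts, shuffles the resulting clips into a
#' uniformly random order, and distributes the white-noise slack
#' (`duration_s - n_clips * clip_s`) across the `n_clips + 1` gaps by uniform
#' stick-breaking. Clips never overlap but may be played back-to-back. The
#' truth interval of a clip is the grid interval containing its onset.
#'
#' @param config A [schedule_config()].
#' @param survey_id Identifier recorded on every clip row.
#' @param seed Optional integer; when given, the schedule is drawn from a
#'   private stream seeded with it and the caller's RNG state is untouched.
#' @return An object of class `survey_schedule`: a list with `survey_id`,
#'   `config`, and `clips`, a data.frame with one row per clip
#'   (`clip_id`, `species`, `onset_s`, `onset_interval`), sorted by onset.
#' @export
generate_schedule <- function(config, survey_id = "survey_001", seed = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  if (!is.null(seed)) {
    return(with_seed(seed, generate_schedule(config, survey_id)))
  }
  counts <- draw_species_counts(config)
  n <- sum(counts)
  slack <- config$duration_s - n * config$clip_s
  if (slack < 0) {
    stop(sprintf(paste0(
      "infeasible draw for survey '%s': %d clips x %gs = %gs of audio ",
      "exceed the %gs survey"),
      survey_id, n, config$clip_s, n * config$clip_s, config$duration_s))
  }
  species <- rep(names(counts), counts)
  if (n > 1L) species <- species[sample.int(n)]
  # n + 1 gaps summing to the slack: order statistics of n uniforms on [0, slack]
  cuts <- sort(stats::runif(n, 0, slack))
  gap_before <- diff(c(0, cuts))
  onset <- cumsum(gap_before) + (seq_len(n) - 1) * config$clip_s
  clips <- data.frame(
    clip_id = seq_len(n),
    species = species,
    onset_s = onset,
    onset_interval = as.integer(floor(onset / config$interval_s)),
    stringsAsFactors = FALSE)
  structure(list(survey_id = survey_id, config = config, clips = clips),
            class = "survey_schedule")
}

#' Generate a batch of independent truth lists
#'
#' Each survey is drawn from its own substream derived deterministically from
#' `seed` and the survey index, so the batch is reproducible and individual
#' surveys can be regenerated in isolation.
#'
#' @param config A [schedule_config()].
#' @param n_surveys Number of surveys (>= 1).
#' @param seed Integer root seed.
#' @param id_prefix Prefix for survey identifiers.
#' @return Object of class `schedule_batch`: list with `schedules` (named
#'   list of `survey_schedule`) and `summary` (total, mean, sd, min, max of
#'   per-survey clip counts).
#' @export
generate_batch <- function(config, n_surveys, seed, id_prefix = "survey") {
  stopifnot(inherits(config, "schedule_config"))
  n_surveys <- as.integer(n_surveys)
  if (is.na(n_surveys) || n_surveys < 1L) stop("n_surveys must be >= 1")
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n_surveys))
  schedules <- lapply(seq_len(n_surveys), function(i) {
    generate_schedule(config, survey_id = ids[i],
                      seed = substream_seed(seed, i))
  })
  names(schedules) <- ids
  per_survey <- vapply(schedules, function(s) nrow(s$clips), integer(1))
  structure(
    list(schedules = schedules,
         summary = list(
           n_surveys = n_surveys,
           total_clips = sum(per_survey),
           mean = mean(per_survey),
           sd = if (n_surveys > 1L) stats::sd(per_survey) else 0,
           min = min(per_survey),
           max = max(per_survey)),
         seed = seed),
    class = "schedule_batch")
}

#' @export
print.survey_schedule <- function(x, ...) {
  cat(sprintf("survey_schedule '%s': %d clips on a %gs / %gs-interval grid\n",
              x$survey_id, nrow(x$clips), x$config$duration_s,
              x$config$interval_s))
  invisible(x)
}

#' @export
print.schedule_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "schedule_batch: %d surveys, %d clips (mean %.1f, sd %.1f, range %d-%d)\n",
    s$n_surveys, s$total_clips, s$mean, s$sd, s$min, s$max))
  invisible(x)
}
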