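# Hand-built fixtures and independent oracles used across the suite.

# Build a survey_schedule with clips at given grid intervals, bypassing the
# generator (onsets at interval starts; spacing constraints deliberately not
# enforced so adversarial matching instances can be expressed).
make_schedule <- function(intervals, species,
                          config = schedule_config(),
                          survey_id = "T1") {
  o <- order(intervals, seq_along(intervals))
  intervals <- intervals[o]
  species <- rep_len(species, length(intervals))[o]
  structure(
    list(survey_id = survey_id, config = config,
         clips = data.frame(
           clip_id = seq_along(intervals),
           species = species,
           onset_s = intervals * config$interval_s,
           onset_interval = as.integer(intervals),
           stringsAsFactors = FALSE)),
    class = "survey_schedule")
}

make_detections <- function(intervals, species, survey_id = "T1",
                            role = "single") {
  data.frame(survey_id = rep_len(survey_id, length(intervals)),
             detection_id = seq_along(intervals),
             interval_index = as.integer(intervals),
             reported_species = rep_len(species, length(intervals)),
             role = rep_len(role, length(intervals)),
             stringsAsFactors = FALSE)
}

# Independent maximum-matching oracle (Kuhn's augmenting-path algorithm) for
# the one-to-one detection/clip assignment: a detection may take any clip of
# its reported species within one grid interval. Returns the maximum number
# of correct matches achievable by ANY one-to-one assignment.
oracle_max_matches <- function(clips, detections) {
  n_det <- nrow(detections)
  n_clip <- nrow(clips)
  adj <- lapply(seq_len(n_det), function(k) {
    which(clips$species == detections$reported_species[k] &
            abs(clips$onset_interval - detections$interval_index[k]) <= 1L)
  })
  owner <- rep(0L, n_clip) # clip -> detection holding it, 0 = free
  seen <- logical(n_clip)
  try_augment <- function(k) {
    for (j in adj[[k]]) {
      if (!seen[j]) {
        seen[j] <<- TRUE
        if (owner[j] == 0L || try_augment(owner[j])) {
          owner[j] <<- k
          return(TRUE)
        }
      }
    }
    FALSE
  }
  matched <- 0L
  for (k in seq_len(n_det)) {
    seen <- logical(n_clip)
    if (try_augment(k)) matched <- matched + 1L
  }
  matched
}

# Closed-form per-clip outcome probabilities for the DDO branch logic with
# uniform-diagonal profiles: primary (p1, c1), secondary (p2, c2),
# collaboration kappa. Derived by enumerating the outcome tree.
ddo_expected <- function(p1, c1, p2, c2, kappa) {
  p_primary_mis <- p1 * (1 - c1) * (1 - kappa * p2 * c2)
  p_primary_ok <- p1 * (c1 + (1 - c1) * kappa * p2 * c2)
  p_secondary <- (1 - p1) * p2
  p_record <- p1 + p_secondary
  p_mis <- p_primary_mis + p_secondary * (1 - c2)
  list(p_record = p_record, p_mis = p_mis,
       misid_fraction = p_mis / p_record)
}

# All multisets of a given size from a value pool (for the exhaustive
# small-instance sweep).
multisets <- function(values, size) {
  if (size == 0L) return(list(integer(0)))
  combs <- utils::combn(length(values) + size - 1L, size)
  lapply(seq_len(ncol(combs)), function(i) {
    values[combs[, i] - seq_len(size) + 1L]
  })
}

roster_codes <- function() study_roster()$code

# Recover the true species behind each record of a jitter-free observer:
# generated schedules never put two clips in one grid interval, and with a
# point-mass-at-0 jitter every record sits in its clip's onset interval.
truth_species_for <- function(schedule, detections) {
  idx <- match(detections$interval_index, schedule$clips$onset_interval)
  stopifnot(!anyNA(idx))
  schedule$clips$species[idx]
}

std_scenarios <- function(n_surveys = 5L) {
  data.frame(
    scenario = c("expert_ddo", "expert_iso", "naive_ddo", "naive_iso"),
    experience = c("expert", "expert", "naive", "naive"),
    method = c("DDO", "ISO", "DDO", "ISO"),
    n_surveys = as.integer(n_surveys),
    observer_a = c("expert1", "expert1", "naive1", "naive1"),
    observer_b = c("expert2", NA, "naive2", NA),
    stringsAsFactors = FALSE)
}

std_profiles <- function(species = roster_codes()) {
  list(
    expert1 = observer_profile("expert", 0.95,
                               uniform_confusion(species, 0.97),
                               jitter = c(0.05, 0.9, 0.05)),
    expert2 = observer_profile("expert", 0.95,
                               uniform_confusion(species, 0.97),
                               jitter = c(0.05, 0.9, 0.05)),
    naive1 = observer_profile("naive", 0.85,
                              uniform_confusion(species, 0.75),
                              jitter = c(0.1, 0.8, 0.1)),
    naive2 = observer_profile("naive", 0.85,
                              uniform_confusion(species, 0.75),
                              jitter = c(0.1, 0.8, 0.1)))
}
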