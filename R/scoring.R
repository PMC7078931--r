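#' Score one survey's detections against its truth list
#'
#' Every detection is compared with the truth list under the 9-second
#' allowable window: a detection is correct when a clip of the reported
#' species lies in the same grid interval or one interval to either side,
#' and that clip is assigned to it. Assignment is one-to-one — each clip can
#' absorb at most one correct detection (removal logic), so a surplus
#' same-species detection near an already-matched clip is a false positive.
#'
#' Detections are processed in increasing interval order (ties by detection
#' id) and each takes the earliest unmatched same-species clip inside its
#' window (ties by clip id). For windows one interval wide on either side
#' this left-to-right, earliest-clip rule attains the maximum achievable
#' number of correct matches of any one-to-one assignment (it is the classic
#' exchange-argument greedy for interval-constrained bipartite matching);
#' counts are therefore invariant to the input order of detections.
#'
#' Unassigned detections are false positives. The cause is
#' `"misidentification"` when an unmatched clip of a different species lies
#' within the window — the detection is then attributed to the nearest such
#' clip (smaller absolute interval offset first, then earlier clip), each
#' clip absorbing at most one attribution — and `"out_of_window"` otherwise.
#'
#' @param schedule A [generate_schedule()] truth list.
#' @param detections Detections data.frame for the same survey (any row
#'   order; `role` is ignored — DDO surveys are scored on the union log).
#' @return Object of class `survey_score`: list with
#'   \describe{
#'     \item{detections}{scored data.frame adding `classification`
#'       (`correct`/`false_positive`), `fp_cause` (`none`/
#'       `misidentification`/`out_of_window`), `matched_clip_id`,
#'       `inferred_true_species`.}
#'     \item{n_detections, n_correct, n_fp}{partition counts
#'       (`n_correct + n_fp == n_detections` always).}
#'     \item{nondetections}{ids of truth clips with no correct detection.}
#'     \item{misid_clip_ids}{subset of `nondetections` attributed as the
#'       source of a misidentification.}
#'     \item{confusion_counts}{data.frame `true_species`,
#'       `reported_species`, `n` over attributed misidentifications.}
#'   }
#' @export
match_survey <- function(schedule, detections) {
  stopifnot(inherits(schedule, "survey_schedule"))
  clips <- schedule$clips
  if (nrow(detections) > 0 &&
      any(detections$survey_id != schedule$survey_id)) {
    stop("detections contain survey ids foreign to schedule '",
         schedule$survey_id, "'")
  }
  det <- detections[order(detections$interval_index,
                          detections$detection_id), , drop = FALSE]
  n_det <- nrow(det)
  matched <- rep(NA_integer_, n_det)
  taken <- rep(FALSE, nrow(clips))

  for (k in seq_len(n_det)) {
    cand <- which(!taken &
                    clips$species == det$reported_species[k] &
                    abs(clips$onset_interval - det$interval_index[k]) <= 1L)
    if (length(cand)) {
      pick <- cand[order(clips$onset_interval[cand], clips$clip_id[cand])][1L]
      taken[pick] <- TRUE
      matched[k] <- clips$clip_id[pick]
    }
  }

  fp_cause <- ifelse(is.na(matched), NA_character_, "none")
  inferred <- rep(NA_character_, n_det)
  attributed <- rep(FALSE, nrow(clips)) # one misID attribution per clip
  for (k in which(is.na(matched))) {
    off <- clips$onset_interval - det$interval_index[k]
    cand <- which(!taken &
                    clips$species != det$reported_species[k] &
                    abs(off) <= 1L)
    if (!length(cand)) {
      fp_cause[k] <- "out_of_window"
      next
    }
    fp_cause[k] <- "misidentification"
    fresh <- cand[!attributed[cand]]
    pool <- if (length(fresh)) fresh else cand
    pick <- pool[order(abs(off[pool]), clips$onset_interval[pool],
                       clips$clip_id[pool])][1L]
    inferred[k] <- clips$species[pick]
    attributed[pick] <- TRUE
  }

  det$classification <- ifelse(is.na(matched), "false_positive", "correct")
  det$fp_cause <- fp_cause
  det$matched_clip_id <- matched
  det$inferred_true_species <- inferred
  rownames(det) <- NULL

  misid <- det[det$fp_cause %in% "misidentification", , drop = FALSE]
  confusion <- if (nrow(misid)) {
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(misid))),
      by = list(true_species = misid$inferred_true_species,
                reported_species = misid$reported_species),
      FUN = sum)
    agg[order(agg$true_species, agg$reported_species), , drop = FALSE]
  } else {
    data.frame(true_species = character(0), reported_species = character(0),
               n = integer(0), stringsAsFactors = FALSE)
  }

  structure(
    list(survey_id = schedule$survey_id,
         detections = det,
         n_detections = n_det,
         n_correct = sum(!is.na(matched)),
         n_fp = sum(is.na(matched)),
         nondetections = clips$clip_id[!taken],
         misid_clip_ids = clips$clip_id[attributed],
         confusion_counts = confusion),
    class = "survey_score")
}

#' @export
print.survey_score <- function(x, ...) {
  cat(sprintf(
    "survey_score '%s': %d detections = %d correct + %d false positive; %d nondetections\n",
    x$survey_id, x$n_detections, x$n_correct, x$n_fp,
    length(x$nondetections)))
  invisible(x)
}

#' Score every survey of a campaign
#'
#' @param campaign A [simulate_campaign()] result.
#' @return Named list of [match_survey()] scores, keyed by survey id.
#' @export
score_campaign <- function(campaign) {
  stopifnot(inherits(campaign, "survey_campaign"))
  det <- campaign$detections
  lapply(campaign$schedules, function(sched) {
    d <- det[det$survey_id == sched$survey_id,
             c("survey_id", "detection_id", "interval_index",
               "reported_species", "role"), drop = FALSE]
    match_survey(sched, d)
  })
}

#' Aggregate pairwise misidentification counts
#'
#' Sums the attributed (true species -> reported species) misidentification
#' counts over many scored surveys into a square roster-ordered matrix.
#' Asymmetric by construction: confusing A for B is counted separately from
#' confusing B for A.
#'
#' @param scores List of [match_survey()] results.
#' @param species Character vector fixing row/column order (default the
#'   study roster codes).
#' @return Integer matrix, rows = true species, columns = reported species.
#' @export
confusion_counts <- function(scores, species = study_roster()$code) {
  m <- matrix(0L, length(species), length(species),
              dimnames = list(true = species, reported = species))
  for (s in scores) {
    cc <- s$confusion_counts
    for (r in seq_len(nrow(cc))) {
      if (!(cc$true_species[r] %in% species) ||
          !(cc$reported_species[r] %in% species)) {
        stop("confusion counts contain species outside the given roster")
      }
      m[cc$true_species[r], cc$reported_species[r]] <-
        m[cc$true_species[r], cc$reported_species[r]] + cc$n[r]
    }
  }
  m
}

#' Per-species truth/observation accounting
#'
#' For each species: the number of clips truly played (`truth_total`), the
#' number of detections reported as that species (`observed_total`), their
#' difference (`bias`), and the species' false positives and false
#' negatives. A misidentification simultaneously creates a false positive
#' for the reported species and a false negative for the true species, so
#' the identity `observed - truth = FP - FN` holds exactly for every
#' species (a species' FN count is its truth clips without a correct
#' detection: nondetections plus clips reported as something else).
#'
#' @param schedules Named list of truth lists.
#' @param scores List of [match_survey()] results for the same surveys.
#' @param species Species codes fixing the row order.
#' @return data.frame with columns `species`, `truth_total`,
#'   `observed_total`, `bias`, `n_fp`, `n_fn`.
#' @export
species_totals <- function(schedules, scores,
                           species = study_roster()$code) {
  schedules <- if (inherits(schedules, "survey_schedule")) list(schedules)
               else schedules
  scores <- if (inherits(scores, "survey_score")) list(scores) else scores
  sched_ids <- vapply(schedules, `[[`, character(1), "survey_id")
  score_ids <- vapply(scores, `[[`, character(1), "survey_id")
  if (!setequal(sched_ids, score_ids)) {
    stop("schedules and scores must cover the same surveys")
  }
  names(schedules) <- sched_ids
  tally <- function(codes) {
    as.integer(table(factor(codes, levels = species)))
  }
  truth <- observed <- fp <- correct <- integer(length(species))
  for (s in scores) {
    clips <- schedules[[s$survey_id]]$clips
    truth <- truth + tally(clips$species)
    d <- s$detections
    observed <- observed + tally(d$reported_species)
    fp <- fp + tally(d$reported_species[d$classification == "false_positive"])
    correct <- correct + tally(d$reported_species[
      d$classification == "correct"])
  }
  data.frame(species = species,
             truth_total = as.integer(truth),
             observed_total = as.integer(observed),
             bias = as.integer(observed - truth),
             n_fp = as.integer(fp),
             n_fn = as.integer(truth - correct),
             row.names = NULL, stringsAsFactors = FALSE)
}
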