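# Plain-text interchange formats. Schedules and detections travel as
# tab-delimited UTF-8 files with header rows so any stage can be rerun from
# files alone.

#' Write truth lists to a schedule TSV
#'
#' One clip per row: `survey_id`, `clip_id`, `species`, `onset_s`,
#' `onset_interval`. Tab-delimited with a header.
#'
#' @param schedules A `survey_schedule`, a list of them, or a
#'   `schedule_batch`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedules <- function(schedules, path) {
  schedules <- as_schedule_list(schedules)
  rows <- lapply(schedules, function(s) {
    cbind(survey_id = s$survey_id, s$clips, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read truth lists from a schedule TSV
#'
#' @param path File written by [write_schedules()].
#' @param config The [schedule_config()] the schedules were generated
#'   under (the file stores clips, not the grid geometry).
#' @return Named list of `survey_schedule` objects.
#' @export
read_schedules <- function(path, config = schedule_config()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("survey_id", "clip_id", "species", "onset_s", "onset_interval")
  if (!all(need %in% names(tab))) {
    stop("schedule file must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$survey_id), function(d) {
    sid <- d$survey_id[1]
    clips <- d[order(d$onset_s),
               c("clip_id", "species", "onset_s", "onset_interval")]
    rownames(clips) <- NULL
    clips$clip_id <- as.integer(clips$clip_id)
    clips$onset_interval <- as.integer(clips$onset_interval)
    structure(list(survey_id = sid, config = config, clips = clips),
              class = "survey_schedule")
  })
  out[unique(tab$survey_id)]
}

#' Write a detections TSV
#'
#' @param detections Detections data.frame (from [simulate_iso()],
#'   [simulate_ddo()] or a campaign's `$detections`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.table(detections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a detections TSV
#'
#' @param path File written by [write_detections()].
#' @return Detections data.frame.
#' @export
read_detections <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("survey_id", "detection_id", "interval_index",
            "reported_species", "role")
  if (!all(need %in% names(tab))) {
    stop("detections file must have columns: ", paste(need, collapse = ", "))
  }
  tab$detection_id <- as.integer(tab$detection_id)
  tab$interval_index <- as.integer(tab$interval_index)
  tab
}

as_schedule_list <- function(schedules) {
  if (inherits(schedules, "schedule_batch")) return(schedules$schedules)
  if (inherits(schedules, "survey_schedule")) return(list(schedules))
  stopifnot(is.list(schedules),
            all(vapply(schedules, inherits, logical(1), "survey_schedule")))
  schedules
}
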