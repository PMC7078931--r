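# Interval 25 is the 1:15-1:18 window of a 3-minute survey.

test_that("the 9-second allowable window accepts a one-interval offset and rejects two", {
  s <- make_schedule(25, "WEME")
  for (int in 24:26) {
    sc <- match_survey(s, make_detections(int, "WEME"))
    expect_identical(sc$n_correct, 1L)
    expect_identical(sc$detections$fp_cause, "none")
    expect_identical(sc$detections$matched_clip_id, 1L)
  }
  for (int in c(23, 27)) {
    sc <- match_survey(s, make_detections(int, "WEME"))
    expect_identical(sc$n_fp, 1L)
    expect_identical(sc$detections$fp_cause, "out_of_window")
  }
})

test_that("an empty detection log leaves every clip a nondetection", {
  s <- make_schedule(c(2, 10, 30), c("BHCO", "HOLA", "KILL"))
  sc <- match_survey(s, make_detections(integer(0), character(0)))
  expect_identical(sc$n_detections, 0L)
  expect_identical(sc$n_fp, 0L)
  expect_identical(sc$nondetections, 1:3)
})

test_that("detections from a foreign survey are refused", {
  s <- make_schedule(5, "BHCO", survey_id = "A")
  expect_error(match_survey(s, make_detections(5, "BHCO", survey_id = "B")),
               "foreign")
})

test_that("a wrong-species report is a misidentification attributed to the source clip", {
  s <- make_schedule(25, "MCLO")
  sc <- match_survey(s, make_detections(25, "HOLA"))
  expect_identical(sc$n_fp, 1L)
  expect_identical(sc$detections$fp_cause, "misidentification")
  expect_identical(sc$detections$inferred_true_species, "MCLO")
  expect_identical(sc$misid_clip_ids, 1L)
  expect_identical(sc$nondetections, 1L)
  cc <- sc$confusion_counts
  expect_identical(nrow(cc), 1L)
  expect_identical(cc$true_species, "MCLO")
  expect_identical(cc$reported_species, "HOLA")
  expect_identical(cc$n, 1L)
})

test_that("each clip absorbs at most one correct detection (removal logic)", {
  s <- make_schedule(25, "VESP")
  sc <- match_survey(s, make_detections(c(25, 26), c("VESP", "VESP")))
  expect_identical(sc$n_correct, 1L)
  expect_identical(sc$n_fp, 1L)
  # the surplus same-species detection has no unmatched clip to blame
  expect_identical(sc$detections$fp_cause[sc$detections$classification ==
                                            "false_positive"],
                   "out_of_window")
})

test_that("misidentification cause requires an unmatched different-species clip in window", {
  # SAVS clip is matched by its own detection, so the stray VESP report two
  # intervals from anything unmatched is out_of_window
  s <- make_schedule(c(10, 20), c("SAVS", "VESP"))
  det <- make_detections(c(10, 14), c("SAVS", "SAVS"))
  sc <- match_survey(s, det)
  expect_identical(sc$n_correct, 1L)
  fp <- sc$detections[sc$detections$classification == "false_positive", ]
  expect_identical(fp$fp_cause, "out_of_window")

  # but an unmatched VESP clip next door makes it a misidentification
  det <- make_detections(c(10, 21), c("SAVS", "SAVS"))
  sc <- match_survey(s, det)
  fp <- sc$detections[sc$detections$classification == "false_positive", ]
  expect_identical(fp$fp_cause, "misidentification")
  expect_identical(fp$inferred_true_species, "VESP")
})

test_that("misidentification attribution prefers the smaller offset and is one-to-one", {
  s <- make_schedule(c(9, 10), c("HOLA", "LBCU"))
  sc <- match_survey(s, make_detections(10, "KILL"))
  expect_identical(sc$detections$inferred_true_species, "LBCU")
  # two identical FPs: second attribution falls to the remaining clip
  sc <- match_survey(s, make_detections(c(10, 10), c("KILL", "KILL")))
  expect_setequal(sc$detections$inferred_true_species, c("LBCU", "HOLA"))
  expect_setequal(sc$misid_clip_ids, 1:2)
})

test_that("classification partitions detections and conserves clips", {
  profs <- std_profiles()
  for (seed in 1:15) {
    s <- generate_schedule(schedule_config(), seed = seed)
    d <- simulate_iso(s, profs$naive1, seed = 100 + seed)
    sc <- match_survey(s, d)
    expect_identical(sc$n_correct + sc$n_fp, sc$n_detections)
    expect_identical(sc$n_detections, nrow(d))
    # clip conservation: matched + nondetections = all clips;
    # misID-attributed clips are a subset of the nondetections
    expect_identical(sc$n_correct + length(sc$nondetections), nrow(s$clips))
    expect_true(all(sc$misid_clip_ids %in% sc$nondetections))
    # no clip double-credited
    m <- sc$detections$matched_clip_id
    expect_identical(anyDuplicated(m[!is.na(m)]), 0L)
  }
})

test_that("scoring counts are invariant to detection input order", {
  profs <- std_profiles()
  for (seed in 1:10) {
    s <- generate_schedule(schedule_config(), seed = seed)
    d <- simulate_iso(s, profs$naive1, seed = 200 + seed)
    if (nrow(d) < 2) next
    sc1 <- match_survey(s, d)
    set.seed(seed)
    sc2 <- match_survey(s, d[sample.int(nrow(d)), ])
    expect_identical(sc1$n_correct, sc2$n_correct)
    expect_identical(sc1$detections, sc2$detections)
    expect_identical(sc1$nondetections, sc2$nondetections)
  }
})

test_that("greedy matching attains the assignment optimum on an exhaustive small sweep", {
  cfg <- schedule_config()
  # one species: every clip multiset from intervals 0..3 (size <= 3) against
  # every detection multiset from intervals 0..4 (size <= 3)
  clip_sets <- unlist(lapply(0:3, function(k) multisets(0:3, k)),
                      recursive = FALSE)
  det_sets <- unlist(lapply(0:3, function(k) multisets(0:4, k)),
                     recursive = FALSE)
  for (cs in clip_sets) {
    for (ds in det_sets) {
      s <- make_schedule(cs, "WEME", config = cfg)
      d <- make_detections(ds, "WEME")
      sc <- match_survey(s, d)
      expect_identical(sc$n_correct, oracle_max_matches(s$clips, d))
    }
  }
})

test_that("greedy matching attains the optimum on random two-species instances", {
  set.seed(404)
  for (i in 1:300) {
    n_c <- sample(0:6, 1)
    n_d <- sample(0:6, 1)
    s <- make_schedule(sample(0:7, n_c, replace = TRUE),
                       sample(c("HOLA", "MCLO"), max(n_c, 1), replace = TRUE))
    d <- make_detections(sample(0:8, n_d, replace = TRUE),
                         sample(c("HOLA", "MCLO"), max(n_d, 1),
                                replace = TRUE))
    d <- d[seq_len(n_d), , drop = FALSE]
    sc <- match_survey(s, d)
    expect_identical(sc$n_correct, oracle_max_matches(s$clips, d))
  }
})

test_that("the adversarial staircase instance is matched optimally", {
  # exact-interval-first or later-clip-first preferences would strand the
  # second detection here; earliest-clip greedy must find both matches
  s <- make_schedule(c(1, 3), c("LARB", "LARB"))
  sc <- match_survey(s, make_detections(c(2, 4), c("LARB", "LARB")))
  expect_identical(sc$n_correct, 2L)
  s <- make_schedule(c(1, 2), c("LARB", "LARB"))
  sc <- match_survey(s, make_detections(c(2, 3), c("LARB", "LARB")))
  expect_identical(sc$n_correct, 2L)
})

test_that("aggregated confusion counts reproduce a planted asymmetry", {
  sp <- roster_codes()
  conf <- uniform_confusion(sp, 1)
  q_mh <- 0.35; q_hm <- 0.05
  conf["MCLO", "MCLO"] <- 1 - q_mh; conf["MCLO", "HOLA"] <- q_mh
  conf["HOLA", "HOLA"] <- 1 - q_hm; conf["HOLA", "MCLO"] <- q_hm
  obs <- observer_profile("x", 1, conf)
  scores <- list()
  for (seed in 1:120) {
    s <- generate_schedule(schedule_config(), seed = seed)
    scores[[seed]] <- match_survey(s, simulate_iso(s, obs,
                                                   seed = 900 + seed))
  }
  m <- confusion_counts(scores)
  expect_gt(m["MCLO", "HOLA"], m["HOLA", "MCLO"])
  expect_identical(sum(m) - m["MCLO", "HOLA"] - m["HOLA", "MCLO"], 0L)
})

test_that("confusion aggregation of no-error surveys is the zero matrix", {
  s <- generate_schedule(schedule_config(), seed = 5)
  sc <- match_survey(s, simulate_iso(s, perfect_observer(), seed = 1))
  expect_identical(sum(confusion_counts(list(sc))), 0L)
})

test_that("species accounting: perfect observers have zero bias everywhere", {
  s <- generate_schedule(schedule_config(), seed = 6)
  sc <- match_survey(s, simulate_iso(s, perfect_observer(), seed = 1))
  tot <- species_totals(s, sc)
  expect_true(all(tot$bias == 0L))
  expect_true(all(tot$n_fp == 0L))
  expect_true(all(tot$n_fn == 0L))
})

test_that("one misidentification debits the true species and credits the reported one", {
  s <- make_schedule(25, "MCLO")
  sc <- match_survey(s, make_detections(25, "HOLA"))
  tot <- species_totals(s, sc)
  expect_identical(tot$bias[tot$species == "MCLO"], -1L)
  expect_identical(tot$n_fn[tot$species == "MCLO"], 1L)
  expect_identical(tot$bias[tot$species == "HOLA"], 1L)
  expect_identical(tot$n_fp[tot$species == "HOLA"], 1L)
})

test_that("the bias identity observed - truth = FP - FN holds on random campaigns", {
  camp <- simulate_campaign(std_scenarios(3L), std_profiles(), seed = 51)
  scores <- score_campaign(camp)
  tot <- species_totals(camp$schedules, scores)
  expect_identical(tot$observed_total - tot$truth_total,
                   tot$n_fp - tot$n_fn)
  expect_identical(sum(tot$truth_total),
                   sum(vapply(camp$schedules,
                              function(s) nrow(s$clips), integer(1))))
})
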