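reg <- default_registry("in_vivo")

test_that("validate_evaluation flags coverage, range and system mismatch", {
  ev <- uniform_evaluation(reg, 0)
  expect_equal(nrow(validate_evaluation(ev, reg)), 0)

  missing <- ev
  missing$scores <- ev$scores[setdiff(names(ev$scores), "pc_shape")]
  issues <- validate_evaluation(missing, reg)
  expect_equal(issues$rule, "missing_criterion")
  expect_equal(issues$criterion_id, "pc_shape")

  out_of_range <- ev
  out_of_range$scores[["ra_statistics"]] <- 3L
  issues <- validate_evaluation(out_of_range, reg)
  expect_equal(issues$rule, "score_out_of_range")

  wrong_system <- uniform_evaluation(default_registry("in_vitro"), 1)
  wrong_system$scores <- ev$scores
  expect_true("study_system_mismatch" %in%
                validate_evaluation(wrong_system, reg)$rule)
})

test_that("consensus rules: min, mode with low tie-break, strict", {
  base <- uniform_evaluation(reg, 2, rater_id = "a")
  r2 <- uniform_evaluation(reg, 2, rater_id = "b")
  r2$scores[["pc_size"]] <- 1L
  r3 <- uniform_evaluation(reg, 2, rater_id = "c")
  r3$scores[["pc_size"]] <- 1L
  r3$scores[["ra_statistics"]] <- 0L

  cmin <- consensus(list(base, r2, r3), "min")
  expect_equal(unname(cmin$scores[["pc_size"]]), 1L)
  expect_equal(unname(cmin$scores[["ra_statistics"]]), 0L)
  expect_setequal(cmin$discordant$criterion_id, c("pc_size", "ra_statistics"))

  # mode: (2,1,1) -> 1 by majority; two-rater (2,1) tie -> lower level
  cmode <- consensus(list(base, r2, r3), "mode")
  expect_equal(unname(cmode$scores[["pc_size"]]), 1L)
  ctie <- consensus(list(base, r2), "mode")
  expect_equal(unname(ctie$scores[["pc_size"]]), 1L)

  expect_error(consensus(list(base, r2), "strict"), "pc_size")
  expect_error(consensus(list(), "min"), "no evaluations")

  # identical raters agree under every rule, with empty discordance
  for (rule in c("min", "mode", "strict")) {
    cc <- consensus(list(base, base), rule)
    expect_equal(cc$scores, base$scores)
    expect_equal(nrow(cc$discordant), 0)
  }
})

test_that("consensus(min) is a pointwise lower bound and idempotent", {
  set.seed(41)
  for (i in 1:20) {
    raters <- lapply(c("a", "b", "c"), function(r)
      random_evaluation(reg, "s1", r))
    cc <- consensus(raters, "min")
    for (ev in raters) {
      expect_true(all(cc$scores[names(ev$scores)] <= ev$scores))
    }
    for (rule in c("min", "mode", "strict")) {
      expect_equal(consensus(list(raters[[1]]), rule)$scores,
                   raters[[1]]$scores)
    }
  }
})

test_that("summarize_evaluation computes subtotals, TAS, percent, fraction", {
  top <- summarize_evaluation(uniform_evaluation(reg, 2), reg)
  expect_equal(top$tas, 52)
  expect_equal(top$tas_percent, 100)
  expect_equal(top$max_score_fraction, 1.0)
  expect_equal(top$n_zero, 0)
  expect_equal(top$particle_characterization, 16)
  expect_equal(top$study_design, 26)
  expect_equal(top$risk_assessment, 10)

  mid <- summarize_evaluation(uniform_evaluation(reg, 1), reg)
  expect_equal(mid$tas, 26)
  expect_equal(mid$tas_percent, 50)
  expect_equal(mid$max_score_fraction, 0)

  bottom <- summarize_evaluation(uniform_evaluation(reg, 0), reg)
  expect_equal(bottom$tas, 0)
  expect_equal(bottom$tas_percent, 0)
  expect_equal(bottom$n_zero, 26)

  bad <- uniform_evaluation(reg, 1)
  bad$scores <- bad$scores[-1]
  expect_error(summarize_evaluation(bad, reg), "missing_criterion")
})

test_that("TAS equals the sum of category subtotals on random evaluations", {
  set.seed(42)
  for (i in 1:50) {
    r <- if (i %% 2) reg else default_registry("in_vitro")
    ev <- random_evaluation(r, "s1")
    summ <- summarize_evaluation(ev, r)
    expect_equal(summ$tas, summ$particle_characterization +
                   summ$study_design + summ$risk_assessment)
    expect_equal(summ$tas, oracle_tas(ev$scores))
    for (cat in c("particle_characterization", "study_design",
                  "risk_assessment")) {
      expect_equal(summ[[cat]], oracle_subtotal(ev$scores, r, cat))
    }
  }
})

test_that("tas_percent rounds half away from zero and guards its domain", {
  expect_equal(tas_percent(44, 52), 85)
  expect_equal(tas_percent(37, 52), 71)
  expect_equal(tas_percent(34, 46), 74)
  expect_equal(tas_percent(12, 52), 23)
  expect_equal(tas_percent(16, 46), 35)
  # exact-half case rounds up
  expect_equal(tas_percent(1, 8), 13)
  for (tmax in c(1, 2, 46, 52)) {
    expect_equal(tas_percent(tmax, tmax), 100)
    expect_equal(tas_percent(0, tmax), 0)
  }
  expect_error(tas_percent(5, 0), "positive")
  expect_error(tas_percent(53, 52), "lie in")
  expect_error(tas_percent(-1, 52), "lie in")
})

test_that("dose-response suggestion implements the 3-dose / 3x rule", {
  expect_equal(suggest_dose_response_score(3, TRUE, 3.0), 2L)
  expect_equal(suggest_dose_response_score(5, TRUE, 10), 2L)
  expect_equal(suggest_dose_response_score(2, TRUE, 10.0), 1L)
  expect_equal(suggest_dose_response_score(3, TRUE, 2.0), 1L)
  expect_equal(suggest_dose_response_score(3, FALSE, 10.0), 0L)
  expect_equal(suggest_dose_response_score(1, FALSE), 0L)
  expect_equal(suggest_dose_response_score(0, TRUE), 0L)
  expect_error(suggest_dose_response_score(-1, TRUE), "non-negative")
})

test_that("particle size context follows the 150 um and 1.5 um bounds", {
  expect_equal(particle_size_context(200), "unlikely_absorbed_local_effects")
  expect_equal(particle_size_context(1.0), "epithelial_crossing_possible")
  expect_equal(particle_size_context(50), "intermediate_limited_absorption")
  # bounds themselves are intermediate (the stated rules are strict)
  expect_equal(particle_size_context(150), "intermediate_limited_absorption")
  expect_equal(particle_size_context(1.5), "intermediate_limited_absorption")
  expect_error(particle_size_context(0), "positive")
})
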