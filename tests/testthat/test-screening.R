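reg <- default_registry("in_vivo")

test_that("red-criteria gate passes on red levels alone, independent of TAS", {
  # red criteria at 1, everything else 0: a low-TAS study still passes
  ev <- red_profile_evaluation(reg, red_level = 1, other_level = 0)
  check <- red_criteria_check(ev, reg)
  expect_true(check$pass)
  expect_equal(check$failing, character(0))

  top <- uniform_evaluation(reg, 2)
  expect_true(red_criteria_check(top, reg)$pass)

  one_fail <- top
  one_fail$scores[["pc_size"]] <- 0L
  check <- red_criteria_check(one_fail, reg)
  expect_false(check$pass)
  expect_equal(check$failing, "pc_size")

  # failing list keeps registry order
  two_fail <- top
  two_fail$scores[["ra_dose_response"]] <- 0L
  two_fail$scores[["pc_shape"]] <- 0L
  expect_equal(red_criteria_check(two_fail, reg)$failing,
               c("pc_shape", "ra_dose_response"))

  # a registry without red criteria cannot gate
  no_red <- reg
  no_red$criteria$red <- FALSE
  expect_error(red_criteria_check(uniform_evaluation(no_red, 1), no_red),
               "no red criteria")

  # stricter minimum level
  strict_cfg <- classification_config(red_min_level = 2)
  expect_false(red_criteria_check(ev, reg, strict_cfg)$pass)
  expect_true(red_criteria_check(top, reg, strict_cfg)$pass)
})

test_that("Fernandez-Cruz classes and boundary inclusivity", {
  expect_equal(fernandez_cruz_class(uniform_evaluation(reg, 2), reg),
               "reliable")
  # straight 1s: half the TAS maximum but nothing at the maximum score
  expect_equal(fernandez_cruz_class(uniform_evaluation(reg, 1), reg),
               "not_reliable")

  # 20/26 criteria at 2, rest 1, red pass: 0.769 in the restricted band
  ev <- uniform_evaluation(reg, 2)
  non_red <- setdiff(criterion_ids(reg), red_criteria(reg))
  ev$scores[non_red[1:6]] <- 1L
  expect_equal(sum(ev$scores == 2L), 20)
  expect_equal(fernandez_cruz_class(ev, reg), "reliable_with_restrictions")

  # red failure forces not_reliable whatever the fraction
  red_fail <- uniform_evaluation(reg, 2)
  red_fail$scores[["pc_polymer"]] <- 0L
  expect_equal(fernandez_cruz_class(red_fail, reg), "not_reliable")

  # boundary behaviour on a 20-criterion synthetic registry:
  # 17/20 = 0.85 exactly -> restricted (cutoff is strict >)
  reg20 <- criteria_registry("r20", "0", "in_vivo", reg$criteria[1:20, ])
  ids20 <- criterion_ids(reg20)
  ev20 <- uniform_evaluation(reg20, 2)
  ev20$scores[setdiff(ids20, red_criteria(reg20))[1:3]] <- 1L
  expect_equal(sum(ev20$scores == 2L) / 20, 0.85)
  expect_equal(fernandez_cruz_class(ev20, reg20),
               "reliable_with_restrictions")

  # 61/100 = 0.61 exactly -> restricted (lower bound inclusive)
  reg100 <- criteria_registry("r100", "0", "in_vivo",
    do.call(rbind, lapply(1:100, function(i) {
      row <- reg$criteria[1 + (i - 1) %% 26, ]
      row$id <- sprintf("c%03d", i)
      row$red <- i == 1
      row
    })))
  ev100 <- uniform_evaluation(reg100, 1)
  ev100$scores[sprintf("c%03d", 1:61)] <- 2L
  expect_equal(fernandez_cruz_class(ev100, reg100),
               "reliable_with_restrictions")
  ev100$scores[["c061"]] <- 1L  # 0.60 -> below the band
  expect_equal(fernandez_cruz_class(ev100, reg100), "not_reliable")
})

test_that("the tas_percent basis classifies TAS/TAS-max against the cutoffs", {
  cfg <- classification_config(basis = "tas_percent")
  # straight 1s = 50% of maximum: still below the restricted band
  expect_equal(fernandez_cruz_class(uniform_evaluation(reg, 1), reg, cfg),
               "not_reliable")
  # 44/52 = 0.846: restricted under the percent basis
  ev <- red_profile_evaluation(reg, 2, 2)
  non_red <- setdiff(criterion_ids(reg), red_criteria(reg))
  ev$scores[non_red[1:8]] <- 1L
  expect_equal(sum(ev$scores), 44)
  expect_equal(fernandez_cruz_class(ev, reg, cfg),
               "reliable_with_restrictions")
})

test_that("de Ruijter adequacy is the all-nonzero rule", {
  expect_true(de_ruijter_adequate(uniform_evaluation(reg, 1), reg))
  expect_true(de_ruijter_adequate(uniform_evaluation(reg, 2), reg))
  one_zero <- uniform_evaluation(reg, 2)
  one_zero$scores[["sd_stability"]] <- 0L
  expect_false(de_ruijter_adequate(one_zero, reg))
})

test_that("tier1_screen orders stably and is permutation invariant", {
  set.seed(99)
  evs <- c(
    list(red_profile_evaluation(reg, 1, 0, "low_pass"),
         uniform_evaluation(reg, 2, study_id = "top"),
         red_profile_evaluation(reg, 0, 2, "red_fail")),
    lapply(sprintf("s%02d", 1:5), function(id) random_evaluation(reg, id))
  )
  scr <- tier1_screen(evs, reg)
  expect_equal(nrow(scr), 8)
  expect_equal(scr$tier1_prioritized, scr$red_pass)
  # prioritized block first, decreasing TAS within, id as tie-break
  expect_true(all(diff(scr$tier1_prioritized) <= 0))
  pri <- scr[scr$tier1_prioritized, ]
  expect_true(all(diff(pri$tas) <= 0))
  expect_false(scr$tier1_prioritized[scr$study_id == "red_fail"])

  shuffled <- tier1_screen(evs[sample(length(evs))], reg)
  expect_identical(scr, shuffled)

  expect_equal(nrow(tier1_screen(list(), reg)), 0)

  mixed <- c(evs[1], list(uniform_evaluation(default_registry("in_vitro"), 1)))
  expect_error(tier1_screen(mixed, reg), "mixes study systems")
})

test_that("scheme implications hold on randomized evaluations", {
  set.seed(7)
  for (i in 1:100) {
    r <- if (i %% 2) reg else default_registry("in_vitro")
    ev <- random_evaluation(r, "s1", prob = c(1, 2, 3))
    red_pass <- red_criteria_check(ev, r)$pass
    if (de_ruijter_adequate(ev, r)) expect_true(red_pass)
    if (fernandez_cruz_class(ev, r) != "not_reliable") expect_true(red_pass)
  }
})
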