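reg <- default_registry("in_vivo")

test_that("criterion distributions match a brute-force recount", {
  evs <- list(
    random_evaluation(reg, "a", exposure_route = "oral",
                      material_class = "nmp"),
    random_evaluation(reg, "b", exposure_route = "oral",
                      material_class = "nmp"),
    random_evaluation(reg, "c", exposure_route = "oral",
                      material_class = "cellulose"),
    random_evaluation(reg, "d", exposure_route = "inhalation",
                      material_class = "nmp"))
  dist <- criterion_distributions(evs, reg)
  # one row per (criterion, stratum); three strata here
  expect_equal(nrow(dist), 26 * 3)

  for (stratum in split(dist, paste(dist$exposure_route,
                                    dist$material_class))) {
    in_stratum <- Filter(function(ev)
      ev$metadata$exposure_route == stratum$exposure_route[1] &&
        ev$metadata$material_class == stratum$material_class[1], evs)
    maps <- lapply(in_stratum, `[[`, "scores")
    for (j in seq_len(nrow(stratum))) {
      counts <- oracle_level_counts(maps, stratum$criterion_id[j])
      expect_equal(unname(unlist(stratum[j, c("n0", "n1", "n2")])),
                   unname(counts))
      # partition: levels sum to the stratum size
      expect_equal(sum(stratum[j, c("n0", "n1", "n2")]), length(in_stratum))
    }
  }

  # nmp and cellulose rows are disjoint
  expect_equal(sum(dist$material_class == "cellulose"), 26)
  expect_equal(nrow(criterion_distributions(list(), reg)), 0)
})

test_that("single-study distributions put the whole mass on the scored level", {
  ev <- uniform_evaluation(reg, 2)
  dist <- criterion_distributions(list(ev), reg, strata = character(0))
  expect_equal(nrow(dist), 26)
  expect_true(all(dist$n2 == 1 & dist$n0 == 0 & dist$n1 == 0))
})

test_that("corpus_summary computes stratum TAS statistics and metadata", {
  mk <- function(id, level, size = NA_real_, polymer = NA_character_) {
    ev <- uniform_evaluation(reg, level, study_id = id)
    ev$metadata <- study_meta(study_system = "in_vivo",
                              exposure_route = "oral", material_class = "nmp",
                              polymer = polymer, median_size_um = size)
    ev
  }
  single <- corpus_summary(list(mk("a", 1)), reg)
  expect_equal(single$tas_by_stratum$tas_min, 26)
  expect_equal(single$tas_by_stratum$tas_mean, 26)
  expect_equal(single$tas_by_stratum$tas_max_observed, 26)
  expect_equal(single$tas_by_stratum$tas_mean_percent, 50)

  two <- corpus_summary(list(mk("a", 0), mk("b", 2)), reg)
  expect_equal(two$tas_by_stratum$n_studies, 2)
  expect_equal(two$tas_by_stratum$tas_mean, 26)
  expect_equal(two$tas_by_stratum$tas_min, 0)
  expect_equal(two$tas_by_stratum$tas_max_observed, 52)

  # mean percent comes from the unrounded mean
  three <- corpus_summary(list(mk("a", 1), mk("b", 1), mk("c", 2)), reg)
  expect_equal(three$tas_by_stratum$tas_mean, mean(c(26, 26, 52)))
  expect_equal(three$tas_by_stratum$tas_mean_percent,
               100 * mean(c(26, 26, 52)) / 52)

  with_meta <- corpus_summary(
    list(mk("a", 1, size = 2.2, polymer = "polystyrene"),
         mk("b", 1, size = 0.5, polymer = "polystyrene"),
         mk("c", 1, size = 12, polymer = "polyethylene")), reg)
  expect_equal(with_meta$particle_size$median, 2.2)
  expect_equal(with_meta$particle_size$mean, mean(c(2.2, 0.5, 12)))
  expect_equal(with_meta$particle_size$sd, sd(c(2.2, 0.5, 12)))
  expect_equal(with_meta$polymer_freq$value[1], "polystyrene")
  expect_equal(with_meta$polymer_freq$n, c(2L, 1L))

  expect_error(corpus_summary(list(), reg), "no evaluations")
})

test_that("adding a study never decreases the observed TAS maximum", {
  set.seed(11)
  evs <- lapply(sprintf("s%d", 1:5), function(id) random_evaluation(reg, id))
  for (n in 2:5) {
    prev <- corpus_summary(evs[1:(n - 1)], reg, strata = character(0))
    curr <- corpus_summary(evs[1:n], reg, strata = character(0))
    expect_gte(curr$tas_by_stratum$tas_max_observed,
               prev$tas_by_stratum$tas_max_observed)
    expect_equal(curr$tas_by_stratum$n_studies, n)
  }
})

test_that("prioritization_table lists red-passing studies by TAS then id", {
  evs <- list(red_profile_evaluation(reg, 1, 1, "b_mid"),
              red_profile_evaluation(reg, 1, 1, "a_mid"),
              uniform_evaluation(reg, 2, study_id = "top"),
              red_profile_evaluation(reg, 0, 2, "gated_out"))
  scr <- tier1_screen(evs, reg)
  tab <- prioritization_table(evs, scr,
    annotations = list(top = list(strengths = "full marks")))
  expect_equal(tab$study_id, c("top", "a_mid", "b_mid"))  # tie by id
  expect_equal(tab$tas[1], 52)
  expect_equal(tab$tas_label[1], "52 /52")
  expect_equal(tab$strengths[1], "full marks")
  expect_equal(tab$strengths[2], "")

  expect_warning(prioritization_table(evs, scr,
    annotations = list(ghost = list(strengths = "x"))), "unknown")

  none <- tier1_screen(list(red_profile_evaluation(reg, 0, 2, "x")), reg)
  expect_equal(nrow(prioritization_table(list(), none)), 0)
})
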