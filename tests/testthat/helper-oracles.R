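# Independent brute-force oracles and random-input generators. These
# recompute every quantity from the raw score maps by plain loops, never
# through the package's aggregation code paths.

oracle_tas <- function(scores) {
  total <- 0L
  for (s in scores) total <- total + s
  total
}

oracle_subtotal <- function(scores, registry, category) {
  total <- 0L
  for (i in seq_len(nrow(registry$criteria))) {
    if (registry$criteria$category[i] == category) {
      total <- total + scores[[registry$criteria$id[i]]]
    }
  }
  total
}

oracle_fraction_at_max <- function(scores) {
  n2 <- 0L
  for (s in scores) if (s == 2L) n2 <- n2 + 1L
  n2 / length(scores)
}

oracle_red_pass <- function(scores, registry, red_min = 1L) {
  for (id in registry$criteria$id[registry$criteria$red]) {
    if (scores[[id]] < red_min) return(FALSE)
  }
  TRUE
}

oracle_fernandez <- function(scores, registry, basis = "max_score_fraction",
                             red_min = 1L) {
  frac <- if (basis == "max_score_fraction") oracle_fraction_at_max(scores)
          else oracle_tas(scores) / (2 * nrow(registry$criteria))
  if (!oracle_red_pass(scores, registry, red_min)) return("not_reliable")
  if (frac > 0.85) "reliable"
  else if (frac >= 0.61) "reliable_with_restrictions"
  else "not_reliable"
}

oracle_de_ruijter <- function(scores) {
  for (s in scores) if (s == 0L) return(FALSE)
  TRUE
}

# level counts for one criterion over a list of score maps
oracle_level_counts <- function(score_maps, criterion_id) {
  counts <- c(`0` = 0L, `1` = 0L, `2` = 0L)
  for (m in score_maps) {
    lev <- as.character(m[[criterion_id]])
    counts[lev] <- counts[lev] + 1L
  }
  counts
}

# ---- generators -------------------------------------------------------------

random_scores <- function(registry, prob = NULL) {
  ids <- registry$criteria$id
  stats::setNames(sample(0:2, length(ids), replace = TRUE, prob = prob), ids)
}

random_evaluation <- function(registry, study_id, rater_id = "r1",
                              prob = NULL,
                              exposure_route = "oral",
                              material_class = "nmp") {
  study_evaluation(
    study_id, rater_id, random_scores(registry, prob),
    registry_name = registry$name,
    metadata = study_meta(study_system = registry$study_system,
                          exposure_route = exposure_route,
                          material_class = material_class))
}

uniform_evaluation <- function(registry, level, study_id = "s1",
                               rater_id = "r1") {
  ids <- registry$criteria$id
  study_evaluation(
    study_id, rater_id,
    stats::setNames(rep(as.integer(level), length(ids)), ids),
    registry_name = registry$name,
    metadata = study_meta(study_system = registry$study_system))
}

# evaluation scoring `red_level` on every red criterion and `other_level`
# elsewhere
red_profile_evaluation <- function(registry, red_level, other_level,
                                   study_id = "s1") {
  ids <- registry$criteria$id
  sc <- stats::setNames(rep(as.integer(other_level), length(ids)), ids)
  sc[registry$criteria$id[registry$criteria$red]] <- as.integer(red_level)
  study_evaluation(study_id, "r1", sc, registry_name = registry$name,
                   metadata = study_meta(study_system = registry$study_system))
}
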