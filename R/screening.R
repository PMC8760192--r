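# The three screening/classification schemes: red-criteria Tier-1 gate,
# Fernandez-Cruz reliability classes, de Ruijter all-nonzero adequacy.

FERNANDEZ_CLASSES <- c("reliable", "reliable_with_restrictions", "not_reliable")

#' Classification configuration
#'
#' Tuning knobs for the screening schemes. The Fernandez-Cruz cut-offs
#' are applied by default to the fraction of criteria at the maximum
#' score (`basis = "max_score_fraction"`): reliable strictly above 0.85,
#' reliable with restrictions from 0.61 up to and including 0.85, not
#' reliable below 0.61 — in each case additionally requiring the red
#' criteria to be met. The same cut-offs can instead be applied to
#' TAS/TAS-max (`basis = "tas_percent"`). `red_min_level` is the minimum
#' score every red criterion must reach for the Tier-1 gate (default 1).
#'
#' @param basis `"max_score_fraction"` (default) or `"tas_percent"`.
#' @param reliable_cutoff Proportion above which (strictly) a red-passing
#'   study is `reliable`. Default 0.85.
#' @param restricted_lower Inclusive lower bound of the
#'   `reliable_with_restrictions` band. Default 0.61.
#' @param red_min_level Minimum score required on every red criterion,
#'   1 or 2. Default 1.
#' @return A list of class `tsat_classification_config`.
#' @export
classification_config <- function(basis = c("max_score_fraction", "tas_percent"),
                                  reliable_cutoff = 0.85,
                                  restricted_lower = 0.61,
                                  red_min_level = 1L) {
  basis <- match.arg(basis)
  if (!(restricted_lower > 0 && restricted_lower <= reliable_cutoff &&
        reliable_cutoff < 1)) {
    stop("need 0 < restricted_lower <= reliable_cutoff < 1", call. = FALSE)
  }
  if (!red_min_level %in% c(1L, 2L)) {
    stop("red_min_level must be 1 or 2", call. = FALSE)
  }
  structure(list(basis = basis, reliable_cutoff = reliable_cutoff,
                 restricted_lower = restricted_lower,
                 red_min_level = as.integer(red_min_level)),
            class = "tsat_classification_config")
}

#' Red-criteria (Tier-1) gate
#'
#' A study passes the gate when every red (critical) criterion scores at
#' least `red_min_level`, regardless of its total assessment score.
#' Red-passing studies are the ones prioritized for Tier-2 expert
#' elicitation.
#'
#' @inheritParams validate_evaluation
#' @param config A [classification_config()].
#' @return A list with `pass` (logical) and `failing` (ids of red
#'   criteria below the minimum, in registry order).
#' @export
red_criteria_check <- function(evaluation, registry,
                               config = classification_config()) {
  stop_if_invalid(evaluation, registry)
  reds <- red_criteria(registry)
  if (!length(reds)) {
    stop("registry '", registry$name, "' defines no red criteria",
         call. = FALSE)
  }
  failing <- reds[evaluation$scores[reds] < config$red_min_level]
  list(pass = length(failing) == 0L, failing = failing)
}

#' Fernandez-Cruz reliability class
#'
#' Classifies a study as `reliable` (share of criteria at the maximum
#' score strictly above the reliable cut-off, and all red criteria met),
#' `reliable_with_restrictions` (share within the restricted band, red
#' criteria met) or `not_reliable` (otherwise). With
#' `basis = "tas_percent"` the proportion TAS/TAS-max is classified
#' against the same cut-offs. Note that under the default basis an
#' evaluation of straight 1s scores 50% of the TAS maximum yet has no
#' criterion at the maximum, so it is not reliable.
#'
#' @inheritParams red_criteria_check
#' @return One of `"reliable"`, `"reliable_with_restrictions"`,
#'   `"not_reliable"`.
#' @export
fernandez_cruz_class <- function(evaluation, registry,
                                 config = classification_config()) {
  stop_if_invalid(evaluation, registry)
  sc <- evaluation$scores[criterion_ids(registry)]
  frac <- if (config$basis == "max_score_fraction") {
    sum(sc == 2L) / length(sc)
  } else {
    sum(sc) / max_tas(registry)
  }
  red_pass <- red_criteria_check(evaluation, registry, config)$pass
  if (!red_pass) return("not_reliable")
  if (frac > config$reliable_cutoff) "reliable"
  else if (frac >= config$restricted_lower) "reliable_with_restrictions"
  else "not_reliable"
}

#' de Ruijter adequacy
#'
#' Under the all-criteria-equal view a study is adequate only when no
#' criterion scores 0, i.e. every criterion reaches at least the
#' adequate-with-restrictions level.
#'
#' @inheritParams validate_evaluation
#' @return Logical.
#' @export
de_ruijter_adequate <- function(evaluation, registry) {
  stop_if_invalid(evaluation, registry)
  all(evaluation$scores[criterion_ids(registry)] >= 1L)
}

#' Screen one evaluation under all three schemes
#'
#' @inheritParams red_criteria_check
#' @return A one-row data.frame: `study_id`, `study_system`, `tas`,
#'   `tas_max`, `tas_percent`, `max_score_fraction`, `red_pass`,
#'   `failing_red` (semicolon-joined), `fernandez_class`,
#'   `de_ruijter_adequate`, `tier1_prioritized`.
#' @export
screen_evaluation <- function(evaluation, registry,
                              config = classification_config()) {
  summ <- summarize_evaluation(evaluation, registry)
  red <- red_criteria_check(evaluation, registry, config)
  data.frame(
    study_id = evaluation$study_id,
    study_system = registry$study_system,
    tas = summ$tas, tas_max = summ$tas_max, tas_percent = summ$tas_percent,
    max_score_fraction = summ$max_score_fraction,
    red_pass = red$pass,
    failing_red = paste(red$failing, collapse = ";"),
    fernandez_class = fernandez_cruz_class(evaluation, registry, config),
    de_ruijter_adequate = de_ruijter_adequate(evaluation, registry),
    tier1_prioritized = red$pass,
    stringsAsFactors = FALSE)
}

#' Tier-1 screening of a corpus
#'
#' Screens every evaluation and returns one row per study, ordered for
#' stable reporting: prioritized (red-passing) studies first, then by
#' decreasing TAS, then by study id. The prioritized subset is exactly
#' the set of red-passing studies.
#'
#' @param evaluations List of evaluations, all against `registry` (one
#'   study system per call).
#' @inheritParams red_criteria_check
#' @return A data.frame of [screen_evaluation()] rows in report order;
#'   zero rows for an empty corpus.
#' @export
tier1_screen <- function(evaluations, registry,
                         config = classification_config()) {
  if (!length(evaluations)) {
    return(screen_evaluation(
      study_evaluation("x", "r",
                       stats::setNames(rep(0L, nrow(registry$criteria)),
                                       criterion_ids(registry)),
                       metadata = study_meta(study_system = registry$study_system)),
      registry, config)[0, ])
  }
  systems <- unique(vapply(evaluations, function(ev)
    ev$metadata$study_system, character(1)))
  if (length(systems) > 1L) {
    stop("corpus mixes study systems (", paste(systems, collapse = ", "),
         "); screen each system against its own registry", call. = FALSE)
  }
  out <- do.call(rbind, lapply(evaluations, screen_evaluation, registry, config))
  out <- out[order(-out$tier1_prioritized, -out$tas, out$study_id), ]
  rownames(out) <- NULL
  out
}
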