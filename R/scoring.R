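# Per-study evaluations, multi-rater consensus and total-assessment-score
# (TAS) aggregation.

EXPOSURE_ROUTES <- c("oral", "inhalation", "other")
MATERIAL_CLASSES <- c("nmp", "cellulose", "other")
SHAPES <- c("sphere", "fragment", "fibre", "other")
CONSENSUS_RULES <- c("min", "mode", "strict")

#' Study metadata
#'
#' Descriptive metadata attached to an evaluation: the citation, the test
#' system, the exposure route and the test material. A study reporting
#' both in vivo and in vitro arms is two evaluations, keyed by
#' `(study_id, study_system)`, each scored against its own registry.
#'
#' @param citation Author-year citation text.
#' @param year Publication year.
#' @param study_system `"in_vivo"` or `"in_vitro"`.
#' @param exposure_route `"oral"`, `"inhalation"` or `"other"`.
#' @param material_class `"nmp"`, `"cellulose"` or `"other"`.
#' @param polymer Optional polymer name (e.g. `"polystyrene"`).
#' @param shape Optional particle shape: `"sphere"`, `"fragment"`,
#'   `"fibre"` or `"other"`.
#' @param median_size_um Optional median particle size tested, in
#'   micrometres (must be positive).
#' @return A list of class `tsat_study_meta`.
#' @export
study_meta <- function(citation = NA_character_, year = NA_integer_,
                       study_system = "in_vivo",
                       exposure_route = "other", material_class = "nmp",
                       polymer = NA_character_, shape = NA_character_,
                       median_size_um = NA_real_) {
  study_system <- match.arg(study_system, STUDY_SYSTEMS)
  exposure_route <- match.arg(exposure_route, EXPOSURE_ROUTES)
  material_class <- match.arg(material_class, MATERIAL_CLASSES)
  if (!is.na(shape)) shape <- match.arg(shape, SHAPES)
  if (!is.na(median_size_um) && median_size_um <= 0) {
    stop("median_size_um must be positive", call. = FALSE)
  }
  structure(list(citation = as.character(citation), year = as.integer(year),
                 study_system = study_system, exposure_route = exposure_route,
                 material_class = material_class,
                 polymer = as.character(polymer), shape = as.character(shape),
                 median_size_um = as.numeric(median_size_um)),
            class = "tsat_study_meta")
}

#' One rater's evaluation of one study
#'
#' @param study_id Study identifier (unique together with the study
#'   system).
#' @param rater_id Rater identifier.
#' @param scores Named integer vector, one score in `{0, 1, 2}` per
#'   criterion id of the registry the study was evaluated under.
#' @param registry_name Name of that registry.
#' @param metadata A [study_meta()] object.
#' @return An object of class `tsat_evaluation`.
#' @export
study_evaluation <- function(study_id, rater_id, scores,
                             registry_name = NA_character_,
                             metadata = study_meta()) {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id),
            inherits(metadata, "tsat_study_meta"))
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named vector of criterion scores", call. = FALSE)
  }
  structure(list(study_id = study_id, rater_id = as.character(rater_id),
                 registry_name = as.character(registry_name),
                 scores = stats::setNames(as.integer(scores), names(scores)),
                 metadata = metadata),
            class = "tsat_evaluation")
}

#' @export
print.tsat_evaluation <- function(x, ...) {
  cat(sprintf("<tsat_evaluation> %s (rater %s), %d criteria, sum %d\n",
              x$study_id, x$rater_id, length(x$scores), sum(x$scores)))
  invisible(x)
}

#' Validate an evaluation against a registry
#'
#' A valid evaluation covers exactly the registry's criterion ids (no
#' criterion missing, none extra), every score lies in `{0, 1, 2}`, and
#' the metadata's study system matches the registry's.
#'
#' @param evaluation A `tsat_evaluation` or `tsat_consensus`.
#' @param registry The `tsat_registry` it was scored under.
#' @return A data.frame of issues (`criterion_id`, `rule`, `message`);
#'   zero rows when valid.
#' @export
validate_evaluation <- function(evaluation, registry) {
  stopifnot(inherits(registry, "tsat_registry"))
  sc <- evaluation$scores
  ids <- criterion_ids(registry)
  issues <- list()
  add <- function(criterion_id, rule, message) {
    issues[[length(issues) + 1L]] <<-
      data.frame(criterion_id = criterion_id, rule = rule, message = message,
                 stringsAsFactors = FALSE)
  }
  for (id in setdiff(ids, names(sc)))
    add(id, "missing_criterion", sprintf("no score for criterion '%s'", id))
  for (id in setdiff(names(sc), ids))
    add(id, "unknown_criterion",
        sprintf("score for criterion '%s' not in registry", id))
  for (id in intersect(names(sc), ids)) {
    if (is.na(sc[[id]]) || !sc[[id]] %in% SCORE_LEVELS)
      add(id, "score_out_of_range",
          sprintf("criterion '%s' scored %s; scores must be 0, 1 or 2",
                  id, sc[[id]]))
  }
  meta_sys <- evaluation$metadata$study_system
  if (!is.null(meta_sys) && !is.na(meta_sys) &&
      meta_sys != registry$study_system)
    add(NA_character_, "study_system_mismatch",
        sprintf("study system '%s' does not match registry system '%s'",
                meta_sys, registry$study_system))
  if (length(issues)) do.call(rbind, issues)
  else data.frame(criterion_id = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

stop_if_invalid <- function(evaluation, registry) {
  issues <- validate_evaluation(evaluation, registry)
  if (nrow(issues)) {
    stop(sprintf("invalid evaluation '%s':\n%s", evaluation$study_id,
                 paste(sprintf("  [%s] %s", issues$rule, issues$message),
                       collapse = "\n")), call. = FALSE)
  }
  invisible(evaluation)
}

#' Merge multiple raters' evaluations of one study
#'
#' Every study is scored by at least two raters; `consensus()` merges
#' their score maps into one. Three rules are available:
#' * `"min"` (default): the per-criterion minimum across raters — the
#'   conservative choice for screening, since no criterion is credited
#'   beyond what every rater would grant.
#' * `"mode"`: the per-criterion majority level, with ties broken to the
#'   lower level.
#' * `"strict"`: raters must agree on every criterion; any disagreement
#'   is an error listing the discordant criteria.
#' Whatever the rule, every criterion on which raters differ is recorded
#' in the `discordant` field for review.
#'
#' @param evaluations List of `tsat_evaluation` objects sharing one
#'   `study_id` and registry.
#' @param rule `"min"`, `"mode"` or `"strict"`.
#' @return An object of class `tsat_consensus` with fields `study_id`,
#'   `scores`, `rule`, `discordant` (data.frame `criterion_id`,
#'   `rater_levels`) and the metadata of the first evaluation.
#' @export
consensus <- function(evaluations, rule = c("min", "mode", "strict")) {
  rule <- match.arg(rule)
  if (!length(evaluations)) stop("no evaluations to merge", call. = FALSE)
  stopifnot(all(vapply(evaluations, inherits, logical(1), "tsat_evaluation")))
  ids <- unique(vapply(evaluations, `[[`, character(1), "study_id"))
  if (length(ids) != 1L) {
    stop("evaluations span multiple studies: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  crits <- names(evaluations[[1]]$scores)
  for (ev in evaluations[-1]) {
    if (!setequal(names(ev$scores), crits))
      stop("raters scored different criterion sets for study '", ids,
           "'", call. = FALSE)
  }
  # raters x criteria score matrix, criterion order from the first rater
  mat <- do.call(rbind, lapply(evaluations, function(ev) ev$scores[crits]))
  disagree <- crits[apply(mat, 2, function(v) length(unique(v)) > 1L)]
  if (rule == "strict" && length(disagree)) {
    stop("raters disagree on: ", paste(disagree, collapse = ", "),
         call. = FALSE)
  }
  merged <- switch(rule,
    min = apply(mat, 2, min),
    mode = apply(mat, 2, function(v) {
      counts <- tabulate(v + 1L, nbins = 3L)  # counts of levels 0,1,2
      min(which(counts == max(counts))) - 1L  # tie -> lower level
    }),
    strict = mat[1L, ]
  )
  discordant <- data.frame(
    criterion_id = disagree,
    rater_levels = vapply(disagree, function(id)
      paste(mat[, id], collapse = "/"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(study_id = ids, rater_id = "consensus",
                 registry_name = evaluations[[1]]$registry_name,
                 scores = stats::setNames(as.integer(merged), crits),
                 rule = rule, discordant = discordant,
                 n_raters = length(evaluations),
                 metadata = evaluations[[1]]$metadata),
            class = c("tsat_consensus", "tsat_evaluation"))
}

#' @export
print.tsat_consensus <- function(x, ...) {
  cat(sprintf("<tsat_consensus> %s (%d raters, rule '%s'), sum %d, %d discordant\n",
              x$study_id, x$n_raters, x$rule, sum(x$scores),
              nrow(x$discordant)))
  invisible(x)
}

#' Convert a total assessment score to an integer percent of maximum
#'
#' Percentages are rounded half away from zero, the convention that
#' reproduces all printed score/percent pairs for the shipped registries
#' (e.g. 44/52 is 85, 12/52 is 23, 16/46 is 35).
#'
#' @param tas Total assessment score(s), `0 <= tas <= tas_max`.
#' @param tas_max Maximum achievable score (positive).
#' @return Integer percent(s).
#' @export
tas_percent <- function(tas, tas_max) {
  if (any(tas_max <= 0)) stop("tas_max must be positive", call. = FALSE)
  if (any(tas < 0 | tas > tas_max)) {
    stop("tas must lie in [0, tas_max]", call. = FALSE)
  }
  as.integer(floor(100 * tas / tas_max + 0.5))
}

#' Summarize an evaluation: category subtotals, TAS, percent, fraction at max
#'
#' The total assessment score (TAS) is the plain sum of the 0/1/2 scores;
#' the maximum is 2 per criterion (52 in vivo, 46 in vitro for the
#' defaults). `max_score_fraction` — the share of criteria at the maximum
#' score of 2 — is the quantity the Fernandez-Cruz reliability cut-offs
#' apply to; `n_zero` supports the de Ruijter all-nonzero adequacy rule.
#'
#' @inheritParams validate_evaluation
#' @return A one-row data.frame with columns `study_id`,
#'   `particle_characterization`, `study_design`, `risk_assessment`
#'   (category subtotals), `tas`, `tas_max`, `tas_percent`,
#'   `max_score_fraction`, `n_zero`.
#' @export
summarize_evaluation <- function(evaluation, registry) {
  stop_if_invalid(evaluation, registry)
  cr <- registry$criteria
  sc <- evaluation$scores[cr$id]
  subtotals <- vapply(CATEGORIES, function(cat)
    sum(sc[cr$category == cat]), integer(1))
  tas <- sum(sc)
  tmax <- max_tas(registry)
  out <- data.frame(study_id = evaluation$study_id,
                    t(subtotals),
                    tas = as.integer(tas), tas_max = as.integer(tmax),
                    tas_percent = tas_percent(tas, tmax),
                    max_score_fraction = sum(sc == 2L) / length(sc),
                    n_zero = sum(sc == 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a corpus of evaluations
#'
#' @param evaluations List of evaluations (single-rater or consensus),
#'   all valid against `registry`.
#' @inheritParams validate_evaluation
#' @return A data.frame with one [summarize_evaluation()] row per
#'   evaluation, in input order.
#' @export
summarize_corpus <- function(evaluations, registry) {
  do.call(rbind, lapply(evaluations, summarize_evaluation, registry))
}

# ---- advisory rubric helpers ------------------------------------------------

#' Suggested score for the dose-response criterion
#'
#' Encodes the adequacy rule for dose-response designs: at least three
#' concentration doses plus a control, spanning a concentration range of
#' at least 3x, earns the full score; two doses plus a control earns the
#' intermediate score; anything less is inadequate. Advisory only — the
#' rater's judgement is never overwritten.
#'
#' @param n_doses Number of concentration doses (excluding the control).
#' @param has_control Whether a control group is included.
#' @param range_ratio Ratio of highest to lowest concentration dose.
#' @return A score level in `{0, 1, 2}`.
#' @export
suggest_dose_response_score <- function(n_doses, has_control, range_ratio = NA) {
  if (n_doses < 0) stop("n_doses must be non-negative", call. = FALSE)
  if (n_doses >= 2 && !is.na(range_ratio) && range_ratio < 1) {
    stop("range_ratio must be >= 1", call. = FALSE)
  }
  if (n_doses >= 3 && isTRUE(has_control) &&
      !is.na(range_ratio) && range_ratio >= 3) return(2L)
  if (n_doses >= 2 && isTRUE(has_control)) return(1L)
  0L
}

#' Oral absorption context for a particle size
#'
#' Annotates a study's median particle size with its likely uptake
#' regime after oral exposure: particles above 150 micrometres are
#' unlikely to be absorbed by the intestinal epithelium (local effects
#' only), particles below 1.5 micrometres can cross the epithelium and
#' reach systemic circulation, and sizes in between see limited
#' absorption. Advisory annotation for reports; it never affects scores.
#'
#' @param median_size_um Median particle size in micrometres (positive).
#' @return One of `"unlikely_absorbed_local_effects"`,
#'   `"intermediate_limited_absorption"`,
#'   `"epithelial_crossing_possible"`.
#' @export
particle_size_context <- function(median_size_um) {
  if (is.na(median_size_um) || median_size_um <= 0) {
    stop("median_size_um must be positive", call. = FALSE)
  }
  if (median_size_um > 150) "unlikely_absorbed_local_effects"
  else if (median_size_um < 1.5) "epithelial_crossing_possible"
  else "intermediate_limited_absorption"
}
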