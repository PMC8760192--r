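# Criteria registry: the QA/QC rubric against which studies are scored.

CATEGORIES <- c("particle_characterization", "study_design", "risk_assessment")
STUDY_SYSTEMS <- c("in_vivo", "in_vitro")
SCORE_LEVELS <- 0:2

#' Construct a criteria registry
#'
#' A registry is the rubric: an ordered set of scoring criteria, each
#' belonging to one of three assessment areas (particle characterization,
#' study design, applicability for risk assessment), each scored on the
#' three-level scale 0 (inadequate), 1 (adequate with restrictions),
#' 2 (adequate). A subset of criteria may be flagged `red` (critical):
#' the Tier-1 screening gate requires a minimum score on every red
#' criterion. Red flags are configurable; they mark criteria critical for
#' a particular screening purpose, not criteria that decide overall study
#' quality.
#'
#' @param name Registry name.
#' @param version Registry version string.
#' @param study_system `"in_vivo"` or `"in_vitro"`.
#' @param criteria A data.frame with columns `id`, `label`, `category`,
#'   `red`, `guidance_0`, `guidance_1`, `guidance_2` and optionally
#'   `applicability_note`.
#' @return An object of class `tsat_registry`.
#' @seealso [default_registry()], [load_registry()], [validate_registry()]
#' @export
criteria_registry <- function(name, version, study_system, criteria) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(version), length(version) == 1L,
            is.data.frame(criteria))
  if (!study_system %in% STUDY_SYSTEMS) {
    stop("study_system must be one of: ", paste(STUDY_SYSTEMS, collapse = ", "),
         call. = FALSE)
  }
  if (!"applicability_note" %in% names(criteria)) {
    criteria$applicability_note <- NA_character_
  }
  needed <- c("id", "label", "category", "red",
              "guidance_0", "guidance_1", "guidance_2", "applicability_note")
  missing_cols <- setdiff(needed, names(criteria))
  if (length(missing_cols)) {
    stop("criteria table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  criteria <- criteria[, needed]
  criteria$red <- as.logical(criteria$red)
  rownames(criteria) <- NULL
  structure(
    list(name = name, version = version, study_system = study_system,
         criteria = criteria, max_score_per_criterion = 2L),
    class = "tsat_registry"
  )
}

#' Criterion identifiers of a registry
#' @param registry A `tsat_registry`.
#' @return Character vector of criterion ids, in registry order.
#' @export
criterion_ids <- function(registry) registry$criteria$id

#' Red (critical) criterion identifiers of a registry
#' @inheritParams criterion_ids
#' @return Character vector of the red criterion ids, in registry order.
#' @export
red_criteria <- function(registry) {
  registry$criteria$id[registry$criteria$red]
}

#' Maximum achievable total assessment score
#'
#' The TAS maximum is twice the number of criteria: 52 for the shipped
#' in vivo registry (26 criteria) and 46 for the in vitro registry (23).
#'
#' @inheritParams criterion_ids
#' @return Integer.
#' @export
max_tas <- function(registry) {
  stopifnot(inherits(registry, "tsat_registry"))
  registry$max_score_per_criterion * nrow(registry$criteria)
}

#' @export
print.tsat_registry <- function(x, ...) {
  cat(sprintf("<tsat_registry> %s (v%s), %s\n", x$name, x$version,
              x$study_system))
  tab <- table(factor(x$criteria$category, levels = CATEGORIES))
  cat(sprintf("  %d criteria (%s), %d red, max TAS %d\n",
              nrow(x$criteria),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              sum(x$criteria$red), max_tas(x)))
  invisible(x)
}

#' Validate a criteria registry
#'
#' Checks the structural rules a usable registry must satisfy: unique
#' non-empty criterion ids and labels, a known category for every
#' criterion, guidance text for each of the three score levels, and a
#' non-empty red set. Issues are returned as data, not raised.
#'
#' @inheritParams criterion_ids
#' @return A data.frame with columns `criterion_id` (NA for
#'   registry-level issues), `rule` and `message`; zero rows when the
#'   registry is valid.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "tsat_registry"))
  cr <- registry$criteria
  issues <- list()
  add <- function(criterion_id, rule, message) {
    issues[[length(issues) + 1L]] <<-
      data.frame(criterion_id = criterion_id, rule = rule, message = message,
                 stringsAsFactors = FALSE)
  }

  dup <- unique(cr$id[duplicated(cr$id)])
  for (id in dup) add(id, "unique_id", sprintf("duplicate criterion id '%s'", id))
  for (i in seq_len(nrow(cr))) {
    if (is.na(cr$id[i]) || !nzchar(cr$id[i]))
      add(cr$id[i], "nonempty_id", "criterion id is empty")
    if (is.na(cr$label[i]) || !nzchar(cr$label[i]))
      add(cr$id[i], "nonempty_label",
          sprintf("criterion '%s' has an empty label", cr$id[i]))
    if (!cr$category[i] %in% CATEGORIES)
      add(cr$id[i], "known_category",
          sprintf("criterion '%s' has unknown category '%s'",
                  cr$id[i], cr$category[i]))
    for (lev in SCORE_LEVELS) {
      g <- cr[[paste0("guidance_", lev)]][i]
      if (is.na(g) || !nzchar(g))
        add(cr$id[i], "three_level_guidance",
            sprintf("criterion '%s' lacks guidance for level %d", cr$id[i], lev))
    }
    if (is.na(cr$red[i]))
      add(cr$id[i], "red_flag", sprintf("criterion '%s' red flag is NA", cr$id[i]))
  }
  if (!any(cr$red %in% TRUE))
    add(NA_character_, "no_red_criteria", "registry has no red criteria")
  if (!registry$study_system %in% STUDY_SYSTEMS)
    add(NA_character_, "known_study_system",
        sprintf("unknown study system '%s'", registry$study_system))

  if (length(issues)) do.call(rbind, issues)
  else data.frame(criterion_id = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

# ---- shipped defaults -------------------------------------------------------

crit <- function(id, label, category, red, g2, g1, g0, note = NA_character_) {
  data.frame(id = id, label = label, category = category, red = red,
             guidance_0 = g0, guidance_1 = g1, guidance_2 = g2,
             applicability_note = note, stringsAsFactors = FALSE)
}

# Particle characterization block is shared by both study systems.
default_pc_criteria <- function() {
  rbind(
    crit("pc_size", "Particle size and size distribution",
         "particle_characterization", TRUE,
         "Size distribution measured by the authors in the exposure medium (e.g. DLS, microscopy) with dispersion statistics",
         "Nominal or supplier-reported size only, or measured outside the exposure medium",
         "Particle size not reported or ambiguous"),
    crit("pc_shape", "Particle shape (sphere, fragment, fibre)",
         "particle_characterization", TRUE,
         "Shape confirmed by imaging; for fibres, aspect ratio, length-to-diameter relationship and rigidity are addressed",
         "Shape stated from supplier information without confirmation",
         "Shape not reported",
         "Fibre-specific sub-aspects (aspect ratio, flexural rigidity, biopersistence) are folded into this criterion"),
    crit("pc_polymer", "Polymer type verification",
         "particle_characterization", TRUE,
         "Polymer composition verified analytically (e.g. FTIR, Raman)",
         "Polymer type taken from supplier information only",
         "Polymer type not reported"),
    crit("pc_source", "Source of the particles",
         "particle_characterization", TRUE,
         "Source and production process of the particles described",
         "Supplier named without production details",
         "Particle source not reported"),
    crit("pc_surface_chemistry", "Surface chemistry and charge",
         "particle_characterization", FALSE,
         "Surface charge or chemistry measured in the exposure medium (e.g. zeta potential, functional groups)",
         "Nominal surface properties from supplier data only",
         "Surface chemistry not reported"),
    crit("pc_chemical_purity", "Chemical purity of the test material",
         "particle_characterization", FALSE,
         "Residual monomers, additives, surfactants or dispersants quantified",
         "Purity addressed only qualitatively (e.g. a stated grade)",
         "Chemical purity not addressed"),
    crit("pc_microbial_contamination", "Microbial contamination / endotoxin testing",
         "particle_characterization", FALSE,
         "Endotoxin or other microbial contamination of the test material tested and reported",
         "Sterile handling described without contamination testing",
         "Microbial contamination not addressed"),
    crit("pc_production_cleaning", "Particle production and cleaning procedures",
         "particle_characterization", FALSE,
         "Production method and any cleaning of the particles described",
         "Production or cleaning only partially described",
         "No information on production or cleaning")
  )
}

# Study-design criteria shared by both systems (dosing and controls).
default_sd_shared <- function(system) {
  medium <- if (system == "in_vivo") "exposure media" else "culture medium"
  rbind(
    crit("sd_administration_route", "Administration route",
         "study_design", FALSE,
         "Administration route fully described and appropriate for the exposure pathway",
         "Route stated without procedural detail",
         "Administration route unclear"),
    crit("sd_vehicle_medium", "Vehicle / exposure medium",
         "study_design", FALSE,
         "Composition of the vehicle or exposure medium reported, with a vehicle control",
         "Vehicle or medium named without composition",
         "Vehicle or medium not reported"),
    crit("sd_dose_metric", "Dose metric reporting",
         "study_design", FALSE,
         "Concentrations reported in more than one dose metric (e.g. mass plus particle count or surface area)",
         "A single dose metric reported",
         "Dose metric unclear or not reported"),
    crit("sd_homogeneity", paste("Homogeneity of particles in the", medium),
         "study_design", FALSE,
         "Homogeneity of the particle suspension verified analytically",
         "Dispersion procedures (e.g. sonication, stirring) described without verification",
         "Homogeneity not addressed"),
    crit("sd_stability", paste("Particle stability in the", medium),
         "study_design", FALSE,
         "Stability / agglomeration state measured over the exposure period",
         "Stability addressed qualitatively",
         "Stability not addressed"),
    crit("sd_frequency_duration", "Frequency and duration of exposure",
         "study_design", FALSE,
         "Frequency and duration of exposure fully reported",
         "Frequency or duration partially reported",
         "Frequency and duration not reported"),
    crit("sd_negative_control", "Negative / vehicle control",
         "study_design", FALSE,
         "Negative or vehicle control included and its results reported",
         "Control mentioned but results unclear",
         "No negative control"),
    crit("sd_positive_control", "Positive or benchmark particle control",
         "study_design", FALSE,
         "Positive control or benchmark particle included to demonstrate test-system performance",
         "Historical or literature control referenced only",
         "No positive control")
  )
}

default_sd_invivo <- function() {
  rbind(
    crit("sd_species_strain", "Test species and strain",
         "study_design", FALSE,
         "Species, strain and supplier of the animals reported",
         "Species reported without strain detail",
         "Species not reported"),
    crit("sd_sex_age", "Sex and age/weight of animals",
         "study_design", FALSE,
         "Sex and age or body weight at study start reported",
         "Sex or age reported, not both",
         "Sex and age not reported"),
    crit("sd_n_per_group", "Animal numbers per test group",
         "study_design", FALSE,
         "Total animals and number per test group reported and consistent with guideline recommendations",
         "Group sizes reported but small or unclear",
         "Animal numbers not reported"),
    crit("sd_housing_feeding", "Housing and feeding conditions",
         "study_design", FALSE,
         "Housing and feeding conditions described in detail",
         "Housing or feeding partially described",
         "Housing and feeding not described"),
    default_sd_shared("in_vivo"),
    crit("sd_exposure_verification", "Verification of exposure / internal dose",
         "study_design", FALSE,
         "Exposure concentration verified analytically and/or internal dose quantified in affected tissues",
         "Semi-quantitative confirmation (e.g. histological images)",
         "Nominal concentrations only, no verification")
  )
}

default_sd_invitro <- function() {
  rbind(
    crit("sd_cell_model_source", "Cell model and its source",
         "study_design", FALSE,
         "Cell model, origin and authentication reported",
         "Cell model named without sourcing detail",
         "Cell model not adequately identified"),
    crit("sd_culture_conditions", "Culture and maintenance conditions",
         "study_design", FALSE,
         "Culture conditions reported (medium, passage, submerged vs air-liquid interface)",
         "Culture conditions partially reported",
         "Culture conditions not reported"),
    crit("sd_replicates", "Independent replicates per exposure dose",
         "study_design", FALSE,
         "Number of independent replicates per dose reported and adequate",
         "Replication unclear or technical replicates only",
         "Replication not reported"),
    default_sd_shared("in_vitro")
  )
}

default_ra_criteria <- function(system) {
  out <- rbind(
    crit("ra_endpoints", "Endpoints reported and their relevance",
         "risk_assessment", TRUE,
         "Endpoints clearly defined and include organism-level effects or a link to an adverse outcome",
         "Sub-organismal biomarker endpoints only",
         "Endpoints unclear or not interpretable"),
    crit("ra_dose_response", "Dose-response design",
         "risk_assessment", TRUE,
         "At least three concentration doses plus a control, spanning a concentration range of 3x or more",
         "Two concentration doses plus a control",
         "A single concentration, or no control")
  )
  if (system == "in_vivo") {
    out <- rbind(out,
      crit("ra_effect_threshold", "Effect threshold reporting (NOAEL/LOAEL/BMD)",
           "risk_assessment", TRUE,
           "An effect threshold reported with error data (confidence interval, SE or SD)",
           "A threshold derivable from the dose-response data presented",
           "No effect threshold reported or derivable"))
  }
  rbind(out,
    crit("ra_statistics", "Statistical methods",
         "risk_assessment", FALSE,
         "Statistical methods stated, appropriate and reported with error estimates",
         "Methods stated without sufficient detail",
         "No statistical analysis reported"),
    crit("ra_environmental_relevance", "Environmental relevance of particles and concentrations",
         "risk_assessment", FALSE,
         "Particle types and concentrations environmentally relevant or their choice justified",
         "Relevance partially addressed",
         "No consideration of environmental relevance"))
}

#' Shipped default registries
#'
#' Returns the default rubric for one of the two supported study systems:
#' 26 criteria for in vivo mammalian studies (8 particle characterization,
#' 13 study design, 5 risk assessment; maximum TAS 52) or 23 criteria for
#' in vitro bioassays (8 + 11 + 4; maximum TAS 46). The default red set
#' comprises particle size, shape, polymer type and source, plus the
#' endpoint, dose-response and (in vivo) effect-threshold criteria.
#'
#' @param study_system `"in_vivo"` or `"in_vitro"`.
#' @return A `tsat_registry`.
#' @examples
#' reg <- default_registry("in_vivo")
#' max_tas(reg)   # 52
#' red_criteria(reg)
#' @export
default_registry <- function(study_system = c("in_vivo", "in_vitro")) {
  study_system <- match.arg(study_system)
  if (study_system == "in_vivo") {
    criteria <- rbind(default_pc_criteria(), default_sd_invivo(),
                      default_ra_criteria("in_vivo"))
    criteria_registry("nmp_tsat_invivo", "1.0", "in_vivo", criteria)
  } else {
    criteria <- rbind(default_pc_criteria(), default_sd_invitro(),
                      default_ra_criteria("in_vitro"))
    criteria_registry("nmp_tsat_invitro", "1.0", "in_vitro", criteria)
  }
}

# ---- file I/O ---------------------------------------------------------------

registry_to_list <- function(registry) {
  cr <- registry$criteria
  list(
    name = registry$name,
    version = registry$version,
    study_system = registry$study_system,
    criteria = lapply(seq_len(nrow(cr)), function(i) {
      item <- list(
        id = cr$id[i], label = cr$label[i], category = cr$category[i],
        red = cr$red[i],
        score_guidance = list("0" = cr$guidance_0[i], "1" = cr$guidance_1[i],
                              "2" = cr$guidance_2[i]))
      if (!is.na(cr$applicability_note[i]))
        item$applicability_note <- cr$applicability_note[i]
      item
    })
  )
}

registry_from_list <- function(x, source = "registry") {
  needed <- c("name", "version", "study_system", "criteria")
  missing_keys <- setdiff(needed, names(x))
  if (length(missing_keys)) {
    stop(sprintf("%s: missing top-level keys: %s", source,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  if (!length(x$criteria)) stop(source, ": 'criteria' is empty", call. = FALSE)
  rows <- lapply(seq_along(x$criteria), function(i) {
    ci <- x$criteria[[i]]
    miss <- setdiff(c("id", "label", "category", "red", "score_guidance"),
                    names(ci))
    if (length(miss)) {
      stop(sprintf("%s: criterion %d is missing fields: %s", source, i,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    g <- ci$score_guidance
    glev <- function(lev) {
      v <- g[[as.character(lev)]]
      if (is.null(v)) NA_character_ else as.character(v)
    }
    crit(as.character(ci$id), as.character(ci$label),
         as.character(ci$category), as.logical(ci$red),
         glev(2), glev(1), glev(0),
         if (is.null(ci$applicability_note)) NA_character_
         else as.character(ci$applicability_note))
  })
  reg <- criteria_registry(as.character(x$name), as.character(x$version),
                           as.character(x$study_system), do.call(rbind, rows))
  issues <- validate_registry(reg)
  if (nrow(issues)) {
    stop(sprintf("%s: invalid registry:\n%s", source,
                 paste(sprintf("  [%s] %s", issues$rule, issues$message),
                       collapse = "\n")), call. = FALSE)
  }
  reg
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else stop("cannot infer registry format from extension '.", ext,
            "'; pass format = 'yaml' or 'json'", call. = FALSE)
}

#' Read a criteria registry from a YAML or JSON file
#'
#' Both dialects share one schema: top-level `name`, `version`,
#' `study_system` and an ordered `criteria` array of
#' `{id, label, category, red, score_guidance: {"0","1","2"},
#' applicability_note?}` objects. Criterion order in the file is
#' preserved, and the loaded registry must pass [validate_registry()].
#'
#' @param path Path to the registry file.
#' @param format `"auto"` (from the extension), `"yaml"` or `"json"`.
#' @return A `tsat_registry`.
#' @export
load_registry <- function(path, format = c("auto", "yaml", "json")) {
  format <- guess_format(path, match.arg(format))
  x <- if (format == "yaml") {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("failed to parse YAML registry '", path,
                                      "': ", conditionMessage(e), call. = FALSE))
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) stop("failed to parse JSON registry '", path,
                                      "': ", conditionMessage(e), call. = FALSE))
  }
  registry_from_list(x, source = path)
}

#' Write a criteria registry to a YAML or JSON file
#'
#' @inheritParams load_registry
#' @param registry A `tsat_registry`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, format = c("auto", "yaml", "json")) {
  stopifnot(inherits(registry, "tsat_registry"))
  format <- guess_format(path, match.arg(format))
  x <- registry_to_list(registry)
  if (format == "yaml") {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Path to a shipped default registry file
#'
#' The package ships its default rubrics as YAML under
#' `inst/registries/`; this helper resolves the installed path.
#'
#' @inheritParams default_registry
#' @return File path to the YAML registry.
#' @export
default_registry_path <- function(study_system = c("in_vivo", "in_vitro")) {
  study_system <- match.arg(study_system)
  fname <- if (study_system == "in_vivo") "nmp_tsat_invivo_v1.yaml"
           else "nmp_tsat_invitro_v1.yaml"
  system.file("registries", fname, package = "tsat", mustWork = TRUE)
}
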