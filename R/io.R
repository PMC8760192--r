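# Evaluation-sheet and metadata-sheet readers/writers, and the markdown
# report renderer.
#
# Evaluation sheet: long format, UTF-8, header row, columns exactly
#   study_id, rater_id, study_system, criterion_id, score
# Metadata sheet: one row per (study_id, study_system), columns
#   study_id, citation, year, study_system, exposure_route,
#   material_class, polymer, shape, median_size_um
# Comma vs tab is inferred from the file extension (.csv / .tsv, .tab).

sheet_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") ","
  else if (ext %in% c("tsv", "tab")) "\t"
  else stop("cannot infer delimiter from extension '.", ext,
            "'; use .csv or .tsv", call. = FALSE)
}

EVAL_SHEET_COLS <- c("study_id", "rater_id", "study_system", "criterion_id",
                     "score")
META_SHEET_COLS <- c("study_id", "citation", "year", "study_system",
                     "exposure_route", "material_class", "polymer", "shape",
                     "median_size_um")

#' Read an evaluation sheet into a list of study evaluations
#'
#' Parses a long-format sheet (one row per study x rater x criterion)
#' into `tsat_evaluation` objects, one per `(study_id, study_system,
#' rater_id)`. Malformed scores are reported with their line numbers;
#' duplicate `(study, rater, criterion)` rows are an error. When a
#' registry is supplied, criterion ids not present in it are an error
#' listing the offending ids.
#'
#' @param path Path to a `.csv` or `.tsv` sheet.
#' @param registry Optional `tsat_registry` to check criterion ids
#'   against.
#' @param metadata Optional metadata data.frame (from
#'   [read_study_metadata()]) to attach to the evaluations.
#' @return A list of `tsat_evaluation` objects, in first-appearance
#'   order.
#' @export
read_evaluations <- function(path, registry = NULL, metadata = NULL) {
  sep <- sheet_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", encoding = "UTF-8",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVAL_SHEET_COLS, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  line_no <- seq_len(nrow(df)) + 1L  # +1 for the header row
  score_num <- suppressWarnings(as.integer(df$score))
  bad <- which(is.na(score_num) | !score_num %in% SCORE_LEVELS)
  if (length(bad)) {
    stop(path, ": invalid score(s) (must be 0, 1 or 2) at line(s) ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  }
  bad_sys <- which(!df$study_system %in% STUDY_SYSTEMS)
  if (length(bad_sys)) {
    stop(path, ": unknown study_system at line(s) ",
         paste(line_no[bad_sys], collapse = ", "), call. = FALSE)
  }
  key <- paste(df$study_id, df$study_system, df$rater_id, df$criterion_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop(path, ": duplicate (study, rater, criterion) rows at line(s) ",
         paste(line_no[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  if (!is.null(registry)) {
    unknown <- setdiff(unique(df$criterion_id), criterion_ids(registry))
    if (length(unknown)) {
      stop(path, ": criterion ids not in registry '", registry$name, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  ev_key <- paste(df$study_id, df$study_system, df$rater_id, sep = "\r")
  lapply(unique(ev_key), function(k) {
    rows <- which(ev_key == k)
    meta <- build_meta(df$study_id[rows[1]], df$study_system[rows[1]],
                       metadata)
    study_evaluation(
      study_id = df$study_id[rows[1]],
      rater_id = df$rater_id[rows[1]],
      scores = stats::setNames(score_num[rows], df$criterion_id[rows]),
      registry_name = if (is.null(registry)) NA_character_ else registry$name,
      metadata = meta)
  })
}

build_meta <- function(study_id, study_system, metadata) {
  if (is.null(metadata)) return(study_meta(study_system = study_system))
  row <- metadata[metadata$study_id == study_id &
                  metadata$study_system == study_system, , drop = FALSE]
  if (!nrow(row)) return(study_meta(study_system = study_system))
  row <- row[1, ]
  study_meta(citation = row$citation, year = row$year,
             study_system = row$study_system,
             exposure_route = row$exposure_route,
             material_class = row$material_class,
             polymer = row$polymer, shape = row$shape,
             median_size_um = row$median_size_um)
}

#' Write evaluations to a long-format sheet
#'
#' @param evaluations List of `tsat_evaluation` objects.
#' @inheritParams read_evaluations
#' @return `path`, invisibly.
#' @export
write_evaluations <- function(evaluations, path) {
  sep <- sheet_sep(path)
  df <- do.call(rbind, lapply(evaluations, function(ev) {
    data.frame(study_id = ev$study_id, rater_id = ev$rater_id,
               study_system = ev$metadata$study_system,
               criterion_id = names(ev$scores),
               score = unname(ev$scores), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a study metadata sheet
#'
#' @inheritParams read_evaluations
#' @return `read_study_metadata()`: a data.frame with the metadata
#'   columns, `year` and `median_size_um` parsed as numbers.
#' @export
read_study_metadata <- function(path) {
  sep <- sheet_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", encoding = "UTF-8",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(META_SHEET_COLS, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$year <- suppressWarnings(as.integer(df$year))
  df$median_size_um <- suppressWarnings(as.numeric(df$median_size_um))
  df
}

#' @rdname read_study_metadata
#' @param metadata A metadata data.frame.
#' @export
write_study_metadata <- function(metadata, path) {
  sep <- sheet_sep(path)
  utils::write.table(metadata[, META_SHEET_COLS], path, sep = sep,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the metadata sheet of a corpus of evaluations
#'
#' @inheritParams write_evaluations
#' @return A data.frame with one row per `(study_id, study_system)`.
#' @export
corpus_metadata <- function(evaluations) {
  meta <- eval_meta_df(evaluations)
  meta[!duplicated(paste(meta$study_id, meta$study_system)), META_SHEET_COLS]
}

# ---- report ----------------------------------------------------------------

#' Render a markdown screening report
#'
#' One section per study, ordered as in the screening table: TAS and
#' percent of maximum, reliability class, adequacy, red-criteria
#' failures, rater discordance (if consensus objects are supplied) and
#' advisory particle-size annotation when a median size is on record.
#'
#' @param evaluations List of evaluations (consensus or single-rater).
#' @inheritParams validate_evaluation
#' @param screening Output of [tier1_screen()] for the same corpus.
#' @param title Report title.
#' @return A character scalar of markdown text.
#' @export
render_report <- function(evaluations, registry, screening,
                          title = "Study screening report") {
  by_id <- stats::setNames(evaluations,
                           vapply(evaluations, `[[`, character(1), "study_id"))
  lines <- c(paste("#", title), "",
             sprintf("Registry: %s (v%s), %s, %d criteria, max TAS %d.",
                     registry$name, registry$version, registry$study_system,
                     nrow(registry$criteria), max_tas(registry)),
             sprintf("Studies screened: %d; prioritized (red-criteria pass): %d.",
                     nrow(screening), sum(screening$tier1_prioritized)), "")
  for (i in seq_len(nrow(screening))) {
    row <- screening[i, ]
    ev <- by_id[[row$study_id]]
    cit <- ev$metadata$citation
    header <- if (!is.na(cit) && nzchar(cit)) cit else row$study_id
    lines <- c(lines, paste("##", header), "",
      sprintf("- TAS: %d / %d (%d%%); criteria at maximum score: %.1f%%",
              row$tas, row$tas_max, row$tas_percent,
              100 * row$max_score_fraction),
      sprintf("- Tier-1 prioritized: %s%s",
              if (row$red_pass) "yes" else "no",
              if (nzchar(row$failing_red))
                paste0(" (red criteria below minimum: ",
                       gsub(";", ", ", row$failing_red), ")") else ""),
      sprintf("- Reliability class: %s", gsub("_", " ", row$fernandez_class)),
      sprintf("- Adequate (no criterion scored 0): %s",
              if (row$de_ruijter_adequate) "yes" else "no"))
    if (inherits(ev, "tsat_consensus") && nrow(ev$discordant)) {
      lines <- c(lines,
        sprintf("- Rater discordance on %d criteria: %s",
                nrow(ev$discordant),
                paste(sprintf("%s (%s)", ev$discordant$criterion_id,
                              ev$discordant$rater_levels), collapse = ", ")))
    }
    size <- ev$metadata$median_size_um
    if (!is.na(size)) {
      lines <- c(lines,
        sprintf("- Median particle size %g um: %s", size,
                gsub("_", " ", particle_size_context(size))))
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}
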