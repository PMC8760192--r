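# Corpus-level analytics: per-criterion score distributions, TAS league
# statistics, stratified metadata summaries and the prioritization table.

eval_meta_df <- function(evaluations) {
  do.call(rbind, lapply(evaluations, function(ev) {
    m <- ev$metadata
    data.frame(study_id = ev$study_id, citation = m$citation, year = m$year,
               study_system = m$study_system,
               exposure_route = m$exposure_route,
               material_class = m$material_class,
               polymer = m$polymer, shape = m$shape,
               median_size_um = m$median_size_um, stringsAsFactors = FALSE)
  }))
}

#' Per-criterion score distributions
#'
#' Counts, for every criterion and every stratum of the corpus, how many
#' studies scored 0, 1 and 2 — the tabulation behind per-criterion
#' score-distribution figures. Strata are the combinations of study
#' system, exposure route and material class present in the corpus.
#'
#' @param evaluations List of evaluations (one per study; merge raters
#'   with [consensus()] first), all valid against `registry`.
#' @inheritParams validate_evaluation
#' @param strata Metadata fields to stratify by; any subset of
#'   `c("study_system", "exposure_route", "material_class")`. Use
#'   `character(0)` for a single whole-corpus stratum.
#' @return A data.frame with columns `criterion_id`, `category`, the
#'   stratum fields, and counts `n0`, `n1`, `n2`; one row per
#'   (criterion, stratum). Zero rows for an empty corpus.
#' @export
criterion_distributions <- function(evaluations, registry,
                                    strata = c("study_system",
                                               "exposure_route",
                                               "material_class")) {
  strata <- if (length(strata)) match.arg(strata, several.ok = TRUE)
            else character(0)
  if (!length(evaluations)) {
    out <- data.frame(criterion_id = character(), category = character(),
                      n0 = integer(), n1 = integer(), n2 = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  for (ev in evaluations) stop_if_invalid(ev, registry)
  meta <- eval_meta_df(evaluations)
  key <- if (length(strata)) {
    do.call(paste, c(meta[strata], sep = "\r"))
  } else rep("all", nrow(meta))
  cr <- registry$criteria
  score_mat <- do.call(rbind, lapply(evaluations, function(ev)
    ev$scores[cr$id]))

  pieces <- lapply(unique(key), function(k) {
    rows <- which(key == k)
    counts <- t(apply(score_mat[rows, , drop = FALSE], 2, function(v)
      tabulate(v + 1L, nbins = 3L)))
    block <- data.frame(criterion_id = cr$id, category = cr$category,
                        stringsAsFactors = FALSE)
    if (length(strata)) {
      for (s in strata) block[[s]] <- meta[[s]][rows[1]]
    }
    block$n0 <- counts[, 1]; block$n1 <- counts[, 2]; block$n2 <- counts[, 3]
    block
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Corpus summary: TAS statistics and particle metadata, per stratum
#'
#' For each stratum, the number of studies and the minimum, mean
#' (unrounded) and maximum TAS together with the percent of maximum
#' computed from the unrounded mean; plus a corpus-wide particle-size
#' summary (median and mean +/- sd of the per-study median sizes) and
#' polymer/shape frequency tables.
#'
#' @inheritParams criterion_distributions
#' @return A list of class `tsat_corpus_summary` with elements
#'   `tas_by_stratum` (data.frame), `particle_size` (list: `n`, `median`,
#'   `mean`, `sd`), `polymer_freq` and `shape_freq` (data.frames).
#' @export
corpus_summary <- function(evaluations, registry,
                           strata = c("study_system", "exposure_route",
                                      "material_class")) {
  if (!length(evaluations)) stop("no evaluations in corpus", call. = FALSE)
  strata <- if (length(strata)) match.arg(strata, several.ok = TRUE)
            else character(0)
  summ <- summarize_corpus(evaluations, registry)
  meta <- eval_meta_df(evaluations)
  key <- if (length(strata)) do.call(paste, c(meta[strata], sep = "\r"))
         else rep("all", nrow(meta))

  tas_by_stratum <- do.call(rbind, lapply(unique(key), function(k) {
    rows <- which(key == k)
    tmax <- unique(summ$tas_max[rows])
    m <- mean(summ$tas[rows])
    block <- meta[rows[1], strata, drop = FALSE]
    cbind(block,
          data.frame(n_studies = length(rows),
                     tas_min = min(summ$tas[rows]),
                     tas_mean = m,
                     tas_max_observed = max(summ$tas[rows]),
                     tas_mean_percent = 100 * m / tmax,
                     stringsAsFactors = FALSE))
  }))
  rownames(tas_by_stratum) <- NULL

  sizes <- meta$median_size_um[!is.na(meta$median_size_um)]
  particle_size <- list(n = length(sizes),
                        median = if (length(sizes)) stats::median(sizes) else NA_real_,
                        mean = if (length(sizes)) mean(sizes) else NA_real_,
                        sd = if (length(sizes) > 1) stats::sd(sizes) else NA_real_)
  freq_table <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(data.frame(value = character(), n = integer(),
                                      stringsAsFactors = FALSE))
    tab <- sort(table(v), decreasing = TRUE)
    data.frame(value = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  structure(list(tas_by_stratum = tas_by_stratum,
                 particle_size = particle_size,
                 polymer_freq = freq_table(meta$polymer),
                 shape_freq = freq_table(meta$shape)),
            class = "tsat_corpus_summary")
}

#' @export
print.tsat_corpus_summary <- function(x, ...) {
  cat("<tsat_corpus_summary>\n")
  print(x$tas_by_stratum)
  ps <- x$particle_size
  if (ps$n > 0) {
    cat(sprintf("particle size (um): median %.3g, mean %.3g +/- %.3g (n = %d)\n",
                ps$median, ps$mean, if (is.na(ps$sd)) 0 else ps$sd, ps$n))
  }
  invisible(x)
}

#' Prioritization table of Tier-1 studies
#'
#' Builds the report table of prioritized (red-passing) studies: one row
#' per study, ordered by decreasing TAS with ties broken by study id,
#' with the citation, optional strengths/weaknesses annotations and the
#' score as "TAS /max".
#'
#' @inheritParams criterion_distributions
#' @param screening Output of [tier1_screen()] computed with the same
#'   registry.
#' @param annotations Optional named list: `study_id` to a list with
#'   `strengths` and/or `weaknesses` text. Annotations for unknown
#'   studies raise a warning and are dropped.
#' @return A data.frame with columns `study_id`, `citation`,
#'   `strengths`, `weaknesses`, `tas`, `tas_max`, `tas_label`.
#' @export
prioritization_table <- function(evaluations, screening, annotations = NULL) {
  meta <- if (length(evaluations)) eval_meta_df(evaluations) else NULL
  pri <- screening[screening$tier1_prioritized, , drop = FALSE]
  pri <- pri[order(-pri$tas, pri$study_id), , drop = FALSE]
  unknown <- setdiff(names(annotations), screening$study_id)
  if (length(unknown)) {
    warning("annotations for unknown studies ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  ann_field <- function(id, field) {
    a <- annotations[[id]]
    if (is.null(a) || is.null(a[[field]])) "" else a[[field]]
  }
  out <- data.frame(
    study_id = pri$study_id,
    citation = if (is.null(meta)) pri$study_id
               else meta$citation[match(pri$study_id, meta$study_id)],
    strengths = vapply(pri$study_id, ann_field, character(1), "strengths"),
    weaknesses = vapply(pri$study_id, ann_field, character(1), "weaknesses"),
    tas = pri$tas, tas_max = pri$tas_max,
    tas_label = sprintf("%d /%d", pri$tas, pri$tas_max),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
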