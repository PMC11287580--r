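SHIELD_CATEGORIES <- c("SHIELD", "SELF_ISOLATE", "SOCIAL_DISTANCE", "MANUAL_REVIEW")

#' Load and validate a rule table
#'
#' Reads a YAML rule config. Two kinds are supported: `grid` (the numerical
#' scoring grid: point values, steroid dose/duration bands, cyclophosphamide
#' window, demographic cap, category thresholds, overrides) and `guide` (the
#' non-numerical risk-stratification guide: ordered condition/medication
#' clauses mapping straight to categories). All numeric cell values live in
#' the config, not in code; the engine only assumes the structure.
#'
#' @param path YAML path; the packaged defaults are
#'   `shieldtext_file("bsr_grid.yaml")` and `shieldtext_file("bsr_guide.yaml")`.
#' @return an object of class `rule_table`.
#' @export
load_rule_table <- function(path = shieldtext_file("bsr_grid.yaml")) {
  cfg <- yaml::read_yaml(path)
  kind <- if (is.null(cfg$kind)) "grid" else cfg$kind
  if (!kind %in% c("grid", "guide")) stop("rule table kind must be grid or guide")
  if (kind == "grid") validate_grid(cfg) else validate_guide(cfg)
  cfg$kind <- kind
  structure(cfg, class = "rule_table")
}

validate_grid <- function(cfg) {
  need <- c("age_threshold_years", "age_point", "demographic_block_cap",
            "comorbidity_points", "med_class_points", "steroid_bands",
            "cyclo_rule", "thresholds")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("rule table missing mandatory block(s): ", paste(missing, collapse = ", "))
  th <- cfg$thresholds
  if (is.null(th$shield_min) || is.null(th$self_isolate_exact))
    stop("thresholds must define shield_min and self_isolate_exact")
  if (th$shield_min <= th$self_isolate_exact)
    stop("thresholds: shield_min must exceed self_isolate_exact")
  pts <- c(cfg$age_point, unlist(cfg$comorbidity_points),
           unlist(cfg$med_class_points),
           vapply(cfg$steroid_bands, `[[`, 0, "points"),
           cfg$cyclo_rule$points)
  if (any(pts < 0)) stop("rule table: negative point value")
  mins <- vapply(cfg$steroid_bands, `[[`, 0, "min_per_day_mg")
  if (is.unsorted(rev(mins), strictly = TRUE))
    stop("steroid_bands must be ordered by strictly descending min_per_day_mg")
  if (is.null(cfg$cyclo_rule$window_days))
    stop("cyclo_rule must define window_days")
  invisible(cfg)
}

validate_guide <- function(cfg) {
  if (is.null(cfg$clauses) || !length(cfg$clauses))
    stop("guide rule table must define clauses")
  for (cl in cfg$clauses) {
    if (is.null(cl$category) || !cl$category %in% SHIELD_CATEGORIES)
      stop("guide clause ", cl$id, " has no valid category")
  }
  if (is.null(cfg$default)) stop("guide rule table must define a default category")
  invisible(cfg)
}

#' @export
print.rule_table <- function(x, ...) {
  cat("<rule_table>", if (!is.null(x$name)) x$name, "kind:", x$kind, "\n")
  if (x$kind == "grid")
    cat("  thresholds: shield >=", x$thresholds$shield_min,
        ", self-isolate =", x$thresholds$self_isolate_exact, "\n")
  else cat("  clauses:", length(x$clauses), "\n")
  invisible(x)
}

SCORING_MED_CLASSES <- c("GLUCOCORTICOID", "IMMUNOSUPPRESSANT", "BIOLOGIC",
                         "SMALL_MOLECULE_IS", "CYCLOPHOSPHAMIDE")

steroid_band_points <- function(per_day_mg, duration_weeks, bands) {
  if (is.na(per_day_mg)) per_day_mg <- 0
  for (b in bands) {
    dur_req <- b$min_duration_weeks
    dur_ok <- is.null(dur_req) ||
      (!is.na(duration_weeks) && duration_weeks >= dur_req)
    if (per_day_mg >= b$min_per_day_mg && dur_ok)
      return(list(points = b$points, band = b))
  }
  list(points = 0, band = NULL)
}

# TRUE when an unknown duration was the binding constraint: some higher band
# needed only a duration the letter did not state
duration_was_binding <- function(per_day_mg, duration_weeks, bands, got_points) {
  if (!is.na(duration_weeks)) return(FALSE)
  if (is.na(per_day_mg)) per_day_mg <- 0
  any(vapply(bands, function(b)
    !is.null(b$min_duration_weeks) && per_day_mg >= b$min_per_day_mg &&
      b$points > got_points, logical(1)))
}

#' Score one consolidated patient record with the numerical grid
#'
#' Demographic points are `age_point` (when age is at or above the
#' threshold) plus one point per flagged scoring comorbidity, capped at
#' `demographic_block_cap`. Medication points sum class points over active
#' medications, except glucocorticoids, which score by the highest matching
#' dose/duration band (unknown duration fails the duration criterion, so the
#' drug falls to the highest band without a duration requirement, flagged
#' `LOW_CONFIDENCE`), and cyclophosphamide, which scores when the last
#' administration is within `window_days` of the index date (or no date is
#' recorded but the drug is ACTIVE, flagged `LOW_CONFIDENCE`). Overrides
#' (pulmonary hypertension -> SHIELD) apply last. When review flags are
#' present and `review_policy = "route"`, the category is `MANUAL_REVIEW`
#' carrying the provisional score.
#'
#' @param rec a [consolidate()] record.
#' @param rules a grid [load_rule_table()].
#' @param index_date reference date (default: the record's own index date).
#' @param review_policy `"route"` (default; taper and other review flags send
#'   the patient to MANUAL_REVIEW) or `"score-anyway"` (score regardless).
#' @param taper_policy `"review"` (default; a tapering dose contributes no
#'   per-day dose) or `"initial-dose"` (use the first stated dose as the
#'   daily dose).
#' @return object of class `shielding_result`.
#' @export
score_patient <- function(rec, rules = load_rule_table(),
                          index_date = rec$index_date,
                          review_policy = c("route", "score-anyway"),
                          taper_policy = c("review", "initial-dose")) {
  stopifnot(rules$kind == "grid")
  review_policy <- match.arg(review_policy)
  taper_policy <- match.arg(taper_policy)
  index_date <- as.Date(index_date)
  contributions <- list()
  add <- function(src, pts) {
    if (pts != 0)
      contributions[[length(contributions) + 1L]] <<- list(source = src, points = pts)
  }
  flags <- character()

  # demographic block: age + comorbidities, capped
  demo <- 0
  if (rec$age_at_index >= rules$age_threshold_years) {
    demo <- demo + rules$age_point
    add(paste0("age ", rec$age_at_index, " >= ", rules$age_threshold_years),
        rules$age_point)
  }
  for (cat in names(rules$comorbidity_points)) {
    if (isTRUE(rec$comorbidities$flags[[cat]])) {
      p <- rules$comorbidity_points[[cat]]
      demo <- demo + p
      add(paste0("comorbidity ", cat), p)
    }
  }
  if (demo > rules$demographic_block_cap) {
    add(paste0("age/comorbidity cap at ", rules$demographic_block_cap),
        rules$demographic_block_cap - demo)
    demo <- rules$demographic_block_cap
  }

  med <- 0
  for (m in rec$active_medications) {
    cls <- m$classes
    if (!any(cls %in% SCORING_MED_CLASSES)) next
    if ("GLUCOCORTICOID" %in% cls) {
      per_day <- if (is.null(m$dose)) NA_real_ else m$dose$per_day_mg
      if (!is.null(m$dose) && isTRUE(m$dose$taper) && taper_policy == "initial-dose")
        per_day <- m$dose$value_mg
      band <- steroid_band_points(per_day, m$duration_weeks, rules$steroid_bands)
      if (is.na(per_day) ||
          duration_was_binding(per_day, m$duration_weeks, rules$steroid_bands,
                               band$points))
        flags <- c(flags, "LOW_CONFIDENCE")
      med <- med + band$points
      add(paste0(m$generic_name, " (glucocorticoid",
                 if (!is.na(per_day)) paste0(" ", per_day, " mg/day"), ")"),
          band$points)
    } else if ("CYCLOPHOSPHAMIDE" %in% cls) {
      within <- if (!is.null(m$last_admin_date)) {
        gap <- as.numeric(index_date - as.Date(m$last_admin_date))
        gap >= 0 && gap <= rules$cyclo_rule$window_days
      } else {
        flags <- c(flags, "LOW_CONFIDENCE")
        TRUE  # active with no recorded date: assume within window, flagged
      }
      if (within) {
        med <- med + rules$cyclo_rule$points
        add(paste0(m$generic_name, " within ", rules$cyclo_rule$window_days,
                   " days"), rules$cyclo_rule$points)
      }
    } else {
      scoring <- intersect(cls, names(rules$med_class_points))
      if (length(scoring)) {
        p <- max(unlist(rules$med_class_points[scoring]))
        med <- med + p
        add(paste0(m$generic_name, " (", tolower(scoring[1]), ")"), p)
      }
    }
  }

  total <- demo + med
  category <- categorize(total, rules)
  override <- NULL
  for (ov in rules$overrides) {
    if (isTRUE(rec$comorbidities$flags[[ov$category]])) {
      category <- ov$force
      override <- ov$category
      break
    }
  }
  discretion <- FALSE
  dc <- rules$discretion
  if (!is.null(dc)) {
    for (cat in dc$categories)
      if (isTRUE(rec$comorbidities$flags[[cat]])) discretion <- TRUE
    if (isTRUE(dc$ra_with_ild) &&
        isTRUE(rec$comorbidities$flags[["RA"]]) &&
        isTRUE(rec$comorbidities$flags[["ILD"]]))
      discretion <- TRUE
  }
  review <- rec$review_flags
  if (length(review) && review_policy == "route" && is.null(override))
    category <- "MANUAL_REVIEW"

  structure(list(patient_id = rec$patient_id,
                 total_score = total,
                 category = category,
                 contributions = contributions,
                 override_applied = override,
                 discretion_flag = discretion,
                 review_reasons = review,
                 low_confidence = "LOW_CONFIDENCE" %in% flags),
            class = "shielding_result")
}

#' Map a total score to a shielding category
#'
#' Score at or above `shield_min` -> SHIELD; exactly `self_isolate_exact` ->
#' SELF_ISOLATE; anything lower -> SOCIAL_DISTANCE.
#'
#' @param score non-negative integer score.
#' @param rules a grid [load_rule_table()].
#' @return category string.
#' @export
categorize <- function(score, rules = load_rule_table()) {
  stopifnot(score >= 0)
  th <- rules$thresholds
  if (score >= th$shield_min) "SHIELD"
  else if (score >= th$self_isolate_exact) "SELF_ISOLATE"
  else "SOCIAL_DISTANCE"
}

#' @export
print.shielding_result <- function(x, ...) {
  cat("<shielding_result>", x$patient_id, "score", x$total_score,
      "->", x$category,
      if (!is.null(x$override_applied)) paste0("(override: ", x$override_applied, ")"),
      if (x$discretion_flag) "(clinical discretion)", "\n")
  for (co in x$contributions)
    cat(sprintf("  %+d  %s\n", as.integer(co$points), co$source))
  invisible(x)
}

#' @export
summary.shielding_result <- function(object, ...) {
  cat("Patient", object$patient_id, "- total score", object$total_score,
      "- category", object$category, "\n")
  if (length(object$review_reasons))
    cat("Review reasons:", paste(object$review_reasons, collapse = ", "), "\n")
  invisible(object)
}

clause_matches <- function(cl, rec, index_date) {
  w <- cl$when
  flags <- rec$comorbidities$flags
  active <- rec$active_medications
  if (!is.null(w$category) && !isTRUE(flags[[w$category]])) return(FALSE)
  if (isTRUE(w$demographic)) {
    demo <- rec$age_at_index >= 70 ||
      any(vapply(c("DIABETES", "ISCHAEMIC_HEART_DISEASE", "HYPERTENSION",
                   "LUNG_DISEASE", "CKD", "RA"),
                 function(cat) isTRUE(flags[[cat]]), logical(1)))
    if (!demo) return(FALSE)
  }
  if (isTRUE(w$cyclo_recent)) {
    cyc <- Filter(function(m) "CYCLOPHOSPHAMIDE" %in% m$classes, active)
    ok <- any(vapply(cyc, function(m) {
      if (is.null(m$last_admin_date)) TRUE
      else {
        gap <- as.numeric(as.Date(index_date) - as.Date(m$last_admin_date))
        gap >= 0 && gap <= 183
      }
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  if (!is.null(w$steroid_min_per_day_mg)) {
    ster <- Filter(function(m) "GLUCOCORTICOID" %in% m$classes, active)
    ok <- any(vapply(ster, function(m) {
      per_day <- if (is.null(m$dose)) NA_real_ else m$dose$per_day_mg
      if (is.na(per_day) || per_day < w$steroid_min_per_day_mg) return(FALSE)
      if (!is.null(w$steroid_min_weeks))
        return(!is.na(m$duration_weeks) && m$duration_weeks >= w$steroid_min_weeks)
      TRUE
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  n_is <- sum(vapply(active, function(m)
    any(m$classes %in% SCORING_MED_CLASSES), logical(1)))
  if (!is.null(w$min_is_meds) && n_is < w$min_is_meds) return(FALSE)
  if (!is.null(w$min_other_is_meds)) {
    n_other <- sum(vapply(active, function(m)
      any(m$classes %in% setdiff(SCORING_MED_CLASSES, "GLUCOCORTICOID")),
      logical(1)))
    if (n_other < w$min_other_is_meds) return(FALSE)
  }
  TRUE
}

#' Classify a patient with the non-numerical risk-stratification guide
#'
#' Walks the guide's ordered clauses; the first matching clause decides the
#' category, else the configured default. Disease-activity clauses are not
#' represented: activity lives in the narrative part of letters, which this
#' tool does not read.
#'
#' @param rec a [consolidate()] record.
#' @param guide_rules a guide [load_rule_table()].
#' @param index_date reference date.
#' @param review_policy as in [score_patient()].
#' @return object of class `shielding_result` (score is `NA` for the guide).
#' @export
classify_guide <- function(rec, guide_rules = load_rule_table(shieldtext_file("bsr_guide.yaml")),
                           index_date = rec$index_date,
                           review_policy = c("route", "score-anyway")) {
  stopifnot(guide_rules$kind == "guide")
  review_policy <- match.arg(review_policy)
  category <- guide_rules$default
  matched <- "default"
  for (cl in guide_rules$clauses) {
    if (clause_matches(cl, rec, index_date)) {
      category <- cl$category
      matched <- if (is.null(cl$id)) "clause" else cl$id
      break
    }
  }
  override <- NULL
  if (matched == "pulmonary_hypertension") override <- "PULMONARY_HYPERTENSION"
  if (length(rec$review_flags) && review_policy == "route" && is.null(override))
    category <- "MANUAL_REVIEW"
  structure(list(patient_id = rec$patient_id,
                 total_score = NA_integer_,
                 category = category,
                 contributions = list(list(source = paste("guide clause:", matched),
                                           points = NA_integer_)),
                 override_applied = override,
                 discretion_flag = FALSE,
                 review_reasons = rec$review_flags,
                 low_confidence = FALSE),
            class = "shielding_result")
}
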