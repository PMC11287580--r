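#' Default synthetic-cohort generator configuration
#'
#' The defaults emulate the case mix of a UK secondary/tertiary rheumatology
#' outpatient cohort: age normal(58, 14) truncated to 18-95, 60% female,
#' comorbidity prevalences (diabetes 11%, ischaemic heart disease 5%,
#' hypertension 22%, pre-existing lung disease 26%, chronic kidney
#' impairment 5%, rheumatoid arthritis 47%, psoriatic arthritis 22%,
#' ankylosing spondylitis 17%) and medication-class exposure (glucocorticoids
#' 14%, conventional immunosuppressants 50%, biologics 52%). Rates that a
#' disclosure-controlled report would suppress (pulmonary hypertension, JAK
#' inhibitors, cyclophosphamide) are set to small plausible values. Noise
#' switches (tapers, stop-notes, planned medications, typos) default to 0.
#'
#' @param n_patients number of patients.
#' @param seed RNG seed.
#' @param ... overrides of any default field.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 100L, seed = 1L, ...) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    index_date = as.Date("2020-04-01"),
    age_mean = 58, age_sd = 14, age_min = 18, age_max = 95,
    p_female = 0.60,
    prevalence = c(DIABETES = 0.11, ISCHAEMIC_HEART_DISEASE = 0.05,
                   HYPERTENSION = 0.22, LUNG_DISEASE = 0.26, CKD = 0.05,
                   PULMONARY_HYPERTENSION = 0.004, RA = 0.47, PSA = 0.22,
                   AS = 0.17, ILD = 0.03, CTD_ILD = 0.01),
    p_nonscoring_dx = 0.5,
    med_probabilities = c(GLUCOCORTICOID = 0.14, IMMUNOSUPPRESSANT = 0.50,
                          BIOLOGIC = 0.52, SMALL_MOLECULE_IS = 0.02,
                          CYCLOPHOSPHAMIDE = 0.01),
    steroid_dose_grid = c(`5` = 0.35, `7.5` = 0.15, `10` = 0.25,
                          `15` = 0.10, `20` = 0.10, `30` = 0.05),
    p_steroid_duration_stated = 0.7,
    steroid_duration_months = c(1, 2, 3, 6, 12, 24),
    p_past_dmard = 0.30,
    p_taper = 0, p_stop_note = 0, p_planned = 0, p_typo = 0,
    p_temporal_mention = 1,
    letters_per_patient = 2L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  probs <- c(cfg$prevalence, cfg$med_probabilities, cfg$p_taper,
             cfg$p_stop_note, cfg$p_planned, cfg$p_typo, cfg$p_female)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_patients >= 1)
  structure(cfg, class = "generator_config")
}

DX_TERMS <- list(
  DIABETES = c("Type 2 diabetes", "Type 1 diabetes", "Diabetes mellitus"),
  ISCHAEMIC_HEART_DISEASE = c("Ischaemic heart disease", "Angina"),
  HYPERTENSION = c("Hypertension", "High blood pressure"),
  LUNG_DISEASE = c("COPD", "Asthma", "Bronchiectasis", "Pneumonia"),
  CKD = c("Chronic kidney disease", "CKD stage 3"),
  PULMONARY_HYPERTENSION = c("Pulmonary hypertension"),
  RA = c("Rheumatoid arthritis", "Seropositive rheumatoid arthritis"),
  PSA = c("Psoriatic arthritis"),
  AS = c("Ankylosing spondylitis"),
  ILD = c("Interstitial lung disease"),
  CTD_ILD = c("CTD-ILD")
)
RHEUM_CATS <- c("RA", "PSA", "AS", "CTD_ILD", "ILD")
NONSCORING_DX <- c("Osteoarthritis", "Osteoporosis", "Gout", "Fibromyalgia")

MED_CHOICES <- list(
  GLUCOCORTICOID = c("Prednisolone"),
  IMMUNOSUPPRESSANT = c("Methotrexate", "Azathioprine", "Leflunomide",
                        "Mycophenolate"),
  BIOLOGIC = c("Adalimumab", "Etanercept", "Rituximab", "Tocilizumab",
               "Infliximab"),
  SMALL_MOLECULE_IS = c("Tofacitinib", "Baricitinib"),
  CYCLOPHOSPHAMIDE = c("Cyclophosphamide")
)
PAST_DMARDS <- c("Sulfasalazine", "Hydroxychloroquine", "Methotrexate")

# comorbidity implications mirrored by the terminology hierarchy:
# CTD-ILD is an ILD, and any ILD is a pre-existing lung disease
close_flags <- function(flags) {
  if (flags[["CTD_ILD"]]) flags[["ILD"]] <- TRUE
  if (flags[["ILD"]]) flags[["LUNG_DISEASE"]] <- TRUE
  flags
}

draw_truth_patient <- function(cfg, pid) {
  age <- round(min(cfg$age_max,
                   max(cfg$age_min, stats::rnorm(1, cfg$age_mean, cfg$age_sd))))
  sex <- if (stats::runif(1) < cfg$p_female) "F" else "M"
  flags <- stats::setNames(stats::runif(length(cfg$prevalence)) < cfg$prevalence,
                           names(cfg$prevalence))
  flags <- close_flags(flags)
  dx_terms <- character()
  for (cat in names(DX_TERMS)) {
    if (!flags[[cat]]) next
    if (cat == "LUNG_DISEASE" && (flags[["ILD"]] || flags[["CTD_ILD"]])) next
    if (cat == "ILD" && flags[["CTD_ILD"]]) next
    dx_terms <- c(dx_terms,
                  sample(DX_TERMS[[cat]], 1))
  }
  if (stats::runif(1) < cfg$p_nonscoring_dx)
    dx_terms <- c(dx_terms, sample(NONSCORING_DX, 1))

  meds <- list()
  for (cl in names(cfg$med_probabilities)) {
    if (stats::runif(1) >= cfg$med_probabilities[[cl]]) next
    drug <- sample(MED_CHOICES[[cl]], 1)
    m <- list(generic_name = tolower(drug), display = drug, class = cl,
              status = "ACTIVE", per_day_mg = NA_real_,
              duration_weeks = NA_real_, taper = FALSE,
              last_admin_date = NULL)
    if (cl == "GLUCOCORTICOID") {
      m$per_day_mg <- as.numeric(sample(names(cfg$steroid_dose_grid), 1,
                                        prob = cfg$steroid_dose_grid))
      if (stats::runif(1) < cfg$p_steroid_duration_stated) {
        m$duration_months <- sample(cfg$steroid_duration_months, 1)
        m$duration_weeks <- m$duration_months * 4.345
      }
      if (stats::runif(1) < cfg$p_taper) {
        m$taper <- TRUE
        m$per_day_mg <- NA_real_
        m$duration_weeks <- NA_real_
        m$duration_months <- NULL
      }
    }
    if (cl == "CYCLOPHOSPHAMIDE") {
      back <- sample(30:400, 1)
      d <- cfg$index_date - back
      lt <- as.POSIXlt(d)
      lt$mday <- 15L  # rendered as month-year; mid-month convention
      m$last_admin_date <- as.Date(lt)
    }
    if (m$status == "ACTIVE" && stats::runif(1) < cfg$p_stop_note) {
      m$status <- "PAST"
      m$stop_note <- TRUE
    }
    if (m$status == "ACTIVE" && stats::runif(1) < cfg$p_planned) {
      m$status <- "PLANNED"
    }
    meds[[length(meds) + 1L]] <- m
  }
  past <- if (stats::runif(1) < cfg$p_past_dmard) {
    avoided <- vapply(meds, `[[`, "", "display")
    pick <- setdiff(PAST_DMARDS, avoided)
    if (length(pick)) sample(pick, 1) else NULL
  }
  list(patient_id = pid, age = age, sex = sex, comorbidities = flags,
       dx_terms = dx_terms, medications = meds, past_dmard = past,
       expected_review = any(vapply(meds, function(m)
         isTRUE(m$taper) && m$class == "GLUCOCORTICOID", logical(1))))
}

render_med_line <- function(m, cfg) {
  if (isTRUE(m$taper))
    return(paste0(m$display, " 30 mg to be reduced in 5 mg increments every ",
                  "7 days until reduced to a dose of 10 mg"))
  line <- switch(m$class,
    GLUCOCORTICOID = {
      l <- paste0(m$display, " ", m$per_day_mg, "mg daily")
      if (!is.null(m$duration_months))
        l <- paste0(l, " for ", m$duration_months, " months")
      l
    },
    IMMUNOSUPPRESSANT = paste0(m$display, " ",
                               sample(c("15mg weekly", "20mg weekly",
                                        "100mg daily", "2g daily"), 1)),
    BIOLOGIC = paste0(m$display, " ",
                      sample(c("40mg alternate weeks", "50mg weekly",
                               "162mg weekly", "infusion 8 weekly"), 1)),
    SMALL_MOLECULE_IS = paste0(m$display, " 5mg bd"),
    CYCLOPHOSPHAMIDE = paste0(m$display, " - last IV infusion ",
                              format(m$last_admin_date, "%B %Y")),
    m$display)
  if (isTRUE(m$stop_note))
    line <- paste0(line, " - stopped due to ",
                   sample(c("nausea", "rash", "infection"), 1))
  if (m$status == "PLANNED")
    line <- paste0(m$display, " - to start next month")
  line
}

apply_typo <- function(word) {
  i <- sample(seq_len(nchar(word) - 1), 1)
  paste0(substr(word, 1, i - 1), substr(word, i + 1, i + 1),
         substr(word, i, i), substr(word, i + 2, nchar(word)))
}

#' Render one patient letter from structured truth
#'
#' Emits headed sections with one item per line: rheumatological diagnoses,
#' other diagnoses, current medications and previous DMARDs. Noise switches
#' add taper phrasing, stop-notes under the current-medication heading,
#' planned-start notes and character-level typos in drug names.
#'
#' @param truth one patient's structured truth from the generator.
#' @param letter_index 1 for the most recent letter, 2 for the one before.
#' @param cfg a [generator_config()].
#' @param full include every item (the most recent letter always does).
#' @return the raw letter text.
#' @export
render_letter <- function(truth, letter_index, cfg, full = TRUE) {
  rheum <- intersect(truth$dx_terms, unlist(DX_TERMS[RHEUM_CATS]))
  other <- setdiff(truth$dx_terms, rheum)
  med_lines <- vapply(truth$medications, function(m) {
    line <- render_med_line(m, cfg)
    if (cfg$p_typo > 0 && stats::runif(1) < cfg$p_typo) {
      word <- m$display
      line <- sub(word, apply_typo(word), line, fixed = TRUE)
    }
    line
  }, character(1))
  if (!full && length(med_lines) > 1) {
    keep <- sort(sample(seq_along(med_lines),
                        max(1, length(med_lines) - 1)))
    med_lines <- med_lines[keep]
  }
  past_lines <- if (!is.null(truth$past_dmard))
    paste0(truth$past_dmard, " - ", sample(c("rash", "nausea", "inefficacy"), 1))
  blocks <- c(
    if (length(rheum)) c("Rheumatological diagnoses:", rheum),
    if (length(other)) c("Other diagnoses:", other),
    "Current medications:", med_lines,
    if (length(past_lines)) c("Previous DMARDs:", past_lines))
  paste(blocks, collapse = "\n")
}

#' Independent oracle score over structured truth
#'
#' A deliberately separate, minimal arithmetic over the generator's
#' structured truth: no text processing and no code shared with
#' [score_patient()]. Used as the reference for end-to-end pipeline checks.
#'
#' @param truth one patient's structured truth.
#' @param rules a grid [load_rule_table()].
#' @param index_date reference date.
#' @param review_policy `"route"` or `"score-anyway"` as in [score_patient()].
#' @return list with `score` and `category`.
#' @export
oracle_score <- function(truth, rules, index_date = as.Date("2020-04-01"),
                         review_policy = c("route", "score-anyway")) {
  review_policy <- match.arg(review_policy)
  f <- truth$comorbidities
  demo <- 0
  if (truth$age >= rules$age_threshold_years) demo <- demo + rules$age_point
  for (cat in names(rules$comorbidity_points))
    if (isTRUE(f[[cat]])) demo <- demo + rules$comorbidity_points[[cat]]
  demo <- min(demo, rules$demographic_block_cap)
  med <- 0
  for (m in truth$medications) {
    if (m$status != "ACTIVE") next
    if (m$class == "GLUCOCORTICOID") {
      pd <- if (isTRUE(m$taper) || is.na(m$per_day_mg)) 0 else m$per_day_mg
      pts <- 0
      for (b in rules$steroid_bands) {
        ok_dur <- is.null(b$min_duration_weeks) ||
          (!is.na(m$duration_weeks) && m$duration_weeks >= b$min_duration_weeks)
        if (pd >= b$min_per_day_mg && ok_dur) { pts <- b$points; break }
      }
      med <- med + pts
    } else if (m$class == "CYCLOPHOSPHAMIDE") {
      gap <- as.numeric(as.Date(index_date) - m$last_admin_date)
      if (gap >= 0 && gap <= rules$cyclo_rule$window_days)
        med <- med + rules$cyclo_rule$points
    } else if (m$class %in% names(rules$med_class_points)) {
      med <- med + rules$med_class_points[[m$class]]
    }
  }
  score <- demo + med
  th <- rules$thresholds
  category <- if (score >= th$shield_min) "SHIELD"
              else if (score == th$self_isolate_exact) "SELF_ISOLATE"
              else "SOCIAL_DISTANCE"
  if (isTRUE(f[["PULMONARY_HYPERTENSION"]])) category <- "SHIELD"
  else if (isTRUE(truth$expected_review) && review_policy == "route")
    category <- "MANUAL_REVIEW"
  list(score = score, category = category)
}

#' Generate a synthetic letter cohort with ground truth
#'
#' Draws structured truth per patient from the configured distributions,
#' renders the letters, and computes the independent oracle score and
#' category from the truth alone. Byte-identical output under a fixed seed.
#'
#' @param cfg a [generator_config()].
#' @param rules grid rule table used by the oracle.
#' @return list with `records` (list of [patient_record()], letters as raw
#'   text) and `truth` (list of per-patient truth, each with `oracle_score`
#'   and `oracle_category`).
#' @export
generate_cohort <- function(cfg = generator_config(),
                            rules = load_rule_table()) {
  set.seed(cfg$seed)
  records <- vector("list", cfg$n_patients)
  truths <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%05d", i)
    truth <- draw_truth_patient(cfg, pid)
    birth <- add_months(cfg$index_date, -(12L * truth$age + 6L))
    newest_gap <- sample(10:100, 1)
    letters <- list()
    for (k in seq_len(cfg$letters_per_patient)) {
      gap <- newest_gap + (k - 1L) * sample(60:400, 1)
      date <- cfg$index_date - gap
      text <- render_letter(truth, k, cfg, full = (k == 1L))
      letters[[k]] <- outpatient_letter(sprintf("%s_L%d", pid, k), pid,
                                        date, sections = list(), text = text)
    }
    records[[i]] <- patient_record(pid, letters, birth_date = birth,
                                   sex = truth$sex)
    o <- oracle_score(truth, rules, cfg$index_date)
    truth$oracle_score <- o$score
    truth$oracle_category <- o$category
    truths[[i]] <- truth
  }
  list(records = records, truth = truths)
}

#' Ground truth as a data.frame
#'
#' @param truth list of per-patient truth from [generate_cohort()].
#' @return data.frame with one row per patient.
#' @export
truth_table <- function(truth) {
  data.frame(
    patient_id = vapply(truth, `[[`, "", "patient_id"),
    age = vapply(truth, `[[`, 0, "age"),
    sex = vapply(truth, `[[`, "", "sex"),
    oracle_score = vapply(truth, `[[`, 0, "oracle_score"),
    oracle_category = vapply(truth, `[[`, "", "oracle_category"),
    expected_review = vapply(truth, `[[`, FALSE, "expected_review"),
    stringsAsFactors = FALSE)
}
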