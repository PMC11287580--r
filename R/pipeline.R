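mentions_to_df <- function(records) {
  rows <- list()
  for (r in records) {
    for (m in r$all_mentions) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = r$patient_id,
        letter_id = m$source$letter_id,
        generic_name = m$generic_name,
        classes = paste(m$classes, collapse = "|"),
        status = m$status,
        per_day_mg = if (is.null(m$dose)) NA_real_ else m$dose$per_day_mg,
        duration_weeks = m$duration_weeks,
        last_admin_date = if (is.null(m$last_admin_date)) NA_character_
                          else format(m$last_admin_date),
        needs_review = m$needs_review,
        review_reasons = paste(m$review_reasons, collapse = "|"),
        raw_text = m$raw_text,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), letter_id = character(),
                      generic_name = character(), classes = character(),
                      status = character(), per_day_mg = numeric(),
                      duration_weeks = numeric(), last_admin_date = character(),
                      needs_review = logical(), review_reasons = character(),
                      raw_text = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

results_to_df <- function(results, guide_results = NULL) {
  df <- data.frame(
    patient_id = vapply(results, `[[`, "", "patient_id"),
    score = vapply(results, function(r)
      if (is.na(r$total_score)) NA_integer_ else as.integer(r$total_score), 1L),
    category = vapply(results, `[[`, "", "category"),
    override = vapply(results, function(r)
      if (is.null(r$override_applied)) "" else r$override_applied, ""),
    discretion_flag = vapply(results, `[[`, FALSE, "discretion_flag"),
    review_reasons = vapply(results, function(r)
      paste(r$review_reasons, collapse = "|"), ""),
    contributions = vapply(results, function(r)
      as.character(jsonlite::toJSON(r$contributions, auto_unbox = TRUE)), ""),
    stringsAsFactors = FALSE)
  if (!is.null(guide_results))
    df$guide_category <- vapply(guide_results, `[[`, "", "category")
  df
}

#' Run the full shielding pipeline on a letter corpus
#'
#' parse -> extract medications -> consolidate -> score (-> evaluate when a
#' gold standard is given), materialising every intermediate artifact under
#' `outdir` with stable filenames (`parsed.jsonl`, `mentions.csv`,
#' `results.csv`, `metrics.json`, `manifest.json`) so any stage can be
#' audited or re-run.
#'
#' @param corpus_path JSONL corpus of patient records (raw or parsed letters).
#' @param outdir output directory (created if needed).
#' @param headings,drugs,diagnoses,categories lexicon TSV paths (packaged
#'   defaults).
#' @param rules_path grid rule YAML; `guide_path` optionally adds the
#'   non-numerical guide's categories alongside.
#' @param index_date reference date.
#' @param gold_path optional gold-standard CSV (`patient_id,label`).
#' @param review_policy,taper_policy passed to [score_patient()].
#' @param n_letters letters consolidated per patient.
#' @return invisibly, a list with `results` (data.frame), `records`,
#'   `metrics` (or NULL) and `manifest`.
#' @export
run_pipeline <- function(corpus_path, outdir,
                         headings = shieldtext_file("headings.tsv"),
                         drugs = shieldtext_file("drugs.tsv"),
                         diagnoses = shieldtext_file("diagnoses.tsv"),
                         categories = shieldtext_file("categories.tsv"),
                         rules_path = shieldtext_file("bsr_grid.yaml"),
                         guide_path = NULL,
                         index_date = as.Date("2020-04-01"),
                         gold_path = NULL,
                         review_policy = "route",
                         taper_policy = "review",
                         n_letters = 2L) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  heading_lex <- read_heading_lexicon(headings)
  drug_lex <- read_drug_lexicon(drugs)
  dx_lex <- read_diagnosis_lexicon(diagnoses)
  cmap <- read_category_map(categories, dx_lex)
  rules <- load_rule_table(rules_path)
  guide <- if (!is.null(guide_path)) load_rule_table(guide_path)

  raw <- read_corpus(corpus_path)
  parsed <- parse_corpus(raw, heading_lex)
  write_corpus(parsed, file.path(outdir, "parsed.jsonl"))

  cons <- consolidate_corpus(parsed, index_date, drug_lex, dx_lex, cmap,
                             n_letters)
  utils::write.csv(mentions_to_df(cons$records),
                   file.path(outdir, "mentions.csv"), row.names = FALSE)

  results <- lapply(cons$records, score_patient, rules = rules,
                    index_date = index_date, review_policy = review_policy,
                    taper_policy = taper_policy)
  guide_results <- if (!is.null(guide))
    lapply(cons$records, classify_guide, guide_rules = guide,
           index_date = index_date, review_policy = review_policy)
  rdf <- results_to_df(results, guide_results)
  utils::write.csv(rdf, file.path(outdir, "results.csv"), row.names = FALSE)

  metrics <- NULL
  if (!is.null(gold_path)) {
    gold <- utils::read.csv(gold_path, stringsAsFactors = FALSE)
    ev <- evaluate_predictions(rdf[, c("patient_id", "category")], gold)
    metrics <- ev
    jsonlite::write_json(
      list(confusion = ev$confusion[c("tp", "fp", "fn", "tn")],
           metrics = lapply(unclass(ev$metrics)[setdiff(names(ev$metrics), "meta")],
                            function(e) e[c("value", "lower", "upper")]),
           display = format_metrics(ev$metrics),
           n_excluded_review = ev$n_excluded_review,
           n_matched = ev$n_matched),
      file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }

  manifest <- list(
    tool = paste0("shieldtext ",
                  as.character(utils::packageVersion("shieldtext"))),
    inputs = list(corpus = corpus_path, headings = headings, drugs = drugs,
                  diagnoses = diagnoses, categories = categories,
                  rules = rules_path, guide = guide_path, gold = gold_path),
    config_md5 = as.list(tools::md5sum(c(headings, drugs, diagnoses,
                                         categories, rules_path))),
    index_date = format(as.Date(index_date)),
    review_policy = review_policy,
    taper_policy = taper_policy,
    counts = list(patients_in = length(raw),
                  patients_scored = length(cons$records),
                  patients_errored = length(cons$errors),
                  errors = as.list(cons$errors),
                  mentions = sum(vapply(cons$records, function(r)
                    length(r$all_mentions), 0L))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  if (length(cons$errors))
    warning(length(cons$errors), " patient(s) errored; see manifest.json")
  invisible(list(results = rdf, records = cons$records,
                 scored = results, guide_scored = guide_results,
                 metrics = metrics, manifest = manifest))
}
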