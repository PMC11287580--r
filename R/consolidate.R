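#' Consolidate a patient's recent letters into one structured record
#'
#' Combines the `n_letters` most recent letters before the index date.
#' Comorbidity categories are the union over the selected letters; for a drug
#' (by generic name) mentioned in more than one letter the newer letter's
#' mention replaces the older entirely (status, dose, dates). Only mentions
#' ACTIVE at the index date enter `active_medications`; review reasons are
#' unioned across all mentions of the selected letters.
#'
#' @param record a [patient_record()] with parsed letters.
#' @param index_date reference date (default 2020-04-01).
#' @param drug_lexicon from [read_drug_lexicon()].
#' @param diagnosis_lexicon from [read_diagnosis_lexicon()].
#' @param category_map from [read_category_map()].
#' @param n_letters how many recent letters to combine (default 2).
#' @param freq frequency-multiplier table.
#' @return an object of class `consolidated_record` with `patient_id`,
#'   `age_at_index`, `sex`, `comorbidities`, `active_medications`,
#'   `all_mentions`, `review_flags`, `unmatched_diagnoses` and `letters_used`.
#' @export
consolidate <- function(record, index_date = as.Date("2020-04-01"),
                        drug_lexicon = read_drug_lexicon(),
                        diagnosis_lexicon = read_diagnosis_lexicon(),
                        category_map = read_category_map(),
                        n_letters = 2L, freq = frequency_table()) {
  index_date <- as.Date(index_date)
  letters <- select_recent_letters(record, index_date, n_letters)
  if (!length(letters))
    stop("NO_ELIGIBLE_LETTERS: patient ", record$patient_id,
         " has no letter before ", format(index_date))
  if (length(letters) < n_letters)
    warning("patient ", record$patient_id, ": only ", length(letters),
            " eligible letter(s) before ", format(index_date))

  # letters is newest first; walk oldest -> newest so newer mentions replace
  profiles <- list()
  unmatched <- character()
  mention_map <- list()
  for (l in rev(letters)) {
    diag_items <- unlist(lapply(
      Filter(function(s) s$kind == "DIAGNOSIS_LIST", l$sections),
      `[[`, "items"))
    concepts <- list()
    for (item in diag_items) {
      tags <- tag_diagnosis(item, diagnosis_lexicon)
      if (!length(tags)) unmatched <- c(unmatched, item)
      concepts <- c(concepts, tags)
    }
    profiles[[length(profiles) + 1L]] <-
      build_comorbidity_profile(concepts, category_map, diagnosis_lexicon,
                                source_id = l$letter_id)
    for (m in letter_medications(l, drug_lexicon, freq))
      mention_map[[m$generic_name]] <- m  # newer letter overwrites
  }
  comorbidities <- do.call(merge_profiles, profiles)
  mentions <- if (length(mention_map)) mention_map[order(names(mention_map))]
              else list()
  active <- Filter(function(m) m$status == "ACTIVE", mentions)
  review <- sort(unique(unlist(lapply(mentions, `[[`, "review_reasons"))))
  structure(list(patient_id = record$patient_id,
                 age_at_index = age_at(record, index_date),
                 sex = record$sex,
                 index_date = index_date,
                 comorbidities = comorbidities,
                 active_medications = unname(active),
                 all_mentions = unname(mentions),
                 review_flags = review,
                 unmatched_diagnoses = unmatched,
                 letters_used = vapply(letters, `[[`, "", "letter_id")),
            class = "consolidated_record")
}

#' @export
print.consolidated_record <- function(x, ...) {
  cat("<consolidated_record>", x$patient_id, "age", x$age_at_index,
      "at", format(x$index_date), "\n")
  on <- names(x$comorbidities$flags)[x$comorbidities$flags]
  cat("  comorbidities:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  cat("  active medications:",
      if (length(x$active_medications))
        paste(vapply(x$active_medications, `[[`, "", "generic_name"),
              collapse = ", ")
      else "none", "\n")
  if (length(x$review_flags))
    cat("  review flags:", paste(x$review_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Consolidate a whole corpus
#'
#' Applies [consolidate()] to every patient, collecting per-patient errors
#' instead of aborting the run.
#'
#' @param records list of parsed [patient_record()].
#' @inheritParams consolidate
#' @return list with `records` (consolidated) and `errors` (named character
#'   vector of per-patient error messages).
#' @export
consolidate_corpus <- function(records, index_date = as.Date("2020-04-01"),
                               drug_lexicon = read_drug_lexicon(),
                               diagnosis_lexicon = read_diagnosis_lexicon(),
                               category_map = read_category_map(),
                               n_letters = 2L) {
  freq <- frequency_table()
  out <- list()
  errors <- character()
  for (r in records) {
    res <- tryCatch(
      suppressWarnings(consolidate(r, index_date, drug_lexicon,
                                   diagnosis_lexicon, category_map,
                                   n_letters, freq)),
      error = function(e) e)
    if (inherits(res, "error")) errors[[r$patient_id]] <- conditionMessage(res)
    else out[[length(out) + 1L]] <- res
  }
  list(records = out, errors = errors)
}
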