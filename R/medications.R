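DRUG_CLASSES <- c("GLUCOCORTICOID", "IMMUNOSUPPRESSANT", "BIOLOGIC",
                  "SMALL_MOLECULE_IS", "CYCLOPHOSPHAMIDE", "NON_SCORING")

MED_STATUSES <- c("ACTIVE", "PAST", "PLANNED", "UNKNOWN")

#' Read a drug lexicon
#'
#' RxNorm-style brand -> generic -> class table. TSV columns: `generic_name`,
#' `brands` (pipe-separated, may be empty), `classes` (pipe-separated,
#' non-empty).
#'
#' @param path TSV path; defaults to the packaged lexicon.
#' @return object of class `drug_lexicon`: `drugs` keyed by generic name and
#'   `name_index` mapping normalized brand/generic names to generic names.
#' @export
read_drug_lexicon <- function(path = shieldtext_file("drugs.tsv")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", na.strings = NULL)
  need <- c("generic_name", "brands", "classes")
  if (!all(need %in% names(df)))
    stop("drug lexicon must have columns: ", paste(need, collapse = ", "))
  split_pipe <- function(x) if (!nzchar(x)) character()
                            else strsplit(x, "|", fixed = TRUE)[[1]]
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    cls <- split_pipe(df$classes[i])
    bad <- setdiff(cls, DRUG_CLASSES)
    if (length(bad)) stop("unknown drug class(es): ", paste(bad, collapse = ", "))
    if (!length(cls)) stop("drug ", df$generic_name[i], " has no classes")
    list(generic_name = df$generic_name[i],
         brands = split_pipe(df$brands[i]),
         classes = cls)
  })
  names(drugs) <- df$generic_name
  if (anyDuplicated(names(drugs))) stop("duplicate generic_name in drug lexicon")
  idx <- unlist(unname(lapply(drugs, function(d)
    stats::setNames(rep(d$generic_name, 1 + length(d$brands)),
                    normalize_term(c(d$generic_name, d$brands))))))
  structure(list(drugs = drugs, name_index = idx[!duplicated(names(idx))]),
            class = "drug_lexicon")
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon>", length(x$drugs), "generics,",
      length(x$name_index), "names\n")
  invisible(x)
}

#' Match a medication line against the drug lexicon
#'
#' Brand and generic names are matched case-insensitively as whole words
#' (multi-word names allowed); a brand resolves to its generic. When several
#' lexicon drugs appear on one line the leftmost match wins and the rest are
#' reported in `also_matched`.
#'
#' @param line a medication free-text line.
#' @param lexicon a [read_drug_lexicon()] object.
#' @return `NULL` when no lexicon drug is present, else a list with
#'   `generic_name`, `classes` and `also_matched`.
#' @export
match_drug <- function(line, lexicon) {
  stopifnot(nzchar(line))
  norm <- paste0(" ", normalize_term(line), " ")
  hits <- lapply(names(lexicon$name_index), function(nm) {
    pos <- regexpr(paste0(" ", nm, " "), norm, fixed = TRUE)
    if (pos > 0) list(pos = as.integer(pos), generic = unname(lexicon$name_index[[nm]]),
                      len = nchar(nm))
    else NULL
  })
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) return(NULL)
  generics <- vapply(hits, `[[`, "", "generic")
  pos <- vapply(hits, `[[`, 0L, "pos")
  len <- vapply(hits, `[[`, 0L, "len")
  # leftmost-longest wins
  ord <- order(pos, -len)
  first <- generics[ord][1]
  rest <- setdiff(unique(generics[ord]), first)
  list(generic_name = first,
       classes = lexicon$drugs[[first]]$classes,
       also_matched = rest)
}

#' Read the frequency-multiplier table
#'
#' Maps dosing-frequency abbreviations to administrations per day. TSV
#' columns `token`, `per_day`.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return named numeric vector.
#' @export
read_frequency_table <- function(path = shieldtext_file("frequencies.tsv")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  stats::setNames(as.numeric(df$per_day), df$token)
}

.freq_cache <- new.env(parent = emptyenv())
frequency_table <- function() {
  if (is.null(.freq_cache$tab)) .freq_cache$tab <- read_frequency_table()
  .freq_cache$tab
}

TAPER_RE <- "(?i)\\b(taper|wean|weaning|reduc\\w*|decreas\\w*)\\b"

#' Parse a dose specification from a medication line
#'
#' Extracts the first dose quantity with a mass unit (mg, g, mcg/micrograms),
#' interprets daily-type frequencies (od, bd, tds, qds, daily, twice daily,
#' mane, nocte, alternate days, "x mg per day") into `per_day_mg`, and flags
#' taper instructions (reduce/wean/taper ... language). For tapers
#' `per_day_mg` is left absent: the dose at the index date cannot be read off
#' the instruction.
#'
#' @param line medication text.
#' @param freq frequency-multiplier table from [read_frequency_table()].
#' @return `NULL` when no dose quantity is present, else a list of class
#'   `dose_spec`: `value`, `unit`, `value_mg`, `per_day_mg` (or `NA`),
#'   `frequency_text`, `taper`, `n_doses` (count of dose quantities on the
#'   line).
#' @export
parse_dose <- function(line, freq = frequency_table()) {
  taper <- grepl(TAPER_RE, line, perl = TRUE)
  m <- gregexpr("(?i)\\b([0-9]+(?:\\.[0-9]+)?)\\s*(mg|mcg|micrograms?|g(?![a-z]))\\b",
                line, perl = TRUE)[[1]]
  if (m[1] == -1) {
    if (taper) return(structure(list(value = NA_real_, unit = NA_character_,
                                     value_mg = NA_real_, per_day_mg = NA_real_,
                                     frequency_text = NA_character_,
                                     taper = TRUE, n_doses = 0L),
                                class = "dose_spec"))
    return(NULL)
  }
  txts <- regmatches(line, gregexpr(
    "(?i)\\b([0-9]+(?:\\.[0-9]+)?)\\s*(mg|mcg|micrograms?|g(?![a-z]))\\b",
    line, perl = TRUE))[[1]]
  first <- txts[1]
  value <- as.numeric(sub("(?i)^([0-9.]+).*$", "\\1", first, perl = TRUE))
  unit <- tolower(trimws(sub("(?i)^[0-9.]+\\s*", "", first, perl = TRUE)))
  unit <- c(mg = "mg", g = "g", mcg = "mcg",
            microgram = "mcg", micrograms = "mcg")[[unit]]
  value_mg <- switch(unit, mg = value, g = value * 1000, mcg = value / 1000)
  norm <- normalize_term(line)
  freq_hit <- NA_character_
  mult <- NA_real_
  for (tok in names(freq)) {
    if (grepl(paste0("\\b", tok, "\\b"), norm)) { freq_hit <- tok; mult <- freq[[tok]]; break }
  }
  if (is.na(mult) && grepl("\\bper day\\b|\\ba day\\b|\\beach day\\b", norm)) {
    freq_hit <- "per day"; mult <- 1
  }
  per_day <- if (taper) NA_real_ else if (!is.na(mult)) value_mg * mult else NA_real_
  structure(list(value = value, unit = unit, value_mg = value_mg,
                 per_day_mg = per_day, frequency_text = freq_hit,
                 taper = taper, n_doses = length(txts)),
            class = "dose_spec")
}

STOP_CUES <- c("stopped", "stop", "discontinued", "discontinue", "ceased",
               "withdrawn", "never started", "not started", "on hold",
               "held", "paused", "no longer taking", "came off", "off since")
PLAN_CUES <- c("to start", "to commence", "commencing", "starting soon",
               "planned", "awaiting", "due to start", "for consideration")

#' Resolve medication status from heading and free-text cues
#'
#' The section heading sets the default (`CURRENT_MEDS` -> ACTIVE,
#' `PAST_MEDS` -> PAST, `PLANNED_MEDS` -> PLANNED, anything else ->
#' UNKNOWN); stop cues ("stopped", "discontinued", "never started", ...)
#' override to PAST and plan cues ("to start", "to commence", ...) override
#' to PLANNED regardless of the heading.
#'
#' @param section_kind section kind string.
#' @param line the medication line.
#' @return one of `ACTIVE`, `PAST`, `PLANNED`, `UNKNOWN`.
#' @export
resolve_status <- function(section_kind, line) {
  default <- switch(section_kind,
                    CURRENT_MEDS = "ACTIVE",
                    PAST_MEDS = "PAST",
                    PLANNED_MEDS = "PLANNED",
                    "UNKNOWN")
  norm <- normalize_term(line)
  has_cue <- function(cues) any(vapply(cues, function(cue)
    grepl(paste0("\\b", cue, "\\b"), norm), logical(1)))
  if (has_cue(STOP_CUES)) return("PAST")
  if (has_cue(PLAN_CUES)) return("PLANNED")
  default
}

MONTHS <- c(january = 1, february = 2, march = 3, april = 4, may = 5,
            june = 6, july = 7, august = 8, september = 9, october = 10,
            november = 11, december = 12,
            jan = 1, feb = 2, mar = 3, apr = 4, jun = 6, jul = 7, aug = 8,
            sep = 9, sept = 9, oct = 10, nov = 11, dec = 12)

#' Resolve a temporal expression against the letter date
#'
#' Handles numeric dates ("04/01/2020", day-first by default,
#' "2020-01-04"), day-month-year and month-year phrases ("4 January 2020",
#' "January 2020" -> mid-month, the 15th), bare years ("in 2015" -> 1 July),
#' and relative phrases ("last month", "6 weeks ago", "3 months ago").
#' Returns `NULL` when the line carries no temporal expression.
#'
#' @param line medication text.
#' @param letter_date the letter's encounter date.
#' @param day_first interpret "a/b/year" as day/month (UK convention).
#' @return a `Date`, or `NULL`.
#' @export
parse_temporal <- function(line, letter_date, day_first = TRUE) {
  letter_date <- as.Date(letter_date)
  norm <- tolower(line)

  m <- regmatches(norm, regexpr("\\b([0-9]{4})-([0-9]{2})-([0-9]{2})\\b", norm))
  if (length(m)) return(as.Date(m))

  m <- regmatches(norm,
    regexpr("\\b([0-9]{1,2})[/.]([0-9]{1,2})[/.]([0-9]{4})\\b", norm))
  if (length(m)) {
    parts <- as.integer(strsplit(m, "[/.]")[[1]])
    d <- if (day_first) parts[1] else parts[2]
    mo <- if (day_first) parts[2] else parts[1]
    return(as.Date(sprintf("%04d-%02d-%02d", parts[3], mo, d)))
  }

  month_re <- paste0("\\b(", paste(names(MONTHS), collapse = "|"), ")\\b")
  m <- regexpr(paste0("\\b([0-9]{1,2})(?:st|nd|rd|th)?\\s+", month_re,
                      "\\s+([0-9]{4})\\b"), norm, perl = TRUE)
  if (m > 0) {
    txt <- regmatches(norm, m)
    toks <- strsplit(gsub("(st|nd|rd|th)\\b", "", txt), "\\s+")[[1]]
    return(as.Date(sprintf("%s-%02d-%02d", toks[3], MONTHS[[toks[2]]],
                           as.integer(toks[1]))))
  }
  m <- regexpr(paste0(month_re, "\\s+([0-9]{1,2})(?:st|nd|rd|th)?,?\\s+([0-9]{4})\\b"),
               norm, perl = TRUE)
  if (m > 0) {
    txt <- regmatches(norm, m)
    toks <- strsplit(gsub("(st|nd|rd|th)\\b|,", "", txt), "\\s+")[[1]]
    return(as.Date(sprintf("%s-%02d-%02d", toks[3], MONTHS[[toks[1]]],
                           as.integer(toks[2]))))
  }
  m <- regexpr(paste0(month_re, "\\s+([0-9]{4})\\b"), norm, perl = TRUE)
  if (m > 0) {
    toks <- strsplit(regmatches(norm, m), "\\s+")[[1]]
    # month-only: mid-month convention
    return(as.Date(sprintf("%s-%02d-15", toks[2], MONTHS[[toks[1]]])))
  }

  m <- regexpr("\\b([0-9]+)\\s+(day|week|month|year)s?\\s+ago\\b", norm, perl = TRUE)
  if (m > 0) {
    toks <- strsplit(regmatches(norm, m), "\\s+")[[1]]
    k <- as.integer(toks[1])
    unit <- toks[2]
    return(switch(sub("s$", "", unit),
                  day = letter_date - k,
                  week = letter_date - 7 * k,
                  month = add_months(letter_date, -k),
                  year = add_months(letter_date, -12 * k)))
  }
  if (grepl("\\blast (month|week|year)\\b", norm)) {
    unit <- regmatches(norm, regexpr("(?<=last )(month|week|year)", norm, perl = TRUE))
    return(switch(unit,
                  week = letter_date - 7,
                  month = add_months(letter_date, -1),
                  year = add_months(letter_date, -12)))
  }

  m <- regexpr("\\b(in|since|completed|during)\\s+((19|20)[0-9]{2})\\b", norm, perl = TRUE)
  if (m > 0) {
    txt <- regmatches(norm, m)
    yr <- regmatches(txt, regexpr("(19|20)[0-9]{2}", txt))
    # year-only: mid-year convention
    return(as.Date(paste0(yr, "-07-01")))
  }
  NULL
}

add_months <- function(date, k) {
  lt <- as.POSIXlt(date)
  lt$mon <- lt$mon + k
  out <- as.Date(lt)
  if (is.na(out)) {  # day overflow (e.g. 31st) -> clamp to end of month
    lt$mday <- 28L
    out <- as.Date(lt)
  }
  out
}

#' Parse a treatment-duration phrase into weeks
#'
#' Reads "for N weeks/months/years", "since <year or month year>" (relative
#' to the letter date) and "long-term"/"longstanding" (taken as one year).
#' Returns `NA` when the line states no duration.
#'
#' @param line medication text.
#' @param letter_date the letter date, used to anchor "since ...".
#' @return numeric weeks or `NA`.
#' @export
parse_duration_weeks <- function(line, letter_date) {
  norm <- tolower(line)
  m <- regexpr("\\bfor\\s+(the\\s+last\\s+|past\\s+)?([0-9]+)\\s+(day|week|month|year)s?\\b",
               norm, perl = TRUE)
  if (m > 0) {
    txt <- regmatches(norm, m)
    k <- as.integer(regmatches(txt, regexpr("[0-9]+", txt)))
    unit <- regmatches(txt, regexpr("(day|week|month|year)", txt))
    return(switch(unit, day = k / 7, week = k, month = k * 4.345, year = k * 52.18))
  }
  m <- regexpr(paste0("\\bsince\\s+(", paste(names(MONTHS), collapse = "|"),
                      ")?\\s*((19|20)[0-9]{2})\\b"), norm, perl = TRUE)
  if (m > 0) {
    txt <- regmatches(norm, m)
    start <- parse_temporal(sub("^since\\s+", "in ", txt), letter_date)
    if (grepl(paste0("(", paste(names(MONTHS), collapse = "|"), ")"), txt)) {
      toks <- strsplit(txt, "\\s+")[[1]]
      start <- as.Date(sprintf("%s-%02d-15", toks[3], MONTHS[[toks[2]]]))
    }
    return(max(0, as.numeric(as.Date(letter_date) - start) / 7))
  }
  if (grepl("\\blong[ -]?term\\b|\\blongstanding\\b", norm)) return(52.18)
  NA_real_
}

#' Extract medication mentions from a letter section
#'
#' One mention per line with a matched lexicon drug. Attributes come from
#' [match_drug()], [parse_dose()], [resolve_status()], [parse_temporal()] and
#' [parse_duration_weeks()]. A mention needs review (`needs_review = TRUE`)
#' with reason `TAPER` when a taper instruction attaches to a glucocorticoid,
#' and `MULTI_DOSE` when more than one dose quantity attaches to one drug.
#'
#' @param section a `letter_section` of kind CURRENT_MEDS, PAST_MEDS or
#'   PLANNED_MEDS.
#' @param lexicon a [read_drug_lexicon()] object.
#' @param letter the containing [outpatient_letter()] (provenance + date).
#' @param freq frequency-multiplier table.
#' @return list of `medication_mention` objects.
#' @export
extract_medications <- function(section, lexicon, letter,
                                freq = frequency_table()) {
  stopifnot(section$kind %in% c("CURRENT_MEDS", "PAST_MEDS", "PLANNED_MEDS"))
  out <- list()
  for (line in section$items) {
    hit <- match_drug(line, lexicon)
    if (is.null(hit)) next
    dose <- parse_dose(line, freq)
    status <- resolve_status(section$kind, line)
    last_admin <- parse_temporal(line, letter$encounter_date)
    dur <- parse_duration_weeks(line, letter$encounter_date)
    reasons <- character()
    if (!is.null(dose) && isTRUE(dose$taper) && "GLUCOCORTICOID" %in% hit$classes)
      reasons <- c(reasons, "TAPER")
    if (!is.null(dose) && dose$n_doses > 1 && !isTRUE(dose$taper))
      reasons <- c(reasons, "MULTI_DOSE")
    out[[length(out) + 1L]] <- structure(
      list(raw_text = line,
           generic_name = hit$generic_name,
           classes = hit$classes,
           also_matched = hit$also_matched,
           dose = dose,
           duration_weeks = dur,
           last_admin_date = last_admin,
           status = status,
           needs_review = length(reasons) > 0,
           review_reasons = reasons,
           source = list(letter_id = letter$letter_id,
                         heading = section$heading,
                         encounter_date = letter$encounter_date)),
      class = "medication_mention")
  }
  out
}

#' @export
print.medication_mention <- function(x, ...) {
  cat("<medication_mention>", x$generic_name,
      paste0("[", paste(x$classes, collapse = ","), "]"), x$status,
      if (!is.null(x$dose) && !is.na(x$dose$per_day_mg))
        paste0(x$dose$per_day_mg, " mg/day"),
      if (x$needs_review) paste0("REVIEW:", paste(x$review_reasons, collapse = "+")),
      "\n")
  invisible(x)
}

#' Extract medication mentions from all medication sections of a letter
#'
#' @param letter a parsed [outpatient_letter()].
#' @param lexicon drug lexicon.
#' @param freq frequency table.
#' @return list of `medication_mention`.
#' @export
letter_medications <- function(letter, lexicon, freq = frequency_table()) {
  med_secs <- Filter(function(s)
    s$kind %in% c("CURRENT_MEDS", "PAST_MEDS", "PLANNED_MEDS"), letter$sections)
  unlist(lapply(med_secs, extract_medications, lexicon = lexicon,
                letter = letter, freq = freq), recursive = FALSE)
}
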