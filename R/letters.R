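SECTION_KINDS <- c("DIAGNOSIS_LIST", "CURRENT_MEDS", "PAST_MEDS", "PLANNED_MEDS", "OTHER")

#' Normalize a free-text term or heading
#'
#' Lower-cases, maps punctuation to spaces, collapses repeated whitespace and
#' trims. This is the single normalization used for heading lookup, diagnosis
#' lexicon matching and drug-name matching, so all three are invariant to
#' case, punctuation and spacing.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' normalize_term("Rheumatoid Arthritis (seropositive)")
#' @export
normalize_term <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Construct a letter section
#'
#' @param heading verbatim heading line (may be "").
#' @param kind one of `DIAGNOSIS_LIST`, `CURRENT_MEDS`, `PAST_MEDS`,
#'   `PLANNED_MEDS`, `OTHER`.
#' @param items character vector of free-text item lines; empty strings and
#'   surrounding whitespace are removed.
#' @return an object of class `letter_section`.
#' @export
letter_section <- function(heading, kind, items = character()) {
  kind <- match.arg(kind, SECTION_KINDS)
  items <- trimws(as.character(items))
  items <- items[nzchar(items)]
  structure(list(heading = as.character(heading), kind = kind, items = items),
            class = "letter_section")
}

#' Construct an outpatient letter
#'
#' @param letter_id opaque letter identifier.
#' @param patient_id opaque patient identifier.
#' @param encounter_date letter date (`Date` or ISO-8601 string).
#' @param sections list of [letter_section()] objects in document order.
#' @param text optional raw letter text (kept for unparsed letters).
#' @return an object of class `outpatient_letter`.
#' @export
outpatient_letter <- function(letter_id, patient_id, encounter_date,
                              sections = list(), text = NULL) {
  encounter_date <- as.Date(encounter_date)
  if (is.na(encounter_date)) stop("encounter_date is not a valid date")
  stopifnot(all(vapply(sections, inherits, logical(1), "letter_section")))
  structure(list(letter_id = as.character(letter_id),
                 patient_id = as.character(patient_id),
                 encounter_date = encounter_date,
                 sections = sections,
                 text = text),
            class = "outpatient_letter")
}

#' Construct a patient record
#'
#' Exactly one of `birth_date` and `age_at_index` must be supplied; age at an
#' index date is computed by completed years when `birth_date` is present.
#'
#' @param patient_id opaque patient identifier.
#' @param letters list of [outpatient_letter()]; sorted ascending by date.
#' @param birth_date `Date` or ISO string, or `NULL`.
#' @param age_at_index integer years at the index date, or `NULL`.
#' @param sex `"F"`, `"M"` or `"UNKNOWN"`.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, letters = list(), birth_date = NULL,
                           age_at_index = NULL, sex = "UNKNOWN") {
  if (is.null(birth_date) == is.null(age_at_index))
    stop("exactly one of birth_date and age_at_index must be given")
  if (!is.null(birth_date)) {
    birth_date <- as.Date(birth_date)
    if (is.na(birth_date)) stop("birth_date is not a valid date")
  }
  sex <- match.arg(sex, c("F", "M", "UNKNOWN"))
  stopifnot(all(vapply(letters, inherits, logical(1), "outpatient_letter")))
  pid <- as.character(patient_id)
  for (l in letters)
    if (!identical(l$patient_id, pid))
      stop("letter ", l$letter_id, " does not belong to patient ", pid)
  ord <- order(vapply(letters, function(l) as.numeric(l$encounter_date), 0),
               vapply(letters, `[[`, "", "letter_id"))
  structure(list(patient_id = pid, birth_date = birth_date,
                 age_at_index = if (is.null(age_at_index)) NULL else as.integer(age_at_index),
                 sex = sex, letters = letters[ord]),
            class = "patient_record")
}

#' @export
print.outpatient_letter <- function(x, ...) {
  cat("<outpatient_letter>", x$letter_id, "patient", x$patient_id,
      "dated", format(x$encounter_date), "\n")
  for (s in x$sections)
    cat("  [", s$kind, "] ", if (nzchar(s$heading)) s$heading else "<no heading>",
        ": ", length(s$items), " item(s)\n", sep = "")
  invisible(x)
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "sex", x$sex,
      if (!is.null(x$birth_date)) paste("born", format(x$birth_date))
      else paste("age_at_index", x$age_at_index),
      "-", length(x$letters), "letter(s)\n")
  invisible(x)
}

#' Age in completed years at a date
#'
#' @param record a [patient_record()].
#' @param index_date reference date.
#' @return integer age in completed years.
#' @export
age_at <- function(record, index_date) {
  if (!is.null(record$age_at_index)) return(record$age_at_index)
  index_date <- as.Date(index_date)
  b <- as.POSIXlt(record$birth_date)
  i <- as.POSIXlt(index_date)
  age <- i$year - b$year
  if (i$mon < b$mon || (i$mon == b$mon && i$mday < b$mday)) age <- age - 1L
  as.integer(age)
}

#' Read a heading lexicon
#'
#' Two-column TSV (`heading_synonym`, `kind`) mapping normalized heading
#' strings to section kinds. One row per synonym.
#'
#' @param path TSV path; defaults to the packaged lexicon.
#' @return named character vector: normalized heading -> kind.
#' @export
read_heading_lexicon <- function(path = shieldtext_file("headings.tsv")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("heading_synonym", "kind") %in% names(df)))
    stop("heading lexicon must have columns heading_synonym, kind")
  bad <- setdiff(unique(df$kind), SECTION_KINDS)
  if (length(bad)) stop("unknown section kind(s): ", paste(bad, collapse = ", "))
  keys <- normalize_term(df$heading_synonym)
  dup <- keys[duplicated(keys)]
  if (any(tapply(df$kind, keys, function(k) length(unique(k))) > 1))
    stop("heading lexicon maps a synonym to two kinds")
  lex <- stats::setNames(df$kind, keys)
  lex[!duplicated(keys)]
}

#' Classify a heading line
#'
#' Looks the normalized heading up in the lexicon; a trailing colon is
#' ignored. Unknown headings classify as `OTHER` (not an error).
#'
#' @param heading heading string.
#' @param lexicon named vector from [read_heading_lexicon()].
#' @return section kind string.
#' @export
classify_heading <- function(heading, lexicon) {
  stopifnot(nzchar(heading))
  key <- normalize_term(sub(":\\s*$", "", heading))
  kind <- unname(lexicon[key])
  if (is.na(kind) || is.null(kind)) "OTHER" else kind
}

is_heading_line <- function(line, lexicon) {
  key <- normalize_term(sub(":\\s*$", "", line))
  nzchar(key) && key %in% names(lexicon)
}

#' Parse raw letter text into headed sections
#'
#' A line is a heading iff its normalized form (optionally suffixed ":") is a
#' key of the heading lexicon; every other non-blank line becomes an item of
#' the most recent heading's section. Lines before any heading go to an
#' `OTHER` section with heading `""`.
#'
#' @param raw_text the letter text.
#' @param lexicon heading lexicon.
#' @param letter_id,patient_id,encounter_date letter metadata.
#' @return an [outpatient_letter()].
#' @export
parse_letter <- function(raw_text, lexicon, letter_id, patient_id, encounter_date) {
  lines <- if (is.null(raw_text) || !nzchar(raw_text)) character()
           else strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  sections <- list()
  cur_heading <- NULL
  cur_items <- character()
  flush <- function() {
    if (!is.null(cur_heading) || length(cur_items)) {
      h <- if (is.null(cur_heading)) "" else cur_heading
      kind <- if (is.null(cur_heading)) "OTHER" else classify_heading(h, lexicon)
      sections[[length(sections) + 1L]] <<- letter_section(h, kind, cur_items)
    }
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    if (is_heading_line(line, lexicon)) {
      flush()
      cur_heading <- trimws(line)
      cur_items <- character()
    } else {
      cur_items <- c(cur_items, trimws(line))
    }
  }
  flush()
  outpatient_letter(letter_id, patient_id, encounter_date, sections,
                    text = raw_text)
}

#' Render an outpatient letter back to text
#'
#' Inverse of [parse_letter()] for letters whose sections all carry headings.
#'
#' @param letter an [outpatient_letter()].
#' @return a single string.
#' @export
render_letter_text <- function(letter) {
  paste(unlist(lapply(letter$sections, function(s) {
    c(if (nzchar(s$heading)) s$heading, s$items)
  })), collapse = "\n")
}

#' Select the most recent letters before an index date
#'
#' Letters dated strictly before `index_date`, newest first; ties on date are
#' broken by ascending lexicographic `letter_id` so selection is
#' deterministic.
#'
#' @param record a [patient_record()].
#' @param index_date reference date.
#' @param n maximum number of letters (default 2).
#' @return list of [outpatient_letter()], possibly shorter than `n`.
#' @export
select_recent_letters <- function(record, index_date, n = 2L) {
  stopifnot(n >= 1L)
  index_date <- as.Date(index_date)
  dates <- as.Date(vapply(record$letters, function(l) format(l$encounter_date), ""))
  keep <- record$letters[dates < index_date]
  if (!length(keep)) return(list())
  kd <- vapply(keep, function(l) as.numeric(l$encounter_date), 0)
  ids <- vapply(keep, `[[`, "", "letter_id")
  # newest first; date ties broken by ascending letter_id
  ord <- order(-kd, ids)
  keep <- keep[ord]
  keep[seq_len(min(n, length(keep)))]
}

section_to_list <- function(s) {
  list(heading = s$heading, kind = s$kind, items = as.list(s$items))
}

letter_to_list <- function(l) {
  out <- list(letter_id = l$letter_id,
              encounter_date = format(l$encounter_date))
  if (length(l$sections))
    out$sections <- lapply(l$sections, section_to_list)
  if (!is.null(l$text)) out$text <- l$text
  out
}

record_to_list <- function(r) {
  out <- list(patient_id = r$patient_id, sex = r$sex)
  if (!is.null(r$birth_date)) out$birth_date <- format(r$birth_date)
  if (!is.null(r$age_at_index)) out$age_at_index <- r$age_at_index
  out$letters <- lapply(r$letters, letter_to_list)
  out
}

record_from_list <- function(x, locus) {
  need <- function(field) {
    if (is.null(x[[field]]))
      stop(locus, ": missing field '", field, "'", call. = FALSE)
    x[[field]]
  }
  pid <- need("patient_id")
  letters <- lapply(seq_along(x$letters), function(i) {
    li <- x$letters[[i]]
    lloc <- paste0(locus, ", letter ", i)
    if (is.null(li$encounter_date))
      stop(lloc, ": missing field 'encounter_date'", call. = FALSE)
    secs <- lapply(li$sections, function(s)
      letter_section(s$heading, s$kind, unlist(s$items, use.names = FALSE)))
    outpatient_letter(if (is.null(li$letter_id)) paste0(pid, "_", i) else li$letter_id,
                      pid, li$encounter_date, secs, text = li$text)
  })
  patient_record(pid, letters,
                 birth_date = x$birth_date,
                 age_at_index = x$age_at_index,
                 sex = if (is.null(x$sex)) "UNKNOWN" else x$sex)
}

#' Read / write a JSONL letter corpus
#'
#' One patient record per line; dates ISO-8601. The round trip is lossless
#' for all fields, including raw letter text where present.
#'
#' @param path file path.
#' @return `read_corpus`: list of [patient_record()].
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e)
                    stop("line ", i, ": invalid JSON: ", conditionMessage(e),
                         call. = FALSE))
    record_from_list(x, paste0("line ", i))
  })
}

#' @param records list of [patient_record()].
#' @rdname read_corpus
#' @export
write_corpus <- function(records, path) {
  lines <- vapply(records, function(r)
    jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE, null = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse every raw-text letter in a corpus into sections
#'
#' @param records list of [patient_record()].
#' @param lexicon heading lexicon.
#' @return list of records whose letters all carry parsed sections.
#' @export
parse_corpus <- function(records, lexicon = read_heading_lexicon()) {
  lapply(records, function(r) {
    letters <- lapply(r$letters, function(l) {
      if (length(l$sections) || is.null(l$text)) l
      else parse_letter(l$text, lexicon, l$letter_id, r$patient_id,
                        l$encounter_date)
    })
    patient_record(r$patient_id, letters, birth_date = r$birth_date,
                   age_at_index = r$age_at_index, sex = r$sex)
  })
}

#' Path to a packaged data file
#'
#' @param ... file name under `inst/extdata`.
#' @return file path.
#' @export
shieldtext_file <- function(...) {
  system.file("extdata", ..., package = "shieldtext", mustWork = TRUE)
}
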