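# shared fixtures: packaged lexicons loaded once per test run
HEADINGS <- read_heading_lexicon()
DRUGS <- read_drug_lexicon()
DIAGNOSES <- read_diagnosis_lexicon()
CATEGORIES <- read_category_map(lexicon = DIAGNOSES)
GRID <- load_rule_table()
GUIDE <- load_rule_table(shieldtext_file("bsr_guide.yaml"))
INDEX <- as.Date("2020-04-01")

# one-letter patient built from raw text; age given directly
make_patient <- function(text, age = 50, pid = "P1", lid = "L1",
                         date = "2020-01-15") {
  letter <- parse_letter(text, HEADINGS, lid, pid, date)
  patient_record(pid, list(letter), age_at_index = age)
}

consolidate1 <- function(record, n_letters = 1L) {
  suppressWarnings(consolidate(record, INDEX, DRUGS, DIAGNOSES, CATEGORIES,
                               n_letters = n_letters))
}

# the worked-example patient: 71 years old, type 2 diabetes, on active
# adalimumab and methotrexate
worked_example_text <- function(meds = c("Adalimumab 40mg alternate weeks",
                                         "Methotrexate 15mg weekly")) {
  paste(c("Rheumatological diagnoses:",
          "Other diagnoses:", "Type 2 diabetes",
          "Current medications:", meds), collapse = "\n")
}

# write a diagnosis lexicon TSV from a parent list and read it back
lexicon_from_parents <- function(parents) {
  ids <- names(parents)
  tsv <- tempfile(fileext = ".tsv")
  lines <- c("concept_id\tpreferred_term\tsynonyms\tparent_ids",
             vapply(ids, function(id)
               paste(id, paste("term", id), "",
                     paste(parents[[id]], collapse = "|"), sep = "\t"),
               character(1)))
  writeLines(lines, tsv)
  read_diagnosis_lexicon(tsv)
}
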