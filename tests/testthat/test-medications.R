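test_that("drug matching resolves brands to generics with classes", {
  hit <- match_drug("Humira 40mg alternate weeks", DRUGS)
  expect_equal(hit$generic_name, "adalimumab")
  expect_equal(hit$classes, "BIOLOGIC")
  hit <- match_drug("Methotrexate 15mg weekly", DRUGS)
  expect_equal(hit$generic_name, "methotrexate")
  expect_equal(hit$classes, "IMMUNOSUPPRESSANT")
  expect_null(match_drug("Vitamin D 800 units", DRUGS))
  # whole-word only: no match inside another token
  expect_null(match_drug("pararacetamololol 500mg", DRUGS))
  # two drugs on one line: leftmost wins, remainder reported
  hit <- match_drug("methotrexate and folic acid", DRUGS)
  expect_equal(hit$generic_name, "methotrexate")
  expect_equal(hit$also_matched, "folic acid")
})

test_that("parse_dose matches a brute-force frequency-multiplier oracle", {
  freq <- read_frequency_table()
  mult <- c(od = 1, bd = 2, tds = 3, qds = 4, daily = 1)
  for (dose in c(2.5, 5, 7.5, 10, 20, 30)) {
    for (f in names(mult)) {
      d <- parse_dose(sprintf("Prednisolone %smg %s", dose, f), freq)
      expect_equal(d$per_day_mg, dose * mult[[f]],
                   label = sprintf("%s mg %s", dose, f))
    }
    # weekly dosing is not daily-interpretable
    d <- parse_dose(sprintf("Methotrexate %smg weekly", dose), freq)
    expect_equal(d$value_mg, dose)
    expect_true(is.na(d$per_day_mg))
  }
  # unit conversion to mg
  expect_equal(parse_dose("Rituximab 1g", freq)$value_mg, 1000)
  expect_equal(parse_dose("Drug 500mcg daily", freq)$per_day_mg, 0.5)
  expect_null(parse_dose("Adalimumab alternate weeks", freq))
})

test_that("taper instructions are detected and leave the daily dose unknown", {
  d <- parse_dose(paste("Prednisolone 30 mg to be reduced in 5 mg increments",
                        "every x days until reduced to a dose of 10 mg"))
  expect_true(d$taper)
  expect_true(is.na(d$per_day_mg))
  expect_equal(d$value_mg, 30)
  expect_false(parse_dose("Prednisolone 5mg daily")$taper)
})

test_that("status resolution defaults by heading with cue override dominance", {
  expect_equal(resolve_status("CURRENT_MEDS", "methotrexate 15mg weekly"), "ACTIVE")
  expect_equal(resolve_status("PAST_MEDS", "sulfasalazine - rash"), "PAST")
  expect_equal(resolve_status("PLANNED_MEDS", "baricitinib"), "PLANNED")
  expect_equal(resolve_status("OTHER", "methotrexate"), "UNKNOWN")
  expect_equal(resolve_status("CURRENT_MEDS", "azathioprine - stopped due to nausea"),
               "PAST")
  expect_equal(resolve_status("CURRENT_MEDS", "rituximab - to start next month"),
               "PLANNED")
  # a stop-cue line is never ACTIVE regardless of heading
  cues <- c("stopped due to rash", "discontinued", "never started",
            "on hold", "patient ceased this")
  for (k in c("CURRENT_MEDS", "PAST_MEDS", "PLANNED_MEDS", "OTHER"))
    for (cue in cues)
      expect_equal(resolve_status(k, paste("methotrexate -", cue)), "PAST",
                   label = paste(k, cue))
})

test_that("temporal expressions resolve with mid-month and mid-year conventions", {
  ld <- as.Date("2020-03-10")
  expect_equal(parse_temporal("last IV cyclophosphamide January 2020", ld),
               as.Date("2020-01-15"))
  expect_equal(parse_temporal("cyclophosphamide course completed 2015", ld),
               as.Date("2015-07-01"))
  expect_equal(parse_temporal("infusion on 04/01/2020", ld), as.Date("2020-01-04"))
  expect_equal(parse_temporal("infusion on 04/01/2020", ld, day_first = FALSE),
               as.Date("2020-04-01"))
  expect_equal(parse_temporal("given 6 weeks ago", ld), ld - 42)
  expect_equal(parse_temporal("last month", ld), as.Date("2020-02-10"))
  expect_null(parse_temporal("rituximab 1g", ld))
})

test_that("duration phrases parse to weeks", {
  ld <- as.Date("2020-03-10")
  expect_equal(parse_duration_weeks("prednisolone 5mg daily for 6 weeks", ld), 6)
  expect_equal(parse_duration_weeks("prednisolone 5mg daily for 6 months", ld),
               6 * 4.345)
  expect_gt(parse_duration_weeks("on prednisolone since 2018", ld), 52)
  expect_true(is.na(parse_duration_weeks("prednisolone 5mg daily", ld)))
})

test_that("extract_medications populates attributes and review reasons", {
  txt <- paste("Current medications:",
               "Adalimumab 40mg alternate weeks",
               "Methotrexate 15mg weekly",
               "Prednisolone 30 mg to be reduced in 5 mg increments every x days until reduced to a dose of 10 mg",
               "Vitamin D 800 units", sep = "\n")
  let <- parse_letter(txt, HEADINGS, "L1", "P1", "2020-01-15")
  ms <- extract_medications(let$sections[[1]], DRUGS, let)
  expect_length(ms, 3)  # vitamin D is not in the lexicon
  expect_setequal(vapply(ms, `[[`, "", "generic_name"),
                  c("adalimumab", "methotrexate", "prednisolone"))
  expect_true(all(vapply(ms, `[[`, "", "status") == "ACTIVE"))
  pred <- ms[[which(vapply(ms, `[[`, "", "generic_name") == "prednisolone")]]
  expect_true(pred$needs_review)
  expect_equal(pred$review_reasons, "TAPER")
  # provenance: every raw_text is an input line
  expect_true(all(vapply(ms, `[[`, "", "raw_text") %in% let$sections[[1]]$items))
  expect_length(extract_medications(letter_section("Current medications:",
                                                   "CURRENT_MEDS"),
                                    DRUGS, let), 0)
})

test_that("status counts partition all mentions over a generated corpus", {
  cfg <- generator_config(n_patients = 60, seed = 5,
                          p_stop_note = 0.15, p_planned = 0.05)
  gen <- generate_cohort(cfg)
  parsed <- parse_corpus(gen$records, HEADINGS)
  statuses <- unlist(lapply(parsed, function(r)
    lapply(r$letters, function(l)
      vapply(letter_medications(l, DRUGS), `[[`, "", "status"))))
  expect_gt(length(statuses), 0)
  tab <- table(factor(statuses, levels = c("ACTIVE", "PAST", "PLANNED", "UNKNOWN")))
  expect_equal(sum(tab), length(statuses))
  expect_true(all(statuses %in% c("ACTIVE", "PAST", "PLANNED", "UNKNOWN")))
  expect_gt(tab[["ACTIVE"]], tab[["PAST"]])
})
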