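test_that("binarize maps categories and honours the review policy", {
  expect_equal(binarize(c("SHIELD", "SELF_ISOLATE", "SOCIAL_DISTANCE")),
               c("positive", "negative", "negative"))
  expect_error(binarize("MANUAL_REVIEW"), "resolution policy")
  out <- binarize(c("SHIELD", "MANUAL_REVIEW"), review_policy = "exclude")
  expect_equal(out, c("positive", NA))
})

test_that("confusion_matrix agrees with a hand-count oracle on random labels", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 50
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    gold <- sample(c("positive", "negative"), n, replace = TRUE)
    cm <- confusion_matrix(pred, gold)
    # brute-force loop count
    counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in seq_len(n)) {
      key <- if (pred[i] == "positive" && gold[i] == "positive") "tp"
             else if (pred[i] == "positive") "fp"
             else if (gold[i] == "positive") "fn" else "tn"
      counts[key] <- counts[key] + 1
    }
    expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), counts)
  }
  expect_error(confusion_matrix("positive", c("positive", "negative")),
               "different lengths")
  cm <- confusion_matrix(rep("positive", 10),
                         rep(c("positive", "negative"), 5))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 5, fp = 5, fn = 0, tn = 0))
})

test_that("diagnostic metrics satisfy their algebraic identities", {
  set.seed(7)
  for (rep in 1:10) {
    cells <- sample(1:200, 4)
    m <- diagnostic_metrics(confusion_counts(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(m$fnr$value, 1 - m$sensitivity$value)
    expect_equal(m$fpr$value, 1 - m$specificity$value)
    expect_equal(m$lr_pos$value * (1 - m$specificity$value), m$sensitivity$value)
    expect_equal(m$lr_neg$value * m$specificity$value, 1 - m$sensitivity$value)
    expect_equal(m$f1$value,
                 2 / (1 / m$ppv$value + 1 / m$sensitivity$value))
    for (nm in c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg")) {
      e <- m[[nm]]
      expect_lte(e$lower, e$value)
      expect_gte(e$upper, e$value)
    }
  }
})

test_that("hand-computed small matrices reproduce", {
  m <- diagnostic_metrics(confusion_counts(9, 1, 1, 9))
  expect_equal(m$sensitivity$value, 0.9)
  expect_equal(m$lr_pos$value, 9.0)
  perfect <- diagnostic_metrics(confusion_counts(50, 0, 0, 50))
  expect_equal(perfect$sensitivity$value, 1)
  expect_equal(perfect$specificity$value, 1)
  expect_equal(perfect$f1$value, 1)
  expect_equal(perfect$lr_neg$value, 0)
})

test_that("zero denominators yield absent metrics with a reason, not NaN", {
  m <- diagnostic_metrics(confusion_counts(0, 0, 0, 10))
  expect_true(is.na(m$sensitivity$value))
  expect_match(m$sensitivity$reason, "no gold positives")
  expect_true(is.na(m$ppv$value))
  expect_false(any(vapply(m[c("sensitivity", "ppv")], function(e)
    is.nan(e$value), logical(1))))
})

test_that("deployment summary counts and percentages", {
  cats <- c(rep("SHIELD", 5), rep("SELF_ISOLATE", 10), rep("SOCIAL_DISTANCE", 85))
  tab <- deployment_summary(cats)
  expect_equal(tab$n[tab$category == "SHIELD"], 5L)
  expect_equal(tab$pct[tab$category == "SHIELD"], 5)
  expect_equal(sum(tab$n), 100L)
  empty <- deployment_summary(character())
  expect_true(all(empty$n == 0))
})

test_that("cohort summary suppresses small cells and recovers prevalences", {
  cfg <- generator_config(n_patients = 400, seed = 31)
  gen <- generate_cohort(cfg)
  parsed <- parse_corpus(gen$records, HEADINGS)
  cons <- consolidate_corpus(parsed, INDEX, DRUGS, DIAGNOSES, CATEGORIES)
  results <- lapply(cons$records, score_patient, rules = GRID)
  tab <- cohort_summary(cons$records, results)
  lung <- tab[tab$characteristic == "comorbidity LUNG_DISEASE", ]
  p <- cfg$prevalence[["LUNG_DISEASE"]]
  se <- sqrt(p * (1 - p) / 400)
  expect_lt(abs(lung$all_n / 400 - p), 3 * se + 1e-9)
  # every surviving count is 0 or >= the suppression threshold
  counts <- c(tab$all_n, tab$shield_n, tab$noshield_n)
  expect_true(all(is.na(counts) | counts == 0 | counts >= 5))
  # a cell of 3 is suppressed to NA
  small <- cohort_summary(cons$records[1:3], results[1:3])
  expect_true(any(is.na(small$all_n)))
})

test_that("evaluate_predictions aligns by patient and reports exclusions", {
  pred <- data.frame(patient_id = c("a", "b", "c", "d"),
                     category = c("SHIELD", "MANUAL_REVIEW", "SOCIAL_DISTANCE",
                                  "SHIELD"),
                     stringsAsFactors = FALSE)
  gold <- data.frame(patient_id = c("a", "b", "c", "d"),
                     label = c("positive", "positive", "negative", "negative"),
                     stringsAsFactors = FALSE)
  ev <- evaluate_predictions(pred, gold)
  expect_equal(ev$n_excluded_review, 1L)
  expect_equal(ev$n_matched, 4L)
  expect_equal(unlist(ev$confusion[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 0, tn = 1))
})
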