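#' Binarize a shielding category
#'
#' SHIELD is the positive class; SELF_ISOLATE and SOCIAL_DISTANCE are
#' negative. MANUAL_REVIEW rows must be resolved upstream or excluded with
#' `review_policy = "exclude"`.
#'
#' @param category character vector of categories.
#' @param review_policy `"error"` (default) or `"exclude"` (MANUAL_REVIEW
#'   rows become `NA`, to be dropped and counted by the caller).
#' @return character vector of `"positive"` / `"negative"` (with `NA` for
#'   excluded rows).
#' @export
binarize <- function(category, review_policy = c("error", "exclude")) {
  review_policy <- match.arg(review_policy)
  bad <- setdiff(unique(category), SHIELD_CATEGORIES)
  if (length(bad)) stop("unknown categor(ies): ", paste(bad, collapse = ", "))
  if (any(category == "MANUAL_REVIEW") && review_policy == "error")
    stop("MANUAL_REVIEW without a resolution policy; use review_policy = \"exclude\" or resolve upstream")
  out <- ifelse(category == "SHIELD", "positive", "negative")
  out[category == "MANUAL_REVIEW"] <- NA_character_
  out
}

#' Build a 2x2 confusion matrix
#'
#' @param pred,gold equal-length vectors of `"positive"`/`"negative"` labels.
#' @return object of class `confusion_matrix` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop("pred and gold have different lengths (", length(pred), " vs ",
         length(gold), ")")
  stopifnot(all(pred %in% c("positive", "negative")),
            all(gold %in% c("positive", "negative")))
  structure(list(tp = sum(pred == "positive" & gold == "positive"),
                 fp = sum(pred == "positive" & gold == "negative"),
                 fn = sum(pred == "negative" & gold == "positive"),
                 tn = sum(pred == "negative" & gold == "negative")),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative cell counts.
#' @return a `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("pred positive", "pred negative"),
                              c("gold positive", "gold negative")))
  print(m)
  invisible(x)
}

wilson_ci <- function(k, n, level) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- suppressWarnings(stats::prop.test(k, n, conf.level = level,
                                          correct = FALSE)$conf.int)
  as.numeric(ci)
}

lr_ci <- function(lr, a, n1, b, n0, level) {
  # log-method interval for a likelihood ratio built from a/n1 over b/n0
  if (is.na(lr) || a == 0 || b == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic-accuracy metrics from a confusion matrix
#'
#' Sensitivity, specificity, PPV, NPV, false positive/negative rates, the
#' positive and negative likelihood ratios and the F1 score, each with a 95%
#' confidence interval: Wilson score intervals for proportions and
#' log-method intervals for likelihood ratios (recorded in
#' `$meta$ci_method`). A metric with a zero denominator is reported as
#' absent (`NA`) with a reason, never as propagated NaN.
#'
#' @param m a [confusion_matrix()].
#' @param ci_level confidence level (default 0.95).
#' @return object of class `diagnostic_metrics`: a list of metric entries
#'   (`value`, `lower`, `upper`) plus `meta`.
#' @export
diagnostic_metrics <- function(m, ci_level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  tp <- m$tp; fp <- m$fp; fn <- m$fn; tn <- m$tn
  absent <- list(value = NA_real_, lower = NA_real_, upper = NA_real_)
  prop <- function(k, n, reason) {
    if (n == 0) return(c(absent, list(reason = reason)))
    ci <- wilson_ci(k, n, ci_level)
    list(value = k / n, lower = ci[1], upper = ci[2])
  }
  out <- list(
    sensitivity = prop(tp, tp + fn, "no gold positives"),
    specificity = prop(tn, tn + fp, "no gold negatives"),
    ppv = prop(tp, tp + fp, "no positive predictions"),
    npv = prop(tn, tn + fn, "no negative predictions"),
    fpr = prop(fp, fp + tn, "no gold negatives"),
    fnr = prop(fn, fn + tp, "no gold positives")
  )
  sens <- out$sensitivity$value
  spec <- out$specificity$value
  lrp <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  lrn <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  ci_p <- lr_ci(lrp, tp, tp + fn, fp, fp + tn, ci_level)
  ci_n <- lr_ci(lrn, fn, tp + fn, tn, fp + tn, ci_level)
  out$lr_pos <- list(value = lrp, lower = ci_p[1], upper = ci_p[2])
  out$lr_neg <- list(value = lrn, lower = ci_n[1], upper = ci_n[2])
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  out$f1 <- list(value = f1, lower = NA_real_, upper = NA_real_)
  out$meta <- list(counts = list(tp = tp, fp = fp, fn = fn, tn = tn),
                   n = tp + fp + fn + tn,
                   ci_level = ci_level,
                   ci_method = list(proportions = "wilson",
                                    likelihood_ratios = "log"),
                   lr_pos_roundings = if (!is.na(lrp))
                     list(nearest_integer = round(lrp),
                          two_decimals = round(lrp, 2)))
  structure(out, class = "diagnostic_metrics")
}

#' Round metrics for report display
#'
#' Proportions to whole percent, ratios to two decimals, with the positive
#' likelihood ratio to the nearest integer when it is 10 or more. Raw values
#' stay available in the `diagnostic_metrics` object.
#'
#' @param metrics a [diagnostic_metrics()] object.
#' @return named list of display strings / numbers.
#' @export
format_metrics <- function(metrics) {
  pct <- function(e) if (is.na(e$value)) NA else round(100 * e$value)
  pct_ci <- function(e) {
    if (is.na(e$value)) return(NA)
    sprintf("%d%% (%d%%, %d%%)", round(100 * e$value),
            round(100 * e$lower), round(100 * e$upper))
  }
  lr_round <- function(v) {
    if (is.na(v)) return(NA)
    if (v >= 10) round(v) else round(v, 2)
  }
  list(sensitivity_pct = pct(metrics$sensitivity),
       sensitivity = pct_ci(metrics$sensitivity),
       specificity_pct = pct(metrics$specificity),
       specificity = pct_ci(metrics$specificity),
       ppv_pct = pct(metrics$ppv),
       ppv = pct_ci(metrics$ppv),
       npv_pct = pct(metrics$npv),
       npv = pct_ci(metrics$npv),
       fpr_pct = pct(metrics$fpr),
       fnr_pct = pct(metrics$fnr),
       lr_pos = lr_round(metrics$lr_pos$value),
       lr_pos_ci = if (!is.na(metrics$lr_pos$value))
         sprintf("(%s, %s)", lr_round(metrics$lr_pos$lower),
                 lr_round(metrics$lr_pos$upper)),
       lr_neg = if (is.na(metrics$lr_neg$value)) NA else round(metrics$lr_neg$value, 2),
       f1 = if (is.na(metrics$f1$value)) NA else round(metrics$f1$value, 2))
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  f <- format_metrics(x)
  cat("Diagnostic accuracy (n =", x$meta$n, ")\n")
  cat("  Sensitivity:", f$sensitivity, "\n")
  cat("  Specificity:", f$specificity, "\n")
  cat("  PPV:        ", f$ppv, "\n")
  cat("  NPV:        ", f$npv, "\n")
  cat("  LR+:        ", f$lr_pos, f$lr_pos_ci, "\n")
  cat("  LR-:        ", f$lr_neg, "\n")
  cat("  FPR:", paste0(f$fpr_pct, "%"), " FNR:", paste0(f$fnr_pct, "%"), "\n")
  cat("  F1 score:   ", f$f1, "\n")
  invisible(x)
}

#' Per-category deployment summary
#'
#' Counts and whole-percent shares of each shielding category over a set of
#' results — the shape of a deployment report over a whole clinic cohort.
#'
#' @param results list of `shielding_result` (or a character vector of
#'   categories).
#' @return data.frame with columns `category`, `n`, `pct`.
#' @export
deployment_summary <- function(results) {
  cats <- if (is.character(results)) results
          else vapply(results, `[[`, "", "category")
  lev <- c("SOCIAL_DISTANCE", "SELF_ISOLATE", "SHIELD", "MANUAL_REVIEW")
  n <- vapply(lev, function(l) sum(cats == l), 0L)
  total <- length(cats)
  out <- data.frame(category = lev, n = as.integer(n),
                    pct = if (total) round(100 * n / total) else rep(0L, 4),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!"MANUAL_REVIEW" %in% cats) out <- out[out$category != "MANUAL_REVIEW", ]
  rownames(out) <- NULL
  out
}

suppress_small <- function(n, suppress_below) {
  ifelse(!is.na(n) & n > 0 & n < suppress_below, NA_integer_, n)
}

#' Baseline cohort summary with small-cell suppression
#'
#' Age bands (18-39, 40-54, 55-69, >=70), sex, comorbidity and
#' medication-class counts with percentages, split by predicted shielding
#' status. Any non-zero cell below `suppress_below` is reported as `NA`
#' (statistical disclosure control).
#'
#' @param records list of `consolidated_record`.
#' @param results matching list of `shielding_result`.
#' @param suppress_below suppression threshold (default 5).
#' @return data.frame with rows per characteristic and count/percent columns
#'   for all patients and the shielding / not-shielding splits.
#' @export
cohort_summary <- function(records, results, suppress_below = 5) {
  stopifnot(length(records) == length(results))
  ages <- vapply(records, `[[`, 0L, "age_at_index")
  sexes <- vapply(records, `[[`, "", "sex")
  shield <- vapply(results, `[[`, "", "category") == "SHIELD"
  band <- cut(ages, c(-Inf, 39, 54, 69, Inf),
              labels = c("18-39", "40-54", "55-69", ">=70"))
  cats <- names(records[[1]]$comorbidities$flags)
  flag_mat <- t(vapply(records, function(r) r$comorbidities$flags,
                       logical(length(cats))))
  med_classes <- c("GLUCOCORTICOID", "IMMUNOSUPPRESSANT", "BIOLOGIC",
                   "SMALL_MOLECULE_IS", "CYCLOPHOSPHAMIDE")
  med_mat <- t(vapply(records, function(r) {
    cls <- unique(unlist(lapply(r$active_medications, `[[`, "classes")))
    med_classes %in% cls
  }, logical(length(med_classes))))
  colnames(med_mat) <- med_classes

  one_split <- function(mask) {
    n <- sum(mask)
    cell <- function(k) {
      ks <- suppress_small(k, suppress_below)
      list(n = ks, pct = if (is.na(ks) || n == 0) NA_real_ else round(100 * ks / n))
    }
    rows <- list()
    for (b in levels(band)) rows[[paste0("age ", b)]] <- cell(sum(band[mask] == b))
    rows[["female sex"]] <- cell(sum(sexes[mask] == "F"))
    for (cat in cats) rows[[paste0("comorbidity ", cat)]] <-
      cell(sum(flag_mat[mask, cat]))
    for (cl in med_classes) rows[[paste0("medication ", cl)]] <-
      cell(sum(med_mat[mask, cl]))
    rows
  }
  all_rows <- one_split(rep(TRUE, length(records)))
  sh_rows <- one_split(shield)
  no_rows <- one_split(!shield)
  data.frame(
    characteristic = names(all_rows),
    all_n = vapply(all_rows, function(x) as.integer(x$n), 1L),
    all_pct = vapply(all_rows, function(x) as.numeric(x$pct), 1),
    shield_n = vapply(sh_rows, function(x) as.integer(x$n), 1L),
    shield_pct = vapply(sh_rows, function(x) as.numeric(x$pct), 1),
    noshield_n = vapply(no_rows, function(x) as.integer(x$n), 1L),
    noshield_pct = vapply(no_rows, function(x) as.numeric(x$pct), 1),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate predictions against a gold standard
#'
#' @param pred data.frame with columns `patient_id`, `category` (or a named
#'   vector of categories).
#' @param gold data.frame with columns `patient_id`, `label`
#'   (`positive`/`negative`).
#' @param review_policy how MANUAL_REVIEW predictions are handled:
#'   `"exclude"` drops them (counted in the report) or `"error"`.
#' @param ci_level confidence level.
#' @return list: `metrics` ([diagnostic_metrics()]), `confusion`
#'   ([confusion_matrix()]), `n_excluded_review`, `n_matched`.
#' @export
evaluate_predictions <- function(pred, gold,
                                 review_policy = c("exclude", "error"),
                                 ci_level = 0.95) {
  review_policy <- match.arg(review_policy)
  if (is.data.frame(pred))
    pred <- stats::setNames(pred$category, pred$patient_id)
  if (is.data.frame(gold))
    gold <- stats::setNames(gold$label, gold$patient_id)
  ids <- intersect(names(pred), names(gold))
  if (!length(ids)) stop("no patient_id overlap between predictions and gold standard")
  p <- binarize(unname(pred[ids]),
                review_policy = if (review_policy == "exclude") "exclude" else "error")
  g <- unname(gold[ids])
  stopifnot(all(g %in% c("positive", "negative")))
  keep <- !is.na(p)
  cm <- confusion_matrix(p[keep], g[keep])
  list(metrics = diagnostic_metrics(cm, ci_level),
       confusion = cm,
       n_excluded_review = sum(!keep),
       n_matched = length(ids))
}
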