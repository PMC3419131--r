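# Reporting pipeline: ties cohort tables, threshold rules and the
# statistical machinery into reproducible group-comparison, correlation,
# diagnostic-accuracy and agreement reports.

#' Default diagnostic-accuracy rule set
#'
#' The standard cutpoints for detecting pulmonary hypertension from
#' right-heart CMR indices: morphology (RVEDVI >= 75 mL/m^2, RV mass index
#' >= 20 g/m^2, VMI >= 0.4), function (RVEF <= 35%, RVSVI <= 30 mL/m^2,
#' TAPSE <= 2 cm, f-TAAD <= 25%, SFD <= 1 cm, f-SFD <= 25%, RVRAC <= 30%,
#' sEI >= 1.2, dEI >= 1.17) and phase contrast (average velocity <= 10
#' cm/s, retrograde flow >= 0.3 L/min/m^2, retrograde percentage >= 10%,
#' PA relative area change <= 15%, systolic PA area >= 8 cm^2, diastolic
#' PA area >= 6 cm^2).  Low PA pulsatility indicates a stiff hypertensive
#' vessel, so the PA relative area change rule is
#' low-positive.
#'
#' @return data frame with columns `metric`, `cutpoint`, `direction`.
#' @export
default_rules <- function() {
  data.frame(
    metric = c("rvedvi", "rv_mass_index", "vmi",
               "rvef", "rvsvi", "tapse", "f_taad", "sfd", "f_sfd",
               "rvrac", "sei", "dei",
               "avg_velocity", "retro_flow", "retro_pct", "pa_rac",
               "sys_area", "dia_area"),
    cutpoint = c(75, 20, 0.4,
                 35, 30, 2, 25, 1, 25,
                 30, 1.2, 1.17,
                 10, 0.3, 10, 15,
                 8, 6),
    direction = c("GE_POSITIVE", "GE_POSITIVE", "GE_POSITIVE",
                  "LE_POSITIVE", "LE_POSITIVE", "LE_POSITIVE",
                  "LE_POSITIVE", "LE_POSITIVE", "LE_POSITIVE",
                  "LE_POSITIVE", "GE_POSITIVE", "GE_POSITIVE",
                  "LE_POSITIVE", "GE_POSITIVE", "GE_POSITIVE",
                  "LE_POSITIVE", "GE_POSITIVE", "GE_POSITIVE"),
    stringsAsFactors = FALSE)
}

#' Read or write a rule set as YAML
#'
#' Round-trips the rule table losslessly: a list of
#' `{metric, cutpoint, direction}` entries.
#'
#' @param path YAML file path.
#' @return `read_rules_yaml()` returns the rules data frame.
#' @export
read_rules_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(raw$rules, function(r) {
    data.frame(metric = r$metric, cutpoint = as.numeric(r$cutpoint),
               direction = match.arg(r$direction,
                                     c("GE_POSITIVE", "LE_POSITIVE")),
               stringsAsFactors = FALSE)
  }))
  df
}

#' @rdname read_rules_yaml
#' @param rules rules data frame (`metric`, `cutpoint`, `direction`).
#' @export
write_rules_yaml <- function(rules, path) {
  yaml::write_yaml(list(rules = lapply(seq_len(nrow(rules)), function(i) {
    list(metric = rules$metric[i], cutpoint = rules$cutpoint[i],
         direction = rules$direction[i])
  })), path)
  invisible(path)
}

analysis_records <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    rhcmr_error("cohort is empty", "rhcmr_validation")
  }
  req <- c("group", "mpap")
  missing <- setdiff(req, names(cohort))
  if (length(missing)) {
    rhcmr_error(sprintf("cohort lacks required column(s): %s",
                        paste(missing, collapse = ", ")),
                "rhcmr_validation")
  }
  if ("non_diagnostic" %in% names(cohort)) {
    cohort <- cohort[!isTRUE_vec(cohort$non_diagnostic), , drop = FALSE]
  }
  bad <- which((cohort$group == "PH") != (cohort$mpap >= 25))
  if (length(bad)) {
    rhcmr_error(
      sprintf("group label inconsistent with mPAP >= 25 mmHg in row %d",
              bad[1]),
      "rhcmr_validation")
  }
  cohort
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Diagnostic-accuracy table for a cohort
#'
#' For every rule, records missing the metric are dropped (reproducing
#' per-metric analysis denominators), the rule dichotomises the remainder,
#' and a [confusion_metrics()] row is produced together with the rank-based
#' AUC of the underlying continuous metric.  A binary column (e.g. late
#' gadolinium enhancement) can be appended via `binary_markers`.
#'
#' @param cohort cohort data frame (rows flagged `non_diagnostic` are
#'   excluded first).
#' @param rules rules data frame as from [default_rules()].
#' @param binary_markers character vector of logical cohort columns to
#'   report as binary tests.
#' @param rounded apply the reporting precision (integer percentages,
#'   2-decimal AUC); `FALSE` keeps full precision.
#' @return data frame, one row per rule/marker, columns `metric`, `rule`,
#'   `n`, `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `auc`, `fisher_p`.
#' @export
diagnose_cohort <- function(cohort, rules = default_rules(),
                            binary_markers = intersect("lge_present",
                                                       names(cohort)),
                            rounded = TRUE) {
  cohort <- analysis_records(cohort)
  disease <- cohort$group == "PH"
  rows <- list()

  add_row <- function(metric, rule_txt, test, dis, auc) {
    keep <- !is.na(test)
    test <- test[keep]; dis <- dis[keep]
    cm <- confusion_metrics(tp = sum(test & dis), fp = sum(test & !dis),
                            fn = sum(!test & dis), tn = sum(!test & !dis))
    data.frame(metric = metric, rule = rule_txt, n = length(test),
               tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               ppv = cm$ppv, npv = cm$npv, auc = auc,
               fisher_p = cm$fisher_p, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(rules))) {
    metric <- rules$metric[i]
    if (!metric %in% names(cohort)) next
    rule <- threshold_rule(metric, rules$cutpoint[i], rules$direction[i])
    vals <- cohort[[metric]]
    keep <- !is.na(vals)
    auc <- roc_auc(vals[keep], disease[keep], rule$direction)
    op <- if (rule$direction == "GE_POSITIVE") ">=" else "<="
    rows[[length(rows) + 1]] <-
      add_row(metric, sprintf("%s %s %g", metric, op, rule$cutpoint),
              classify(rule, vals), disease, auc)
  }

  for (bm in binary_markers) {
    vals <- as.logical(cohort[[bm]])
    keep <- !is.na(vals)
    cmtab <- add_row(bm, sprintf("%s present", bm), vals, disease,
                     NA_real_)
    cmtab$auc <- binary_test_auc(cmtab$tp, cmtab$fp, cmtab$fn, cmtab$tn)
    rows[[length(rows) + 1]] <- cmtab
  }

  out <- do.call(rbind, rows)
  if (rounded) {
    for (col in c("sensitivity", "specificity", "ppv", "npv")) {
      out[[col]] <- round_half_up(out[[col]])
    }
    out$auc <- round_half_up(out$auc, 2)
  }
  rownames(out) <- NULL
  out
}

#' Group-comparison table (two-group means and tests)
#'
#' Mean and SD per group for every metric with an independent t-test, plus
#' a chi-square comparison for binary columns.
#'
#' @inheritParams diagnose_cohort
#' @param metrics metric columns to summarise; defaults to every numeric
#'   metric shared with the default rule set plus mPAP and haemodynamics.
#' @param welch use Welch's t-test instead of pooled-variance Student.
#' @return data frame with per-group `mean_*`/`sd_*`, `n`, and `p_value`.
#' @export
compare_groups_table <- function(cohort, metrics = NULL, welch = FALSE) {
  cohort <- analysis_records(cohort)
  if (is.null(metrics)) {
    candidates <- c("age", "mrap", "mpap", "co", "ci", "pvr", "trjv",
                    "echo_mpap", default_rules()$metric)
    metrics <- intersect(candidates, names(cohort))
  }
  g <- factor(cohort$group, levels = c("NO_PH", "PH"))
  rows <- lapply(metrics, function(m) {
    v <- cohort[[m]]
    keep <- !is.na(v)
    p <- tryCatch(group_compare(v[keep], g[keep], type = "continuous",
                                welch = welch)$p_value,
                  error = function(e) NA_real_)
    data.frame(metric = m,
               n = sum(keep),
               mean_no_ph = mean(v[keep & g == "NO_PH"]),
               sd_no_ph = sd(v[keep & g == "NO_PH"]),
               mean_ph = mean(v[keep & g == "PH"]),
               sd_ph = sd(v[keep & g == "PH"]),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation table against invasive haemodynamics
#'
#' Pearson correlation of each metric with catheter mPAP and (when present)
#' PVR, with t-distribution p-values, over the per-metric complete cases.
#'
#' @inheritParams compare_groups_table
#' @return data frame with `metric`, `n`, `r_mpap`, `p_mpap`, and when PVR
#'   is available `r_pvr`, `p_pvr`.
#' @export
correlation_table <- function(cohort, metrics = NULL) {
  cohort <- analysis_records(cohort)
  if (is.null(metrics)) {
    metrics <- intersect(c(default_rules()$metric, "trjv", "echo_mpap"),
                         names(cohort))
  }
  has_pvr <- "pvr" %in% names(cohort)
  rows <- lapply(metrics, function(m) {
    ct <- pearson_r(cohort[[m]], cohort$mpap)
    row <- data.frame(metric = m, n = unname(ct["n"]),
                      r_mpap = unname(ct["r"]), p_mpap = unname(ct["p"]),
                      stringsAsFactors = FALSE)
    if (has_pvr) {
      cp <- pearson_r(cohort[[m]], cohort$pvr)
      row$r_pvr <- unname(cp["r"]); row$p_pvr <- unname(cp["p"])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full reporting pipeline
#'
#' Validates the cohort, drops records flagged non-diagnostic, logs the
#' per-analysis denominators, and produces the group-comparison,
#' correlation and diagnostic-accuracy tables (and, when observer pairs
#' are supplied, a Bland-Altman agreement report).  With `out_dir` set the
#' tables are written as CSV plus a markdown summary; outputs are
#' deterministic for fixed inputs.
#'
#' @param cohort cohort data frame (see [make_cohort()] /
#'   [read_cohort_csv()]).
#' @param rules rules data frame; default [default_rules()].
#' @param observer_pairs optional data frame or list with elements/columns
#'   `obs1`, `obs2` of paired re-measurements for agreement analysis.
#' @param out_dir optional output directory.
#' @param rounded apply reporting precision to the accuracy table.
#' @return an object of class `rhcmr_report`: list with `denominators`,
#'   `group_table`, `correlation_table`, `accuracy_table`, and optionally
#'   `agreement`.
#' @export
run_pipeline <- function(cohort, rules = default_rules(),
                         observer_pairs = NULL, out_dir = NULL,
                         rounded = TRUE) {
  analysed <- analysis_records(cohort)
  denominators <- list(
    input = nrow(cohort),
    excluded_non_diagnostic = nrow(cohort) - nrow(analysed),
    analysed = nrow(analysed),
    ph = sum(analysed$group == "PH"),
    no_ph = sum(analysed$group == "NO_PH"),
    lge = if ("lge_present" %in% names(analysed)) {
      sum(!is.na(analysed$lge_present))
    } else 0L,
    phase_contrast = if ("avg_velocity" %in% names(analysed)) {
      sum(!is.na(analysed$avg_velocity))
    } else 0L)

  report <- list(
    denominators = denominators,
    group_table = compare_groups_table(analysed),
    correlation_table = correlation_table(analysed),
    accuracy_table = diagnose_cohort(analysed, rules, rounded = rounded))
  if (!is.null(observer_pairs)) {
    report$agreement <- bland_altman(observer_pairs$obs1,
                                     observer_pairs$obs2)
  }
  class(report) <- "rhcmr_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$group_table,
              file.path(out_dir, "group_comparison.csv"), row.names = FALSE)
    write.csv(report$correlation_table,
              file.path(out_dir, "correlations.csv"), row.names = FALSE)
    write.csv(report$accuracy_table,
              file.path(out_dir, "diagnostic_accuracy.csv"),
              row.names = FALSE)
    writeLines(format_report_md(report), file.path(out_dir, "summary.md"))
  }
  report
}

format_report_md <- function(report) {
  d <- report$denominators
  lines <- c(
    "# Right-heart CMR analysis summary", "",
    sprintf("- records in: %d; excluded non-diagnostic: %d; analysed: %d",
            d$input, d$excluded_non_diagnostic, d$analysed),
    sprintf("- groups: %d PH / %d no-PH (mPAP >= 25 mmHg rule)",
            d$ph, d$no_ph),
    sprintf("- subsets: late gadolinium enhancement n = %d, phase contrast n = %d",
            d$lge, d$phase_contrast), "",
    "## Diagnostic accuracy", "",
    paste(utils::capture.output(print(report$accuracy_table)),
          collapse = "\n"))
  if (!is.null(report$agreement)) {
    a <- report$agreement
    lines <- c(lines, "", "## Inter-observer agreement", "",
               sprintf("bias %.3g (SD %.3g), limits of agreement %.3g to %.3g",
                       a$bias, a$sd_diff, a$loa_low, a$loa_high))
  }
  lines
}

#' @export
print.rhcmr_report <- function(x, ...) {
  d <- x$denominators
  cat(sprintf("<rhcmr_report> analysed %d of %d records (%d PH / %d no-PH); LGE n=%d, phase contrast n=%d\n",
              d$analysed, d$input, d$ph, d$no_ph, d$lge, d$phase_contrast))
  cat("  tables: group_table, correlation_table, accuracy_table",
      if (!is.null(x$agreement)) "+ agreement" else "", "\n")
  invisible(x)
}
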