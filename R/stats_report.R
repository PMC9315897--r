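# Paired and association statistics, table rendering, and the end-to-end
# pipeline driver.

#' Continuity-corrected McNemar test
#'
#' Edwards-corrected statistic `(|b - c| - 1)^2 / (b + c)` on the
#' discordant pair counts, with a chi-square(1) upper-tail p-value. The
#' uncorrected variant `(b - c)^2 / (b + c)` is available with
#' `correct = FALSE`.
#'
#' @param b,c discordant counts (before-only, after-only).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return a `mcnemar_result` list: `b`, `c`, `chi2`, `df`, `p`.
#' @examples
#' mcnemar_cc(89, 575)   # chi2 = 354.25
#' @export
mcnemar_cc <- function(b, c, correct = TRUE) {
  stopifnot(length(b) == 1, length(c) == 1, b >= 0, c >= 0)
  if (b + c < 1) {
    stop("McNemar test undefined for b = c = 0 (no discordant pairs)",
         call. = FALSE)
  }
  chi2 <- if (correct) {
    (abs(b - c) - 1)^2 / (b + c)
  } else {
    (b - c)^2 / (b + c)
  }
  structure(list(b = b, c = c, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 correct = correct),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat("McNemar test", if (x$correct) "(continuity-corrected)" else "",
      "\n  b =", x$b, ", c =", x$c,
      sprintf("\n  chi-squared = %.2f, df = 1, p = %.3g\n", x$chi2, x$p))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Wrapper around the Pearson statistic without continuity correction,
#' with margin validation, for r x k contingency tables (e.g.
#' chemotherapy x depression).
#'
#' @param tab matrix of counts with at least 2 rows and 2 columns.
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need a contingency table with >= 2 rows and columns of ",
         "non-negative counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: every row and column needs a positive total",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Format an "n/N (%)" table cell
#'
#' Percent is half-up rounded to one decimal; integer-valued percents are
#' printed bare (e.g. `"568/624 (91)"`, not `"(91.0)"`).
#'
#' @param n numerator count.
#' @param d denominator count (> 0).
#' @return formatted string.
#' @examples
#' proportion_cell(575, 664)
#' @export
proportion_cell <- function(n, d) {
  stopifnot(length(n) == length(d))
  if (any(d <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(n < 0 | n > d)) stop("need 0 <= n <= d", call. = FALSE)
  pct <- half_up(100 * n / d, 1L)
  pct_str <- sprintf("%.1f", pct)
  whole <- pct == floor(pct)
  pct_str[whole] <- sprintf("%d", as.integer(pct[whole]))
  sprintf("%d/%d (%s)", as.integer(n), as.integer(d), pct_str)
}

#' Percentage as printed in report cells
#'
#' Numeric companion of [proportion_cell()]: half-up rounding of
#' `100 * n / d` to one decimal.
#' @param n numerator count.
#' @param d denominator count (> 0).
#' @return numeric percentage.
#' @examples
#' proportion_percent(575, 664)
#' @export
proportion_percent <- function(n, d) {
  stopifnot(all(d > 0))
  half_up(100 * n / d, 1L)
}

# internal alias
percent_value <- proportion_percent

# ---- report tables ----------------------------------------------------------

channel_titles <- c(
  icd = "ICD-9-CM depression diagnosis codes",
  drug = "antidepressant drug mentions",
  disorder = "depressive-disorder concept mentions",
  combined = "any evidence channel (codes, drugs, or disorder concepts)")

paired_rows <- function(cls, patients) {
  # per cancer-type and total rows of a paired before/after table
  types <- c("breast", "colorectal")
  mk <- function(label, classes) {
    pt <- build_paired_table(classes)
    tibble::tibble(
      row = label, b = pt$b, c = pt$c, n_with = pt$n_with,
      n_without = pt$n_without, n_considered = pt$n_total_considered,
      n_both_excluded = pt$n_both_excluded,
      before_cell = if (pt$n_with > 0) proportion_cell(pt$b, pt$n_with)
                    else "0/0",
      after_cell = if (pt$n_with > 0) proportion_cell(pt$c, pt$n_with)
                   else "0/0",
      with_cell = if (pt$n_total_considered > 0)
        proportion_cell(pt$n_with, pt$n_total_considered) else "0/0",
      without_cell = if (pt$n_total_considered > 0)
        proportion_cell(pt$n_without, pt$n_total_considered) else "0/0")
  }
  idx <- match(cls$patient_id, patients$patient_id)
  rows <- lapply(types, function(tp) {
    mk(tp, cls$temporal_class[patients$cancer_type[idx] == tp])
  })
  rbind(do.call(rbind, rows), mk("total", cls$temporal_class))
}

#' Render the study's report tables
#'
#' Builds the six tables of the analysis: T1 (cancer type x stage with
#' after-index ICD depression), T2-T4 (per-channel paired before/after
#' tables), T5 (combined channel), T6 (attribution of depression-positive
#' patients to ICD vs text-only detection), plus the per-channel McNemar
#' results. Every "n/N (%)" cell is recomputed from its own counts.
#'
#' @param patients selected patients tibble.
#' @param classifications long tibble from [classify_cohort()].
#' @return list with `tables` (named list T1..T6 of tibbles) and `stats`
#'   (per-channel `mcnemar_result`s).
#' @export
render_tables <- function(patients, classifications) {
  split_cls <- split(classifications,
                     factor(classifications$channel,
                            levels = c("icd", "drug", "disorder",
                                       "combined")))
  for (ch in names(split_cls)) {
    if (anyDuplicated(split_cls[[ch]]$patient_id)) {
      stop("duplicate patient ids in channel ", ch, call. = FALSE)
    }
    if (!setequal(split_cls[[ch]]$patient_id, patients$patient_id)) {
      stop("classification and patient sets disagree for channel ", ch,
           call. = FALSE)
    }
  }

  # T1: type x stage distribution and ICD-detected depression after index
  icd <- split_cls$icd
  icd_after <- icd$patient_id[icd$temporal_class %in%
                                c("after_only", "both")]
  t1 <- list()
  for (tp in c("breast", "colorectal")) {
    sub <- patients[patients$cancer_type == tp, ]
    n_type <- nrow(sub)
    for (st in c("in_situ", "I", "II", "III")) {
      n_st <- sum(sub$stage == st)
      n_dep <- sum(sub$stage == st & sub$patient_id %in% icd_after)
      t1[[length(t1) + 1L]] <- tibble::tibble(
        cancer_type = tp, stage = st, n = n_st, n_type = n_type,
        n_depression_after = n_dep,
        patients_cell = if (n_type > 0) proportion_cell(n_st, n_type)
                        else "0/0",
        depression_cell = if (n_st > 0) proportion_cell(n_dep, n_st)
                          else "0/0")
    }
    t1[[length(t1) + 1L]] <- tibble::tibble(
      cancer_type = tp, stage = "all", n = n_type, n_type = n_type,
      n_depression_after = sum(sub$patient_id %in% icd_after),
      patients_cell = if (n_type > 0) proportion_cell(n_type, n_type)
                      else "0/0",
      depression_cell = if (n_type > 0)
        proportion_cell(sum(sub$patient_id %in% icd_after), n_type)
        else "0/0")
  }
  t1 <- do.call(rbind, t1)

  tables <- list(T1 = t1)
  stats <- list()
  for (ch in c("icd", "drug", "disorder", "combined")) {
    tab <- paired_rows(split_cls[[ch]], patients)
    key <- c(icd = "T2", drug = "T3", disorder = "T4", combined = "T5")[[ch]]
    tables[[key]] <- tab
    tot <- tab[tab$row == "total", ]
    stats[[ch]] <- if (tot$b + tot$c >= 1) mcnemar_cc(tot$b, tot$c) else NULL
  }

  # T6: attribution among evidence-positive patients
  comb <- split_cls$combined
  idx <- match(comb$patient_id, patients$patient_id)
  t6 <- list()
  for (tp in c("breast", "colorectal", "total")) {
    keep <- if (tp == "total") rep(TRUE, nrow(comb))
            else patients$cancer_type[idx] == tp
    at <- attribution_split(
      split_cls$icd$temporal_class[match(comb$patient_id[keep],
                                         split_cls$icd$patient_id)],
      comb$temporal_class[keep])
    t6[[length(t6) + 1L]] <- tibble::tibble(
      row = tp, icd_detected = at$icd_detected, text_only = at$text_only,
      n_positive = at$n_positive,
      icd_cell = if (at$n_positive > 0)
        proportion_cell(at$icd_detected, at$n_positive) else "0/0",
      text_only_cell = if (at$n_positive > 0)
        proportion_cell(at$text_only, at$n_positive) else "0/0")
  }
  tables$T6 <- do.call(rbind, t6)

  list(tables = tables, stats = stats)
}

#' Write rendered tables and statistics to disk as JSON/CSV
#' @param report output of [render_tables()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(tolower(nm), ".csv")),
                     row.names = FALSE)
  }
  stats <- lapply(report$stats, function(s) {
    if (is.null(s)) NULL else s[c("b", "c", "chi2", "df", "p")]
  })
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- end-to-end pipeline ----------------------------------------------------

#' Run the full phenotyping pipeline on a cohort
#'
#' Selection filters, note mining (language identification, fuzzy term
#' matching, negation exclusion), per-channel temporal classification,
#' paired tables, McNemar statistics, and the chemotherapy association
#' test.
#'
#' @param cohort a `synth_cohort` (or compatible list of `patients`,
#'   `visits`, `notes` tibbles).
#' @param lexicon matching vocabulary; defaults to the bundled drug +
#'   disorder lexicons.
#' @param codes depression ICD-9-CM `tp_codeset`.
#' @param max_edits fuzzy tolerance (0 or 1).
#' @param negation `"rule"`, `"crf"`, or `"none"`.
#' @param model CRF model when `negation = "crf"`.
#' @param window rule-baseline scope window.
#' @param index_day_counts_as tie rule for diagnosis-day events.
#' @return list with `selection`, `mentions`, `classifications`,
#'   `paired` (per-channel `paired_table`s), `report` (tables + McNemar),
#'   and `chemo_association` (chi-square on chemotherapy x depression).
#' @export
run_pipeline <- function(cohort, lexicon = NULL,
                         codes = default_depression_codes(),
                         max_edits = 1L, negation = "rule", model = NULL,
                         window = 5L, index_day_counts_as = "after") {
  if (is.null(lexicon)) {
    lexicon <- combine_lexicons(default_drug_lexicon(),
                                default_disorder_lexicon())
  }
  sel <- apply_selection_criteria(cohort$patients, cohort$visits)
  keep <- sel$included$patient_id
  notes <- cohort$notes[cohort$notes$patient_id %in% keep, , drop = FALSE]
  visits <- cohort$visits[cohort$visits$patient_id %in% keep, , drop = FALSE]

  mentions <- mine_notes(notes, lexicon, max_edits = max_edits,
                         negation = negation, model = model, window = window)
  cls <- classify_cohort(sel$included, visits, mentions, codes = codes,
                         index_day_counts_as = index_day_counts_as)
  paired <- lapply(split(cls, cls$channel), function(d) {
    build_paired_table(d$temporal_class, d$patient_id)
  })
  report <- render_tables(sel$included, cls)

  comb <- cls[cls$channel == "combined", ]
  dep <- comb$temporal_class != "none"
  chemo <- sel$included$chemotherapy[match(comb$patient_id,
                                           sel$included$patient_id)]
  chemo_assoc <- if (length(unique(chemo[!is.na(chemo)])) == 2 &&
                     length(unique(dep)) == 2) {
    chisq_independence(table(chemo, dep))
  } else {
    NULL
  }

  list(selection = sel, mentions = mentions, classifications = cls,
       paired = paired, report = report, chemo_association = chemo_assoc)
}
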