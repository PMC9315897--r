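mk_patient <- function(pid = "P1", type = "breast", stage = "II",
                       chemo = TRUE, dx = as.Date("2010-06-01")) {
  tibble::tibble(patient_id = pid, sex = "F", age = 60L, cancer_type = type,
                 stage = stage, chemotherapy = chemo, diagnosis_date = dx)
}

mk_visits <- function(pid, dates) {
  tibble::tibble(patient_id = pid,
                 visit_id = paste0(pid, "-V", seq_along(dates)),
                 date = as.Date(dates), icd_codes = "")
}

test_that("selection criteria exclude with the first failing rule", {
  dx <- as.Date("2010-06-01")
  good_dates <- c("2009-01-01", "2009-06-01", "2010-07-01", "2011-01-01")
  pats <- rbind(
    mk_patient("Pok"),
    mk_patient("Pfew"),
    mk_patient("Piv", stage = "IV"),
    mk_patient("Pnotx", chemo = NA),
    mk_patient("Pmult"))
  pats$n_cancers <- c(1L, 1L, 1L, 1L, 2L)
  vis <- rbind(
    mk_visits("Pok", good_dates),
    mk_visits("Pfew", c("2009-01-01", "2010-07-01", "2011-01-01")),
    mk_visits("Piv", good_dates),
    mk_visits("Pnotx", good_dates),
    mk_visits("Pmult", good_dates))
  sel <- apply_selection_criteria(pats, vis)
  expect_identical(sel$included$patient_id, "Pok")
  reasons <- setNames(sel$exclusions$reason, sel$exclusions$patient_id)
  expect_identical(reasons[["Pfew"]], "insufficient_visits")
  expect_identical(reasons[["Piv"]], "ineligible_stage")
  expect_identical(reasons[["Pnotx"]], "incomplete_treatment_information")
  expect_identical(reasons[["Pmult"]], "multiple_or_unqualifying_cancer")

  # a stage-IV patient with too few visits fails on visits first
  p <- mk_patient("Pboth", stage = "IV")
  v <- mk_visits("Pboth", c("2009-01-01", "2010-07-01"))
  expect_identical(apply_selection_criteria(p, v)$exclusions$reason,
                   "insufficient_visits")

  p$diagnosis_date <- as.Date(NA)
  expect_error(apply_selection_criteria(p, v), "diagnosis date")
})

test_that("temporal classification respects the index-day tie rule", {
  dx <- as.Date("2010-06-01")
  expect_identical(classify_channel(as.Date("2011-01-01"), dx), "after_only")
  expect_identical(classify_channel(as.Date("2009-01-01"), dx),
                   "before_only")
  expect_identical(classify_channel(as.Date(c("2009-01-01", "2011-01-01")),
                                    dx), "both")
  expect_identical(classify_channel(as.Date(character()), dx), "none")
  # diagnosis-day events: "after" by default, "before" when configured
  expect_identical(classify_channel(dx, dx), "after_only")
  expect_identical(classify_channel(dx, dx, "before"), "before_only")
})

test_that("channel combination uses union semantics", {
  expect_identical(combine_channels(c("after_only", "before_only", "none")),
                   "both")
  expect_identical(combine_channels(c("none", "none", "none")), "none")
  expect_identical(combine_channels(c("none", "after_only", "none")),
                   "after_only")
  expect_identical(combine_channels(c("both", "none", "none")), "both")
  expect_error(combine_channels(c("none", NA, "none")), "valid")
  expect_error(combine_channels(character()), "valid")
})

test_that("negated mentions contribute no evidence; channels independent", {
  pat <- mk_patient("P1")
  vis <- mk_visits("P1", c("2009-01-01", "2009-06-01", "2010-07-01",
                           "2011-01-01"))
  mentions <- tibble::tibble(
    patient_id = "P1", visit_id = "P1-V1", note_id = "P1-V1-n1",
    date = as.Date(c("2009-01-01", "2009-06-01")),
    language = "es", start = c(0L, 0L), end = c(5L, 5L),
    surface = c("rexer", "tristeza"),
    category = c("drug_brand", "disorder_term"),
    concept_id = c("N06AX11", "C1"), canonical = c("mirtazapina", "x"),
    edit_distance = 0L, negated = c(TRUE, FALSE))
  cls <- classify_cohort(pat, vis, mentions)
  got <- setNames(cls$temporal_class, cls$channel)
  expect_identical(got[["drug"]], "none")        # only a negated mention
  expect_identical(got[["disorder"]], "before_only")
  expect_identical(got[["icd"]], "none")
  expect_identical(got[["combined"]], "before_only")
})

test_that("icd channel reads coded visits through the code set", {
  pat <- mk_patient("P1")
  vis <- mk_visits("P1", c("2009-01-01", "2009-06-01", "2010-07-01",
                           "2011-01-01"))
  vis$icd_codes <- c("401.9", "", "311;174.9", "296.25")
  empty_mentions <- fixture_pipeline()$mentions[0, ]
  cls <- classify_cohort(pat, vis, empty_mentions)
  got <- setNames(cls$temporal_class, cls$channel)
  expect_identical(got[["icd"]], "after_only")
  expect_identical(got[["combined"]], "after_only")
})

test_that("paired tables reproduce printed-table arithmetic", {
  classes <- c(rep("both", 164), rep("before_only", 89),
               rep("after_only", 575), rep("none", 3410))
  pt <- build_paired_table(classes)
  expect_identical(pt$n_total_considered, 4074L)
  expect_identical(pt$n_both_excluded, 164L)
  expect_identical(pt$b, 89L)
  expect_identical(pt$c, 575L)
  expect_identical(pt$n_with, 664L)
  expect_identical(pt$n_without, 3410L)

  all_none <- build_paired_table(rep("none", 10))
  expect_identical(all_none$n_with, 0L)
  all_both <- build_paired_table(rep("both", 5))
  expect_identical(all_both$n_total_considered, 0L)
  expect_error(build_paired_table(c("none", "none"), c("a", "a")),
               "duplicate")
  expect_error(build_paired_table("sometimes"), "invalid")
})

test_that("attribution split partitions the evidence-positive set", {
  # 10-patient fixture, verified by hand set arithmetic:
  icd <- c("none", "after_only", "none", "both", "none",
           "before_only", "none", "none", "after_only", "none")
  comb <- c("none", "after_only", "after_only", "both", "before_only",
            "before_only", "none", "both", "after_only", "after_only")
  at <- attribution_split(icd, comb)
  # positives: patients 2,3,4,5,6,8,9,10 (8); of those without ICD: 3,5,8,10
  expect_identical(at$n_positive, 8L)
  expect_identical(at$text_only, 4L)
  expect_identical(at$icd_detected, 4L)
  expect_identical(at$icd_detected + at$text_only, at$n_positive)

  none_only <- attribution_split(comb, comb)
  expect_identical(none_only$text_only, 0L)
  expect_error(attribution_split(icd[1:3], comb), "different")
})

test_that("per-channel classes partition the selected patients", {
  res <- fixture_pipeline()
  n <- nrow(res$selection$included)
  for (ch in unique(res$classifications$channel)) {
    cls <- res$classifications$temporal_class[
      res$classifications$channel == ch]
    expect_identical(length(cls), n)
    expect_identical(sum(table(factor(cls, levels = c(
      "none", "before_only", "after_only", "both")))), n)
  }
  # combined positives contain each channel's positives
  wide <- split(res$classifications, res$classifications$channel)
  pos <- function(d) d$patient_id[d$temporal_class != "none"]
  for (ch in c("icd", "drug", "disorder")) {
    expect_true(all(pos(wide[[ch]]) %in% pos(wide$combined)))
  }
})

test_that("pipeline recovers planted temporal classes end to end", {
  co <- fixture_cohort_clean()   # misspelling_rate = 0
  res <- run_pipeline(co, negation = "rule", max_edits = 0L)
  truth <- co$truth$classes
  for (ch in c("icd", "drug", "disorder", "combined")) {
    d <- res$classifications[res$classifications$channel == ch, ]
    expect_identical(
      d$temporal_class,
      truth[[ch]][match(d$patient_id, truth$patient_id)])
  }
})
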