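test_that("continuity-corrected McNemar matches its closed forms", {
  expect_equal(round(mcnemar_cc(89, 575)$chi2, 2), 354.25)
  for (k in c(1, 5, 40)) {
    expect_equal(mcnemar_cc(k, k)$chi2, 1 / (2 * k))
  }
  expect_equal(mcnemar_cc(10, 20, correct = FALSE)$chi2, 100 / 30)
  expect_error(mcnemar_cc(0, 0), "undefined")
})

test_that("mcnemar_cc agrees with the standard-library implementation", {
  set.seed(19)
  for (i in 1:100) {
    b <- rpois(1, 40)
    cc <- rpois(1, 40)
    # at b == c the library clamps the corrected difference to zero while
    # this package keeps the closed form 1/(2b); compare where they agree
    if (b + cc == 0 || b == cc) next
    ours <- mcnemar_cc(b, cc)
    ref <- stats::mcnemar.test(matrix(c(5, b, cc, 7), 2, 2), correct = TRUE)
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$p, unname(ref$p.value))
  }
})

test_that("McNemar is symmetric and monotone in the discordance", {
  set.seed(23)
  for (i in 1:200) {
    b <- sample(0:500, 1)
    cc <- sample(0:500, 1)
    if (b + cc == 0) next
    expect_identical(mcnemar_cc(b, cc)$chi2, mcnemar_cc(cc, b)$chi2)
  }
  # non-decreasing in |b - c| at fixed b + c (for |b - c| >= 1)
  for (total in c(30, 101, 664)) {
    ds <- seq(1, total - 1, by = 2)
    chis <- vapply(ds, function(d) {
      b <- (total - d) / 2
      mcnemar_cc(b, b + d)$chi2
    }, numeric(1))
    expect_true(all(diff(chis) >= 0))
  }
})

test_that("chi-square p-values stay close to the exact sign test", {
  set.seed(29)
  rel_dev <- c()
  for (i in 1:1000) {
    total <- sample(30:400, 1)
    b <- rbinom(1, total, 0.5)
    cc <- total - b
    if (b + cc < 30) next
    p_chi <- mcnemar_cc(b, cc)$p
    p_exact <- stats::binom.test(b, total, 0.5)$p.value
    rel_dev <- c(rel_dev, abs(p_chi - p_exact) / p_exact)
  }
  expect_lt(stats::median(rel_dev), 0.15)
  expect_lt(stats::quantile(rel_dev, 0.99), 0.6)
})

test_that("chi-square independence matches hand computation", {
  flat <- matrix(c(10, 10, 10, 10), 2, 2)
  expect_equal(chisq_independence(flat)$chi2, 0)
  tab <- matrix(c(20, 10, 10, 20), 2, 2)
  # hand: n(ad-bc)^2 / (r1 r2 c1 c2) = 60 * 300^2 / 30^4 = 20/3
  expect_equal(chisq_independence(tab)$chi2, 20 / 3)
  expect_identical(chisq_independence(tab)$df, 1L)
  expect_error(chisq_independence(matrix(c(1, 0, 2, 0), 2, 2)), "margins")
  expect_error(chisq_independence(matrix(1:3, 1)), "2 rows")
})

test_that("a true chemotherapy association is detected with high power", {
  set.seed(37)
  hits <- 0L
  for (i in 1:500) {
    chemo <- rbinom(400, 1, 0.45)
    p_dep <- ifelse(chemo == 1, 0.45, 0.25)
    dep <- rbinom(400, 1, p_dep)
    tab <- table(factor(chemo, 0:1), factor(dep, 0:1))
    if (any(tab == 0)) next
    if (chisq_independence(tab)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.95)
})

test_that("proportion cells print like the published tables", {
  expect_identical(proportion_cell(575, 664), "575/664 (86.6)")
  expect_identical(proportion_cell(568, 624), "568/624 (91)")
  expect_identical(proportion_cell(379, 426), "379/426 (89)")
  expect_identical(proportion_cell(920, 1021), "920/1021 (90.1)")
  expect_identical(proportion_cell(441, 1269), "441/1269 (34.8)")
  expect_identical(proportion_cell(0, 10), "0/10 (0)")
  expect_error(proportion_cell(1, 0), "denominator")
  expect_error(proportion_cell(5, 3), "n <= d")
})

test_that("rendered tables are internally consistent", {
  res <- fixture_pipeline()
  tables <- res$report$tables
  expect_setequal(names(tables), c("T1", "T2", "T3", "T4", "T5", "T6"))

  check_cell <- function(cell, n, d) {
    if (d == 0) return(invisible())
    expect_identical(cell, proportion_cell(n, d))
  }
  for (key in c("T2", "T3", "T4", "T5")) {
    tb <- tables[[key]]
    for (i in seq_len(nrow(tb))) {
      check_cell(tb$before_cell[i], tb$b[i], tb$n_with[i])
      check_cell(tb$after_cell[i], tb$c[i], tb$n_with[i])
      check_cell(tb$with_cell[i], tb$n_with[i], tb$n_considered[i])
      check_cell(tb$without_cell[i], tb$n_without[i], tb$n_considered[i])
      expect_identical(tb$n_with[i] + tb$n_without[i], tb$n_considered[i])
    }
    tot <- tb[tb$row == "total", ]
    expect_identical(tot$b, sum(tb$b[tb$row != "total"]))
    expect_identical(tot$c, sum(tb$c[tb$row != "total"]))
  }
  t6 <- tables$T6
  for (i in seq_len(nrow(t6))) {
    expect_identical(t6$icd_detected[i] + t6$text_only[i], t6$n_positive[i])
    check_cell(t6$icd_cell[i], t6$icd_detected[i], t6$n_positive[i])
  }
  t1 <- tables$T1
  for (tp in c("breast", "colorectal")) {
    sub <- t1[t1$cancer_type == tp, ]
    expect_identical(sum(sub$n[sub$stage != "all"]),
                     sub$n[sub$stage == "all"])
  }
})

test_that("paired-table inputs reproduce the published total row", {
  classes <- c(rep("both", 164), rep("before_only", 89),
               rep("after_only", 575), rep("none", 3410))
  ids <- sprintf("P%04d", seq_along(classes))
  patients <- tibble::tibble(
    patient_id = ids,
    cancer_type = rep_len(c("breast", "colorectal"), length(ids)),
    stage = "II")
  cls <- rbind(
    tibble::tibble(patient_id = ids, channel = "icd",
                   temporal_class = classes),
    tibble::tibble(patient_id = ids, channel = "drug",
                   temporal_class = "none"),
    tibble::tibble(patient_id = ids, channel = "disorder",
                   temporal_class = "none"),
    tibble::tibble(patient_id = ids, channel = "combined",
                   temporal_class = classes))
  rep <- render_tables(patients, cls)
  tot <- rep$tables$T2[rep$tables$T2$row == "total", ]
  expect_identical(tot$before_cell, "89/664 (13.4)")
  expect_identical(tot$after_cell, "575/664 (86.6)")
  expect_identical(tot$with_cell, "664/4074 (16.3)")
  expect_equal(round(rep$stats$icd$chi2, 2), 354.25)
})

test_that("degenerate inputs render without error", {
  patients <- tibble::tibble(patient_id = character(),
                             cancer_type = character(),
                             stage = character())
  cls <- tibble::tibble(patient_id = character(), channel = character(),
                        temporal_class = character())
  cls <- rbind(cls, tibble::tibble(
    patient_id = character(), channel = character(),
    temporal_class = character()))
  # empty cohort: every channel absent -> build tables from empty splits
  empty <- lapply(c("icd", "drug", "disorder", "combined"), function(ch) {
    tibble::tibble(patient_id = character(), channel = ch,
                   temporal_class = character())
  })
  rep <- render_tables(patients, do.call(rbind, empty))
  expect_true(all(rep$tables$T2$n_considered == 0))
  expect_null(rep$stats$icd)
})

test_that("reports serialize to disk", {
  res <- fixture_pipeline()
  dir <- withr::local_tempdir()
  write_report(res$report, dir)
  expect_true(file.exists(file.path(dir, "t2.csv")))
  expect_true(file.exists(file.path(dir, "stats.json")))
  st <- jsonlite::fromJSON(file.path(dir, "stats.json"))
  expect_equal(st$icd$chi2, res$report$stats$icd$chi2)
})
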