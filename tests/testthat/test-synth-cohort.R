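test_that("cohort generation is a pure function of its config", {
  cfg <- sim_config(n_patients = 25L, seed = 33L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # and does not disturb the caller's RNG stream
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_cohort(cfg))
  expect_identical(runif(1), before)
})

test_that("zero depression probability plants no evidence anywhere", {
  co <- generate_cohort(sim_config(n_patients = 40L,
                                   p_depression_before = 0,
                                   p_depression_after = 0, seed = 9L))
  expect_true(all(co$truth$classes$combined == "none"))
  expect_true(all(co$truth$mentions$negated))  # only decoys remain
  dep <- default_depression_codes()
  codes <- unlist(strsplit(co$visits$icd_codes, ";", fixed = TRUE))
  codes <- codes[nzchar(codes)]
  expect_false(any(code_matches(codes, dep)))
})

test_that("noise-free config plants exact, non-negated surfaces", {
  co <- generate_cohort(sim_config(n_patients = 40L, negation_rate = 0,
                                   misspelling_rate = 0, seed = 10L))
  tm <- co$truth$mentions
  expect_true(nrow(tm) > 0)
  expect_false(any(tm$negated))
  expect_false(any(tm$misspelled))
  lex <- fixture_lexicon()
  expect_true(all(normalize_surface(tm$surface) %in% lex$norm_surface))
  expect_identical(nrow(co$truth$negations), 0L)
})

test_that("planted spans index exactly the planted surfaces", {
  co <- fixture_cohort()
  tm <- co$truth$mentions
  texts <- co$notes$text[match(tm$note_id, co$notes$note_id)]
  extracted <- stringi::stri_sub(texts, tm$start + 1L, tm$end)
  expect_identical(extracted, tm$surface)
  # scopes and markers lie within their notes and markers precede scopes
  ng <- co$truth$negations
  lens <- stringi::stri_length(co$notes$text[match(ng$note_id,
                                                   co$notes$note_id)])
  expect_true(all(ng$scope_end <= lens))
  expect_true(all(ng$marker_start >= 0))
  expect_true(all(ng$marker_end <= ng$scope_start))
})

test_that("negated planted mentions sit inside a trigger-opened scope", {
  co <- fixture_cohort()
  tm <- co$truth$mentions[co$truth$mentions$negated, ]
  ng <- co$truth$negations
  for (i in seq_len(nrow(tm))) {
    sp <- ng[ng$note_id == tm$note_id[i], ]
    expect_true(any(tm$start[i] < sp$scope_end & tm$end[i] > sp$scope_start))
  }
  # markers are genuine trigger words
  texts <- co$notes$text[match(ng$note_id, co$notes$note_id)]
  markers <- normalize_surface(
    stringi::stri_sub(texts, ng$marker_start + 1L, ng$marker_end))
  expect_true(all(markers %in% union(negation_triggers("es"),
                                     negation_triggers("ca"))))
})

test_that("filler prose contains no lexicon surface", {
  co <- generate_cohort(sim_config(n_patients = 30L,
                                   p_depression_before = 0,
                                   p_depression_after = 0,
                                   negation_rate = 0, seed = 12L))
  lex <- fixture_lexicon()
  for (text in co$notes$text) {
    expect_identical(nrow(match_terms(text, NULL, lex, max_edits = 1L)), 0L)
  }
})

test_that("lexicon categories stay separable at the matcher's tolerance", {
  # a 1-edit perturbation of any surface must never be matchable to a
  # surface of the other category, or planted-category recall would break
  drug <- default_drug_lexicon()
  dis <- default_disorder_lexicon()
  for (a in drug$norm_surface) {
    for (b in dis$norm_surface) {
      expect_gte(osa_distance(a, b, cap = 3), 3L)
    }
  }
})

test_that("misspelling injection lands at edit distance exactly one", {
  set.seed(77)
  words <- c("citalopram", "depresion", "tristeza", "mirtazapina",
             "trastorno", "fluoxetina")
  for (i in 1:2000) {
    w <- sample(words, 1)
    out <- inject_misspelling(w)
    expect_false(identical(out, w))
    expect_identical(r_osa(w, out), 1L)
  }
  expect_warning(out <- inject_misspelling("no"), "short")
  expect_identical(out, "no")
})

test_that("after-only frequency matches the sampling scheme's binomial law", {
  # combined-channel after_only ~ Binomial(n, p_after * (1 - p_before))
  n <- 4000L
  co <- generate_cohort(sim_config(n_patients = n,
                                   p_depression_before = 0.02,
                                   p_depression_after = 0.15,
                                   visits_per_patient = c(4L, 5L),
                                   negation_rate = 0, seed = 4000L))
  p <- 0.15 * (1 - 0.02)
  observed <- sum(co$truth$classes$combined == "after_only")
  expect_lt(abs(observed - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("temporal classes partition the cohort on every channel", {
  co <- fixture_cohort()
  for (ch in c("icd", "drug", "disorder", "combined")) {
    expect_identical(sum(co$truth$summary[, ch]), nrow(co$patients))
  }
})

test_that("default negation corpus has the configured bilingual sizes", {
  corp <- fixture_corpus()
  all_lang <- c(vapply(corp$train, `[[`, character(1), "language"),
                vapply(corp$heldout, `[[`, character(1), "language"))
  expect_identical(sum(all_lang == "es"), 572L)
  expect_identical(sum(all_lang == "ca"), 277L)
  expect_error(
    emit_negation_corpus(fixture_cohort(), n_es = 100000L, n_ca = 0L),
    "too few")
})

test_that("corpus labels are valid BIO and O tokens lie outside scopes", {
  corp <- fixture_corpus()
  sentences <- c(corp$train[seq_len(100L)], corp$heldout[seq_len(50L)])
  for (s in sentences) {
    lab <- s$labels
    expect_true(all(lab %in% c("O", "B-MARK", "I-MARK", "B-SCOPE",
                               "I-SCOPE")))
    prev <- "O"
    for (l in lab) {
      if (startsWith(l, "I-")) {
        expect_true(prev %in% paste0(c("B-", "I-"), substring(l, 3)))
      }
      prev <- l
    }
  }
})

test_that("cohort serialization round-trips through disk formats", {
  co <- generate_cohort(sim_config(n_patients = 12L, seed = 55L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("patients.csv", "visits.csv", "notes.jsonl", "truth.json")))))
  back <- read_cohort(dir)
  expect_identical(as.data.frame(back$patients), as.data.frame(co$patients))
  expect_identical(as.data.frame(back$visits), as.data.frame(co$visits))
  expect_identical(back$notes$text, co$notes$text)
  expect_identical(as.data.frame(back$truth$classes),
                   as.data.frame(co$truth$classes))
})

test_that("render_note errors usefully and respects its plan", {
  plan <- tibble::tibble(surface = "citalopram", category = "drug_substance",
                         concept_id = "N06AB04", negated = FALSE,
                         misspelled = FALSE)
  set.seed(3)
  out <- render_note(plan, "es")
  expect_identical(
    stringi::stri_sub(out$text, out$mentions$start + 1L, out$mentions$end),
    "citalopram")
  set.seed(3)
  neg <- render_note(tibble::tibble(
    surface = "trastorno depresivo", category = "disorder_term",
    concept_id = "35489007", negated = TRUE, misspelled = FALSE), "es")
  expect_identical(nrow(neg$negations), 1L)
  expect_true(neg$mentions$start >= neg$negations$scope_start &
                neg$mentions$end <= neg$negations$scope_end)
})
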