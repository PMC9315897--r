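# Patient-level phenotyping: mine notes for mentions, apply the study
# selection filters, classify per-channel depression evidence relative to
# the cancer-diagnosis index date, and build the paired before/after
# tables.

#' Mine all notes of a cohort for lexicon mentions with negation flags
#'
#' For each note: identify the language, tokenize, find fuzzy lexicon
#' mentions, detect negation spans (CRF or rule baseline), and flag
#' mentions whose span lies inside a scope.
#'
#' @param notes tibble with `patient_id`, `visit_id`, `note_id`, `date`,
#'   `text` columns (e.g. `cohort$notes`); a stored `language` column is
#'   ignored -- language is always re-identified from the text.
#' @param lexicon a `tp_lexicon` (combine drug and disorder lexicons with
#'   [combine_lexicons()]).
#' @param max_edits fuzzy-matching tolerance, 0 or 1.
#' @param negation `"rule"`, `"crf"`, or `"none"`.
#' @param model `negation_tagger` for `negation = "crf"`.
#' @param window rule-baseline scope window.
#' @return tibble of mentions with note metadata, spans, concepts,
#'   `edit_distance`, detected `language`, and `negated` flag.
#' @export
mine_notes <- function(notes, lexicon, max_edits = 1L,
                       negation = c("rule", "crf", "none"), model = NULL,
                       window = 5L) {
  negation <- match.arg(negation)
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    text <- notes$text[i]
    lang <- detect_language(text)
    toks <- tokenize(text)
    men <- match_terms(text, toks, lexicon, max_edits = max_edits,
                       language = if (lang == "unknown") "both" else lang)
    if (nrow(men) == 0) next
    if (negation != "none") {
      spans <- note_negation_spans(text, lang, mode = negation,
                                   model = model, window = window)
      men$negated <- is_negated(men, spans)
    }
    out[[i]] <- cbind(
      tibble::tibble(patient_id = notes$patient_id[i],
                     visit_id = notes$visit_id[i],
                     note_id = notes$note_id[i],
                     date = rep(notes$date[i], nrow(men)),
                     language = lang),
      men)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble::tibble(
      patient_id = character(), visit_id = character(),
      note_id = character(), date = as.Date(character()),
      language = character(), start = integer(), end = integer(),
      surface = character(), category = character(),
      concept_id = character(), canonical = character(),
      edit_distance = integer(), negated = logical()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Apply the study's patient-selection criteria
#'
#' A patient is included iff, in this order of reasons: (1) exactly one
#' qualifying cancer (breast or colorectal) is recorded; (2) at least 2
#' visits strictly before and 2 on-or-after the diagnosis date; (3) stage
#' is in situ, I, II, or III (stage IV excluded); (4) treatment
#' information (the chemotherapy flag) is present.
#'
#' @param patients tibble with `patient_id`, `cancer_type`, `stage`,
#'   `chemotherapy`, `diagnosis_date` (and optionally `n_cancers`).
#' @param visits tibble with `patient_id`, `date`.
#' @return list with `included` (filtered patients tibble) and
#'   `exclusions` (tibble of `patient_id`, `reason` -- first failing rule).
#' @export
apply_selection_criteria <- function(patients, visits) {
  if (anyNA(patients$diagnosis_date)) {
    stop("patients without a diagnosis date: ",
         paste(patients$patient_id[is.na(patients$diagnosis_date)],
               collapse = ", "), call. = FALSE)
  }
  n_cancers <- if ("n_cancers" %in% names(patients)) patients$n_cancers
               else rep(1L, nrow(patients))
  reasons <- character(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    dx <- patients$diagnosis_date[i]
    vd <- visits$date[visits$patient_id == pid]
    if (n_cancers[i] != 1L ||
        !patients$cancer_type[i] %in% c("breast", "colorectal")) {
      reasons[i] <- "multiple_or_unqualifying_cancer"
    } else if (sum(vd < dx) < 2L || sum(vd >= dx) < 2L) {
      reasons[i] <- "insufficient_visits"
    } else if (!patients$stage[i] %in% c("in_situ", "I", "II", "III")) {
      reasons[i] <- "ineligible_stage"
    } else if (is.na(patients$chemotherapy[i])) {
      reasons[i] <- "incomplete_treatment_information"
    }
  }
  list(included = patients[reasons == "", , drop = FALSE],
       exclusions = tibble::tibble(
         patient_id = patients$patient_id[reasons != ""],
         reason = reasons[reasons != ""]))
}

#' Classify evidence dates relative to the index date
#'
#' @param event_dates dates of evidence events for one patient/channel.
#' @param index_date the cancer-diagnosis date.
#' @param index_day_counts_as which period an event dated exactly on the
#'   index date belongs to (default `"after"`).
#' @return one of `"none"`, `"before_only"`, `"after_only"`, `"both"`.
#' @export
classify_channel <- function(event_dates, index_date,
                             index_day_counts_as = c("after", "before")) {
  index_day_counts_as <- match.arg(index_day_counts_as)
  event_dates <- event_dates[!is.na(event_dates)]
  before <- if (index_day_counts_as == "after") {
    any(event_dates < index_date)
  } else {
    any(event_dates <= index_date)
  }
  after <- if (index_day_counts_as == "after") {
    any(event_dates >= index_date)
  } else {
    any(event_dates > index_date)
  }
  temporal_class(before, after)
}

#' Combine per-channel temporal classes into the COMBINED channel
#'
#' Union semantics: combined before-evidence is any channel's
#' before-evidence, likewise after.
#'
#' @param classes character vector of temporal classes (icd, drug,
#'   disorder for one patient).
#' @return the combined temporal class.
#' @export
combine_channels <- function(classes) {
  if (length(classes) == 0 || anyNA(classes) ||
      any(!classes %in% .temporal_classes)) {
    stop("need valid temporal classes for all channels", call. = FALSE)
  }
  before <- any(classes %in% c("before_only", "both"))
  after <- any(classes %in% c("after_only", "both"))
  temporal_class(before, after)
}

#' Classify all patients on all evidence channels
#'
#' Evidence events: ICD -- a visit bearing a depression code; DRUG -- a
#' non-negated antidepressant mention; DISORDER -- a non-negated
#' disorder-term mention. The COMBINED channel is the union.
#'
#' @param patients selected patients tibble (with `diagnosis_date`).
#' @param visits visits tibble with `icd_codes` (semicolon-joined).
#' @param mentions mined mentions from [mine_notes()] (negation-flagged).
#' @param codes depression `tp_codeset`
#'   (default [default_depression_codes()]).
#' @param index_day_counts_as tie rule for events on the diagnosis day.
#' @return tibble: `patient_id`, `channel`
#'   (icd/drug/disorder/combined), `temporal_class`.
#' @export
classify_cohort <- function(patients, visits, mentions,
                            codes = default_depression_codes(),
                            index_day_counts_as = "after") {
  # visit dates carrying at least one depression code
  vis_codes <- strsplit(visits$icd_codes, ";", fixed = TRUE)
  has_dep <- vapply(vis_codes, function(cd) {
    cd <- cd[nzchar(cd)]
    length(cd) > 0 && any(code_matches(cd, codes))
  }, logical(1))
  icd_events <- visits[has_dep, c("patient_id", "date")]

  active <- mentions[!mentions$negated, , drop = FALSE]
  drug_events <- active[active$category %in% c("drug_substance", "drug_brand"),
                        c("patient_id", "date")]
  dis_events <- active[active$category == "disorder_term",
                       c("patient_id", "date")]

  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    dx <- patients$diagnosis_date[i]
    cls <- c(
      icd = classify_channel(icd_events$date[icd_events$patient_id == pid],
                             dx, index_day_counts_as),
      drug = classify_channel(drug_events$date[drug_events$patient_id == pid],
                              dx, index_day_counts_as),
      disorder = classify_channel(
        dis_events$date[dis_events$patient_id == pid], dx,
        index_day_counts_as))
    tibble::tibble(patient_id = pid,
                   channel = c(names(cls), "combined"),
                   temporal_class = c(unname(cls), combine_channels(cls)))
  })
  do.call(rbind, rows)
}

#' Build the paired before/after table for one channel
#'
#' Patients with evidence both before and after the index date are
#' excluded; among the rest, `b` = before-only and `c` = after-only are
#' the discordant counts feeding McNemar's test.
#'
#' @param temporal_class character vector of temporal classes, one per
#'   patient.
#' @param patient_id optional ids, checked for duplicates.
#' @return a `paired_table` list: `n_total_considered`, `n_both_excluded`,
#'   `b`, `c`, `n_with`, `n_without`.
#' @export
build_paired_table <- function(temporal_class, patient_id = NULL) {
  if (!is.null(patient_id) && anyDuplicated(patient_id)) {
    stop("duplicate patient ids in classification", call. = FALSE)
  }
  if (any(!temporal_class %in% .temporal_classes)) {
    stop("invalid temporal classes", call. = FALSE)
  }
  n_both <- sum(temporal_class == "both")
  b <- sum(temporal_class == "before_only")
  cc <- sum(temporal_class == "after_only")
  n_total <- length(temporal_class) - n_both
  structure(list(
    n_total_considered = n_total, n_both_excluded = n_both,
    b = b, c = cc, n_with = b + cc, n_without = n_total - b - cc
  ), class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  cat("<paired before/after table>\n")
  cat("  considered:", x$n_total_considered,
      "(excluded 'both':", x$n_both_excluded, ")\n")
  cat("  before-only b =", x$b, "; after-only c =", x$c,
      "; with =", x$n_with, "; without =", x$n_without, "\n")
  invisible(x)
}

#' Split depression-positive patients by detection source
#'
#' Among patients with any depression evidence (any channel, any period),
#' `text_only` counts those with no ICD evidence at all -- the patients
#' found exclusively by mining clinical notes; `icd_detected` is the rest.
#'
#' @param icd_class,combined_class temporal-class vectors over the same
#'   patients (same order).
#' @return list with `icd_detected`, `text_only`, `n_positive`.
#' @export
attribution_split <- function(icd_class, combined_class) {
  if (length(icd_class) != length(combined_class)) {
    stop("classification vectors cover different patient sets",
         call. = FALSE)
  }
  positive <- combined_class != "none"
  text_only <- sum(positive & icd_class == "none")
  list(icd_detected = sum(positive) - text_only,
       text_only = text_only,
       n_positive = sum(positive))
}
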