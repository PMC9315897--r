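# Synthetic EHR cohort generator: patients, visits, bilingual clinical
# notes with planted (and ground-truthed) term mentions, negations and
# misspellings, plus an annotated negation corpus. Emulates the structure
# of a two-cancer (breast/colorectal) hospital cohort whose depression
# prevalence rises after the cancer-diagnosis index date.

# ---- note templates ---------------------------------------------------------
# Template-based prose so ground-truth spans and negation scopes are exact.
# Negated templates record their trigger word; `scope_to` is "eos" (scope
# runs to the end of the sentence) or "term" (scope stops before a
# conjunction such as "pero"/"però" and covers only the term).

.templates <- list(
  es = list(
    filler = c(
      "acude a control rutinario en consultas externas",
      "exploración física dentro de la normalidad",
      "se solicita analítica de control para la próxima visita",
      "pendiente de resultados de pruebas de imagen",
      "buena evolución clínica tras el alta",
      "la paciente acude acompañada a la visita de hoy"
    ),
    positive_drug = c(
      "en tratamiento con {T} desde hace meses",
      "se pauta {T} por indicación de psiquiatría",
      "buena tolerancia a {T} en la actualidad",
      "continúa con {T} a dosis habitual"
    ),
    positive_disorder = c(
      "la paciente presenta {T} en seguimiento",
      "diagnóstico de {T} confirmado en consulta",
      "refiere {T} desde hace meses",
      "clínica compatible con {T} en la actualidad"
    ),
    negated = list(
      list(text = "niega {T} en la actualidad",
           trigger = "niega", scope_to = "eos"),
      list(text = "no refiere {T} tras la intervención",
           trigger = "no", scope_to = "eos"),
      list(text = "sin {T} clínicamente evidente",
           trigger = "sin", scope_to = "eos"),
      list(text = "se descarta {T} de forma mantenida en los últimos meses",
           trigger = "descarta", scope_to = "eos"),
      list(text = "niega {T} pero refiere ansiedad",
           trigger = "niega", scope_to = "term")
    )
  ),
  ca = list(
    filler = c(
      "acudeix a control rutinari a consultes externes",
      "exploració física dins de la normalitat",
      "es demana analítica de control per a la propera visita",
      "pendent de resultats de proves d'imatge",
      "bona evolució clínica després de l'alta",
      "la pacient acudeix acompanyada a la visita d'avui"
    ),
    positive_drug = c(
      "en tractament amb {T} des de fa mesos",
      "es pauta {T} per indicació de psiquiatria",
      "bona tolerància a {T} actualment",
      "continua amb {T} a dosi habitual"
    ),
    positive_disorder = c(
      "la pacient presenta {T} en seguiment",
      "diagnòstic de {T} confirmat a consulta",
      "refereix {T} des de fa mesos",
      "clínica compatible amb {T} actualment"
    ),
    negated = list(
      list(text = "nega {T} actualment",
           trigger = "nega", scope_to = "eos"),
      list(text = "no refereix {T} després de la intervenció",
           trigger = "no", scope_to = "eos"),
      list(text = "sense {T} clínicament evident",
           trigger = "sense", scope_to = "eos"),
      list(text = "es descarta {T} de manera mantinguda en els últims mesos",
           trigger = "descarta", scope_to = "eos"),
      list(text = "nega {T} però refereix ansietat",
           trigger = "nega", scope_to = "term")
    )
  )
)

.background_icd <- c("401.9", "250.00", "272.4", "530.81", "715.90",
                     "786.2", "486", "599.0", "780.79", "414.01")
.depression_icd_pool <- c("311", "300.4", "296.20", "296.30", "309.0",
                          "309.1", "298.0")
.cancer_icd <- list(breast = "174.9", colorectal = c("153.9", "154.1"))

.stages <- c("in_situ", "I", "II", "III", "IV")
.channels <- c("icd", "drug", "disorder")
.temporal_classes <- c("none", "before_only", "after_only", "both")

# ---- configuration ----------------------------------------------------------

#' Simulation configuration for the synthetic cohort
#'
#' Defaults emulate the study conditions this package is built around:
#' a roughly even breast/colorectal mix, stage distribution concentrated in
#' stages I-III with a small stage-IV mass (so the selection filter is
#' exercised), patient-level depression probability much larger after the
#' index date than before, and per-channel evidence emission rates with the
#' ICD channel most frequent. See the methods vignette for the derivation
#' of every default.
#'
#' @param n_patients number of patients.
#' @param cancer_mix proportion of breast cancer (vs colorectal).
#' @param stage_probs named probability vector over
#'   `in_situ, I, II, III, IV`; must sum to 1.
#' @param p_depression_before,p_depression_after patient-level probability
#'   of depression evidence in the period before / on-or-after the index
#'   date (sampled independently).
#' @param channel_probs named probabilities that a depressed period emits
#'   evidence on the `icd`, `drug`, `disorder` channel; if no channel
#'   fires, one is forced (proportionally) so every depressed period is
#'   observable.
#' @param negation_rate probability that a note carries a negated decoy
#'   mention (never counted as evidence).
#' @param misspelling_rate probability that a planted term surface is
#'   perturbed by one edit.
#' @param visits_per_patient integer range `c(min, max)`, min >= 4.
#' @param language_mix proportion of Spanish notes (vs Catalan).
#' @param chemo_base named per-stage baseline chemotherapy probability.
#' @param chemo_depression_boost additive chemotherapy probability for
#'   patients with depression evidence after the index date (creates the
#'   chemotherapy-depression association).
#' @param seed integer seed; the whole cohort is a pure function of the
#'   config including this seed.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_patients = 500L,
                       cancer_mix = 0.48,
                       stage_probs = c(in_situ = 0.18, I = 0.27, II = 0.33,
                                       III = 0.19, IV = 0.03),
                       p_depression_before = 0.08,
                       p_depression_after = 0.28,
                       channel_probs = c(icd = 0.65, drug = 0.55,
                                         disorder = 0.35),
                       negation_rate = 0.10,
                       misspelling_rate = 0.10,
                       visits_per_patient = c(4L, 12L),
                       language_mix = 0.6,
                       chemo_base = c(in_situ = 0.10, I = 0.35, II = 0.60,
                                      III = 0.80, IV = 0.90),
                       chemo_depression_boost = 0.15,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), cancer_mix = cancer_mix,
              stage_probs = stage_probs,
              p_depression_before = p_depression_before,
              p_depression_after = p_depression_after,
              channel_probs = channel_probs, negation_rate = negation_rate,
              misspelling_rate = misspelling_rate,
              visits_per_patient = as.integer(visits_per_patient),
              language_mix = language_mix, chemo_base = chemo_base,
              chemo_depression_boost = chemo_depression_boost,
              seed = as.integer(seed))
  probs <- c(cfg$cancer_mix, cfg$p_depression_before, cfg$p_depression_after,
             cfg$channel_probs, cfg$negation_rate, cfg$misspelling_rate,
             cfg$language_mix, cfg$stage_probs, cfg$chemo_base)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(names(cfg$stage_probs), .stages) ||
      abs(sum(cfg$stage_probs) - 1) > 1e-9) {
    stop("stage_probs must be named over ", paste(.stages, collapse = ", "),
         " and sum to 1", call. = FALSE)
  }
  if (!identical(sort(names(cfg$channel_probs)), sort(.channels))) {
    stop("channel_probs must be named over icd, drug, disorder", call. = FALSE)
  }
  if (cfg$n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (length(cfg$visits_per_patient) != 2 ||
      cfg$visits_per_patient[1] < 4 ||
      cfg$visits_per_patient[2] < cfg$visits_per_patient[1]) {
    stop("visits_per_patient must be c(min, max) with min >= 4",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Perturb a word by one edit
#'
#' Applies one random substitution, deletion, insertion, or adjacent
#' transposition (lower-case letters only), guaranteeing the result differs
#' from the input, hence sits at restricted Damerau-Levenshtein distance
#' exactly 1. Words shorter than 4 characters are returned unchanged with a
#' warning.
#'
#' @param word a single word.
#' @return the perturbed word.
#' @export
inject_misspelling <- function(word) {
  stopifnot(length(word) == 1L)
  n <- stringi::stri_length(word)
  if (n < 4L) {
    warning("word too short to misspell: ", word, call. = FALSE)
    return(word)
  }
  letters_pool <- letters
  for (attempt in 1:20) {
    op <- sample(c("sub", "del", "ins", "swap"), 1L)
    out <- switch(op,
      sub = {
        i <- sample.int(n, 1L)
        repl <- sample(letters_pool, 1L)
        paste0(stringi::stri_sub(word, 1, i - 1), repl,
               stringi::stri_sub(word, i + 1, n))
      },
      del = {
        i <- sample.int(n, 1L)
        paste0(stringi::stri_sub(word, 1, i - 1),
               stringi::stri_sub(word, i + 1, n))
      },
      ins = {
        i <- sample.int(n + 1L, 1L)
        paste0(stringi::stri_sub(word, 1, i - 1), sample(letters_pool, 1L),
               stringi::stri_sub(word, i, n))
      },
      swap = {
        i <- sample.int(n - 1L, 1L)
        paste0(stringi::stri_sub(word, 1, i - 1),
               stringi::stri_sub(word, i + 1, i + 1),
               stringi::stri_sub(word, i, i),
               stringi::stri_sub(word, i + 2, n))
      })
    if (out != word) return(out)
  }
  word  # unreachable in practice
}

# Perturb one eligible word (>= 4 chars) of a possibly multi-word surface.
misspell_surface <- function(surface) {
  words <- strsplit(surface, " ", fixed = TRUE)[[1]]
  eligible <- which(stringi::stri_length(words) >= 4L)
  if (length(eligible) == 0) return(surface)
  i <- eligible[sample.int(length(eligible), 1L)]
  words[i] <- inject_misspelling(words[i])
  paste(words, collapse = " ")
}

# ---- note rendering ---------------------------------------------------------

#' Render one clinical note from a mention plan
#'
#' Builds note text from language-specific sentence templates: filler
#' sentences (which contain no lexicon surface and no negation trigger),
#' one sentence per planned mention. Negated mentions sit inside a scope
#' opened by a language-appropriate trigger. Returns exact character spans
#' for every planted surface and negation marker/scope.
#'
#' @param plan a data frame with one row per planted mention: columns
#'   `surface` (raw lexicon surface), `category`, `negated`, `misspelled`
#'   (logical).
#' @param language `"es"` or `"ca"`.
#' @param n_filler number of filler sentences (default drawn 1-3).
#' @return a list with `text`, `mentions` (tibble of 0-based spans,
#'   `surface` as planted, `category`, `negated`, `misspelled`), and
#'   `negations` (tibble of marker/scope spans).
#' @export
render_note <- function(plan, language, n_filler = NULL) {
  stopifnot(language %in% c("es", "ca"))
  tpl <- .templates[[language]]
  if (is.null(n_filler)) n_filler <- sample.int(3L, 1L)

  sent <- character(0)
  meta <- list()  # per planted sentence: rel spans
  if (nrow(plan) > 0) {
    for (r in seq_len(nrow(plan))) {
      surf <- plan$surface[r]
      if (isTRUE(plan$misspelled[r])) surf <- misspell_surface(surf)
      if (isTRUE(plan$negated[r])) {
        ng <- tpl$negated[[sample.int(length(tpl$negated), 1L)]]
        pieces <- strsplit(ng$text, "{T}", fixed = TRUE)[[1]]
        s <- paste0(pieces[1], surf, pieces[2])
        term_start <- stringi::stri_length(pieces[1])
        term_end <- term_start + stringi::stri_length(surf)
        mk <- stringi::stri_locate_first_regex(
          s, paste0("\\b", ng$trigger, "\\b"))
        marker_start <- mk[1, 1] - 1L
        marker_end <- mk[1, 2]
        scope_start <- marker_end + 1L  # skip the following space
        scope_end <- if (ng$scope_to == "eos") {
          stringi::stri_length(s)
        } else {
          term_end
        }
        neg <- c(marker_start, marker_end, scope_start, scope_end)
      } else {
        pool <- if (plan$category[r] %in% c("drug_substance", "drug_brand")) {
          tpl$positive_drug
        } else {
          tpl$positive_disorder
        }
        t0 <- pool[sample.int(length(pool), 1L)]
        pieces <- strsplit(t0, "{T}", fixed = TRUE)[[1]]
        s <- paste0(pieces[1], surf, pieces[2])
        term_start <- stringi::stri_length(pieces[1])
        term_end <- term_start + stringi::stri_length(surf)
        neg <- NULL
      }
      meta[[length(meta) + 1L]] <- list(
        sentence = s, term = c(term_start, term_end), planted = surf,
        row = r, negation = neg)
      sent <- c(sent, s)
    }
  }
  filler <- sample(tpl$filler, min(n_filler, length(tpl$filler)))
  all_sent <- c(sent, filler)
  ord <- sample.int(length(all_sent))
  all_sent <- all_sent[ord]

  # assemble text; sentence i starts at cumulative offset
  sep <- ". "
  lens <- stringi::stri_length(all_sent)
  starts <- cumsum(c(0L, utils::head(lens + nchar(sep), -1L)))
  text <- paste0(paste(all_sent, collapse = sep), ".")

  pos_of <- match(seq_along(sent), ord)  # where planted sentence i ended up
  mention_rows <- list()
  negation_rows <- list()
  for (i in seq_along(meta)) {
    off <- starts[pos_of[i]]
    m <- meta[[i]]
    r <- m$row
    mention_rows[[i]] <- tibble::tibble(
      start = off + m$term[1], end = off + m$term[2],
      surface = m$planted, category = plan$category[r],
      concept_id = if ("concept_id" %in% names(plan)) plan$concept_id[r]
                   else NA_character_,
      negated = isTRUE(plan$negated[r]),
      misspelled = isTRUE(plan$misspelled[r])
    )
    if (!is.null(m$negation)) {
      negation_rows[[length(negation_rows) + 1L]] <- tibble::tibble(
        marker_start = off + m$negation[1], marker_end = off + m$negation[2],
        scope_start = off + m$negation[3], scope_end = off + m$negation[4]
      )
    }
  }
  empty_m <- tibble::tibble(start = integer(), end = integer(),
                            surface = character(), category = character(),
                            concept_id = character(), negated = logical(),
                            misspelled = logical())
  empty_n <- tibble::tibble(marker_start = integer(), marker_end = integer(),
                            scope_start = integer(), scope_end = integer())
  list(
    text = text,
    mentions = if (length(mention_rows)) do.call(rbind, mention_rows)
               else empty_m,
    negations = if (length(negation_rows)) do.call(rbind, negation_rows)
                else empty_n
  )
}

# ---- cohort generation ------------------------------------------------------

sample_lexicon_entry <- function(lex, language, category_set) {
  pool <- which(lex$category %in% category_set &
                  lex$language %in% c(language, "both"))
  lex[pool[sample.int(length(pool), 1L)], ]
}

temporal_class <- function(before, after) {
  if (before && after) "both"
  else if (before) "before_only"
  else if (after) "after_only"
  else "none"
}

#' Generate a synthetic cohort with full ground truth
#'
#' A pure function of the configuration (including its seed): patients
#' with registry attributes, dated visits straddling the diagnosis date
#' (at least 2 strictly before and 2 on-or-after), one bilingual note per
#' visit, planted ICD codes and term mentions per evidence channel, negated
#' decoy mentions, and misspellings. The returned object carries the
#' planted truth needed to score every downstream stage.
#'
#' @param config a [sim_config()].
#' @param lexicon lexicon used for planting terms; defaults to the bundled
#'   drug + disorder lexicons combined.
#' @return a `synth_cohort` list: `patients`, `visits`, `notes` tibbles,
#'   `truth` (classes, mentions, negations, summary), and `config`.
#' @export
generate_cohort <- function(config = sim_config(), lexicon = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(lexicon)) {
    lexicon <- combine_lexicons(default_drug_lexicon(),
                                default_disorder_lexicon())
  }
  with_seed(config$seed, generate_cohort_impl(config, lexicon))
}

generate_cohort_impl <- function(cfg, lex) {
  n <- cfg$n_patients
  patients <- vector("list", n)
  visits <- vector("list", n)
  notes <- vector("list", n)
  truth_classes <- vector("list", n)
  truth_mentions <- list()
  truth_negations <- list()

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    breast <- runif(1) < cfg$cancer_mix
    ctype <- if (breast) "breast" else "colorectal"
    sex <- if (breast) "F" else if (runif(1) < 0.579) "M" else "F"
    stage <- sample(.stages, 1L, prob = cfg$stage_probs)
    age <- if (breast) rnorm(1, 62.3, 13.2) else rnorm(1, 70.5, 11.4)
    age <- as.integer(round(min(max(age, 25), 95)))
    dx_date <- as.Date("2005-01-01") + sample.int(4017L, 1L) - 1L

    dep_before <- runif(1) < cfg$p_depression_before
    dep_after <- runif(1) < cfg$p_depression_after
    p_chemo <- min(1, cfg$chemo_base[[stage]] +
                     if (dep_after) cfg$chemo_depression_boost else 0)
    chemo <- runif(1) < p_chemo

    nv_range <- seq(cfg$visits_per_patient[1], cfg$visits_per_patient[2])
    nv <- nv_range[sample.int(length(nv_range), 1L)]
    nb_range <- seq(2L, nv - 2L)
    n_before <- nb_range[sample.int(length(nb_range), 1L)]
    n_after <- nv - n_before
    d_before <- sort(dx_date - sample(1:1095, n_before))
    d_after <- sort(dx_date + sample(0:1095, n_after) )
    vdates <- c(d_before, d_after)
    vids <- sprintf("%s-V%02d", pid, seq_len(nv))
    is_after <- vdates >= dx_date

    # per-period channel emissions (forced non-empty for depressed periods)
    emit <- matrix(FALSE, nrow = 2, ncol = 3,
                   dimnames = list(c("before", "after"), .channels))
    for (p in 1:2) {
      depressed <- if (p == 1) dep_before else dep_after
      if (!depressed) next
      e <- runif(3) < cfg$channel_probs[.channels]
      if (!any(e)) {
        e[sample.int(3L, 1L, prob = cfg$channel_probs[.channels])] <- TRUE
      }
      emit[p, ] <- e
    }

    # visit ICD codes: background + cancer coding + planted depression codes
    vcodes <- lapply(seq_len(nv), function(v) {
      k <- sample(0:2, 1L)
      cds <- if (k > 0) sample(.background_icd, k) else character(0)
      if (is_after[v] && (v == which(is_after)[1] || runif(1) < 0.3)) {
        cds <- c(cds, sample(.cancer_icd[[ctype]], 1L))
      }
      cds
    })
    for (p in 1:2) {
      if (!emit[p, "icd"]) next
      pool <- which(is_after == (p == 2))
      v <- pool[sample.int(length(pool), 1L)]
      vcodes[[v]] <- c(vcodes[[v]], sample(.depression_icd_pool, 1L))
    }

    # per-note mention plans
    lang <- ifelse(runif(nv) < cfg$language_mix, "es", "ca")
    plans <- rep(list(NULL), nv)
    add_plan <- function(v, entry, negated) {
      misspell_ok <- stringi::stri_length(entry$norm_surface) >= 5L &&
        any(stringi::stri_length(
          strsplit(entry$surface, " ", fixed = TRUE)[[1]]) >= 4L)
      row <- tibble::tibble(
        surface = entry$surface, category = entry$category,
        concept_id = entry$concept_id, negated = negated,
        misspelled = misspell_ok && runif(1) < cfg$misspelling_rate)
      plans[[v]] <<- rbind(plans[[v]], row)
    }
    for (p in 1:2) {
      for (ch in c("drug", "disorder")) {
        if (!emit[p, ch]) next
        pool <- which(is_after == (p == 2))
        v <- pool[sample.int(length(pool), 1L)]
        cats <- if (ch == "drug") c("drug_substance", "drug_brand")
                else "disorder_term"
        add_plan(v, sample_lexicon_entry(lex, lang[v], cats), FALSE)
      }
    }
    for (v in seq_len(nv)) {  # negated decoys, independent of depression
      if (runif(1) < cfg$negation_rate) {
        add_plan(v, sample_lexicon_entry(
          lex, lang[v], c("drug_substance", "drug_brand", "disorder_term")),
          TRUE)
      }
    }

    nrows <- vector("list", nv)
    for (v in seq_len(nv)) {
      plan <- if (is.null(plans[[v]])) {
        tibble::tibble(surface = character(), category = character(),
                       concept_id = character(), negated = logical(),
                       misspelled = logical())
      } else {
        plans[[v]]
      }
      rendered <- render_note(plan, lang[v])
      nid <- paste0(vids[v], "-n1")
      nrows[[v]] <- tibble::tibble(
        patient_id = pid, visit_id = vids[v], note_id = nid,
        date = vdates[v], language = lang[v], text = rendered$text)
      if (nrow(rendered$mentions) > 0) {
        truth_mentions[[length(truth_mentions) + 1L]] <- cbind(
          tibble::tibble(patient_id = pid, visit_id = vids[v], note_id = nid,
                         date = rep(vdates[v], nrow(rendered$mentions))),
          rendered$mentions)
      }
      if (nrow(rendered$negations) > 0) {
        truth_negations[[length(truth_negations) + 1L]] <- cbind(
          tibble::tibble(patient_id = pid, visit_id = vids[v], note_id = nid),
          rendered$negations)
      }
    }

    patients[[i]] <- tibble::tibble(
      patient_id = pid, sex = sex, age = age, cancer_type = ctype,
      stage = stage, chemotherapy = chemo, diagnosis_date = dx_date)
    visits[[i]] <- tibble::tibble(
      patient_id = pid, visit_id = vids, date = vdates,
      icd_codes = vapply(vcodes, paste, character(1), collapse = ";"))
    notes[[i]] <- do.call(rbind, nrows)
    truth_classes[[i]] <- tibble::tibble(
      patient_id = pid,
      icd = temporal_class(emit["before", "icd"], emit["after", "icd"]),
      drug = temporal_class(emit["before", "drug"], emit["after", "drug"]),
      disorder = temporal_class(emit["before", "disorder"],
                                emit["after", "disorder"]),
      combined = temporal_class(dep_before, dep_after))
  }

  empty_m <- tibble::tibble(
    patient_id = character(), visit_id = character(), note_id = character(),
    date = as.Date(character()), start = integer(), end = integer(),
    surface = character(), category = character(), concept_id = character(),
    negated = logical(), misspelled = logical())
  empty_n <- tibble::tibble(
    patient_id = character(), visit_id = character(), note_id = character(),
    marker_start = integer(), marker_end = integer(),
    scope_start = integer(), scope_end = integer())
  classes <- do.call(rbind, truth_classes)
  summary_tab <- vapply(c(.channels, "combined"), function(ch) {
    table(factor(classes[[ch]], levels = .temporal_classes))
  }, integer(4))

  structure(list(
    patients = do.call(rbind, patients),
    visits = do.call(rbind, visits),
    notes = do.call(rbind, notes),
    truth = list(
      classes = classes,
      mentions = tibble::as_tibble(
        if (length(truth_mentions)) do.call(rbind, truth_mentions)
        else empty_m),
      negations = tibble::as_tibble(
        if (length(truth_negations)) do.call(rbind, truth_negations)
        else empty_n),
      summary = summary_tab),
    config = cfg), class = "synth_cohort")
}

#' Combine two lexicons into one matching vocabulary
#' @param ... `tp_lexicon` objects.
#' @return a `tp_lexicon`.
#' @export
combine_lexicons <- function(...) {
  new_lexicon(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synthetic cohort>", nrow(x$patients), "patients,",
      nrow(x$visits), "visits,", nrow(x$notes), "notes\n")
  cat("planted mentions:", nrow(x$truth$mentions),
      "(", sum(x$truth$mentions$negated), "negated,",
      sum(x$truth$mentions$misspelled), "misspelled )\n")
  cat("combined temporal classes:\n")
  print(x$truth$summary[, "combined"])
  invisible(x)
}

# ---- cohort serialization ---------------------------------------------------

#' Write a cohort to disk
#'
#' Writes `patients.csv`, `visits.csv` (semicolon-joined ICD codes),
#' `notes.jsonl` (one JSON object per note), and `truth.json`.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$patients
  p$diagnosis_date <- as.character(p$diagnosis_date)
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE)
  v <- cohort$visits
  v$date <- as.character(v$date)
  utils::write.csv(v, file.path(dir, "visits.csv"), row.names = FALSE)
  con <- file(file.path(dir, "notes.jsonl"), open = "w", encoding = "UTF-8")
  nt <- cohort$notes
  for (i in seq_len(nrow(nt))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = nt$patient_id[i], visit_id = nt$visit_id[i],
      note_id = nt$note_id[i], date = as.character(nt$date[i]),
      language = nt$language[i], text = nt$text[i]), auto_unbox = TRUE), con)
  }
  close(con)
  truth <- cohort$truth
  truth$mentions$date <- as.character(truth$mentions$date)
  truth$summary <- as.data.frame.matrix(truth$summary)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing the cohort files.
#' @return a `synth_cohort` (config slot is `NULL`; truth present only if
#'   `truth.json` exists).
#' @export
read_cohort <- function(dir) {
  p <- tibble::as_tibble(utils::read.csv(file.path(dir, "patients.csv"),
                                         colClasses = "character"))
  p$age <- as.integer(p$age)
  p$chemotherapy <- as.logical(p$chemotherapy)
  p$diagnosis_date <- as.Date(p$diagnosis_date)
  v <- tibble::as_tibble(utils::read.csv(file.path(dir, "visits.csv"),
                                         colClasses = "character"))
  v$date <- as.Date(v$date)
  lines <- readLines(file.path(dir, "notes.jsonl"), encoding = "UTF-8")
  nt <- do.call(rbind, lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble::tibble(patient_id = x$patient_id, visit_id = x$visit_id,
                   note_id = x$note_id, date = as.Date(x$date),
                   language = x$language, text = x$text)
  }))
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tr <- jsonlite::fromJSON(tp)
    truth <- list(
      classes = tibble::as_tibble(tr$classes),
      mentions = {
        m <- tibble::as_tibble(tr$mentions)
        if (nrow(m) > 0) m$date <- as.Date(m$date)
        m
      },
      negations = tibble::as_tibble(tr$negations),
      summary = as.matrix(tr$summary))
  }
  structure(list(patients = p, visits = v, notes = nt, truth = truth,
                 config = NULL), class = "synth_cohort")
}
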