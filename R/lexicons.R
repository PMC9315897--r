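# Term lexicons and ICD-9-CM code sets used as detection vocabularies.
#
# A lexicon is a tibble with class "tp_lexicon" and columns:
#   surface, norm_surface, language (es/ca/both),
#   category (drug_substance/drug_brand/disorder_term),
#   concept_id, canonical.
# Matching always runs on norm_surface; raw surfaces are kept for reporting.

.lexicon_categories <- c("drug_substance", "drug_brand", "disorder_term")
.lexicon_languages <- c("es", "ca", "both")

#' Normalize a term or note surface for matching
#'
#' Lower-cases, folds Spanish/Catalan diacritics to ASCII base letters,
#' removes the Catalan middle dot, and collapses internal whitespace. The
#' transform is idempotent, so lexicon surfaces and note windows can be
#' compared directly.
#'
#' @param text character vector, each element non-empty.
#' @param language language tag ("es", "ca", or "both"); currently the
#'   folding rules are shared, the argument documents intent and keeps the
#'   interface stable.
#' @return character vector of normalized strings.
#' @examples
#' normalize_surface("Citalopram ")
#' normalize_surface("depresión")
#' @export
normalize_surface <- function(text, language = "both") {
  if (length(text) == 0) stop("`text` must be non-empty", call. = FALSE)
  text <- as.character(text)
  if (anyNA(text) || any(!nzchar(trimws(text)))) {
    stop("`text` must not contain empty or missing strings", call. = FALSE)
  }
  x <- stringi::stri_trans_tolower(text)
  x <- chartr(.diacritic_from, .diacritic_to, x)
  x <- gsub("·", "", x, fixed = TRUE)  # col·lateral -> collateral
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

new_lexicon <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("tp_lexicon", class(df))
  validate_lexicon(df)
}

validate_lexicon <- function(lex) {
  required <- c("surface", "norm_surface", "language", "category",
                "concept_id", "canonical")
  missing <- setdiff(required, names(lex))
  if (length(missing) > 0) {
    stop("lexicon is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(lex) == 0) return(lex)
  if (any(!nzchar(trimws(lex$surface)))) {
    stop("lexicon surfaces must be non-empty", call. = FALSE)
  }
  if (any(!lex$language %in% .lexicon_languages)) {
    stop("lexicon language must be one of: ",
         paste(.lexicon_languages, collapse = ", "), call. = FALSE)
  }
  if (any(!lex$category %in% .lexicon_categories)) {
    stop("lexicon category must be one of: ",
         paste(.lexicon_categories, collapse = ", "), call. = FALSE)
  }
  key <- paste(lex$norm_surface, lex$category)
  if (anyDuplicated(key)) {
    stop("duplicate (normalized surface, category) pairs in lexicon",
         call. = FALSE)
  }
  # every brand must resolve to exactly one substance concept
  brands <- lex[lex$category == "drug_brand", ]
  if (nrow(brands) > 0) {
    substance_ids <- unique(lex$concept_id[lex$category == "drug_substance"])
    orphan <- !brands$concept_id %in% substance_ids
    if (any(orphan)) {
      stop("drug_brand entries without a matching drug_substance concept: ",
           paste(unique(brands$surface[orphan]), collapse = ", "),
           call. = FALSE)
    }
  }
  lex
}

#' Load a term lexicon from a TSV file
#'
#' Expected dialect: UTF-8, header row, `#` comment lines, columns
#' `surface`, `language`, `category`, `concept_id`, `canonical`.
#' Surfaces are normalized with [normalize_surface()]; duplicate
#' (normalized surface, category) rows are collapsed with a warning.
#'
#' @param path path to the TSV file.
#' @param category_filter optional category to keep
#'   ("drug_substance", "drug_brand", "disorder_term").
#' @return a `tp_lexicon` tibble.
#' @seealso [default_drug_lexicon()], [default_disorder_lexicon()]
#' @export
load_lexicon <- function(path, category_filter = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  raw <- read_lines_nocomment(path)
  if (length(raw) == 0) {
    warning("empty lexicon file: ", path, call. = FALSE)
    return(new_lexicon(tibble::tibble(
      surface = character(), norm_surface = character(),
      language = character(), category = character(),
      concept_id = character(), canonical = character()
    )))
  }
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  expected <- c("surface", "language", "category", "concept_id", "canonical")
  if (!identical(header, expected)) {
    stop("lexicon header must be: ", paste(expected, collapse = "\t"),
         call. = FALSE)
  }
  rows <- strsplit(raw[-1], "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) != 5L)
  if (length(bad) > 0) {
    stop("malformed lexicon row (expected 5 tab-separated fields) at data line ",
         bad[1], " of ", path, call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- expected
  df <- tibble::as_tibble(df)
  if (!is.null(category_filter)) {
    category_filter <- match.arg(category_filter, .lexicon_categories)
    keep_subst <- category_filter == "drug_brand" &
      df$category == "drug_substance"  # brands need their substances to validate
    df <- df[df$category == category_filter | keep_subst, ]
  }
  df$norm_surface <- normalize_surface(df$surface)
  key <- paste(df$norm_surface, df$category)
  if (anyDuplicated(key)) {
    warning("collapsing ", sum(duplicated(key)),
            " duplicate (normalized surface, category) entries in ", path,
            call. = FALSE)
    df <- df[!duplicated(key), ]
  }
  new_lexicon(df[, c("surface", "norm_surface", "language", "category",
                     "concept_id", "canonical")])
}

#' Write a lexicon back to its TSV dialect
#'
#' Inverse of [load_lexicon()]: the raw surfaces and metadata round-trip;
#' normalized surfaces are recomputed on load.
#'
#' @param lexicon a `tp_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "tp_lexicon"))
  df <- as.data.frame(lexicon)[, c("surface", "language", "category",
                                   "concept_id", "canonical")]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Bundled antidepressant lexicon (synthetic stand-in)
#'
#' Thirty-five active substances with ATC-style concept ids and 82 brand
#' names marketed-in-Spain style. The brand list mixes real and invented
#' names and is a synthetic stand-in for a proprietary drug dictionary;
#' replace it with [load_lexicon()] on your own file for real analyses.
#' @return a `tp_lexicon`.
#' @export
default_drug_lexicon <- function() {
  load_lexicon(tp_extdata("lexicon_antidepressants_synthetic.tsv"))
}

#' Bundled depressive-disorder term lexicon (synthetic stand-in)
#'
#' A representative bilingual (Spanish/Catalan) set of surface forms for
#' concepts under the SNOMED CT "trastorno depresivo" hierarchy. It is a
#' small synthetic stand-in, not the full 139-concept terminology; the
#' pipeline is lexicon-agnostic and accepts any file in the documented TSV
#' dialect.
#' @return a `tp_lexicon`.
#' @export
default_disorder_lexicon <- function() {
  load_lexicon(tp_extdata("lexicon_disorder_terms_synthetic.tsv"))
}

#' @export
print.tp_lexicon <- function(x, ...) {
  cat("<lexicon>", nrow(x), "entries;",
      length(unique(x$concept_id)), "concepts\n")
  tab <- table(x$category)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  NextMethod()
}

# ---- ICD-9-CM code sets -----------------------------------------------------

.icd9_pattern <- "^[0-9]{3}(\\.[0-9]{1,2})?$"

#' Construct an ICD-9-CM code set
#'
#' Members may be full codes ("300.4") or 3-digit hierarchical prefixes
#' ("311"), which match all their subcodes.
#'
#' @param codes character vector of codes/prefixes.
#' @param label short description.
#' @return an object of class `tp_codeset`.
#' @export
code_set <- function(codes, label = "") {
  codes <- trimws(as.character(codes))
  bad <- !grepl(.icd9_pattern, codes)
  if (any(bad)) {
    stop("invalid ICD-9-CM codes: ", paste(codes[bad], collapse = ", "),
         call. = FALSE)
  }
  structure(list(codes = sort(unique(codes)), label = label),
            class = "tp_codeset")
}

#' Read a code set from a plain-text file (one code per line, # comments)
#' @param path file path.
#' @param label label for the set; defaults to the file name.
#' @return a `tp_codeset`.
#' @export
load_code_set <- function(path, label = basename(path)) {
  code_set(read_lines_nocomment(path), label = label)
}

#' Default depressive-disorder ICD-9-CM code set
#'
#' Configurable stand-in covering the major depressive episode, dysthymia,
#' adjustment-reaction, and depression NOS families:
#' 296.2, 296.3, 298.0, 300.4, 309.0, 309.1, 311.
#' @return a `tp_codeset`.
#' @export
default_depression_codes <- function() {
  load_code_set(tp_extdata("icd9_depression_codes.txt"),
                label = "depressive disorders (ICD-9-CM)")
}

#' Test whether an ICD-9-CM code belongs to a code set
#'
#' A code matches if it equals a member or extends a member prefix
#' (e.g. "174.9" matches the prefix "174"). Matching is closed under prefix
#' refinement by construction.
#'
#' @param code character vector of syntactically valid ICD-9-CM codes.
#' @param set a `tp_codeset`.
#' @return logical vector.
#' @examples
#' code_matches("174.9", code_set("174"))
#' @export
code_matches <- function(code, set) {
  stopifnot(inherits(set, "tp_codeset"))
  code <- trimws(as.character(code))
  bad <- !grepl(.icd9_pattern, code)
  if (any(bad)) {
    stop("invalid ICD-9-CM codes: ", paste(code[bad], collapse = ", "),
         call. = FALSE)
  }
  vapply(code, function(cd) {
    any(vapply(set$codes, function(m) {
      if (cd == m) return(TRUE)
      if (!startsWith(cd, m)) return(FALSE)
      # "174" extends to "174.9"; "296.2" extends to "296.25"
      nxt <- substr(cd, nchar(m) + 1L, nchar(m) + 1L)
      if (nchar(m) == 3L) nxt == "." else TRUE
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
print.tp_codeset <- function(x, ...) {
  cat("<ICD-9-CM code set>", x$label, "\n  ",
      paste(x$codes, collapse = ", "), "\n")
  invisible(x)
}
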