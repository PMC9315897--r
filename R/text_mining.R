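# Note-level NLP: language identification, tokenization, and
# misspelling-tolerant dictionary matching with character offsets.
#
# All offsets are 0-based, half-open [start, end) character positions into
# the original note text, so `substr(text, start + 1, end)` recovers the
# surface.

.lang_profiles <- new.env(parent = emptyenv())

lang_profile <- function(language) {
  if (is.null(.lang_profiles[[language]])) {
    .lang_profiles[[language]] <-
      read_lines_nocomment(tp_extdata(paste0("langprofile_", language, ".txt")))
  }
  .lang_profiles[[language]]
}

#' Identify the language of a clinical note
#'
#' Compares counts of language-discriminative function/clinical words
#' (two fixed profile lists shipped with the package) over the normalized
#' tokens of the note. Returns `"unknown"` when the evidence margin is
#' below `margin`.
#'
#' @param text character vector of note texts.
#' @param margin minimum difference in discriminative-word hits required to
#'   decide (default 1).
#' @return character vector over `{"es", "ca", "unknown"}`.
#' @examples
#' detect_language("la paciente no presenta síntomas")
#' detect_language("la pacient no presenta símptomes")
#' @export
detect_language <- function(text, margin = 1L) {
  es <- lang_profile("es")
  ca <- lang_profile("ca")
  vapply(as.character(text), function(tx) {
    if (is.na(tx) || !nzchar(trimws(tx))) return("unknown")
    words <- stringi::stri_extract_all_regex(
      normalize_surface(tx), "[\\p{L}\\p{N}]+")[[1]]
    if (length(words) == 0 || all(is.na(words))) return("unknown")
    es_score <- sum(words %in% es)
    ca_score <- sum(words %in% ca)
    if (es_score - ca_score >= margin) "es"
    else if (ca_score - es_score >= margin) "ca"
    else "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize note text
#'
#' Splits on whitespace; punctuation characters become single-character
#' tokens. Offsets are 0-based half-open into the original text, and the
#' token surfaces plus inter-token gaps reassemble the text exactly.
#'
#' @param text a single note string.
#' @param language language tag (kept for interface symmetry; tokenization
#'   rules are shared between Spanish and Catalan).
#' @return a tibble with columns `surface`, `start`, `end`, `normalized`,
#'   `is_word`.
#' @export
tokenize <- function(text, language = "both") {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(surface = character(), start = integer(),
                          end = integer(), normalized = character(),
                          is_word = logical()))
  }
  loc <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}]+|[^\\s\\p{L}\\p{N}]")[[1]]
  if (nrow(loc) == 0 || anyNA(loc[1, ])) {
    return(tibble::tibble(surface = character(), start = integer(),
                          end = integer(), normalized = character(),
                          is_word = logical()))
  }
  surface <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  tibble::tibble(
    surface = surface,
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2]),
    normalized = normalize_surface(surface),
    is_word = stringi::stri_detect_regex(surface, "^[\\p{L}\\p{N}]")
  )
}

# Split note text into sentence character ranges at '.', ';' and newline.
# Returns 0-based half-open [start, end) ranges covering the sentence text
# without its terminator.
sentence_ranges <- function(text) {
  stopifnot(length(text) == 1L)
  n <- stringi::stri_length(text)
  if (is.na(text) || n == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  brk <- c(0L, stringi::stri_locate_all_regex(text, "[.;\n]")[[1]][, 1], n + 1L)
  brk <- brk[!is.na(brk)]
  starts <- utils::head(brk, -1L)          # 0-based start of each segment
  ends <- brk[-1] - 1L                     # 0-based end (exclusive)
  keep <- ends > starts
  tibble::tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Find misspelling-tolerant lexicon mentions in a note
#'
#' Every window of k consecutive tokens (k = token count of a lexicon
#' surface) whose space-joined normalized form is within restricted
#' Damerau-Levenshtein distance `max_edits` of that surface yields a
#' candidate mention. Surfaces with fewer than `min_fuzzy_nchar` normalized
#' characters must match exactly. Overlapping candidates are resolved by
#' longest span, then smallest edit distance, then leftmost position (then
#' lexicon order, for full determinism); survivors are returned in
#' left-to-right span order.
#'
#' @param text the note text.
#' @param tokens its tokenization from [tokenize()]; pass `NULL` to
#'   tokenize internally.
#' @param lexicon a `tp_lexicon`.
#' @param max_edits 0 or 1 (default 1).
#' @param min_fuzzy_nchar surfaces shorter than this require an exact match
#'   (default 5).
#' @param language restrict matching to lexicon entries usable in this
#'   language (`"es"`, `"ca"`, or `"both"` for no restriction).
#' @return a tibble of mentions: `start`, `end`, `surface`, `category`,
#'   `concept_id`, `canonical`, `edit_distance`, `negated` (initialized
#'   `FALSE`; set by the negation module).
#' @export
match_terms <- function(text, tokens = NULL, lexicon, max_edits = 1L,
                        min_fuzzy_nchar = 5L, language = "both") {
  stopifnot(max_edits %in% c(0L, 1L))
  if (!inherits(lexicon, "tp_lexicon")) {
    stop("`lexicon` must be a tp_lexicon (see load_lexicon())", call. = FALSE)
  }
  if (!"norm_surface" %in% names(lexicon) ||
      (nrow(lexicon) > 0 &&
       !identical(lexicon$norm_surface, normalize_surface(lexicon$surface)))) {
    stop("lexicon is not normalized; load it with load_lexicon()",
         call. = FALSE)
  }
  if (is.null(tokens)) tokens <- tokenize(text)

  empty <- tibble::tibble(
    start = integer(), end = integer(), surface = character(),
    category = character(), concept_id = character(),
    canonical = character(), edit_distance = integer(), negated = logical()
  )
  if (nrow(tokens) == 0 || nrow(lexicon) == 0) return(empty)

  lex <- lexicon
  if (language %in% c("es", "ca")) {
    lex <- lex[lex$language %in% c(language, "both"), ]
  }
  if (nrow(lex) == 0) return(empty)
  lex_k <- lengths(strsplit(lex$norm_surface, " ", fixed = TRUE))

  cands <- list()
  for (k in sort(unique(lex_k))) {
    if (nrow(tokens) < k) next
    n_win <- nrow(tokens) - k + 1L
    first <- seq_len(n_win)
    last <- first + k - 1L
    joined <- vapply(first, function(i) {
      paste(tokens$normalized[i:(i + k - 1L)], collapse = " ")
    }, character(1))
    sub <- which(lex_k == k)
    hits <- fuzzy_pairs_cpp(joined, lex$norm_surface[sub],
                            as.integer(max_edits), as.integer(min_fuzzy_nchar))
    if (nrow(hits) == 0) next
    li <- sub[hits$surf_idx]
    cands[[length(cands) + 1L]] <- tibble::tibble(
      start = tokens$start[first[hits$cand_idx]],
      end = tokens$end[last[hits$cand_idx]],
      lex_row = li,
      edit_distance = hits$dist
    )
  }
  if (length(cands) == 0) return(empty)
  cand <- do.call(rbind, cands)

  # overlap resolution: longest span, then smallest distance, then leftmost,
  # then lexicon order
  span <- cand$end - cand$start
  ord <- order(-span, cand$edit_distance, cand$start, cand$lex_row)
  cand <- cand[ord, ]
  keep <- logical(nrow(cand))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(cand$start[i] < taken_end & cand$end[i] > taken_start)
    if (!overlaps) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$start, cand$end), ]

  tibble::tibble(
    start = as.integer(cand$start),
    end = as.integer(cand$end),
    surface = stringi::stri_sub(text, cand$start + 1L, cand$end),
    category = lex$category[cand$lex_row],
    concept_id = lex$concept_id[cand$lex_row],
    canonical = lex$canonical[cand$lex_row],
    edit_distance = as.integer(cand$edit_distance),
    negated = FALSE
  )
}
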