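# Building, sampling, and serializing the annotated negation corpus
# (token-level BIO labels for markers and scopes) from a synthetic cohort.

new_negation_corpus <- function(sentences) {
  structure(sentences, class = "negation_corpus")
}

#' @export
print.negation_corpus <- function(x, ...) {
  langs <- table(vapply(x, `[[`, character(1), "language"))
  n_neg <- sum(vapply(x, function(s) any(s$labels != "O"), logical(1)))
  cat("<negation corpus>", length(x), "sentences (",
      paste(names(langs), langs, collapse = ", "), ");",
      n_neg, "with negation\n")
  invisible(x)
}

#' @export
`[.negation_corpus` <- function(x, i) {
  new_negation_corpus(unclass(x)[i])
}

# All sentences of a cohort with BIO labels derived from planted truth.
cohort_sentences <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"), !is.null(cohort$truth))
  neg <- cohort$truth$negations
  out <- list()
  for (i in seq_len(nrow(cohort$notes))) {
    text <- cohort$notes$text[i]
    nid <- cohort$notes$note_id[i]
    lang <- cohort$notes$language[i]
    nn <- neg[neg$note_id == nid, , drop = FALSE]
    sr <- sentence_ranges(text)
    for (s in seq_len(nrow(sr))) {
      sub <- stringi::stri_sub(text, sr$start[s] + 1L, sr$end[s])
      toks <- tokenize(sub)
      if (nrow(toks) == 0) next
      inside <- nn[nn$scope_start >= sr$start[s] &
                     nn$scope_end <= sr$end[s], , drop = FALSE]
      spans <- tibble::tibble(
        marker_start = inside$marker_start - sr$start[s],
        marker_end = inside$marker_end - sr$start[s],
        scope_start = inside$scope_start - sr$start[s],
        scope_end = inside$scope_end - sr$start[s])
      out[[length(out) + 1L]] <- list(
        tokens = toks, labels = spans_to_bio(toks, spans),
        language = lang, note_id = nid)
    }
  }
  new_negation_corpus(out)
}

#' Emit an annotated negation corpus from a synthetic cohort
#'
#' Draws sentences (with token-level BIO negation labels derived from the
#' planted ground truth) from the cohort's notes, stratified per language,
#' and splits them into training and held-out parts. Defaults mirror a
#' 572 Spanish / 277 Catalan corpus of 949 sentences. Negation-bearing
#' sentences are over-sampled up to half of each language quota so the
#' tagger sees enough positive structure.
#'
#' @param cohort a `synth_cohort` generated with `negation_rate > 0`.
#' @param n_es,n_ca sentences per language (defaults 572 / 277).
#' @param heldout_frac fraction held out for evaluation (default 0.25,
#'   stratified by language and negation presence).
#' @param seed sampling seed.
#' @return list with `train` and `heldout` `negation_corpus` objects.
#' @export
emit_negation_corpus <- function(cohort, n_es = 572L, n_ca = 277L,
                                 heldout_frac = 0.25, seed = 1L) {
  all_sent <- cohort_sentences(cohort)
  langs <- vapply(all_sent, `[[`, character(1), "language")
  has_neg <- vapply(all_sent, function(s) any(s$labels != "O"), logical(1))
  quota <- c(es = as.integer(n_es), ca = as.integer(n_ca))

  with_seed(seed, {
    chosen <- integer(0)
    for (lg in names(quota)) {
      q <- quota[[lg]]
      if (q == 0L) next
      idx_neg <- which(langs == lg & has_neg)
      idx_plain <- which(langs == lg & !has_neg)
      n_neg <- min(length(idx_neg), ceiling(q / 2))
      n_plain <- q - n_neg
      if (n_plain > length(idx_plain)) {
        stop("cohort has too few ", lg, " sentences for the requested ",
             "corpus size (", q, " requested)", call. = FALSE)
      }
      chosen <- c(chosen,
                  idx_neg[sample.int(length(idx_neg), n_neg)],
                  idx_plain[sample.int(length(idx_plain), n_plain)])
    }
    chosen <- chosen[sample.int(length(chosen))]
    sel <- all_sent[chosen]
    sel_lang <- langs[chosen]
    sel_neg <- has_neg[chosen]

    heldout_idx <- integer(0)
    for (lg in unique(sel_lang)) {
      for (ng in c(TRUE, FALSE)) {
        stratum <- which(sel_lang == lg & sel_neg == ng)
        k <- floor(length(stratum) * heldout_frac)
        if (k > 0) {
          heldout_idx <- c(heldout_idx,
                           stratum[sample.int(length(stratum), k)])
        }
      }
    }
    list(train = sel[setdiff(seq_along(sel), heldout_idx)],
         heldout = sel[sort(heldout_idx)])
  })
}

# ---- CoNLL-style TSV interface ---------------------------------------------

#' Write a negation corpus in CoNLL-style TSV
#'
#' One `token<TAB>label` line per token, a blank line between sentences,
#' and a `# language = xx` comment line before each sentence.
#'
#' @param corpus a `negation_corpus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  stopifnot(inherits(corpus, "negation_corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus) {
    writeLines(paste("# language =", s$language), con)
    writeLines(paste(s$tokens$surface, s$labels, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a CoNLL-style TSV negation corpus
#'
#' Inverse of [write_conll()]. Token offsets are reconstructed by joining
#' surfaces with single spaces (the original note offsets are not stored in
#' this format); that is sufficient for training and evaluation.
#'
#' @param path input file.
#' @param default_language language for sentences without a comment header.
#' @return a `negation_corpus`.
#' @export
read_conll <- function(path, default_language = "es") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  cur_tok <- character(0)
  cur_lab <- character(0)
  cur_lang <- default_language
  flush <- function() {
    if (length(cur_tok) > 0) {
      ends <- cumsum(stringi::stri_length(cur_tok) + 1L)
      toks <- tibble::tibble(
        surface = cur_tok,
        start = as.integer(c(0L, utils::head(ends, -1L))),
        end = as.integer(ends - 1L),
        normalized = normalize_surface(cur_tok),
        is_word = stringi::stri_detect_regex(cur_tok, "^[\\p{L}\\p{N}]"))
      sentences[[length(sentences) + 1L]] <<- list(
        tokens = toks, labels = cur_lab, language = cur_lang)
    }
    cur_tok <<- character(0)
    cur_lab <<- character(0)
    cur_lang <<- default_language
  }
  for (ln in lines) {
    if (grepl("^#", ln)) {
      m <- regmatches(ln, regexec("language\\s*=\\s*(\\w+)", ln))[[1]]
      if (length(m) == 2) cur_lang <- m[2]
    } else if (!nzchar(trimws(ln))) {
      flush()
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("malformed CoNLL line: ", ln, call. = FALSE)
      }
      cur_tok <- c(cur_tok, parts[1])
      cur_lab <- c(cur_lab, parts[2])
    }
  }
  flush()
  new_negation_corpus(sentences)
}
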