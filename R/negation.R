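# Negation-marker and negation-scope detection for Spanish/Catalan
# clinical text: a linear-chain CRF token tagger over BIO labels
# {O, B-MARK, I-MARK, B-SCOPE, I-SCOPE}, plus a NegEx-style rule baseline.
# Mentions whose span overlaps a detected scope are excluded from
# phenotype evidence.

.neg_labels <- c("O", "B-MARK", "I-MARK", "B-SCOPE", "I-SCOPE")
.neg_terminators <- c("pero", "aunque", "sino", ",")
.feature_version <- "orthographic-trigger-v1"

.trigger_cache <- new.env(parent = emptyenv())

#' Negation trigger words for a language
#' @param language `"es"` or `"ca"`.
#' @return character vector of normalized trigger words.
#' @export
negation_triggers <- function(language) {
  language <- match.arg(language, c("es", "ca"))
  if (is.null(.trigger_cache[[language]])) {
    .trigger_cache[[language]] <- read_lines_nocomment(
      tp_extdata(paste0("negation_triggers_", language, ".txt")))
  }
  .trigger_cache[[language]]
}

word_shape <- function(x) {
  s <- stringi::stri_replace_all_regex(x, "\\p{L}", "x")
  s <- stringi::stri_replace_all_regex(s, "\\p{N}", "d")
  s <- stringi::stri_replace_all_regex(s, "[^xd]", "p")
  gsub("(.)\\1+", "\\1", s)
}

#' Orthographic + trigger-lexicon features for one token position
#'
#' Deterministic features over a -2..+2 token window: lower-cased surface,
#' word shape, 3-character prefix/suffix, trigger-list membership,
#' punctuation and digit flags, and begin/end-of-sentence markers.
#'
#' @param tokens a sentence tokenization from [tokenize()].
#' @param index 1-based token position; `NULL` returns the feature vectors
#'   for all positions as a list.
#' @param language `"es"` or `"ca"` (selects the trigger list).
#' @return a character vector of feature strings (or a list of them).
#' @export
featurize <- function(tokens, index = NULL, language = "es") {
  trig <- negation_triggers(language)
  n <- nrow(tokens)
  norm <- tokens$normalized
  shp <- word_shape(norm)
  pre <- stringi::stri_sub(norm, 1, 3)
  suf <- stringi::stri_sub(norm, pmax(1L, stringi::stri_length(norm) - 2L),
                           stringi::stri_length(norm))
  is_trig <- norm %in% trig
  is_punct <- !tokens$is_word
  is_digit <- stringi::stri_detect_regex(norm, "^\\p{N}+$")

  one <- function(i) {
    out <- "b"
    for (d in -2:2) {
      j <- i + d
      tag <- sprintf("%+d", d)
      if (j < 1L) {
        out <- c(out, paste0("bos", tag))
      } else if (j > n) {
        out <- c(out, paste0("eos", tag))
      } else {
        out <- c(out,
                 paste0("w", tag, "=", norm[j]),
                 paste0("sh", tag, "=", shp[j]),
                 paste0("p", tag, "=", pre[j]),
                 paste0("s", tag, "=", suf[j]))
        if (is_trig[j]) out <- c(out, paste0("trg", tag))
        if (is_punct[j]) out <- c(out, paste0("pct", tag))
        if (is_digit[j]) out <- c(out, paste0("dig", tag))
      }
    }
    out
  }
  if (is.null(index)) lapply(seq_len(n), one) else one(index)
}

validate_bio <- function(labels_list) {
  bad <- integer(0)
  for (i in seq_along(labels_list)) {
    lab <- labels_list[[i]]
    if (any(!lab %in% .neg_labels)) {
      bad <- c(bad, i)
      next
    }
    prev <- "O"
    for (l in lab) {
      if (startsWith(l, "I-")) {
        type <- substring(l, 3)
        if (!(prev %in% paste0(c("B-", "I-"), type))) {
          bad <- c(bad, i)
          break
        }
      }
      prev <- l
    }
  }
  bad
}

# I-X without a compatible predecessor is read as B-X.
repair_bio <- function(lab) {
  prev <- "O"
  for (i in seq_along(lab)) {
    if (startsWith(lab[i], "I-")) {
      type <- substring(lab[i], 3)
      if (!(prev %in% paste0(c("B-", "I-"), type))) {
        lab[i] <- paste0("B-", type)
      }
    }
    prev <- lab[i]
  }
  lab
}

.simple_hash <- function(strings) {
  h <- 0
  for (s in strings) {
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  }
  sprintf("%d", h)
}

#' Train the CRF negation tagger
#'
#' Fits a linear-chain conditional random field (L2-regularized maximum
#' likelihood, L-BFGS) over the BIO label set on an annotated sentence
#' corpus. Training is deterministic given the corpus and hyperparameters;
#' the seed is recorded in the model metadata.
#'
#' @param corpus a `negation_corpus` (see [emit_negation_corpus()] or
#'   [read_conll()]).
#' @param lambda L2 regularization strength (default 0.05).
#' @param maxit maximum L-BFGS iterations (default 200).
#' @param seed recorded in metadata.
#' @return a `negation_tagger` model.
#' @export
train_tagger <- function(corpus, lambda = 0.05, maxit = 200L, seed = 1L) {
  stopifnot(inherits(corpus, "negation_corpus"), length(corpus) > 0)
  labels_list <- lapply(corpus, `[[`, "labels")
  bad <- validate_bio(labels_list)
  if (length(bad) > 0) {
    stop("invalid BIO label sequences in sentences: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  feats_str <- lapply(corpus, function(s) {
    featurize(s$tokens, NULL, s$language)
  })
  feature_names <- sort(unique(unlist(feats_str)))
  nfeat <- length(feature_names)
  nlab <- length(.neg_labels)
  feats_id <- lapply(feats_str, function(sf) {
    lapply(sf, function(fv) match(fv, feature_names))
  })
  y <- lapply(labels_list, function(l) match(l, .neg_labels))

  npar <- nfeat * nlab + nlab * nlab
  cache <- new.env(parent = emptyenv())
  objective <- function(w) {
    res <- crf_nll_grad_cpp(feats_id, y, w, nfeat, nlab, lambda)
    cache$w <- w
    cache$grad <- res$grad
    res$nll
  }
  gradient <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(cache$grad)
    crf_nll_grad_cpp(feats_id, y, w, nfeat, nlab, lambda)$grad
  }
  fit <- stats::optim(rep(0, npar), objective, gradient, method = "L-BFGS-B",
                      control = list(maxit = as.integer(maxit)))

  model <- structure(list(
    weights = fit$par,
    feature_names = feature_names,
    labels = .neg_labels,
    meta = list(feature_version = .feature_version, seed = as.integer(seed),
                lambda = lambda, maxit = as.integer(maxit),
                n_sentences = length(corpus),
                corpus_hash = .simple_hash(c(unlist(lapply(corpus, function(s)
                  s$tokens$surface)), unlist(labels_list))),
                convergence = fit$convergence, nll = fit$value)
  ), class = "negation_tagger")

  pred <- lapply(corpus, function(s) tag_sentence(s$tokens, model, s$language))
  model$train_accuracy <-
    mean(unlist(pred) == unlist(labels_list))
  model
}

#' @export
print.negation_tagger <- function(x, ...) {
  cat("<CRF negation tagger>", length(x$feature_names), "features,",
      length(x$labels), "labels\n")
  cat("trained on", x$meta$n_sentences, "sentences; train accuracy",
      format(round(x$train_accuracy, 4)), "\n")
  invisible(x)
}

# Viterbi labels for one tokenized sentence.
tag_sentence <- function(tokens, model, language = "es") {
  if (nrow(tokens) == 0) return(character(0))
  fv <- featurize(tokens, NULL, language)
  ids <- lapply(fv, function(f) {
    m <- match(f, model$feature_names)
    as.integer(m[!is.na(m)])
  })
  pred <- crf_viterbi_cpp(ids, model$weights, length(model$feature_names),
                          length(model$labels))
  repair_bio(model$labels[pred])
}

bio_spans <- function(tokens, labels) {
  runs <- function(type) {
    hits <- which(labels %in% paste0(c("B-", "I-"), type))
    if (length(hits) == 0) {
      return(tibble::tibble(start = integer(), end = integer()))
    }
    new_run <- labels[hits] == paste0("B-", type) |
      c(TRUE, diff(hits) != 1L)
    id <- cumsum(new_run)
    tibble::tibble(
      start = tokens$start[hits[!duplicated(id)]],
      end = tokens$end[hits[rev(!duplicated(rev(id)))]])
  }
  mark <- runs("MARK")
  scope <- runs("SCOPE")
  if (nrow(scope) == 0) {
    return(tibble::tibble(marker_start = integer(), marker_end = integer(),
                          scope_start = integer(), scope_end = integer()))
  }
  pair <- vapply(seq_len(nrow(scope)), function(i) {
    if (nrow(mark) == 0) return(NA_integer_)
    before <- which(mark$end <= scope$start[i])
    if (length(before) > 0) return(before[length(before)])
    1L
  }, integer(1))
  tibble::tibble(
    marker_start = ifelse(is.na(pair), NA_integer_, mark$start[pair]),
    marker_end = ifelse(is.na(pair), NA_integer_, mark$end[pair]),
    scope_start = scope$start, scope_end = scope$end)
}

#' Detect negation spans in one sentence with a trained CRF
#'
#' Decodes the Viterbi path, repairs malformed BIO transitions
#' (I-X without a compatible predecessor becomes B-X), and returns
#' marker/scope character spans in the coordinates of the supplied tokens.
#'
#' @param tokens sentence tokens from [tokenize()].
#' @param model a `negation_tagger`.
#' @param language `"es"` or `"ca"`.
#' @return tibble with `marker_start`, `marker_end`, `scope_start`,
#'   `scope_end` (0-based half-open).
#' @export
tag_negation <- function(tokens, model, language = "es") {
  stopifnot(inherits(model, "negation_tagger"))
  if (!identical(model$meta$feature_version, .feature_version)) {
    stop("model feature version does not match this featurizer",
         call. = FALSE)
  }
  if (nrow(tokens) == 0) {
    return(tibble::tibble(marker_start = integer(), marker_end = integer(),
                          scope_start = integer(), scope_end = integer()))
  }
  bio_spans(tokens, tag_sentence(tokens, model, language))
}

#' Rule-based (NegEx-style) negation detection
#'
#' Every trigger token opens a scope over the next `window` tokens,
#' truncated at the sentence end or before a terminator
#' (`pero`, `aunque`, `sino`, `,`).
#'
#' @param tokens sentence tokens from [tokenize()].
#' @param language `"es"` or `"ca"`; ignored when `triggers` is given.
#' @param triggers optional custom normalized trigger list.
#' @param window scope length in tokens (default 5).
#' @return tibble of marker/scope spans as in [tag_negation()].
#' @export
rule_based_negation <- function(tokens, language = "es", triggers = NULL,
                                window = 5L) {
  stopifnot(window >= 1L)
  if (is.null(triggers)) triggers <- negation_triggers(language)
  n <- nrow(tokens)
  out <- list()
  if (n > 0) {
    hits <- which(tokens$normalized %in% triggers)
    for (t in hits) {
      if (t == n) next
      span <- seq(t + 1L, min(t + window, n))
      term <- which(tokens$normalized[span] %in% .neg_terminators)
      if (length(term) > 0) span <- span[seq_len(term[1] - 1L)]
      span <- span[tokens$is_word[span]]  # drop trailing punctuation
      if (length(span) == 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        marker_start = tokens$start[t], marker_end = tokens$end[t],
        scope_start = tokens$start[span[1]],
        scope_end = tokens$end[span[length(span)]])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(marker_start = integer(), marker_end = integer(),
                          scope_start = integer(), scope_end = integer()))
  }
  do.call(rbind, out)
}

#' Detect negation spans across a whole note
#'
#' Splits the note into sentences at `.`, `;` and newline, tags each
#' sentence with the CRF or the rule baseline, and returns spans in note
#' coordinates.
#'
#' @param text note text.
#' @param language `"es"` or `"ca"` (an unknown tag falls back to `"es"`).
#' @param mode `"rule"` or `"crf"`.
#' @param model `negation_tagger`, required for `mode = "crf"`.
#' @param window rule-baseline scope window.
#' @return tibble of marker/scope spans.
#' @export
note_negation_spans <- function(text, language = "es", mode = c("rule", "crf"),
                                model = NULL, window = 5L) {
  mode <- match.arg(mode)
  if (!language %in% c("es", "ca")) language <- "es"
  if (mode == "crf" && is.null(model)) {
    stop("mode = 'crf' requires a trained model", call. = FALSE)
  }
  sr <- sentence_ranges(text)
  out <- vector("list", nrow(sr))
  for (i in seq_len(nrow(sr))) {
    sub <- stringi::stri_sub(text, sr$start[i] + 1L, sr$end[i])
    toks <- tokenize(sub)
    if (nrow(toks) == 0) next
    sp <- if (mode == "rule") {
      rule_based_negation(toks, language, window = window)
    } else {
      tag_negation(toks, model, language)
    }
    if (nrow(sp) > 0) {
      sp[c("marker_start", "marker_end", "scope_start", "scope_end")] <-
        lapply(sp[c("marker_start", "marker_end", "scope_start",
                    "scope_end")], function(x) x + sr$start[i])
      out[[i]] <- sp
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble::tibble(marker_start = integer(), marker_end = integer(),
                          scope_start = integer(), scope_end = integer()))
  }
  do.call(rbind, out)
}

#' Is a mention negated?
#'
#' A mention is negated iff its character span overlaps any detected scope
#' span by at least one character (half-open interval overlap).
#'
#' @param mentions tibble with `start`, `end` columns (one note).
#' @param spans negation spans for the same note.
#' @return logical vector, one element per mention.
#' @export
is_negated <- function(mentions, spans) {
  if (nrow(mentions) == 0) return(logical(0))
  if (nrow(spans) == 0) return(rep(FALSE, nrow(mentions)))
  vapply(seq_len(nrow(mentions)), function(i) {
    any(mentions$start[i] < spans$scope_end &
          mentions$end[i] > spans$scope_start)
  }, logical(1))
}

# ---- evaluation -------------------------------------------------------------

#' Token-level evaluation of label predictions
#'
#' @param gold,pred lists of per-sentence label vectors of equal shape.
#' @return list with `confusion` (5x5 gold x predicted), `per_label`
#'   precision/recall/F1, `class_metrics` with B-/I- merged per span type
#'   (MARK, SCOPE), and `token_accuracy`.
#' @export
evaluate_predictions <- function(gold, pred) {
  stopifnot(length(gold) == length(pred), length(gold) > 0)
  g <- unlist(gold)
  p <- unlist(pred)
  stopifnot(length(g) == length(p))
  conf <- table(factor(g, levels = .neg_labels),
                factor(p, levels = .neg_labels))
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
          else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  per_label <- do.call(rbind, lapply(.neg_labels, function(l) {
    tp <- sum(g == l & p == l)
    v <- prf(tp, sum(p == l) - tp, sum(g == l) - tp)
    tibble::tibble(label = l, precision = v[[1]], recall = v[[2]],
                   f1 = v[[3]])
  }))
  cls <- function(type) {
    in_cls <- function(x) x %in% paste0(c("B-", "I-"), type)
    tp <- sum(in_cls(g) & in_cls(p))
    v <- prf(tp, sum(in_cls(p)) - tp, sum(in_cls(g)) - tp)
    tibble::tibble(class = type, precision = v[[1]], recall = v[[2]],
                   f1 = v[[3]])
  }
  list(confusion = conf,
       per_label = per_label,
       class_metrics = rbind(cls("MARK"), cls("SCOPE")),
       token_accuracy = mean(g == p))
}

#' Evaluate a trained tagger on a held-out corpus
#' @param model a `negation_tagger`.
#' @param corpus a held-out `negation_corpus` (disjoint from training).
#' @return see [evaluate_predictions()].
#' @export
evaluate_tagger <- function(model, corpus) {
  stopifnot(inherits(corpus, "negation_corpus"))
  if (length(corpus) == 0) stop("held-out corpus is empty", call. = FALSE)
  pred <- lapply(corpus, function(s) tag_sentence(s$tokens, model,
                                                  s$language))
  evaluate_predictions(lapply(corpus, `[[`, "labels"), pred)
}

#' Evaluate the rule baseline on a corpus
#' @param corpus a `negation_corpus`.
#' @param window rule scope window.
#' @return see [evaluate_predictions()].
#' @export
evaluate_rule_baseline <- function(corpus, window = 5L) {
  stopifnot(inherits(corpus, "negation_corpus"), length(corpus) > 0)
  pred <- lapply(corpus, function(s) {
    sp <- rule_based_negation(s$tokens, s$language, window = window)
    spans_to_bio(s$tokens, sp)
  })
  evaluate_predictions(lapply(corpus, `[[`, "labels"), pred)
}

# Convert marker/scope spans back to token BIO labels.
spans_to_bio <- function(tokens, spans) {
  lab <- rep("O", nrow(tokens))
  if (nrow(spans) == 0) return(lab)
  mark_cover <- function(s, e) {
    which(tokens$start < e & tokens$end > s)
  }
  assign_run <- function(lab, idx, type) {
    if (length(idx) == 0) return(lab)
    lab[idx] <- paste0("I-", type)
    lab[idx[1]] <- paste0("B-", type)
    lab
  }
  for (i in seq_len(nrow(spans))) {
    if (!is.na(spans$marker_start[i])) {
      lab <- assign_run(lab, mark_cover(spans$marker_start[i],
                                        spans$marker_end[i]), "MARK")
    }
    lab <- assign_run(lab, mark_cover(spans$scope_start[i],
                                      spans$scope_end[i]), "SCOPE")
  }
  lab
}

# ---- model serialization ----------------------------------------------------

#' Save / load a negation tagger
#'
#' The model is serialized to a single file with a JSON sidecar
#' (`<path>.json`) recording the feature version, label set, seed, and
#' corpus hash. `load_tagger()` restores a model whose predictions are
#' identical token for token.
#'
#' @param model a `negation_tagger`.
#' @param path file path.
#' @return `path` invisibly; `load_tagger()` returns the model.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "negation_tagger"))
  saveRDS(model, path)
  jsonlite::write_json(model$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "negation_tagger"))
  model
}
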