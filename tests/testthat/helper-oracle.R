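# Independent pure-R oracles, kept deliberately separate from the package
# implementation (the package uses compiled code; these are plain DP/loops).

# Restricted Damerau-Levenshtein distance, full-matrix dynamic programme.
r_osa <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# Brute-force fuzzy matcher: every k-token window against every k-token
# surface with the pure-R distance, identical tie-breaking rules.
brute_force_match <- function(text, lexicon, max_edits = 1L,
                              min_fuzzy_nchar = 5L, language = "both") {
  toks <- tokenize(text)
  lex <- lexicon
  if (language %in% c("es", "ca")) {
    lex <- lex[lex$language %in% c(language, "both"), ]
  }
  if (nrow(toks) == 0 || nrow(lex) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      category = character(), concept_id = character(),
                      edit_distance = integer()))
  }
  lex_k <- lengths(strsplit(lex$norm_surface, " ", fixed = TRUE))
  cand <- list()
  for (w in seq_len(nrow(toks))) {
    for (li in seq_len(nrow(lex))) {
      k <- lex_k[li]
      if (w + k - 1L > nrow(toks)) next
      joined <- paste(toks$normalized[w:(w + k - 1L)], collapse = " ")
      allowed <- if (nchar(lex$norm_surface[li]) < min_fuzzy_nchar) 0L
                 else max_edits
      if (abs(nchar(joined) - nchar(lex$norm_surface[li])) > allowed) next
      d <- r_osa(joined, lex$norm_surface[li])
      if (d <= allowed) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = toks$start[w], end = toks$end[w + k - 1L],
          lex_row = li, edit_distance = d)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      category = character(), concept_id = character(),
                      edit_distance = integer()))
  }
  cand <- do.call(rbind, cand)
  span <- cand$end - cand$start
  cand <- cand[order(-span, cand$edit_distance, cand$start, cand$lex_row), ]
  keep <- logical(nrow(cand))
  ts <- integer(0)
  te <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < te & cand$end[i] > ts)) {
      keep[i] <- TRUE
      ts <- c(ts, cand$start[i])
      te <- c(te, cand$end[i])
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$start, cand$end), ]
  data.frame(start = cand$start, end = cand$end,
             category = lex$category[cand$lex_row],
             concept_id = lex$concept_id[cand$lex_row],
             edit_distance = cand$edit_distance)
}
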